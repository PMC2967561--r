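#' @rdname PdzInteractionSet-class
#' @aliases interactions,PdzInteractionSet-method
#' @export
setMethod("interactions", "PdzInteractionSet", function(x) x@interactions)

#' @rdname PdzInteractionSet-class
#' @export
setMethod("domainTable", "PdzInteractionSet", function(x) x@domains)

#' @rdname PdzInteractionSet-class
#' @export
setMethod("nPositive", "PdzInteractionSet",
          function(x) sum(x@interactions$label == 1L))

#' @rdname PdzInteractionSet-class
#' @export
setMethod("nNegative", "PdzInteractionSet",
          function(x) sum(x@interactions$label == -1L))

#' @rdname ContactMap-class
#' @export
setMethod("contactPairs", "ContactMap", function(x) x@pairs)

#' @rdname PWM-class
#' @export
setMethod("pwmMatrix", "PWM", function(x) x@probs)

setMethod("show", "ContactMap", function(object) {
  p <- object@pairs
  cat("ContactMap with", nrow(p), "pairs covering",
      length(unique(p$domain_pos)), "domain positions and",
      length(unique(p$peptide_pos)), "peptide positions\n")
})

setMethod("show", "PWM", function(object) {
  cat("PWM (20 residues x 5 positions) built from", object@nSequences,
      "peptides, pseudocount", object@pseudocount, "\n")
  cat("consensus:", consensusPeptide(object), "\n")
})

setMethod("show", "PdzInteractionSet", function(object) {
  it <- object@interactions
  cat("PdzInteractionSet:", nrow(it), "interactions (",
      sum(it$label == 1L), "positive /", sum(it$label == -1L), "negative ) over",
      nrow(object@domains), "domains\n")
})

setMethod("show", "PdzSVM", function(object) {
  cat("PdzSVM (RBF kernel): gamma =", object@gamma,
      ", C+ =", signif(object@costPos, 5),
      ", C- =", signif(object@costNeg, 5), "\n")
  cat(" ", nrow(object@supportVectors), "support vectors;",
      "trained on", object@nPos, "positive /", object@nNeg,
      "negative examples;", object@encoding, "encoding\n")
})

setMethod("show", "ScanResult", function(object) {
  p <- object@predictions
  cat("ScanResult for", object@domainId, ":", nrow(p), "tails scanned,",
      sum(p$label == 1L), "predicted binders,",
      object@nSkipped, "tails skipped\n")
})

#' Predictions table of a ScanResult
#'
#' @param x a \code{\linkS4class{ScanResult}}.
#' @return data.frame of per-tail predictions.
#' @export
scanPredictions <- function(x) {
  stopifnot(is(x, "ScanResult"))
  x@predictions
}
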