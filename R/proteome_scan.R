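# Proteome scanning: classify every unique C-terminal tail of a proteome
# against a trained model, and validate predictions against known
# interaction lists.

#' Scan a proteome's C-terminal tails for predicted binders
#'
#' Encodes every unique tail against the domain's binding site and classifies
#' it with the trained SVM. Tails containing non-standard residues (X, U, B,
#' ...) cannot be encoded and are skipped with a warning. The scan is
#' deterministic given the model.
#'
#' @param model a trained \code{\linkS4class{PdzSVM}}.
#' @param bindingSite the domain's 16-residue binding site (or a domain id
#'   resolvable in `domains`).
#' @param tails tail map from [extractCTerminalTails()] (named list
#'   tail -> protein ids) or a character vector of tails.
#' @param cmap contact map used by the model's encoding.
#' @param domainId id recorded in the result (defaults to the binding site).
#' @param physchem descriptor table for the physicochemical encoding.
#' @param scaler optional \code{\linkS4class{FeatureScaler}} to apply
#'   (fitted on the training encoding).
#' @return a \code{\linkS4class{ScanResult}}.
#' @export
scanProteome <- function(model, bindingSite, tails,
                         cmap = defaultContactMap(), domainId = NULL,
                         physchem = physChemTable(), scaler = NULL) {
  stopifnot(is(model, "PdzSVM"))
  hasIds <- is.list(tails)
  keys <- if (hasIds) names(tails) else unique(as.character(tails))
  if (!length(keys)) stop("no tails to scan")
  if (!.isValidSite(bindingSite))
    stop("invalid binding site '", bindingSite, "'")
  ok <- vapply(keys, .isValidPeptide, logical(1))
  if (any(!ok))
    warning(sum(!ok), " tail(s) with non-standard residues skipped")
  keys <- keys[ok]
  ids <- if (hasIds) vapply(tails[keys], paste, character(1), collapse = ",")
    else rep("", length(keys))

  fake <- methods::new("PdzInteractionSet",
    interactions = data.frame(domain_id = "q", peptide = keys,
                              label = 1L, source = "scan",
                              stringsAsFactors = FALSE),
    domains = data.frame(id = "q", organism = "query",
                         binding_site = bindingSite, source = "scan",
                         stringsAsFactors = FALSE))
  X <- encodeInteractions(fake, method = model@encoding, cmap = cmap,
                          physchem = physchem)
  if (!is.null(scaler)) X <- applyScaler(scaler, as.matrix(X))
  dec <- .decideMatrix(model, X)
  methods::new("ScanResult",
               domainId = domainId %||% bindingSite,
               predictions = data.frame(tail = keys, score = dec$score,
                                        label = dec$label,
                                        protein_ids = unname(ids),
                                        stringsAsFactors = FALSE),
               nSkipped = as.integer(sum(!ok)))
}

#' Validate a scan against known interactions
#'
#' Measures recall over known positive tails, the false positive rate when
#' known negatives are supplied (reported as `NA`, not 0, otherwise), and
#' the one-sided Fisher overlap p-value of predicted versus known binders in
#' the scanned universe. Known tails absent from the scan are logged and
#' ignored.
#'
#' @param result a \code{\linkS4class{ScanResult}}.
#' @param knownPositives character vector of known binder tails (required).
#' @param knownNegatives optional character vector of known non-binder tails.
#' @return list with `recall`, `fpr` (NA without negatives), `fisherP`, and
#'   the underlying counts.
#' @export
validateScan <- function(result, knownPositives, knownNegatives = NULL) {
  stopifnot(is(result, "ScanResult"))
  if (!length(knownPositives)) stop("knownPositives must be non-empty")
  p <- result@predictions
  kp <- unique(knownPositives)
  missing <- setdiff(kp, p$tail)
  if (length(missing))
    message(length(missing), " known positive(s) not in the scanned universe, ignored")
  kp <- intersect(kp, p$tail)
  if (!length(kp)) stop("no known positives inside the scanned universe")
  predPos <- p$tail[p$label == 1L]
  hits <- intersect(kp, predPos)
  recall <- length(hits) / length(kp)
  fpr <- NA_real_
  if (!is.null(knownNegatives) && length(knownNegatives)) {
    kn <- intersect(unique(knownNegatives), p$tail)
    if (length(kn)) fpr <- length(intersect(kn, predPos)) / length(kn)
  }
  fisherP <- fisherOverlapTest(length(hits), length(predPos), length(kp),
                               nrow(p))
  list(recall = recall, fpr = fpr, fisherP = fisherP,
       nHits = length(hits), nPredicted = length(predPos),
       nKnown = length(kp), nUniverse = nrow(p))
}
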