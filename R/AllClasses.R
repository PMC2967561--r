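#' ContactMap: domain-peptide contacting position pairs
#'
#' A fixed set of (domain position, peptide position) pairs defining which
#' residue pairs of a domain binding site and a bound C-terminal peptide are
#' encoded as features. Domain positions index the 16 aligned binding-site
#' columns (1..16); peptide positions are numbered backwards from the
#' C-terminus, 0 (p0) to -4 (p-4).
#'
#' @slot pairs data.frame with integer columns `domain_pos` (1..16) and
#'   `peptide_pos` (-4..0); rows are unique.
#' @export
setClass("ContactMap", representation(pairs = "data.frame"))

setValidity("ContactMap", function(object) {
  p <- object@pairs
  if (!all(c("domain_pos", "peptide_pos") %in% names(p)))
    return("pairs must have columns domain_pos, peptide_pos")
  if (nrow(p) == 0L) return("contact map has no pairs")
  if (!all(p$domain_pos %in% seq_len(.SITE_LEN)))
    return("domain_pos out of range 1..16")
  if (!all(p$peptide_pos %in% .PEP_POS))
    return("peptide_pos out of range -4..0")
  if (anyDuplicated(p[, c("domain_pos", "peptide_pos")]))
    return("duplicate contact pairs")
  TRUE
})

#' PWM: position weight matrix over peptide positions p-4..p0
#'
#' Column-stochastic 20 x 5 matrix of amino-acid probabilities summarizing a
#' binding specificity: cell (a, j) is the probability of observing residue a
#' at ligand position j. Built from observed binder peptides with an optional
#' pseudocount.
#'
#' @slot probs numeric 20 x 5 matrix; rows are amino acids in the order of
#'   [aminoAcids()], columns are positions p-4..p0; each column sums to 1.
#' @slot pseudocount numeric, the pseudocount used when building.
#' @slot nSequences integer, number of peptides the PWM was built from.
#' @export
setClass("PWM", representation(probs = "matrix",
                               pseudocount = "numeric",
                               nSequences = "integer"))

setValidity("PWM", function(object) {
  m <- object@probs
  if (!all(dim(m) == c(20L, 5L))) return("probs must be 20 x 5")
  if (!identical(rownames(m), .AA)) return("rownames must be the amino-acid alphabet")
  if (any(m < 0)) return("negative probabilities")
  if (any(abs(colSums(m) - 1) > 1e-9)) return("columns must sum to 1")
  if (object@pseudocount > 0 && any(m == 0))
    return("zero cell despite positive pseudocount")
  TRUE
})

#' PdzInteractionSet: labelled domain-peptide interactions
#'
#' Container pairing an interaction table with the definitions of the domains
#' it references. Each interaction is a (domain, 5-mer peptide) pair with a
#' binary label: +1 for binders, -1 for non-binders.
#'
#' @slot interactions data.frame with columns `domain_id` (character),
#'   `peptide` (character, 5 residues, no gaps), `label` (integer, +1 or -1)
#'   and `source` (character).
#' @slot domains data.frame with columns `id`, `organism`, `binding_site`
#'   (character, exactly 16 characters over the amino-acid alphabet plus the
#'   gap '-') and `source`; one row per distinct domain id.
#' @export
setClass("PdzInteractionSet", representation(interactions = "data.frame",
                                             domains = "data.frame"))

setValidity("PdzInteractionSet", function(object) {
  it <- object@interactions
  dm <- object@domains
  need <- c("domain_id", "peptide", "label", "source")
  if (!all(need %in% names(it)))
    return(paste("interactions must have columns:", paste(need, collapse = ", ")))
  needd <- c("id", "organism", "binding_site", "source")
  if (!all(needd %in% names(dm)))
    return(paste("domains must have columns:", paste(needd, collapse = ", ")))
  if (anyDuplicated(dm$id)) return("duplicate domain ids")
  if (nrow(it)) {
    if (!all(it$label %in% c(-1L, 1L))) return("labels must be +1 or -1")
    bad <- which(!vapply(it$peptide, .isValidPeptide, logical(1)))
    if (length(bad))
      return(paste0("invalid peptide at row ", bad[1], ": '", it$peptide[bad[1]], "'"))
    miss <- setdiff(unique(it$domain_id), dm$id)
    if (length(miss))
      return(paste("interaction references unknown domain:", miss[1]))
  }
  if (nrow(dm)) {
    badd <- which(!vapply(dm$binding_site, .isValidSite, logical(1)))
    if (length(badd))
      return(paste0("invalid binding site for domain '", dm$id[badd[1]], "'"))
  }
  TRUE
})

#' PdzSVM: weighted-cost RBF support vector machine model
#'
#' A trained binary classifier of domain-peptide feature vectors. The decision
#' score of a query x is \eqn{f(x) = \sum_i c_i K(s_i, x) + b} with
#' \eqn{K(u,v) = \exp(-\gamma ||u - v||^2)}, support vectors \eqn{s_i}, dual
#' coefficients \eqn{c_i = \alpha_i y_i} and bias b; the predicted label is +1
#' when the score is >= 0 (sgn(0) = +1) and -1 otherwise. Class imbalance is
#' handled with weighted costs \eqn{C^+ = (n^+/n^-) C^-}.
#'
#' @slot gamma numeric RBF width, > 0.
#' @slot costPos,costNeg numeric box constraints for positive/negative class.
#' @slot bias numeric additive bias b.
#' @slot dualCoefs numeric vector, one per support vector (alpha_i * y_i).
#' @slot supportVectors matrix or sparse Matrix of support vectors (rows).
#' @slot nPos,nNeg integer training class counts.
#' @slot encoding character, the feature encoding the model expects.
#' @export
setClass("PdzSVM", representation(gamma = "numeric",
                                  costPos = "numeric",
                                  costNeg = "numeric",
                                  bias = "numeric",
                                  dualCoefs = "numeric",
                                  supportVectors = "ANY",
                                  nPos = "integer",
                                  nNeg = "integer",
                                  encoding = "character"))

setValidity("PdzSVM", function(object) {
  if (object@gamma <= 0) return("gamma must be > 0")
  if (object@costPos <= 0 || object@costNeg <= 0) return("costs must be > 0")
  if (length(object@dualCoefs) != nrow(object@supportVectors))
    return("one dual coefficient per support vector required")
  TRUE
})

#' FeatureScaler: per-dimension min-max scaler fitted on training vectors
#'
#' @slot mins,ranges numeric vectors of per-dimension training minima and
#'   ranges (max - min); constant dimensions have range 0 and scale to 0.
#' @export
setClass("FeatureScaler", representation(mins = "numeric", ranges = "numeric"))

setValidity("FeatureScaler", function(object) {
  if (length(object@mins) != length(object@ranges))
    return("mins and ranges must have equal length")
  if (any(object@ranges < 0)) return("negative range")
  TRUE
})

#' ScanResult: predictions from scanning a proteome for one domain
#'
#' @slot domainId character, the scanned domain.
#' @slot predictions data.frame with one row per unique scanned tail:
#'   columns `tail`, `score`, `label` (+1/-1) and `protein_ids`
#'   (comma-separated ids of proteins sharing that C-terminal tail).
#' @slot nSkipped integer, tails skipped because of non-standard residues.
#' @export
setClass("ScanResult", representation(domainId = "character",
                                      predictions = "data.frame",
                                      nSkipped = "integer"))

setValidity("ScanResult", function(object) {
  p <- object@predictions
  need <- c("tail", "score", "label", "protein_ids")
  if (!all(need %in% names(p)))
    return(paste("predictions must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p$tail)) return("each tail must appear once")
  TRUE
})
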