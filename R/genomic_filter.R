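# Genomic-likeness classification of peptides and domains, and enrichment
# filtering of positive-only (phage display style) data.

#' Is a peptide genomic-like?
#'
#' A peptide is genomic-like when its last four residues (positions p-3..p0)
#' match the last four residues of at least one C-terminal tail of a real
#' proteome. Phage-display selections can yield optimal binders that do not
#' exist in any proteome; this test separates those from peptides a genomic
#' predictor should learn from.
#'
#' @param peptide a 5-residue peptide string (or vector of them).
#' @param tails a tail map from [extractCTerminalTails()] built with k >= 4,
#'   or a character vector of tails.
#' @return logical, one value per peptide.
#' @export
isGenomicLike <- function(peptide, tails) {
  keys <- if (is.list(tails)) names(tails) else as.character(tails)
  if (any(nchar(keys) < 4L)) stop("tails must have length >= 4")
  suffix4 <- function(x) substr(x, nchar(x) - 3L, nchar(x))
  tail4 <- unique(suffix4(keys))
  suffix4(peptide) %in% tail4
}

#' Categorize a domain by its genomic-like peptide counts
#'
#' Assigns one of four categories from the numbers of unique genomic-like and
#' non-genomic-like interacting peptides: at least 10 genomic-like and fewer
#' than 10 non-genomic-like is `genomic_like`; the reverse is
#' `non_genomic_like`; at least 10 of both is `dual`; fewer than 10 of both
#' is `non_specific`.
#'
#' @param nGenomic,nNonGenomic counts of unique genomic-like and
#'   non-genomic-like peptides (vectors allowed).
#' @param threshold the category cut, 10 unique peptides.
#' @return character vector of categories.
#' @export
categorizeDomain <- function(nGenomic, nNonGenomic, threshold = 10L) {
  stopifnot(all(nGenomic >= 0), all(nNonGenomic >= 0))
  g <- nGenomic >= threshold
  ng <- nNonGenomic >= threshold
  out <- rep("non_specific", length(g))
  out[g & !ng] <- "genomic_like"
  out[!g & ng] <- "non_genomic_like"
  out[g & ng] <- "dual"
  out
}

#' Enrich positive-only interaction data in genomic-like interactions
#'
#' Applies the enrichment filter for phage-display style data, which contains
#' positives only: (1) domains are categorized on the unfiltered data with
#' [categorizeDomain()]; (2) all interactions of non-genomic-like domains are
#' dropped; (3) non-genomic-like interactions are removed from dual domains,
#' and a dual domain left with fewer than `minPeptides` unique genomic-like
#' peptides is dropped entirely; (4) genomic-like and non-specific domains
#' are kept unfiltered provided they have at least `minPeptides` unique
#' peptides in total.
#'
#' @param data a \code{\linkS4class{PdzInteractionSet}} containing only
#'   positive interactions.
#' @param tails tail map (or tail vector) of the reference proteome.
#' @param minPeptides minimum unique peptide count for a domain to survive;
#'   default 10.
#' @return the filtered \code{\linkS4class{PdzInteractionSet}}; the returned
#'   object also carries per-domain categories in
#'   `attr(, "domainCategories")`.
#' @export
enrichGenomicLike <- function(data, tails, minPeptides = 10L) {
  stopifnot(is(data, "PdzInteractionSet"))
  it <- data@interactions
  if (any(it$label == -1L))
    stop("enrichGenomicLike is defined for positive-only data")
  gl <- isGenomicLike(it$peptide, tails)
  perDomain <- split(data.frame(peptide = it$peptide, gl = gl,
                                stringsAsFactors = FALSE), it$domain_id)
  nG <- vapply(perDomain, function(d) length(unique(d$peptide[d$gl])), integer(1))
  nN <- vapply(perDomain, function(d) length(unique(d$peptide[!d$gl])), integer(1))
  cat0 <- categorizeDomain(nG, nN, threshold = minPeptides)
  names(cat0) <- names(perDomain)

  keepRow <- rep(TRUE, nrow(it))
  for (d in names(cat0)) {
    rows <- it$domain_id == d
    if (cat0[[d]] == "non_genomic_like") {
      keepRow[rows] <- FALSE
    } else if (cat0[[d]] == "dual") {
      keepRow[rows & !gl] <- FALSE
      if (length(unique(it$peptide[rows & gl])) < minPeptides)
        keepRow[rows] <- FALSE
    } else {
      # genomic_like / non_specific: unfiltered, but require enough data
      if (length(unique(it$peptide[rows])) < minPeptides)
        keepRow[rows] <- FALSE
    }
  }
  out <- it[keepRow, , drop = FALSE]
  rownames(out) <- NULL
  dom <- data@domains[data@domains$id %in% unique(out$domain_id), , drop = FALSE]
  rownames(dom) <- NULL
  res <- methods::new("PdzInteractionSet", interactions = out, domains = dom)
  attr(res, "domainCategories") <- cat0
  res
}
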