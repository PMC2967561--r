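# Seeded synthetic data: domains with planted per-position binding
# specificities, positive/negative interaction sets, and decoy proteome
# tails. Emulates the statistical shape of protein-microarray and
# phage-display training data so every module is testable without external
# downloads.

# Planted specificity model: per peptide position an independent categorical
# distribution putting weight w = sharpness/(sharpness+1) on a favoured
# residue and spreading 1-w uniformly over all 20 residues. sharpness -> Inf
# concentrates all mass on the favoured residue (positives collapse onto the
# consensus); sharpness 0 is uniform.
.specColumn <- function(favoured, sharpness) {
  w <- if (is.infinite(sharpness)) 1 else sharpness / (sharpness + 1)
  p <- rep((1 - w) / 20, 20)
  p[.aaIndex(favoured)] <- p[.aaIndex(favoured)] + w
  p
}

.specMatrix <- function(favoured, sharpness) {
  m <- vapply(favoured, .specColumn, numeric(20), sharpness = sharpness)
  dimnames(m) <- list(.AA, .PEP_LAB)
  m
}

.samplePeptides <- function(spec, n) {
  chars <- vapply(seq_len(.PEP_LEN), function(j)
    sample(.AA, n, replace = TRUE, prob = spec[, j]), character(n))
  if (n == 1L) paste(chars, collapse = "") else
    apply(matrix(chars, nrow = n), 1L, paste, collapse = "")
}

#' Generate a synthetic domain-peptide interaction dataset
#'
#' Builds `nDomains` synthetic PDZ-like domains organized into families:
#' each family founder receives a random 16-residue binding site and a
#' planted 5-position binding specificity (a favoured residue per position
#' with concentration `sharpness`); family members mutate the founder's site
#' at a variable number of positions and, with probability proportional to
#' the site divergence, re-draw favoured residues -- so similar binding
#' sites imply similar specificities, making similarity-stratified analyses
#' meaningful. Positive peptides are sampled from each domain's specificity;
#' negatives are drawn from the decoy tails; labels are flipped with
#' probability `labelNoise`. The decoy tail map doubles as the synthetic
#' proteome: it contains `nDecoyTails` uniform random tails plus every
#' positive peptide (so positives are genomic-like by construction).
#'
#' @param nDomains number of domains.
#' @param peptidesPerDomain positive peptides sampled per domain.
#' @param sharpness specificity concentration (>= 0, may be `Inf`);
#'   default 4, putting 81 percent of the mass on the favoured residue.
#' @param negativesPerPositive negatives drawn per positive; default 2.
#' @param labelNoise per-interaction label-flip probability in \[0, 0.5).
#' @param nDecoyTails number of decoy proteome tails.
#' @param nFamilies number of domain families; default `ceiling(nDomains/5)`.
#' @param seed RNG seed fixing the entire dataset.
#' @return list with `interactions` (a
#'   \code{\linkS4class{PdzInteractionSet}}), `tails` (named list
#'   tail -> protein ids), and `specificities` (list of true 20 x 5
#'   probability matrices per domain id).
#' @export
syntheticDataset <- function(nDomains = 20L, peptidesPerDomain = 20L,
                             sharpness = 4, negativesPerPositive = 2,
                             labelNoise = 0, nDecoyTails = 1000L,
                             nFamilies = NULL, seed = 1L) {
  stopifnot(nDomains >= 1L, peptidesPerDomain >= 1L, sharpness >= 0,
            labelNoise >= 0, labelNoise < 0.5, nDecoyTails >= 1L)
  nFamilies <- as.integer(nFamilies %||% ceiling(nDomains / 5))
  stopifnot(nFamilies >= 1L, nFamilies <= nDomains)
  .withSeed(seed, {
    fam <- sort(rep_len(seq_len(nFamilies), nDomains))
    ids <- sprintf("SYND%03d", seq_len(nDomains))
    sites <- character(nDomains)
    favs <- vector("list", nDomains)
    for (f in seq_len(nFamilies)) {
      members <- which(fam == f)
      founderSite <- paste(sample(.AA, .SITE_LEN, replace = TRUE),
                           collapse = "")
      founderFav <- sample(.AA, .PEP_LEN, replace = TRUE)
      for (k in seq_along(members)) {
        i <- members[k]
        if (k == 1L) {
          sites[i] <- founderSite
          favs[[i]] <- founderFav
        } else {
          nMut <- sample(0:8, 1L)
          s <- .splitChars(founderSite)
          if (nMut > 0) {
            at <- sample(.SITE_LEN, nMut)
            s[at] <- sample(.AA, nMut, replace = TRUE)
          }
          sites[i] <- paste(s, collapse = "")
          fv <- founderFav
          flip <- stats::runif(.PEP_LEN) < nMut / .SITE_LEN
          if (any(flip)) fv[flip] <- sample(.AA, sum(flip), replace = TRUE)
          favs[[i]] <- fv
        }
      }
    }
    specs <- lapply(favs, .specMatrix, sharpness = sharpness)
    names(specs) <- ids

    decoys <- unique(vapply(seq_len(nDecoyTails), function(i)
      paste(sample(.AA, .PEP_LEN, replace = TRUE), collapse = ""),
      character(1)))

    rows <- vector("list", nDomains)
    for (i in seq_len(nDomains)) {
      pos <- .samplePeptides(specs[[i]], peptidesPerDomain)
      nNeg <- ceiling(negativesPerPositive * peptidesPerDomain)
      neg <- sample(decoys, min(nNeg, length(decoys)))
      lab <- c(rep(1L, length(pos)), rep(-1L, length(neg)))
      if (labelNoise > 0) {
        flip <- stats::runif(length(lab)) < labelNoise
        lab[flip] <- -lab[flip]
      }
      rows[[i]] <- data.frame(domain_id = ids[i],
                              peptide = c(pos, neg), label = lab,
                              source = "synthetic",
                              stringsAsFactors = FALSE)
    }
    # duplicate positive draws are kept: the multiplicity of a peptide is
    # part of the sampled specificity signal
    it <- do.call(rbind, rows)
    rownames(it) <- NULL
    dom <- data.frame(id = ids, organism = "synthetic",
                      binding_site = sites, source = "synthetic",
                      stringsAsFactors = FALSE)
    iset <- methods::new("PdzInteractionSet", interactions = it,
                         domains = dom)

    allTails <- unique(c(decoys, it$peptide[it$label == 1L]))
    tailIds <- lapply(seq_along(allTails), function(i)
      sprintf("SYNP%05d", i))
    tails <- stats::setNames(tailIds, allTails)

    list(interactions = iset, tails = tails, specificities = specs,
         config = list(nDomains = nDomains,
                       peptidesPerDomain = peptidesPerDomain,
                       sharpness = sharpness,
                       negativesPerPositive = negativesPerPositive,
                       labelNoise = labelNoise, nDecoyTails = nDecoyTails,
                       nFamilies = nFamilies, seed = seed))
  })
}

#' Positive-only view of a dataset
#'
#' Drops all negative interactions, emulating phage-display data (positives
#' only) for the artificial-negatives workflow. Idempotent.
#'
#' @param data a \code{\linkS4class{PdzInteractionSet}} or the list returned
#'   by [syntheticDataset()].
#' @return a positive-only \code{\linkS4class{PdzInteractionSet}}.
#' @export
positiveOnlyView <- function(data) {
  if (is.list(data) && !is(data, "PdzInteractionSet"))
    data <- data$interactions
  stopifnot(is(data, "PdzInteractionSet"))
  it <- data@interactions[data@interactions$label == 1L, , drop = FALSE]
  rownames(it) <- NULL
  dom <- data@domains[data@domains$id %in% unique(it$domain_id), ,
                      drop = FALSE]
  rownames(dom) <- NULL
  methods::new("PdzInteractionSet", interactions = it, domains = dom)
}

#' Write a synthetic dataset to standard files
#'
#' Writes the interaction TSV and a FASTA proteome whose sequences end with
#' the dataset's tails, the formats consumed by the rest of the package.
#'
#' @param dataset list from [syntheticDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ipath <- file.path(dir, "interactions.tsv")
  writeInteractions(dataset$interactions, ipath)
  fpath <- file.path(dir, "proteome.fasta")
  tails <- dataset$tails
  ids <- vapply(tails, `[`, character(1), 1L)
  # pad each tail with a fixed N-terminal stub so records look like proteins
  seqs <- paste0("MSSG", names(tails))
  writeLines(paste0(">", ids, "\n", seqs), fpath)
  invisible(c(interactions = ipath, proteome = fpath))
}
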