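# Position weight matrices: construction, scoring, similarity, sequence-logo
# export and the nearest-neighbour PWM ensemble baseline.

#' Build a position weight matrix from binder peptides
#'
#' Each cell holds the probability of observing an amino acid at a ligand
#' position: `cell(a, j) = (count(a at j) + pseudocount) / (n + 20 *
#' pseudocount)`. A small positive pseudocount keeps unseen residues
#' scoreable.
#'
#' @param peptides character vector of 5-residue peptides.
#' @param pseudocount nonnegative pseudocount; default 0.01.
#' @return a \code{\linkS4class{PWM}}.
#' @examples
#' pwm <- buildPWM(c("AETWV", "SETWV", "TDTWV"))
#' consensusPeptide(pwm)
#' @export
buildPWM <- function(peptides, pseudocount = 0.01) {
  if (length(peptides) == 0L) stop("cannot build a PWM from zero peptides")
  stopifnot(pseudocount >= 0)
  ok <- vapply(peptides, .isValidPeptide, logical(1))
  if (!all(ok)) stop("invalid peptide: '", peptides[!ok][1], "'")
  n <- length(peptides)
  chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE)),
                  nrow = .PEP_LEN)
  counts <- vapply(seq_len(.PEP_LEN), function(j) {
    tabulate(.aaIndex(chars[j, ]), nbins = 20L)
  }, numeric(20L))
  probs <- (counts + pseudocount) / (n + 20 * pseudocount)
  dimnames(probs) <- list(.AA, .PEP_LAB)
  methods::new("PWM", probs = probs, pseudocount = pseudocount,
               nSequences = as.integer(n))
}

#' Score peptides against a PWM
#'
#' The score of a peptide is the sum over its five positions of the log2
#' probability of its residue: higher scores indicate better-matching
#' binders. With a zero pseudocount an unobserved residue has probability 0
#' and the score is `-Inf` (or an error when `strict = TRUE`).
#'
#' @param pwm a \code{\linkS4class{PWM}}.
#' @param peptides character vector of 5-residue peptides.
#' @param strict error (instead of `-Inf`) on zero-probability cells.
#' @return numeric vector of log2-probability scores.
#' @export
scorePeptides <- function(pwm, peptides, strict = FALSE) {
  stopifnot(is(pwm, "PWM"))
  ok <- vapply(peptides, .isValidPeptide, logical(1))
  if (!all(ok)) stop("invalid peptide: '", peptides[!ok][1], "'")
  m <- pwm@probs
  chars <- matrix(unlist(strsplit(peptides, "", fixed = TRUE)),
                  nrow = .PEP_LEN)
  scores <- vapply(seq_along(peptides), function(i) {
    p <- m[cbind(.aaIndex(chars[, i]), seq_len(.PEP_LEN))]
    if (strict && any(p == 0))
      stop("zero-probability residue in '", peptides[i],
           "' with pseudocount 0 (strict mode)")
    sum(log2(p))
  }, numeric(1))
  unname(scores)
}

#' @rdname scorePeptides
#' @param peptide a single peptide.
#' @export
scorePeptide <- function(pwm, peptide, strict = FALSE)
  scorePeptides(pwm, peptide, strict = strict)[1]

#' Consensus peptide of a PWM
#'
#' @param pwm a \code{\linkS4class{PWM}}.
#' @return the 5-residue peptide taking the most probable residue at each
#'   position (ties broken alphabetically).
#' @export
consensusPeptide <- function(pwm) {
  stopifnot(is(pwm, "PWM"))
  paste(.AA[apply(pwm@probs, 2L, which.max)], collapse = "")
}

#' Similarity between two PWMs
#'
#' Column-wise Pearson correlation between the 20-entry probability vectors,
#' mapped from \[-1, 1\] to \[0, 100\] via `(r + 1) / 2` and averaged over the
#' five positions. 100 means identical matrices; a zero-variance column
#' (all cells equal) contributes 50, treating its correlation as 0.
#'
#' @param a,b \code{\linkS4class{PWM}} objects of equal dimensions.
#' @return similarity percentage in \[0, 100\]; symmetric in its arguments.
#' @export
pwmSimilarity <- function(a, b) {
  stopifnot(is(a, "PWM"), is(b, "PWM"))
  ma <- a@probs; mb <- b@probs
  cols <- vapply(seq_len(ncol(ma)), function(j) {
    va <- ma[, j]; vb <- mb[, j]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
      message("zero-variance PWM column ", j, ": contributes 50")
      return(0)
    }
    stats::cor(va, vb)
  }, numeric(1))
  100 * mean((cols + 1) / 2)
}

#' Sequence-logo height matrix of a PWM
#'
#' Computes per-position information content in bits, `IC_j = log2(20) +
#' sum_a p(a,j) log2 p(a,j)` (0 for a uniform column, log2(20) for a
#' single-residue column), and the per-residue letter heights
#' `p(a,j) * IC_j` used to draw a sequence logo.
#'
#' @param pwm a \code{\linkS4class{PWM}}.
#' @return 20 x 5 numeric matrix of letter heights (bits); column sums equal
#'   the per-position information content.
#' @export
logoMatrix <- function(pwm) {
  stopifnot(is(pwm, "PWM"))
  m <- pwm@probs
  plogp <- ifelse(m > 0, m * log2(m), 0)
  ic <- log2(20) + colSums(plogp)
  sweep(m, 2L, ic, `*`)
}

#' Export a sequence-logo height matrix as TSV
#'
#' Writes the [logoMatrix()] of a PWM as a tab-delimited table (rows =
#' residues, columns = positions p-4..p0) renderable as a sequence logo by
#' any plotting tool.
#'
#' @param pwm a \code{\linkS4class{PWM}}.
#' @param path output path.
#' @return invisibly, the path written.
#' @export
exportLogoMatrix <- function(pwm, path) {
  h <- logoMatrix(pwm)
  utils::write.table(data.frame(aa = rownames(h), h, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / read a PWM as TSV
#'
#' @param pwm a \code{\linkS4class{PWM}}.
#' @param path file path.
#' @return `writePWM` invisibly returns the path; `readPWM` returns the PWM
#'   (pseudocount and sequence count are carried in a header comment).
#' @export
writePWM <- function(pwm, path) {
  stopifnot(is(pwm, "PWM"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pwm pseudocount=%g n=%d", pwm@pseudocount,
                     pwm@nSequences), con)
  utils::write.table(data.frame(aa = rownames(pwm@probs), pwm@probs,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePWM
#' @export
readPWM <- function(path) {
  hdr <- readLines(path, n = 1L)
  pc <- as.numeric(sub(".*pseudocount=([0-9.eE+-]+).*", "\\1", hdr))
  n <- as.integer(sub(".*n=([0-9]+).*", "\\1", hdr))
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$aa
  colnames(m) <- .PEP_LAB
  methods::new("PWM", probs = m[.AA, , drop = FALSE], pseudocount = pc,
               nSequences = n)
}

#' Nearest-neighbour PWM ensemble baseline predictor
#'
#' The baseline proteome-scanning predictor: for a test domain, pick the
#' training domain with the most similar binding site (ties broken toward
#' the domain with more positive peptides, then lexicographic id), build a
#' PWM from its positive peptides, score every proteome tail and return the
#' top fraction by score.
#'
#' @param testDomain id of a domain in `training`, or a 16-residue
#'   binding-site string.
#' @param training a \code{\linkS4class{PdzInteractionSet}} with positive
#'   interactions.
#' @param tails tail map (or character vector of tails) to scan.
#' @param topFraction fraction of tails to return; default 0.01 (the top 1%).
#' @param pseudocount pseudocount for the neighbour's PWM.
#' @return data.frame of the top `ceiling(topFraction * N)` tails with
#'   columns `tail` and `score`, sorted by decreasing score (ties broken
#'   lexicographically); the chosen neighbour id is in
#'   `attr(, "neighbour")`.
#' @export
pwmEnsemblePredict <- function(testDomain, training, tails,
                               topFraction = 0.01, pseudocount = 0.01) {
  stopifnot(is(training, "PdzInteractionSet"), topFraction > 0)
  site <- if (.isValidSite(testDomain)) testDomain else {
    dm <- training@domains
    hit <- match(testDomain, dm$id)
    if (is.na(hit)) stop("testDomain is neither a known id nor a binding site")
    dm$binding_site[hit]
  }
  it <- training@interactions[training@interactions$label == 1L, , drop = FALSE]
  if (!nrow(it)) stop("training set has no positive interactions")
  dm <- training@domains[training@domains$id %in% it$domain_id, , drop = FALSE]
  sim <- vapply(dm$binding_site, bindingSiteSimilarity, numeric(1), b = site)
  npos <- vapply(dm$id, function(d)
    length(unique(it$peptide[it$domain_id == d])), integer(1))
  ord <- order(-sim, -npos, dm$id)
  best <- dm$id[ord[1]]
  if (sum(sim == sim[ord[1]]) > 1L)
    message("nearest-neighbour tie broken toward '", best, "'")
  pwm <- buildPWM(unique(it$peptide[it$domain_id == best]),
                  pseudocount = pseudocount)
  keys <- if (is.list(tails)) names(tails) else as.character(tails)
  keys <- unique(keys)
  sc <- scorePeptides(pwm, keys)
  k <- ceiling(topFraction * length(keys))
  ordk <- order(-sc, keys)[seq_len(k)]
  out <- data.frame(tail = keys[ordk], score = sc[ordk],
                    stringsAsFactors = FALSE)
  attr(out, "neighbour") <- best
  out
}
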