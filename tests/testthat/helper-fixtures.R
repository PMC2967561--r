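# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except the package's own shipped extdata.

AA <- pdzscan::aminoAcids()

randomPeptides <- function(n, seed = NULL, alphabet = AA) {
  gen <- function() vapply(seq_len(n), function(i)
    paste(sample(alphabet, 5, replace = TRUE), collapse = ""), character(1))
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

randomSites <- function(n, seed = NULL) {
  gen <- function() vapply(seq_len(n), function(i)
    paste(sample(AA, 16, replace = TRUE), collapse = ""), character(1))
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# A small deterministic interaction set: 2 domains, mixed labels.
makeToyISet <- function() {
  it <- data.frame(
    domain_id = c("D1", "D1", "D1", "D2", "D2"),
    peptide = c("ETWVF", "ESWVF", "KKKKK", "GTWVF", "PPPPP"),
    label = c(1L, 1L, -1L, 1L, -1L),
    source = "toy",
    stringsAsFactors = FALSE)
  dom <- data.frame(
    id = c("D1", "D2"),
    organism = "toy",
    binding_site = c(strrep("A", 16), paste0(strrep("A", 12), "CDEF")),
    source = "toy",
    stringsAsFactors = FALSE)
  new("PdzInteractionSet", interactions = it, domains = dom)
}

writeTempInteractions <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(c("domain_id\tbinding_site\tpeptide\tlabel\tsource", lines), f)
  f
}

# Tiny linearly separable 2-D toy problem for SVM contract tests.
makeToySVMData <- function(n = 10, seed = 42, sep = 3) {
  withr::with_seed(seed, {
    npos <- ceiling(n / 2)
    X <- rbind(matrix(rnorm(npos * 2, mean = sep), ncol = 2),
               matrix(rnorm((n - npos) * 2, mean = -sep), ncol = 2))
    list(X = X, y = c(rep(1, npos), rep(-1, n - npos)))
  })
}
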