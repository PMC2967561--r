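# Internal constants and helpers shared across modules.

# Canonical 20-letter amino-acid alphabet, alphabetical by one-letter code.
# All encodings and PWMs index residues in this order.
.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.GAP <- "-"

# Peptide positions p-4..p0, left to right; p0 is the C-terminus.
.PEP_POS <- -4:0
.PEP_LAB <- c("p-4", "p-3", "p-2", "p-1", "p0")

.SITE_LEN <- 16L
.PEP_LEN <- 5L

.aaIndex <- function(ch) match(ch, .AA)

.splitChars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.isValidPeptide <- function(x) {
  nchar(x) == .PEP_LEN && all(.splitChars(x) %in% .AA)
}

.isValidSite <- function(x) {
  nchar(x) == .SITE_LEN && all(.splitChars(x) %in% c(.AA, .GAP))
}

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Amino-acid alphabet used by pdzscan
#'
#' Returns the 20 standard one-letter amino-acid codes in the fixed
#' (alphabetical) order used by every encoding and PWM in the package.
#'
#' @return Character vector of length 20.
#' @export
aminoAcids <- function() .AA
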