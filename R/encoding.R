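# Feature encodings of domain-peptide pairs: contact-map (the principal
# encoding), flat binary sequence, and physicochemical descriptors, plus the
# [0,1] min-max scaler.

#' Physicochemical descriptor table
#'
#' Five-factor numeric descriptors for the 20 amino acids (each factor
#' summarizes many individual physicochemical properties), min-max scaled to
#' \[0, 1\] per factor across the 20 residues. Shipped as data under
#' `inst/extdata`.
#'
#' @param scaled scale each factor to \[0, 1\] (default); otherwise return
#'   the raw factor scores.
#' @return 20 x 5 numeric matrix, rows named by amino acid.
#' @export
physChemTable <- function(scaled = TRUE) {
  path <- system.file("extdata", "physchem_factors.tsv", package = "pdzscan",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$aa
  m <- m[.AA, , drop = FALSE]
  if (scaled) {
    rng <- apply(m, 2L, range)
    m <- sweep(sweep(m, 2L, rng[1L, ], `-`), 2L, rng[2L, ] - rng[1L, ], `/`)
  }
  m
}

# Nonzero feature indices of the contact-map encoding for one pair.
# Pair-major layout: pair k occupies indices (k-1)*400 + 1 .. k*400, within
# which the bit for (domain residue a, peptide residue b) is
# (idx(a)-1)*20 + idx(b). A gap at the domain position leaves the block zero.
.contactIndices <- function(siteChars, pepChars, pairs) {
  d <- siteChars[pairs$domain_pos]
  p <- pepChars[pairs$peptide_pos + 5L]   # -4..0 -> 1..5
  k <- seq_len(nrow(pairs))
  keep <- d != .GAP
  (k[keep] - 1L) * 400L + (.aaIndex(d[keep]) - 1L) * 20L + .aaIndex(p[keep])
}

#' Encode a domain-peptide pair as a feature vector
#'
#' Three encodings are available. `contact_map` (the default and the one the
#' predictor is built on): each contacting (domain position, peptide
#' position) pair is encoded as a binary block of length 400 representing the
#' 20 x 20 residue-pair matrix, giving a vector of length `400 * n_pairs`
#' (15,200 for the default 38-pair map) with at most one set bit per block.
#' `binary_sequence`: one-hot length-20 blocks for the 16 binding-site
#' residues followed by the 5 peptide residues (length 420).
#' `physicochemical`: the scaled 5-number descriptor of each of the 21
#' residues in the same order (length 105). In every encoding a gap '-' at a
#' domain position yields an all-zero block.
#'
#' @param bindingSite 16-character binding-site string (gaps allowed).
#' @param peptide 5-residue peptide.
#' @param method encoding name.
#' @param cmap a \code{\linkS4class{ContactMap}}; default the shipped map.
#' @param physchem descriptor matrix from [physChemTable()].
#' @return numeric feature vector.
#' @examples
#' v <- encodePair(strrep("A", 16), "ETWVF")
#' length(v)   # 15200
#' sum(v)      # 38: one bit per contacting pair
#' @export
encodePair <- function(bindingSite, peptide,
                       method = c("contact_map", "binary_sequence",
                                  "physicochemical"),
                       cmap = defaultContactMap(),
                       physchem = physChemTable()) {
  method <- match.arg(method)
  if (!.isValidSite(bindingSite))
    stop("invalid binding site '", bindingSite, "'")
  if (!.isValidPeptide(peptide))
    stop("invalid peptide '", peptide, "'")
  s <- .splitChars(bindingSite)
  p <- .splitChars(peptide)
  if (method == "contact_map") {
    pairs <- cmap@pairs
    v <- numeric(400L * nrow(pairs))
    v[.contactIndices(s, p, pairs)] <- 1
    v
  } else if (method == "binary_sequence") {
    res <- c(s, p)
    v <- numeric(20L * length(res))
    keep <- res != .GAP
    v[(which(keep) - 1L) * 20L + .aaIndex(res[keep])] <- 1
    v
  } else {
    res <- c(s, p)
    blocks <- lapply(res, function(r) {
      if (r == .GAP) numeric(5L) else physchem[r, ]
    })
    unname(unlist(blocks))
  }
}

#' Encode all interactions of a set as a feature matrix
#'
#' Vectorized encoding of every (domain, peptide) row of an interaction set.
#' Binary encodings are returned as a sparse \code{Matrix}; the
#' physicochemical encoding is dense.
#'
#' @param data a \code{\linkS4class{PdzInteractionSet}}.
#' @inheritParams encodePair
#' @return feature matrix with one row per interaction; labels in
#'   `attr(, "labels")`.
#' @export
encodeInteractions <- function(data,
                               method = c("contact_map", "binary_sequence",
                                          "physicochemical"),
                               cmap = defaultContactMap(),
                               physchem = physChemTable()) {
  method <- match.arg(method)
  stopifnot(is(data, "PdzInteractionSet"))
  it <- data@interactions
  dm <- data@domains
  sites <- dm$binding_site[match(it$domain_id, dm$id)]
  n <- nrow(it)
  if (method %in% c("contact_map", "binary_sequence")) {
    dim2 <- if (method == "contact_map") 400L * nrow(cmap@pairs) else 420L
    siteSplit <- strsplit(sites, "", fixed = TRUE)
    pepSplit <- strsplit(it$peptide, "", fixed = TRUE)
    idx <- vector("list", n)
    for (i in seq_len(n)) {
      idx[[i]] <- if (method == "contact_map") {
        .contactIndices(siteSplit[[i]], pepSplit[[i]], cmap@pairs)
      } else {
        res <- c(siteSplit[[i]], pepSplit[[i]])
        keep <- res != .GAP
        (which(keep) - 1L) * 20L + .aaIndex(res[keep])
      }
    }
    X <- Matrix::sparseMatrix(i = rep(seq_len(n), lengths(idx)),
                              j = unlist(idx), x = 1,
                              dims = c(n, dim2))
  } else {
    X <- t(vapply(seq_len(n), function(i)
      encodePair(sites[i], it$peptide[i], method = "physicochemical",
                 physchem = physchem), numeric(105L)))
  }
  attr(X, "labels") <- it$label
  attr(X, "encoding") <- method
  X
}

#' Fit / apply a per-dimension min-max scaler
#'
#' `fitScaler` learns per-dimension minima and ranges on training vectors;
#' `applyScaler` maps values to \[0, 1\], clipping test values outside the
#' training range. A constant training dimension scales to 0 by convention.
#' Binary encodings pass through unchanged (they already lie in \[0, 1\]).
#'
#' @param training numeric matrix (rows = vectors) to fit on.
#' @return `fitScaler`: a \code{\linkS4class{FeatureScaler}};
#'   `applyScaler`: the scaled matrix/vector.
#' @export
fitScaler <- function(training) {
  training <- as.matrix(training)
  if (!nrow(training)) stop("empty training set")
  mins <- apply(training, 2L, min)
  maxs <- apply(training, 2L, max)
  methods::new("FeatureScaler", mins = unname(mins),
               ranges = unname(maxs - mins))
}

#' @rdname fitScaler
#' @param scaler a fitted \code{\linkS4class{FeatureScaler}}.
#' @param x matrix or single vector to scale.
#' @export
applyScaler <- function(scaler, x) {
  stopifnot(is(scaler, "FeatureScaler"))
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(m) != length(scaler@mins)) stop("dimension mismatch")
  r <- scaler@ranges
  out <- sweep(m, 2L, scaler@mins, `-`)
  nz <- r > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, r[nz], `/`)
  out[, !nz] <- 0   # constant training dimension -> 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (vec) out[1L, ] else out
}

#' Export a labelled feature matrix in sparse "index:value" format
#'
#' One vector per line: the label first, then `index:value` entries for the
#' nonzero features (1-based indices), the interchange format of standard
#' SVM tooling.
#'
#' @param X feature matrix (rows = vectors).
#' @param labels numeric labels, one per row.
#' @param path output path.
#' @return invisibly, the path written.
#' @export
exportSparseMatrix <- function(X, labels, path) {
  stopifnot(nrow(X) == length(labels))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(X))) {
    v <- as.numeric(X[i, ])
    nz <- which(v != 0)
    writeLines(paste(labels[i],
                     paste(sprintf("%d:%g", nz, v[nz]), collapse = " ")), con)
  }
  invisible(path)
}
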