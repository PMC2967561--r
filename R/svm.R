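# Weighted-cost binary SVM with RBF kernel. The quadratic program is solved
# by libsvm (via e1071), which accepts the package's sparse feature matrices
# directly; everything around it -- the kernel, the class-weighted costs
# C+ = (n+/n-) C-, the decision function, model serialization and grid
# search -- lives here. The decision function is evaluated by an explicit
# kernel expansion over the stored support vectors, so models survive text
# serialization and do not depend on the solver object.

#' Radial basis function kernel
#'
#' `K(x, z) = exp(-gamma * ||x - z||^2)`, in (0, 1], equal to 1 exactly when
#' `x == z`.
#'
#' @param x,z numeric vectors of equal length.
#' @param gamma kernel width, > 0.
#' @return kernel value.
#' @export
rbfKernel <- function(x, z, gamma) {
  stopifnot(gamma > 0)
  if (length(x) != length(z)) stop("length mismatch")
  exp(-gamma * sum((x - z)^2))
}

# Full RBF kernel matrix between rows of X and rows of Z (Z = X when NULL).
# Sparse-aware: uses ||x||^2 + ||z||^2 - 2 x.z so that sparse feature
# matrices (contact-map encodings have <= 38 nonzeros of 15,200) stay cheap.
.rbfKernelMatrix <- function(X, Z = NULL, gamma) {
  sym <- is.null(Z)
  if (sym) Z <- X
  rx <- Matrix::rowSums(X^2)
  rz <- Matrix::rowSums(Z^2)
  cross <- as.matrix(Matrix::tcrossprod(X, Z))
  d2 <- outer(rx, rz, `+`) - 2 * cross
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  if (sym) diag(K) <- 1
  K
}

#' Train a weighted-cost RBF SVM
#'
#' Solves the soft-margin dual problem with per-class box constraints: the
#' negative class uses `C- = cost` and the positive class `C+ = (n+/n-) C-`
#' when `weighted = TRUE` (the weighted-cost rule balancing the number of
#' positive and negative training interactions), or `C` for both classes
#' otherwise. The dual is solved by libsvm; the fitted model stores its
#' support vectors, dual coefficients (alpha_i * y_i) and bias, with the
#' decision-function sign normalized against the training labels (solver
#' libraries orient it by factor-level internals).
#'
#' @param X feature matrix (rows = training vectors), dense or sparse.
#' @param y numeric labels in \{+1, -1\}; both classes must be present.
#' @param gamma RBF kernel width.
#' @param cost the negative-class cost C-; default 1.
#' @param weighted apply the `C+ = (n+/n-) C-` class weighting; default TRUE.
#' @param tol solver termination tolerance; default 1e-3.
#' @param encoding name of the feature encoding, stored with the model.
#' @return a \code{\linkS4class{PdzSVM}}.
#' @export
trainSVM <- function(X, y, gamma, cost = 1, weighted = TRUE, tol = 1e-3,
                     encoding = "contact_map") {
  if (is.null(dim(X))) X <- matrix(X, nrow = length(y))
  stopifnot(nrow(X) == length(y), gamma > 0, cost > 0)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 or -1")
  nPos <- sum(y == 1); nNeg <- sum(y == -1)
  if (nPos == 0L || nNeg == 0L) stop("both classes required for training")
  costNeg <- cost
  costPos <- if (weighted) (nPos / nNeg) * cost else cost
  yf <- factor(ifelse(y > 0, "pos", "neg"), levels = c("pos", "neg"))
  fit <- e1071::svm(X, yf, type = "C-classification", kernel = "radial",
                    gamma = gamma, cost = costNeg,
                    class.weights = c(pos = costPos / costNeg, neg = 1),
                    scale = FALSE, tolerance = tol)
  sv <- X[fit$index, , drop = FALSE]
  coefs <- as.numeric(fit$coefs)
  bias <- -fit$rho
  scores <- as.vector(.rbfKernelMatrix(X, sv, gamma) %*% coefs) + bias
  if (mean((scores >= 0) == (y > 0)) < 0.5) {
    coefs <- -coefs
    bias <- -bias
  }
  methods::new("PdzSVM", gamma = gamma, costPos = costPos, costNeg = costNeg,
               bias = bias, dualCoefs = coefs, supportVectors = sv,
               nPos = as.integer(nPos), nNeg = as.integer(nNeg),
               encoding = encoding)
}

.decideMatrix <- function(model, X) {
  if (ncol(X) != ncol(model@supportVectors))
    stop("feature length mismatch: model expects ",
         ncol(model@supportVectors), " dimensions")
  Kq <- .rbfKernelMatrix(X, model@supportVectors, model@gamma)
  score <- as.vector(Kq %*% model@dualCoefs) + model@bias
  data.frame(score = score, label = ifelse(score >= 0, 1L, -1L))
}

#' @rdname decide
#' @export
setMethod("decide", "PdzSVM", function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  .decideMatrix(model, x)
})

#' Grid search for (C, gamma)
#'
#' Exhaustive search over log2-spaced cost and kernel-width grids, scoring
#' each point by mean ROC AUC under seeded stratified k-fold
#' cross-validation (the same folds for every grid point). Ties are broken
#' toward smaller C, then smaller gamma.
#'
#' @param X feature matrix.
#' @param y labels in \{+1, -1\}.
#' @param cGrid,gammaGrid numeric grids; defaults are the conventional
#'   exhaustive RBF ranges `2^(-5..15)` and `2^(-15..3)`.
#' @param folds number of CV folds; default 5.
#' @param seed RNG seed for the fold assignment.
#' @param weighted apply the weighted-cost rule within each fold.
#' @return list with `grid` (data.frame of C, gamma, meanAUC) and `best`
#'   (named vector C, gamma).
#' @export
gridSearch <- function(X, y, cGrid = 2^seq(-5, 15, 2),
                       gammaGrid = 2^seq(-15, 3, 2), folds = 5L,
                       seed = 1L, weighted = TRUE) {
  stopifnot(length(cGrid) > 0, length(gammaGrid) > 0)
  if (is.null(dim(X))) X <- matrix(X, nrow = length(y))
  nPos <- sum(y == 1); nNeg <- sum(y == -1)
  if (folds > min(nPos, nNeg))
    stop("fold count exceeds the size of a class")
  foldId <- .stratifiedFolds(y, folds, seed)
  grid <- expand.grid(C = cGrid, gamma = gammaGrid, KEEP.OUT.ATTRS = FALSE)
  grid$meanAUC <- vapply(seq_len(nrow(grid)), function(i) {
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- which(foldId != f); te <- which(foldId == f)
      m <- trainSVM(X[tr, , drop = FALSE], y[tr], gamma = grid$gamma[i],
                    cost = grid$C[i], weighted = weighted)
      rocAUC(y[te], .decideMatrix(m, X[te, , drop = FALSE])$score)
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  ord <- order(-grid$meanAUC, grid$C, grid$gamma)
  best <- grid[ord[1L], ]
  list(grid = grid, best = c(C = best$C, gamma = best$gamma))
}

# Seeded stratified fold assignment: each class is split as evenly as
# possible across folds.
.stratifiedFolds <- function(y, folds, seed) {
  .withSeed(seed, {
    id <- integer(length(y))
    for (cl in unique(y)) {
      w <- which(y == cl)
      id[w] <- sample(rep_len(seq_len(folds), length(w)))
    }
    id
  })
}

#' Serialize / read an SVM model as versioned text
#'
#' The file stores gamma, the class costs, bias, training counts, encoding
#' name, and each support vector as its dual coefficient followed by sparse
#' `index:value` features, so models survive round trips through plain text.
#'
#' @param model a \code{\linkS4class{PdzSVM}}.
#' @param path file path.
#' @return `writeSVMModel` invisibly returns the path; `readSVMModel` the
#'   reconstructed model.
#' @export
writeSVMModel <- function(model, path) {
  stopifnot(is(model, "PdzSVM"))
  sv <- as.matrix(model@supportVectors)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("pdzscan-svm-model v1",
               sprintf("gamma\t%.17g", model@gamma),
               sprintf("cost_pos\t%.17g", model@costPos),
               sprintf("cost_neg\t%.17g", model@costNeg),
               sprintf("bias\t%.17g", model@bias),
               sprintf("n_pos\t%d", model@nPos),
               sprintf("n_neg\t%d", model@nNeg),
               sprintf("encoding\t%s", model@encoding),
               sprintf("dim\t%d", ncol(sv)),
               sprintf("n_sv\t%d", nrow(sv))), con)
  for (i in seq_len(nrow(sv))) {
    nz <- which(sv[i, ] != 0)
    writeLines(paste(sprintf("%.17g", model@dualCoefs[i]),
                     paste(sprintf("%d:%g", nz, sv[i, nz]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' @rdname writeSVMModel
#' @export
readSVMModel <- function(path) {
  ln <- readLines(path)
  if (ln[1] != "pdzscan-svm-model v1") stop("unrecognized model file")
  hdr <- strsplit(ln[2:10], "\t")
  val <- vapply(hdr, `[`, character(1), 2L)
  names(val) <- vapply(hdr, `[`, character(1), 1L)
  d <- as.integer(val[["dim"]]); nsv <- as.integer(val[["n_sv"]])
  sv <- matrix(0, nsv, d)
  coefs <- numeric(nsv)
  for (i in seq_len(nsv)) {
    toks <- strsplit(ln[10L + i], " ")[[1]]
    coefs[i] <- as.numeric(toks[1])
    if (length(toks) > 1L) {
      kv <- strsplit(toks[-1], ":", fixed = TRUE)
      sv[i, as.integer(vapply(kv, `[`, character(1), 1L))] <-
        as.numeric(vapply(kv, `[`, character(1), 2L))
    }
  }
  methods::new("PdzSVM", gamma = as.numeric(val[["gamma"]]),
               costPos = as.numeric(val[["cost_pos"]]),
               costNeg = as.numeric(val[["cost_neg"]]),
               bias = as.numeric(val[["bias"]]),
               dualCoefs = coefs, supportVectors = sv,
               nPos = as.integer(val[["n_pos"]]),
               nNeg = as.integer(val[["n_neg"]]),
               encoding = val[["encoding"]])
}
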