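test_that("the RBF kernel has its closed-form values and symmetry", {
  x <- c(1, 0, 1, 0)
  expect_equal(rbfKernel(x, x, gamma = 0.5), 1.0)
  z <- c(1, 1, 0, 0)   # differs in 2 bits
  expect_equal(rbfKernel(x, z, gamma = 0.5), exp(-1))
  withr::with_seed(8, {
    for (i in 1:5) {
      a <- rnorm(6); b <- rnorm(6); g <- runif(1, 0.1, 2)
      expect_equal(rbfKernel(a, b, g), rbfKernel(b, a, g))
      expect_true(rbfKernel(a, b, g) > 0 && rbfKernel(a, b, g) <= 1)
    }
  })
  expect_error(rbfKernel(1:3, 1:4, 1), "length mismatch")
})

test_that("weighted costs follow C+ = (n+/n-) C- and balance reduces to plain C", {
  toy <- makeToySVMData(n = 12, seed = 1)
  m <- trainSVM(toy$X, toy$y, gamma = 0.5, cost = 2, weighted = TRUE)
  expect_equal(m@costPos / m@costNeg, sum(toy$y == 1) / sum(toy$y == -1))
  # balanced classes: weighted and unweighted coincide
  mw <- trainSVM(toy$X, toy$y, gamma = 0.5, cost = 2, weighted = FALSE)
  expect_equal(m@costPos, mw@costPos)
  expect_equal(decide(m, toy$X)$score, decide(mw, toy$X)$score)
})

test_that("separable toy problems are classified perfectly", {
  toy <- makeToySVMData(n = 10, seed = 2)
  m <- trainSVM(toy$X, toy$y, gamma = 0.5)
  d <- decide(m, toy$X)
  expect_equal(d$label, as.integer(toy$y))
  expect_error(trainSVM(toy$X, rep(1, 10), gamma = 0.5), "both classes")
  expect_error(trainSVM(toy$X, c(rep(2, 5), rep(-1, 5)), gamma = 0.5),
               "labels")
})

test_that("decide evaluates the kernel expansion and sgn(0) = +1", {
  # hand-built model: score is exactly the explicit sum over SVs
  sv <- matrix(c(0, 1, 1, 0, 1, 1), 3, 2)
  model <- new("PdzSVM", gamma = 0.3, costPos = 1, costNeg = 1, bias = 0.2,
               dualCoefs = c(0.5, -0.25, 0.1), supportVectors = sv,
               nPos = 1L, nNeg = 2L, encoding = "contact_map")
  q <- c(0.5, 0.5)
  oracle <- sum(vapply(1:3, function(i)
    model@dualCoefs[i] * rbfKernel(sv[i, ], q, 0.3), numeric(1))) + 0.2
  expect_equal(decide(model, q)$score, oracle)
  # a model whose score is identically zero labels +1
  zero <- new("PdzSVM", gamma = 1, costPos = 1, costNeg = 1, bias = 0,
              dualCoefs = 0, supportVectors = matrix(0, 1, 2),
              nPos = 1L, nNeg = 1L, encoding = "contact_map")
  d <- decide(zero, c(1, 1))
  expect_equal(d$score, 0)
  expect_equal(d$label, 1L)
  expect_error(decide(model, c(1, 2, 3)), "length mismatch")
})

test_that("label negation retrains to the mirrored decision (antisymmetry)", {
  toy <- makeToySVMData(n = 14, seed = 3)
  m1 <- trainSVM(toy$X, toy$y, gamma = 0.7, weighted = FALSE, tol = 1e-6)
  m2 <- trainSVM(toy$X, -toy$y, gamma = 0.7, weighted = FALSE, tol = 1e-6)
  s1 <- decide(m1, toy$X)$score
  s2 <- decide(m2, toy$X)$score
  expect_equal(s1, -s2, tolerance = 1e-4)
})

test_that("dual coefficients satisfy the box and equality constraints", {
  ds <- syntheticDataset(nDomains = 5, peptidesPerDomain = 10,
                         nDecoyTails = 300, seed = 19)
  X <- encodeInteractions(ds$interactions)
  y <- attr(X, "labels")
  m <- trainSVM(X, y, gamma = 0.05, cost = 1.5)
  a <- m@dualCoefs
  expect_lte(max(a), m@costPos + 1e-6)
  expect_gte(min(a), -m@costNeg - 1e-6)
  expect_equal(sum(a), 0, tolerance = 1e-6)
})

test_that("grid search returns the singleton grid, is seeded, and validates folds", {
  ds <- syntheticDataset(nDomains = 5, peptidesPerDomain = 10,
                         nDecoyTails = 300, seed = 23)
  X <- encodeInteractions(ds$interactions)
  y <- attr(X, "labels")
  g1 <- gridSearch(X, y, cGrid = 2, gammaGrid = 0.05, folds = 3, seed = 5)
  expect_equal(unname(g1$best), c(2, 0.05))
  expect_equal(nrow(g1$grid), 1L)
  g2 <- gridSearch(X, y, cGrid = c(0.5, 2), gammaGrid = c(0.01, 0.1),
                   folds = 3, seed = 5)
  g3 <- gridSearch(X, y, cGrid = c(0.5, 2), gammaGrid = c(0.01, 0.1),
                   folds = 3, seed = 5)
  expect_identical(g2, g3)
  expect_true(max(g2$grid$meanAUC) == g2$grid$meanAUC[
    g2$grid$C == g2$best["C"] & g2$grid$gamma == g2$best["gamma"]])
  expect_error(gridSearch(X, y, cGrid = 1, gammaGrid = 1,
                          folds = length(y)), "fold count")
})

test_that("text model serialization round-trips decisions exactly", {
  ds <- syntheticDataset(nDomains = 4, peptidesPerDomain = 8,
                         nDecoyTails = 200, seed = 29)
  X <- encodeInteractions(ds$interactions)
  y <- attr(X, "labels")
  m <- trainSVM(X, y, gamma = 0.05)
  f <- withr::local_tempfile(fileext = ".txt")
  writeSVMModel(m, f)
  back <- readSVMModel(f)
  expect_equal(back@gamma, m@gamma)
  expect_equal(back@costPos, m@costPos)
  expect_equal(decide(back, X[1:10, ])$score, decide(m, X[1:10, ])$score,
               tolerance = 1e-10)
})
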