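test_that("confusion metrics follow their defining formulas", {
  perfect <- computeMetrics(c(1, 1, -1, -1), c(1, 1, -1, -1))
  expect_equal(perfect[c("tpr", "fpr", "precision", "f1")],
               list(tpr = 1, fpr = 0, precision = 1, f1 = 1))
  # precision = recall = 0.5 gives F1 = 0.5
  half <- computeMetrics(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(half$precision, 0.5)
  expect_equal(half$tpr, 0.5)
  expect_equal(half$f1, 0.5)
  expect_message(z <- computeMetrics(c(1, -1), c(-1, -1)), "precision")
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)
  expect_error(computeMetrics(integer(0), integer(0)), "empty")
})

test_that("metrics agree with a brute-force confusion-matrix oracle", {
  withr::with_seed(77, {
    truth <- sample(c(-1, 1), 200, replace = TRUE)
    pred <- sample(c(-1, 1), 200, replace = TRUE)
  })
  m <- suppressMessages(computeMetrics(truth, pred))
  tab <- table(factor(truth, c(-1, 1)), factor(pred, c(-1, 1)))
  expect_equal(m$tp, tab["1", "1"], ignore_attr = TRUE)
  expect_equal(m$tn, tab["-1", "-1"], ignore_attr = TRUE)
  expect_equal(m$tp + m$fp + m$tn + m$fn, 200)
  expect_equal(m$tpr, tab["1", "1"] / sum(tab["1", ]), ignore_attr = TRUE)
})

test_that("ROC AUC spans perfect, anti-perfect and the U-statistic", {
  truth <- c(1, 1, -1, -1)
  expect_equal(rocAUC(truth, c(4, 3, 2, 1)), 1.0)
  expect_equal(rocAUC(truth, c(1, 2, 3, 4)), 0.0)
  # U-statistic oracle with ties, on 50 random points
  withr::with_seed(31, {
    t50 <- sample(c(-1, 1), 50, replace = TRUE, prob = c(0.6, 0.4))
    s50 <- sample(1:8, 50, replace = TRUE)   # heavy ties
  })
  pos <- s50[t50 == 1]; neg <- s50[t50 == -1]
  u <- (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
  expect_equal(rocAUC(t50, s50), u)
  expect_error(rocAUC(rep(1, 4), 1:4), "both classes")
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(41, {
    truth <- sample(c(-1, 1), 80, replace = TRUE)
    scores <- rnorm(80) + truth
  })
  ours <- rocAUC(truth, scores)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c(-1, 1),
    direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("PR curves use achievable-point interpolation", {
  # perfectly ranked: PR AUC 1
  cur <- rocPrCurves(c(1, 1, -1, -1), c(4, 3, 2, 1))
  expect_equal(cur$pr$auc, 1.0)
  expect_equal(cur$roc$auc, 1.0)
  # hand-checked: scores rank pos, neg, pos, neg
  cur2 <- rocPrCurves(c(1, -1, 1, -1), c(4, 3, 2, 1))
  # interpolated PR points: (0,1) (0.5,1) (0.5,.5) (1,2/3) (1,.5)
  expect_equal(cur2$pr$points$x[1], 0)
  expect_equal(cur2$pr$auc, 0.5 * 1 + 0.5 * mean(c(0.5, 2 / 3)),
               tolerance = 1e-12)
  # ROC curve points are monotone nondecreasing
  expect_true(all(diff(cur2$roc$points$x) >= 0))
  expect_true(all(diff(cur2$roc$points$y) >= 0))
})

test_that("sequence similarity counts matching positions", {
  a <- strrep("A", 16)
  expect_equal(bindingSiteSimilarity(a, a), 1.0)
  b <- paste0(strrep("A", 12), "CDEF")
  expect_equal(bindingSiteSimilarity(a, b), 0.75)
  expect_error(bindingSiteSimilarity(a, "AAA"), "length mismatch")
  withr::with_seed(9, {
    for (i in 1:10) {
      p <- randomPeptides(1); q <- randomPeptides(1)
      oracle <- sum(strsplit(p, "")[[1]] == strsplit(q, "")[[1]]) / 5
      expect_equal(peptideSimilarity(p, q), oracle)
    }
  })
})

test_that("nearest-neighbour prediction matches brute-force search", {
  iset <- makeToyISet()
  # test pair identical to a training positive / negative
  expect_equal(nearestNeighbourPredict(strrep("A", 16), "ETWVF", iset)$label, 1L)
  expect_equal(nearestNeighbourPredict(strrep("A", 16), "ETWVF", iset)$score, 1.0)
  expect_equal(nearestNeighbourPredict(strrep("A", 16), "KKKKK", iset)$label, -1L)
  # randomized instances vs exhaustive argmax oracle
  ds <- syntheticDataset(nDomains = 6, peptidesPerDomain = 8,
                         nDecoyTails = 150, seed = 61)
  tr <- ds$interactions
  it <- interactions(tr); dm <- domainTable(tr)
  queries <- data.frame(site = randomSites(5, seed = 62),
                        pep = randomPeptides(5, seed = 63))
  for (i in seq_len(nrow(queries))) {
    got <- nearestNeighbourPredict(queries$site[i], queries$pep[i], tr)
    dsim <- vapply(dm$binding_site[match(it$domain_id, dm$id)],
                   bindingSiteSimilarity, numeric(1), b = queries$site[i])
    psim <- vapply(it$peptide, peptideSimilarity, numeric(1),
                   b = queries$pep[i])
    best <- max(dsim)
    cand <- which(dsim == best)
    cand <- cand[psim[cand] == max(psim[cand])]
    expect_equal(got$score, best * max(psim[which(dsim == best)]))
    expect_true(got$label %in% it$label[cand])
    if (all(it$label[cand] == it$label[cand][1]))
      expect_equal(got$label, it$label[cand][1])
    else
      expect_equal(got$label, 1L)   # tie prefers the positive label
  }
})

test_that("Fisher overlap p-values are hypergeometric upper tails", {
  expect_equal(fisherOverlapTest(0, 0, 10, 100), 1.0)
  expect_lt(fisherOverlapTest(0, 50, 40, 100), 1 + 1e-12)
  expect_error(fisherOverlapTest(5, 4, 10, 100), "inconsistent")
  # agreement with stats::fisher.test one-sided
  p1 <- fisherOverlapTest(5, 20, 10, 100)
  ft <- stats::fisher.test(matrix(c(5, 15, 5, 75), 2), alternative = "greater")
  expect_equal(p1, ft$p.value, tolerance = 1e-12)
})

test_that("ten-fold CV partitions the data and is reproducible", {
  ds <- syntheticDataset(nDomains = 6, peptidesPerDomain = 10,
                         nDecoyTails = 400, seed = 71)
  cv1 <- runCV(ds$interactions, gamma = 0.05, scheme = "ten_fold",
               folds = 5, seed = 8)
  expect_equal(nrow(cv1$perRun), 5L)
  n <- nrow(interactions(ds$interactions))
  expect_equal(sum(cv1$perRun$n_test), n)        # folds cover the data
  expect_length(cv1$pooled$truth, n)             # disjoint union
  cv2 <- runCV(ds$interactions, gamma = 0.05, scheme = "ten_fold",
               folds = 5, seed = 8)
  expect_equal(cv1$perRun, cv2$perRun)
  expect_gt(cv1$meanRocAUC, 0.8)                 # planted signal is learnable
})

test_that("held-out domains never appear in training interactions", {
  ds <- syntheticDataset(nDomains = 10, peptidesPerDomain = 8,
                         nDecoyTails = 400, seed = 73)
  it <- interactions(ds$interactions)
  # reproduce the scheme's draw to verify containment
  cv <- runCV(ds$interactions, gamma = 0.05, scheme = "leave_domains_out",
              fractionDomains = 0.2, repeats = 3, seed = 9)
  expect_equal(nrow(cv$perRun), 3L)
  # the held-out count per repeat must equal all interactions of the drawn
  # domains: every held-out set is a union of whole domains
  sizes <- table(it$domain_id)
  nd <- max(1L, round(0.2 * length(unique(it$domain_id))))
  for (nTest in cv$perRun$n_test) {
    combos <- utils::combn(as.integer(sizes), nd, sum)
    expect_true(nTest %in% combos)
  }
})

test_that("leave-one-domain-out reports per-entity AUCs with neighbour similarity", {
  ds <- syntheticDataset(nDomains = 6, peptidesPerDomain = 10,
                         nDecoyTails = 300, seed = 75)
  cv <- runCV(ds$interactions, gamma = 0.05, scheme = "leave_one_domain_out",
              seed = 10)
  pe <- cv$perEntity
  expect_setequal(pe$entity, domainTable(ds$interactions)$id)
  expect_true(all(pe$nnSimilarity >= 0 & pe$nnSimilarity <= 1))
  # stratification partitions the entities
  tab <- similarityStratifiedAUC(cv, breaks = c(0, 0.5, 1))
  expect_equal(sum(tab$n), nrow(pe))
  one <- similarityStratifiedAUC(cv, breaks = c(0, 1))
  expect_equal(one$n, nrow(pe))
  expect_error(similarityStratifiedAUC(
    runCV(ds$interactions, gamma = 0.05, scheme = "ten_fold", folds = 3,
          seed = 2)), "leave-one-entity")
})
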