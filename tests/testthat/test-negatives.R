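test_that("PWM-selected negatives score strictly below every positive", {
  ds <- syntheticDataset(nDomains = 8, peptidesPerDomain = 15,
                         nDecoyTails = 500, seed = 41)
  pos <- positiveOnlyView(ds$interactions)
  it <- interactions(pos)
  pool <- unique(it$peptide)
  for (d in unique(it$domain_id)[1:4]) {
    peps <- unique(it$peptide[it$domain_id == d])
    neg <- generateNegatives(d, peps, pool = pool, method = "pwm_selected")
    pwm <- buildPWM(peps)
    cutoff <- min(scorePeptides(pwm, peps))
    if (nrow(neg)) {
      expect_true(all(scorePeptides(pwm, neg$peptide) < cutoff))
      expect_length(intersect(neg$peptide, peps), 0L)
      expect_true(all(neg$label == -1L))
    }
  }
})

test_that("selected negatives respect the pairwise redundancy cap", {
  ds <- syntheticDataset(nDomains = 8, peptidesPerDomain = 15,
                         nDecoyTails = 500, seed = 42)
  it <- interactions(positiveOnlyView(ds$interactions))
  pool <- unique(it$peptide)
  d <- unique(it$domain_id)[1]
  peps <- unique(it$peptide[it$domain_id == d])
  for (cap in c(1L, 3L)) {
    neg <- generateNegatives(d, peps, pool = pool, method = "pwm_selected",
                             redundancyMaxIdentity = cap)
    sel <- neg$peptide
    if (length(sel) > 1L) {
      mat <- do.call(cbind, strsplit(sel, ""))
      for (i in seq_len(length(sel) - 1L)) {
        ident <- colSums(mat[, -(1:i), drop = FALSE] == mat[, i])
        expect_true(all(ident <= cap))
      }
    }
  }
})

test_that("the greedy selection matches a brute-force oracle on a small pool", {
  positives <- c("ETWVA", "ESWVA", "DTWVA")
  pool <- c(positives, "KKKKK", "KKKKR", "PGPGP", "LLLLL", "AAAAA",
            "RRRRR", "KRKRK", "GGGGG")
  neg <- generateNegatives("D", positives, pool = pool,
                           method = "pwm_selected", ratio = 1,
                           redundancyMaxIdentity = 2L, pseudocount = 0.01)
  # independent re-implementation of the greedy rule
  pwm <- buildPWM(positives, pseudocount = 0.01)
  cutoff <- min(scorePeptides(pwm, positives))
  cand <- setdiff(pool, positives)
  sc <- scorePeptides(pwm, cand)
  cand <- cand[sc < cutoff]; sc <- sc[sc < cutoff]
  ord <- order(sc, cand)
  accepted <- character(0)
  for (p in cand[ord]) {
    if (length(accepted) >= ceiling(1 * length(positives))) break
    okAll <- all(vapply(accepted, function(q)
      sum(strsplit(p, "")[[1]] == strsplit(q, "")[[1]]) <= 2L, logical(1)))
    if (okAll) accepted <- c(accepted, p)
  }
  expect_equal(neg$peptide, accepted)
})

test_that("insufficient candidate pools are flagged", {
  positives <- c("AAAAA", "AAAAC")
  pool <- c(positives, "AAAAD")   # at most one candidate below the cutoff
  neg <- generateNegatives("D", positives, pool = pool,
                           method = "pwm_selected", ratio = 2)
  expect_lt(nrow(neg), ceiling(2 * length(positives)))
  expect_true(attr(neg, "insufficient"))
})

test_that("shuffled negatives are anagrams and seeds fix all stochastic methods", {
  positives <- c("ETWVA", "KQRST")
  shuf <- generateNegatives("D", positives, method = "shuffled", ratio = 1,
                            seed = 7)
  srt <- function(x) vapply(strsplit(x, ""), function(c)
    paste(sort(c), collapse = ""), character(1))
  expect_equal(sort(srt(shuf$peptide)), sort(srt(positives)))
  pool <- randomPeptides(60, seed = 50)
  for (m in c("random", "shuffled", "randomly_selected")) {
    a <- generateNegatives("D", positives, pool = pool, method = m,
                           ratio = 3, seed = 99)
    b <- generateNegatives("D", positives, pool = pool, method = m,
                           ratio = 3, seed = 99)
    expect_identical(a, b)
    c <- generateNegatives("D", positives, pool = pool, method = m,
                           ratio = 3, seed = 100)
    expect_false(identical(a$peptide, c$peptide))
  }
  # randomly_selected draws from the same below-cutoff pool as pwm_selected
  rs <- generateNegatives("D", positives, pool = pool,
                          method = "randomly_selected", ratio = 2, seed = 1)
  pwm <- buildPWM(positives)
  cutoff <- min(scorePeptides(pwm, positives))
  expect_true(all(scorePeptides(pwm, rs$peptide) < cutoff))
})

test_that("negative reports count per domain and in total", {
  sets <- list(A = data.frame(x = 1:10), B = data.frame(x = 1:10))
  rep1 <- negativesReport(sets)
  expect_equal(attr(rep1, "total"), 20L)
  expect_equal(negativesReport(list())$domain_id, character(0))
  # ratio arithmetic at the dataset level: ~2 negatives per positive
  ds <- syntheticDataset(nDomains = 10, peptidesPerDomain = 12,
                         nDecoyTails = 2000, seed = 43)
  pos <- positiveOnlyView(ds$interactions)
  tr <- addArtificialNegatives(pos, ratio = 2, seed = 44)
  repAll <- negativesReport(tr)
  it <- interactions(pos)
  # the per-domain quota is 2 x the domain's unique positives
  nUnique <- sum(vapply(split(it$peptide, it$domain_id),
                        function(p) length(unique(p)), integer(1)))
  expect_equal(attr(repAll, "total"), nNegative(tr))
  expect_true(abs(attr(repAll, "total") - 2 * nUnique) <= nrow(repAll))
})
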