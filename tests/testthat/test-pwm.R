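test_that("PWM cells follow the pseudocount formula and columns normalize", {
  # degenerate column without pseudocount
  pwm0 <- buildPWM(c("AETWV", "AETWV"), pseudocount = 0)
  m0 <- pwmMatrix(pwm0)
  expect_equal(unname(m0["V", "p0"]), 1)
  expect_equal(sum(m0[, "p0"] > 0), 1L)
  # single peptide with pseudocount 0.01: observed 1.01/1.2, unseen 0.01/1.2
  pwm1 <- buildPWM("AETWV", pseudocount = 0.01)
  m1 <- pwmMatrix(pwm1)
  expect_equal(unname(m1["A", "p-4"]), 1.01 / 1.2)
  expect_equal(unname(m1["C", "p-4"]), 0.01 / 1.2)
  # normalization holds for arbitrary input
  pwmR <- buildPWM(randomPeptides(30, seed = 9))
  expect_equal(unname(colSums(pwmMatrix(pwmR))), rep(1, 5))
  expect_error(buildPWM(character(0)), "zero peptides")
})

test_that("PWM construction is permutation-invariant", {
  peps <- randomPeptides(25, seed = 10)
  a <- buildPWM(peps)
  b <- buildPWM(withr::with_seed(1, sample(peps)))
  expect_equal(pwmMatrix(a), pwmMatrix(b))
})

test_that("peptide scoring is the sum of log2 cell probabilities", {
  uniform <- buildPWM(randomPeptides(1, seed = 2), pseudocount = 1e12)
  expect_equal(scorePeptide(uniform, "ACDEF"), 5 * log2(1 / 20),
               tolerance = 1e-6)
  ident <- buildPWM("AAAAA", pseudocount = 0)
  expect_equal(scorePeptide(ident, "AAAAA"), 0)
  expect_equal(scorePeptide(ident, "AAAAC"), -Inf)
  expect_error(scorePeptide(ident, "AAAAC", strict = TRUE), "zero-probability")
})

test_that("the consensus peptide maximizes the PWM score", {
  pwm <- buildPWM(randomPeptides(40, seed = 3), pseudocount = 0.01)
  cons <- consensusPeptide(pwm)
  consScore <- scorePeptide(pwm, cons)
  others <- randomPeptides(100, seed = 4)
  expect_true(all(scorePeptides(pwm, others) <= consScore))
})

test_that("scoring is monotone in the peptide's own cell probabilities", {
  peps <- randomPeptides(20, seed = 6)
  pwm <- buildPWM(peps)
  target <- peps[1]
  base <- scorePeptide(pwm, target)
  # raising the probability of the target's p0 residue raises its score
  m <- pwmMatrix(pwm)
  r <- substr(target, 5, 5)
  m[, 5] <- m[, 5] * 0.9
  m[r, 5] <- m[r, 5] + sum(pwmMatrix(pwm)[, 5]) * 0.1
  m <- sweep(m, 2, colSums(m), "/")
  bumped <- new("PWM", probs = m, pseudocount = 0.01,
                nSequences = pwm@nSequences)
  expect_gt(scorePeptide(bumped, target), base)
})

test_that("PWM similarity is 100 at identity, symmetric, and matches the formula", {
  a <- buildPWM(randomPeptides(15, seed = 7))
  b <- buildPWM(randomPeptides(15, seed = 8))
  expect_equal(pwmSimilarity(a, a), 100)
  expect_equal(pwmSimilarity(a, b), pwmSimilarity(b, a))
  # independent direct computation
  ma <- pwmMatrix(a); mb <- pwmMatrix(b)
  oracle <- 100 * mean((vapply(1:5, function(j)
    cor(ma[, j], mb[, j]), numeric(1)) + 1) / 2)
  expect_equal(pwmSimilarity(a, b), oracle)
  # zero-variance column contributes 50
  flat <- new("PWM", probs = matrix(1 / 20, 20, 5,
                                    dimnames = list(aminoAcids(), colnames(ma))),
              pseudocount = 0, nSequences = 1L)
  expect_message(s <- pwmSimilarity(flat, flat), "zero-variance")
  expect_equal(s, 50)
})

test_that("logo heights encode per-position information content", {
  degen <- buildPWM(c("VVVVV"), pseudocount = 0)
  h <- logoMatrix(degen)
  expect_equal(unname(colSums(h)), rep(log2(20), 5))
  uniformCol <- new("PWM",
                    probs = matrix(1 / 20, 20, 5,
                                   dimnames = list(aminoAcids(),
                                                   colnames(pwmMatrix(degen)))),
                    pseudocount = 0, nSequences = 1L)
  expect_equal(unname(colSums(logoMatrix(uniformCol))), rep(0, 5))
  # exported file round-trips the information content
  f <- withr::local_tempfile(fileext = ".tsv")
  pwm <- buildPWM(randomPeptides(12, seed = 12))
  exportLogoMatrix(pwm, f)
  back <- utils::read.delim(f)
  expect_equal(unname(colSums(back[, -1])),
               unname(colSums(logoMatrix(pwm))), tolerance = 1e-12)
})

test_that("PWM TSV serialization round-trips", {
  pwm <- buildPWM(randomPeptides(9, seed = 13), pseudocount = 0.05)
  f <- withr::local_tempfile(fileext = ".tsv")
  writePWM(pwm, f)
  back <- readPWM(f)
  expect_equal(pwmMatrix(back), pwmMatrix(pwm), tolerance = 1e-12)
  expect_equal(back@pseudocount, 0.05)
  expect_equal(back@nSequences, 9L)
})

test_that("the PWM ensemble uses the nearest training neighbour", {
  ds <- syntheticDataset(nDomains = 6, peptidesPerDomain = 15,
                         nDecoyTails = 1000, seed = 31)
  pos <- positiveOnlyView(ds$interactions)
  dm <- domainTable(pos)
  # a test domain identical to a training domain selects that domain
  pred <- pwmEnsemblePredict(dm$binding_site[2], pos, ds$tails,
                             topFraction = 0.01)
  expect_equal(attr(pred, "neighbour"), dm$id[2])
  # count arithmetic: top 1% of N tails
  N <- length(ds$tails)
  expect_equal(nrow(pred), ceiling(0.01 * N))
  # sort-and-slice oracle
  pwm <- buildPWM(unique(interactions(pos)$peptide[
    interactions(pos)$domain_id == dm$id[2]]))
  keys <- names(ds$tails)
  sc <- scorePeptides(pwm, keys)
  ord <- order(-sc, keys)[seq_len(ceiling(0.01 * N))]
  expect_equal(pred$tail, keys[ord])
  expect_equal(pred$score, sc[ord])
})
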