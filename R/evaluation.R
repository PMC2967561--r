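# Performance metrics, ROC / precision-recall curves, cross-validation
# schemes (including leave-domain-out and leave-peptide-out), sequence
# similarities, the nearest-neighbour baseline and the Fisher overlap test.

#' Confusion-matrix performance metrics
#'
#' Computes TPR (recall) = TP/P, FPR = FP/N, precision = TP/(TP+FP) and
#' F1 = 2 * precision * recall / (precision + recall) from true and
#' predicted +1/-1 labels. Precision and F1 are reported as 0 (with a
#' message) when their denominators are 0.
#'
#' @param truth,predicted equal-length vectors of labels in \{+1, -1\}.
#' @return list with `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`, `precision`, `f1`.
#' @export
computeMetrics <- function(truth, predicted) {
  if (!length(truth)) stop("empty input")
  if (length(truth) != length(predicted)) stop("length mismatch")
  stopifnot(all(truth %in% c(-1, 1)), all(predicted %in% c(-1, 1)))
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == -1 & predicted == 1)
  tn <- sum(truth == -1 & predicted == -1)
  fn <- sum(truth == 1 & predicted == -1)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  fpr <- if (fp + tn > 0) fp / (fp + tn) else 0
  if (tp + fp == 0) {
    message("no positive predictions: precision reported as 0")
    precision <- 0
  } else precision <- tp / (tp + fp)
  f1 <- if (precision + tpr > 0) 2 * precision * tpr / (precision + tpr) else {
    message("precision + recall is 0: F1 reported as 0")
    0
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       tpr = tpr, fpr = fpr, precision = precision, f1 = f1)
}

# Cumulative TP/FP counts per distinct score threshold (descending scores,
# ties grouped). Shared by the ROC and PR curve constructions.
.rankCounts <- function(truth, scores) {
  stopifnot(length(truth) == length(scores))
  ord <- order(scores, decreasing = TRUE)
  t <- truth[ord]; s <- scores[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t == 1); fp <- cumsum(t == -1)
  last <- !duplicated(grp, fromLast = TRUE)
  list(tp = tp[last], fp = fp[last],
       P = sum(truth == 1), N = sum(truth == -1))
}

#' ROC curve area under the curve
#'
#' Trapezoidal ROC AUC over all score thresholds (ties grouped); equals the
#' Mann-Whitney U statistic P(score+ > score-) + 0.5 P(score+ = score-).
#'
#' @param truth labels in \{+1, -1\}.
#' @param scores numeric scores, higher meaning more positive.
#' @return AUC in \[0, 1\].
#' @export
rocAUC <- function(truth, scores) {
  rc <- .rankCounts(truth, scores)
  if (rc$P == 0 || rc$N == 0) stop("both classes required")
  x <- c(0, rc$fp / rc$N); y <- c(0, rc$tp / rc$P)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' ROC and precision-recall curves with AUCs
#'
#' Sweeps all score thresholds (grouping tied scores) to build the ROC curve
#' (AUC by the trapezoidal rule) and the precision-recall curve, whose AUC
#' uses the nonlinear interpolation of Davis & Goadrich between achievable
#' points: between adjacent threshold points, true positives are stepped one
#' at a time and false positives interpolated linearly, which is the correct
#' interpolation in PR space. The PR curve is anchored at recall 0 with the
#' precision of the highest-scoring group.
#'
#' @param truth labels in \{+1, -1\}; both classes must be present.
#' @param scores numeric scores, higher meaning more positive.
#' @return list of two elements, `roc` and `pr`, each with `points`
#'   (data.frame x, y) and `auc`.
#' @export
rocPrCurves <- function(truth, scores) {
  rc <- .rankCounts(truth, scores)
  if (rc$P == 0 || rc$N == 0) stop("both classes required")
  rocPoints <- data.frame(x = c(0, rc$fp / rc$N), y = c(0, rc$tp / rc$P))
  rocA <- sum(diff(rocPoints$x) *
                (utils::head(rocPoints$y, -1) + utils::tail(rocPoints$y, -1)) / 2)
  # Davis-Goadrich interpolation in (TP, FP) space
  tps <- rc$tp; fps <- rc$fp
  itp <- numeric(0); ifp <- numeric(0)
  prevTP <- tps[1]; prevFP <- fps[1]
  itp <- prevTP; ifp <- prevFP
  if (length(tps) > 1L) {
    for (i in 2:length(tps)) {
      dtp <- tps[i] - prevTP
      if (dtp > 0) {
        step <- (fps[i] - prevFP) / dtp
        news <- seq_len(dtp)
        itp <- c(itp, prevTP + news)
        ifp <- c(ifp, prevFP + step * news)
      } else {
        itp <- c(itp, tps[i]); ifp <- c(ifp, fps[i])
      }
      prevTP <- tps[i]; prevFP <- fps[i]
    }
  }
  rec <- itp / rc$P
  prec <- ifelse(itp + ifp > 0, itp / (itp + ifp), 1)
  # anchor at recall 0 with the earliest achievable precision
  rec <- c(0, rec); prec <- c(prec[1], prec)
  keep <- !duplicated(data.frame(rec, prec))
  prPoints <- data.frame(x = rec[keep], y = prec[keep])
  prA <- sum(diff(prPoints$x) *
               (utils::head(prPoints$y, -1) + utils::tail(prPoints$y, -1)) / 2)
  list(roc = list(points = rocPoints, auc = rocA),
       pr = list(points = prPoints, auc = prA))
}

#' Sequence similarity between binding sites or peptides
#'
#' Fraction of aligned positions with identical characters. A gap matches
#' only another gap.
#'
#' @param a,b equal-length sequences (16 residues for binding sites, 5 for
#'   peptides).
#' @return similarity in \[0, 1\].
#' @export
bindingSiteSimilarity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("length mismatch")
  mean(.splitChars(a) == .splitChars(b))
}

#' @rdname bindingSiteSimilarity
#' @export
peptideSimilarity <- bindingSiteSimilarity

#' Nearest-neighbour baseline predictor
#'
#' Finds the training domain(s) with maximal binding-site similarity to the
#' test domain; among their interactions, returns the label of the one whose
#' peptide is most similar to the test peptide. The score is the product of
#' the two similarities. Ties prefer the positive label, then the
#' lexicographically smallest peptide and domain id.
#'
#' @param testSite 16-residue binding site of the test domain.
#' @param testPeptide 5-residue test peptide.
#' @param training a \code{\linkS4class{PdzInteractionSet}}.
#' @return list with `label`, `score`, and the matched `domain_id` /
#'   `peptide`.
#' @export
nearestNeighbourPredict <- function(testSite, testPeptide, training) {
  stopifnot(is(training, "PdzInteractionSet"))
  it <- training@interactions
  if (!nrow(it)) stop("empty training set")
  dm <- training@domains
  dsim <- vapply(dm$binding_site, bindingSiteSimilarity, numeric(1),
                 b = testSite)
  names(dsim) <- dm$id
  best <- max(dsim)
  cand <- it[it$domain_id %in% dm$id[dsim == best], , drop = FALSE]
  psim <- vapply(cand$peptide, peptideSimilarity, numeric(1), b = testPeptide)
  ord <- order(-psim, -cand$label, cand$peptide, cand$domain_id)
  i <- ord[1L]
  list(label = cand$label[i], score = unname(best * psim[i]),
       domain_id = cand$domain_id[i], peptide = cand$peptide[i])
}

#' Fisher overlap test for scan validation
#'
#' One-sided significance of the overlap between predicted binders and known
#' binders inside a scanned universe: the upper-tail hypergeometric
#' probability of observing at least the given number of hits when
#' `nPredicted` tails are drawn from a universe containing `nKnown` known
#' binders.
#'
#' @param nHits predicted tails that are known binders.
#' @param nPredicted total predicted tails.
#' @param nKnown known binders in the universe.
#' @param nUniverse size of the scanned universe.
#' @return the one-sided p-value.
#' @export
fisherOverlapTest <- function(nHits, nPredicted, nKnown, nUniverse) {
  stopifnot(nHits >= 0, nPredicted >= 0, nKnown >= 0, nUniverse >= 1)
  if (nHits > min(nPredicted, nKnown) || max(nPredicted, nKnown) > nUniverse)
    stop("inconsistent counts")
  stats::phyper(nHits - 1, nKnown, nUniverse - nKnown, nPredicted,
                lower.tail = FALSE)
}

# -- cross-validation ---------------------------------------------------

.evalSplit <- function(X, y, trainIdx, testIdx, gamma, cost, weighted) {
  m <- trainSVM(X[trainIdx, , drop = FALSE], y[trainIdx], gamma = gamma,
                cost = cost, weighted = weighted)
  dec <- .decideMatrix(m, X[testIdx, , drop = FALSE])
  sc <- dec$score
  pred <- dec$label
  m <- suppressMessages(computeMetrics(y[testIdx], pred))
  both <- length(unique(y[testIdx])) == 2L
  cur <- if (both) rocPrCurves(y[testIdx], sc) else NULL
  list(scores = sc, metrics = m,
       rocAUC = if (both) cur$roc$auc else NA_real_,
       prAUC = if (both) cur$pr$auc else NA_real_)
}

#' Cross-validation of the SVM predictor
#'
#' Estimates generalization performance under the schemes used to
#' characterize domain-peptide predictors:
#'
#' * `ten_fold`: stratified interaction-level folds, each held out once.
#' * `leave_domains_out`: per repeat, a fraction of the domains is sampled
#'   and *all* their interactions held out (default 12 percent).
#' * `leave_peptides_out`: likewise for unique peptides (default 8 percent).
#' * `leave_both_out`: both holdouts applied together.
#' * `leave_one_domain_out`, `leave_one_peptide_out`: one entity per
#'   iteration; per-entity AUCs are returned together with the entity's
#'   similarity to its nearest training neighbour, for
#'   similarity-stratified analysis.
#'
#' A repeat whose held-out or training side lacks both classes is redrawn
#' (with a message), up to `retryCap` attempts.
#'
#' @param data a labelled \code{\linkS4class{PdzInteractionSet}}.
#' @param gamma,cost,weighted SVM parameters (see [trainSVM()]).
#' @param scheme the CV scheme.
#' @param encoding,cmap feature encoding configuration.
#' @param fractionDomains,fractionPeptides held-out fractions for the
#'   leave-percent-out schemes (defaults 0.12 and 0.08).
#' @param folds folds for `ten_fold`; default 10.
#' @param repeats repeats for the leave-percent-out schemes; default 10.
#' @param seed RNG seed controlling every split.
#' @param retryCap redraw limit for degenerate holdouts.
#' @return object of class `pdzscanCV`: a list with `scheme`, `perRun`
#'   (per-fold/repeat metrics and AUCs), `pooled` (truth and scores pooled
#'   across runs), `meanRocAUC`, `meanPrAUC`, and for the leave-one-out
#'   schemes `perEntity` (entity, AUCs, nearest-neighbour similarity).
#' @export
runCV <- function(data, gamma, cost = 1,
                  scheme = c("ten_fold", "leave_domains_out",
                             "leave_peptides_out", "leave_both_out",
                             "leave_one_domain_out", "leave_one_peptide_out"),
                  encoding = "contact_map", cmap = defaultContactMap(),
                  fractionDomains = 0.12, fractionPeptides = 0.08,
                  folds = 10L, repeats = 10L, seed = 1L, weighted = TRUE,
                  retryCap = 20L) {
  scheme <- match.arg(scheme)
  stopifnot(is(data, "PdzInteractionSet"))
  it <- data@interactions
  y <- it$label
  if (length(unique(y)) < 2L) stop("data must contain both labels")
  X <- encodeInteractions(data, method = encoding, cmap = cmap)
  perRun <- list(); pooledTruth <- integer(0); pooledScores <- numeric(0)
  perEntity <- NULL

  addRun <- function(res, runId, teIdx) {
    perRun[[length(perRun) + 1L]] <<- data.frame(
      run = runId, n_test = length(teIdx),
      tp = res$metrics$tp, fp = res$metrics$fp,
      tn = res$metrics$tn, fn = res$metrics$fn,
      tpr = res$metrics$tpr, fpr = res$metrics$fpr,
      precision = res$metrics$precision, f1 = res$metrics$f1,
      rocAUC = res$rocAUC, prAUC = res$prAUC)
    pooledTruth <<- c(pooledTruth, y[teIdx])
    pooledScores <<- c(pooledScores, res$scores)
  }

  if (scheme == "ten_fold") {
    foldId <- .stratifiedFolds(y, folds, seed)
    for (f in seq_len(folds)) {
      te <- which(foldId == f); tr <- which(foldId != f)
      res <- .evalSplit(X, y, tr, te, gamma, cost, weighted)
      addRun(res, f, te)
    }
  } else if (scheme %in% c("leave_domains_out", "leave_peptides_out",
                           "leave_both_out")) {
    doms <- unique(it$domain_id)
    peps <- unique(it$peptide)
    nd <- max(1L, round(fractionDomains * length(doms)))
    np <- max(1L, round(fractionPeptides * length(peps)))
    for (r in seq_len(repeats)) {
      ok <- FALSE
      for (attempt in seq_len(retryCap)) {
        draw <- .withSeed(seed + 1000L * r + attempt, {
          list(d = sample(doms, nd), p = sample(peps, np))
        })
        heldD <- scheme != "leave_peptides_out"
        heldP <- scheme != "leave_domains_out"
        te <- which((heldD & it$domain_id %in% draw$d) |
                      (heldP & it$peptide %in% draw$p))
        tr <- setdiff(seq_along(y), te)
        if (length(unique(y[te])) == 2L && length(unique(y[tr])) == 2L) {
          ok <- TRUE; break
        }
      }
      if (!ok) {
        message("repeat ", r, ": degenerate holdout after ", retryCap,
                " redraws, skipped")
        next
      }
      if (attempt > 1L) message("repeat ", r, ": holdout redrawn ",
                                attempt - 1L, " time(s)")
      res <- .evalSplit(X, y, tr, te, gamma, cost, weighted)
      addRun(res, r, te)
    }
  } else {
    # leave-one-entity-out
    byDomain <- scheme == "leave_one_domain_out"
    ents <- if (byDomain) unique(it$domain_id) else unique(it$peptide)
    dm <- data@domains
    rows <- list()
    for (e in ents) {
      te <- if (byDomain) which(it$domain_id == e) else
        which(it$peptide == e)
      tr <- setdiff(seq_along(y), te)
      if (length(unique(y[tr])) < 2L) next
      res <- .evalSplit(X, y, tr, te, gamma, cost, weighted)
      addRun(res, e, te)
      nn <- if (byDomain) {
        site <- dm$binding_site[match(e, dm$id)]
        others <- dm$binding_site[dm$id %in% unique(it$domain_id[tr])]
        max(vapply(others, bindingSiteSimilarity, numeric(1), b = site))
      } else {
        others <- unique(it$peptide[tr])
        max(vapply(others, peptideSimilarity, numeric(1), b = e))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        entity = e, n = length(te), rocAUC = res$rocAUC, prAUC = res$prAUC,
        nnSimilarity = nn, stringsAsFactors = FALSE)
    }
    perEntity <- do.call(rbind, rows)
  }

  perRun <- do.call(rbind, perRun)
  pooled <- rocPrCurves(pooledTruth, pooledScores)
  structure(list(scheme = scheme, perRun = perRun,
                 pooled = list(truth = pooledTruth, scores = pooledScores,
                               rocAUC = pooled$roc$auc, prAUC = pooled$pr$auc),
                 meanRocAUC = mean(perRun$rocAUC, na.rm = TRUE),
                 meanPrAUC = mean(perRun$prAUC, na.rm = TRUE),
                 perEntity = perEntity),
            class = "pdzscanCV")
}

#' @export
print.pdzscanCV <- function(x, ...) {
  cat("Cross-validation (", x$scheme, "): ", nrow(x$perRun), " runs\n",
      sep = "")
  cat("  mean ROC AUC:", round(x$meanRocAUC, 4),
      " mean PR AUC:", round(x$meanPrAUC, 4), "\n")
  cat("  pooled ROC AUC:", round(x$pooled$rocAUC, 4),
      " pooled PR AUC:", round(x$pooled$prAUC, 4), "\n")
  invisible(x)
}

#' Stratify leave-one-out AUCs by nearest-neighbour similarity
#'
#' Groups the per-entity AUCs of a leave-one-domain-out (or
#' leave-one-peptide-out) run into bins of the entity's binding-site (or
#' peptide) similarity to its nearest training neighbour, summarizing each
#' bin by its median AUCs. Performance rising with similarity indicates the
#' predictor depends on having seen similar training entities.
#'
#' @param cv a `pdzscanCV` from a leave-one-entity-out [runCV()].
#' @param breaks bin boundaries over \[0, 1\].
#' @return data.frame per bin: `bin`, `n`, `medianRocAUC`, `medianPrAUC`.
#' @export
similarityStratifiedAUC <- function(cv, breaks = c(0, 0.5, 0.7, 0.9, 1)) {
  if (is.null(cv$perEntity))
    stop("cv must come from a leave-one-entity-out scheme")
  pe <- cv$perEntity
  bin <- cut(pe$nnSimilarity, breaks = breaks, include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- which(bin == b)
    data.frame(bin = b, n = length(sel),
               medianRocAUC = if (length(sel))
                 stats::median(pe$rocAUC[sel], na.rm = TRUE) else NA_real_,
               medianPrAUC = if (length(sel))
                 stats::median(pe$prAUC[sel], na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
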