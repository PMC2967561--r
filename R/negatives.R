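# Artificial negative interactions for positive-only (phage display style)
# data: PWM-selected negatives plus the three baseline strategies used for
# comparison (random, shuffled, randomly selected).

#' Generate artificial negative interactions for one domain
#'
#' Positive-only experiments (phage display) give no non-binders, so
#' negatives must be constructed. The principal method, `pwm_selected`,
#' builds a PWM from the domain's positive peptides and selects, from the
#' pool of unique real binders of *all* domains, peptides that score strictly
#' below the minimum PWM score of the domain's own positives (so every
#' negative looks less like a binder than any observed binder) and have low
#' redundancy with each other. Candidates are visited in ascending score
#' order and accepted greedily: a candidate is kept only if it shares at most
#' `redundancyMaxIdentity` identical positions with every already-accepted
#' negative. Selection stops at `ceiling(ratio * n_positives)` negatives or
#' when candidates run out, in which case the result carries
#' `attr(, "insufficient") = TRUE` (such domains are the ones "difficult to
#' generate artificial negatives for" and can then be excluded from
#' training).
#'
#' Baselines: `random` draws peptides of five i.i.d. uniform residues;
#' `shuffled` permutes the residues of each positive; `randomly_selected`
#' samples uniformly (without replacement) from the same below-cutoff
#' candidate pool as `pwm_selected`, ignoring score order.
#'
#' @param domainId id attached to the returned interactions.
#' @param positives character vector of the domain's positive peptides.
#' @param pool character vector of unique positive peptides across all
#'   domains (required for `pwm_selected` and `randomly_selected`).
#' @param method one of `"pwm_selected"`, `"random"`, `"shuffled"`,
#'   `"randomly_selected"`.
#' @param ratio negatives per positive; default 2 (roughly the 745/363
#'   negative-to-positive ratio of the original phage-display set).
#' @param redundancyMaxIdentity maximum identical positions allowed between
#'   two selected negatives (0..5); default 3.
#' @param pseudocount pseudocount for the selection PWM.
#' @param seed RNG seed for the stochastic methods.
#' @return data.frame of interactions with columns `domain_id`, `peptide`,
#'   `label` (all -1) and `source` (the method name).
#' @export
generateNegatives <- function(domainId, positives, pool = NULL,
                              method = c("pwm_selected", "random", "shuffled",
                                         "randomly_selected"),
                              ratio = 2, redundancyMaxIdentity = 3L,
                              pseudocount = 0.01, seed = NULL) {
  method <- match.arg(method)
  stopifnot(ratio > 0, redundancyMaxIdentity >= 0L, redundancyMaxIdentity <= 5L)
  if (!length(positives)) stop("no positive peptides supplied")
  positives <- unique(positives)
  target <- as.integer(ceiling(ratio * length(positives)))
  insufficient <- FALSE

  if (method %in% c("pwm_selected", "randomly_selected")) {
    if (is.null(pool)) stop(method, " requires a candidate pool")
    pwm <- buildPWM(positives, pseudocount = pseudocount)
    cutoff <- min(scorePeptides(pwm, positives))
    cand <- setdiff(unique(pool), positives)
    sc <- scorePeptides(pwm, cand)
    keep <- sc < cutoff      # strictly below the minimum positive score
    cand <- cand[keep]; sc <- sc[keep]
    if (method == "pwm_selected") {
      ord <- order(sc, cand)  # ascending score, lexicographic tie-break
      cand <- cand[ord]
      sel <- character(0)
      selMat <- NULL
      for (p in cand) {
        if (length(sel) >= target) break
        pc <- .splitChars(p)
        if (length(sel)) {
          ident <- colSums(selMat == pc)
          if (any(ident > redundancyMaxIdentity)) next
        }
        sel <- c(sel, p)
        selMat <- cbind(selMat, pc)
      }
    } else {
      sel <- .withSeed(seed, {
        if (length(cand) <= target) cand else sample(cand, target)
      })
    }
    if (length(sel) < target) insufficient <- TRUE
  } else if (method == "random") {
    sel <- .withSeed(seed, {
      vapply(seq_len(target), function(i)
        paste(sample(.AA, .PEP_LEN, replace = TRUE), collapse = ""),
        character(1))
    })
  } else { # shuffled
    src <- rep_len(positives, target)
    sel <- .withSeed(seed, {
      vapply(src, function(p)
        paste(sample(.splitChars(p)), collapse = ""), character(1))
    })
    sel <- unname(sel)
  }

  out <- data.frame(domain_id = rep(domainId, length(sel)),
                    peptide = sel,
                    label = rep(-1L, length(sel)),
                    source = rep(method, length(sel)),
                    stringsAsFactors = FALSE)
  attr(out, "insufficient") <- insufficient
  out
}

#' Generate negatives for every domain of a positive-only set
#'
#' Applies [generateNegatives()] per domain, using the unique positive
#' peptides across all domains as the candidate pool, and returns the input
#' augmented with the generated negatives. Domains flagged insufficient
#' (fewer negatives available than requested) are reported in
#' `attr(, "insufficientDomains")`; set `dropInsufficient = TRUE` to exclude
#' them (positives and negatives) from the result.
#'
#' @param data positive-only \code{\linkS4class{PdzInteractionSet}}.
#' @inheritParams generateNegatives
#' @param dropInsufficient drop domains whose negative quota cannot be met.
#' @return a \code{\linkS4class{PdzInteractionSet}} with labels +1 and -1.
#' @export
addArtificialNegatives <- function(data, method = "pwm_selected", ratio = 2,
                                   redundancyMaxIdentity = 3L,
                                   pseudocount = 0.01, seed = NULL,
                                   dropInsufficient = FALSE) {
  stopifnot(is(data, "PdzInteractionSet"))
  it <- data@interactions
  if (any(it$label == -1L)) stop("input must be positive-only")
  pool <- unique(it$peptide)
  ids <- unique(it$domain_id)
  res <- vector("list", length(ids))
  insuff <- character(0)
  for (i in seq_along(ids)) {
    d <- ids[i]
    pos <- unique(it$peptide[it$domain_id == d])
    neg <- generateNegatives(d, pos, pool = pool, method = method,
                             ratio = ratio,
                             redundancyMaxIdentity = redundancyMaxIdentity,
                             pseudocount = pseudocount,
                             seed = if (is.null(seed)) NULL else seed + i)
    if (isTRUE(attr(neg, "insufficient"))) insuff <- c(insuff, d)
    res[[i]] <- neg
  }
  neg <- do.call(rbind, res)
  if (dropInsufficient && length(insuff)) {
    it <- it[!it$domain_id %in% insuff, , drop = FALSE]
    neg <- neg[!neg$domain_id %in% insuff, , drop = FALSE]
  }
  all <- rbind(it, neg)
  rownames(all) <- NULL
  dom <- data@domains[data@domains$id %in% unique(all$domain_id), , drop = FALSE]
  rownames(dom) <- NULL
  out <- methods::new("PdzInteractionSet", interactions = all, domains = dom)
  attr(out, "insufficientDomains") <- insuff
  out
}

#' Summarize generated negatives per domain
#'
#' @param sets either a \code{\linkS4class{PdzInteractionSet}} or a named
#'   list mapping domain id to a vector/data.frame of negatives.
#' @return data.frame with columns `domain_id` and `n_negatives`, plus a
#'   `"total"` attribute; empty input gives an empty table.
#' @export
negativesReport <- function(sets) {
  if (is(sets, "PdzInteractionSet")) {
    it <- sets@interactions
    neg <- it[it$label == -1L, , drop = FALSE]
    counts <- table(neg$domain_id)
  } else if (is.list(sets)) {
    counts <- vapply(sets, function(x) if (is.data.frame(x)) nrow(x) else
      length(x), integer(1))
  } else {
    stop("unsupported input")
  }
  if (!length(counts)) {
    out <- data.frame(domain_id = character(0), n_negatives = integer(0))
    attr(out, "total") <- 0L
    return(out)
  }
  out <- data.frame(domain_id = names(counts),
                    n_negatives = as.integer(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$domain_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- sum(out$n_negatives)
  out
}
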