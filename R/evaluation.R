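# Ranking and classification metrics for scored decoy sets: ROC/AUC with
# midrank tie handling, the step-sum average precision, top-N hit rates with
# an explicit deterministic tie rule, and the resampled AP comparison.

check_scored_set <- function(set) {
  need <- c("decoy_id", "score", "label")
  if (!all(need %in% names(set))) {
    stop("scored set needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(set$label %in% c(0L, 1L))) stop("labels must be 0/1")
  set
}

#' ROC curve and AUC of a scored decoy set
#'
#' AUC via the rank (Mann-Whitney) formulation; tied scores are handled by
#' midranks, equivalent to counting ties as half-successes.
#'
#' @param set data.frame with columns `decoy_id`, `score`, `label` (0/1).
#' @return list with `curve` (data.frame `threshold`, `tpr`, `fpr`) and
#'   `auc`.
#' @export
roc_auc <- function(set) {
  set <- check_scored_set(set)
  n_pos <- sum(set$label == 1L); n_neg <- sum(set$label == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: need at least one positive and one negative")
  }
  r <- rank(set$score, ties.method = "average")
  auc <- (sum(r[set$label == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(set$score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(set$label == 1L & set$score >= t) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(set$label == 0L & set$score >= t) / n_neg,
                numeric(1))
  list(curve = data.frame(threshold = thr, tpr = tpr, fpr = fpr), auc = auc)
}

#' Average precision of a scored decoy set
#'
#' The step-sum `AP = sum_n (R_n - R_{n-1}) P_n` over thresholds at each
#' distinct score in descending order, with `R_0 = 0` and no interpolation;
#' tied scores enter a threshold group jointly.
#'
#' @inheritParams roc_auc
#' @return list with `curve` (data.frame `threshold`, `precision`, `recall`)
#'   and `ap`.
#' @export
average_precision <- function(set) {
  set <- check_scored_set(set)
  n_pos <- sum(set$label == 1L)
  if (n_pos == 0L) stop("AP undefined: no positive examples")
  thr <- sort(unique(set$score), decreasing = TRUE)
  prec <- numeric(length(thr)); rec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    sel <- set$score >= thr[i]
    prec[i] <- sum(set$label[sel] == 1L) / sum(sel)
    rec[i] <- sum(set$label[sel] == 1L) / n_pos
  }
  ap <- sum((rec - c(0, rec[-length(rec)])) * prec)
  list(curve = data.frame(threshold = thr, precision = prec, recall = rec),
       ap = ap)
}

# Deterministic ranking order: descending score, ties broken by decoy_id
# lexicographic order (C locale).
rank_order <- function(set) {
  order(-set$score, rank(set$decoy_id, ties.method = "first"))
}

#' Hit rate in the top N ranked decoys
#'
#' `100 * n_near_native / N`, where `n_near_native` counts label-1 decoys
#' among the top N by descending score (ties broken by `decoy_id`).
#'
#' @inheritParams roc_auc
#' @param n top-N cutoff; clamped to the set size with a warning.
#' @return hit rate percentage.
#' @export
hit_rate <- function(set, n) {
  set <- check_scored_set(set)
  stopifnot(n >= 1L)
  if (n > nrow(set)) {
    warning("n = ", n, " exceeds set size ", nrow(set), "; clamping")
    n <- nrow(set)
  }
  top <- set[rank_order(set)[seq_len(n)], ]
  100 * sum(top$label == 1L) / n
}

#' Cumulative hits curve
#'
#' Number of near-native decoys among the top N for N = 1..n_max;
#' non-decreasing by construction.
#'
#' @inheritParams hit_rate
#' @param n_max largest N.
#' @return data.frame with columns `N` and `hits`.
#' @export
hits_curve <- function(set, n_max) {
  set <- check_scored_set(set)
  n_max <- min(n_max, nrow(set))
  ord <- rank_order(set)
  hits <- cumsum(set$label[ord] == 1L)[seq_len(n_max)]
  data.frame(N = seq_len(n_max), hits = hits)
}

#' Per-target hit-rate table
#'
#' @inheritParams roc_auc
#' @param ns top-N cutoffs to report.
#' @return data.frame: `target_id` plus one `top<N>_hr` column per cutoff.
#' @export
hit_rate_table <- function(set, ns = c(5L, 10L)) {
  set <- check_scored_set(set)
  if (!"target_id" %in% names(set)) set$target_id <- "all"
  targets <- sort(unique(set$target_id))
  out <- data.frame(target_id = targets)
  for (n in ns) {
    out[[sprintf("top%d_hr", n)]] <- vapply(targets, function(t) {
      suppressWarnings(hit_rate(set[set$target_id == t, ], n))
    }, numeric(1))
  }
  out
}

#' Resampled comparison of two models' average precision
#'
#' For `n_resamples` draws, the same seeded `fraction` of decoys (without
#' replacement) is scored by both models and the difference in AP recorded;
#' subsamples with no positive decoy are redrawn. The mean difference is
#' tested against zero with a one-sample t test (the Welch formulation of
#' the paired location test); with identical inputs the difference is
#' degenerate and the p-value is 1 by convention.
#'
#' @param set_1,set_2 scored sets over identical `decoy_id`s.
#' @param n_resamples number of subsamples.
#' @param fraction subsample fraction.
#' @param seed RNG seed.
#' @param n_comparisons Bonferroni factor applied to the p-value.
#' @return list: `mean_delta`, `p_value`, `deltas`, `n_redrawn`, `alpha`.
#' @export
resampled_ap_comparison <- function(set_1, set_2, n_resamples = 1000L,
                                    fraction = 0.10, seed = 1L,
                                    n_comparisons = 1L) {
  set_1 <- check_scored_set(set_1); set_2 <- check_scored_set(set_2)
  if (!setequal(set_1$decoy_id, set_2$decoy_id) ||
      nrow(set_1) != nrow(set_2)) {
    stop("the two scored sets must cover identical decoy ids")
  }
  set_2 <- set_2[match(set_1$decoy_id, set_2$decoy_id), ]
  n <- nrow(set_1)
  n_sub <- max(2L, round(fraction * n))
  deltas <- numeric(n_resamples)
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_resamples)) {
      repeat {
        idx <- sample.int(n, n_sub)
        if (sum(set_1$label[idx] == 1L) > 0L) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100L * n_resamples) {
          stop("could not draw subsamples containing positives")
        }
      }
      ap1 <- average_precision(set_1[idx, ])$ap
      ap2 <- average_precision(set_2[idx, ])$ap
      deltas[b] <- ap1 - ap2
    }
  })
  p <- if (stats::sd(deltas) == 0) 1 else {
    stats::t.test(deltas, mu = 0)$p.value
  }
  p <- min(1, p * n_comparisons)
  list(mean_delta = mean(deltas), p_value = p, deltas = deltas,
       n_redrawn = n_redrawn, alpha = 0.05)
}

#' Summarize a scored set
#'
#' Global AUC and AP plus per-target hit-rate columns; the JSON-ready bundle
#' written by the command-line `evaluate` workflow.
#'
#' @inheritParams roc_auc
#' @param ns top-N cutoffs for the hit table.
#' @return list with `auc`, `ap`, `n`, `n_positive`, `hit_table`.
#' @export
evaluate_scored_set <- function(set, ns = c(5L, 10L)) {
  set <- check_scored_set(set)
  list(auc = roc_auc(set)$auc,
       ap = average_precision(set)$ap,
       n = nrow(set),
       n_positive = sum(set$label == 1L),
       hit_table = hit_rate_table(set, ns))
}
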