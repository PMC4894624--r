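#' Rank-cutoff ROC evaluation over replicates
#'
#' Sweeps a rank cutoff k over replicated rankings: at each k, sensitivity
#' is the fraction of causal units (variants or genes) ranked at or above
#' k across replicates, and specificity the fraction of non-causal units
#' ranked below k. The AUC is the trapezoidal area under the
#' (1 - specificity, sensitivity) curve with (0,0) and (1,1) endpoints
#' appended.
#'
#' @param ranked_lists list (one element per replicate) of character
#'   vectors of unit ids in rank order (rank 1 first, complete rankings).
#' @param truth list (same length) of character vectors of causal unit
#'   ids per replicate; must be non-empty overall.
#' @param rank_cutoffs integer cutoffs; defaults to 1..max ranking length.
#' @return list of class `roc_eval`: `points` (data frame `cutoff`,
#'   `sensitivity`, `specificity`) and `auc`.
#' @export
roc_evaluate <- function(ranked_lists, truth, rank_cutoffs = NULL) {
  stopifnot(length(ranked_lists) == length(truth))
  if (sum(lengths(truth)) == 0L) stop("empty truth set")
  if (is.null(rank_cutoffs))
    rank_cutoffs <- seq_len(max(lengths(ranked_lists)))
  causal_ranks <- numeric(0)
  null_ranks <- numeric(0)
  for (r in seq_along(ranked_lists)) {
    rk <- seq_along(ranked_lists[[r]])
    is_causal <- ranked_lists[[r]] %in% truth[[r]]
    causal_ranks <- c(causal_ranks, rk[is_causal])
    null_ranks <- c(null_ranks, rk[!is_causal])
  }
  sens <- vapply(rank_cutoffs, function(k) mean(causal_ranks <= k), 0)
  spec <- vapply(rank_cutoffs, function(k) mean(null_ranks > k), 0)
  fpr <- 1 - spec
  o <- order(fpr, sens)
  xs <- c(0, fpr[o], 1)
  ys <- c(0, sens[o], 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  structure(list(points = data.frame(cutoff = rank_cutoffs,
                                     sensitivity = sens,
                                     specificity = spec),
                 auc = auc),
            class = "roc_eval")
}

#' @export
print.roc_eval <- function(x, ...) {
  cat(sprintf("Rank-cutoff ROC: AUC = %.4f over %d cutoff(s)\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' Bootstrap standard error of an AUC difference
#'
#' Resamples replicates with replacement and recomputes
#' `roc_evaluate()$auc` for two methods on the same replicates, returning
#' the bootstrap standard error of the AUC difference. Used to judge
#' whether one prioritization strategy dominates another beyond
#' Monte-Carlo noise.
#'
#' @param ranked_a,ranked_b per-replicate rankings for the two methods.
#' @param truth_a,truth_b per-replicate truth sets (unit types may differ
#'   between methods, e.g. variants vs genes).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return list: `diff` (AUC_a - AUC_b on the original replicates), `se`,
#'   `auc_a`, `auc_b`.
#' @export
auc_diff_bootstrap <- function(ranked_a, truth_a, ranked_b, truth_b,
                               n_boot = 200L, seed = 1L) {
  stopifnot(length(ranked_a) == length(ranked_b))
  n <- length(ranked_a)
  auc_a <- roc_evaluate(ranked_a, truth_a)$auc
  auc_b <- roc_evaluate(ranked_b, truth_b)$auc
  set.seed(seed)
  diffs <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    roc_evaluate(ranked_a[idx], truth_a[idx])$auc -
      roc_evaluate(ranked_b[idx], truth_b[idx])$auc
  }, 0)
  list(diff = auc_a - auc_b, se = stats::sd(diffs),
       auc_a = auc_a, auc_b = auc_b)
}
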