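#' Corrected resampled paired t-test
#'
#' Compares two classifiers over the same repeated cross-validation
#' schedule using the variance-inflated paired t statistic
#' `t = mean(d) / sqrt((1/n + n2/n1) * var(d))` with `d` the per-run score
#' differences, `n2/n1` the test/train size ratio (1/9 for 10-fold CV) and
#' `var` the unbiased sample variance; `df = n - 1`, two-tailed. The
#' inflation accounts for the overlap between CV training sets; at
#' `test_train_ratio = 0` the statistic reduces to the classic paired t.
#'
#' Degenerate runs: `var(d) = 0` with `mean(d) = 0` gives `t = 0` (not
#' significant); `var(d) = 0` with `mean(d) != 0` is flagged as an
#' infinite t and reported significant.
#'
#' @param scores_a,scores_b per-run scores (e.g. fold accuracies), equal
#'   length `n >= 2`, same fold/seed schedule.
#' @param test_train_ratio `n2/n1`; `1/9` for 10-fold CV.
#' @param alpha two-tailed significance level.
#' @return A list with `t`, `df`, `p_value`, `significant`, `mean_diff`
#'   and `degenerate`.
#' @export
corrected_ttest <- function(scores_a, scores_b, test_train_ratio = 1 / 9,
                            alpha = 0.05) {
  if (length(scores_a) != length(scores_b))
    stop("paired runs must have equal length")
  n <- length(scores_a)
  if (n < 2) stop("need at least two paired runs")
  d <- scores_a - scores_b
  md <- mean(d)
  vd <- stats::var(d)
  df <- n - 1L
  if (vd == 0) {
    if (md == 0)
      return(list(t = 0, df = df, p_value = 1, significant = FALSE,
                  mean_diff = 0, degenerate = FALSE))
    return(list(t = sign(md) * Inf, df = df, p_value = 0,
                significant = TRUE, mean_diff = md, degenerate = TRUE))
  }
  t <- md / sqrt((1 / n + test_train_ratio) * vd)
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p_value = p, significant = p < alpha,
       mean_diff = md, degenerate = FALSE)
}

#' Rank classifiers against a baseline
#'
#' Mean and SD per classifier plus the corrected paired t-test of each
#' against the baseline, marked win/tie/loss. Rows are stably sorted by
#' mean score, best first.
#'
#' @param all_runs named list of per-run score vectors sharing one
#'   schedule.
#' @param baseline name of the baseline classifier (default: first).
#' @param test_train_ratio `n2/n1` of the CV schedule.
#' @param alpha two-tailed significance level.
#' @return A data.frame with `name`, `mean`, `sd`, `t`, `p_value`,
#'   `outcome` (`win`/`tie`/`loss` vs the baseline; the baseline row is
#'   `baseline`).
#' @export
rank_classifiers <- function(all_runs, baseline = names(all_runs)[1],
                             test_train_ratio = 1 / 9, alpha = 0.05) {
  stopifnot(length(all_runs) >= 1, baseline %in% names(all_runs))
  base <- all_runs[[baseline]]
  rows <- lapply(names(all_runs), function(nm) {
    sc <- all_runs[[nm]]
    if (nm == baseline) {
      t <- NA_real_; p <- NA_real_; outcome <- "baseline"
    } else {
      tt <- corrected_ttest(sc, base, test_train_ratio, alpha)
      t <- tt$t; p <- tt$p_value
      outcome <- if (!tt$significant) "tie"
                 else if (tt$mean_diff > 0) "win" else "loss"
    }
    data.frame(name = nm, mean = mean(sc), sd = stats::sd(sc),
               t = t, p_value = p, outcome = outcome,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean), , drop = FALSE]
}
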