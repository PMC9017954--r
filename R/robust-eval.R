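# Robust evaluation statistics: skipped correlation (MCD centre +
# projection distances + ideal-fourths boxplot rule, Pearson on survivors),
# squared-error comparison against the mean-assignment baseline,
# normality-gated two-sample tests, and the outlier-burden test.

# Ideal fourths (interpolated quartiles).
ideal_fourths <- function(x) {
  x <- sort(x)
  n <- length(x)
  j <- floor(n / 4 + 5 / 12)
  h <- n / 4 + 5 / 12 - j
  q1 <- (1 - h) * x[j] + h * x[j + 1]
  k <- n - j + 1
  q2 <- (1 - h) * x[k] + h * x[k - 1]
  c(q1, q2)
}

#' Skipped correlation
#'
#' Robust correlation that removes bivariate outliers before computing
#' Pearson's r. The robust centre is the minimum-covariance-determinant
#' (MCD) location; every point defines a projection direction from the
#' centre, all points are projected onto it, and a point is flagged if its
#' projection falls outside the ideal-fourths boxplot bound
#' `[q1 - 1.5 IQR, q3 + 1.5 IQR]` on any direction. Pearson's correlation
#' and a t-based p-value are then computed on the unflagged pairs.
#'
#' @param x,y paired numeric vectors, n >= 10.
#' @param method correlation on the surviving pairs: `"pearson"` (default)
#'   or `"spearman"`.
#' @return list with `r`, `p`, `n_used`, `flags` (logical vector of
#'   removed pairs).
#' @export
skipped_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 10L) stop("skipped correlation needs n >= 10", call. = FALSE)
  if (sample_sd(x) == 0 || sample_sd(y) == 0)
    stop("degenerate (constant) input", call. = FALSE)
  m <- cbind(x, y)
  centre <- tryCatch(MASS::cov.mcd(m)$center,
                     error = function(e) apply(m, 2, stats::median))
  flags <- rep(FALSE, n)
  dm <- sweep(m, 2, centre)
  for (i in seq_len(n)) {
    d <- dm[i, ]
    nrm <- sqrt(sum(d^2))
    if (nrm < .Machine$double.eps) next
    proj <- drop(dm %*% (d / nrm))
    q <- ideal_fourths(proj)
    iqr <- q[2] - q[1]
    flags <- flags | proj < q[1] - 1.5 * iqr | proj > q[2] + 1.5 * iqr
  }
  keep <- !flags
  n_used <- sum(keep)
  if (n_used < 3L) stop("too few pairs survive outlier removal",
                        call. = FALSE)
  r <- stats::cor(x[keep], y[keep], method = method)
  tstat <- r * sqrt((n_used - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n_used - 2)
  list(r = r, p = p, n_used = n_used, flags = flags)
}

#' Compare model squared errors to the mean-assignment baseline
#'
#' One-sided Wilcoxon signed-rank test that a model's per-participant
#' squared d_s errors are smaller than those of the baseline that assigns
#' every test participant the training-set average d_s.
#'
#' @param predicted,actual per-participant d_s values for one feature.
#' @param training_mean the training-set mean d_s for the feature.
#' @return list with `W`, `p`, `model_mse`, `baseline_mse`; `p` is `NA`
#'   with an explanatory `note` when every paired difference is zero.
#' @export
compare_to_mean_baseline <- function(predicted, actual, training_mean) {
  stopifnot(length(predicted) == length(actual))
  model_err <- (predicted - actual)^2
  base_err <- (training_mean - actual)^2
  d <- model_err - base_err
  if (all(d == 0))
    return(list(W = NA_real_, p = NA_real_,
                model_mse = mean(model_err), baseline_mse = mean(base_err),
                note = "all paired differences are zero; test undefined"))
  wt <- suppressWarnings(
    stats::wilcox.test(model_err, base_err, paired = TRUE,
                       alternative = "less"))
  list(W = unname(wt$statistic), p = wt$p.value,
       model_mse = mean(model_err), baseline_mse = mean(base_err))
}

#' Normality-gated two-sample test
#'
#' Shapiro-Wilk tests each sample at alpha = 0.05; if either rejects
#' normality the comparison uses a Mann-Whitney U test, otherwise an
#' independent two-sample t-test.
#'
#' @param sample_a,sample_b numeric samples, each n >= 3.
#' @param alternative passed to the chosen test.
#' @return list with `test` (`"t"` or `"mann-whitney"`), `statistic`, `p`.
#' @export
gated_two_sample_test <- function(sample_a, sample_b,
                                  alternative = "two.sided") {
  stopifnot(length(sample_a) >= 3L, length(sample_b) >= 3L)
  sw <- function(s) {
    if (length(s) > 5000L) s <- s[seq(1L, length(s), length.out = 5000L)]
    if (stats::sd(s) == 0) return(0)
    stats::shapiro.test(s)$p.value
  }
  normal <- sw(sample_a) >= 0.05 && sw(sample_b) >= 0.05
  if (normal) {
    tt <- stats::t.test(sample_a, sample_b, alternative = alternative)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(sample_a, sample_b, alternative = alternative))
    list(test = "mann-whitney", statistic = unname(wt$statistic),
         p = wt$p.value)
  }
}

#' Outlier-burden test between sensitive and resilient participants
#'
#' One-sided Mann-Whitney U test of whether stress-sensitive participants
#' had more hourly records flagged as outliers than stress-resilient ones.
#' A significant result would indicate that the outlier filter removes
#' label-informative hours.
#'
#' @param outlier_counts per-participant flagged-hour counts.
#' @param resilient logical labels aligned with `outlier_counts`.
#' @return list with `U`, `p`.
#' @export
outlier_burden_test <- function(outlier_counts, resilient) {
  stopifnot(length(outlier_counts) == length(resilient))
  resilient <- as.logical(resilient)
  if (!any(resilient) || all(resilient))
    stop("both label groups must be non-empty", call. = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(outlier_counts[!resilient],
                       outlier_counts[resilient],
                       alternative = "greater"))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Per-feature evaluation report for one model
#'
#' Skipped correlations between actual and predicted per-participant d_s,
#' plus the Wilcoxon comparison against the mean-assignment baseline, for
#' each of the five hourly features.
#'
#' @param actual_ds,predicted_ds data.frames with `participant_id` and one
#'   `<feature>__cohens_ds__DIFF` column per feature.
#' @param training_means named numeric vector of training-set mean d_s per
#'   d_s column.
#' @return data.frame keyed by feature with `r`, `r_p`, `n_used`,
#'   `n_flagged`, `wilcoxon_W`, `wilcoxon_p`, `model_mse`, `baseline_mse`.
#' @export
evaluate_predictions <- function(actual_ds, predicted_ds, training_means) {
  predicted_ds <- predicted_ds[match(actual_ds$participant_id,
                                     predicted_ds$participant_id), ]
  cols <- grep("__cohens_ds__DIFF$", names(actual_ds), value = TRUE)
  rows <- lapply(cols, function(nm) {
    a <- actual_ds[[nm]]
    pr <- predicted_ds[[nm]]
    sc <- skipped_correlation(a, pr)
    cb <- compare_to_mean_baseline(pr, a, training_means[[nm]])
    data.frame(feature = sub("__cohens_ds__DIFF$", "", nm),
               r = sc$r, r_p = sc$p, n_used = sc$n_used,
               n_flagged = sum(sc$flags),
               wilcoxon_W = cb$W, wilcoxon_p = cb$p,
               model_mse = cb$model_mse, baseline_mse = cb$baseline_mse,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
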