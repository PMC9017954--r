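# Per-participant summary indicators of the baseline (A) and internship (B)
# multivariate hourly feature distributions.

#' Pearson's skew coefficient
#'
#' `3 * (mean - median) / sd`, with the sample (n-1 denominator) standard
#' deviation and the mid-rank median. The sign encodes the direction of the
#' distribution tail; zero for symmetric samples.
#'
#' @param sample numeric vector, length >= 2.
#' @return a single numeric skew value.
#' @examples
#' pearson_skew(c(1, 2, 3))          # 0
#' pearson_skew(c(1, 2, 3, 4, 100))  # strongly right-skewed
#' @export
pearson_skew <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 2L || anyNA(sample))
    stop("pearson_skew needs >= 2 non-missing values", call. = FALSE)
  s <- sample_sd(sample)
  if (!is.finite(s) || s <= 0)
    stop("degenerate sample: zero standard deviation", call. = FALSE)
  3 * (mean(sample) - stats::median(sample)) / s
}

#' Cohen's d_s between two periods from summary statistics
#'
#' Standardized difference in means between an internship-period (B) and a
#' baseline-period (A) feature distribution, using the pooled standard
#' deviation with (n-1) weights:
#' `(mean_b - mean_a) / sqrt(((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a+n_b-2))`.
#'
#' @param mean_a,sd_a,n_a baseline mean, sample SD and hour count.
#' @param mean_b,sd_b,n_b internship mean, sample SD and hour count.
#' @return a single numeric effect size; positive when B exceeds A.
#' @export
cohens_ds <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2L || n_b < 2L)
    stop("cohens_ds needs n >= 2 in both periods", call. = FALSE)
  pooled <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (!is.finite(pooled) || pooled <= 0)
    stop("degenerate sample: zero pooled standard deviation", call. = FALSE)
  (mean_b - mean_a) / pooled
}

#' Cohen's d_s from raw points
#'
#' Convenience wrapper around [cohens_ds()] computing the summary statistics
#' from two raw samples.
#'
#' @param a,b numeric vectors of baseline and internship hourly values.
#' @export
cohens_ds_points <- function(a, b) {
  cohens_ds(mean(a), sample_sd(a), length(a),
            mean(b), sample_sd(b), length(b))
}

#' Construct a period distribution for one participant
#'
#' A thin container for the n x 5 table of hourly feature vectors of one
#' participant in one period (baseline `"A"` or internship `"B"`).
#'
#' @param participant_id identifier.
#' @param label `"A"` (baseline) or `"B"` (internship).
#' @param points data.frame with the five feature columns `step_count`,
#'   `sleep_seconds`, `in_bed_seconds`, `mean_heart_rate`, `mood`.
#' @return an object of class `period_distribution`.
#' @export
period_distribution <- function(participant_id, label = c("A", "B"), points) {
  label <- match.arg(label)
  missing_cols <- setdiff(FEATURES, names(points))
  if (length(missing_cols))
    stop("points is missing feature columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  structure(
    list(participant_id = participant_id, label = label,
         points = as.data.frame(points)[FEATURES], n = nrow(points)),
    class = "period_distribution")
}

#' @export
print.period_distribution <- function(x, ...) {
  cat(sprintf("period_distribution: participant %s, period %s, %d hours x %d features\n",
              x$participant_id, x$label, x$n, length(FEATURES)))
  invisible(x)
}

#' Canonical names of the 37 indicators
#'
#' `<feature>__<metric>__<period>` for the 35 per-feature statistics plus
#' the two data counts.
#'
#' @return character vector of length 37.
#' @export
indicator_names <- function() {
  c(as.vector(t(outer(FEATURES, c("mean__BL", "sd__BL", "skew__BL",
                                  "mean__INTERN", "sd__INTERN", "skew__INTERN",
                                  "cohens_ds__DIFF"),
                      paste, sep = "__"))),
    "hours__count__BL", "hours__count__INTERN")
}

#' Build the 37-indicator vector for one participant
#'
#' For each of the five hourly features, computes the mean, sample SD and
#' Pearson skew of both the baseline and internship distributions plus the
#' between-period Cohen's d_s (5 x 7 = 35 indicators), and appends the hour
#' counts of the two periods (2 more), for 37 indicators in total.
#'
#' @param dist_a baseline [period_distribution()] (label `"A"`).
#' @param dist_b internship [period_distribution()] (label `"B"`).
#' @return a named numeric vector with 37 entries; names follow the
#'   `<feature>__<metric>__<period>` scheme.
#' @export
build_indicator_vector <- function(dist_a, dist_b) {
  stopifnot(inherits(dist_a, "period_distribution"),
            inherits(dist_b, "period_distribution"))
  if (dist_a$label != "A" || dist_b$label != "B")
    stop("expected a baseline ('A') and an internship ('B') distribution",
         call. = FALSE)
  if (!identical(dist_a$participant_id, dist_b$participant_id))
    stop("both distributions must belong to one participant", call. = FALSE)
  out <- numeric(0)
  for (f in FEATURES) {
    a <- dist_a$points[[f]]
    b <- dist_b$points[[f]]
    vals <- tryCatch(
      c(mean(a), sample_sd(a), pearson_skew(a),
        mean(b), sample_sd(b), pearson_skew(b),
        cohens_ds_points(a, b)),
      error = function(e) stop(sprintf("feature '%s': %s", f,
                                       conditionMessage(e)), call. = FALSE))
    out <- c(out, vals)
  }
  out <- c(out, length(dist_a$points[[1L]]), length(dist_b$points[[1L]]))
  names(out) <- indicator_names()
  out
}

#' Build the indicator table for a cohort of cleaned hourly records
#'
#' Splits each participant's cleaned hourly records into the baseline (`BL`)
#' and pooled internship (`Q1`-`Q4`) periods and computes one 37-indicator
#' row per participant via [build_indicator_vector()].
#'
#' @param records cleaned hourly records with columns `participant_id`,
#'   `period` and the five feature columns.
#' @return data.frame with `participant_id` plus the 37 indicator columns.
#' @export
build_indicator_table <- function(records) {
  stopifnot(all(c("participant_id", "period", FEATURES) %in% names(records)))
  ids <- unique(records$participant_id)
  rows <- lapply(ids, function(id) {
    rec <- records[records$participant_id == id, , drop = FALSE]
    a <- rec[rec$period == "BL", FEATURES, drop = FALSE]
    b <- rec[rec$period != "BL", FEATURES, drop = FALSE]
    build_indicator_vector(period_distribution(id, "A", a),
                           period_distribution(id, "B", b))
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(participant_id = ids, out, stringsAsFactors = FALSE)
}
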