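# Shared fixtures: small synthetic cohorts and cleaned records built once
# per test run.

two_cluster_shifts <- function(sleep1 = 0.6, sleep2 = -0.4, prop1 = 0.8) {
  list(
    list(prop = prop1,
         mean_shift = c(step_count = 0.1, sleep_seconds = sleep1,
                        in_bed_seconds = sleep1, mean_heart_rate = -0.1,
                        mood = 0.25),
         sd_scale = c(step_count = 1, sleep_seconds = 1, in_bed_seconds = 1,
                      mean_heart_rate = 1, mood = 1)),
    list(prop = 1 - prop1,
         mean_shift = c(step_count = -0.3, sleep_seconds = sleep2,
                        in_bed_seconds = sleep2, mean_heart_rate = 0.5,
                        mood = -0.35),
         sd_scale = c(step_count = 1, sleep_seconds = 1, in_bed_seconds = 1,
                      mean_heart_rate = 1, mood = 1)))
}

no_shift_clusters <- function() {
  zero <- c(step_count = 0, sleep_seconds = 0, in_bed_seconds = 0,
            mean_heart_rate = 0, mood = 0)
  one <- zero + 1
  list(list(prop = 1, mean_shift = zero, sd_scale = one))
}

small_config <- function(n = 20, seed = 1, ...) {
  cohort_config(n_participants = n, baseline_weeks = 2,
                weeks_per_quarter = 1, seed = seed, ...)
}

# memoised small cleaned cohort used by several test files
small_clean_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config(n = 25, seed = 401)
      coh <- apply_missingness(simulate_cohort(cfg))
      cl <- clean_hourly(coh$hourly, coh$ema, seed = 402)
      cache <<- list(cohort = coh, records = cl$records,
                     report = cl$report, forest = cl$forest, config = cfg)
    }
    cache
  }
})

# raw hourly records for one hand-built participant, on the hourly grid
hand_hourly <- function(participant_id = "H1", hours, step_count = 0,
                        sleep_seconds = 0, in_bed_seconds = NULL,
                        mean_heart_rate = 70) {
  if (is.null(in_bed_seconds)) in_bed_seconds <- sleep_seconds
  origin <- as.POSIXct("2020-05-01 00:00:00", tz = "UTC")
  data.frame(participant_id = participant_id, period = "BL",
             hour_start = origin + hours * 3600,
             step_count = step_count, sleep_seconds = sleep_seconds,
             in_bed_seconds = in_bed_seconds,
             mean_heart_rate = mean_heart_rate,
             stringsAsFactors = FALSE)
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
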