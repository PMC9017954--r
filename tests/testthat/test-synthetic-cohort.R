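# Synthetic cohort generator: configuration validation, marginal families,
# planted structure, missingness, determinism.

test_that("invalid configurations name the offending field", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(ema_completion_rate = 1.2),
               "ema_completion_rate")
  bad_classes <- list(list(gamma = c(0, 1, 0), prop = 0.5),
                      list(gamma = c(0, 2, 0), prop = 0.6))
  expect_error(cohort_config(trajectory_classes = bad_classes),
               "trajectory_classes")
  bad_clusters <- list(list(prop = 1, mean_shift = c(step_count = 1),
                            sd_scale = c(step_count = 1)))
  expect_error(cohort_config(shift_clusters = bad_clusters),
               "shift_clusters")
})

test_that("hourly streams respect physical ranges and in_bed >= sleep", {
  coh <- simulate_cohort(small_config(n = 12, seed = 88))
  h <- coh$hourly
  expect_true(all(h$step_count[!is.na(h$step_count)] >= 0))
  expect_true(all(h$sleep_seconds[!is.na(h$sleep_seconds)] >= 0))
  expect_true(all(h$in_bed_seconds >= h$sleep_seconds, na.rm = TRUE))
  expect_true(all(h$mean_heart_rate >= 35 & h$mean_heart_rate <= 204))
  expect_true(all(coh$ema$mood %in% 1:10))
  # at most one record per participant-hour
  expect_false(anyDuplicated(paste(h$participant_id, h$hour_start)) > 0)
  # every participant with internship records has a baseline segment
  with_int <- unique(h$participant_id[h$period != "BL"])
  with_bl <- unique(h$participant_id[h$period == "BL"])
  expect_true(all(with_int %in% with_bl))
})

test_that("step counts are zero-inflated and right-skewed; sleep is zero-heavy", {
  coh <- simulate_cohort(small_config(n = 15, seed = 99))
  steps <- coh$hourly$step_count[!is.na(coh$hourly$step_count)]
  expect_gt(mean(steps == 0), 0.3)
  expect_gt(mean(steps) , median(steps))  # right skew
  slp <- coh$hourly$sleep_seconds[!is.na(coh$hourly$sleep_seconds)]
  expect_gt(mean(slp == 0), 0.5)
  expect_gt(max(slp), 3600)  # occasional multi-hour cycles booked per hour
})

test_that("no-shift configurations centre every d_s at zero", {
  cfg <- cohort_config(n_participants = 200, baseline_weeks = 2,
                       weeks_per_quarter = 1,
                       shift_clusters = no_shift_clusters(),
                       indicator_effects = list(), seed = 17)
  coh <- simulate_cohort(cfg)
  rec <- coh$hourly
  rec <- rec[complete.cases(rec[c("step_count", "sleep_seconds",
                                  "in_bed_seconds", "mean_heart_rate")]), ]
  for (f in c("step_count", "sleep_seconds", "mean_heart_rate")) {
    ds <- vapply(unique(rec$participant_id), function(id) {
      r <- rec[rec$participant_id == id, ]
      cohens_ds_points(r[[f]][r$period == "BL"], r[[f]][r$period != "BL"])
    }, numeric(1))
    expect_lt(abs(mean(ds)), 0.05)
  }
})

test_that("a planted heart-rate shift is recovered by empirical d_s", {
  shifts <- two_cluster_shifts()
  shifts[[1]]$mean_shift["mean_heart_rate"] <- 0.5
  cfg <- cohort_config(n_participants = 40, baseline_weeks = 4,
                       weeks_per_quarter = 1, shift_clusters = shifts,
                       indicator_effects = list(), seed = 23)
  coh <- simulate_cohort(cfg)
  in_c1 <- coh$truth$participant_id[coh$truth$cluster_id == 1]
  ds <- vapply(in_c1, function(id) {
    r <- coh$hourly[coh$hourly$participant_id == id, ]
    a <- r$mean_heart_rate[r$period == "BL"]
    b <- r$mean_heart_rate[r$period != "BL"]
    stopifnot(length(a) >= 500, length(b) >= 500)
    cohens_ds_points(a, b)
  }, numeric(1))
  expect_lt(abs(mean(ds) - 0.5), 0.1)
})

test_that("simulation is byte-identical across calls with one seed", {
  cfg <- small_config(n = 8, seed = 5)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$hourly, c2$hourly)
  expect_identical(c1$ema, c2$ema)
  expect_identical(c1$phq, c2$phq)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(small_config(n = 8, seed = 6))
  expect_false(identical(c1$hourly, c3$hourly))
})

test_that("phq series follow the quadratic exactly when noise is off", {
  ser <- simulate_phq_series(list(gamma = c(0, 2, -0.5), prop = 1),
                             n_per_class = 5, seed = 2,
                             residual_sd = 0, random_intercept_sd = 0)
  expect_true(all(ser$delta[ser$period == "BL"] == 0))
  expect_equal(unique(ser$delta[ser$period == "Q4"]), 2 * 4 - 0.5 * 16)
  expect_equal(unique(ser$delta[ser$period == "Q2"]), 2 * 2 - 0.5 * 4)
  expect_equal(unique(ser$class_id), 1L)
})

test_that("class mixing proportions are realized within binomial error", {
  classes <- list(list(gamma = c(0, 0.2, 0), prop = 0.68),
                  list(gamma = c(0, 5, -1), prop = 0.32))
  cfg <- cohort_config(n_participants = 1000, trajectory_classes = classes,
                       seed = 12)
  lat <- simulate_participants(cfg)
  expect_lt(abs(mean(lat$truth$class_id == 1) - 0.68), 0.05)
})

test_that("planted indicator log-odds are recoverable by a logistic fit", {
  cfg <- cohort_config(n_participants = 775, seed = 300)
  lat <- simulate_participants(cfg)
  fit <- glm(lat$truth$resilient ~ lat$truth$planted_mood__cohens_ds__DIFF,
             family = binomial)
  est <- coef(summary(fit))[2, ]
  expect_lt(abs(est["Estimate"] - 0.5), 2 * est["Std. Error"])
})

test_that("missingness rules thin EMA days and whole participant-quarters", {
  cfg <- small_config(n = 10, seed = 7, dropout_hazard_per_quarter = 0,
                      ema_completion_rate = 1)
  coh <- simulate_cohort(cfg)
  expect_identical(apply_missingness(coh)$hourly, coh$hourly)
  expect_identical(apply_missingness(coh)$ema, coh$ema)

  cfg0 <- small_config(n = 10, seed = 7, ema_completion_rate = 0)
  coh0 <- apply_missingness(simulate_cohort(cfg0))
  expect_equal(nrow(coh0$ema), 0L)
})

test_that("dropout follows geometric survival into Q4", {
  cfg <- cohort_config(n_participants = 500, baseline_weeks = 1,
                       weeks_per_quarter = 1,
                       dropout_hazard_per_quarter = 0.3, seed = 31)
  coh <- apply_missingness(simulate_cohort(cfg))
  q4 <- length(unique(coh$hourly$participant_id[coh$hourly$period == "Q4"]))
  expect_lt(abs(q4 / 500 - 0.7^3), 0.05)
  # retained participants decrease monotonically across quarters
  per_q <- vapply(c("Q1", "Q2", "Q3", "Q4"), function(q)
    length(unique(coh$hourly$participant_id[coh$hourly$period == q])),
    numeric(1))
  expect_true(all(diff(per_q) <= 0))
})
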