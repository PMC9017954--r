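# Cleaning pipeline: mood interpolation window rules, zero-filling,
# incomplete-hour dropping, isolation-forest filtering, participant
# eligibility.

test_that("mood fills from the previous wake to the next long-sleep wake", {
  # one participant; sleep 00:00-07:59 day 0 (wake anchor hour 8), EMA = 7
  # at 18:00 day 0, next night sleep 23:00 day0 - 06:59 day1 (wake hour 31)
  rec <- hand_hourly(hours = 0:47)
  rec$sleep_seconds[1:8] <- 3600          # hours 0-7
  rec$sleep_seconds[24:32] <- 3600        # hours 23-31
  rec$in_bed_seconds <- rec$sleep_seconds
  origin <- as.POSIXct("2020-05-01 00:00:00", tz = "UTC")
  ema <- data.frame(participant_id = "H1", timestamp = origin + 18 * 3600,
                    mood = 7)
  out <- interpolate_mood(rec, ema, noise_seed = 3)
  filled <- which(!is.na(out$mood))
  expect_equal(range(filled - 1L), c(8, 31))  # hours 8..31 inclusive
  expect_true(all(out$mood[filled] >= 7 & out$mood[filled] < 7.2))
})

test_that("same-day EMAs are averaged before filling", {
  rec <- hand_hourly(hours = 0:23)
  origin <- as.POSIXct("2020-05-01 00:00:00", tz = "UTC")
  ema <- data.frame(participant_id = "H1",
                    timestamp = origin + c(10, 19) * 3600, mood = c(6, 7))
  out <- interpolate_mood(rec, ema, noise_seed = 3)
  filled <- out$mood[!is.na(out$mood)]
  expect_true(all(filled >= 6.5 & filled < 6.7))
})

test_that("no fill extends more than 24 hours past the EMA", {
  rec <- hand_hourly(hours = 0:71)  # no sleep at all: no anchors
  origin <- as.POSIXct("2020-05-01 00:00:00", tz = "UTC")
  ema <- data.frame(participant_id = "H1", timestamp = origin + 18 * 3600,
                    mood = 5)
  out <- interpolate_mood(rec, ema, noise_seed = 3)
  filled <- which(!is.na(out$mood)) - 1L
  expect_equal(min(filled), 0)       # fill starts at the day's midnight
  expect_equal(max(filled), 18 + 23) # ends just before EMA + 24 h
})

test_that("short sleep does not end the fill window but >2 h sleep does", {
  rec <- hand_hourly(hours = 0:47)
  rec$sleep_seconds[15] <- 3000      # 1-hour nap, total 3000 s <= 7200
  rec$sleep_seconds[25:29] <- 3600   # night sleep > 2 h, wake anchor 29
  rec$in_bed_seconds <- rec$sleep_seconds
  origin <- as.POSIXct("2020-05-01 00:00:00", tz = "UTC")
  ema <- data.frame(participant_id = "H1", timestamp = origin + 18 * 3600,
                    mood = 8)
  out <- interpolate_mood(rec, ema, noise_seed = 3)
  filled <- which(!is.na(out$mood)) - 1L
  expect_equal(max(filled), 28)      # stops at the long-sleep wake anchor
  expect_true(15 %in% filled)        # nap hour itself still filled
})

test_that("per-day noise mode shares one draw across a day's hours", {
  rec <- hand_hourly(hours = 0:23)
  origin <- as.POSIXct("2020-05-01 00:00:00", tz = "UTC")
  ema <- data.frame(participant_id = "H1", timestamp = origin + 12 * 3600,
                    mood = 4)
  per_hour <- interpolate_mood(rec, ema, noise_seed = 5, noise_per = "hour")
  per_day <- interpolate_mood(rec, ema, noise_seed = 5, noise_per = "ema")
  expect_gt(length(unique(na.omit(per_hour$mood))), 1L)
  expect_equal(length(unique(na.omit(per_day$mood))), 1L)
})

test_that("EMA values outside 1-10 are rejected", {
  rec <- hand_hourly(hours = 0:5)
  origin <- as.POSIXct("2020-05-01 00:00:00", tz = "UTC")
  ema <- data.frame(participant_id = "H1", timestamp = origin, mood = 11)
  expect_error(interpolate_mood(rec, ema), "\\[1, 10\\]")
})

test_that("step/sleep missingness is zero-filled symmetrically", {
  rec <- hand_hourly(hours = 0:3)
  rec$sleep_seconds <- c(3600, NA, 3600, 0)
  rec$in_bed_seconds <- c(3600, NA, 3600, 0)
  rec$step_count <- c(NA, 400, 250, NA)
  out <- fill_step_sleep_missing(rec)
  expect_equal(out$step_count[1], 0L)        # sleep, no steps
  expect_equal(out$sleep_seconds[2], 0)      # steps, no sleep
  expect_equal(out$in_bed_seconds[2], 0)
  expect_equal(out$step_count[3], 250L)      # both present: unchanged
  expect_equal(out$sleep_seconds[3], 3600)
  expect_true(is.na(out$step_count[4]))      # neither rule applies
})

test_that("only hours with all five features survive", {
  rec <- hand_hourly(hours = 0:3)
  rec$mood <- c(7.1, NA, 7.05, 7.2)
  rec$mean_heart_rate[3] <- NA
  out <- drop_incomplete_hours(rec)
  expect_equal(nrow(out), 2L)
})

test_that("planted extreme hours are flagged and removal is deterministic", {
  sc <- small_clean_cohort()
  base <- sc$records
  set.seed(14)
  extremes <- base[sample.int(nrow(base), 50), ]
  extremes$step_count <- 50000L
  x <- rbind(base, extremes)
  r1 <- filter_outliers(x, seed = 9)
  r2 <- filter_outliers(x, seed = 9)
  expect_identical(r1$records, r2$records)
  flagged_extreme <- nrow(x) - nrow(r1$records)
  # all 50 planted extremes must be gone
  expect_equal(sum(r1$records$step_count == 50000), 0L)
  expect_gte(flagged_extreme, 50L)
  expect_equal(r1$report$n_hours_in - r1$report$n_hours_out,
               r1$report$n_outliers_removed)
})

test_that("flagged fraction on clean synthetic data stays small", {
  # first filtering pass over anomaly-free synthetic hours: the flag rate
  # should sit in the low single percentages (the regime reported for real
  # cohorts)
  sc <- small_clean_cohort()
  rec <- interpolate_mood(sc$cohort$hourly, sc$cohort$ema, noise_seed = 31)
  rec <- drop_incomplete_hours(fill_step_sleep_missing(rec))
  r <- filter_outliers(rec, seed = 33)
  expect_lte(r$report$n_outliers_removed / r$report$n_hours_in, 0.05)
})

test_that("cleaning is idempotent when the forest is reused", {
  sc <- small_clean_cohort()
  again <- filter_outliers(sc$records, forest = sc$forest)
  expect_identical(again$records, sc$records)
})

test_that("participant eligibility enforces hour thresholds and variance", {
  mk <- function(id, n_bl, n_int, hr = NULL) {
    r <- hand_hourly(id, hours = seq_len(n_bl + n_int) - 1L,
                     step_count = rpois(n_bl + n_int, 100),
                     sleep_seconds = 0)
    r$period <- c(rep("BL", n_bl), rep("Q1", n_int))
    r$sleep_seconds <- pmax(rnorm(n_bl + n_int, 600, 700), 0)
    r$in_bed_seconds <- r$sleep_seconds
    r$mean_heart_rate <- if (is.null(hr)) rnorm(n_bl + n_int, 70, 5) else hr
    r$mood <- runif(n_bl + n_int, 1, 10)
    r
  }
  set.seed(2)
  rec <- rbind(mk("A", 99, 150), mk("B", 150, 99), mk("C", 150, 150),
               mk("D", 150, 150, hr = 70))
  out <- filter_participants(rec)
  expect_setequal(unique(out$records$participant_id), "C")
  reasons <- out$report$dropped_participants
  expect_equal(reasons$reason[reasons$participant_id == "A"],
               "baseline hours")
  expect_equal(reasons$reason[reasons$participant_id == "B"],
               "internship hours")
  expect_equal(reasons$reason[reasons$participant_id == "D"],
               "zero variance")
})

test_that("outlier burden is label-neutral when nothing is planted", {
  # counts drawn independently of labels: the one-sided Mann-Whitney should
  # reject at roughly its nominal 5% rate
  set.seed(77)
  p <- replicate(200, {
    counts <- rpois(300, 6)
    labels <- sample(c(TRUE, FALSE), 300, replace = TRUE, prob = c(.68, .32))
    outlier_burden_test(counts, labels)$p
  })
  expect_lte(mean(p < 0.05), 0.12)
})
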