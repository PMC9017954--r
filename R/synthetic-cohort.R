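# Synthetic cohort generator: hourly wearable streams (steps, sleep, in-bed,
# heart rate), daily evening mood EMAs, quarterly PHQ-9 series with latent
# quadratic trajectory classes, and two latent behaviour-shift clusters
# between baseline and internship. Provides the statistical structure the
# downstream analysis assumes, so the whole pipeline is testable without any
# raw study data.

#' Default trajectory classes and behaviour-shift clusters
#'
#' `default_trajectory_classes()` returns four quadratic delta-PHQ classes
#' over quarter index t in 1..4 with distinct curve shapes: a majority
#' minimal-change (resilient) class, an early-peaking class that recovers
#' by year end, a late-rising class, and a smaller high-sustained class.
#' Peak values (0.4, 6, 12, 12.7 PHQ points) are separated by at least 4
#' and the shapes are mutually distant in curve space, making the classes
#' identifiable in the presence of the shared random intercept.
#' `default_shift_clusters()` returns the two behaviour-shift clusters
#' (80/20) differing mainly on sleep, in-bed and heart rate.
#'
#' @return a list in the format of `cohort_config()`'s
#'   `trajectory_classes` / `shift_clusters` arguments.
#' @export
default_trajectory_classes <- function() {
  list(
    list(gamma = c(0.0, 0.3, -0.06), prop = 0.68),
    list(gamma = c(0.0, 6.0, -1.50), prop = 0.15),
    list(gamma = c(0.0, 1.0,  0.50), prop = 0.10),
    list(gamma = c(0.0, 9.0, -1.60), prop = 0.07))
}

#' @rdname default_trajectory_classes
#' @export
default_shift_clusters <- function() {
  # Mean shifts are in units of each feature's marginal hourly SD; sd_scale
  # multiplies the spread of the internship distribution about its mean.
  list(
    list(prop = 0.8,
         mean_shift = c(step_count = 0.05, sleep_seconds = 0.10,
                        in_bed_seconds = 0.10, mean_heart_rate = -0.05,
                        mood = 0.05),
         sd_scale = c(step_count = 1, sleep_seconds = 1, in_bed_seconds = 1,
                      mean_heart_rate = 1, mood = 1)),
    list(prop = 0.2,
         mean_shift = c(step_count = -0.20, sleep_seconds = -0.60,
                        in_bed_seconds = -0.60, mean_heart_rate = 0.40,
                        mood = -0.20),
         sd_scale = c(step_count = 1, sleep_seconds = 1, in_bed_seconds = 1,
                      mean_heart_rate = 1, mood = 1)))
}

SPECIALTIES <- c("internal_medicine", "surgery", "obgyn", "pediatrics",
                 "psychiatry", "emergency_medicine", "med_peds",
                 "family_practice", "transitional", "anesthesiology",
                 "neurology", "otolaryngology", "other")
SPECIALTY_PROPS <- c(0.22, 0.10, 0.06, 0.14, 0.05, 0.09, 0.03, 0.09, 0.04,
                     0.05, 0.02, 0.01, 0.10)

#' Configuration for a synthetic cohort
#'
#' Defaults emulate a year-long internship study: 775 participants, a
#' 6-week pre-internship baseline, four 13-week internship quarters,
#' a four-class quadratic delta-PHQ-9 trajectory mixture with a 68% majority
#' minimal-change class, two behaviour-shift clusters (80/20) differing
#' mainly on sleep, in-bed and heart-rate, evening mood EMAs completed on
#' 85% of days, and a 15% per-quarter dropout hazard.
#'
#' @param n_participants cohort size.
#' @param baseline_weeks weeks of pre-internship data per participant.
#' @param internship_quarters number of internship quarters (default 4).
#' @param weeks_per_quarter simulated weeks per quarter; lower it to scale
#'   cohorts down while retaining all four quarters.
#' @param trajectory_classes list of `list(gamma = c(g0, g1, g2), prop = p)`;
#'   delta-PHQ at quarter t (1..4) is `g0 + g1 t + g2 t^2` plus a random
#'   intercept and residual noise. Proportions must sum to 1.
#' @param residual_sd,random_intercept_sd PHQ-point noise SDs.
#' @param shift_clusters list of per-feature mean-shift (hourly-SD units) and
#'   SD-scale multipliers between baseline and internship.
#' @param resilient_cluster_logodds log-odds added to membership in shift
#'   cluster 1 for resilient-class participants; this couples the
#'   cluster-separated features to resilience.
#' @param shift_heterogeneity SD (in hourly-SD units) of per-participant
#'   Gaussian deviations around the cluster mean shifts, applied
#'   independently per feature; individual behavioural responses to the
#'   internship vary around their cluster's typical change.
#' @param indicator_effects list of `list(indicator = name, beta = log_odds)`
#'   planted indicator-resilience couplings. Planted values are recorded in
#'   the truth table; for `<feature>__cohens_ds__DIFF` indicators the value
#'   additionally feeds the participant's internship mean shift.
#' @param plant_scale hourly-SD units of internship mean shift per unit of
#'   planted indicator value.
#' @param ema_completion_rate probability a given day's mood EMA is answered
#'   (applied by [apply_missingness()]).
#' @param dropout_hazard_per_quarter probability a participant drops out at
#'   each quarter transition after Q1 (applied by [apply_missingness()]).
#' @param wear_prob probability any given hour is recorded by the wearable.
#' @param seed master integer seed; every draw is a deterministic function
#'   of it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 775,
                          baseline_weeks = 6,
                          internship_quarters = 4,
                          weeks_per_quarter = 13,
                          trajectory_classes = default_trajectory_classes(),
                          residual_sd = 2,
                          random_intercept_sd = 1,
                          shift_clusters = default_shift_clusters(),
                          resilient_cluster_logodds = 0.8,
                          shift_heterogeneity = 0.1,
                          indicator_effects = list(
                            list(indicator = "mood__cohens_ds__DIFF",
                                 beta = 0.5)),
                          plant_scale = 0.25,
                          ema_completion_rate = 0.85,
                          dropout_hazard_per_quarter = 0.15,
                          wear_prob = 0.92,
                          seed = 1L) {
  n_participants <- check_count(n_participants, "n_participants")
  baseline_weeks <- check_count(baseline_weeks, "baseline_weeks")
  internship_quarters <- check_count(internship_quarters,
                                     "internship_quarters")
  weeks_per_quarter <- check_count(weeks_per_quarter, "weeks_per_quarter")
  if (!length(trajectory_classes))
    stop_config("trajectory_classes", "at least one class is required")
  props <- vapply(trajectory_classes, function(k) k$prop, numeric(1))
  if (abs(sum(props) - 1) > 1e-9)
    stop_config("trajectory_classes", "mixing proportions must sum to 1")
  for (k in trajectory_classes)
    if (length(k$gamma) != 3L || !is.numeric(k$gamma))
      stop_config("trajectory_classes",
                  "each class needs 3 quadratic coefficients")
  if (residual_sd < 0) stop_config("residual_sd", "must be >= 0")
  if (random_intercept_sd < 0)
    stop_config("random_intercept_sd", "must be >= 0")
  cprops <- vapply(shift_clusters, function(k) k$prop, numeric(1))
  if (abs(sum(cprops) - 1) > 1e-9)
    stop_config("shift_clusters", "cluster proportions must sum to 1")
  for (k in shift_clusters) {
    if (!all(FEATURES %in% names(k$mean_shift)))
      stop_config("shift_clusters", "mean_shift must name all five features")
    if (!all(FEATURES %in% names(k$sd_scale)))
      stop_config("shift_clusters", "sd_scale must name all five features")
  }
  check_prob(ema_completion_rate, "ema_completion_rate")
  check_prob(dropout_hazard_per_quarter, "dropout_hazard_per_quarter")
  check_prob(wear_prob, "wear_prob")
  for (ef in indicator_effects)
    if (is.null(ef$indicator) || is.null(ef$beta))
      stop_config("indicator_effects", "each effect needs indicator and beta")
  structure(as.list(environment()), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("cohort_config: %d participants, %d baseline weeks, ",
                     "%d quarters x %d weeks, %d trajectory classes, ",
                     "%d shift clusters, seed %d\n"),
              x$n_participants, x$baseline_weeks, x$internship_quarters,
              x$weeks_per_quarter, length(x$trajectory_classes),
              length(x$shift_clusters), x$seed))
  invisible(x)
}

#' Simulate participant-level latent structure only
#'
#' The cheap margin of [simulate_cohort()]: trajectory-class and
#' shift-cluster memberships, covariates, and planted indicator values,
#' without synthesising any hourly streams. Useful for calibration studies
#' of the label-association stages.
#'
#' @param config a [cohort_config()].
#' @return a list with `truth` (participant_id, class_id, cluster_id,
#'   resilient, one `planted_<indicator>` column per configured effect) and
#'   `covariates` (participant_id, sex, age, specialty).
#' @export
simulate_participants <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(derive_seed(config$seed, "participants"), {
    n <- config$n_participants
    ids <- sprintf("P%04d", seq_len(n))
    props <- vapply(config$trajectory_classes, function(k) k$prop, numeric(1))
    class_id <- sample.int(length(props), n, replace = TRUE, prob = props)
    resilient <- class_id == resilient_class_index(config$trajectory_classes)

    # Shift-cluster membership depends on resilience through a log-odds
    # offset on cluster 1, planting associations between the
    # cluster-separated features and resilience.
    cprops <- vapply(config$shift_clusters, function(k) k$prop, numeric(1))
    base_logit <- log(cprops[1L] / max(1 - cprops[1L], 1e-12))
    p1 <- stats::plogis(base_logit +
                          config$resilient_cluster_logodds * (resilient - mean(resilient)))
    cluster_id <- ifelse(stats::runif(n) < p1, 1L,
                         if (length(cprops) > 2L) {
                           1L + sample.int(length(cprops) - 1L, n, replace = TRUE,
                                           prob = cprops[-1L])
                         } else 2L)

    truth <- data.frame(participant_id = ids, class_id = class_id,
                        cluster_id = cluster_id, resilient = resilient,
                        stringsAsFactors = FALSE)
    for (ef in config$indicator_effects) {
      z <- stats::rnorm(n) + ef$beta * as.numeric(resilient)
      truth[[paste0("planted_", ef$indicator)]] <- z
    }

    covariates <- data.frame(
      participant_id = ids,
      sex = stats::rbinom(n, 1L, 0.55),
      age = pmin(pmax(round(stats::rnorm(n, 27, 1.5)), 24), 35),
      specialty = sample(SPECIALTIES, n, replace = TRUE,
                         prob = SPECIALTY_PROPS),
      stringsAsFactors = FALSE)
    list(truth = truth, covariates = covariates)
  })
}

resilient_class_index <- function(classes) {
  peaks <- vapply(classes, function(k) {
    t <- 1:4
    max(abs(k$gamma[1] + k$gamma[2] * t + k$gamma[3] * t^2))
  }, numeric(1))
  props <- vapply(classes, function(k) k$prop, numeric(1))
  cand <- which(peaks == min(peaks))
  cand[which.max(props[cand])]
}

#' Simulate PHQ-9 series for given trajectory classes
#'
#' Delta-PHQ at baseline is exactly 0; at quarters t = 1..4 it is the class
#' quadratic `g0 + g1 t + g2 t^2` plus a participant random intercept and
#' residual noise. Absolute PHQ-9 scores are the baseline score plus delta,
#' clamped to the 0-27 instrument range.
#'
#' @param class_params list of `list(gamma = c(g0, g1, g2), prop = p)`, or a
#'   single class list.
#' @param n_per_class integer vector of series counts per class (recycled).
#' @param seed integer seed.
#' @param residual_sd,random_intercept_sd noise SDs in PHQ points.
#' @param quarters number of post-baseline quarters.
#' @return data.frame with `participant_id`, `period`, `phq9`, `delta`,
#'   `class_id`.
#' @export
simulate_phq_series <- function(class_params, n_per_class, seed = 1L,
                                residual_sd = 2, random_intercept_sd = 1,
                                quarters = 4L) {
  if (!is.null(class_params$gamma)) class_params <- list(class_params)
  if (!length(class_params)) stop_config("class_params", "need >= 1 class")
  n_per_class <- rep_len(as.integer(n_per_class), length(class_params))
  with_seed(derive_seed(seed, "phq"), {
    rows <- list()
    pid <- 0L
    for (k in seq_along(class_params)) {
      g <- class_params[[k]]$gamma
      for (i in seq_len(n_per_class[k])) {
        pid <- pid + 1L
        b <- stats::rnorm(1L, 0, random_intercept_sd)
        t <- seq_len(quarters)
        delta <- c(0, g[1] + g[2] * t + g[3] * t^2 + b +
                     stats::rnorm(quarters, 0, residual_sd))
        bl <- max(0, min(27, round(stats::rnorm(1L, 3, 2))))
        phq <- pmin(pmax(round(bl + delta), 0), 27)
        rows[[pid]] <- data.frame(
          participant_id = sprintf("P%04d", pid),
          period = PERIODS[seq_len(quarters + 1L)],
          phq9 = phq, delta = delta, class_id = k,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# Marginal-SD references used to express mean shifts in SD units for the
# additive-shift features. Heart rate and mood get exact additive treatment
# (see simulate_cohort); hurdle-type features are shifted through their
# generating process instead.
MOOD_DAILY_SD <- 1.2

#' Simulate a complete synthetic cohort
#'
#' Generates hourly wearable records (zero-inflated right-skewed step counts
#' via an hourly activity-gate/negative-binomial hurdle; zero-heavy sleep and
#' in-bed seconds built from 1-3 nightly sleep cycles, where a cycle crossing
#' an hour boundary may book more than 3600 s into its start hour; truncated
#' normal heart rate in [35, 204] BPM), integer 1-10 mood EMAs delivered at a
#' fixed per-participant evening hour, quarterly PHQ-9 series following the
#' participant's latent quadratic class, and participant covariates.
#' Internship distributions differ from baseline according to the
#' participant's latent shift cluster; heart-rate and mood cluster shifts are
#' additive in units of the participant's own pooled hourly SD, so empirical
#' Cohen's d_s recovers the configured multiplier.
#'
#' The returned cohort is complete; use [apply_missingness()] to thin EMA
#' days and drop participant-quarters.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: list with `hourly`, `ema`,
#'   `phq`, `covariates`, `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  latent <- simulate_participants(config)
  truth <- latent$truth
  n <- config$n_participants
  ids <- truth$participant_id

  n_bl_days <- config$baseline_weeks * 7L
  n_q_days <- config$weeks_per_quarter * 7L
  n_days <- n_bl_days + config$internship_quarters * n_q_days
  day_period <- c(rep("BL", n_bl_days),
                  rep(PERIODS[2:(1 + config$internship_quarters)],
                      each = n_q_days))
  origin <- as.POSIXct("2020-05-01 00:00:00", tz = "UTC")

  # Per-participant internship mean shifts in SD units: cluster shift plus
  # any planted d_s-indicator contribution.
  shift <- matrix(0, n, length(FEATURES), dimnames = list(NULL, FEATURES))
  sd_scale <- matrix(1, n, length(FEATURES), dimnames = list(NULL, FEATURES))
  for (cl in seq_along(config$shift_clusters)) {
    sel <- truth$cluster_id == cl
    shift[sel, ] <- matrix(config$shift_clusters[[cl]]$mean_shift[FEATURES],
                           sum(sel), length(FEATURES), byrow = TRUE)
    sd_scale[sel, ] <- matrix(config$shift_clusters[[cl]]$sd_scale[FEATURES],
                              sum(sel), length(FEATURES), byrow = TRUE)
  }
  if (config$shift_heterogeneity > 0)
    shift <- shift + with_seed(derive_seed(config$seed, "shift_het"),
      matrix(stats::rnorm(length(shift), 0, config$shift_heterogeneity),
             nrow(shift)))
  for (ef in config$indicator_effects) {
    feat <- sub("__cohens_ds__DIFF$", "", ef$indicator)
    if (feat != ef$indicator && feat %in% FEATURES)
      shift[, feat] <- shift[, feat] +
        config$plant_scale * truth[[paste0("planted_", ef$indicator)]]
  }

  phq <- simulate_cohort_phq(config, truth)

  hourly_list <- vector("list", n)
  ema_list <- vector("list", n)
  with_seed(derive_seed(config$seed, "streams"), {
    # participant-level behavioural latents
    act <- exp(stats::rnorm(n, 0, 0.3))
    dur_h <- stats::rnorm(n, 7, 0.7)
    bedtime <- stats::rnorm(n, 23, 0.8)
    hr_base <- stats::rnorm(n, 72, 5)
    mood_base <- stats::rnorm(n, 7, 1)
    ema_hour <- sample(17:21, n, replace = TRUE)
    for (i in seq_len(n)) {
      sim <- simulate_participant_streams(
        n_days = n_days, day_period = day_period, n_bl_days = n_bl_days,
        act = act[i], dur_h = dur_h[i], bedtime = bedtime[i],
        hr_base = hr_base[i], mood_base = mood_base[i],
        ema_hour = ema_hour[i], shift = shift[i, ], sd_scale = sd_scale[i, ],
        wear_prob = config$wear_prob)
      sim$hourly$participant_id <- ids[i]
      sim$ema$participant_id <- ids[i]
      hourly_list[[i]] <- sim$hourly
      ema_list[[i]] <- sim$ema
    }
  })
  hourly <- do.call(rbind, hourly_list)
  ema <- do.call(rbind, ema_list)
  hourly$hour_start <- origin + hourly$hour_index * 3600
  hourly$hour_index <- NULL
  ema$timestamp <- origin + ema$hour_index * 3600
  ema$hour_index <- NULL
  hourly <- hourly[c("participant_id", "period", "hour_start", "step_count",
                     "sleep_seconds", "in_bed_seconds", "mean_heart_rate")]
  ema <- ema[c("participant_id", "timestamp", "mood")]
  rownames(hourly) <- rownames(ema) <- NULL

  structure(list(hourly = hourly, ema = ema, phq = phq,
                 covariates = latent$covariates, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

simulate_cohort_phq <- function(config, truth) {
  with_seed(derive_seed(config$seed, "cohort_phq"), {
    q <- config$internship_quarters
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      g <- config$trajectory_classes[[truth$class_id[i]]]$gamma
      b <- stats::rnorm(1L, 0, config$random_intercept_sd)
      t <- seq_len(q)
      delta <- c(0, g[1] + g[2] * t + g[3] * t^2 + b +
                   stats::rnorm(q, 0, config$residual_sd))
      bl <- max(0, min(27, round(stats::rnorm(1L, 3, 2))))
      data.frame(participant_id = truth$participant_id[i],
                 period = PERIODS[seq_len(q + 1L)],
                 phq9 = pmin(pmax(round(bl + delta), 0), 27),
                 delta = delta, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# One participant's hourly streams over the whole study, on an hourly index
# grid (hours since study origin, participant-local clock).
simulate_participant_streams <- function(n_days, day_period, n_bl_days,
                                         act, dur_h, bedtime, hr_base,
                                         mood_base, ema_hour, shift,
                                         sd_scale, wear_prob) {
  n_hours <- n_days * 24L
  hour_of_day <- rep(0:23, n_days)
  day_idx <- rep(seq_len(n_days) - 1L, each = 24L)
  intern <- rep(day_period != "BL", each = 24L)

  sleep <- numeric(n_hours)
  in_bed <- numeric(n_hours)

  # Nightly sleep: onset near bedtime, 1-3 cycles separated by short awake
  # gaps (in bed, not asleep). Internship sleep shift scales nightly
  # duration; nap probability tracks the shift's sign.
  sleep_shift <- shift[["sleep_seconds"]]
  nap_p_bl <- 0.05
  for (d in seq_len(n_days) - 1L) {
    is_int <- day_period[d + 1L] != "BL"
    dur <- dur_h + stats::rnorm(1L, 0, 0.8) +
      if (is_int) 3.0 * sleep_shift else 0
    dur <- min(max(dur, 2.5), 12)
    onset <- d * 24 + bedtime + stats::rnorm(1L, 0, 0.6)
    ncyc <- sample.int(3L, 1L)
    cuts <- sort(stats::runif(ncyc - 1L, 0.2, 0.8))
    lens <- diff(c(0, cuts, 1)) * dur
    gaps <- if (ncyc > 1L) stats::runif(ncyc - 1L, 5, 20) / 60 else numeric(0)
    t0 <- onset
    for (cc in seq_len(ncyc)) {
      res <- book_cycle(t0, lens[cc], n_hours)
      sleep[res$idx] <- sleep[res$idx] + res$sleep
      in_bed[res$idx] <- in_bed[res$idx] + res$sleep
      if (cc < ncyc) {
        gres <- book_interval(t0 + lens[cc], gaps[cc], n_hours)
        in_bed[gres$idx] <- in_bed[gres$idx] + gres$secs
        t0 <- t0 + lens[cc] + gaps[cc]
      }
    }
    # occasional afternoon nap
    nap_p <- nap_p_bl + if (is_int) 0.12 * sleep_shift else 0
    if (stats::runif(1L) < max(min(nap_p, 0.5), 0)) {
      res <- book_cycle(d * 24 + stats::runif(1L, 13, 16),
                        stats::runif(1L, 0.5, 1.5), n_hours)
      sleep[res$idx] <- sleep[res$idx] + res$sleep
      in_bed[res$idx] <- in_bed[res$idx] + res$sleep
    }
  }

  asleep_frac <- pmin(sleep / 3600, 1)

  # Steps: circadian activity gate times negative-binomial counts, zeroed
  # while mostly asleep. Internship shift scales the count rate.
  gate_p <- c(rep(0.04, 6), 0.35, 0.65, 0.75, 0.75, 0.75, 0.78,
              0.78, 0.75, 0.72, 0.72, 0.72, 0.78, 0.72, 0.6, 0.5,
              0.4, 0.25, 0.1)[hour_of_day + 1L]
  gate <- stats::runif(n_hours) < gate_p * (1 - asleep_frac)
  rate_mult <- ifelse(intern, pmax(1 + 0.8 * shift[["step_count"]], 0.05), 1)
  mu <- 330 * act * rate_mult
  steps <- integer(n_hours)
  steps[gate] <- stats::rnbinom(sum(gate), size = 1.2, mu = mu[gate])

  # Heart rate: truncated normal around an awake/asleep-dependent mean. The
  # internship shift is additive in units of the participant's own pooled
  # (unshifted) hourly SD, so empirical d_s matches the configured
  # multiplier up to sampling noise.
  hr_raw <- stats::rnorm(n_hours, hr_base + 3 - 11 * asleep_frac, 6)
  hr_sd <- stats::sd(hr_raw)
  hr_mean_int <- mean(hr_raw[intern])
  hr <- hr_raw
  hr[intern] <- hr_mean_int +
    (hr_raw[intern] - hr_mean_int) * sd_scale[["mean_heart_rate"]] +
    shift[["mean_heart_rate"]] * hr_sd
  hr <- pmin(pmax(hr, HR_RANGE[1]), HR_RANGE[2])

  # Daily mood: latent AR-free normal around the participant mean, shifted
  # additively during the internship, rounded onto the 1-10 scale and
  # delivered at the participant's fixed evening EMA hour.
  day_is_int <- day_period != "BL"
  mood_noise <- stats::rnorm(n_days, 0, MOOD_DAILY_SD) *
    ifelse(day_is_int, sd_scale[["mood"]], 1)
  mood_lat <- mood_base + mood_noise +
    day_is_int * shift[["mood"]] * MOOD_DAILY_SD
  mood <- pmin(pmax(round(mood_lat), 1), 10)
  ema_idx <- (seq_len(n_days) - 1L) * 24L + ema_hour
  ema <- data.frame(hour_index = ema_idx, mood = as.integer(mood))

  worn <- stats::runif(n_hours) < wear_prob | sleep > 0
  hourly <- data.frame(
    period = rep(day_period, each = 24L),
    hour_index = seq_len(n_hours) - 1L,
    step_count = steps,
    sleep_seconds = round(sleep),
    in_bed_seconds = round(in_bed),
    mean_heart_rate = round(hr, 1))[worn, ]

  # device-style missingness: sleeping hours often lack a step record and
  # active hours lack a sleep record; these become NA in the raw table and
  # are zero-filled by the cleaning rules.
  slp_hr <- hourly$sleep_seconds > 0 & hourly$step_count == 0
  hourly$step_count[slp_hr & stats::runif(nrow(hourly)) < 0.5] <- NA_integer_
  stp_hr <- hourly$step_count > 0 & hourly$sleep_seconds == 0
  stp_hr[is.na(stp_hr)] <- FALSE
  na_sel <- stp_hr & stats::runif(nrow(hourly)) < 0.5
  hourly$sleep_seconds[na_sel] <- NA_real_
  hourly$in_bed_seconds[na_sel] <- NA_real_
  list(hourly = hourly, ema = ema)
}

# Book a sleep cycle of `len` hours starting at continuous hour `t0` into
# the hourly grid. With probability 0.15 a multi-hour cycle is recorded
# entirely in its start hour (so that hour can carry > 3600 s).
book_cycle <- function(t0, len, n_hours) {
  if (stats::runif(1L) < 0.15) {
    h <- floor(t0)
    if (h < 0 || h >= n_hours) return(list(idx = integer(0), sleep = numeric(0)))
    return(list(idx = h + 1L, sleep = len * 3600))
  }
  res <- book_interval(t0, len, n_hours)
  list(idx = res$idx, sleep = res$secs)
}

# Split a [t0, t0+len) interval (hours) into per-hour second totals.
book_interval <- function(t0, len, n_hours) {
  if (len <= 0) return(list(idx = integer(0), secs = numeric(0)))
  h0 <- floor(t0); h1 <- floor(t0 + len - 1e-9)
  hrs <- h0:h1
  secs <- vapply(hrs, function(h) {
    (min(t0 + len, h + 1) - max(t0, h)) * 3600
  }, numeric(1))
  keep <- hrs >= 0 & hrs < n_hours
  list(idx = hrs[keep] + 1L, secs = secs[keep])
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d participants, %d hourly records, ",
                     "%d EMA events, %d PHQ rows\n"),
              nrow(x$truth), nrow(x$hourly), nrow(x$ema), nrow(x$phq)))
  invisible(x)
}

#' Apply EMA and dropout missingness to a cohort
#'
#' Thins whole participant-quarters via a per-quarter dropout hazard
#' (participants present in Q1 remain present in quarter k with probability
#' `(1 - hazard)^(k-1)`; once dropped they stay dropped) and removes
#' individual EMA days via the completion rate. Dropped quarters lose their
#' hourly records, EMA events and PHQ scores.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param config optionally a different [cohort_config()]; defaults to the
#'   cohort's own.
#' @return a `synthetic_cohort` with missingness applied.
#' @export
apply_missingness <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  hazard <- config$dropout_hazard_per_quarter
  completion <- config$ema_completion_rate
  with_seed(derive_seed(config$seed, "missingness"), {
    ids <- cohort$truth$participant_id
    nq <- config$internship_quarters
    # quarter reached per participant: geometric survival after Q1
    keep_q <- matrix(TRUE, length(ids), nq,
                     dimnames = list(ids, PERIODS[2:(nq + 1)]))
    if (hazard > 0 && nq > 1L) {
      for (q in 2:nq)
        keep_q[, q] <- keep_q[, q - 1L] & stats::runif(length(ids)) >= hazard
    }
    dropped <- function(pid, period) {
      out <- logical(length(pid))
      int_sel <- period != "BL"
      if (any(int_sel))
        out[int_sel] <- !keep_q[cbind(pid[int_sel], period[int_sel])]
      out
    }
    cohort$hourly <- cohort$hourly[!dropped(cohort$hourly$participant_id,
                                            cohort$hourly$period), ]
    cohort$phq <- cohort$phq[!dropped(cohort$phq$participant_id,
                                      cohort$phq$period), ]
    if (nrow(cohort$ema)) {
      ema_period <- period_of_timestamp(cohort$ema$timestamp, config)
      keep_ema <- !dropped(cohort$ema$participant_id, ema_period) &
        stats::runif(nrow(cohort$ema)) < completion
      cohort$ema <- cohort$ema[keep_ema, ]
    }
  })
  rownames(cohort$hourly) <- rownames(cohort$ema) <- rownames(cohort$phq) <- NULL
  cohort
}

period_of_timestamp <- function(ts, config) {
  origin <- as.POSIXct("2020-05-01 00:00:00", tz = "UTC")
  day <- floor(as.numeric(difftime(ts, origin, units = "days")))
  n_bl <- config$baseline_weeks * 7L
  nq_days <- config$weeks_per_quarter * 7L
  q <- pmin(pmax(floor((day - n_bl) / nq_days) + 1L, 0L),
            config$internship_quarters)
  ifelse(day < n_bl, "BL", PERIODS[q + 1L])
}
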