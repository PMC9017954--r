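# Cleaning pipeline: daily mood EMAs are interpolated onto the hourly grid,
# step/sleep missingness is zero-filled under a non-random-missingness
# assumption, incomplete hours are dropped, multivariate outliers are
# removed with an isolation forest, and low-data participants are filtered.

#' Interpolate daily mood EMAs onto the hourly grid
#'
#' For each day with at least one EMA, every hourly record between the wake
#' time ending the previous sleep cycle and the wake time ending the next
#' sleep cycle longer than two hours is filled with the day's EMA value
#' (same-day EMAs are averaged first). No fill extends more than 24 hours
#' past the EMA. If no prior wake anchor exists the fill starts at the EMA
#' day's midnight; if no qualifying following sleep exists it ends at EMA
#' time + 24 h. Independent Uniform(0, 0.2) noise is added to each filled
#' value so the discrete 0.5-increment scale becomes continuous while the
#' underlying values stay recoverable.
#'
#' Sleep-cycle anchors are contiguous runs of recorded hours with
#' `sleep_seconds > 0`; a run qualifies as "longer than two hours" when its
#' summed sleep exceeds 7200 s.
#'
#' @param records hourly records (with `sleep_seconds` for anchoring).
#' @param ema EMA events: `participant_id`, `timestamp`, `mood` in 1-10.
#' @param noise_seed integer seed for the added noise.
#' @param noise_per `"hour"` draws noise independently per filled hour
#'   (default); `"ema"` draws one value per EMA day shared by its hours.
#' @return `records` with a `mood` column (NA where no EMA covers the hour).
#' @export
interpolate_mood <- function(records, ema, noise_seed = 1L,
                             noise_per = c("hour", "ema")) {
  noise_per <- match.arg(noise_per)
  if (nrow(ema) && (any(ema$mood < 1 | ema$mood > 10)))
    stop("EMA mood values must lie in [1, 10]", call. = FALSE)
  records$mood <- NA_real_
  if (!nrow(ema)) return(records)
  records <- records[order(records$participant_id, records$hour_start), ]
  ema_hour <- floor(as.numeric(ema$timestamp) / 3600)
  rec_hour <- floor(as.numeric(records$hour_start) / 3600)
  with_seed(derive_seed(noise_seed, paste0("mood_noise_", noise_per)), {
    for (id in unique(ema$participant_id)) {
      rsel <- which(records$participant_id == id)
      if (!length(rsel)) next
      hrs <- rec_hour[rsel]
      slp <- records$sleep_seconds[rsel]
      slp[is.na(slp)] <- 0
      anchors <- sleep_run_anchors(hrs, slp)
      esel <- which(ema$participant_id == id)
      eh <- ema_hour[esel]
      eday <- floor(eh / 24)
      for (d in sort(unique(eday))) {
        dsel <- esel[eday == d]
        v <- mean(ema$mood[dsel])
        at <- max(eh[eday == d])
        prev_wake <- anchors$wake[anchors$wake <= at]
        start <- if (length(prev_wake)) max(prev_wake) else d * 24
        next_wake <- anchors$wake[anchors$qualifying & anchors$wake > at]
        end <- if (length(next_wake)) min(next_wake) else at + 24
        end <- min(end, at + 24)
        fill <- rsel[hrs >= start & hrs < end]
        if (!length(fill)) next
        eps <- if (noise_per == "hour") {
          stats::runif(length(fill), 0, 0.2)
        } else rep(stats::runif(1L, 0, 0.2), length(fill))
        records$mood[fill] <- v + eps
      }
    }
  })
  records
}

# Wake anchors: for each contiguous run of hours with sleep > 0, the hour
# after the run ends; qualifying means the run's summed sleep > 7200 s.
sleep_run_anchors <- function(hours, sleep_seconds) {
  asleep <- sleep_seconds > 0
  if (!any(asleep)) return(list(wake = numeric(0), qualifying = logical(0)))
  h <- hours[asleep]
  s <- sleep_seconds[asleep]
  run_id <- cumsum(c(1L, diff(h) > 1L))
  wake <- tapply(h, run_id, max) + 1
  total <- tapply(s, run_id, sum)
  list(wake = as.numeric(wake), qualifying = as.numeric(total) > 7200)
}

#' Zero-fill non-random step/sleep missingness
#'
#' Hours with classified sleep but no recorded steps get `step_count = 0`
#' (the participant was in bed, not walking); hours with steps but no sleep
#' record get `sleep_seconds = 0` and `in_bed_seconds = 0` (the participant
#' was awake). The assumption is applied symmetrically; hours missing both
#' are left untouched.
#'
#' @param records hourly records.
#' @return records with the two rules applied.
#' @export
fill_step_sleep_missing <- function(records) {
  slp <- !is.na(records$sleep_seconds) & records$sleep_seconds > 0
  records$step_count[slp & is.na(records$step_count)] <- 0L
  stp <- !is.na(records$step_count) & records$step_count > 0
  fix <- stp & is.na(records$sleep_seconds)
  records$sleep_seconds[fix] <- 0
  records$in_bed_seconds[fix] <- 0
  records
}

#' Drop hours missing any of the five features
#'
#' Run after [interpolate_mood()] and [fill_step_sleep_missing()]: only
#' hours with step count, sleep, in-bed, heart rate and an interpolated mood
#' all present survive.
#'
#' @param records hourly records with a `mood` column.
#' @return complete hourly records.
#' @export
drop_incomplete_hours <- function(records) {
  keep <- stats::complete.cases(records[FEATURES])
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove multivariate hourly outliers with an isolation forest
#'
#' Fits one isolation forest (default 250 trees, per-tree feature budget
#' equal to the full five-feature dimension) over all participant-hours
#' pooled, and removes rows whose anomaly score exceeds the standard 0.5
#' decision threshold (shorter-than-average isolation paths).
#'
#' @param records complete hourly records (five feature columns).
#' @param n_trees trees in the forest.
#' @param seed integer seed.
#' @param forest optionally a previously fitted forest to reuse (disables
#'   refitting, making the cleaning pass idempotent).
#' @return list with `records` (outliers removed), `report` (counts, per
#'   participant outlier counts) and `forest`.
#' @export
filter_outliers <- function(records, n_trees = 250L, seed = 1L,
                            forest = NULL) {
  x <- as.matrix(records[FEATURES])
  if (is.null(forest))
    forest <- fit_isolation_forest(x, n_trees = n_trees, seed = seed)
  scores <- iforest_scores(forest, x)
  flagged <- scores > 0.5
  per_part <- tapply(flagged, records$participant_id, sum)
  per_part_all <- stats::setNames(as.integer(per_part), names(per_part))
  out <- records[!flagged, , drop = FALSE]
  rownames(out) <- NULL
  report <- list(n_hours_in = nrow(records), n_hours_out = nrow(out),
                 n_outliers_removed = sum(flagged),
                 outliers_per_participant = per_part_all)
  list(records = out, report = report, forest = forest)
}

#' Filter out participants with extremely low data quality
#'
#' Retains participants with at least `min_hours` cleaned hours in the
#' baseline period and at least `min_hours` across the internship quarters,
#' and with nonzero variance on every hourly feature in their retained data.
#'
#' @param records cleaned hourly records with `period` labels.
#' @param min_hours eligibility threshold (default 100).
#' @return list with `records` and `report` (participant counts, reasons per
#'   dropped participant).
#' @export
filter_participants <- function(records, min_hours = 100L) {
  ids <- unique(records$participant_id)
  reasons <- character(0)
  drop_ids <- character(0)
  for (id in ids) {
    rec <- records[records$participant_id == id, , drop = FALSE]
    n_bl <- sum(rec$period == "BL")
    n_int <- sum(rec$period != "BL")
    if (n_bl < min_hours) {
      drop_ids <- c(drop_ids, id); reasons <- c(reasons, "baseline hours")
    } else if (n_int < min_hours) {
      drop_ids <- c(drop_ids, id); reasons <- c(reasons, "internship hours")
    } else {
      vars <- vapply(FEATURES, function(f) stats::var(rec[[f]]), numeric(1))
      if (any(vars == 0)) {
        drop_ids <- c(drop_ids, id); reasons <- c(reasons, "zero variance")
      }
    }
  }
  out <- records[!(records$participant_id %in% drop_ids), , drop = FALSE]
  rownames(out) <- NULL
  report <- list(
    n_participants_in = length(ids),
    n_participants_out = length(ids) - length(drop_ids),
    dropped_participants = data.frame(participant_id = drop_ids,
                                      reason = reasons,
                                      stringsAsFactors = FALSE))
  list(records = out, report = report)
}

#' Run the full hourly cleaning pipeline
#'
#' Applies, in order: mood interpolation, step/sleep zero-filling,
#' incomplete-hour dropping, isolation-forest outlier filtering, and
#' participant eligibility filtering.
#'
#' @param records raw hourly records.
#' @param ema EMA events.
#' @param seed integer seed (mood noise and forest).
#' @param min_hours participant eligibility threshold.
#' @param forest optional pre-fitted isolation forest to reuse.
#' @param noise_per see [interpolate_mood()].
#' @return list with cleaned `records`, a `report` combining all stage
#'   reports, and the fitted `forest`.
#' @export
clean_hourly <- function(records, ema, seed = 1L, min_hours = 100L,
                         forest = NULL, noise_per = "hour") {
  n_in <- nrow(records)
  records <- interpolate_mood(records, ema, noise_seed = seed,
                              noise_per = noise_per)
  records <- fill_step_sleep_missing(records)
  records <- drop_incomplete_hours(records)
  of <- filter_outliers(records, seed = seed, forest = forest)
  fp <- filter_participants(of$records, min_hours = min_hours)
  report <- c(list(n_hours_in = n_in, n_hours_out = nrow(fp$records)),
              of$report[c("n_outliers_removed", "outliers_per_participant")],
              fp$report)
  list(records = fp$records, report = report, forest = of$forest)
}
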