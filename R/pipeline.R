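# End-to-end orchestration: simulate (optional) -> clean -> indicators ->
# trajectories -> GEE screen -> participant split -> cluster -> train ->
# predict -> evaluate -> predicted-indicator GEE -> coefficient contrast.

#' Validate input tables against the pipeline schema
#'
#' Checks column presence and types, value ranges (PHQ-9 in 0-27, mood in
#' 1-10, non-negative counts/durations, heart rate within its physical
#' range), hourly-grid alignment and per-(participant, hour) uniqueness.
#'
#' @param hourly,ema,phq,covariates data.frames (any may be `NULL` to skip).
#' @return data.frame of violations (`table`, `problem`, `detail`); zero
#'   rows when everything conforms.
#' @export
validate_inputs <- function(hourly = NULL, ema = NULL, phq = NULL,
                            covariates = NULL) {
  v <- list()
  add <- function(tab, problem, detail)
    v[[length(v) + 1L]] <<- data.frame(table = tab, problem = problem,
                                       detail = detail,
                                       stringsAsFactors = FALSE)
  if (!is.null(hourly)) {
    need <- c("participant_id", "hour_start", "step_count", "sleep_seconds",
              "in_bed_seconds", "mean_heart_rate")
    miss <- setdiff(need, names(hourly))
    if (length(miss)) add("hourly", "missing columns",
                          paste(miss, collapse = ", "))
    else {
      secs <- as.numeric(hourly$hour_start)
      off <- which(secs %% 3600 != 0)
      if (length(off)) add("hourly", "hour grid",
                           sprintf("%d timestamps not on the hour (first row %d)",
                                   length(off), off[1]))
      key <- paste(hourly$participant_id, secs)
      dup <- which(duplicated(key))
      if (length(dup)) add("hourly", "uniqueness",
                           sprintf("%d duplicated (participant, hour) rows (first row %d)",
                                   length(dup), dup[1]))
      for (col in c("step_count", "sleep_seconds", "in_bed_seconds")) {
        bad <- which(hourly[[col]] < 0)
        if (length(bad)) add("hourly", "range",
                             sprintf("%s negative in row %d", col, bad[1]))
      }
      bad <- which(hourly$mean_heart_rate < HR_RANGE[1] |
                     hourly$mean_heart_rate > HR_RANGE[2])
      if (length(bad)) add("hourly", "range",
                           sprintf("mean_heart_rate outside [%d, %d] in row %d",
                                   HR_RANGE[1], HR_RANGE[2], bad[1]))
    }
  }
  if (!is.null(ema)) {
    miss <- setdiff(c("participant_id", "timestamp", "mood"), names(ema))
    if (length(miss)) add("ema", "missing columns",
                          paste(miss, collapse = ", "))
    else {
      bad <- which(ema$mood < 1 | ema$mood > 10)
      if (length(bad)) add("ema", "range",
                           sprintf("mood outside [1, 10] in row %d", bad[1]))
    }
  }
  if (!is.null(phq)) {
    miss <- setdiff(c("participant_id", "period", "phq9"), names(phq))
    if (length(miss)) add("phq", "missing columns",
                          paste(miss, collapse = ", "))
    else {
      bad <- which(phq$phq9 < 0 | phq$phq9 > 27)
      if (length(bad)) add("phq", "range",
                           sprintf("phq9 outside [0, 27] in row %d", bad[1]))
      bad <- which(!phq$period %in% PERIODS)
      if (length(bad)) add("phq", "range",
                           sprintf("unknown period in row %d", bad[1]))
    }
  }
  if (!is.null(covariates)) {
    miss <- setdiff(c("participant_id", "sex", "age", "specialty"),
                    names(covariates))
    if (length(miss)) add("covariates", "missing columns",
                          paste(miss, collapse = ", "))
  }
  if (!length(v))
    return(data.frame(table = character(0), problem = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Split participants into training and test sets
#'
#' Participant-level (leave-subject-out) split, stratified by trajectory
#' class, with largest-remainder rounding so the realized training size is
#' `round(n * train_fraction)`.
#'
#' @param ids participant identifiers.
#' @param train_fraction fraction in (0, 1), default 0.8.
#' @param strata optional factor aligned with `ids` (trajectory classes).
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_participants <- function(ids, train_fraction = 0.8, strata = NULL,
                               seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction", "must be in (0, 1)")
  if (is.null(strata)) strata <- rep(1L, length(ids))
  target <- round(length(ids) * train_fraction)
  groups <- split(seq_along(ids), strata)
  quota_raw <- vapply(groups, length, integer(1)) * train_fraction
  quota <- floor(quota_raw)
  short <- target - sum(quota)
  if (short > 0) {
    extra <- order(quota_raw - quota, decreasing = TRUE)[seq_len(short)]
    quota[extra] <- quota[extra] + 1L
  }
  train_idx <- with_seed(derive_seed(seed, "split"), {
    unlist(lapply(seq_along(groups), function(g)
      sample(groups[[g]], min(quota[g], length(groups[[g]])))))
  })
  list(train = ids[sort(train_idx)], test = ids[sort(setdiff(
    seq_along(ids), train_idx))])
}

#' Run the full analysis pipeline
#'
#' Executes every stage end to end on a synthetic cohort (or supplied
#' tables) and writes the artifact files to `out_dir`:
#' `clean_hourly.parquet` (CSV fallback when arrow is unavailable),
#' `cleaning_report.json`, `indicators.csv`, `classes.csv`, `fit.json`,
#' `gee_univariate.csv`, `gee_multivariate.csv`, `gee_contrasts.csv` and
#' `eval_report.json`. Every artifact records the master seed and a hash of
#' the configuration.
#'
#' @param config a [cohort_config()] used to simulate when no `cohort` is
#'   given, and as the source of the master seed.
#' @param out_dir output directory (created if needed).
#' @param cohort optionally a pre-built [simulate_cohort()] result.
#' @param train_fraction participant-level training fraction.
#' @param family generator family for the prediction stage.
#' @param epochs training epochs for the generator stage.
#' @param k_range trajectory class counts to consider.
#' @param n_restarts EM restarts per K.
#' @param stages character vector of stages to run after cleaning;
#'   subset of `c("gee", "predict")`. The indicator and trajectory stages
#'   always run.
#' @return invisibly, a list with every intermediate object.
#' @export
run_pipeline <- function(config, out_dir = tempfile("resilmark_run_"),
                         cohort = NULL, train_fraction = 0.8,
                         family = "FP-CGAN", epochs = 30L,
                         k_range = 2:5, n_restarts = 5L,
                         stages = c("gee", "predict")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stamp <- list(seed = seed,
                config_hash = config_hash(config),
                timestamp = format(Sys.time(), tz = "UTC"))

  log_msg <- function(...) message(sprintf(...))
  if (is.null(cohort)) {
    log_msg("simulate: %d participants", config$n_participants)
    cohort <- apply_missingness(simulate_cohort(config))
  }
  bad <- validate_inputs(cohort$hourly, cohort$ema, cohort$phq,
                         cohort$covariates)
  if (nrow(bad))
    stop("stage 'validate': ", paste(bad$table, bad$problem, bad$detail,
                                     collapse = "; "), call. = FALSE)

  log_msg("clean: %d raw hours", nrow(cohort$hourly))
  cl <- clean_hourly(cohort$hourly, cohort$ema,
                     seed = derive_seed(seed, "clean"))
  write_clean_records(cl$records, out_dir)
  jsonlite::write_json(c(stamp, cl$report[setdiff(names(cl$report),
                                                  "outliers_per_participant")],
                         list(outliers_per_participant =
                                as.list(cl$report$outliers_per_participant))),
                       file.path(out_dir, "cleaning_report.json"),
                       auto_unbox = TRUE, digits = NA)

  log_msg("indicators")
  indicators <- build_indicator_table(cl$records)
  utils::write.csv(indicators, file.path(out_dir, "indicators.csv"),
                   row.names = FALSE)

  log_msg("trajectories")
  phq <- cohort$phq[cohort$phq$participant_id %in%
                      indicators$participant_id, ]
  fit <- select_class_count(phq, k_range, n_restarts = n_restarts,
                            seed = derive_seed(seed, "gmm"))
  labels <- label_resilience(fit)
  utils::write.csv(labels, file.path(out_dir, "classes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(stamp, list(K = fit$K, gamma = fit$gamma, pi = fit$pi,
                  tau2 = fit$tau2, sigma2 = fit$sigma2,
                  loglik = fit$loglik, AIC = fit$AIC, BIC = fit$BIC,
                  criteria = attr(fit, "criteria"))),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)

  aligned <- merge(indicators, labels[c("participant_id", "resilient")],
                   by = "participant_id")
  aligned <- merge(aligned, cohort$covariates, by = "participant_id")
  std <- standardize_indicators(
    aligned[c("participant_id", indicator_names())])

  gee_uni <- NULL; gee_multi <- NULL
  if ("gee" %in% stages) {
    log_msg("gee screen")
    covs <- aligned[c("sex", "age", "specialty")]
    gee_uni <- screen_indicators(std, aligned$resilient, covs)
    utils::write.csv(cbind(gee_uni, model = "univariate"),
                     file.path(out_dir, "gee_univariate.csv"),
                     row.names = FALSE)
    sig <- gee_uni[gee_uni$significant, ]
    if (nrow(sig)) {
      keep <- prune_collinear(std, stats::setNames(sig$p, sig$indicator))
      gee_multi <- fit_multivariate_gee(std, keep, aligned$resilient, covs)
      tab <- gee_multi$table
      utils::write.csv(cbind(tab[tab$term %in% keep,
                                 c("term", "beta", "ci_lo", "ci_hi", "p")],
                             model = "multivariate"),
                       file.path(out_dir, "gee_multivariate.csv"),
                       row.names = FALSE)
    } else {
      utils::write.csv(data.frame(), file.path(out_dir,
                                               "gee_multivariate.csv"),
                       row.names = FALSE)
    }
  }

  gen <- NULL; eval_report <- NULL; contrasts <- NULL
  pred <- NULL
  if ("predict" %in% stages) {
    log_msg("split/cluster/train (%s)", family)
    cls_by_id <- labels$class_id[match(indicators$participant_id,
                                       labels$participant_id)]
    sp <- split_participants(indicators$participant_id, train_fraction,
                             strata = cls_by_id,
                             seed = derive_seed(seed, "traintest"))
    train_rec <- cl$records[cl$records$participant_id %in% sp$train, ]
    test_rec <- cl$records[cl$records$participant_id %in% sp$test, ]
    train_ind <- indicators[indicators$participant_id %in% sp$train, ]
    clusters <- if (grepl("^F?P", family))
      cluster_participants(train_ind,
                           seed = derive_seed(seed, "cluster")) else NULL
    spec <- generator_spec(family = family, epochs = epochs,
                           seed = derive_seed(seed, "train"))
    gen <- train_generator(spec, train_rec, clusters)

    log_msg("predict + evaluate")
    pred <- predict_indicators(gen, rbind(train_rec, test_rec),
                               noise_seed = derive_seed(seed, "predict"))
    ds_cols <- grep("__cohens_ds__DIFF$", names(indicators), value = TRUE)
    train_means <- colMeans(train_ind[ds_cols])
    test_act <- indicators[indicators$participant_id %in% sp$test, ]
    test_pred <- pred[pred$participant_id %in% sp$test, ]
    eval_report <- evaluate_predictions(test_act, test_pred, train_means)
    jsonlite::write_json(c(stamp, list(family = family,
                                       split = lapply(sp, length),
                                       evaluation = eval_report)),
                         file.path(out_dir, "eval_report.json"),
                         auto_unbox = TRUE, digits = NA)

    log_msg("predicted-indicator contrast")
    pred_aligned <- pred[match(aligned$participant_id,
                               pred$participant_id), ]
    contrasts <- compare_actual_vs_predicted(
      aligned[c("participant_id", ds_cols)],
      pred_aligned[c("participant_id", ds_cols)],
      aligned$resilient, aligned[c("sex", "age", "specialty")])
    utils::write.csv(contrasts, file.path(out_dir, "gee_contrasts.csv"),
                     row.names = FALSE)
  }
  invisible(list(cohort = cohort, records = cl$records,
                 cleaning_report = cl$report, indicators = indicators,
                 fit = fit, labels = labels, gee_univariate = gee_uni,
                 gee_multivariate = gee_multi, generator = gen,
                 predicted = pred, evaluation = eval_report,
                 contrasts = contrasts, out_dir = out_dir))
}

config_hash <- function(config) {
  flat <- paste(utils::capture.output(utils::str(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(flat) * (seq_along(utf8ToInt(flat)) %% 97)))
}

write_clean_records <- function(records, out_dir) {
  if (requireNamespace("arrow", quietly = TRUE)) {
    arrow::write_parquet(records, file.path(out_dir, "clean_hourly.parquet"))
  } else {
    utils::write.csv(records, file.path(out_dir, "clean_hourly.csv"),
                     row.names = FALSE)
  }
}
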