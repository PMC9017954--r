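# Participant clustering, generator training across families, generation,
# cluster matching, predicted indicators. Heavier simulations live in the
# acceptance suite; these tests use small cohorts and short schedules.

tiny_records <- function(n_participants = 20, shift = 0.5, seed = 3,
                         hours = 150, clusters = c(0.7, 0.3)) {
  # hand-built continuous features so training is fast and well-behaved
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_participants), function(i) {
    cl <- 1L + (runif(1) > clusters[1])
    sh <- if (cl == 1L) shift else -shift
    mk <- function(n, s) data.frame(
      step_count = rnorm(n, 5 + s), sleep_seconds = rnorm(n, s),
      in_bed_seconds = rnorm(n, s), mean_heart_rate = rnorm(n, 70 + 5 * s),
      mood = rnorm(n, 7))
    rbind(cbind(participant_id = sprintf("T%02d", i), period = "BL",
                mk(hours, 0), cluster = cl),
          cbind(participant_id = sprintf("T%02d", i), period = "Q1",
                mk(hours, sh), cluster = cl))
  }))
}

test_that("planted d_s clusters are recovered with sizes near truth", {
  shifts <- two_cluster_shifts(sleep1 = 0.8, sleep2 = -0.8)
  cfg <- cohort_config(n_participants = 60, baseline_weeks = 2,
                       weeks_per_quarter = 1, shift_clusters = shifts,
                       dropout_hazard_per_quarter = 0, seed = 19)
  coh <- simulate_cohort(cfg)
  cl <- clean_hourly(coh$hourly, coh$ema, seed = 20)
  ind <- build_indicator_table(cl$records)
  cm <- cluster_participants(ind, seed = 21)
  expect_equal(cm$k, 2L)
  truth <- coh$truth$cluster_id[match(names(cm$labels),
                                      coh$truth$participant_id)]
  agree <- max(mean(cm$labels == truth), mean(cm$labels == 3 - truth))
  expect_gte(agree, 0.9)
  planted_sizes <- tabulate(truth)
  expect_true(all(abs(sort(cm$sizes, decreasing = TRUE) -
                        sort(planted_sizes, decreasing = TRUE)) <=
                    0.1 * length(truth)))
  # determinism
  cm2 <- cluster_participants(ind, seed = 21)
  expect_identical(cm$labels, cm2$labels)
})

test_that("identical d_s profiles cannot be clustered", {
  tab <- data.frame(participant_id = letters[1:12])
  for (f in c("step_count", "sleep_seconds", "in_bed_seconds",
              "mean_heart_rate", "mood"))
    tab[[paste0(f, "__cohens_ds__DIFF")]] <- 0.3
  expect_error(cluster_participants(tab), "failure to cluster")
})

test_that("generator specs validate families and P-variants need clusters", {
  expect_error(generator_spec("XGAN"))
  spec <- generator_spec("P-CGAN", epochs = 1)
  rec <- tiny_records(6)
  expect_error(train_generator(spec, rec, clusters = NULL), "cluster")
})

test_that("training logs are seed-reproducible", {
  rec <- tiny_records(8, hours = 60)
  spec <- generator_spec("CGAN", epochs = 3, seed = 5)
  g1 <- suppressWarnings(train_generator(spec, rec))
  g2 <- suppressWarnings(train_generator(spec, rec))
  expect_identical(g1$training_log, g2$training_log)
  expect_equal(nrow(g1$training_log), 3L)
})

test_that("GEN regression learns an identity-shift null", {
  rec <- tiny_records(12, shift = 0, hours = 120)
  spec <- generator_spec("GEN", epochs = 25, lr_g = 1e-3, seed = 7)
  gen <- suppressWarnings(train_generator(spec, rec))
  ids <- unique(rec$participant_id)[1:6]
  ds <- vapply(ids, function(id) {
    A <- rec[rec$participant_id == id & rec$period == "BL",
             resilmark:::FEATURES]
    Bp <- generate_internship(gen, A, draws_per_point = 1, noise_seed = 4)
    mean(vapply(seq_along(resilmark:::FEATURES), function(j)
      cohens_ds_points(A[[j]], Bp[, j]), numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(ds)), 0.15)
})

test_that("generated output is deterministic, sized and range-clipped", {
  rec <- tiny_records(10, hours = 80)
  spec <- generator_spec("CGAN", epochs = 5, seed = 8)
  gen <- suppressWarnings(train_generator(spec, rec))
  A <- rec[rec$participant_id == "T01" & rec$period == "BL",
           resilmark:::FEATURES][1:60, ]
  b1 <- generate_internship(gen, A, draws_per_point = 3, noise_seed = 11)
  b2 <- generate_internship(gen, A, draws_per_point = 3, noise_seed = 11)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 180L)
  for (j in seq_along(resilmark:::FEATURES)) {
    expect_gte(min(b1[, j]), gen$norm$lo[j])
    expect_lte(max(b1[, j]), gen$norm$hi[j])
  }
  b3 <- generate_internship(gen, A, draws_per_point = 3, noise_seed = 12)
  expect_false(identical(b1, b3))
})

test_that("a zero-weight generator without skip emits its bias", {
  rec <- tiny_records(6, hours = 50)
  spec <- generator_spec("CGAN", epochs = 1, identity_skip = FALSE,
                         seed = 2)
  gen <- suppressWarnings(train_generator(spec, rec))
  for (l in seq_along(gen$model$trunk)) gen$model$trunk[[l]]$W[] <- 0
  for (h in seq_along(gen$model$heads))
    for (l in seq_along(gen$model$heads[[h]])) {
      gen$model$heads[[h]][[l]]$W[] <- 0
      gen$model$heads[[h]][[l]]$b[] <- 0
    }
  gen$model$heads[[1]][[length(gen$model$heads[[1]])]]$b[] <- 0.25
  A <- rec[rec$participant_id == "T01" & rec$period == "BL",
           resilmark:::FEATURES][1:20, ]
  out <- generate_internship(gen, A, noise_seed = 3)
  z <- sweep(sweep(out, 2, gen$norm$mean), 2, gen$norm$sd, `/`)
  expect_true(all(abs(z - 0.25) < 1e-10))
})

test_that("MLP families predict d_s from baseline means", {
  rec <- tiny_records(16, shift = 0.6, hours = 100)
  spec <- generator_spec("MLP", epochs = 60, lr_g = 3e-3, seed = 6)
  gen <- train_generator(spec, rec)
  expect_error(generate_internship(gen, rec[1:10, resilmark:::FEATURES]),
               "MLP")
  A <- rec[rec$participant_id == "T01" & rec$period == "BL",
           resilmark:::FEATURES]
  pred <- predict(gen, A)
  expect_length(pred, 5L)
  expect_named(pred, resilmark:::FEATURES)
  # training loss decreased
  log <- gen$training_log
  expect_lt(mean(tail(log$loss, 3)), mean(head(log$loss, 3)))
})

test_that("cluster matching recovers the generating head and breaks ties", {
  rec <- tiny_records(24, shift = 0.8, seed = 9, hours = 200)
  ind <- build_indicator_table(rec)
  cm <- cluster_participants(ind, k_range = 2, seed = 10)
  spec <- generator_spec("P-GEN", epochs = 30, lr_g = 1e-3, seed = 11)
  gen <- suppressWarnings(train_generator(spec, rec, cm))
  truth <- rec$cluster[match(names(cm$labels), rec$participant_id)]
  ids <- names(cm$labels)
  matched <- vapply(ids, function(id) {
    A <- rec[rec$participant_id == id & rec$period == "BL",
             resilmark:::FEATURES]
    Q <- rec[rec$participant_id == id & rec$period == "Q1",
             resilmark:::FEATURES]
    match_cluster(gen, A, Q, noise_seed = 12)
  }, integer(1))
  agree <- max(mean(matched == truth), mean(matched == 3 - truth))
  expect_gte(agree, 0.85)
  # no Q1 data: instructed fallback
  A <- rec[rec$participant_id == ids[1] & rec$period == "BL",
           resilmark:::FEATURES]
  expect_error(match_cluster(gen, A, A[0, ]), "larger training cluster")
  # identical heads tie toward the larger cluster
  gen2 <- gen
  big <- which.max(gen2$clusters$sizes)
  for (h in seq_along(gen2$model$heads))
    gen2$model$heads[[h]] <- gen2$model$heads[[1]]
  expect_equal(match_cluster(gen2, A,
                             rec[rec$participant_id == ids[1] &
                                   rec$period == "Q1",
                                 resilmark:::FEATURES]),
               as.integer(big))
})

test_that("predicted indicator tables mirror the actual schema", {
  rec <- tiny_records(12, shift = 0.4, hours = 80)
  ind <- build_indicator_table(rec)
  cm <- cluster_participants(ind, k_range = 2, seed = 13)
  spec <- generator_spec("P-CGAN", epochs = 4, seed = 14)
  gen <- suppressWarnings(train_generator(spec, rec, cm))
  pred <- predict_indicators(gen, rec, noise_seed = 15)
  expect_setequal(setdiff(names(pred), "matched_cluster"), names(ind))
  expect_equal(nrow(pred), nrow(ind))
  # baseline-only entries are the actual baseline statistics
  i <- match(pred$participant_id, ind$participant_id)
  for (col in grep("__BL$", names(ind), value = TRUE))
    expect_equal(pred[[col]], ind[[col]][i], tolerance = 1e-10)
})
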