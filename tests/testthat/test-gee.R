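# Logistic GEE screening: standardization, estimation, pruning,
# multivariate fit, actual-vs-predicted contrasts.

make_cohort_xy <- function(n = 775, beta = 0.5, seed = 1) {
  lat <- simulate_participants(cohort_config(n_participants = n,
                                             seed = seed))
  list(x = lat$truth$planted_mood__cohens_ds__DIFF,
       y = lat$truth$resilient,
       cov = lat$covariates)
}

test_that("standardization yields unit-variance columns and a constant", {
  tab <- data.frame(participant_id = letters[1:10],
                    a = 1:10, b = rnorm(10), c = rep(4, 10))
  out <- suppressWarnings(standardize_indicators(tab))
  expect_equal(mean(out$a), 0)
  expect_equal(sd(out$a), 1)
  expect_equal(out$a[1:3], (1:3 - 5.5) / sd(1:10))
  expect_null(out[["c"]])                # zero-SD column dropped
  expect_warning(standardize_indicators(tab), "zero-variance")
  expect_true(all(out$const == 1))
  # idempotence
  out2 <- standardize_indicators(out)
  expect_equal(out2$a, out$a, tolerance = 1e-12)
})

test_that("GEE with singleton clusters matches ordinary logistic regression", {
  set.seed(7)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.2 + 0.4 * x))
  cov <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 27, 2),
                    specialty = paste0("s", seq_len(n)))
  fit <- fit_univariate_gee(x, y, cov, "x")
  ref <- glm(y ~ x + sex + age, data = cbind(cov, x = x, y = y),
             family = binomial)
  expect_equal(unname(coef(fit)),
               unname(coef(ref)[c("(Intercept)", "x", "sex", "age")]),
               tolerance = 1e-4)
})

test_that("planted effects are estimated with correct sign and coverage", {
  covered <- vapply(1:20, function(s) {
    d <- make_cohort_xy(seed = 100 + s)
    fit <- fit_univariate_gee(d$x, d$y, d$cov, "planted")
    tab <- fit$table[fit$table$term == "planted", ]
    tab$ci_lo <= 0.5 && 0.5 <= tab$ci_hi
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("flipping the outcome coding flips the coefficient sign", {
  d <- make_cohort_xy(seed = 9)
  f1 <- fit_univariate_gee(d$x, d$y, d$cov, "v")
  f2 <- fit_univariate_gee(d$x, !d$y, d$cov, "v")
  expect_equal(coef(f1)[["v"]], -coef(f2)[["v"]], tolerance = 1e-6)
})

test_that("scale of the raw indicator does not affect the standardized beta", {
  d <- make_cohort_xy(seed = 13)
  z1 <- (d$x - mean(d$x)) / sd(d$x)
  x2 <- d$x * 37.5
  z2 <- (x2 - mean(x2)) / sd(x2)
  f1 <- fit_univariate_gee(z1, d$y, d$cov, "v")
  f2 <- fit_univariate_gee(z2, d$y, d$cov, "v")
  expect_equal(coef(f1)[["v"]], coef(f2)[["v"]], tolerance = 1e-8)
})

test_that("complete separation is reported as an error", {
  n <- 60
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- ifelse(y, 1, -1) + rnorm(n, 0, 1e-4)
  cov <- data.frame(sex = rbinom(n, 1, .5), age = rnorm(n, 27),
                    specialty = rep(c("a", "b", "c"), length.out = n))
  expect_error(fit_univariate_gee(x, y, cov, "sep"), "separation|singular")
})

test_that("collinearity pruning keeps the smallest-p representative", {
  set.seed(3)
  base <- rnorm(200)
  tab <- data.frame(i1 = base + rnorm(200, 0, 0.1),
                    i2 = base + rnorm(200, 0, 0.1),
                    i3 = base + rnorm(200, 0, 0.1),
                    solo = rnorm(200))
  p <- c(i1 = 0.01, i2 = 0.002, i3 = 0.03, solo = 0.04)
  keep <- prune_collinear(tab, p, threshold = 0.7)
  expect_setequal(keep, c("i2", "solo"))
  # identical columns: exactly one survives
  tab2 <- data.frame(a = base, b = base)
  expect_equal(length(prune_collinear(tab2, c(a = 0.5, b = 0.5))), 1L)
  # orthogonal indicators all survive
  tab3 <- data.frame(x = rnorm(100), y = rnorm(100), z = rnorm(100))
  expect_setequal(prune_collinear(tab3, c(x = .1, y = .2, z = .3)),
                  c("x", "y", "z"))
})

test_that("a single-indicator multivariate model equals the univariate fit", {
  d <- make_cohort_xy(seed = 17)
  ind <- data.frame(participant_id = d$cov$participant_id, v = d$x)
  std <- standardize_indicators(ind)
  f_multi <- fit_multivariate_gee(std, "v", d$y, d$cov)
  f_uni <- fit_univariate_gee(std$v, d$y, d$cov, "v")
  expect_equal(coef(f_multi)[["v"]], coef(f_uni)[["v"]], tolerance = 1e-6)
  expect_error(fit_multivariate_gee(std, character(0), d$y, d$cov),
               "no indicators")
})

test_that("two independent planted effects are both recovered", {
  hits <- vapply(1:20, function(s) {
    cfg <- cohort_config(
      n_participants = 775,
      indicator_effects = list(
        list(indicator = "mood__cohens_ds__DIFF", beta = 0.4),
        list(indicator = "sleep_seconds__cohens_ds__DIFF", beta = -0.3)),
      seed = 700 + s)
    lat <- simulate_participants(cfg)
    ind <- data.frame(
      participant_id = lat$truth$participant_id,
      m = lat$truth$planted_mood__cohens_ds__DIFF,
      s = lat$truth$planted_sleep_seconds__cohens_ds__DIFF)
    std <- standardize_indicators(ind)
    fit <- fit_multivariate_gee(std, c("m", "s"), lat$truth$resilient,
                                lat$covariates)
    coef(fit)[["m"]] > 0 && coef(fit)[["s"]] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("self-comparison of actual vs predicted is never significant", {
  d <- make_cohort_xy(seed = 23)
  act <- data.frame(participant_id = d$cov$participant_id, v = d$x)
  out <- compare_actual_vs_predicted(act, act, d$y, d$cov)
  expect_false(out$significantly_different)
  expect_lt(abs(out$interaction_beta), 0.05)
})

test_that("a sign-flipped predicted indicator is flagged as different", {
  d <- make_cohort_xy(seed = 29)
  act <- data.frame(participant_id = d$cov$participant_id, v = d$x)
  pred <- act; pred$v <- -pred$v
  out <- compare_actual_vs_predicted(act, pred, d$y, d$cov)
  expect_true(out$significantly_different)
  # doubling the association strength moves the interaction the same way
  pred2 <- act; pred2$v <- pred2$v + 0.5 * (2 * as.numeric(d$y) - 1)
  out2 <- compare_actual_vs_predicted(act, pred2, d$y, d$cov)
  expect_gt(out2$interaction_beta, 0)
  # mismatched participant sets abort
  expect_error(compare_actual_vs_predicted(act, pred[-1, ], d$y, d$cov),
               "same participants")
})
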