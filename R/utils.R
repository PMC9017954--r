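# Internal helpers shared across modules.

FEATURES <- c("step_count", "sleep_seconds", "in_bed_seconds",
              "mean_heart_rate", "mood")

PERIODS <- c("BL", "Q1", "Q2", "Q3", "Q4")

HR_RANGE <- c(35, 204)

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so any stage can be replayed in isolation.
#'
#' @param seed master integer seed.
#' @param stream character stream name.
#' @return an integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 69069 + h * 7919) %% 2147483629)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a probability in [0, 1]")
  x
}

check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != as.integer(x))
    stop_config(field, "must be a positive integer count")
  as.integer(x)
}

sample_sd <- function(x) stats::sd(x)

# Truncated-normal draws via inverse-cdf; vectorised over mean.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}
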