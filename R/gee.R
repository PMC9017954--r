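# Logistic generalized estimating equations with an exchangeable working
# correlation and cluster-robust (sandwich) covariance, used to screen
# indicators for association with the resilient class. Clusters are medical
# specialties; sex and age are controls.

#' Standardize indicator columns
#'
#' Centres and scales every numeric indicator column to mean 0, sample SD 1
#' (count indicators included), drops zero-SD columns with a warning, and
#' appends a constant intercept column `const = 1`.
#'
#' @param table data.frame of indicator columns (non-numeric columns such as
#'   `participant_id` are passed through untouched).
#' @return the standardized data.frame.
#' @export
standardize_indicators <- function(table) {
  num <- vapply(table, is.numeric, logical(1)) & names(table) != "const"
  for (nm in names(table)[num]) {
    s <- sample_sd(table[[nm]])
    if (!is.finite(s) || s == 0) {
      warning(sprintf("dropping zero-variance indicator '%s'", nm))
      table[[nm]] <- NULL
    } else {
      table[[nm]] <- (table[[nm]] - mean(table[[nm]])) / s
    }
  }
  table$const <- 1
  table
}

# Core GEE solver: binomial family, logit link, exchangeable working
# correlation within clusters, moment estimate of the correlation, robust
# sandwich covariance. X must already contain an intercept column.
gee_logit_fit <- function(y, X, cluster, max_iter = 50L, tol = 1e-10) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  cl <- split(seq_len(n), cluster)
  # initialise at the GLM estimate
  beta <- tryCatch(
    stats::glm.fit(X, y, family = stats::binomial())$coefficients,
    error = function(e) rep(0, p))
  if (anyNA(beta)) stop("design matrix is rank deficient", call. = FALSE)
  alpha <- 0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-12))
      w <- pmax(w, 1e-12)
    e <- (y - mu) / sqrt(w)
    # moment estimator of the exchangeable correlation
    num <- 0; den <- 0
    for (idx in cl) {
      ni <- length(idx)
      if (ni > 1L) {
        s <- sum(e[idx])
        num <- num + (s^2 - sum(e[idx]^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
    }
    phi <- sum(e^2) / (n - p)
    alpha <- if (den > 0) num / (den * phi) else 0
    # keep the exchangeable working correlation positive definite for the
    # largest cluster: alpha must exceed -1/(max n_i - 1)
    max_ni <- max(lengths(cl))
    alpha_lo <- if (max_ni > 1L) -0.9 / (max_ni - 1) else 0
    alpha <- min(max(alpha, alpha_lo), 0.99)

    A <- matrix(0, p, p)
    b <- numeric(p)
    for (idx in cl) {
      ni <- length(idx)
      Xi <- X[idx, , drop = FALSE]
      wi <- w[idx]
      ri <- y[idx] - mu[idx]
      # D = diag(w) X ; V^-1 = diag(1/sqrt(w)) R^-1 diag(1/sqrt(w))
      # D' V^-1 = X' diag(sqrt(w)) R^-1 diag(1/sqrt(w)) applied to residual
      sw <- sqrt(wi)
      Zi <- Xi * sw                          # rows scaled by sqrt(w)
      ui <- ri / sw                          # Pearson residual
      if (ni == 1L || alpha == 0) {
        Rinv_u <- ui
        Rinv_Z <- Zi
      } else {
        c1 <- 1 / (1 - alpha)
        c2 <- alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
        Rinv_u <- c1 * ui - c2 * sum(ui)
        Rinv_Z <- c1 * Zi - matrix(c2 * colSums(Zi), ni, p, byrow = TRUE)
      }
      A <- A + crossprod(Zi, Rinv_Z)
      b <- b + drop(crossprod(Zi, Rinv_u))
    }
    step <- tryCatch(solve(A, b), error = function(e)
      stop("GEE update failed: singular working information", call. = FALSE))
    beta <- beta + step
    if (max(abs(step)) < tol * (max(abs(beta)) + 1)) {
      converged <- TRUE
      break
    }
  }
  if (max(abs(beta)) > 30)
    stop("apparent complete separation: diverging coefficients",
         call. = FALSE)

  # robust sandwich covariance at the solution
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  A <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (idx in cl) {
    ni <- length(idx)
    Xi <- X[idx, , drop = FALSE]
    sw <- sqrt(w[idx])
    Zi <- Xi * sw
    ui <- (y[idx] - mu[idx]) / sw
    if (ni == 1L || alpha == 0) {
      Rinv_u <- ui
      Rinv_Z <- Zi
    } else {
      c1 <- 1 / (1 - alpha)
      c2 <- alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
      Rinv_u <- c1 * ui - c2 * sum(ui)
      Rinv_Z <- c1 * Zi - matrix(c2 * colSums(Zi), ni, length(beta),
                                 byrow = TRUE)
    }
    A <- A + crossprod(Zi, Rinv_Z)
    g <- drop(crossprod(Zi, Rinv_u))
    M <- M + tcrossprod(g)
  }
  Ainv <- solve(A)
  vcov <- Ainv %*% M %*% Ainv
  list(beta = beta, vcov = vcov, alpha = alpha, converged = converged,
       n = n, n_clusters = length(cl))
}

new_gee_fit <- function(core, terms, kind, indicator) {
  se <- sqrt(diag(core$vcov))
  z <- core$beta / se
  # t-referenced inference with G-1 degrees of freedom: the plain normal
  # reference is anti-conservative when the number of clusters is small
  df <- max(core$n_clusters - 1L, 1L)
  p <- 2 * stats::pt(-abs(z), df)
  crit <- stats::qt(0.975, df)
  tab <- data.frame(term = terms, beta = core$beta, se = se,
                    ci_lo = core$beta - crit * se,
                    ci_hi = core$beta + crit * se,
                    z = z, p = p, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(coefficients = stats::setNames(core$beta, terms),
                 table = tab, vcov = core$vcov, alpha = core$alpha,
                 converged = core$converged, n = core$n,
                 n_clusters = core$n_clusters, kind = kind,
                 indicator = indicator),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, digits = 4, ...) {
  cat(sprintf("GEE (binomial logit, exchangeable): %s model, n = %d, %d clusters%s\n",
              x$kind, x$n, x$n_clusters,
              if (x$converged) "" else " [NOT converged]"))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab)
  invisible(x)
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$vcov

#' @export
summary.gee_fit <- function(object, ...) object$table

#' Univariate GEE screen of one indicator
#'
#' Fits a binomial logit GEE of the resilient label on one standardized
#' indicator plus controls (sex, age) and an intercept, clustered by
#' specialty with an exchangeable working correlation; inference is by the
#' cluster-robust sandwich covariance.
#'
#' @param indicator numeric vector (standardized indicator values).
#' @param labels logical/0-1 vector: resilient or not.
#' @param covariates data.frame with `sex`, `age` and `specialty`.
#' @param indicator_name character label for reporting.
#' @return a `gee_fit`.
#' @export
fit_univariate_gee <- function(indicator, labels, covariates,
                               indicator_name = "indicator") {
  stopifnot(all(c("sex", "age", "specialty") %in% names(covariates)),
            length(indicator) == length(labels),
            nrow(covariates) == length(labels))
  X <- cbind(const = 1, indicator = indicator, sex = covariates$sex,
             age = covariates$age)
  core <- tryCatch(
    gee_logit_fit(labels, X, covariates$specialty),
    error = function(e) stop(sprintf("indicator '%s': %s", indicator_name,
                                     conditionMessage(e)), call. = FALSE))
  new_gee_fit(core, c("const", indicator_name, "sex", "age"),
              "univariate", indicator_name)
}

#' Screen all indicators univariately
#'
#' Runs [fit_univariate_gee()] for every indicator column and collects the
#' indicator-term rows. An optional Benjamini-Hochberg adjustment is
#' available but off by default, matching the unadjusted per-indicator
#' screening convention.
#'
#' @param indicators standardized indicator data.frame (see
#'   [standardize_indicators()]); `participant_id` and `const` columns are
#'   ignored.
#' @param labels resilient labels aligned with `indicators` rows.
#' @param covariates data.frame with `sex`, `age`, `specialty`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame, one row per indicator: `indicator`, `beta`, `ci_lo`,
#'   `ci_hi`, `p`, `significant` (alpha = 0.05).
#' @export
screen_indicators <- function(indicators, labels, covariates,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  cols <- setdiff(names(indicators),
                  c("participant_id", "const"))
  rows <- lapply(cols, function(nm) {
    fit <- fit_univariate_gee(indicators[[nm]], labels, covariates, nm)
    r <- fit$table[fit$table$term == nm, c("beta", "ci_lo", "ci_hi", "p")]
    cbind(indicator = nm, r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p <- stats::p.adjust(out$p, "BH")
  out$significant <- out$p < 0.05
  rownames(out) <- NULL
  out
}

#' Prune highly correlated indicators
#'
#' Greedy removal: among any pair with absolute Spearman correlation above
#' the threshold, the indicator with the larger univariate p-value is
#' dropped. Indicators are visited in deterministic order (ascending p,
#' ties by name), each kept indicator eliminating its correlated partners.
#'
#' @param indicators data.frame of (standardized) indicator columns.
#' @param p_values named numeric vector of univariate p-values for the
#'   columns under consideration.
#' @param threshold absolute Spearman correlation above which a pair is
#'   considered collinear (default 0.7).
#' @return character vector of surviving indicator names.
#' @export
prune_collinear <- function(indicators, p_values, threshold = 0.7) {
  nms <- names(p_values)
  stopifnot(all(nms %in% names(indicators)))
  if (!length(nms)) return(character(0))
  ord <- nms[order(p_values, nms)]
  rho <- suppressWarnings(
    stats::cor(indicators[ord], method = "spearman"))
  keep <- character(0)
  dropped <- character(0)
  for (nm in ord) {
    if (nm %in% dropped) next
    keep <- c(keep, nm)
    worse <- ord[ord != nm & !(ord %in% dropped) & !(ord %in% keep)]
    coll <- worse[abs(rho[nm, worse]) > threshold]
    dropped <- c(dropped, coll)
  }
  keep
}

#' Multivariate GEE over the pruned indicator set
#'
#' One binomial logit GEE with all retained indicators plus controls.
#'
#' @param indicators standardized indicator data.frame.
#' @param keep character vector of indicator columns to include (from
#'   [prune_collinear()]).
#' @param labels,covariates as in [fit_univariate_gee()].
#' @return a `gee_fit`; the indicator rows of its `table` carry the
#'   multivariate coefficients.
#' @export
fit_multivariate_gee <- function(indicators, keep, labels, covariates) {
  if (!length(keep))
    stop("no indicators retained for the multivariate model", call. = FALSE)
  X <- cbind(const = 1, as.matrix(indicators[keep]),
             sex = covariates$sex, age = covariates$age)
  core <- gee_logit_fit(labels, X, covariates$specialty)
  new_gee_fit(core, c("const", keep, "sex", "age"), "multivariate",
              paste(keep, collapse = "+"))
}

#' Compare actual and predicted indicator coefficients
#'
#' Concatenates the actual and predicted indicator tables (same
#' participants), adds a binary source flag (1 = predicted) and a
#' source-by-indicator interaction, and fits the GEE with the same controls
#' and specialty grouping. The interaction coefficient models the change in
#' the indicator's association when predicted values replace actual ones; a
#' significant interaction (alpha = 0.05) marks the coefficients as
#' different.
#'
#' @param actual,predicted data.frames with identical `participant_id` sets
#'   and indicator columns.
#' @param labels,covariates per-participant outcome and controls (aligned
#'   with `actual`'s rows).
#' @param indicators which indicator columns to contrast (default: all
#'   shared numeric columns).
#' @return data.frame: `indicator`, `beta_actual`, `beta_predicted`,
#'   `interaction_beta`, `interaction_p`, `significantly_different`.
#' @export
compare_actual_vs_predicted <- function(actual, predicted, labels,
                                        covariates, indicators = NULL) {
  if (!setequal(actual$participant_id, predicted$participant_id))
    stop("actual and predicted tables must cover the same participants",
         call. = FALSE)
  predicted <- predicted[match(actual$participant_id,
                               predicted$participant_id), ]
  if (is.null(indicators))
    indicators <- setdiff(intersect(names(actual), names(predicted)),
                          c("participant_id", "const"))
  y2 <- rep(as.numeric(labels), 2L)
  cov2 <- rbind(covariates, covariates)
  src <- rep(c(0, 1), each = length(labels))
  rows <- lapply(indicators, function(nm) {
    v <- c(scale_vec(actual[[nm]]), scale_vec(predicted[[nm]]))
    X <- cbind(const = 1, indicator = v, source = src,
               interaction = v * src, sex = cov2$sex, age = cov2$age)
    core <- gee_logit_fit(y2, X, cov2$specialty)
    fit <- new_gee_fit(core, colnames(X), "interaction", nm)
    tab <- fit$table
    b_ind <- tab$beta[tab$term == "indicator"]
    b_int <- tab$beta[tab$term == "interaction"]
    p_int <- tab$p[tab$term == "interaction"]
    data.frame(indicator = nm, beta_actual = b_ind,
               beta_predicted = b_ind + b_int,
               interaction_beta = b_int, interaction_p = p_int,
               significantly_different = p_int < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

scale_vec <- function(x) {
  s <- sample_sd(x)
  if (!is.finite(s) || s == 0) stop("constant indicator column",
                                    call. = FALSE)
  (x - mean(x)) / s
}
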