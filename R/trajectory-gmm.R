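# Quadratic growth mixture model over delta-PHQ-9 series: a finite mixture
# of per-class quadratic mean curves over the quarter index t = 1..4, with a
# shared participant random intercept and shared residual variance, fitted
# by EM on the marginal likelihood over each participant's observed
# quarters. The baseline point is delta = 0 by construction and carries no
# information, so it is excluded from the likelihood.

# Reshape a long PHQ data.frame into a participants x quarters delta matrix.
delta_matrix <- function(series) {
  stopifnot(all(c("participant_id", "period") %in% names(series)))
  if (!"delta" %in% names(series)) {
    bl <- series[series$period == "BL", c("participant_id", "phq9")]
    names(bl)[2] <- "phq_bl"
    series <- merge(series, bl, by = "participant_id")
    series$delta <- series$phq9 - series$phq_bl
  }
  post <- series[series$period != "BL", , drop = FALSE]
  ids <- unique(series$participant_id)
  qs <- PERIODS[-1L]
  y <- matrix(NA_real_, length(ids), length(qs),
              dimnames = list(ids, qs))
  y[cbind(match(post$participant_id, ids), match(post$period, qs))] <-
    post$delta
  y[, colSums(!is.na(y)) > 0, drop = FALSE]
}

#' Fit a quadratic growth mixture model to delta-PHQ-9 series
#'
#' Mixture of K quadratic mean curves `g0 + g1 t + g2 t^2` over the quarter
#' index, with a shared random intercept variance `tau^2` and shared
#' residual variance `sigma^2`. Participants with missing quarters
#' contribute the marginal likelihood over their observed timepoints. EM is
#' initialised from k-means on the (mean-imputed) delta vectors and the best
#' of `n_restarts` runs by final log-likelihood is returned.
#'
#' @param series long data.frame with `participant_id`, `period` and either
#'   `delta` or `phq9` (delta is then computed against the BL row).
#' @param K number of trajectory classes (>= 1).
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return an object of class `quadratic_gmm` with elements `K`, `gamma`
#'   (K x 3), `pi`, `tau2`, `sigma2`, `responsibilities`, `loglik`,
#'   `loglik_trace`, `AIC`, `BIC`, `converged`, `n`.
#' @export
fit_quadratic_gmm <- function(series, K, n_restarts = 10L, seed = 1L,
                              max_iter = 200L, tol = 1e-8) {
  y <- delta_matrix(series)
  keep <- rowSums(!is.na(y)) >= 2L
  y <- y[keep, , drop = FALSE]
  n <- nrow(y)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > n) stop("K exceeds the number of usable series", call. = FALSE)
  if (n < 10L * K)
    warning("fewer than 10 series per class; fit may be unstable")
  t_grid <- seq_len(ncol(y))
  X_full <- cbind(1, t_grid, t_grid^2)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(derive_seed(seed, paste0("gmm_restart_", r)),
                     em_quadratic_gmm(y, X_full, K, max_iter, tol))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  p <- 3 * K + (K - 1) + 2
  best$AIC <- 2 * p - 2 * best$loglik
  best$BIC <- p * log(n) - 2 * best$loglik
  best$n_params <- p
  best$n <- n
  best$participant_id <- rownames(y)
  best$call <- match.call()
  class(best) <- "quadratic_gmm"
  best
}

em_quadratic_gmm <- function(y, X_full, K, max_iter, tol) {
  n <- nrow(y)
  obs <- !is.na(y)
  # group participants by missingness pattern so every E/M computation is
  # vectorised across the participants sharing a pattern
  pat_key <- apply(obs, 1, function(o) paste(as.integer(o), collapse = ""))
  patterns <- lapply(split(seq_len(n), pat_key), identity)
  # initialise from k-means on mean-imputed vectors (imputation used for
  # distances only)
  imp <- y
  for (j in seq_len(ncol(y)))
    imp[is.na(imp[, j]), j] <- mean(y[, j], na.rm = TRUE)
  cl <- if (K == 1L) rep(1L, n) else {
    km <- suppressWarnings(stats::kmeans(imp, centers = K, nstart = 1L))
    km$cluster
  }
  gamma <- matrix(0, K, 3)
  for (k in seq_len(K)) {
    sel <- which(cl == k)
    yy <- as.vector(y[sel, , drop = FALSE])
    xx <- X_full[rep(seq_len(ncol(y)), each = length(sel)), , drop = FALSE]
    ok <- !is.na(yy)
    gamma[k, ] <- tryCatch(stats::lsfit(xx[ok, -1, drop = FALSE], yy[ok])$coef,
                           error = function(e) c(mean(yy[ok], na.rm = TRUE), 0, 0))
  }
  pi_k <- tabulate(cl, K) / n
  pi_k <- pmax(pi_k, 1e-6); pi_k <- pi_k / sum(pi_k)
  tau2 <- 1; sigma2 <- stats::var(as.vector(y), na.rm = TRUE) / 2
  sigma2 <- max(sigma2, 1e-4)

  loglik_trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  resp <- matrix(0, n, K)
  for (iter in seq_len(max_iter)) {
    # E-step: marginal MVN log density per class over observed quarters,
    # Sigma = sigma2 I + tau2 J inverted with the rank-one Woodbury
    # identity.
    logd <- matrix(0, n, K)
    for (k in seq_len(K)) {
      mu_full <- drop(X_full %*% gamma[k, ])
      for (idx in patterns) {
        oi <- obs[idx[1L], ]
        ni <- sum(oi)
        R <- y[idx, oi, drop = FALSE] -
          matrix(mu_full[oi], length(idx), ni, byrow = TRUE)
        denom <- sigma2 + ni * tau2
        quad <- (rowSums(R^2) - tau2 * rowSums(R)^2 / denom) / sigma2
        logdet <- (ni - 1) * log(sigma2) + log(denom)
        logd[idx, k] <- -0.5 * (ni * log(2 * pi) + logdet + quad)
      }
    }
    lw <- sweep(logd, 2, log(pi_k), `+`)
    m <- apply(lw, 1, max)
    ll <- sum(m + log(rowSums(exp(lw - m))))
    loglik_trace <- c(loglik_trace, ll)
    resp <- exp(lw - m - log(rowSums(exp(lw - m))))
    if (is.finite(prev_ll) && abs(ll - prev_ll) < tol * (abs(prev_ll) + 1)) {
      converged <- TRUE
      break
    }
    prev_ll <- ll

    # M-step
    pi_k <- pmax(colMeans(resp), 1e-8); pi_k <- pi_k / sum(pi_k)
    new_tau2 <- 0; new_sig_num <- 0; new_sig_den <- 0
    for (k in seq_len(K)) {
      # weighted GLS for the class curve under Sigma = sigma2 I + tau2 J
      A <- matrix(0, 3, 3); b <- numeric(3)
      for (idx in patterns) {
        oi <- obs[idx[1L], ]
        ni <- sum(oi)
        Xi <- X_full[oi, , drop = FALSE]
        w <- tau2 / (sigma2 + ni * tau2)
        XtSi <- t(Xi) / sigma2 -
          (w / sigma2) * outer(colSums(Xi), rep(1, ni))
        rk <- resp[idx, k]
        A <- A + sum(rk) * (XtSi %*% Xi)
        b <- b + drop(XtSi %*% drop(crossprod(y[idx, oi, drop = FALSE], rk)))
      }
      gamma[k, ] <- drop(solve(A, b))
      mu_full <- drop(X_full %*% gamma[k, ])
      # posterior moments of the random intercept given class k
      for (idx in patterns) {
        oi <- obs[idx[1L], ]
        ni <- sum(oi)
        R <- y[idx, oi, drop = FALSE] -
          matrix(mu_full[oi], length(idx), ni, byrow = TRUE)
        denom <- sigma2 + ni * tau2
        post_var <- tau2 * sigma2 / denom
        post_mean <- tau2 * rowSums(R) / denom
        rk <- resp[idx, k]
        new_tau2 <- new_tau2 + sum(rk * (post_mean^2 + post_var))
        sse <- rowSums(R^2) - 2 * post_mean * rowSums(R) + ni * post_mean^2
        new_sig_num <- new_sig_num + sum(rk * (sse + ni * post_var))
        new_sig_den <- new_sig_den + sum(rk) * ni
      }
    }
    tau2 <- max(new_tau2 / n, 1e-8)
    sigma2 <- max(new_sig_num / new_sig_den, 1e-8)
  }
  list(K = K, gamma = gamma, pi = pi_k, tau2 = tau2, sigma2 = sigma2,
       responsibilities = resp, loglik = loglik_trace[length(loglik_trace)],
       loglik_trace = loglik_trace, converged = converged)
}

#' @export
print.quadratic_gmm <- function(x, digits = 3, ...) {
  cat(sprintf("Quadratic growth mixture model: K = %d classes, n = %d series\n",
              x$K, x$n))
  cat(sprintf("logLik %.2f | AIC %.1f | BIC %.1f | %s\n", x$loglik, x$AIC,
              x$BIC, if (x$converged) "converged" else "NOT converged"))
  tab <- cbind(pi = x$pi, x$gamma)
  colnames(tab) <- c("pi", "g0", "g1", "g2")
  rownames(tab) <- paste0("class", seq_len(x$K))
  print(round(tab, digits))
  cat(sprintf("random-intercept var %.3f, residual var %.3f\n",
              x$tau2, x$sigma2))
  invisible(x)
}

#' @export
summary.quadratic_gmm <- function(object, ...) {
  labels <- label_resilience(object)
  res_class <- unique(labels$class_id[labels$resilient])
  structure(list(fit = object, resilient_class = res_class,
                 class_counts = table(labels$class_id),
                 n_resilient = sum(labels$resilient)),
            class = "summary.quadratic_gmm")
}

#' @export
print.summary.quadratic_gmm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("resilient class: %d (%d of %d participants resilient)\n",
              x$resilient_class, x$n_resilient, x$fit$n))
  invisible(x)
}

#' @export
coef.quadratic_gmm <- function(object, ...) {
  tab <- cbind(pi = object$pi, object$gamma)
  colnames(tab) <- c("pi", "g0", "g1", "g2")
  tab
}

#' @export
logLik.quadratic_gmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' Fitted class mean curves
#'
#' @param object a fitted `quadratic_gmm`.
#' @param t quarter indices (default 0:4; 0 is baseline).
#' @param ... unused.
#' @return matrix of fitted delta-PHQ values, classes in rows.
#' @export
predict.quadratic_gmm <- function(object, t = 0:4, ...) {
  X <- cbind(1, t, t^2)
  out <- object$gamma %*% t(X)
  dimnames(out) <- list(paste0("class", seq_len(object$K)), paste0("t", t))
  out
}

#' @export
plot.quadratic_gmm <- function(x, ...) {
  t <- 0:4
  curves <- predict(x, t)
  graphics::matplot(t, t(curves), type = "b", pch = 19, lty = 1,
                    xlab = "quarter", ylab = "delta PHQ-9",
                    main = "Fitted trajectory classes", ...)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("class %d (pi=%.2f)", seq_len(x$K), x$pi),
                   col = seq_len(x$K), lty = 1)
  invisible(x)
}

#' Select the trajectory class count by information criteria
#'
#' Fits the mixture for each K in `K_range` and returns the fit minimising
#' AIC. When AIC and BIC disagree on the best K, BIC wins and a warning is
#' issued.
#'
#' @param series long PHQ/delta data.frame (see [fit_quadratic_gmm()]).
#' @param K_range candidate class counts (default 2:5).
#' @param n_restarts,seed,max_iter passed to [fit_quadratic_gmm()].
#' @return the selected `quadratic_gmm`; the per-K criteria table is
#'   attached as attribute `"criteria"`.
#' @export
select_class_count <- function(series, K_range = 2:5, n_restarts = 10L,
                               seed = 1L, max_iter = 200L) {
  if (!length(K_range)) stop("K_range must be non-empty", call. = FALSE)
  fits <- lapply(K_range, function(K)
    fit_quadratic_gmm(series, K, n_restarts = n_restarts,
                      seed = derive_seed(seed, paste0("K", K)),
                      max_iter = max_iter))
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  bic <- vapply(fits, `[[`, numeric(1), "BIC")
  k_aic <- which.min(aic)
  k_bic <- which.min(bic)
  pick <- k_aic
  if (k_aic != k_bic) {
    warning(sprintf("AIC prefers K=%d but BIC prefers K=%d; using BIC's choice",
                    K_range[k_aic], K_range[k_bic]))
    pick <- k_bic
  }
  out <- fits[[pick]]
  attr(out, "criteria") <- data.frame(K = K_range, AIC = aic, BIC = bic)
  out
}

#' Label the stress-resilient trajectory class
#'
#' Participants are hard-assigned to their maximum-responsibility class; the
#' resilient class is the one whose fitted curve has the smallest maximum
#' absolute delta-PHQ over quarters 1-4 (minimal symptom change), with ties
#' broken toward the largest mixing proportion. All other classes are pooled
#' as stress-sensitive.
#'
#' @param fit a fitted `quadratic_gmm`.
#' @return data.frame with `participant_id`, `class_id`, `resilient`,
#'   `max_responsibility`.
#' @export
label_resilience <- function(fit) {
  stopifnot(inherits(fit, "quadratic_gmm"))
  t <- 1:4
  curves <- fit$gamma %*% t(cbind(1, t, t^2))
  peak <- apply(abs(curves), 1, max)
  cand <- which(peak == min(peak))
  res_class <- cand[which.max(fit$pi[cand])]
  class_id <- max.col(fit$responsibilities)
  data.frame(participant_id = fit$participant_id,
             class_id = class_id,
             resilient = class_id == res_class,
             max_responsibility = fit$responsibilities[
               cbind(seq_along(class_id), class_id)],
             stringsAsFactors = FALSE)
}
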