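# Baseline-to-internship density and regression models: baseline MLP
# regressors of d_s (MLP, P-MLP), direct generators (GEN, P-GEN) and
# conditional GANs (CGAN, F-CGAN, P-CGAN, FP-CGAN) with multitask heads,
# plus participant clustering on d_s profiles and test-time cluster
# matching against actual first-quarter data.

GENERATOR_FAMILIES <- c("MLP", "P-MLP", "GEN", "P-GEN",
                        "CGAN", "F-CGAN", "P-CGAN", "FP-CGAN")

#' Cluster training participants on their Cohen's d_s profiles
#'
#' Sweeps dimensionality reduction (no reduction and 1-5 principal
#' components) by clustering method (Ward agglomerative, k-means) by k, and
#' returns the configuration with the highest mean silhouette score,
#' computed on the reduced representation used for clustering. The d_s
#' columns are standardized first (correlation-scale PCA): the features'
#' d_s spreads differ several-fold, and unscaled principal components would
#' simply track the widest feature rather than coordinated behaviour shifts.
#'
#' @param ds_table data.frame with `participant_id` and the five
#'   `<feature>__cohens_ds__DIFF` columns (extra columns ignored).
#' @param k_range candidate cluster counts (default 2:5).
#' @param methods subset of `c("ward", "kmeans")`.
#' @param seed integer seed (k-means restarts).
#' @return an object of class `cluster_model`: `labels` (named by
#'   participant), `k`, `method`, `n_pca_components` (0 = none),
#'   `silhouette`, `centers` (per-cluster mean d_s profile), plus the
#'   projection needed to assign new profiles.
#' @export
cluster_participants <- function(ds_table, k_range = 2:5,
                                 methods = c("ward", "kmeans"), seed = 1L) {
  cols <- grep("__cohens_ds__DIFF$", names(ds_table), value = TRUE)
  if (!length(cols)) stop("no d_s columns found", call. = FALSE)
  X0 <- as.matrix(ds_table[cols])
  rownames(X0) <- ds_table$participant_id
  if (all(apply(X0, 2, stats::var) < 1e-12))
    stop("failure to cluster: all d_s profiles are identical", call. = FALSE)
  col_sd <- apply(X0, 2, stats::sd)
  col_sd[col_sd == 0] <- 1
  X <- scale(X0, scale = col_sd)
  pca <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  best <- NULL
  with_seed(derive_seed(seed, "cluster"), {
    for (ncomp in 0:min(5L, ncol(X))) {
      Z <- if (ncomp == 0L) X else pca$x[, seq_len(ncomp), drop = FALSE]
      D <- stats::dist(Z)
      hc <- stats::hclust(D, method = "ward.D2")
      for (k in k_range) {
        if (k >= nrow(Z)) next
        for (method in methods) {
          labels <- if (method == "ward") stats::cutree(hc, k) else
            suppressWarnings(stats::kmeans(Z, k, nstart = 5L)$cluster)
          if (length(unique(labels)) < k) next
          sil <- mean_silhouette(Z, labels, D)
          if (is.null(best) || sil > best$silhouette)
            best <- list(labels = labels, k = k, method = method,
                         n_pca_components = ncomp, silhouette = sil)
        }
      }
    }
  })
  if (is.null(best)) stop("failure to cluster: no valid configuration",
                          call. = FALSE)
  # relabel so cluster 1 is the largest (stable downstream tie-breaks)
  sizes <- table(best$labels)
  remap <- stats::setNames(seq_along(sizes),
                           names(sort(sizes, decreasing = TRUE)))
  best$labels <- stats::setNames(unname(remap[as.character(best$labels)]),
                                 rownames(X0))
  centers <- do.call(rbind, lapply(sort(unique(best$labels)), function(cl)
    colMeans(X0[best$labels == cl, , drop = FALSE])))
  structure(c(best,
              list(centers = centers, ds_columns = cols,
                   scale_center = attr(X, "scaled:center"),
                   scale_sd = col_sd, pca_rotation = pca$rotation,
                   sizes = as.integer(table(best$labels)))),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(paste0("cluster_model: k = %d (%s, %s), silhouette %.3f, ",
                     "sizes %s\n"),
              x$k, x$method,
              if (x$n_pca_components == 0) "no PCA" else
                sprintf("%d PCs", x$n_pca_components),
              x$silhouette, paste(x$sizes, collapse = "/")))
  invisible(x)
}

mean_silhouette <- function(Z, labels, D = stats::dist(Z)) {
  dm <- as.matrix(D)
  n <- nrow(dm)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) <= 1L) { s[i] <- 0; next }
    a <- sum(dm[i, own]) / (sum(own) - 1L)
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(dm[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Specification of a baseline-to-internship model
#'
#' @param family one of `"MLP"`, `"P-MLP"`, `"GEN"`, `"P-GEN"`, `"CGAN"`,
#'   `"F-CGAN"`, `"P-CGAN"`, `"FP-CGAN"`. `P-` families route participants
#'   through per-cluster output heads, `F-` families emit each feature from
#'   its own head, `FP-` does both.
#' @param trunk_sizes widths of the shared trunk layers.
#' @param head_hidden widths of the per-task head hidden layers.
#' @param noise_dim generator noise dimension (GAN families).
#' @param epochs,batch_size training schedule.
#' @param lr_g,lr_d Adam learning rates for the generator (also used by the
#'   regression families) and discriminator.
#' @param pairs_per_participant per-epoch cap on sampled within-participant
#'   (baseline, internship) hour pairs.
#' @param identity_skip if `TRUE` (default) the generator output is the
#'   baseline point plus a learned residual.
#' @param feature_matching weight of the feature-matching term in the
#'   generator loss: squared differences between the per-batch (and, for
#'   `P-` families, per-cluster) means and SDs of generated and real
#'   internship points. Stabilises the minimax game and anchors the
#'   conditional moments the d_s evaluation depends on; 0 disables it.
#' @param instance_noise SD of Gaussian noise added to the internship point
#'   the discriminator sees (real and generated alike). Hourly features are
#'   zero-inflated with point masses the generator cannot reproduce
#'   exactly; without overlap noise the discriminator separates the
#'   supports perfectly and its gradients stop carrying moment
#'   information. Annealed linearly to zero over training.
#' @param conditional_discriminator if `TRUE` (default) the discriminator
#'   sees the conditioning baseline point alongside the candidate
#'   internship point.
#' @param seed integer seed for initialisation and pair resampling.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(family = "FP-CGAN",
                           trunk_sizes = c(64, 64),
                           head_hidden = 32,
                           noise_dim = 8,
                           epochs = 100L,
                           batch_size = 256L,
                           lr_g = 1e-4,
                           lr_d = 4e-4,
                           pairs_per_participant = 100L,
                           identity_skip = TRUE,
                           feature_matching = 1,
                           instance_noise = 0.2,
                           conditional_discriminator = TRUE,
                           seed = 1L) {
  family <- match.arg(family, GENERATOR_FAMILIES)
  structure(as.list(environment()), class = "generator_spec")
}

spec_is_gan <- function(spec) grepl("CGAN", spec$family)
spec_is_mlp <- function(spec) grepl("MLP", spec$family)
spec_per_cluster <- function(spec) grepl("^F?P", spec$family)
spec_per_feature <- function(spec) grepl("^F", spec$family)

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf(paste0("generator_spec: %s | trunk %s, head %s, noise %d | ",
                     "%d epochs, batch %d, lr %g/%g, seed %d\n"),
              x$family, paste(x$trunk_sizes, collapse = "x"),
              paste(x$head_hidden, collapse = "x"), x$noise_dim,
              x$epochs, x$batch_size, x$lr_g, x$lr_d, x$seed))
  invisible(x)
}

# Split cleaned hourly records into per-participant z-scored baseline and
# internship matrices using pooled training normalisation statistics.
prepare_training_data <- function(records, norm = NULL) {
  X <- as.matrix(records[FEATURES])
  if (is.null(norm)) {
    mu <- colMeans(X)
    sd_ <- apply(X, 2, stats::sd)
    sd_[sd_ == 0] <- 1
    norm <- list(mean = mu, sd = sd_,
                 lo = apply(X, 2, min), hi = apply(X, 2, max))
  }
  Z <- sweep(sweep(X, 2, norm$mean), 2, norm$sd, `/`)
  ids <- unique(records$participant_id)
  bl <- records$period == "BL"
  A <- lapply(ids, function(id)
    Z[records$participant_id == id & bl, , drop = FALSE])
  B <- lapply(ids, function(id)
    Z[records$participant_id == id & !bl, , drop = FALSE])
  names(A) <- names(B) <- ids
  list(A = A, B = B, ids = ids, norm = norm)
}

#' Train a baseline-to-internship model
#'
#' Family-specific training on cleaned hourly records of the training
#' participants:
#' * `MLP` / `P-MLP`: regress each participant's five d_s values on the
#'   five baseline feature means (MSE loss).
#' * `GEN` / `P-GEN`: feedforward map from a baseline hourly point to an
#'   internship hourly point, trained by MSE against randomly paired
#'   within-participant hours, re-sampled every epoch.
#' * `CGAN` families: generator maps (baseline point, noise) to an
#'   internship point; the discriminator scores (baseline, internship)
#'   pairs; non-saturating adversarial losses; real pairs re-sampled every
#'   epoch.
#' `P-` variants route participants through their cluster's output head
#' (the discriminator additionally sees a cluster one-hot); `F-` variants
#' emit each feature from its own head.
#'
#' A per-epoch mode-diversity guard tracks the ratio of generated to actual
#' per-feature SD and warns if any ratio falls below 0.5.
#'
#' @param spec a [generator_spec()].
#' @param records cleaned hourly records of the training participants.
#' @param clusters a [cluster_participants()] model (required for `P-`
#'   families).
#' @return an object of class `trained_generator`.
#' @export
train_generator <- function(spec, records, clusters = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec_per_cluster(spec) && is.null(clusters))
    stop(sprintf("family %s needs a cluster model", spec$family),
         call. = FALSE)
  data <- prepare_training_data(records)
  cluster_of <- NULL
  n_clusters <- 1L
  if (spec_per_cluster(spec)) {
    missing_cl <- setdiff(data$ids, names(clusters$labels))
    if (length(missing_cl))
      stop("no cluster for participant(s): ",
           paste(utils::head(missing_cl, 5L), collapse = ", "),
           call. = FALSE)
    cluster_of <- clusters$labels[data$ids]
    n_clusters <- max(clusters$labels)
  }
  fit <- if (spec_is_mlp(spec)) {
    train_mlp_family(spec, data, cluster_of, n_clusters)
  } else {
    train_point_family(spec, data, cluster_of, n_clusters)
  }
  structure(list(spec = spec, norm = data$norm, model = fit$model,
                 discriminator = fit$discriminator,
                 training_log = fit$log, clusters = clusters,
                 cluster_of = cluster_of,
                 train_ids = data$ids),
            class = "trained_generator")
}

#' @export
print.trained_generator <- function(x, ...) {
  cat(sprintf("trained_generator: %s, %d training participants, %d epochs\n",
              x$spec$family, length(x$train_ids), nrow(x$training_log)))
  invisible(x)
}

# ---- MLP families: baseline feature means -> d_s -------------------------

participant_ds_matrix <- function(data) {
  ids <- data$ids
  out <- t(vapply(ids, function(id) {
    A <- data$A[[id]]; B <- data$B[[id]]
    vapply(seq_len(ncol(A)), function(j)
      cohens_ds_points(A[, j], B[, j]), numeric(1))
  }, numeric(length(FEATURES))))
  dimnames(out) <- list(ids, FEATURES)
  out
}

train_mlp_family <- function(spec, data, cluster_of, n_clusters) {
  Xin <- t(vapply(data$ids, function(id) colMeans(data$A[[id]]),
                  numeric(length(FEATURES))))
  Y <- participant_ds_matrix(data)
  cl <- if (spec_per_cluster(spec)) as.integer(cluster_of) else NULL
  with_seed(derive_seed(spec$seed, "mlp"), {
    model <- mt_new(ncol(Xin), ncol(Y), spec$trunk_sizes, spec$head_hidden,
                    clusters = if (is.null(cl)) NULL else seq_len(n_clusters),
                    per_feature = spec_per_feature(spec))
    st <- mt_adam_new(model)
    n <- nrow(Xin)
    log <- data.frame(epoch = seq_len(spec$epochs), loss = NA_real_)
    t_step <- 0L
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (batch in split(ord, ceiling(seq_along(ord) / spec$batch_size))) {
        fwd <- mt_forward(model, Xin[batch, , drop = FALSE], cl[batch])
        err <- fwd$out - Y[batch, , drop = FALSE]
        losses <- c(losses, mean(err^2))
        bk <- mt_backward(model, fwd, 2 * err / length(err))
        t_step <- t_step + 1L
        up <- mt_adam_step(model, bk, st, spec$lr_g, t_step)
        model <- up$model; st <- up$state
      }
      log$loss[ep] <- mean(losses)
    }
    list(model = model, discriminator = NULL, log = log)
  })
}

# ---- point families: baseline hour (+ noise) -> internship hour ----------

sample_pairs <- function(data, cap) {
  ids <- data$ids
  idx <- lapply(ids, function(id) {
    nA <- nrow(data$A[[id]]); nB <- nrow(data$B[[id]])
    m <- min(nA, nB, cap)
    list(a = sample.int(nA, m, replace = m > nA),
         b = sample.int(nB, m, replace = m > nB))
  })
  A <- do.call(rbind, lapply(seq_along(ids), function(i)
    data$A[[ids[i]]][idx[[i]]$a, , drop = FALSE]))
  B <- do.call(rbind, lapply(seq_along(ids), function(i)
    data$B[[ids[i]]][idx[[i]]$b, , drop = FALSE]))
  who <- rep(seq_along(ids), vapply(idx, function(x) length(x$a), integer(1)))
  list(A = A, B = B, who = who)
}

train_point_family <- function(spec, data, cluster_of, n_clusters) {
  m <- length(FEATURES)
  is_gan <- spec_is_gan(spec)
  gen_in <- m + if (is_gan) spec$noise_dim else 0L
  cl_ids <- if (spec_per_cluster(spec)) seq_len(n_clusters) else NULL
  with_seed(derive_seed(spec$seed, "pointfam"), {
    G <- mt_new(gen_in, m, spec$trunk_sizes, spec$head_hidden,
                clusters = cl_ids, per_feature = spec_per_feature(spec))
    stG <- mt_adam_new(G)
    D <- NULL; stD <- NULL
    d_in <- if (is_gan) {
      (if (spec$conditional_discriminator) m else 0L) + m +
        (if (spec_per_cluster(spec)) n_clusters else 0L)
    } else 0L
    if (is_gan) {
      D <- mt_new(d_in, 1L, spec$trunk_sizes, spec$head_hidden)
      stD <- mt_adam_new(D)
    }
    log <- data.frame(epoch = seq_len(spec$epochs), loss_g = NA_real_,
                      loss_d = NA_real_, sd_ratio_min = NA_real_)
    tG <- 0L; tD <- 0L
    warned <- FALSE
    for (ep in seq_len(spec$epochs)) {
      pairs <- sample_pairs(data, spec$pairs_per_participant)
      pcl <- if (spec_per_cluster(spec))
        as.integer(cluster_of[pairs$who]) else NULL
      n <- nrow(pairs$A)
      ord <- sample.int(n)
      lg <- numeric(0); ld <- numeric(0)
      fake_all <- NULL
      for (batch in split(ord, ceiling(seq_along(ord) / spec$batch_size))) {
        a <- pairs$A[batch, , drop = FALSE]
        b <- pairs$B[batch, , drop = FALSE]
        bc <- pcl[batch]
        nb <- length(batch)
        if (!is_gan) {
          fwd <- mt_forward(G, a, bc)
          out <- fwd$out + if (spec$identity_skip) a else 0
          err <- out - b
          lg <- c(lg, mean(err^2))
          bk <- mt_backward(G, fwd, 2 * err / length(err))
          tG <- tG + 1L
          up <- mt_adam_step(G, bk, stG, spec$lr_g, tG)
          G <- up$model; stG <- up$state
          fake_all <- rbind(fake_all, out)
          next
        }
        onehot <- if (spec_per_cluster(spec)) {
          oh <- matrix(0, nb, n_clusters); oh[cbind(seq_len(nb), bc)] <- 1; oh
        } else NULL
        inoise_sd <- spec$instance_noise * (1 - (ep - 1) / spec$epochs)
        d_input <- function(bb) {
          if (inoise_sd > 0)
            bb <- bb + matrix(stats::rnorm(length(bb), 0, inoise_sd),
                              nrow(bb))
          cbind(if (spec$conditional_discriminator) a else NULL, bb, onehot)
        }
        # discriminator step
        z <- matrix(stats::rnorm(nb * spec$noise_dim), nb)
        fwdG <- mt_forward(G, cbind(a, z), bc)
        fake <- fwdG$out + if (spec$identity_skip) a else 0
        fwd_r <- mt_forward(D, d_input(b))
        fwd_f <- mt_forward(D, d_input(fake))
        sr <- fwd_r$out; sf <- fwd_f$out
        ld <- c(ld, mean(softplus(-sr)) + mean(softplus(sf)))
        gr <- mt_backward(D, fwd_r, -stats::plogis(-sr) / nb)
        gf <- mt_backward(D, fwd_f, stats::plogis(sf) / nb)
        gD <- add_grads(gr, gf)
        tD <- tD + 1L
        up <- mt_adam_step(D, gD, stD, spec$lr_d, tD)
        D <- up$model; stD <- up$state
        # generator step (non-saturating, plus feature matching)
        z <- matrix(stats::rnorm(nb * spec$noise_dim), nb)
        fwdG <- mt_forward(G, cbind(a, z), bc)
        fake <- fwdG$out + if (spec$identity_skip) a else 0
        fwd_f <- mt_forward(D, d_input(fake))
        sf <- fwd_f$out
        lg <- c(lg, mean(softplus(-sf)))
        bkD <- mt_backward(D, fwd_f, -stats::plogis(-sf) / nb)
        dfake <- bkD$dX[, (if (spec$conditional_discriminator) m else 0L) +
                          seq_len(m), drop = FALSE]
        if (spec$feature_matching > 0) {
          groups <- if (is.null(bc)) list(seq_len(nb)) else
            split(seq_len(nb), bc)
          for (gidx in groups) {
            ng <- length(gidx)
            if (ng < 3L) next
            fg <- fake[gidx, , drop = FALSE]
            bg <- b[gidx, , drop = FALSE]
            dmu <- colMeans(fg) - colMeans(bg)
            sd_f <- apply(fg, 2, stats::sd)
            dsd <- sd_f - apply(bg, 2, stats::sd)
            gmu <- matrix(2 * dmu / ng, ng, m, byrow = TRUE)
            gsd <- sweep(sweep(fg, 2, colMeans(fg)), 2,
                         2 * dsd / ((ng - 1) * pmax(sd_f, 1e-8)), `*`)
            dfake[gidx, ] <- dfake[gidx, ] +
              spec$feature_matching * (gmu + gsd) / m
          }
        }
        bkG <- mt_backward(G, fwdG, dfake)
        tG <- tG + 1L
        up <- mt_adam_step(G, bkG, stG, spec$lr_g, tG)
        G <- up$model; stG <- up$state
        if (anyNA(fake) || !all(is.finite(fake)))
          stop("NaN loss/output during GAN training; check learning rates",
               call. = FALSE)
        fake_all <- rbind(fake_all, fake)
      }
      sd_ratio <- apply(fake_all, 2, stats::sd) /
        pmax(apply(pairs$B, 2, stats::sd), 1e-12)
      log$sd_ratio_min[ep] <- min(sd_ratio)
      if (!warned && min(sd_ratio) < 0.5) {
        warning(sprintf(paste0("mode-diversity guard: generated/actual SD ",
                               "ratio %.2f < 0.5 for feature '%s' at epoch ",
                               "%d"),
                        min(sd_ratio), FEATURES[which.min(sd_ratio)], ep))
        warned <- TRUE
      }
      log$loss_g[ep] <- mean(lg)
      log$loss_d[ep] <- if (is_gan) mean(ld) else NA_real_
    }
    list(model = G, discriminator = D, log = log)
  })
}

add_grads <- function(g1, g2) {
  g <- g1
  for (l in seq_along(g$trunk)) {
    g$trunk[[l]]$W <- g1$trunk[[l]]$W + g2$trunk[[l]]$W
    g$trunk[[l]]$b <- g1$trunk[[l]]$b + g2$trunk[[l]]$b
  }
  for (i in seq_along(g$heads))
    for (l in seq_along(g$heads[[i]])) {
      g$heads[[i]][[l]]$W <- g1$heads[[i]][[l]]$W + g2$heads[[i]][[l]]$W
      g$heads[[i]][[l]]$b <- g1$heads[[i]][[l]]$b + g2$heads[[i]][[l]]$b
    }
  g
}

#' Generate a predicted internship distribution from baseline points
#'
#' Feeds each baseline hourly point (with fresh noise for GAN families)
#' through the trained generator, de-normalises the outputs to raw feature
#' units, and clips them to the feature ranges observed in training (no
#' negative durations; heart rate within its physical range).
#'
#' @param gen a [train_generator()] result (point families only).
#' @param baseline_points data.frame or matrix of raw baseline hourly
#'   feature values (five columns).
#' @param draws_per_point generated internship points per baseline point.
#' @param noise_seed integer seed making generation deterministic.
#' @param cluster_id routing cluster for `P-` families.
#' @return matrix of generated internship points in raw units, tagged with
#'   attribute `predicted = TRUE`.
#' @export
generate_internship <- function(gen, baseline_points, draws_per_point = 1L,
                                noise_seed = 1L, cluster_id = NULL) {
  stopifnot(inherits(gen, "trained_generator"))
  if (spec_is_mlp(gen$spec))
    stop("MLP families predict d_s directly; use predict()", call. = FALSE)
  X <- as.matrix(as.data.frame(baseline_points)[, FEATURES, drop = FALSE])
  if (!identical(colnames(X), FEATURES))
    stop("feature order mismatch", call. = FALSE)
  if (anyNA(X))
    stop("baseline points contain missing values", call. = FALSE)
  if (spec_per_cluster(gen$spec) && is.null(cluster_id))
    stop("cluster_id required for P- families", call. = FALSE)
  norm <- gen$norm
  Z <- sweep(sweep(X, 2, norm$mean), 2, norm$sd, `/`)
  Z <- Z[rep(seq_len(nrow(Z)), draws_per_point), , drop = FALSE]
  cl <- if (is.null(cluster_id)) NULL else rep(cluster_id, nrow(Z))
  out <- with_seed(derive_seed(noise_seed, "generate"), {
    inp <- if (spec_is_gan(gen$spec)) {
      cbind(Z, matrix(stats::rnorm(nrow(Z) * gen$spec$noise_dim), nrow(Z)))
    } else Z
    fwd <- mt_forward(gen$model, inp, cl)
    fwd$out + if (gen$spec$identity_skip) Z else 0
  })
  raw <- sweep(sweep(out, 2, norm$sd, `*`), 2, norm$mean, `+`)
  for (j in seq_along(FEATURES))
    raw[, j] <- pmin(pmax(raw[, j], norm$lo[j]), norm$hi[j])
  colnames(raw) <- FEATURES
  attr(raw, "predicted") <- TRUE
  raw
}

#' Predict d_s from an MLP-family model
#'
#' @param object a `trained_generator` with an MLP family spec.
#' @param baseline_points raw baseline hourly points of one participant.
#' @param cluster_id routing cluster for `P-MLP`.
#' @param ... unused.
#' @return named numeric vector of predicted per-feature d_s.
#' @export
predict.trained_generator <- function(object, baseline_points,
                                      cluster_id = NULL, ...) {
  if (!spec_is_mlp(object$spec))
    stop("predict() is for MLP families; use generate_internship()",
         call. = FALSE)
  X <- as.matrix(as.data.frame(baseline_points)[, FEATURES, drop = FALSE])
  norm <- object$norm
  Z <- sweep(sweep(X, 2, norm$mean), 2, norm$sd, `/`)
  inp <- matrix(colMeans(Z), 1L)
  cl <- if (spec_per_cluster(object$spec)) {
    if (is.null(cluster_id)) stop("cluster_id required for P-MLP",
                                  call. = FALSE)
    cluster_id
  } else NULL
  out <- drop(mt_forward(object$model, inp, cl)$out)
  stats::setNames(out, FEATURES)
}

#' Match a test participant to a training cluster using Q1 data
#'
#' For each cluster head, generates a predicted internship distribution
#' from the participant's baseline points and measures the mean over
#' features of the absolute difference between the predicted d_s(A, B')
#' and the actual first-quarter d_s(A, Q1). Returns the cluster minimising
#' that error; ties break toward the larger training cluster.
#'
#' @param gen a `P-` family `trained_generator`.
#' @param baseline_points raw baseline hourly points (>= 100 rows).
#' @param q1_points raw Q1 hourly points (>= 1 row; >= 2 needed for d_s).
#' @param noise_seed integer seed.
#' @return integer cluster id.
#' @export
match_cluster <- function(gen, baseline_points, q1_points, noise_seed = 1L) {
  stopifnot(inherits(gen, "trained_generator"))
  if (!spec_per_cluster(gen$spec))
    stop("cluster matching applies to P- families only", call. = FALSE)
  if (is.null(q1_points) || nrow(as.data.frame(q1_points)) < 2L)
    stop(paste("no usable Q1 data: fall back to the larger training",
               "cluster (cluster 1)"), call. = FALSE)
  A <- as.data.frame(baseline_points)[FEATURES]
  Q <- as.data.frame(q1_points)[FEATURES]
  ds_actual <- vapply(FEATURES, function(f)
    cohens_ds_points(A[[f]], Q[[f]]), numeric(1))
  sizes <- gen$clusters$sizes
  errs <- vapply(seq_along(sizes), function(cl) {
    Bp <- generate_internship(gen, A, draws_per_point = 1L,
                              noise_seed = noise_seed, cluster_id = cl)
    ds_pred <- vapply(seq_along(FEATURES), function(j)
      cohens_ds_points(A[[FEATURES[j]]], Bp[, j]), numeric(1))
    mean(abs(ds_pred - ds_actual))
  }, numeric(1))
  cand <- which(errs == min(errs))
  cand[which.max(sizes[cand])]
}

#' Predicted indicator table from a trained generator
#'
#' Builds each participant's predicted internship distribution B' from
#' their baseline points and computes the 37-indicator vector on (A, B').
#' Baseline-only entries are computed from the actual baseline data (they
#' are not predictions). For `P-` families the routing cluster comes from
#' [match_cluster()] against actual Q1 data when available, the training
#' label for training participants, or the larger cluster as fallback.
#'
#' @param gen a point-family `trained_generator`.
#' @param records cleaned hourly records of the participants to predict
#'   (must include the BL period; Q1 rows are used for cluster matching of
#'   participants without a training cluster label).
#' @param draws_per_point generated points per baseline point.
#' @param noise_seed integer seed.
#' @return data.frame like [build_indicator_table()]'s output, with an
#'   extra `matched_cluster` column (NA for non-P families).
#' @export
predict_indicators <- function(gen, records, draws_per_point = 1L,
                               noise_seed = 1L) {
  stopifnot(inherits(gen, "trained_generator"))
  ids <- unique(records$participant_id)
  rows <- lapply(ids, function(id) {
    rec <- records[records$participant_id == id, , drop = FALSE]
    A <- rec[rec$period == "BL", FEATURES, drop = FALSE]
    cl <- NA_integer_
    if (spec_per_cluster(gen$spec)) {
      cl <- if (id %in% names(gen$clusters$labels)) {
        unname(gen$clusters$labels[id])
      } else {
        q1 <- rec[rec$period == "Q1", FEATURES, drop = FALSE]
        tryCatch(match_cluster(gen, A, q1,
                               noise_seed = derive_seed(noise_seed, id)),
                 error = function(e) 1L)
      }
    }
    Bp <- generate_internship(gen, A, draws_per_point = draws_per_point,
                              noise_seed = derive_seed(noise_seed, id),
                              cluster_id = if (is.na(cl)) NULL else cl)
    iv <- build_indicator_vector(
      period_distribution(id, "A", A),
      period_distribution(id, "B", as.data.frame(Bp)))
    c(iv, matched_cluster = cl)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(participant_id = ids, out, stringsAsFactors = FALSE)
}
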