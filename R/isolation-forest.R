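# Isolation forest for multivariate hourly outlier filtering. Trees are
# grown in R on small subsamples; scoring of the full cohort runs in C++.

#' Fit an isolation forest
#'
#' Recursively partitions random subsamples along randomly chosen features
#' at uniform random split points. Points isolated by short paths receive
#' high anomaly scores. Every tree may use the full feature dimension.
#'
#' @param x numeric matrix (rows = observations).
#' @param n_trees number of trees (default 250).
#' @param subsample rows sampled per tree, capped at `nrow(x)`. The default
#'   (8192) grows trees deep enough to resolve the dense zero-heavy clusters
#'   of hourly wearable data; with small subsamples the depth cap binds
#'   before those clusters resolve and ordinary points land in tiny leaves.
#' @param seed integer seed.
#' @return an object of class `isolation_forest`.
#' @export
fit_isolation_forest <- function(x, n_trees = 250L, subsample = 8192L,
                                 seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 8L) stop("too few rows to fit an isolation forest",
                         call. = FALSE)
  storage.mode(x) <- "double"
  psi <- min(as.integer(subsample), nrow(x))
  depth_limit <- ceiling(log2(psi))
  trees <- with_seed(derive_seed(seed, "iforest"), {
    lapply(seq_len(n_trees), function(t) {
      idx <- sample.int(nrow(x), psi)
      grow_itree(x[idx, , drop = FALSE], depth_limit)
    })
  })
  structure(list(trees = trees, subsample = psi, n_trees = n_trees,
                 n_features = ncol(x)),
            class = "isolation_forest")
}

# Grow one isolation tree; returns flat 0-based arrays for the C++ scorer.
grow_itree <- function(x, depth_limit) {
  feature <- integer(0); split <- numeric(0)
  left <- integer(0); right <- integer(0); size <- integer(0)
  new_node <- function() {
    feature <<- c(feature, -1L); split <<- c(split, 0)
    left <<- c(left, -1L); right <<- c(right, -1L); size <<- c(size, 0L)
    length(feature)
  }
  build <- function(rows, depth) {
    node <- new_node()
    n <- length(rows)
    if (n <= 1L || depth >= depth_limit) {
      size[node] <<- n
      return(node - 1L)
    }
    sub <- x[rows, , drop = FALSE]
    rng <- apply(sub, 2L, range)
    usable <- which(rng[2L, ] > rng[1L, ])
    if (!length(usable)) {
      size[node] <<- n
      return(node - 1L)
    }
    f <- if (length(usable) == 1L) usable else sample(usable, 1L)
    sp <- stats::runif(1L, rng[1L, f], rng[2L, f])
    go_left <- sub[, f] < sp
    feature[node] <<- f - 1L
    split[node] <<- sp
    left[node] <<- build(rows[go_left], depth + 1L)
    right[node] <<- build(rows[!go_left], depth + 1L)
    node - 1L
  }
  build(seq_len(nrow(x)), 0L)
  list(feature = feature, split = split, left = left, right = right,
       size = size)
}

#' Anomaly scores from a fitted isolation forest
#'
#' @param forest an [fit_isolation_forest()] result.
#' @param x matrix of observations with the training feature dimension.
#' @return numeric scores in (0, 1); larger means more anomalous. Scores
#'   above 0.5 correspond to shorter-than-average isolation paths and are
#'   the default outlier decision.
#' @export
iforest_scores <- function(forest, x) {
  stopifnot(inherits(forest, "isolation_forest"))
  x <- as.matrix(x)
  if (ncol(x) != forest$n_features)
    stop("feature dimension mismatch", call. = FALSE)
  storage.mode(x) <- "double"
  iforest_score_cpp(x, forest$trees, forest$subsample)
}

#' @export
print.isolation_forest <- function(x, ...) {
  cat(sprintf("isolation_forest: %d trees, subsample %d, %d features\n",
              x$n_trees, x$subsample, x$n_features))
  invisible(x)
}
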