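# Dimensionality reduction and discretization: time-lagged independent
# component analysis (tICA) on feature trajectories, k-means microstate
# clustering in tIC space, and least-count adaptive-sampling seed selection.

as_traj_list <- function(x) {
  if (is.list(x) && !is.data.frame(x)) lapply(x, function(m) rbind(unclass(m)))
  else list(rbind(unclass(x)))
}

#' Fit time-lagged independent component analysis
#'
#' Solves the time-lagged generalized eigenproblem on symmetrized (reversible)
#' lagged covariances. Components are sorted by descending autocorrelation
#' eigenvalue; the projection decorrelates components at lag zero.
#'
#' @param feature_trajectories a frames x features matrix or a list of them
#'   (one per trajectory); every trajectory must be longer than `lag`.
#' @param lag tICA lag in frames.
#' @param n_components number of components retained (default all).
#' @param regularization ridge added to the instantaneous covariance diagonal
#'   (default 1e-6) so duplicated or constant features stay solvable.
#' @return object of class `tica_model` with fields `lag`, `mean`,
#'   `components` (features x k loadings), `eigenvalues`, `n_components`.
#' @export
fit_tica <- function(feature_trajectories, lag, n_components = NULL,
                     regularization = 1e-6) {
  trajs <- as_traj_list(feature_trajectories)
  p <- ncol(trajs[[1]])
  if (p < 2) stop_gpcrmsm("validation", "tICA needs at least 2 features")
  usable <- vapply(trajs, nrow, integer(1)) > lag
  if (!any(usable))
    stop_gpcrmsm("validation", "every trajectory must be longer than the lag")
  trajs <- trajs[usable]

  # pooled mean over the lagged-pair frames
  n_pairs <- 0
  s <- numeric(p)
  for (X in trajs) {
    n <- nrow(X)
    s <- s + colSums(X[1:(n - lag), , drop = FALSE]) +
         colSums(X[(lag + 1):n, , drop = FALSE])
    n_pairs <- n_pairs + (n - lag)
  }
  mu <- s / (2 * n_pairs)

  C0 <- matrix(0, p, p); Ct <- matrix(0, p, p)
  for (X in trajs) {
    n <- nrow(X)
    A <- sweep(X[1:(n - lag), , drop = FALSE], 2, mu)
    B <- sweep(X[(lag + 1):n, , drop = FALSE], 2, mu)
    C0 <- C0 + crossprod(A) + crossprod(B)
    Ct <- Ct + crossprod(A, B) + crossprod(B, A)
  }
  C0 <- C0 / (2 * n_pairs)
  Ct <- Ct / (2 * n_pairs)
  diag(C0) <- diag(C0) + regularization

  e0 <- eigen(C0, symmetric = TRUE)
  if (min(e0$values) <= max(e0$values) * 1e-12)
    stop_gpcrmsm("numeric", paste(
      "singular instantaneous covariance; increase `regularization`",
      "or drop constant/duplicated features"))
  W <- e0$vectors %*% diag(1 / sqrt(e0$values), p) %*% t(e0$vectors)
  M <- W %*% Ct %*% W
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(em$values, decreasing = TRUE)
  k <- n_components %||% p
  k <- min(k, p)
  comps <- W %*% em$vectors[, ord[1:k], drop = FALSE]
  colnames(comps) <- paste0("tic", 1:k)
  rownames(comps) <- colnames(trajs[[1]])
  structure(list(
    lag = lag, mean = mu, components = comps,
    eigenvalues = em$values[ord][1:k], n_components = k,
    regularization = regularization
  ), class = "tica_model")
}

#' Project features onto tICA components
#'
#' @param model a [fit_tica()] model.
#' @param feature_trajectories matrix or list of matrices.
#' @return projected matrix, or list of matrices matching the input.
#' @export
project_tica <- function(model, feature_trajectories) {
  project1 <- function(X)
    sweep(rbind(unclass(X)), 2, model$mean) %*% model$components
  if (is.list(feature_trajectories) && !is.data.frame(feature_trajectories))
    lapply(feature_trajectories, project1)
  else project1(feature_trajectories)
}

kmeanspp_init <- function(X, k) {
  # deterministic given the RNG state; D^2 weighting, ties to lowest index
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  if (k > 1) for (j in 2:k) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

#' k-means microstate clustering
#'
#' k-means++ initialisation (deterministic for a fixed seed) followed by
#' Lloyd iteration; the best of `n_init` starts by total within-cluster sum
#' of squares is kept. Assignment is to the nearest centre in Euclidean
#' distance, ties to the lowest centre index.
#'
#' @param projected_frames matrix or list of matrices (frames x dims) in tIC
#'   space.
#' @param k number of microstates (<= total frames).
#' @param seed integer seed.
#' @param n_init number of restarts (default 5).
#' @return list with `model` (class `cluster_model`: `centers`, `k`, `seed`)
#'   and `dtrajs` (list of integer microstate sequences, 1-based).
#' @export
fit_kmeans <- function(projected_frames, k, seed = 1, n_init = 5) {
  trajs <- as_traj_list(projected_frames)
  X <- do.call(rbind, trajs)
  if (k > nrow(X))
    stop_gpcrmsm("validation", "k (%d) exceeds number of frames (%d)", k, nrow(X))
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    init <- kmeanspp_init(X, k)
    init <- init + rnorm(length(init), sd = 1e-9)  # de-duplicate centres
    fit <- suppressWarnings(
      kmeans(X, centers = init, iter.max = 200, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  centers <- best$centers
  model <- structure(list(centers = centers, k = k, seed = seed),
                     class = "cluster_model")
  dtrajs <- lapply(trajs, function(Y) assign_clusters(model, Y))
  list(model = model, dtrajs = dtrajs)
}

#' Assign frames to the nearest cluster centre
#' @param model a `cluster_model`.
#' @param X frames x dims matrix.
#' @return integer vector of 1-based microstate ids.
#' @export
assign_clusters <- function(model, X) {
  X <- rbind(unclass(X))
  cc <- model$centers
  d2 <- outer(rowSums(X^2), rep(1, nrow(cc))) - 2 * X %*% t(cc) +
    outer(rep(1, nrow(X)), rowSums(cc^2))
  max.col(-d2, ties.method = "first")
}

#' Least-count adaptive-sampling seed selection
#'
#' Returns `n_seeds` frames drawn from microstates in ascending population
#' order, round-robin over the ordered clusters, ties broken toward the
#' lower cluster index. Within a cluster, frames are taken in trajectory
#' order (deterministic).
#'
#' @param dtrajs list of integer microstate sequences.
#' @param n_seeds number of restart frames requested.
#' @return data.frame with columns `traj`, `frame`, `cluster`, one row per
#'   selected seed, in selection order.
#' @export
least_count_seeds <- function(dtrajs, n_seeds) {
  dtrajs <- if (is.list(dtrajs)) dtrajs else list(dtrajs)
  all_states <- sort(unique(unlist(dtrajs)))
  if (!length(all_states)) stop_gpcrmsm("validation", "no populated clusters")
  pop <- vapply(all_states, function(s) sum(vapply(
    dtrajs, function(d) sum(d == s), integer(1))), integer(1))
  order_states <- all_states[order(pop, all_states)]
  frame_index <- do.call(rbind, lapply(seq_along(dtrajs), function(i)
    data.frame(traj = i, frame = seq_along(dtrajs[[i]]),
               cluster = dtrajs[[i]])))
  picked <- data.frame(traj = integer(0), frame = integer(0),
                       cluster = integer(0))
  used <- integer(length(order_states))  # frames consumed per cluster
  names(used) <- order_states
  i <- 0
  while (nrow(picked) < n_seeds) {
    s <- order_states[(i %% length(order_states)) + 1]
    i <- i + 1
    avail <- frame_index[frame_index$cluster == s, , drop = FALSE]
    u <- used[as.character(s)]
    if (u < nrow(avail)) {
      picked <- rbind(picked, avail[u + 1, ])
      used[as.character(s)] <- u + 1
    }
    if (i > n_seeds * length(order_states) + length(order_states)) break
  }
  rownames(picked) <- NULL
  picked
}

#' Write discrete trajectories, one file per trajectory
#' @param dtrajs list of integer vectors.
#' @param prefix file path prefix; files are `<prefix>_<i>.txt`, one integer
#'   per line.
#' @return written paths, invisibly.
#' @export
write_dtrajs <- function(dtrajs, prefix) {
  paths <- vapply(seq_along(dtrajs), function(i) {
    p <- sprintf("%s_%03d.txt", prefix, i)
    writeLines(as.character(dtrajs[[i]]), p)
    p
  }, character(1))
  invisible(paths)
}

#' Read discrete trajectories written by [write_dtrajs()]
#' @param paths file paths, one integer per line each.
#' @return list of integer vectors.
#' @export
read_dtrajs <- function(paths) {
  lapply(paths, function(p) as.integer(readLines(p)))
}
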