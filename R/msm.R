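# Markov state model estimation and validation: transition counting,
# reversible (symmetrized-count) estimation on the largest ergodic set,
# implied timescales, Chapman-Kolmogorov test, cross-validated VAMP-2
# scoring, hyperparameter scanning, and per-frame equilibrium weights.

#' Count microstate transitions at a lag
#'
#' Sliding-window counting pooled over trajectories: `C[i, j]` is the number
#' of `(t, t + lag)` frame pairs observed in states `(i, j)`.
#'
#' @param dtrajs integer vector or list of integer vectors (1-based states).
#' @param lag lag in frames (>= 1).
#' @param n_states matrix dimension (default: largest state observed).
#' @return n_states x n_states count matrix.
#' @export
count_transitions <- function(dtrajs, lag, n_states = NULL) {
  dtrajs <- if (is.list(dtrajs)) dtrajs else list(dtrajs)
  if (lag < 1) stop_gpcrmsm("validation", "lag must be >= 1")
  usable <- vapply(dtrajs, length, integer(1)) >= lag + 1
  if (!any(usable))
    stop_gpcrmsm("validation", "all trajectories are shorter than lag + 1")
  n <- n_states %||% max(unlist(dtrajs))
  C <- matrix(0, n, n)
  for (d in dtrajs[usable]) {
    len <- length(d)
    from <- d[1:(len - lag)]
    to <- d[(lag + 1):len]
    tab <- table(factor(from, levels = 1:n), factor(to, levels = 1:n))
    C <- C + unclass(tab)
  }
  dimnames(C) <- NULL
  C
}

largest_ergodic_set <- function(C, reversible = TRUE) {
  # the reversible estimator symmetrizes counts first, so connectivity is
  # assessed on C + t(C); the non-reversible one needs strong connectivity
  if (reversible) C <- C + t(C)
  g <- igraph::graph_from_adjacency_matrix(C > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership)
  # largest strongly connected set; ties toward higher total counts
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    tot <- vapply(best, function(b)
      sum(C[comp$membership == b, comp$membership == b]), numeric(1))
    best <- best[which.max(tot)]
  }
  sort(which(comp$membership == best))
}

#' Estimate a Markov state model from a count matrix
#'
#' Restricts to the largest strongly connected (ergodic) microstate set. The
#' reversible estimator symmetrizes the counts, `(C + t(C)) / 2`, and row-
#' normalizes, so detailed balance holds exactly and the stationary
#' distribution is the normalised symmetrized row sum. The non-reversible
#' estimator row-normalizes `C` directly.
#'
#' @param counts non-negative square count matrix (or a dtraj list, counted
#'   at `lag`).
#' @param lag lag in frames used for the counts (default 1).
#' @param reversible use the symmetrized-count estimator (default TRUE).
#' @param interval_ns time per frame in ns (default 1): `lag_ns = lag *
#'   interval_ns`.
#' @return object of class `msm_model` with fields `transition_matrix`,
#'   `stationary`, `eigenvalues` (magnitude-sorted), `right_ev`, `left_ev`,
#'   `timescales` (frames, from the second eigenvalue on), `active_set`
#'   (original 1-based microstate ids), `lag`, `lag_ns`, `counts`.
#' @export
estimate_msm <- function(counts, lag = 1, reversible = TRUE, interval_ns = 1) {
  if (is.list(counts) || (is.numeric(counts) && !is.matrix(counts)))
    counts <- count_transitions(counts, lag)
  if (any(counts < 0)) stop_gpcrmsm("validation", "counts must be non-negative")
  active <- largest_ergodic_set(counts, reversible)
  if (!length(active)) stop_gpcrmsm("validation", "empty ergodic set")
  C <- counts[active, active, drop = FALSE]
  n <- nrow(C)
  if (reversible) {
    Cs <- (C + t(C)) / 2
    T <- Cs / rowSums(Cs)
    pi_ <- rowSums(Cs) / sum(Cs)
    # similarity-symmetrized eigenproblem: real spectrum, stable vectors
    sq <- sqrt(pi_)
    Msym <- t(T * sq) / sq        # diag(sq) %*% T %*% diag(1/sq), transposed=same
    Msym <- (Msym + t(Msym)) / 2
    e <- eigen(Msym, symmetric = TRUE)
    ord <- order(abs(e$values), decreasing = TRUE)
    lambda <- e$values[ord]
    V <- e$vectors[, ord, drop = FALSE]
    right_ev <- V / sq
    left_ev <- V * sq
  } else {
    rs <- rowSums(C)
    if (any(rs == 0)) stop_gpcrmsm("validation", "state with no outgoing counts")
    T <- C / rs
    e <- eigen(T)
    ord <- order(abs(e$values), decreasing = TRUE)
    lambda <- e$values[ord]
    V <- e$vectors[, ord, drop = FALSE]
    right_ev <- Re(V)
    pi_ <- stationary_distribution(T)
    left_ev <- Re(solve(V))  # rows are left eigenvectors
    left_ev <- t(left_ev)
  }
  # sign convention: stationary right eigenvector positive
  if (right_ev[1, 1] < 0) { right_ev[, 1] <- -right_ev[, 1]; left_ev[, 1] <- -left_ev[, 1] }
  lam <- if (is.complex(lambda)) Re(lambda) else lambda
  ts <- rep(NA_real_, n)
  if (n >= 2) {
    l2 <- abs(lam[2:n])
    ts[2:n] <- ifelse(l2 >= 1 | l2 <= 0, NA_real_, -lag / log(l2))
  }
  structure(list(
    transition_matrix = T, stationary = pi_, eigenvalues = lam,
    right_ev = right_ev, left_ev = left_ev,
    timescales = ts[-1], lag = lag, lag_ns = lag * interval_ns,
    interval_ns = interval_ns,
    active_set = active, counts = counts, reversible = reversible
  ), class = "msm_model")
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("msm_model: %d states (of %d), lag %d frames (%.3g ns), %s\n",
              nrow(x$transition_matrix), nrow(x$counts), x$lag, x$lag_ns,
              if (x$reversible) "reversible" else "non-reversible"))
  if (length(x$timescales))
    cat("slowest timescales (frames):",
        paste(signif(head(x$timescales, 3), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Implied relaxation timescales across lags
#'
#' `t_i(tau) = -tau / ln|lambda_i(tau)|`. Negative eigenvalues enter through
#' the absolute value; such entries are flagged in the `warned` column. A
#' timescale is flagged converged when its relative change from the previous
#' lag is below `tol`.
#'
#' @param dtrajs list of integer microstate sequences.
#' @param lags integer vector of lags (frames).
#' @param n_timescales how many timescales to report (default 2).
#' @param tol relative-change convergence tolerance (default 0.1).
#' @param reversible passed to [estimate_msm()].
#' @return data.frame with columns `lag`, `index`, `timescale`, `converged`,
#'   `warned`.
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 2, tol = 0.1,
                               reversible = TRUE) {
  rows <- lapply(lags, function(l) {
    m <- estimate_msm(count_transitions(dtrajs, l), lag = l,
                      reversible = reversible)
    k <- min(n_timescales, length(m$eigenvalues) - 1)
    if (k < 1) return(NULL)
    lam <- m$eigenvalues[2:(k + 1)]
    data.frame(lag = l, index = 1:k,
               timescale = ifelse(abs(lam) >= 1 | lam == 0, NA_real_,
                                  -l / log(abs(lam))),
               warned = lam <= 0)
  })
  out <- do.call(rbind, rows)
  out$converged <- NA
  for (i in unique(out$index)) {
    sel <- which(out$index == i)
    tsv <- out$timescale[sel]
    conv <- c(NA, abs(diff(tsv)) / abs(tsv[-length(tsv)]) < tol)
    out$converged[sel] <- conv
  }
  rownames(out) <- NULL
  out
}

coarse_transition_probs <- function(msm, coarse_sets, power = 1) {
  T <- msm$transition_matrix
  Tk <- diag(nrow(T))
  for (i in seq_len(power)) Tk <- Tk %*% T
  pi_ <- msm$stationary
  m <- length(coarse_sets)
  P <- matrix(0, m, m)
  for (a in 1:m) {
    ia <- coarse_sets[[a]]
    wa <- pi_[ia] / sum(pi_[ia])
    for (b in 1:m) {
      P[a, b] <- sum(wa * rowSums(Tk[ia, coarse_sets[[b]], drop = FALSE]))
    }
  }
  P
}

#' Chapman-Kolmogorov test
#'
#' Compares the model propagated to longer times, `T(tau)^k` projected onto
#' coarse sets, against models re-estimated directly at lag `k * tau`.
#' Bootstrap bands (trajectory resampling at the stated fraction) quantify
#' the estimation uncertainty of the re-estimated probabilities.
#'
#' @param dtrajs list of integer microstate sequences.
#' @param msm the reference [estimate_msm()] model at lag tau.
#' @param coarse_sets list of integer vectors partitioning the active set
#'   (indices into the active set, 1-based).
#' @param factors lag multipliers (default 1:5).
#' @param n_boot bootstrap samples for the bands (default 50).
#' @param fraction trajectory fraction per bootstrap sample (default 0.8).
#' @param seed integer seed for the bootstrap.
#' @return object of class `ck_test` with arrays `predicted`, `estimated`,
#'   `band_sd` (factors x sets x sets), `factors`, and `skipped`.
#' @export
ck_test <- function(dtrajs, msm, coarse_sets, factors = 1:5, n_boot = 50,
                    fraction = 0.8, seed = 1) {
  stopifnot(inherits(msm, "msm_model"))
  all_states <- sort(as.integer(unlist(coarse_sets)))
  if (length(all_states) != nrow(msm$transition_matrix) ||
      any(all_states != seq_len(nrow(msm$transition_matrix))))
    stop_gpcrmsm("validation", "coarse_sets must partition the active set")
  dtrajs <- if (is.list(dtrajs)) dtrajs else list(dtrajs)
  m <- length(coarse_sets)
  maxlen <- max(vapply(dtrajs, length, integer(1)))
  est_at <- function(dt, k) {
    Ck <- count_transitions(dt, msm$lag * k, n_states = nrow(msm$counts))
    mk <- estimate_msm(Ck, lag = msm$lag * k, reversible = msm$reversible)
    if (!identical(mk$active_set, msm$active_set)) return(NULL)
    coarse_transition_probs(mk, coarse_sets, power = 1)
  }
  pred <- est <- bsd <- array(NA_real_, c(length(factors), m, m))
  skipped <- logical(length(factors))
  set.seed(seed)
  n_traj <- length(dtrajs)
  n_draw <- max(2, ceiling(fraction * n_traj))
  boot_idx <- replicate(n_boot, sample.int(n_traj, n_draw), simplify = FALSE)
  for (fi in seq_along(factors)) {
    k <- factors[fi]
    if (msm$lag * k + 1 > maxlen) {
      skipped[fi] <- TRUE
      warning(sprintf("factor %d exceeds trajectory lengths; skipped", k))
      next
    }
    pred[fi, , ] <- coarse_transition_probs(msm, coarse_sets, power = k)
    e <- est_at(dtrajs, k)
    if (is.null(e)) { skipped[fi] <- TRUE; next }
    est[fi, , ] <- e
    boots <- vapply(boot_idx, function(ix) {
      b <- tryCatch(est_at(dtrajs[ix], k), error = function(e) NULL)
      if (is.null(b)) array(NA_real_, c(m, m)) else b
    }, matrix(0, m, m))
    bsd[fi, , ] <- apply(boots, c(1, 2), sd, na.rm = TRUE)
  }
  structure(list(predicted = pred, estimated = est, band_sd = bsd,
                 factors = factors, skipped = skipped, n_boot = n_boot),
            class = "ck_test")
}

#' Maximum C-K deviation in units of the bootstrap band
#' @param ck a [ck_test()] result.
#' @return per-factor maximum of |predicted - estimated| / band_sd
#'   (entries with zero band are compared at an absolute 0.01 floor).
#' @export
ck_max_sigma <- function(ck) {
  vapply(seq_along(ck$factors), function(fi) {
    if (ck$skipped[fi]) return(NA_real_)
    dev <- abs(ck$predicted[fi, , ] - ck$estimated[fi, , ])
    band <- pmax(ck$band_sd[fi, , ], 0.01)
    max(dev / band)
  }, numeric(1))
}

sym_test_covariances <- function(dtrajs, lag, n_states) {
  C <- count_transitions(dtrajs, lag, n_states = n_states)
  Cs <- (C + t(C)) / 2
  tot <- sum(Cs)
  list(C0 = diag(rowSums(Cs) / tot, n_states), Ct = Cs / tot)
}

#' Cross-validated VAMP-2 score
#'
#' Score of the model estimated on the training trajectories, evaluated on
#' held-out test trajectories: the training eigenvectors define a k-
#' dimensional subspace, the symmetrized test covariances are projected into
#' it, and the squared generalized eigenvalues are summed. The stationary
#' process is included, so a connected chain scores at least 1. With train =
#' test this reproduces the sum of squared eigenvalues of the directly
#' estimated model.
#'
#' @param dtrajs_train,dtrajs_test lists of integer microstate sequences.
#' @param lag lag in frames.
#' @param k number of eigenvalues scored (including the stationary one).
#' @return VAMP-2 score (numeric scalar).
#' @export
vamp2_score <- function(dtrajs_train, dtrajs_test, lag, k) {
  dtrajs_train <- if (is.list(dtrajs_train)) dtrajs_train else list(dtrajs_train)
  dtrajs_test <- if (is.list(dtrajs_test)) dtrajs_test else list(dtrajs_test)
  n_states <- max(unlist(c(dtrajs_train, dtrajs_test)))
  Ctr <- count_transitions(dtrajs_train, lag, n_states = n_states)
  train <- estimate_msm(Ctr, lag = lag, reversible = TRUE)
  active <- train$active_set
  # restrict to states visited in both halves
  seen_test <- sort(unique(unlist(dtrajs_test)))
  common <- intersect(active, seen_test)
  if (length(common) < length(active))
    warning("test trajectories miss training states; scoring on the common set")
  if (length(common) < 1) stop_gpcrmsm("validation", "no common states")
  k <- min(k, length(common))
  rows <- match(common, active)
  A <- train$right_ev[rows, seq_len(k), drop = FALSE]
  cov <- sym_test_covariances(dtrajs_test, lag, n_states)
  C0 <- cov$C0[common, common, drop = FALSE]
  Ct <- cov$Ct[common, common, drop = FALSE]
  M0 <- t(A) %*% C0 %*% A
  Mt <- t(A) %*% Ct %*% A
  e0 <- eigen((M0 + t(M0)) / 2, symmetric = TRUE)
  keep <- e0$values > max(e0$values) * 1e-12
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep)) %*% t(e0$vectors[, keep, drop = FALSE])
  lam <- eigen((W %*% Mt %*% W + t(W %*% Mt %*% W)) / 2, symmetric = TRUE)$values
  lam <- pmin(pmax(lam, -1), 1)
  sum(sort(abs(lam), decreasing = TRUE)[seq_len(min(k, length(lam)))]^2)
}

#' Hyperparameter scan by cross-validated VAMP-2
#'
#' Grid search over the number of tICA components and microstates. For each
#' grid point the features are projected, clustered, and scored by k-fold
#' cross-validation at the MSM lag: trajectories are split into folds, the
#' model is trained on the complement and scored on the held-out fold. Ties
#' are broken toward fewer clusters, then fewer tICs.
#'
#' @param feature_trajectories list of frames x features matrices.
#' @param lag MSM lag in frames.
#' @param n_tics_grid,n_clusters_grid integer grids.
#' @param folds cross-validation folds (default 10; capped at the number of
#'   trajectories).
#' @param seed integer seed (clustering and fold assignment).
#' @param n_eigen eigenvalues entering the score (default 5, capped at the
#'   smallest cluster count in the grid).
#' @param tica_lag tICA lag (default `lag`).
#' @return list with `best` (row of the table) and `table`
#'   (n_tics, n_clusters, mean_score, sd_score).
#' @export
hyperparameter_scan <- function(feature_trajectories, lag, n_tics_grid,
                                n_clusters_grid, folds = 10, seed = 1,
                                n_eigen = 5, tica_lag = lag) {
  if (!length(n_tics_grid) || !length(n_clusters_grid))
    stop_gpcrmsm("validation", "grid must be nonempty")
  trajs <- as_traj_list(feature_trajectories)
  n_traj <- length(trajs)
  folds <- min(folds, n_traj)
  n_eigen <- min(n_eigen, min(n_clusters_grid))
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n_traj))
  grid <- expand.grid(n_tics = n_tics_grid, n_clusters = n_clusters_grid)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    nt <- grid$n_tics[g]; nc <- grid$n_clusters[g]
    tic <- fit_tica(trajs, lag = tica_lag, n_components = nt)
    proj <- project_tica(tic, trajs)
    km <- fit_kmeans(proj, k = nc, seed = seed)
    scores <- vapply(seq_len(folds), function(f) {
      test <- which(fold_id == f)
      train <- setdiff(seq_len(n_traj), test)
      if (!length(train) || !length(test)) return(NA_real_)
      tryCatch(vamp2_score(km$dtrajs[train], km$dtrajs[test], lag, n_eigen),
               error = function(e) NA_real_)
    }, numeric(1))
    c(mean_score = mean(scores, na.rm = TRUE),
      sd_score = sd(scores, na.rm = TRUE))
  })
  tab <- cbind(grid, do.call(rbind, res))
  # argmax mean score; ties toward fewer clusters, then fewer tICs
  ord <- order(-round(tab$mean_score, 10), tab$n_clusters, tab$n_tics)
  list(best = tab[ord[1], , drop = FALSE], table = tab)
}

#' Build an MSM at a physical lag time
#'
#' Convenience wrapper converting a lag in nanoseconds (default 25 ns, the
#' validated receptor-MSM lag) into frames via the frame interval, then
#' counting and estimating.
#'
#' @param dtrajs list of integer microstate sequences.
#' @param interval_ns time between frames in ns.
#' @param lag_ns lag time in ns (default 25).
#' @param reversible passed to [estimate_msm()].
#' @return an `msm_model`.
#' @export
build_msm <- function(dtrajs, interval_ns = 1, lag_ns = 25,
                      reversible = TRUE) {
  lag <- max(1L, as.integer(round(lag_ns / interval_ns)))
  estimate_msm(count_transitions(dtrajs, lag), lag = lag,
               reversible = reversible, interval_ns = interval_ns)
}

#' Per-frame equilibrium weights from an MSM
#'
#' A frame in active microstate i receives weight `pi_i / n_i`, where `n_i`
#' is the number of frames observed in i; frames in trimmed states receive
#' weight 0 (with a warning). Weights sum to 1.
#'
#' @param msm an [estimate_msm()] model.
#' @param dtrajs list of integer microstate sequences.
#' @return list of per-frame weight vectors matching `dtrajs`.
#' @export
frame_weights <- function(msm, dtrajs) {
  dtrajs <- if (is.list(dtrajs)) dtrajs else list(dtrajs)
  all_states <- unlist(dtrajs)
  counts <- tabulate(all_states, nbins = max(all_states, nrow(msm$counts)))
  w_state <- numeric(length(counts))
  w_state[msm$active_set] <- msm$stationary / pmax(counts[msm$active_set], 1)
  if (any(counts[-msm$active_set] > 0))
    warning("frames in trimmed microstates receive weight 0")
  lapply(dtrajs, function(d) w_state[d])
}

#' Serialize an MSM to JSON
#' @param msm an `msm_model`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_msm_json <- function(msm, file) {
  jsonlite::write_json(list(
    lag = msm$lag, lag_ns = msm$lag_ns, active_set = msm$active_set,
    transition_matrix = msm$transition_matrix, stationary = msm$stationary,
    eigenvalues = msm$eigenvalues, timescales = msm$timescales,
    reversible = msm$reversible
  ), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
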