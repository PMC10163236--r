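# Bootstrap error machinery and MSM-weighted free-energy projections.

new_bootstrap_report <- function(name, values, n_samples, fraction, seed,
                                 n_failed) {
  values <- rbind(values)
  structure(list(
    statistic = name, n_samples = n_samples, fraction = fraction,
    values = values,
    mean = colMeans(values, na.rm = TRUE),
    sd = apply(values, 2, sd, na.rm = TRUE),
    n_failed = n_failed, seed = seed
  ), class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("bootstrap_report '%s': %d samples (%d failed)\n",
              x$statistic, x$n_samples, x$n_failed))
  cat("mean:", paste(signif(head(x$mean, 6), 4), collapse = ", "), "\n")
  cat("sd:  ", paste(signif(head(x$sd, 6), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Trajectory-level bootstrap of a pipeline statistic
#'
#' Each sample draws `ceiling(fraction * N)` trajectories without
#' replacement and recomputes the statistic; the protocol default is 200
#' samples at 80% of the trajectories. Failing samples are excluded and
#' counted.
#'
#' @param trajectories list (of dtrajs, feature matrices, ...; >= 2
#'   entries).
#' @param statistic function taking a trajectory subset (list) and
#'   returning a numeric vector of fixed length.
#' @param n_samples bootstrap samples (default 200).
#' @param fraction trajectory fraction per sample (default 0.8).
#' @param seed integer seed.
#' @param name statistic label for the report.
#' @return a `bootstrap_report`: per-sample values, mean, SD, failure
#'   count.
#' @export
bootstrap_trajectories <- function(trajectories, statistic, n_samples = 200,
                                   fraction = 0.8, seed = 1,
                                   name = "statistic") {
  if (length(trajectories) < 2)
    stop_gpcrmsm("validation", "need at least 2 trajectories")
  set.seed(seed)
  n <- length(trajectories)
  n_draw <- max(1, ceiling(fraction * n))
  vals <- NULL; n_failed <- 0
  for (b in seq_len(n_samples)) {
    idx <- sample.int(n, n_draw)
    v <- tryCatch(as.numeric(statistic(trajectories[idx])),
                  error = function(e) NULL)
    if (is.null(v)) {
      n_failed <- n_failed + 1
      v <- rep(NA_real_, if (is.null(vals)) 1 else ncol(vals))
    }
    vals <- rbind(vals, v)
  }
  new_bootstrap_report(name, vals, n_samples, fraction, seed, n_failed)
}

#' Frame-level bootstrap within a metastable state
#'
#' Each sample selects `n_frames` frames (the protocol default is 20
#' samples of 1000 frames); selection is without replacement when enough
#' frames exist, otherwise with replacement and flagged.
#'
#' @param state_frames frames x features matrix (or data.frame) for one
#'   metastable state.
#' @param statistic function taking the resampled matrix and returning a
#'   numeric vector of fixed length.
#' @param n_samples bootstrap samples (default 20).
#' @param n_frames frames per sample (default 1000).
#' @param seed integer seed.
#' @param name statistic label.
#' @param replace force sampling with (TRUE) or without (FALSE) replacement;
#'   default `NULL` subsamples without replacement and switches to
#'   replacement only when oversampling, flagging it.
#' @return a `bootstrap_report` with an extra `replacement` flag.
#' @export
bootstrap_frames <- function(state_frames, statistic, n_samples = 20,
                             n_frames = 1000, seed = 1, name = "statistic",
                             replace = NULL) {
  X <- rbind(unclass(state_frames))
  set.seed(seed)
  replace <- replace %||% (nrow(X) < n_frames)
  vals <- NULL; n_failed <- 0
  for (b in seq_len(n_samples)) {
    idx <- sample.int(nrow(X), n_frames, replace = replace)
    v <- tryCatch(as.numeric(statistic(X[idx, , drop = FALSE])),
                  error = function(e) NULL)
    if (is.null(v)) {
      n_failed <- n_failed + 1
      v <- rep(NA_real_, if (is.null(vals)) 1 else ncol(vals))
    }
    vals <- rbind(vals, v)
  }
  rep_ <- new_bootstrap_report(name, vals, n_samples, NA_real_, seed, n_failed)
  rep_$replacement <- replace
  rep_
}

#' MSM-weighted free-energy projection
#'
#' `-kT * ln` of the weighted density on a 1-D or 2-D histogram of the
#' projected coordinates, shifted so the minimum bin is exactly 0. Empty
#' bins are NA (undefined), never `-Inf`.
#'
#' @param projection numeric vector (1-D) or 2-column matrix (2-D).
#' @param frame_weights per-frame weights summing to 1 (default uniform).
#' @param bins bins per axis (default 30).
#' @param kT energy unit (default 1; `kT_KCAL_300K` gives kcal/mol at
#'   300 K).
#' @return list with `free_energy` (vector or matrix with NA for empty
#'   bins), `breaks` (list per axis), `kT`.
#' @export
free_energy_surface <- function(projection, frame_weights = NULL, bins = 30,
                                kT = 1) {
  X <- if (is.matrix(projection)) projection else matrix(projection, ncol = 1)
  if (!ncol(X) %in% 1:2)
    stop_gpcrmsm("validation", "projection must be 1-D or 2-D")
  n <- nrow(X)
  w <- frame_weights %||% rep(1 / n, n)
  w <- w / sum(w)
  breaks <- lapply(seq_len(ncol(X)), function(j) {
    rng <- range(X[, j])
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    seq(rng[1], rng[2], length.out = bins + 1)
  })
  bin_of <- function(x, br) {
    b <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
    pmin(pmax(b, 1L), length(br) - 1L)
  }
  if (ncol(X) == 1) {
    dens <- numeric(bins)
    b1 <- bin_of(X[, 1], breaks[[1]])
    for (i in seq_len(n)) dens[b1[i]] <- dens[b1[i]] + w[i]
  } else {
    dens <- matrix(0, bins, bins)
    b1 <- bin_of(X[, 1], breaks[[1]])
    b2 <- bin_of(X[, 2], breaks[[2]])
    for (i in seq_len(n)) dens[b1[i], b2[i]] <- dens[b1[i], b2[i]] + w[i]
  }
  if (sum(dens > 0) <= 1)
    warning("degenerate surface: all weight in one bin")
  fe <- ifelse(dens > 0, -kT * log(dens), NA_real_)
  fe <- fe - min(fe, na.rm = TRUE)
  list(free_energy = fe, breaks = breaks, kT = kT)
}

#' Boltzmann constant times 300 K in kcal/mol
#' @export
kT_KCAL_300K <- 0.0019872041 * 300
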