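# Metastable decomposition: spectral soft coarse-graining of microstates
# (inner-simplex PCCA-style memberships on the leading right eigenvectors),
# state-count selection by the two protocol criteria (minimum 4% population;
# minimum bootstrap error of the slowest implied timescale), and
# population-proportional representative-frame sampling.

inner_simplex_vertices <- function(Psi) {
  # classic inner-simplex search: the m rows of Psi closest to the simplex
  # vertices, found by iterated orthogonal deflation
  m <- ncol(Psi)
  ortho <- Psi
  idx <- integer(m)
  for (j in seq_len(m)) {
    norms <- sqrt(rowSums(ortho^2))
    idx[j] <- which.max(norms)
    v <- ortho[idx[j], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-14) stop_gpcrmsm("numeric", "degenerate eigenvector geometry")
    v <- v / nv
    ortho <- ortho - outer(as.numeric(ortho %*% v), v)
  }
  idx
}

#' Coarse-grain an MSM into metastable states
#'
#' Spectral soft clustering on the top-m right eigenvectors of the
#' transition matrix: the m microstates spanning the eigenvector simplex
#' become vertices, every other microstate gets a membership row by linear
#' inversion, clipped to `[0, 1]` and renormalised. For nearly block-
#' structured chains the memberships are close to crisp.
#'
#' @param msm an [estimate_msm()] model.
#' @param m number of metastable states (2 <= m <= active-set size).
#' @return object of class `metastable_model` with fields `m`, `memberships`
#'   (microstates x m, rows sum to 1), `populations` (sum of pi * chi),
#'   `crisp` (argmax membership per microstate, ties to lower state index),
#'   `msm`.
#' @export
coarse_grain <- function(msm, m) {
  n <- nrow(msm$transition_matrix)
  if (m < 2 || m > n)
    stop_gpcrmsm("validation", "m must be between 2 and the active-set size")
  lam <- abs(msm$eigenvalues)
  if (m < n && abs(lam[m] - lam[m + 1]) < 1e-12)
    stop_gpcrmsm("numeric",
                 "degenerate eigenvalue crossing at m = %d; try a different m", m)
  Psi <- msm$right_ev[, seq_len(m), drop = FALSE]
  Psi[, 1] <- 1
  idx <- inner_simplex_vertices(Psi)
  A <- tryCatch(solve(Psi[idx, , drop = FALSE]),
                error = function(e)
                  stop_gpcrmsm("numeric", "singular vertex system at m = %d", m))
  chi <- Psi %*% A
  chi[chi < 0] <- 0
  rs <- rowSums(chi)
  rs[rs == 0] <- 1
  chi <- chi / rs
  pops <- as.numeric(t(chi) %*% msm$stationary)
  crisp <- apply(chi, 1, which.max)  # which.max ties to lowest index
  structure(list(m = m, memberships = chi, populations = pops,
                 crisp = as.integer(crisp), msm = msm),
            class = "metastable_model")
}

#' @export
print.metastable_model <- function(x, ...) {
  cat(sprintf("metastable_model: %d states over %d microstates\n",
              x$m, nrow(x$memberships)))
  cat("populations:", paste(signif(x$populations, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Microstate sets of each metastable state (crisp assignment)
#' @param meta a [coarse_grain()] model.
#' @return list of integer vectors (active-set indices) per metastable state.
#' @export
metastable_sets <- function(meta) {
  lapply(seq_len(meta$m), function(s) which(meta$crisp == s))
}

#' Crisp per-frame metastable assignment
#' @param meta a [coarse_grain()] model.
#' @param dtrajs list of integer microstate sequences (original ids).
#' @return list of integer vectors; frames in trimmed microstates are NA.
#' @export
assign_frames <- function(meta, dtrajs) {
  dtrajs <- if (is.list(dtrajs)) dtrajs else list(dtrajs)
  map <- rep(NA_integer_, nrow(meta$msm$counts))
  map[meta$msm$active_set] <- meta$crisp
  lapply(dtrajs, function(d) map[d])
}

coarse_grained_matrix <- function(msm, meta) {
  # pi-weighted projection of T onto the membership vectors
  chi <- meta$memberships
  Pi <- msm$stationary
  M0 <- t(chi) %*% (chi * Pi)
  Mt <- t(chi) %*% (Pi * (msm$transition_matrix %*% chi))
  solve(M0, Mt)
}

#' Select the number of metastable states
#'
#' Applies the two selection criteria: candidates producing any metastable
#' state below `min_population` are discarded; among the survivors the
#' candidate minimising the bootstrap standard deviation of the slowest
#' coarse-grained implied timescale is chosen. Bootstrap samples re-estimate
#' the MSM from a resampled trajectory subset and coarse-grain it at the
#' candidate m.
#'
#' @param msm reference [estimate_msm()] model.
#' @param dtrajs list of integer microstate sequences.
#' @param candidates integer vector of candidate state counts.
#' @param min_population minimum allowed metastable population (default
#'   0.04).
#' @param n_boot bootstrap samples (default 20).
#' @param fraction trajectory fraction per sample (default 0.8).
#' @param seed integer seed.
#' @return list with `m` (chosen count) and `report` (data.frame: candidate,
#'   min_population, discarded, timescale_mean, timescale_sd).
#' @export
select_state_count <- function(msm, dtrajs, candidates, min_population = 0.04,
                               n_boot = 20, fraction = 0.8, seed = 1) {
  if (!length(candidates)) stop_gpcrmsm("validation", "candidates must be nonempty")
  dtrajs <- if (is.list(dtrajs)) dtrajs else list(dtrajs)
  set.seed(seed)
  n_traj <- length(dtrajs)
  n_draw <- max(2, ceiling(fraction * n_traj))
  boot_idx <- replicate(n_boot, sample.int(n_traj, n_draw), simplify = FALSE)
  rows <- lapply(candidates, function(m) {
    meta <- tryCatch(coarse_grain(msm, m), error = function(e) NULL)
    if (is.null(meta))
      return(data.frame(candidate = m, min_population = NA_real_,
                        discarded = TRUE, timescale_mean = NA_real_,
                        timescale_sd = NA_real_))
    minp <- min(meta$populations)
    discarded <- minp < min_population
    ts_b <- rep(NA_real_, n_boot)
    if (!discarded) {
      for (b in seq_len(n_boot)) {
        mb <- tryCatch({
          msm_b <- estimate_msm(count_transitions(dtrajs[boot_idx[[b]]], msm$lag,
                                                  n_states = nrow(msm$counts)),
                                lag = msm$lag, reversible = msm$reversible,
                                interval_ns = msm$interval_ns)
          meta_b <- coarse_grain(msm_b, m)
          Tc <- coarse_grained_matrix(msm_b, meta_b)
          l2 <- sort(abs(eigen(Tc, only.values = TRUE)$values),
                     decreasing = TRUE)[2]
          if (l2 >= 1 || l2 <= 0) NA_real_ else -msm$lag / log(l2)
        }, error = function(e) NA_real_)
        ts_b[b] <- mb
      }
    }
    data.frame(candidate = m, min_population = minp, discarded = discarded,
               timescale_mean = mean(ts_b, na.rm = TRUE),
               timescale_sd = sd(ts_b, na.rm = TRUE))
  })
  report <- do.call(rbind, rows)
  surv <- report[!report$discarded & is.finite(report$timescale_sd), , drop = FALSE]
  if (!nrow(surv))
    stop_gpcrmsm("selection",
                 "no candidate satisfies the population rule; per-candidate minima: %s",
                 paste(sprintf("m=%d: %.3f", report$candidate,
                               report$min_population), collapse = ", "))
  list(m = surv$candidate[which.min(surv$timescale_sd)], report = report)
}

#' Sample representative frames per metastable state
#'
#' For metastable state s, frames are drawn with probability proportional to
#' `pi_i * chi_is` of their microstate i (equal sharing within a
#' microstate). Sampling is without replacement unless a state holds fewer
#' frames than requested, in which case replacement is used and flagged.
#'
#' @param meta a [coarse_grain()] model.
#' @param dtrajs list of integer microstate sequences.
#' @param n_per_state frames per state (default 1000; the docking stage of
#'   the protocol uses 100).
#' @param seed integer seed.
#' @return list per state: data.frame(traj, frame) plus attribute
#'   `replacement` flagging oversampled states.
#' @export
sample_state_frames <- function(meta, dtrajs, n_per_state = 1000, seed = 1) {
  if (n_per_state < 1) stop_gpcrmsm("validation", "n_per_state must be >= 1")
  dtrajs <- if (is.list(dtrajs)) dtrajs else list(dtrajs)
  if (any(meta$populations <= 0))
    stop_gpcrmsm("validation", "metastable state with zero population")
  frame_tab <- do.call(rbind, lapply(seq_along(dtrajs), function(i)
    data.frame(traj = i, frame = seq_along(dtrajs[[i]]),
               micro = dtrajs[[i]])))
  # microstate-level sampling weight per state
  active <- meta$msm$active_set
  counts <- tabulate(frame_tab$micro, nbins = nrow(meta$msm$counts))
  set.seed(seed)
  out <- lapply(seq_len(meta$m), function(s) {
    w_micro <- numeric(nrow(meta$msm$counts))
    w_micro[active] <- meta$msm$stationary * meta$memberships[, s]
    w_frame <- w_micro[frame_tab$micro] / pmax(counts[frame_tab$micro], 1)
    pool <- which(w_frame > 0)
    replace <- length(pool) < n_per_state
    pick <- sample(pool, n_per_state, replace = replace,
                   prob = w_frame[pool])
    res <- frame_tab[pick, c("traj", "frame")]
    rownames(res) <- NULL
    attr(res, "replacement") <- replace
    res
  })
  names(out) <- paste0("state", seq_len(meta$m))
  out
}

#' Write metastable memberships and populations as CSV
#' @param meta a `metastable_model`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_metastable_csv <- function(meta, file) {
  df <- data.frame(microstate = meta$msm$active_set,
                   crisp = meta$crisp,
                   meta$memberships)
  names(df)[-(1:2)] <- paste0("chi_", seq_len(meta$m))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
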