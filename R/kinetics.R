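# Transition kinetics: forward committors, reactive flux, mean first
# passage times via the flux formula, and kinetic Monte Carlo simulation on
# the MSM transition matrix.

check_sets <- function(msm, A, B) {
  n <- nrow(msm$transition_matrix)
  A <- as.integer(A); B <- as.integer(B)
  if (!length(A) || !length(B))
    stop_gpcrmsm("validation", "A and B must be nonempty")
  if (length(intersect(A, B)))
    stop_gpcrmsm("validation", "A and B must be disjoint")
  if (min(c(A, B)) < 1 || max(c(A, B)) > n)
    stop_gpcrmsm("validation", "A/B indices outside the active set")
  list(A = A, B = B)
}

#' Forward committor probabilities
#'
#' `q_i` is the probability that a chain started in microstate i reaches the
#' sink set B before the source set A. Solves the harmonic linear system on
#' the intermediate states with boundary conditions q = 0 on A, q = 1 on B.
#'
#' @param msm an [estimate_msm()] model (indices refer to the active set).
#' @param A,B disjoint nonempty integer index sets.
#' @return numeric committor vector over all active microstates.
#' @export
forward_committor <- function(msm, A, B) {
  s <- check_sets(msm, A, B); A <- s$A; B <- s$B
  T <- msm$transition_matrix
  n <- nrow(T)
  q <- numeric(n)
  q[B] <- 1
  inter <- setdiff(seq_len(n), c(A, B))
  if (length(inter)) {
    M <- diag(length(inter)) - T[inter, inter, drop = FALSE]
    rhs <- rowSums(T[inter, B, drop = FALSE])
    qi <- tryCatch(solve(M, rhs), error = function(e)
      stop_gpcrmsm("numeric", "committor system singular (disconnected B?)"))
    q[inter] <- qi
  }
  if (all(q[setdiff(seq_len(n), B)] < 1e-14) && length(inter))
    stop_gpcrmsm("validation", "sink set B unreachable from the intermediates")
  pmin(pmax(q, 0), 1)
}

#' Reactive flux and total A -> B flux
#'
#' Gross flux `f_ij = pi_i (1 - q_i) T_ij q_j` for i != j; the net flux is
#' the positive part of `f_ij - f_ji`; the total flux F is the gross flux
#' out of the source set A.
#'
#' @inheritParams forward_committor
#' @return object of class `tpt_result`: `committor`, `flux_gross`,
#'   `flux_net`, `total_flux` (per lag step), `mfpt_frames`, `mfpt_ns`,
#'   `A`, `B`.
#' @export
reactive_flux <- function(msm, A, B) {
  s <- check_sets(msm, A, B); A <- s$A; B <- s$B
  q <- forward_committor(msm, A, B)
  T <- msm$transition_matrix
  pi_ <- msm$stationary
  f <- (pi_ * (1 - q)) * T * rep(q, each = nrow(T))
  diag(f) <- 0
  Fnet <- pmax(f - t(f), 0)
  total <- sum(f[A, setdiff(seq_len(nrow(T)), A), drop = FALSE])
  if (total <= 0)
    stop_gpcrmsm("validation", "zero flux between A and B (disconnected sets)")
  mfpt_frames <- msm$lag * sum(pi_ * (1 - q)) / total
  structure(list(
    committor = q, flux_gross = f, flux_net = Fnet, total_flux = total,
    mfpt_frames = mfpt_frames,
    mfpt_ns = mfpt_frames * msm$interval_ns,
    A = A, B = B
  ), class = "tpt_result")
}

#' @export
print.tpt_result <- function(x, ...) {
  cat(sprintf("tpt_result: F = %.4g per step, MFPT = %.4g frames (%.4g ns)\n",
              x$total_flux, x$mfpt_frames, x$mfpt_ns))
  invisible(x)
}

#' Mean first passage time A -> B
#'
#' The flux formula `MFPT = tau * sum_i pi_i (1 - q_i) / F` evaluated over
#' all microstates, reported in frames and nanoseconds.
#'
#' @inheritParams forward_committor
#' @return list with `frames` and `ns`.
#' @export
mfpt <- function(msm, A, B) {
  tpt <- reactive_flux(msm, A, B)
  list(frames = tpt$mfpt_frames, ns = tpt$mfpt_ns)
}

#' Kinetic Monte Carlo simulation on a transition matrix
#'
#' Iteratively builds the cumulative transition distribution of the current
#' microstate, draws R in [0, 1), jumps to the first state whose cumulative
#' probability exceeds R, and advances time by one lag. Reproducible for a
#' fixed seed.
#'
#' @param msm an [estimate_msm()] model, or a bare row-stochastic matrix.
#' @param start_state 1-based start microstate (active-set index). For an
#'   activation ensemble the conventional start is the inactive metastable
#'   state's highest-membership microstate.
#' @param n_steps number of kMC steps including the start.
#' @param seed integer seed.
#' @param feature_means optional microstates x features matrix of per-state
#'   feature means; when given, the per-step feature read-out is returned.
#' @return integer state sequence, or (with `feature_means`) a list with
#'   `states` and `features`.
#' @export
kmc_simulate <- function(msm, start_state, n_steps, seed = NULL,
                         feature_means = NULL) {
  T <- if (inherits(msm, "msm_model")) msm$transition_matrix else
    check_stochastic(msm)
  if (start_state < 1 || start_state > nrow(T))
    stop_gpcrmsm("validation", "start_state outside the active set")
  if (!is.null(seed)) set.seed(seed)
  states <- chain_simulate_cpp(T, as.integer(n_steps), as.integer(start_state))
  if (is.null(feature_means)) return(states)
  list(states = states,
       features = feature_means[states, , drop = FALSE])
}

#' Default kMC start microstate for a metastable decomposition
#'
#' The highest-membership microstate of the given (by convention, inactive)
#' metastable state.
#'
#' @param meta a [coarse_grain()] model.
#' @param state metastable state index (default 1).
#' @return active-set microstate index.
#' @export
kmc_start_state <- function(meta, state = 1) {
  which.max(meta$memberships[, state])
}

#' Empirical first-passage times by direct chain simulation
#'
#' Brute-force oracle for the MFPT formula: repeatedly simulate the chain
#' from `start` until the target set is hit and record the number of lag
#' steps.
#'
#' @param msm an `msm_model` or transition matrix.
#' @param start 1-based start state.
#' @param B integer target set.
#' @param n_passages number of passages to sample.
#' @param seed integer seed.
#' @param max_steps per-passage step cap (default 1e7).
#' @return numeric vector of passage times in lag steps.
#' @export
sample_first_passage <- function(msm, start, B, n_passages, seed = NULL,
                                 max_steps = 1e7) {
  T <- if (inherits(msm, "msm_model")) msm$transition_matrix else
    check_stochastic(msm)
  if (!is.null(seed)) set.seed(seed)
  target <- rep(FALSE, nrow(T))
  target[B] <- TRUE
  first_passage_cpp(T, as.integer(start), target, as.integer(n_passages),
                    max_steps)
}

#' Empirical A -> B passage times from an equilibrium trajectory
#'
#' Labels every frame by the core set (A or B) visited most recently, and
#' measures, for each completed A -> B transition, the time elapsed since
#' the trajectory last arrived in A from B. The mean of these durations is
#' the empirical counterpart of the flux-formula MFPT, `tau * sum_i pi_i
#' (1 - q_i) / F`.
#'
#' @param states integer state sequence (e.g. from [kmc_simulate()]).
#' @param A,B disjoint integer core sets.
#' @return numeric vector of passage durations in lag steps (possibly
#'   empty).
#' @export
empirical_passage_times <- function(states, A, B) {
  lab <- rep(NA_integer_, length(states))
  lab[states %in% A] <- 1L
  lab[states %in% B] <- 2L
  known <- !is.na(lab)
  if (!any(known)) return(numeric(0))
  # forward-fill the last visited core label
  idx <- cummax(ifelse(known, seq_along(lab), 0L))
  keep <- idx > 0
  lab_f <- lab[idx[keep]]
  t_f <- which(keep)
  switch_pts <- which(diff(lab_f) != 0) + 1
  if (!length(switch_pts)) return(numeric(0))
  durations <- numeric(0)
  last_entry_a <- if (lab_f[1] == 1) t_f[1] else NA_real_
  for (sp in switch_pts) {
    if (lab_f[sp] == 1) {
      last_entry_a <- t_f[sp]
    } else if (!is.na(last_entry_a)) {
      durations <- c(durations, t_f[sp] - last_entry_a)
      last_entry_a <- NA_real_
    }
  }
  durations
}

#' Write a TPT result as JSON
#' @param tpt a `tpt_result`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tpt_json <- function(tpt, file) {
  jsonlite::write_json(list(
    A = tpt$A, B = tpt$B, committor = tpt$committor,
    total_flux = tpt$total_flux, mfpt_frames = tpt$mfpt_frames,
    mfpt_ns = tpt$mfpt_ns
  ), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
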