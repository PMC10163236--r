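# Shared fixtures, all built in code.

# random ergodic reversible chain: symmetric counts guarantee detailed balance
random_reversible_chain <- function(n, seed) {
  set.seed(seed)
  C <- matrix(rgamma(n * n, 1), n, n) + diag(rgamma(n, 5))
  Cs <- (C + t(C)) / 2
  Cs / rowSums(Cs)
}

# exact "direct input" MSM for a known T: detailed-balance counts diag(pi) T
msm_from_matrix <- function(T, scale = 1e6, interval_ns = 1) {
  pi_ <- stationary_distribution(T)
  estimate_msm(diag(pi_) %*% T * scale, lag = 1, interval_ns = interval_ns)
}

# six-state ground truth used across the suite: hierarchical kinetics with
# well-separated per-state emissions
six_state_spec <- function(inter = 0.002, intra = 0.08) {
  ground_truth_spec(
    hierarchical_transition_matrix(inter = inter, intra = intra),
    emission_means = cbind(f1 = 3 * (0:5), f2 = c(0, 4, 8, 0, 4, 8)),
    emission_sds = 0.5
  )
}

simulate_batch <- function(T, n_traj, n_steps, seed) {
  lapply(seq_len(n_traj), function(i)
    simulate_markov_chain(T, n_steps, start_state = ((i - 1) %% nrow(T)) + 1,
                          seed = seed + i))
}

# Monte-Carlo committor oracle: from one long equilibrium trajectory, the
# fraction of visits to each state whose next A/B hit is B (next-hit labels
# by backward fill)
mc_committor <- function(states, A, B) {
  lab <- rep(NA_integer_, length(states))
  lab[states %in% A] <- 0L
  lab[states %in% B] <- 1L
  pos <- seq_along(lab)
  nk <- rev(cummin(rev(replace(as.numeric(pos), is.na(lab), Inf))))
  ok <- is.finite(nk)
  next_hit <- rep(NA_integer_, length(states))
  next_hit[ok] <- lab[nk[ok]]
  vapply(seq_len(max(states)), function(s) {
    sel <- states == s & ok
    if (!any(sel)) return(NA_real_)
    mean(next_hit[sel])
  }, numeric(1))
}

# minimal hand-built msm_model for boundary-case kinetics tests
fake_msm <- function(T, lag = 1, interval_ns = 1) {
  structure(list(transition_matrix = T,
                 stationary = stationary_distribution(T),
                 lag = lag, lag_ns = lag * interval_ns,
                 interval_ns = interval_ns,
                 active_set = seq_len(nrow(T)),
                 counts = T, reversible = TRUE,
                 eigenvalues = sort(abs(eigen(T)$values), decreasing = TRUE)),
            class = "msm_model")
}

# straight-chain pseudo-structure: one carbon per residue, fixed spacing
chain_structure <- function(n_res, spacing = 4.0) {
  topo <- residue_topology(data.frame(
    index = 1:n_res, name = "CA", element = "C",
    resno = 1:n_res, resid = "ALA", stringsAsFactors = FALSE))
  xyz <- matrix(0, 1, 3 * n_res)
  xyz[1, seq(1, by = 3, length.out = n_res)] <- spacing * (0:(n_res - 1))
  ensemble_frames(xyz, topo)
}
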