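# Synthetic-data module: ground-truth-known surrogates for the MD ensembles
# the pipeline is designed to analyse. A latent Markov chain over a small
# number of metastable states with hierarchically separated exchange
# timescales drives (a) Gaussian feature emissions with optional pairwise
# couplings and (b) pseudo-atomic coordinates interpolated between an
# "inactive" and an "active" reference structure.

#' Ground-truth specification for synthetic trajectory generation
#'
#' Bundles the latent transition matrix, per-state Gaussian emission
#' parameters and optional feature couplings that define a synthetic system.
#'
#' @param transition_matrix row-stochastic matrix over latent states.
#' @param emission_means matrix (states x features) of emission locations;
#'   column names become feature names.
#' @param emission_sds matrix (states x features) of emission scales, all > 0.
#'   A scalar is recycled.
#' @param lag_ns time per chain step in nanoseconds (default 25, the lag at
#'   which the receptor MSMs are built).
#' @param coupling optional list of couplings, each a list with elements
#'   `f1`, `f2` (feature names or indices) and `prob` (co-occurrence
#'   probability of the two features' binarized active states).
#' @return an object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(transition_matrix, emission_means, emission_sds,
                              lag_ns = 25, coupling = NULL) {
  transition_matrix <- check_stochastic(transition_matrix, tol = 1e-12)
  n_states <- nrow(transition_matrix)
  if (n_states < 2) stop_gpcrmsm("validation", "need at least 2 latent states")
  emission_means <- as.matrix(emission_means)
  if (length(emission_sds) == 1)
    emission_sds <- matrix(emission_sds, nrow(emission_means), ncol(emission_means))
  emission_sds <- as.matrix(emission_sds)
  if (nrow(emission_means) != n_states)
    stop_gpcrmsm("validation", "emission_means must have one row per latent state")
  if (!all(dim(emission_sds) == dim(emission_means)))
    stop_gpcrmsm("validation", "emission_sds dimensions must match emission_means")
  if (any(emission_sds < 0))
    stop_gpcrmsm("validation", "emission scales must be >= 0")
  if (is.null(colnames(emission_means)))
    colnames(emission_means) <- paste0("f", seq_len(ncol(emission_means)))
  colnames(emission_sds) <- colnames(emission_means)
  structure(list(
    n_states = n_states,
    transition_matrix = transition_matrix,
    lag_ns = lag_ns,
    emission_means = emission_means,
    emission_sds = emission_sds,
    coupling = coupling
  ), class = "ground_truth_spec")
}

#' Reference transition matrix with hierarchical timescales
#'
#' A six-state chain arranged as two weakly exchanging blocks of three, with
#' faster within-block exchange. This reproduces the timescale hierarchy of
#' an activation ensemble: one slow (activation-like) process well separated
#' from faster intra-basin relaxations.
#'
#' @param inter probability scale of between-block jumps (slow process).
#' @param intra probability scale of within-block jumps (fast processes).
#' @return 6x6 row-stochastic matrix.
#' @export
hierarchical_transition_matrix <- function(inter = 0.01, intra = 0.08) {
  n <- 6
  T <- matrix(0, n, n)
  blocks <- list(1:3, 4:6)
  for (b in blocks) {
    for (i in b) for (j in b) if (i != j) T[i, j] <- intra
  }
  # one slow doorway between the blocks
  T[3, 4] <- inter
  T[4, 3] <- inter
  diag(T) <- 1 - rowSums(T)
  check_stochastic(T)
}

#' Simulate a discrete-time Markov chain
#'
#' @param transition_matrix row-stochastic matrix.
#' @param n_steps number of steps (>= 1), including the start state.
#' @param start_state 1-based start state.
#' @param seed integer seed; the chain is reproducible for a fixed seed.
#' @return integer vector of 1-based states, length `n_steps`.
#' @export
simulate_markov_chain <- function(transition_matrix, n_steps, start_state = 1,
                                  seed = NULL) {
  T <- check_stochastic(transition_matrix)
  if (n_steps < 1) stop_gpcrmsm("validation", "n_steps must be >= 1")
  if (start_state < 1 || start_state > nrow(T))
    stop_gpcrmsm("validation", "start_state out of range")
  if (!is.null(seed)) set.seed(seed)
  chain_simulate_cpp(T, as.integer(n_steps), as.integer(start_state))
}

#' Emit per-frame features from a latent state sequence
#'
#' Each latent state emits every feature from its Gaussian
#' (location/scale) row of the spec. Couplings force the binarized
#' active/inactive status of a feature pair to co-occur with the stated
#' probability: with probability `prob` the second feature's value is
#' reflected across its activity threshold onto the side of the first.
#' Thresholds are the midpoint of the per-state emission means.
#'
#' @param latent_sequence integer vector of 1-based latent states.
#' @param spec a [ground_truth_spec()].
#' @param seed integer seed.
#' @return numeric matrix frames x features with feature column names,
#'   of class `feature_matrix`.
#' @export
emit_features <- function(latent_sequence, spec, seed = NULL) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  if (max(latent_sequence) > spec$n_states || min(latent_sequence) < 1)
    stop_gpcrmsm("validation", "latent state without an emission row")
  if (!is.null(seed)) set.seed(seed)
  n <- length(latent_sequence)
  p <- ncol(spec$emission_means)
  X <- spec$emission_means[latent_sequence, , drop = FALSE] +
    matrix(rnorm(n * p), n, p) * spec$emission_sds[latent_sequence, , drop = FALSE]
  colnames(X) <- colnames(spec$emission_means)
  for (cp in spec$coupling %||% list()) {
    f1 <- cp$f1; f2 <- cp$f2; prob <- cp$prob
    thr1 <- mean(range(spec$emission_means[, f1]))
    thr2 <- mean(range(spec$emission_means[, f2]))
    force_on <- runif(n) < prob
    mismatch <- (X[, f1] > thr1) != (X[, f2] > thr2)
    flip <- force_on & mismatch
    X[flip, f2] <- 2 * thr2 - X[flip, f2]   # reflect across the threshold
  }
  class(X) <- c("feature_matrix", class(X))
  X
}

toy_residue_atoms <- function(n_residues, seed) {
  # 2..5 side-chain pseudo-atoms per residue plus CA, assigned reproducibly
  set.seed(seed)
  sample(3:6, n_residues, replace = TRUE)
}

#' Build a pseudo-atomic inactive/active receptor pair
#'
#' Residues are laid out as a two-strand hairpin so that sequence-distant
#' residues face each other across the strands and form contacts. Each
#' residue carries a CA atom plus several side-chain pseudo-atoms, two of
#' which point toward the facing strand. In the active structure each
#' perturbed residue is rigidly displaced out of the contact plane, breaking
#' its cross-strand contacts; all other residues are identical between the
#' two structures. A manifest records every residue pair (sequence
#' separation > 4) whose contact score changes by more than `margin`.
#'
#' @param n_residues number of residues (>= 10).
#' @param perturbed_residues integer residue indices displaced in the active
#'   structure (may be empty).
#' @param seed integer seed controlling side-chain placement.
#' @param margin contact-score change recorded in the manifest (default 3).
#' @return list of class `toy_receptor_pair` with elements
#'   `inactive`, `active` (atoms x 3 coordinate matrices), `topology`
#'   (a `residue_topology`), `perturbed_residues` and `manifest`
#'   (data.frame res_i, res_j, delta).
#' @export
build_toy_receptor_pair <- function(n_residues, perturbed_residues = integer(),
                                    seed = 1, margin = 3.0) {
  if (n_residues < 10) stop_gpcrmsm("validation", "need at least 10 residues")
  perturbed_residues <- as.integer(perturbed_residues)
  if (length(perturbed_residues) &&
      (min(perturbed_residues) < 1 || max(perturbed_residues) > n_residues))
    stop_gpcrmsm("validation", "perturbed residue index out of range")

  half <- ceiling(n_residues / 2)
  spacing <- 3.8; strand_gap <- 5.5; reach <- 1.4
  n_side <- toy_residue_atoms(n_residues, seed)

  atom_name <- character(0); atom_res <- integer(0)
  coords <- matrix(0, 0, 3)
  for (r in seq_len(n_residues)) {
    on_a <- r <= half
    ca <- if (on_a) c(spacing * (r - 1), 0, 0)
          else c(spacing * (n_residues - r), strand_gap, 0)
    dir_y <- if (on_a) +1 else -1
    # two contact atoms reaching toward the facing strand
    side <- rbind(
      ca + c(+0.35, dir_y * reach, +0.3),
      ca + c(-0.35, dir_y * reach, -0.3)
    )
    extra <- n_side[r] - 3
    if (extra > 0) {
      jitter <- matrix(runif(extra * 3, -0.9, 0.9), extra, 3)
      jitter[, 2] <- jitter[, 2] - dir_y * 0.6  # point away from the interface
      side <- rbind(side, sweep(jitter, 2, ca, `+`))
    }
    res_xyz <- unname(rbind(ca, side))
    coords <- rbind(coords, res_xyz)
    atom_name <- c(atom_name, c("CA", paste0("S", seq_len(nrow(res_xyz) - 1))))
    atom_res <- c(atom_res, rep(r, nrow(res_xyz)))
  }

  topology <- residue_topology(
    atoms = data.frame(
      index = seq_along(atom_res), name = atom_name,
      element = "C", resno = atom_res,
      resid = "ALA", stringsAsFactors = FALSE
    )
  )

  inactive <- coords
  active <- coords
  for (p in perturbed_residues) {
    idx <- which(atom_res == p)
    active[idx, 3] <- active[idx, 3] + 4.0
  }
  # clash check: displaced atoms must not land on unmoved ones
  if (length(perturbed_residues)) {
    moved <- atom_res %in% perturbed_residues
    if (any(moved) && any(!moved)) {
      d2 <- outer(rowSums(active[moved, , drop = FALSE]^2),
                  rowSums(active[!moved, , drop = FALSE]^2), `+`) -
        2 * active[moved, , drop = FALSE] %*% t(active[!moved, , drop = FALSE])
      if (min(d2) < 0.25)
        stop_gpcrmsm("validation", "perturbation produced an atomic clash (< 0.5 A)")
    }
  }

  manifest <- data.frame(res_i = integer(), res_j = integer(), delta = numeric())
  if (length(perturbed_residues)) {
    r_in <- compute_rrcs(inactive, topology)
    r_ac <- compute_rrcs(active, topology)
    delta <- abs(r_ac - r_in)
    hit <- which(delta > margin & upper.tri(delta), arr.ind = TRUE)
    if (nrow(hit)) {
      manifest <- data.frame(res_i = hit[, 1], res_j = hit[, 2],
                             delta = delta[hit])
      manifest <- manifest[order(-manifest$delta), , drop = FALSE]
      rownames(manifest) <- NULL
    }
  }

  structure(list(
    inactive = inactive, active = active, topology = topology,
    perturbed_residues = perturbed_residues, margin = margin,
    manifest = manifest
  ), class = "toy_receptor_pair")
}

#' Emit pseudo-atomic coordinates from a latent state sequence
#'
#' Frame coordinates are the linear interpolation between the inactive
#' (weight 0) and active (weight 1) reference structures at the emitting
#' state's interpolation weight, plus isotropic Gaussian noise. By default
#' the latent states map to evenly spaced weights in \code{[0, 1]}, so each
#' state has a distinct contact-distance distribution.
#'
#' @param latent_sequence integer vector of 1-based latent states.
#' @param pair a [build_toy_receptor_pair()] result.
#' @param noise_scale isotropic coordinate noise SD in Angstrom.
#' @param seed integer seed.
#' @param weights per-state interpolation weights in `[0,1]`; default evenly
#'   spaced over the observed number of states.
#' @param n_states total latent state count (default `max(latent_sequence)`).
#' @param interval_ns time between frames in ns (default 25).
#' @return an `ensemble_frames` object (frames x 3N coordinate matrix plus
#'   topology and frame interval).
#' @export
emit_coordinates <- function(latent_sequence, pair, noise_scale = 0.1,
                             seed = NULL, weights = NULL,
                             n_states = max(latent_sequence),
                             interval_ns = 25) {
  stopifnot(inherits(pair, "toy_receptor_pair"))
  if (is.null(weights)) {
    weights <- if (n_states == 1) 0 else seq(0, 1, length.out = n_states)
  }
  if (any(weights < 0 | weights > 1))
    stop_gpcrmsm("validation", "interpolation weights must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  inact <- coords_to_row(pair$inactive)
  act <- coords_to_row(pair$active)
  w <- weights[latent_sequence]
  xyz <- outer(1 - w, inact) + outer(w, act)
  if (noise_scale > 0)
    xyz <- xyz + matrix(rnorm(length(xyz), sd = noise_scale),
                        nrow(xyz), ncol(xyz))
  ensemble_frames(xyz, pair$topology, interval_ns = interval_ns)
}

#' Write a ground-truth manifest as JSON
#'
#' Records the latent truth (transition matrix, state sequence summaries,
#' manifest of planted contact changes) so downstream recovery can be scored.
#'
#' @param spec a [ground_truth_spec()].
#' @param latent_sequences list of latent state sequences.
#' @param file output path.
#' @param pair optional [build_toy_receptor_pair()] whose manifest to embed.
#' @return `file`, invisibly.
#' @export
write_ground_truth <- function(spec, latent_sequences, file, pair = NULL) {
  obj <- list(
    n_states = spec$n_states,
    transition_matrix = spec$transition_matrix,
    lag_ns = spec$lag_ns,
    stationary = stationary_distribution(spec$transition_matrix),
    n_trajectories = length(latent_sequences),
    trajectory_lengths = vapply(latent_sequences, length, integer(1))
  )
  if (!is.null(pair)) obj$contact_manifest <- pair$manifest
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
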