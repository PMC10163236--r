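test_that("feature-shift metrics vanish on identical ensembles and match direct means", {
  set.seed(60)
  X <- matrix(runif(3000), ncol = 3)
  out0 <- feature_shift_metrics(X, X, X)
  expect_true(all(out0$mean_shift == 0))
  expect_true(all(out0$kl_active < 1e-6))
  expect_true(all(out0$kl_inactive < 1e-6))

  # pooled range [0, 1]: means 0.5 (apo), 0.8 (active), 0.3 (inactive)
  apo <- matrix(runif(20000, 0, 1), ncol = 1)
  act <- matrix(runif(20000, 0.6, 1), ncol = 1)
  ina <- matrix(runif(20000, 0, 0.6), ncol = 1)
  out <- feature_shift_metrics(apo, act, ina)
  expect_equal(out$mean_shift, 0.5, tolerance = 0.02)
  expect_error(feature_shift_metrics(apo[0, , drop = FALSE], act, ina),
               "empty")
})

test_that("conditional coupling is exact on a probability table and bounded by independence", {
  # joint table as weighted frames: P(jA) = 0.5, P(iA|jA) = 0.9, P(iA|jI) = 0.4
  X <- rbind(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1))
  w <- c(0.45, 0.05, 0.20, 0.30)
  M <- conditional_coupling(X, thresholds = c(0, 0), frame_weights = w)
  expect_equal(unname(M[1, 2]), 0.5, tolerance = 1e-12)
  expect_equal(unname(diag(M)), c(1, 1))

  set.seed(61)
  n <- 1e4
  ind <- cbind(rnorm(n), rnorm(n))
  Mi <- conditional_coupling(ind, thresholds = c(0, 0))
  expect_lt(Mi[1, 2], 0.05)

  same <- cbind(a = rnorm(n), b = 0)
  same[, 2] <- same[, 1]
  Ms <- conditional_coupling(same, thresholds = c(0, 0))
  expect_equal(unname(Ms[1, 2]), 1)

  # one-sided conditioning feature -> undefined, not zero
  X1 <- cbind(rnorm(n), abs(rnorm(n)) + 1)
  Mu <- conditional_coupling(X1, thresholds = c(0, 0))
  expect_true(is.na(Mu[1, 2]))
})

test_that("coupling under MSM weights matches the kMC-resampled estimate", {
  # 2-state latent chain; features binarize along the latent state
  T <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  spec <- ground_truth_spec(T, emission_means = cbind(f1 = c(-1, 1),
                                                      f2 = c(-1, 1)),
                            emission_sds = 0.4)
  trajs <- simulate_batch(T, 10, 2000, seed = 2100)
  feats <- lapply(seq_along(trajs), function(i)
    emit_features(trajs[[i]], spec, seed = 2150 + i))
  msm <- estimate_msm(count_transitions(trajs, 1), lag = 1)
  w <- frame_weights(msm, trajs)
  M_w <- conditional_coupling(do.call(rbind, feats), thresholds = c(0, 0),
                              frame_weights = unlist(w))
  # kMC equilibrium resample of the same emission model
  kmc <- kmc_simulate(msm, 1, 2e4, seed = 5)
  feats_kmc <- emit_features(kmc, spec, seed = 6)
  M_k <- conditional_coupling(feats_kmc, thresholds = c(0, 0))
  expect_lt(abs(M_w[1, 2] - M_k[1, 2]), 0.05)
})

test_that("residue KL profile localises planted perturbations and is symmetric", {
  pair <- build_toy_receptor_pair(20, perturbed_residues = c(3, 5, 8),
                                  seed = 42)
  fr_a <- emit_coordinates(rep(1L, 500), pair, noise_scale = 0.3, seed = 1,
                           n_states = 2)
  fr_b <- emit_coordinates(rep(2L, 500), pair, noise_scale = 0.3, seed = 2,
                           n_states = 2)
  prof <- residue_kl_profile(fr_a, fr_b)
  top3 <- prof$resno[order(-prof$kl)][1:3]
  expect_setequal(top3, c(3, 5, 8))

  prof_rev <- residue_kl_profile(fr_b, fr_a)
  expect_equal(prof$kl, prof_rev$kl)

  # null: one state against its own disjoint halves stays below noise floor
  fr_null <- emit_coordinates(rep(1L, 1000), pair, noise_scale = 0.3,
                              seed = 3, n_states = 2)
  half1 <- ensemble_frames(fr_null$xyz[1:500, ], pair$topology)
  half2 <- ensemble_frames(fr_null$xyz[501:1000, ], pair$topology)
  prof0 <- residue_kl_profile(half1, half2)
  expect_lt(max(prof0$kl), 0.05)
  expect_error(residue_kl_profile(half1, ensemble_frames(
    fr_null$xyz[1, , drop = FALSE], pair$topology)), "2 frames")
})

test_that("mutual information matches a direct entropy-summation oracle", {
  set.seed(62)
  n <- 1e4
  ind <- cbind(a = runif(n, -180, 180), b = runif(n, -180, 180))
  Mi <- mutual_information_matrix(ind)
  expect_lt(Mi[1, 2], 0.05)
  expect_equal(unname(Mi[1, 1]), 1)

  dup <- cbind(a = ind[, 1], b = ind[, 1])
  expect_gt(mutual_information_matrix(dup)[1, 2], 0.99)

  # known discrete joint: values at bin centres, counts 30/10/5/55
  bins <- 30
  centers <- seq(-180, 180, length.out = bins + 1)
  mid <- (centers[-1] + centers[-(bins + 1)]) / 2
  va <- c(mid[5], mid[5], mid[20], mid[20])
  vb <- c(mid[8], mid[25], mid[8], mid[25])
  counts <- c(30, 10, 5, 55)
  X <- cbind(a = rep(va, counts), b = rep(vb, counts))
  got <- mutual_information_matrix(X, bins = bins)[1, 2]
  # oracle: H(a) + H(b) - H(a,b) on the same pseudocounted histograms
  pseudo <- 1e-10
  pa <- tabulate(findInterval(X[, 1], centers, rightmost.closed = TRUE),
                 nbins = bins) + pseudo
  pb <- tabulate(findInterval(X[, 2], centers, rightmost.closed = TRUE),
                 nbins = bins) + pseudo
  pa <- pa / sum(pa); pb <- pb / sum(pb)
  ia <- findInterval(X[, 1], centers, rightmost.closed = TRUE)
  ib <- findInterval(X[, 2], centers, rightmost.closed = TRUE)
  pj <- tabulate((ia - 1) * bins + ib, nbins = bins^2) + pseudo / bins
  pj <- pj / sum(pj)
  H <- function(p) -sum(p * log(p))
  want <- (H(pa) + H(pb) - H(pj)) / mean(c(H(pa), H(pb)))
  expect_equal(unname(got), want, tolerance = 1e-12)

  # constant dihedral -> undefined entries
  cst <- cbind(a = ind[, 1], b = rep(10, n))
  Mc <- mutual_information_matrix(cst)
  expect_true(is.na(Mc[1, 2]))

  # invariance to feature ordering
  M2 <- mutual_information_matrix(ind[, c(2, 1)])
  expect_equal(unname(M2[1, 2]), unname(Mi[1, 2]))
})

test_that("pathway search respects contact and endpoint-separation rules", {
  fr <- chain_structure(8, spacing = 4.0)
  set.seed(63)
  n <- 4000
  driver <- runif(n, -180, 180)
  D <- sapply(1:8, function(r) {
    v <- if (r <= 5) driver + rnorm(n, sd = 20) else runif(n, -180, 180)
    ((v + 180) %% 360) - 180
  })
  colnames(D) <- as.character(1:8)
  mi <- mutual_information_matrix(D)
  pw <- allosteric_pathways(mi, fr)
  # every reported path endpoint pair is >= 12 A apart (>= 3 residues here)
  for (p in pw$paths)
    expect_gte(abs(p[1] - p[length(p)]) * 4.0, 12)
  # chain graph: 15 qualifying pairs, fewer than top_n, none fabricated
  expect_lte(length(pw$paths), 15)
  # the top cluster's best path runs r1..r5 in order
  top <- top_cluster_path(pw)
  expect_true(all(diff(match(1:5, top)) > 0) || all(diff(match(5:1, top)) > 0))

  # 3 residues at spacing 4.5: farthest pair 9 A apart -> excluded, empty
  fr3 <- chain_structure(3, spacing = 4.5)
  mi3 <- mutual_information_matrix(D[, 1:3])
  rownames(mi3) <- colnames(mi3) <- as.character(1:3)
  expect_warning(pw3 <- allosteric_pathways(mi3, fr3), "separation")
  expect_length(pw3$paths, 0)

  # forced unique path on a linear chain
  fr4 <- chain_structure(4, spacing = 4.0)
  mi4 <- mutual_information_matrix(D[, 1:4])
  rownames(mi4) <- colnames(mi4) <- as.character(1:4)
  pw4 <- allosteric_pathways(mi4, fr4)
  expect_equal(pw4$paths[[1]], 1:4)
})
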