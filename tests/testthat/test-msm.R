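test_that("transition counting matches hand counts and is additive", {
  expect_equal(count_transitions(c(1, 1, 2, 2, 1), lag = 1),
               rbind(c(1, 1), c(1, 1)))
  expect_equal(count_transitions(c(1, 2, 1, 2), lag = 2),
               rbind(c(1, 0), c(0, 1)))
  a <- c(1, 2, 2, 1); b <- c(2, 2, 1, 1)
  expect_equal(count_transitions(list(a, b), lag = 1),
               count_transitions(a, 1) + count_transitions(b, 1))
  expect_error(count_transitions(c(1, 2), lag = 5), "shorter")
})

test_that("reversible estimation symmetrizes counts as stated", {
  m <- estimate_msm(rbind(c(9, 1), c(1, 9)))
  expect_equal(m$transition_matrix, rbind(c(0.9, 0.1), c(0.1, 0.9)))
  expect_equal(m$stationary, c(0.5, 0.5))

  # hand-computed: symmetrized [[8,1],[1,10]] -> rows /9 and /11
  m2 <- estimate_msm(rbind(c(8, 2), c(0, 10)))
  expect_equal(m2$transition_matrix,
               rbind(c(8 / 9, 1 / 9), c(1 / 11, 10 / 11)))

  # disconnected third state is trimmed from the active set
  C <- rbind(c(5, 1, 0), c(1, 5, 0), c(0, 0, 4))
  m3 <- estimate_msm(C)
  expect_equal(m3$active_set, c(1, 2))
  expect_equal(dim(m3$transition_matrix), c(2, 2))
})

test_that("reversible estimates satisfy detailed balance to 1e-10", {
  set.seed(50)
  for (i in 1:5) {
    C <- matrix(rpois(36, 20), 6, 6)
    m <- estimate_msm(C)
    T <- m$transition_matrix; pi_ <- m$stationary
    expect_lt(max(abs(pi_ * T - t(pi_ * T))), 1e-10)
    expect_lt(max(abs(rowSums(T) - 1)), 1e-10)
    expect_lt(max(abs(pi_ %*% T - pi_)), 1e-8)
  }
})

test_that("implied timescales recover the analytic relaxation time and lag-stability", {
  T <- rbind(c(0.9, 0.1), c(0.2, 0.8))   # lambda2 = 0.7
  trajs <- simulate_batch(T, 10, 5000, seed = 600)
  its <- implied_timescales(trajs, lags = c(1, 2, 4), n_timescales = 1)
  t_true <- -1 / log(0.7)
  t_hat <- its$timescale[its$lag == 1]
  expect_lt(abs(t_hat - t_true) / t_true, 0.1)
  # Markovian self-consistency across a doubled lag
  expect_lt(abs(its$timescale[its$lag == 2] - t_hat) / t_hat, 0.15)

  # identity chain: single absorbing state, no finite relaxation timescale
  its0 <- implied_timescales(list(rep(1L, 100), rep(2L, 100)), lags = 1)
  expect_true(nrow(its0) == 0 || all(is.na(its0$timescale)))
})

test_that("VAMP-2 scoring reproduces the eigenvalue sum and its limits", {
  T <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  trajs <- simulate_batch(T, 10, 5000, seed = 700)
  msm <- estimate_msm(count_transitions(trajs, 1), lag = 1)
  v <- vamp2_score(trajs, trajs, lag = 1, k = 2)
  expect_equal(v, sum(msm$eigenvalues[1:2]^2), tolerance = 1e-8)
  expect_lt(abs(v - (1 + 0.7^2)), 0.05)

  expect_equal(vamp2_score(trajs, trajs, lag = 1, k = 1), 1.0,
               tolerance = 1e-10)

  set.seed(51)
  iid <- lapply(1:5, function(i) sample(1:2, 2000, replace = TRUE))
  expect_lt(vamp2_score(iid, iid, lag = 1, k = 2) - 1, 0.02)
})

test_that("hyperparameter scan returns the grid argmax with sensible tie-breaks", {
  spec <- six_state_spec(inter = 0.01)
  trajs <- simulate_batch(spec$transition_matrix, 10, 1000, seed = 800)
  feats <- lapply(seq_along(trajs), function(i)
    emit_features(trajs[[i]], spec, seed = 850 + i))

  single <- hyperparameter_scan(feats, lag = 5, n_tics_grid = 2,
                                n_clusters_grid = 8, folds = 5, seed = 1,
                                n_eigen = 3)
  expect_equal(single$best$n_clusters, 8)
  expect_equal(nrow(single$table), 1)

  scan <- hyperparameter_scan(feats, lag = 5, n_tics_grid = 2,
                              n_clusters_grid = c(6, 20), folds = 5, seed = 1,
                              n_eigen = 3)
  expect_equal(nrow(scan$table), 2)
  # finer discretization cannot lose by more than CV noise
  s6 <- scan$table$mean_score[scan$table$n_clusters == 6]
  s20 <- scan$table$mean_score[scan$table$n_clusters == 20]
  expect_gt(s20, s6 - 2 * max(scan$table$sd_score))
})

test_that("frame weights redistribute stationary mass over observed frames", {
  # uniform case
  m <- estimate_msm(rbind(c(9, 1), c(1, 9)))
  w <- frame_weights(m, list(rep(1L, 50), rep(2L, 50)))
  expect_equal(unique(unlist(w)), 0.5 / 50)
  expect_equal(sum(unlist(w)), 1)

  # pi = (2/3, 1/3) with 100 frames per state -> 1/150 and 1/300
  T <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  m2 <- msm_from_matrix(T, scale = 300)
  d <- list(rep(1L, 100), rep(2L, 100))
  w2 <- frame_weights(m2, d)
  expect_equal(w2[[1]][1], 1 / 150, tolerance = 1e-10)
  expect_equal(w2[[2]][1], 1 / 300, tolerance = 1e-10)

  # trimmed states carry zero weight
  C <- rbind(c(5, 1, 0), c(1, 5, 0), c(0, 0, 4))
  m3 <- estimate_msm(C)
  expect_warning(w3 <- frame_weights(m3, list(c(1L, 2L, 3L, 3L))), "weight 0")
  expect_equal(w3[[1]][3:4], c(0, 0))
})

test_that("default physical lag of the MSM builder is 25 ns", {
  expect_equal(formals(build_msm)$lag_ns, 25)
  T <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  trajs <- simulate_batch(T, 5, 500, seed = 77)
  m <- build_msm(trajs, interval_ns = 5)   # 25 ns / 5 ns -> lag 5 frames
  expect_equal(m$lag, 5)
  expect_equal(m$lag_ns, 25)
})

test_that("full synthetic pipeline recovers the slowest implied timescale", {
  spec <- six_state_spec(inter = 0.01)
  lam <- sort(abs(eigen(spec$transition_matrix)$values), decreasing = TRUE)
  t_true <- -1 / log(lam[2])
  rel_err <- vapply(1:3, function(s) {
    trajs <- simulate_batch(spec$transition_matrix, 20, 2000, seed = 1000 * s)
    feats <- lapply(seq_along(trajs), function(i)
      emit_features(trajs[[i]], spec, seed = 1000 * s + i))
    tic <- fit_tica(feats, lag = 5, n_components = 2)
    km <- fit_kmeans(project_tica(tic, feats), k = 30, seed = s)
    msm <- estimate_msm(count_transitions(km$dtrajs, 5), lag = 5)
    abs(msm$timescales[1] - t_true) / t_true
  }, numeric(1))
  expect_true(all(rel_err < 0.15))
})
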