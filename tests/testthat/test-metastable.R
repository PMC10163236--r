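block_chain_msm <- function(inter = 1e-3, intra = 0.1) {
  # 4 microstates in two nearly disconnected blocks
  T <- rbind(c(1 - intra - inter, intra, inter, 0),
             c(intra, 1 - intra - inter, 0, inter),
             c(inter, 0, 1 - intra - inter, intra),
             c(0, inter, intra, 1 - intra - inter))
  msm_from_matrix(T)
}

test_that("coarse graining resolves near-disconnected blocks crisply", {
  msm <- block_chain_msm()
  meta <- coarse_grain(msm, 2)
  expect_equal(dim(meta$memberships), c(4, 2))
  expect_true(all(abs(rowSums(meta$memberships) - 1) < 1e-8))
  expect_true(all(apply(meta$memberships, 1, max) > 0.99))
  # blocks {1,2} and {3,4} end up in different metastable states
  expect_equal(meta$crisp[1], meta$crisp[2])
  expect_equal(meta$crisp[3], meta$crisp[4])
  expect_true(meta$crisp[1] != meta$crisp[3])
  expect_equal(sum(meta$populations), 1)
})

test_that("coarse graining at the full active-set size is identity-like", {
  msm <- block_chain_msm(inter = 0.02)
  meta <- coarse_grain(msm, 4)
  expect_equal(sort(meta$crisp), 1:4)
  expect_true(all(apply(meta$memberships, 1, max) > 0.95))
  for (m in 2:4) {
    expect_equal(sum(coarse_grain(msm, m)$populations), 1, tolerance = 1e-10)
  }
})

test_that("state-count selection enforces the minimum-population rule", {
  # microstate 4 is a tiny appendix: any split isolating it dips below 4%
  T <- rbind(c(0.94, 0.03, 0.02, 0.01),
             c(0.03, 0.94, 0.03, 0.00),
             c(0.02, 0.03, 0.95, 0.00),
             c(0.50, 0.00, 0.00, 0.50))
  pi_ <- stationary_distribution(T)
  expect_lt(pi_[4], 0.04)
  trajs <- simulate_batch(T, 10, 3000, seed = 300)
  msm <- estimate_msm(count_transitions(trajs, 1), lag = 1)
  sel <- expect_warning(
    select_state_count(msm, trajs, candidates = 2:4, n_boot = 5, seed = 2),
    regexp = NA)
  # at least one candidate isolates the appendix and is discarded
  expect_true(any(sel$report$discarded))
  expect_false(sel$report$discarded[sel$report$candidate == sel$m])

  # disabling the filter keeps every candidate alive
  sel0 <- select_state_count(msm, trajs, candidates = 2:4,
                             min_population = 0, n_boot = 5, seed = 2)
  expect_false(any(sel0$report$discarded))

  # determinism under a fixed seed
  sel_b <- select_state_count(msm, trajs, candidates = 2:4, n_boot = 5, seed = 2)
  expect_identical(sel$report, sel_b$report)
})

test_that("per-state frame sampling is crisp, proportional and deterministic", {
  msm <- block_chain_msm()
  meta <- coarse_grain(msm, 2)
  trajs <- simulate_batch(msm$transition_matrix, 8, 1500, seed = 400)
  fr <- sample_state_frames(meta, trajs, n_per_state = 500, seed = 9)
  expect_length(fr, 2)
  sets <- metastable_sets(meta)
  for (s in 1:2) {
    micro <- vapply(seq_len(nrow(fr[[s]])), function(i)
      trajs[[fr[[s]]$traj[i]]][fr[[s]]$frame[i]], integer(1))
    expect_true(all(micro %in% sets[[s]]))
  }
  fr2 <- sample_state_frames(meta, trajs, n_per_state = 500, seed = 9)
  expect_identical(fr, fr2)

  # microstate draw frequencies follow pi * chi within the state
  micro1 <- vapply(seq_len(nrow(fr[[1]])), function(i)
    trajs[[fr[[1]]$traj[i]]][fr[[1]]$frame[i]], integer(1))
  w <- msm$stationary * meta$memberships[, 1]
  w <- w[sets[[1]]] / sum(w[sets[[1]]])
  freq <- tabulate(match(micro1, sets[[1]]), length(sets[[1]])) / length(micro1)
  expect_lt(max(abs(freq - w)), 0.08)
})

test_that("full pipeline recovers the latent six metastable states", {
  spec <- six_state_spec(inter = 0.01)
  trajs <- simulate_batch(spec$transition_matrix, 20, 2000, seed = 1500)
  feats <- lapply(seq_along(trajs), function(i)
    emit_features(trajs[[i]], spec, seed = 1550 + i))
  tic <- fit_tica(feats, lag = 5, n_components = 2)
  km <- fit_kmeans(project_tica(tic, feats), k = 40, seed = 4)
  msm <- estimate_msm(count_transitions(km$dtrajs, 5), lag = 5)
  meta <- coarse_grain(msm, 6)
  assigned <- unlist(assign_frames(meta, km$dtrajs))
  latent <- unlist(trajs)
  ok <- !is.na(assigned)
  # label-permutation-invariant agreement: best match per latent state
  tab <- table(latent[ok], assigned[ok])
  agreement <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gt(agreement, 0.95)
  # populations consistent with empirical crisp frequencies
  emp <- tabulate(assigned[ok], 6) / sum(ok)
  perm <- apply(tab, 1, which.max)
  expect_lt(max(abs(sort(meta$populations) - sort(emp))), 0.05)
})
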