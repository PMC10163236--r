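# helper: two single-carbon residues with sequence separation > 4 at a
# chosen distance, plus two spectator residues keeping the topology sane
two_residue_frame <- function(d) {
  topo <- residue_topology(data.frame(
    index = 1:4, name = "CA", element = "C",
    resno = c(1, 6, 20, 30), resid = "ALA", stringsAsFactors = FALSE))
  coords <- rbind(c(0, 0, 0), c(d, 0, 0), c(100, 0, 0), c(200, 0, 0))
  list(coords = coords, topo = topo)
}

test_that("contact kernel hits its piecewise boundaries and separation rule", {
  f <- two_residue_frame(3.23)
  expect_equal(compute_rrcs(f$coords, f$topo)["1", "6"], 1.0)

  f <- two_residue_frame(4.63)
  expect_equal(compute_rrcs(f$coords, f$topo)["1", "6"], 0.0)

  f <- two_residue_frame(3.93)  # midpoint: (4.63 - 3.93) / 1.40 = 0.5
  expect_equal(compute_rrcs(f$coords, f$topo)["1", "6"], 0.5)

  # residues i and i+2 are never scored, however close
  topo <- residue_topology(data.frame(
    index = 1:3, name = "CA", element = "C",
    resno = c(1, 3, 20), resid = "ALA", stringsAsFactors = FALSE))
  r <- compute_rrcs(rbind(c(0, 0, 0), c(1, 0, 0), c(50, 0, 0)), topo)
  expect_equal(r["1", "3"], 0.0)
})

test_that("RRCS matrices are symmetric and non-negative on random coordinates", {
  set.seed(20)
  topo <- residue_topology(data.frame(
    index = 1:30, name = "CA", element = "C",
    resno = rep(1:10, each = 3), resid = "ALA", stringsAsFactors = FALSE))
  for (rep_i in 1:3) {
    crd <- matrix(runif(90, 0, 15), 30, 3)
    r <- compute_rrcs(crd, topo)
    expect_true(isSymmetric(unclass(r)))
    expect_true(all(r >= 0))
  }
})

test_that("feature selection applies the strict contact-change threshold", {
  # residues 1 and 10: three atom pairs in full contact in "active" only
  topo <- residue_topology(data.frame(
    index = 1:6, name = c("C1", "C2", "C3", "C1", "C2", "C3"),
    element = "C", resno = c(1, 1, 1, 10, 10, 10), resid = "ALA",
    stringsAsFactors = FALSE))
  near <- rbind(c(0, 0, 0), c(0, 2, 0), c(0, 4, 0),
                c(2, 0, 0), c(2, 2, 0), c(2, 4, 0))
  far <- near; far[4:6, 1] <- 50
  # delta exactly 3.0 (three pairs at 2.0 A contribute 1 each; the
  # vertical neighbours sit at sqrt(4+4)=2.83 < 3.23 too -> recompute:
  delta <- compute_rrcs(near, topo)["1", "10"] - compute_rrcs(far, topo)["1", "10"]
  sel <- select_rrcs_features(near, far, topo, threshold = delta)
  expect_equal(nrow(sel), 0)  # strict inequality: change == threshold excluded
  sel2 <- select_rrcs_features(near, far, topo, threshold = delta - 0.5)
  expect_equal(sel2$res_i, 1)
  expect_equal(sel2$res_j, 10)
  expect_identical(sel2$kind, "ca_distance")

  expect_equal(nrow(select_rrcs_features(near, near, topo)), 0)
})

test_that("feature selection recovers exactly the planted toy-receptor manifest", {
  pair <- build_toy_receptor_pair(24, perturbed_residues = c(4, 7), seed = 31)
  sel <- select_rrcs_features(pair$active, pair$inactive, pair$topology,
                              threshold = 3.0)
  got <- sort(paste(sel$res_i, sel$res_j))
  want <- sort(paste(pair$manifest$res_i, pair$manifest$res_j))
  expect_identical(got, want)
})

test_that("named features evaluate with textbook geometry", {
  topo <- residue_topology(data.frame(
    index = 1:6,
    name = c("CA", "CB", "CG", "CD1", "CA", "SG"),
    element = c("C", "C", "C", "C", "C", "S"),
    resno = c(1, 1, 1, 1, 2, 2), resid = c(rep("TRP", 4), "CYS", "CYS"),
    stringsAsFactors = FALSE),
    labels = c("6.48" = 1))
  # cis (eclipsed) quadruple -> dihedral 0; CA pair on a 3-4-5 triangle
  coords <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                  c(3, 5, 0), c(3, 5, 2))
  fr <- ensemble_frames(matrix(t(coords), 1), topo)
  defs <- rbind(
    feature_definition("ca_distance", 1, 2),
    feature_definition("dihedral_chi2", "6.48"),
    feature_definition("zcom_difference", 1, 2),
    feature_definition("min_heavy_distance", 1, 2))
  X <- evaluate_features(fr, defs)
  expect_equal(unname(X[1, 1]), 5.0)
  expect_equal(unname(X[1, 2]), 0.0)
  # residue 1 side-chain z-COM = 0, residue 2 side chain (SG) z = 2
  expect_equal(unname(X[1, 3]), -2.0)
  expect_equal(unname(X[1, 4]), sqrt(sum((c(1, 1, 0) - c(3, 5, 0))^2)))

  expect_error(evaluate_features(fr, feature_definition("ca_distance", "3.50", 2)),
               "not present")
})

test_that("pocket volume matches closed-form sphere arithmetic and is monotone", {
  topo <- residue_topology(data.frame(
    index = 1:2, name = c("CA", "CA"), element = c("C", "C"),
    resno = 1:2, resid = "ALA", stringsAsFactors = FALSE))
  # atom 2 far away: empty 5 A sphere centred on residue 1
  crd <- rbind(c(0, 0, 0), c(100, 0, 0))
  v_almost_empty <- pocket_volume(crd, topo, center_residues = 1,
                                  inclusion_radius = 5, voxel = 0.5)
  # centre atom excludes a 3.1 A sphere: V = 4/3 pi (5^3 - 3.1^3)
  v_expect <- 4 / 3 * pi * (125 - 3.1^3)
  expect_lt(abs(v_almost_empty - v_expect) / v_expect, 0.05)

  # empty-sphere limit: centre atoms removed by centring between residues
  crd2 <- rbind(c(-20, 0, 0), c(20, 0, 0))  # centre at origin, atoms far
  v_empty <- pocket_volume(crd2, topo, center_residues = c(1, 2),
                           inclusion_radius = 5, voxel = 0.5)
  expect_lt(abs(v_empty - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.05)

  # monotone non-increasing as atoms are added inside the sphere
  topo3 <- residue_topology(data.frame(
    index = 1:3, name = c("CA", "CA", "CB"), element = "C",
    resno = c(1, 2, 2), resid = "ALA", stringsAsFactors = FALSE))
  crd3 <- rbind(c(-20, 0, 0), c(20, 0, 0), c(1, 1, 0))
  v_one <- pocket_volume(crd3, topo3, center_residues = c(1, 2),
                         inclusion_radius = 5, voxel = 0.5)
  expect_lte(v_one, v_empty)
  expect_error(pocket_volume(crd2, topo, integer(), 5), "nonempty")
})

test_that("RMSD is zero under rigid rotation and tracks pure translation", {
  set.seed(8)
  topo <- residue_topology(data.frame(
    index = 1:10, name = "CA", element = "C", resno = 1:10, resid = "ALA",
    stringsAsFactors = FALSE))
  ref <- matrix(rnorm(30, sd = 4), 10, 3)
  expect_equal(rmsd_frames(matrix(as.numeric(t(ref)), 1), ref), 0)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- ref %*% t(R)
  expect_lt(rmsd_frames(matrix(as.numeric(t(rot)), 1), ref), 1e-6)
  shift <- sweep(ref, 2, c(1, 0, 0), `+`)
  expect_equal(rmsd_frames(matrix(as.numeric(t(shift)), 1), ref, fit = FALSE),
               1.0)
})

test_that("ensembles survive a multi-model PDB round trip", {
  pair <- build_toy_receptor_pair(12, perturbed_residues = 4, seed = 13)
  fr <- emit_coordinates(c(1L, 2L, 1L), pair, noise_scale = 0.05, seed = 1,
                         n_states = 2)
  f <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(fr, f)
  back <- load_ensemble(f)
  expect_equal(nrow(back$xyz), 3)
  expect_equal(back$xyz, fr$xyz, tolerance = 1e-3)
  expect_equal(back$topology$atoms$resno, fr$topology$atoms$resno)

  # 3-atom single-frame parse check against literal file values
  tiny <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.000   5.000   6.000  1.00  0.00           C",
    "END"), tiny)
  ens <- load_ensemble(tiny)
  expect_equal(nrow(ens$xyz), 1)
  expect_equal(as.numeric(ens$xyz[1, 1:3]), c(1, 2, 3))
  expect_equal(nrow(ens$topology$atoms), 3)

  # atom-count mismatch between structure and trajectory errors out
  expect_error(load_ensemble(tiny, trajectory_files = f), "atoms")
})
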