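# Structure I/O and featurization: residue-residue contact scores (RRCS),
# contact-change feature selection, named activation features (distances,
# chi2 dihedral, toggle-switch z-displacement), a grid-based binding-pocket
# volume, and RMSD plumbing.

#' Residue topology
#'
#' Ordered residues with their heavy-atom names and indices. Hydrogens are
#' retained in the atom table but flagged, and ignored by all scoring.
#'
#' @param atoms data.frame with columns `index`, `name`, `element`, `resno`,
#'   `resid`.
#' @param labels optional named character vector mapping generic-number
#'   labels (e.g. "3.50", "6.48", "N-term") to residue numbers.
#' @return object of class `residue_topology`.
#' @export
residue_topology <- function(atoms, labels = NULL) {
  stopifnot(all(c("index", "name", "element", "resno", "resid") %in% names(atoms)))
  if (anyDuplicated(atoms$index))
    stop_gpcrmsm("validation", "atom indices must be unique")
  if (!is.null(labels)) {
    if (anyDuplicated(names(labels)))
      stop_gpcrmsm("validation", "each generic-number label must map to one residue")
    labels <- vapply(labels, as.integer, integer(1))
  }
  residues <- unique(atoms[, c("resno", "resid")])
  residues <- residues[order(residues$resno), , drop = FALSE]
  rownames(residues) <- NULL
  structure(list(
    atoms = atoms,
    residues = residues,
    heavy = toupper(atoms$element) != "H",
    labels = labels
  ), class = "residue_topology")
}

#' @export
print.residue_topology <- function(x, ...) {
  cat(sprintf("residue_topology: %d residues, %d atoms (%d heavy)\n",
              nrow(x$residues), nrow(x$atoms), sum(x$heavy)))
  invisible(x)
}

resolve_label <- function(topology, res) {
  if (is.character(res)) {
    if (!is.null(topology$labels) && res %in% names(topology$labels))
      return(unname(topology$labels[[res]]))
    if (!grepl("^-?[0-9]+$", res))
      stop_gpcrmsm("lookup", "generic number '%s' not present in topology", res)
    return(as.integer(res))
  }
  as.integer(res)
}

topology_from_pdb <- function(pdb) {
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  residue_topology(data.frame(
    index = seq_len(nrow(at)),
    name = at$elety,
    element = ifelse(is.na(elem) | elem == "",
                     substr(gsub("[0-9]", "", at$elety), 1, 1), elem),
    resno = at$resno,
    resid = at$resid,
    stringsAsFactors = FALSE
  ))
}

#' Ensemble frame set
#'
#' Per-frame coordinates (frames x 3N, Angstrom, bio3d xyz layout) plus the
#' residue topology and the time interval between frames.
#'
#' @param xyz numeric matrix, one row per frame, 3 columns per atom.
#' @param topology a [residue_topology()].
#' @param interval_ns time between successive frames, nanoseconds.
#' @return object of class `ensemble_frames`.
#' @export
ensemble_frames <- function(xyz, topology, interval_ns = 25) {
  xyz <- rbind(xyz)
  if (ncol(xyz) != 3 * nrow(topology$atoms))
    stop_gpcrmsm("format", "coordinate width (%d) does not match topology (%d atoms)",
                 ncol(xyz), nrow(topology$atoms))
  structure(list(xyz = xyz, topology = topology, interval_ns = interval_ns),
            class = "ensemble_frames")
}

#' @export
print.ensemble_frames <- function(x, ...) {
  cat(sprintf("ensemble_frames: %d frames x %d atoms, %.3g ns/frame\n",
              nrow(x$xyz), ncol(x$xyz) / 3, x$interval_ns))
  invisible(x)
}

#' Load a structure and optional trajectories
#'
#' Reads a PDB structure (single- or multi-model) and optional trajectory
#' files (DCD, or further multi-model PDB files) into an ensemble.
#'
#' @param structure_file PDB file path.
#' @param trajectory_files optional character vector of DCD or multi-model
#'   PDB trajectory files whose atom count must match the structure.
#' @param interval_ns time between frames in ns.
#' @return an [ensemble_frames()] object. When trajectory files are given the
#'   structure provides topology only and frames come from the trajectories.
#' @export
load_ensemble <- function(structure_file, trajectory_files = NULL,
                          interval_ns = 25) {
  pdb <- tryCatch(bio3d::read.pdb(structure_file, multi = TRUE, verbose = FALSE),
                  error = function(e) stop_gpcrmsm("io", "cannot read PDB '%s': %s",
                                                   structure_file, conditionMessage(e)))
  topology <- topology_from_pdb(pdb)
  n3 <- 3 * nrow(topology$atoms)
  if (is.null(trajectory_files)) {
    xyz <- rbind(pdb$xyz)
    if (ncol(xyz) != n3)
      stop_gpcrmsm("format", "PDB coordinate count does not match its atom records")
    return(ensemble_frames(xyz, topology, interval_ns))
  }
  frames <- lapply(trajectory_files, function(f) {
    xyz <- if (grepl("\\.dcd$", f, ignore.case = TRUE)) {
      tryCatch(bio3d::read.dcd(f, verbose = FALSE),
               error = function(e) stop_gpcrmsm("io", "cannot read DCD '%s'", f))
    } else {
      rbind(bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)$xyz)
    }
    if (ncol(xyz) != n3)
      stop_gpcrmsm("format",
                   "trajectory '%s' has %d atoms but topology has %d",
                   f, ncol(xyz) / 3, nrow(topology$atoms))
    xyz
  })
  ensemble_frames(do.call(rbind, frames), topology, interval_ns)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Text-format trajectory exchange: each frame becomes one MODEL block.
#'
#' @param frames an [ensemble_frames()] or a single atoms x 3 matrix with a
#'   `topology` argument.
#' @param file output path.
#' @param topology required when `frames` is a bare coordinate matrix.
#' @return `file`, invisibly.
#' @export
write_ensemble_pdb <- function(frames, file, topology = NULL) {
  if (inherits(frames, "ensemble_frames")) {
    topology <- frames$topology
    xyz <- frames$xyz
  } else {
    stopifnot(!is.null(topology))
    xyz <- rbind(coords_to_row(frames))
  }
  at <- topology$atoms
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(nrow(xyz))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    crd <- row_to_coords(xyz[f, ])
    lines <- sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      at$index, at$name, at$resid, at$resno,
      crd[, 1], crd[, 2], crd[, 3], at$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

rrcs_kernel <- function(d, d_min = 3.23, d_max = 4.63) {
  s <- (d_max - d) / (d_max - d_min)
  s[d <= d_min] <- 1
  s[d >= d_max] <- 0
  s
}

#' Residue-residue contact score matrix
#'
#' For every residue pair with sequence separation > 4 (more than one
#' alpha-helical turn), the score is the sum over heavy-atom pairs of a
#' piecewise-linear contact kernel: 1 below 3.23 A, 0 above 4.63 A, and
#' linearly interpolated in between. Hydrogens are ignored.
#'
#' @param frame atoms x 3 coordinate matrix, a 3N coordinate vector, or an
#'   [ensemble_frames()] (first frame used).
#' @param topology a [residue_topology()].
#' @param min_separation minimum sequence separation scored (exclusive,
#'   default 4).
#' @return symmetric residues x residues score matrix of class `rrcs_matrix`;
#'   pairs within the separation cutoff are zero.
#' @export
compute_rrcs <- function(frame, topology, min_separation = 4) {
  crd <- frame_coords(frame, topology)
  heavy <- which(topology$heavy)
  resno <- topology$atoms$resno[heavy]
  xyz <- crd[heavy, , drop = FALSE]
  res_levels <- topology$residues$resno
  n_res <- length(res_levels)
  D <- as.matrix(dist(xyz))
  S <- rrcs_kernel(D)
  out <- matrix(0, n_res, n_res,
                dimnames = list(res_levels, res_levels))
  ridx <- match(resno, res_levels)
  for (a in seq_len(n_res - 1)) {
    ia <- which(ridx == a)
    if (!length(ia)) next
    for (b in seq.int(a + 1, n_res)) {
      if (abs(res_levels[b] - res_levels[a]) <= min_separation) next
      ib <- which(ridx == b)
      if (!length(ib)) next
      s <- sum(S[ia, ib])
      out[a, b] <- s
      out[b, a] <- s
    }
  }
  class(out) <- c("rrcs_matrix", class(out))
  out
}

frame_coords <- function(frame, topology) {
  if (inherits(frame, "ensemble_frames")) return(row_to_coords(frame$xyz[1, ]))
  if (is.matrix(frame) && ncol(frame) == 3) return(frame)
  if (is.numeric(frame)) return(row_to_coords(frame))
  stop_gpcrmsm("validation", "unrecognised frame input")
}

#' Select contact-change features between two reference structures
#'
#' Residue pairs whose contact score differs by strictly more than
#' `threshold` between the active and inactive references become
#' alpha-carbon distance features, sorted by descending score change.
#'
#' @param active_ref,inactive_ref coordinate matrices (atoms x 3) sharing
#'   `topology`.
#' @param topology a [residue_topology()].
#' @param threshold contact-score change above which a pair is selected
#'   (strict inequality, default 3).
#' @return data.frame of feature definitions (kind `ca_distance`) with
#'   columns `name`, `kind`, `res_i`, `res_j`, `delta`.
#' @export
select_rrcs_features <- function(active_ref, inactive_ref, topology,
                                 threshold = 3.0) {
  a <- compute_rrcs(active_ref, topology)
  b <- compute_rrcs(inactive_ref, topology)
  if (!all(dim(a) == dim(b)))
    stop_gpcrmsm("validation", "reference structures must share topology")
  delta <- abs(a - b)
  hit <- which(delta > threshold & upper.tri(delta), arr.ind = TRUE)
  res_levels <- topology$residues$resno
  out <- data.frame(
    name = character(0), kind = character(0),
    res_i = integer(0), res_j = integer(0), delta = numeric(0),
    stringsAsFactors = FALSE)
  if (nrow(hit)) {
    out <- data.frame(
      name = sprintf("ca_%d_%d", res_levels[hit[, 1]], res_levels[hit[, 2]]),
      kind = "ca_distance",
      res_i = res_levels[hit[, 1]],
      res_j = res_levels[hit[, 2]],
      delta = delta[hit],
      stringsAsFactors = FALSE)
    out <- out[order(-out$delta), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Define a named structural feature
#'
#' @param kind one of `ca_distance`, `min_heavy_distance`, `dihedral_chi2`,
#'   `zcom_difference`, `named_distance`.
#' @param res_i,res_j residue numbers or generic-number labels (resolved
#'   against the topology at evaluation). `dihedral_chi2` uses `res_i` only.
#' @param atom_i,atom_j atom names for `named_distance`.
#' @param name feature name (auto-generated if missing).
#' @return one-row data.frame composable with `rbind`.
#' @export
feature_definition <- function(kind, res_i, res_j = NA, atom_i = NA, atom_j = NA,
                               name = NULL) {
  kind <- match.arg(kind, c("ca_distance", "min_heavy_distance",
                            "dihedral_chi2", "zcom_difference",
                            "named_distance"))
  name <- name %||% paste0(kind, "_", res_i,
                           ifelse(is.na(res_j), "", paste0("_", res_j)))
  data.frame(name = name, kind = kind,
             res_i = as.character(res_i), res_j = as.character(res_j),
             atom_i = atom_i, atom_j = atom_j, stringsAsFactors = FALSE)
}

residue_atom_idx <- function(topology, resno, atom = NULL, heavy_only = TRUE) {
  sel <- topology$atoms$resno == resno
  if (heavy_only) sel <- sel & topology$heavy
  if (!is.null(atom)) sel <- sel & topology$atoms$name == atom
  idx <- which(sel)
  if (!length(idx))
    stop_gpcrmsm("lookup", "no atoms for residue %s%s", resno,
                 if (is.null(atom)) "" else paste0(" atom ", atom))
  idx
}

dihedral_deg <- function(p1, p2, p3, p4) {
  # vectorized over frames: p* are frames x 3
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross(n1, b2n)
  x <- rowSums(n1 * n2); y <- rowSums(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

atom_xyz <- function(frames, idx) frames$xyz[, c(3 * idx - 2, 3 * idx - 1, 3 * idx), drop = FALSE]

#' Evaluate feature definitions over an ensemble
#'
#' Distances in Angstrom; the chi2 dihedral (CA-CB-CG-CD1, tryptophan
#' convention) in degrees wrapped to (-180, 180]; `zcom_difference` is
#' z(side-chain centre of mass of `res_i`) minus that of `res_j`.
#'
#' @param frames an [ensemble_frames()].
#' @param definitions data.frame of [feature_definition()] rows (the output
#'   of [select_rrcs_features()] qualifies).
#' @return numeric matrix frames x features (class `feature_matrix`).
#' @export
evaluate_features <- function(frames, definitions) {
  stopifnot(inherits(frames, "ensemble_frames"))
  topo <- frames$topology
  n <- nrow(frames$xyz)
  backbone <- c("CA", "N", "C", "O")
  cols <- lapply(seq_len(nrow(definitions)), function(k) {
    def <- definitions[k, ]
    ri <- resolve_label(topo, def$res_i)
    switch(def$kind,
      ca_distance = {
        rj <- resolve_label(topo, def$res_j)
        a <- atom_xyz(frames, residue_atom_idx(topo, ri, "CA"))
        b <- atom_xyz(frames, residue_atom_idx(topo, rj, "CA"))
        sqrt(rowSums((a - b)^2))
      },
      named_distance = {
        rj <- resolve_label(topo, def$res_j)
        a <- atom_xyz(frames, residue_atom_idx(topo, ri, def$atom_i))
        b <- atom_xyz(frames, residue_atom_idx(topo, rj, def$atom_j))
        sqrt(rowSums((a - b)^2))
      },
      min_heavy_distance = {
        rj <- resolve_label(topo, def$res_j)
        closest_heavy_distances(frames, pairs = cbind(ri, rj))[, 1]
      },
      dihedral_chi2 = {
        idx <- vapply(c("CA", "CB", "CG", "CD1"),
                      function(a) residue_atom_idx(topo, ri, a)[1], integer(1))
        dihedral_deg(atom_xyz(frames, idx[1]), atom_xyz(frames, idx[2]),
                     atom_xyz(frames, idx[3]), atom_xyz(frames, idx[4]))
      },
      zcom_difference = {
        rj <- resolve_label(topo, def$res_j)
        side_z <- function(r) {
          idx <- residue_atom_idx(topo, r)
          idx <- idx[!topo$atoms$name[idx] %in% backbone]
          if (!length(idx)) idx <- residue_atom_idx(topo, r)
          z <- frames$xyz[, 3 * idx, drop = FALSE]
          rowMeans(z)
        }
        side_z(ri) - side_z(rj)
      },
      stop_gpcrmsm("validation", "unknown feature kind '%s'", def$kind))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- definitions$name
  class(X) <- c("feature_matrix", class(X))
  X
}

#' Closest heavy-atom distances for residue pairs across frames
#'
#' @param frames an [ensemble_frames()].
#' @param pairs optional 2-column matrix of residue numbers; default all
#'   pairs i < j.
#' @param carbon_only restrict to carbon atoms (the Methods-text variant).
#' @return matrix frames x pairs; column names `"i_j"`.
#' @export
closest_heavy_distances <- function(frames, pairs = NULL, carbon_only = FALSE) {
  topo <- frames$topology
  res_levels <- topo$residues$resno
  if (is.null(pairs)) {
    pairs <- t(combn(res_levels, 2))
  }
  keep <- topo$heavy
  if (carbon_only) keep <- keep & toupper(topo$atoms$element) == "C"
  idx_by_res <- lapply(res_levels, function(r)
    which(topo$atoms$resno == r & keep))
  names(idx_by_res) <- res_levels
  n <- nrow(frames$xyz)
  out <- matrix(NA_real_, n, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ia <- idx_by_res[[as.character(pairs[k, 1])]]
    ib <- idx_by_res[[as.character(pairs[k, 2])]]
    dmin <- rep(Inf, n)
    for (a in ia) {
      ax <- frames$xyz[, 3 * a - 2]; ay <- frames$xyz[, 3 * a - 1]; az <- frames$xyz[, 3 * a]
      for (b in ib) {
        d2 <- (ax - frames$xyz[, 3 * b - 2])^2 +
              (ay - frames$xyz[, 3 * b - 1])^2 +
              (az - frames$xyz[, 3 * b])^2
        dmin <- pmin(dmin, d2)
      }
    }
    out[, k] <- sqrt(dmin)
  }
  colnames(out) <- paste0(pairs[, 1], "_", pairs[, 2])
  out
}

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

#' Grid-based binding-pocket volume
#'
#' Probe-excluded volume inside an inclusion sphere centred at the mean
#' alpha-carbon position of the given residues: the count of grid points
#' inside the sphere and farther than (van der Waals radius + 1.4 A probe)
#' from every heavy atom, times the voxel volume. A trend-level
#' simplification of flood-fill pocket-volume methods.
#'
#' @param frame coordinate frame (matrix, vector, or ensemble first frame).
#' @param topology a [residue_topology()].
#' @param center_residues residue numbers defining the pocket centre.
#' @param inclusion_radius sphere radius, Angstrom.
#' @param voxel grid spacing, Angstrom (default 1).
#' @param probe probe radius, Angstrom (default 1.4).
#' @return volume in cubic Angstrom.
#' @export
pocket_volume <- function(frame, topology, center_residues, inclusion_radius,
                          voxel = 1.0, probe = 1.4) {
  if (!length(center_residues))
    stop_gpcrmsm("validation", "center_residues must be nonempty")
  crd <- frame_coords(frame, topology)
  ca_idx <- unlist(lapply(center_residues, function(r)
    residue_atom_idx(topology, resolve_label(topology, r), "CA")))
  center <- colMeans(crd[ca_idx, , drop = FALSE])
  g1 <- seq(-inclusion_radius, inclusion_radius, by = voxel)
  grid <- as.matrix(expand.grid(x = g1, y = g1, z = g1))
  grid <- grid[rowSums(grid^2) <= inclusion_radius^2, , drop = FALSE]
  grid <- sweep(grid, 2, center, `+`)
  heavy <- which(topology$heavy)
  free <- rep(TRUE, nrow(grid))
  for (a in heavy) {
    r_excl <- unname(VDW_RADII[toupper(topology$atoms$element[a])])
    if (is.na(r_excl)) r_excl <- 1.70
    r_excl <- r_excl + probe
    # atoms beyond the sphere plus exclusion radius cannot touch the grid
    if (sqrt(sum((crd[a, ] - center)^2)) > inclusion_radius + r_excl) next
    d2 <- (grid[, 1] - crd[a, 1])^2 + (grid[, 2] - crd[a, 2])^2 +
          (grid[, 3] - crd[a, 3])^2
    free <- free & d2 > r_excl^2
  }
  sum(free) * voxel^3
}

#' Optimal-superposition RMSD of frames against a reference
#'
#' Kabsch superposition via bio3d; with `fit = FALSE` the raw coordinate
#' RMSD is returned.
#'
#' @param frames an [ensemble_frames()] or frames x 3N matrix.
#' @param reference reference coordinates (3N vector or atoms x 3 matrix).
#' @param atom_selection optional integer atom indices used both for fitting
#'   and the RMSD.
#' @param fit superpose before computing (default TRUE).
#' @return numeric vector of per-frame RMSD values (Angstrom).
#' @export
rmsd_frames <- function(frames, reference, atom_selection = NULL, fit = TRUE) {
  xyz <- if (inherits(frames, "ensemble_frames")) frames$xyz else rbind(frames)
  ref <- if (is.matrix(reference) && ncol(reference) == 3)
    coords_to_row(reference) else as.numeric(reference)
  if (length(ref) != ncol(xyz))
    stop_gpcrmsm("validation", "reference size does not match frames")
  inds <- if (is.null(atom_selection)) seq_len(length(ref) / 3) else atom_selection
  xyz_inds <- as.numeric(rbind(3 * inds - 2, 3 * inds - 1, 3 * inds))
  as.numeric(bio3d::rmsd(ref, xyz, a.inds = xyz_inds, b.inds = xyz_inds,
                         fit = fit))
}

#' Write a feature matrix as CSV
#'
#' One row per frame, header row of feature names.
#'
#' @param features frames x features matrix.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_features_csv <- function(features, file) {
  write.csv(as.data.frame(unclass(features)), file, row.names = FALSE)
  invisible(file)
}

#' Read a feature matrix from CSV
#' @param file CSV path with a header row of feature names.
#' @return feature matrix (frames x features).
#' @export
read_features_csv <- function(file) {
  X <- as.matrix(read.csv(file, check.names = FALSE))
  class(X) <- c("feature_matrix", class(X))
  X
}

#' Write an RRCS matrix in long format
#' @param rrcs matrix from [compute_rrcs()].
#' @param file output CSV path (columns res_i, res_j, score; upper triangle,
#'   nonzero entries).
#' @return `file`, invisibly.
#' @export
write_rrcs_csv <- function(rrcs, file) {
  idx <- which(upper.tri(rrcs) & rrcs > 0, arr.ind = TRUE)
  res <- as.integer(rownames(rrcs))
  write.csv(data.frame(res_i = res[idx[, 1]], res_j = res[idx[, 2]],
                       score = rrcs[idx]),
            file, row.names = FALSE)
  invisible(file)
}
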