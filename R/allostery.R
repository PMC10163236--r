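# Allostery and divergence statistics: apo/holo feature-shift metrics,
# conditional-probability coupling of binarized features under MSM frame
# weights, per-residue symmetric Kullback-Leibler divergence profiles, and
# mutual-information allosteric pathway graphs.

#' Feature-shift metrics between apo and holo ensembles
#'
#' Features are min-max normalised over the pooled three ensembles, then per
#' feature: the mean-shift metric `|E(holo_inactive) - E(apo)| +
#' |E(holo_active) - E(apo)|` and the Kullback-Leibler divergences of the
#' apo distribution from each holo distribution, on shared-support
#' histograms with pseudocounts.
#'
#' @param apo_features,holo_active_features,holo_inactive_features frames x
#'   features matrices sharing the same feature columns.
#' @param bins histogram bins (default 30).
#' @return data.frame: feature, mean_shift, kl_active, kl_inactive.
#' @export
feature_shift_metrics <- function(apo_features, holo_active_features,
                                  holo_inactive_features, bins = 30) {
  mats <- list(apo = rbind(unclass(apo_features)),
               act = rbind(unclass(holo_active_features)),
               inact = rbind(unclass(holo_inactive_features)))
  if (any(vapply(mats, nrow, integer(1)) == 0))
    stop_gpcrmsm("validation", "empty ensemble")
  p <- ncol(mats$apo)
  if (any(vapply(mats, ncol, integer(1)) != p))
    stop_gpcrmsm("validation", "ensembles must share the same feature set")
  out <- data.frame(feature = colnames(mats$apo) %||% paste0("f", 1:p),
                    mean_shift = NA_real_, kl_active = NA_real_,
                    kl_inactive = NA_real_)
  for (j in 1:p) {
    pooled <- c(mats$apo[, j], mats$act[, j], mats$inact[, j])
    rng <- range(pooled)
    span <- if (diff(rng) == 0) 1 else diff(rng)
    norm <- lapply(mats, function(m) (m[, j] - rng[1]) / span)
    out$mean_shift[j] <- abs(mean(norm$inact) - mean(norm$apo)) +
      abs(mean(norm$act) - mean(norm$apo))
    br <- seq(0, 1, length.out = bins + 1)
    pa <- hist_probs(norm$apo, br)
    out$kl_active[j] <- kl_divergence(pa, hist_probs(norm$act, br))
    out$kl_inactive[j] <- kl_divergence(pa, hist_probs(norm$inact, br))
  }
  out
}

binarize_features <- function(features, thresholds, active_is_greater) {
  X <- rbind(unclass(features))
  p <- ncol(X)
  thresholds <- rep_len(thresholds, p)
  active_is_greater <- rep_len(active_is_greater, p)
  B <- matrix(FALSE, nrow(X), p)
  for (j in 1:p) {
    B[, j] <- if (active_is_greater[j]) X[, j] > thresholds[j]
              else X[, j] < thresholds[j]
  }
  colnames(B) <- colnames(X)
  B
}

#' Conditional-probability allosteric coupling matrix
#'
#' Each feature is binarized into active/inactive by a per-feature threshold
#' (conventionally the average of the active and inactive reference
#' structure values; the direction flag says which side is active). Entry
#' `(i, j)` is `|P(F_i active | F_j active) - P(F_i active | F_j inactive)|`
#' under the supplied frame weights (e.g. MSM equilibrium weights). Entries
#' whose conditioning side carries zero weight are NA, not 0.
#'
#' @param features frames x features matrix.
#' @param thresholds per-feature activity thresholds (recycled).
#' @param frame_weights per-frame weights summing to 1 (default uniform).
#' @param active_is_greater logical per feature: active side is above the
#'   threshold (recycled, default TRUE).
#' @return features x features matrix of class `coupling_matrix`; rows are
#'   the conditioned feature i, columns the conditioning feature j;
#'   diagonal is 1 wherever P(F_i active) is in (0, 1).
#' @export
conditional_coupling <- function(features, thresholds, frame_weights = NULL,
                                 active_is_greater = TRUE) {
  B <- binarize_features(features, thresholds, active_is_greater)
  n <- nrow(B); p <- ncol(B)
  w <- frame_weights %||% rep(1 / n, n)
  if (length(w) != n)
    stop_gpcrmsm("validation", "frame_weights length must match frames")
  w <- w / sum(w)
  M <- matrix(NA_real_, p, p, dimnames = list(colnames(B), colnames(B)))
  for (j in 1:p) {
    wa <- sum(w[B[, j]]); wi <- sum(w[!B[, j]])
    for (i in 1:p) {
      if (wa == 0 || wi == 0) next  # undefined conditioning side
      p_a <- sum(w[B[, i] & B[, j]]) / wa
      p_i <- sum(w[B[, i] & !B[, j]]) / wi
      M[i, j] <- abs(p_a - p_i)
    }
  }
  class(M) <- c("coupling_matrix", class(M))
  M
}

#' Per-residue symmetric Kullback-Leibler divergence profile
#'
#' For every residue pair, the closest-heavy-atom distance distribution of
#' ensemble a is compared with that of ensemble b by symmetric KL
#' divergence on shared-support histograms with pseudocounts, minus the
#' first-order plug-in bias (so that comparing a state against itself sits
#' at zero rather than at the histogram bias); the per-residue value is the
#' mean over all pairs involving that residue. Symmetric in its two
#' ensemble arguments by construction.
#'
#' @param frames_a,frames_b [ensemble_frames()] objects sharing a topology
#'   (conventionally 1000 frames sampled per metastable state).
#' @param bins histogram bins (default 30).
#' @param carbon_only restrict distances to carbon atoms.
#' @return object of class `residue_kl_profile`: data.frame(resno, kl) plus
#'   attribute `pair_kl` (per-pair divergences).
#' @export
residue_kl_profile <- function(frames_a, frames_b, bins = 30,
                               carbon_only = FALSE) {
  if (nrow(frames_a$xyz) < 2 || nrow(frames_b$xyz) < 2)
    stop_gpcrmsm("validation", "each ensemble needs at least 2 frames")
  if (!identical(dim(frames_a$topology$atoms), dim(frames_b$topology$atoms)))
    stop_gpcrmsm("validation", "ensembles must share a topology")
  res <- frames_a$topology$residues$resno
  pairs <- t(combn(res, 2))
  da <- closest_heavy_distances(frames_a, pairs, carbon_only = carbon_only)
  db <- closest_heavy_distances(frames_b, pairs, carbon_only = carbon_only)
  na_ <- nrow(da); nb_ <- nrow(db)
  pair_kl <- vapply(seq_len(nrow(pairs)), function(k) {
    br <- shared_breaks(da[, k], db[, k], bins = bins)
    pa <- hist_probs(da[, k], br)
    pb <- hist_probs(db[, k], br)
    # first-order (Miller-Madow-style) correction of the plug-in bias,
    # (B_occ - 1)/2 * (1/n_a + 1/n_b), so the self-comparison null sits
    # at zero instead of at the histogram bias
    occ <- sum(hist_probs(da[, k], br, pseudocount = 0) +
               hist_probs(db[, k], br, pseudocount = 0) > 0)
    bias <- (occ - 1) / 2 * (1 / na_ + 1 / nb_)
    max(symmetric_kl(pa, pb) - bias, 0)
  }, numeric(1))
  kl <- vapply(res, function(r) {
    mean(pair_kl[pairs[, 1] == r | pairs[, 2] == r])
  }, numeric(1))
  structure(data.frame(resno = res, kl = kl),
            pair_kl = data.frame(res_i = pairs[, 1], res_j = pairs[, 2],
                                 kl = pair_kl),
            class = c("residue_kl_profile", "data.frame"))
}

#' Normalized mutual information matrix of dihedral features
#'
#' MI from joint histograms with pseudocounts, normalised by the mean of
#' the two marginal entropies and clipped to `[0, 1]`. Constant features
#' (zero marginal entropy) yield NA entries.
#'
#' @param dihedral_features frames x features matrix, angles in degrees.
#' @param bins histogram bins per axis (default 30, over a shared
#'   (-180, 180] support for angular data; non-angular inputs use their
#'   pooled range).
#' @param angular treat columns as angles on (-180, 180] (default TRUE).
#' @return symmetric features x features matrix, unit diagonal.
#' @export
mutual_information_matrix <- function(dihedral_features, bins = 30,
                                      angular = TRUE) {
  X <- rbind(unclass(dihedral_features))
  p <- ncol(X)
  if (p < 2) stop_gpcrmsm("validation", "need at least 2 dihedral features")
  br <- if (angular) seq(-180, 180, length.out = bins + 1)
        else shared_breaks(as.numeric(X), bins = bins)
  disc <- matrix(0L, nrow(X), p)
  for (j in 1:p) {
    xj <- pmin(pmax(X[, j], br[1] + 1e-9), br[length(br)])
    disc[, j] <- findInterval(xj, br, rightmost.closed = TRUE,
                              left.open = TRUE)
    disc[disc[, j] < 1, j] <- 1L
  }
  pseudo <- 1e-10
  marg <- lapply(1:p, function(j) {
    h <- tabulate(disc[, j], nbins = bins) + pseudo
    h / sum(h)
  })
  H <- vapply(marg, function(m) -sum(m * log(m)), numeric(1))
  # entropy floor: the pseudocount makes H tiny but nonzero for constants
  const <- apply(X, 2, function(x) length(unique(x)) == 1)
  M <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  for (i in 1:p) {
    if (const[i]) next
    M[i, i] <- 1
    for (j in seq_len(i - 1)) {
      if (const[j]) next
      joint <- tabulate((disc[, i] - 1L) * bins + disc[, j],
                        nbins = bins * bins) + pseudo / bins
      joint <- joint / sum(joint)
      pi_ <- marg[[i]]; pj <- marg[[j]]
      mi <- sum(joint * log(joint)) + sum(-pi_ * log(pi_)) + sum(-pj * log(pj))
      v <- mi / mean(c(H[i], H[j]))
      v <- min(max(v, 0), 1)
      M[i, j] <- v
      M[j, i] <- v
    }
  }
  M
}

#' Mutual-information allosteric pathways
#'
#' Builds the residue contact graph (edges between residues whose closest
#' heavy atoms are within `contact_cutoff`), weights each edge `MI_max -
#' MI_ij`, finds the minimum-weight (Dijkstra) path for every residue pair
#' at least `min_endpoint_separation` apart in the representative
#' structure, ranks paths by cumulative MI along their edges, keeps the top
#' `top_n`, and clusters them by residue-set Jaccard distance
#' (average linkage; cluster count by silhouette).
#'
#' @param mi_matrix residues x residues normalized MI matrix (row/col names
#'   are residue numbers; NA entries treated as 0 MI).
#' @param representative_frames an [ensemble_frames()] whose first frame is
#'   the representative structure.
#' @param contact_cutoff contact-edge distance cutoff, Angstrom (default 5).
#' @param min_endpoint_separation minimum endpoint distance, Angstrom
#'   (default 12).
#' @param top_n number of paths retained (default 500).
#' @return object of class `allosteric_pathways`: list with `paths` (list
#'   of integer residue-number vectors, MI-ranked), `path_mi` (cumulative
#'   MI), `clusters` (integer vector), `n_clusters`, `graph`.
#' @export
allosteric_pathways <- function(mi_matrix, representative_frames,
                                contact_cutoff = 5,
                                min_endpoint_separation = 12, top_n = 500) {
  topo <- representative_frames$topology
  res <- topo$residues$resno
  if (length(res) < 3)
    stop_gpcrmsm("validation", "need a contact graph over at least 3 residues")
  first <- ensemble_frames(representative_frames$xyz[1, , drop = FALSE],
                           topo, representative_frames$interval_ns)
  pairs <- t(combn(res, 2))
  dmin <- closest_heavy_distances(first, pairs)[1, ]
  mi_of <- function(i, j) {
    v <- mi_matrix[as.character(i), as.character(j)]
    if (is.na(v)) 0 else v
  }
  contact <- dmin < contact_cutoff
  if (!any(contact))
    stop_gpcrmsm("validation", "no contact edges under the cutoff")
  edges <- pairs[contact, , drop = FALSE]
  mi_e <- vapply(seq_len(nrow(edges)), function(k)
    mi_of(edges[k, 1], edges[k, 2]), numeric(1))
  mi_max <- max(mi_e)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2]),
               weight = mi_max - mi_e + 1e-12, mi = mi_e),
    directed = FALSE, vertices = data.frame(name = as.character(res)))
  far <- pairs[dmin >= min_endpoint_separation, , drop = FALSE]
  if (!nrow(far)) {
    warning("no residue pairs beyond the endpoint separation cutoff")
    return(structure(list(paths = list(), path_mi = numeric(0),
                          clusters = integer(0), n_clusters = 0, graph = g),
                     class = "allosteric_pathways"))
  }
  paths <- list(); path_mi <- numeric(0)
  for (k in seq_len(nrow(far))) {
    sp <- suppressWarnings(igraph::shortest_paths(
      g, from = as.character(far[k, 1]), to = as.character(far[k, 2]),
      weights = igraph::E(g)$weight, output = "vpath"))$vpath[[1]]
    if (length(sp) < 2) next  # endpoints disconnected
    nodes <- as.integer(igraph::V(g)$name[sp])
    cmi <- sum(vapply(seq_len(length(nodes) - 1), function(e)
      mi_of(nodes[e], nodes[e + 1]), numeric(1)))
    paths[[length(paths) + 1]] <- nodes
    path_mi <- c(path_mi, cmi)
  }
  if (!length(paths)) {
    warning("no connected qualifying endpoint pairs")
    return(structure(list(paths = list(), path_mi = numeric(0),
                          clusters = integer(0), n_clusters = 0, graph = g),
                     class = "allosteric_pathways"))
  }
  ord <- order(-path_mi)
  keep <- ord[seq_len(min(top_n, length(ord)))]
  paths <- paths[keep]; path_mi <- path_mi[keep]
  cl <- cluster_paths(paths)
  structure(list(paths = paths, path_mi = path_mi,
                 clusters = cl$clusters, n_clusters = cl$k, graph = g),
            class = "allosteric_pathways")
}

cluster_paths <- function(paths) {
  n <- length(paths)
  if (n == 1) return(list(clusters = 1L, k = 1L))
  sets <- lapply(paths, unique)
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    jac <- length(intersect(sets[[i]], sets[[j]])) /
      length(union(sets[[i]], sets[[j]]))
    D[i, j] <- D[j, i] <- 1 - jac
  }
  if (all(D < 1e-12)) return(list(clusters = rep(1L, n), k = 1L))
  hc <- hclust(as.dist(D), method = "average")
  ks <- 2:min(8, n - 1)
  sil <- vapply(ks, function(k) {
    cl <- cutree(hc, k)
    if (length(unique(cl)) < 2) return(-Inf)
    mean(cluster::silhouette(cl, dmatrix = D)[, 3])
  }, numeric(1))
  k <- ks[which.max(sil)]
  list(clusters = cutree(hc, k), k = k)
}

#' The highest-MI pathway of the top-ranked pathway cluster
#' @param pw an [allosteric_pathways()] result.
#' @return integer residue-number vector (empty when no paths).
#' @export
top_cluster_path <- function(pw) {
  if (!length(pw$paths)) return(integer(0))
  top_cl <- pw$clusters[1]  # cluster containing the highest-MI path
  members <- which(pw$clusters == top_cl)
  pw$paths[[members[which.max(pw$path_mi[members])]]]
}

#' Write allosteric pathways as JSON
#' @param pw an `allosteric_pathways` result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pathways_json <- function(pw, file) {
  jsonlite::write_json(list(
    n_paths = length(pw$paths),
    n_clusters = pw$n_clusters,
    paths = lapply(seq_along(pw$paths), function(i)
      list(residues = pw$paths[[i]], cumulative_mi = pw$path_mi[i],
           cluster = pw$clusters[i]))
  ), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
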