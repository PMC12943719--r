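# Docking-pose clustering by RMSD with lowest-energy coverage selection.

#' Clustering configuration
#'
#' @param rmsd_threshold cluster radius in Angstrom (default 5.0).
#' @param coverage_fraction minimum fraction of all poses the selected
#'   clusters must cover (default 0.70).
#' @return list of class `dockhb_clustering`.
#' @export
clustering_config <- function(rmsd_threshold = 5.0,
                              coverage_fraction = 0.70) {
  stopifnot(rmsd_threshold > 0,
            coverage_fraction > 0, coverage_fraction <= 1)
  structure(list(rmsd_threshold = rmsd_threshold,
                 coverage_fraction = coverage_fraction),
            class = "dockhb_clustering")
}

#' RMSD between two poses without superposition
#'
#' Poses from one docking run share the receptor frame, so the deviation
#' is computed in place: the square root of the mean squared per-atom
#' displacement over matched atoms. Hydrogens are excluded by default.
#'
#' @param pose_a,pose_b n x 3 coordinate matrices with identical atom
#'   order.
#' @param elements optional character vector of element symbols (length
#'   n) used to drop hydrogens when `heavy_only = TRUE`.
#' @param heavy_only restrict to non-hydrogen atoms (default `TRUE`;
#'   ignored when `elements` is `NULL`).
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(pose_a, pose_b, elements = NULL, heavy_only = TRUE) {
  if (!all(dim(pose_a) == dim(pose_b)))
    stop("topology error: pose dimensions differ (",
         nrow(pose_a), " vs ", nrow(pose_b), " atoms)")
  if (heavy_only && !is.null(elements)) {
    keep <- toupper(elements) != "H"
    pose_a <- pose_a[keep, , drop = FALSE]
    pose_b <- pose_b[keep, , drop = FALSE]
  }
  sqrt(mean(rowSums((pose_a - pose_b)^2)))
}

#' Greedy energy-seeded clustering of a pose ensemble
#'
#' Repeatedly seeds a new cluster with the lowest-energy unassigned pose
#' (ties broken by pose index) and assigns every unassigned pose within
#' `rmsd_threshold` of the seed. Clusters come back sorted by best
#' member energy, ascending; every pose belongs to exactly one cluster.
#'
#' Only ligand-role heavy atoms enter the RMSD when the topology carries
#' roles; otherwise all heavy atoms are used.
#'
#' @param ensemble a `dockhb_ensemble`.
#' @param config a [clustering_config()].
#' @return list of clusters, each a list with `member_indices`,
#'   `representative_index` (lowest-energy member), `best_energy`.
#' @export
cluster_poses <- function(ensemble, config = clustering_config()) {
  n <- ensemble$n_poses
  stopifnot(n >= 1L)
  atoms <- ensemble$topology$atoms
  keep <- toupper(atoms$element) != "H"
  if (any(atoms$role == "ligand")) keep <- keep & atoms$role == "ligand"
  poses <- lapply(ensemble$poses, function(p) p[keep, , drop = FALSE])
  energies <- ensemble$energies

  unassigned <- rep(TRUE, n)
  clusters <- list()
  ord <- order(energies, seq_len(n))
  while (any(unassigned)) {
    seed <- ord[unassigned[ord]][1]
    cand <- which(unassigned)
    d <- vapply(cand, function(j) pose_rmsd(poses[[seed]], poses[[j]],
                                            heavy_only = FALSE), 0)
    members <- cand[d <= config$rmsd_threshold]
    members <- sort(unique(c(seed, members)))
    unassigned[members] <- FALSE
    rep_idx <- members[order(energies[members], members)][1]
    clusters[[length(clusters) + 1L]] <- list(
      member_indices = members,
      representative_index = rep_idx,
      best_energy = energies[rep_idx]
    )
  }
  clusters[order(vapply(clusters, `[[`, 0, "best_energy"))]
}

#' Select the lowest-energy clusters covering a pose fraction
#'
#' Takes clusters in best-energy order until the cumulative member count
#' reaches `ceiling(coverage_fraction * n_total)`.
#'
#' @param clusters output of [cluster_poses()] (sorted by best energy).
#' @param config a [clustering_config()].
#' @param n_total total number of poses the coverage refers to.
#' @return the selected head of `clusters` (at least one cluster).
#' @export
select_covering_clusters <- function(clusters,
                                     config = clustering_config(),
                                     n_total = sum(lengths(lapply(
                                       clusters, `[[`, "member_indices")))) {
  if (!length(clusters)) stop("empty cluster list")
  need <- ceiling(config$coverage_fraction * n_total)
  sizes <- vapply(clusters, function(cl) length(cl$member_indices), 0L)
  k <- which(cumsum(sizes) >= need)[1]
  if (is.na(k)) k <- length(clusters)
  clusters[seq_len(max(1L, k))]
}

#' Tabulate clusters for reporting
#'
#' @param clusters output of [cluster_poses()].
#' @return data.frame `cluster_id`, `size`, `best_energy`,
#'   `representative_model`, `member_models` (comma-separated).
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, Map(function(cl, k) data.frame(
    cluster_id = k,
    size = length(cl$member_indices),
    best_energy = cl$best_energy,
    representative_model = cl$representative_index,
    member_models = paste(cl$member_indices, collapse = ","),
    stringsAsFactors = FALSE
  ), clusters, seq_along(clusters)))
}
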