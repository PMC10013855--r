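#' Pairwise ligand RMSD matrix across frames
#'
#' Frames are first rigid-body superposed on a receptor fit group (reference:
#' first frame), then the ligand RMSD between every pair of frames is taken
#' with no further fitting, so poses are compared in the receptor frame.
#'
#' @param traj A [trajectory()].
#' @param ligand [residue_group()] selecting the ligand atoms.
#' @param fit_group Optional [residue_group()] to superpose on first; `NULL`
#'   if the trajectory is already aligned.
#' @return Symmetric n x n matrix of RMSD values (Angstrom), zero diagonal,
#'   class `rmsd_matrix`.
#' @export
ligand_rmsd_matrix <- function(traj, ligand, fit_group = NULL) {
  if (!is.null(fit_group)) traj <- superpose(traj, 1, fit_group)
  idx <- resolve_group(traj$topology, ligand)
  if (length(idx) == 0) stop("empty ligand selection")
  m <- length(idx)
  # flatten ligand coords per frame; Euclidean distance / sqrt(natoms) = RMSD
  flat <- matrix(traj$coords[, idx, , drop = FALSE],
                 nrow = n_frames(traj), ncol = 3 * m)
  D <- as.matrix(stats::dist(flat)) / sqrt(m)
  dimnames(D) <- NULL
  class(D) <- c("rmsd_matrix", class(D))
  D
}

.check_rmsd_matrix <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (any(D < 0) || any(abs(diag(D)) > 1e-9)) {
    stop("RMSD matrix must be non-negative with zero diagonal")
  }
}

#' Ward hierarchical clustering of an RMSD matrix
#'
#' Agglomerative clustering with Ward's minimum-variance criterion
#' (`stats::hclust`, method "ward.D2", operating on the RMSD values as
#' distances), cut to `k` clusters.
#'
#' @param D RMSD matrix from [ligand_rmsd_matrix()].
#' @param k Number of clusters, 1..n.
#' @return Integer vector of cluster labels (1..k).
#' @export
ward_cluster <- function(D, k) {
  .check_rmsd_matrix(D)
  n <- nrow(D)
  if (k < 1 || k > n) stop("k must be in 1..", n)
  if (n == 1) return(1L)
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  unname(stats::cutree(hc, k = k))
}

# within-cluster sum of squares from pairwise distances:
# sum over clusters of sum_{i<j in c} d_ij^2 / n_c
.wss_from_dist <- function(D, labels) {
  sum(vapply(split(seq_along(labels), labels), function(idx) {
    nc <- length(idx)
    if (nc < 2) return(0)
    sum(D[idx, idx]^2) / (2 * nc)
  }, numeric(1)))
}

#' Elbow selection of the cluster count
#'
#' Computes within-cluster sum of squares for Ward partitions at k = 1..k_max
#' and returns the k at the elbow: the point of maximum distance below the
#' chord joining the first and last points of the log-WSS-versus-k curve.
#' The log scale is used because WSS spans orders of magnitude across k and
#' on the raw scale the chord criterion is dominated by the earliest, most
#' expensive merges; on the log scale the knee separating
#' "merging real clusters" from "splitting noise" is the unique extreme
#' point. A curve with no point meaningfully below its chord (a single
#' structureless blob, whose log-WSS is concave in k) and degenerate
#' all-identical input both return 1. Deterministic, no RNG.
#'
#' @param D RMSD matrix.
#' @param k_max Largest k to scan (>= 2).
#' @return List with `k` (selected), `wss` (profile over 1..k_max).
#' @export
select_k_elbow <- function(D, k_max = 10) {
  .check_rmsd_matrix(D)
  if (k_max < 2) stop("k_max must be >= 2")
  n <- nrow(D)
  k_max <- min(k_max, n)
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  ks <- seq_len(k_max)
  wss <- vapply(ks, function(k) {
    .wss_from_dist(D, stats::cutree(hc, k = k))
  }, numeric(1))
  if (wss[1] < 1e-12) return(list(k = 1L, wss = wss))  # no structure at all
  lw <- log(pmax(wss, wss[1] * 1e-9))
  # signed drop below the chord joining (1, lw_1) and (k_max, lw_kmax)
  chord <- lw[1] + (lw[k_max] - lw[1]) * (ks - 1) / (k_max - 1)
  gap <- chord - lw
  # a knee must undercut the geometric trend by at least a factor of 2;
  # smooth profiles (one structureless blob) never do
  if (max(gap) <= log(2)) return(list(k = 1L, wss = wss))
  list(k = as.integer(ks[which.max(gap)]), wss = wss)
}

#' Summarize a clustering: populations and medoid representatives
#'
#' Population is the percentage of frames per cluster; the representative
#' (medoid) of a cluster is its frame with the lowest mean RMSD to the other
#' frames of that cluster (ties broken by lowest frame index).
#'
#' @param D RMSD matrix.
#' @param labels Integer cluster labels for every frame.
#' @return Object of class `cluster_result`: list with `k`, `labels`,
#'   `populations` (named percentages summing to 100) and `medoid_frame`.
#' @export
summarize_clusters <- function(D, labels) {
  .check_rmsd_matrix(D)
  n <- nrow(D)
  if (length(labels) != n) stop("labels length must match matrix size")
  cl <- sort(unique(labels))
  pops <- vapply(cl, function(c) 100 * sum(labels == c) / n, numeric(1))
  med <- vapply(cl, function(c) {
    idx <- which(labels == c)
    if (length(idx) == 1) return(idx)
    mean_r <- rowMeans(D[idx, idx, drop = FALSE]) * length(idx) /
      (length(idx) - 1)  # mean over the *other* frames
    idx[which.min(mean_r)]
  }, numeric(1))
  names(pops) <- names(med) <- paste0("cluster", cl)
  structure(list(k = length(cl), labels = labels, populations = pops,
                 medoid_frame = as.integer(med)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k = %d over %d frames\n",
              x$k, length(x$labels)))
  for (i in seq_len(x$k)) {
    cat(sprintf("  %s: %.1f%% (medoid frame %d)\n",
                names(x$populations)[i], x$populations[i], x$medoid_frame[i]))
  }
  invisible(x)
}

#' Full pose-clustering pipeline
#'
#' Superpose on the receptor, build the pairwise ligand RMSD matrix, pick k
#' by the elbow criterion over Ward partitions, and summarize populations
#' and medoids.
#'
#' @inheritParams ligand_rmsd_matrix
#' @param k_max Largest cluster count scanned by the elbow (default 10).
#' @return A `cluster_result` with the `rmsd_matrix` attached as attribute
#'   `D` and the elbow WSS profile as attribute `wss`.
#' @export
cluster_poses <- function(traj, ligand, fit_group = NULL, k_max = 10) {
  D <- ligand_rmsd_matrix(traj, ligand, fit_group)
  sel <- select_k_elbow(D, k_max)
  labels <- ward_cluster(D, sel$k)
  res <- summarize_clusters(D, labels)
  attr(res, "D") <- D
  attr(res, "wss") <- sel$wss
  res
}
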