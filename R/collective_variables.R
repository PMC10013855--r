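#' Geometric center-to-center distance series
#'
#' Per-frame Euclidean distance between the geometric centers of two residue
#' groups, the workhorse "distance" of the analysis (e.g. the A161-E299
#' opening coordinate, the GsaAH-GsaRas interdomain distance, or receptor to
#' alpha-5 separation).
#'
#' @param traj A [trajectory()].
#' @param groupA,groupB [residue_group()] selections.
#' @param name Series name (default from group names).
#' @return A [cv_series()] in Angstrom.
#' @export
center_distance_series <- function(traj, groupA, groupB, name = NULL) {
  cA <- center_series(traj, groupA)
  cB <- center_series(traj, groupB)
  d <- sqrt(rowSums((cA - cB)^2))
  cv_series(name %||% paste0(groupA$name, "-", groupB$name), d,
            units = "A", timestep = traj$timestep)
}

#' Define an interdomain orientation angle
#'
#' The angle between two vectors, each running from a domain's geometric
#' center to an anchor residue's center (vector 1: domain1 center to anchor1;
#' vector 2: domain2 center to anchor2). Used to track the relative
#' orientation of the G-alpha helical and Ras-like domains.
#'
#' @param domain1,domain2 [residue_group()] for the two domains.
#' @param anchor1,anchor2 [residue_group()] each naming a single residue.
#' @return Object of class `angle_definition`.
#' @export
angle_definition <- function(domain1, anchor1, domain2, anchor2) {
  for (g in list(anchor1, anchor2)) {
    if (length(g$resno) != 1) {
      stop("anchor group '", g$name, "' must contain a single residue")
    }
  }
  structure(list(domain1 = domain1, anchor1 = anchor1,
                 domain2 = domain2, anchor2 = anchor2),
            class = "angle_definition")
}

#' Interdomain angle series
#'
#' @param traj A [trajectory()].
#' @param defn An [angle_definition()].
#' @param name Series name.
#' @return A [cv_series()] in degrees, values in \[0, 180\].
#' @export
interdomain_angle_series <- function(traj, defn, name = "interdomain-angle") {
  stopifnot(inherits(defn, "angle_definition"))
  v1 <- center_series(traj, defn$anchor1) - center_series(traj, defn$domain1)
  v2 <- center_series(traj, defn$anchor2) - center_series(traj, defn$domain2)
  n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  bad <- which(n1 < 1e-12 | n2 < 1e-12)
  if (length(bad) > 0) {
    stop("zero-length orientation vector at frame ", bad[1])
  }
  cosang <- rowSums(v1 * v2) / (n1 * n2)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  cv_series(name, ang, units = "degrees", timestep = traj$timestep)
}

#' RMSD time series of a residue group
#'
#' Per-frame least-squares-fit RMSD of the group's atoms to a reference:
#' either the first frame or the average structure (frames are first
#' superposed on frame 1 using the same group, then averaged). Fitting and
#' RMSD use the same atom selection.
#'
#' @param traj A [trajectory()].
#' @param group A [residue_group()] (>= 3 atoms after the subset rule).
#' @param reference "first_frame" or "average_structure".
#' @param name Series name.
#' @return A [cv_series()] in Angstrom.
#' @export
rmsd_series <- function(traj, group,
                        reference = c("first_frame", "average_structure"),
                        name = NULL) {
  reference <- match.arg(reference)
  idx <- resolve_group(traj$topology, group)
  if (length(idx) < 3) stop("need at least 3 atoms for an RMSD fit")
  xyz <- .traj_xyz(traj)
  inds <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  ref <- if (reference == "first_frame") {
    xyz[1, ]
  } else {
    sup <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                          fixed.inds = inds, mobile.inds = inds)
    colMeans(sup)
  }
  fitted <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                           fixed.inds = inds, mobile.inds = inds)
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1)
  dif <- sweep(fitted[, inds, drop = FALSE], 2, ref[inds])
  r <- sqrt(rowSums(dif^2) / length(idx))
  cv_series(name %||% paste0("rmsd-", group$name), r, units = "A",
            timestep = traj$timestep)
}

#' Mean and SD of a series over its final time window
#'
#' Averages over frames whose time is at least `duration - last_ns`
#' (inclusive at the window start); mirrors per-run summaries taken over the
#' last stretch of each production run.
#'
#' @param series A [cv_series()].
#' @param last_ns Window length in ns from the end of the series.
#' @return List with `mean`, `sd`, `n` (frames in window).
#' @export
window_average <- function(series, last_ns) {
  stopifnot(inherits(series, "cv_series"))
  dur <- cv_duration(series)
  if (last_ns > dur + series$timestep / 2) {
    stop("window of ", last_ns, " ns exceeds series duration of ", dur, " ns")
  }
  t <- cv_times(series)
  keep <- t >= (dur - last_ns) - 1e-9
  if (!any(keep)) stop("empty averaging window")
  v <- series$values[keep]
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}
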