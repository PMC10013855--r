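# coords array <-> bio3d flat xyz helpers
.traj_xyz <- function(traj) {
  nf <- n_frames(traj); natom <- dim(traj$coords)[2]
  xyz <- matrix(NA_real_, nf, 3 * natom)
  for (d in 1:3) xyz[, seq(d, by = 3, length.out = natom)] <- traj$coords[, , d]
  xyz
}

.xyz_to_array <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  natom <- ncol(xyz) / 3
  coords <- array(NA_real_, dim = c(nrow(xyz), natom, 3))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, by = 3, length.out = natom),
                                      drop = FALSE]
  coords
}

#' Geometric center of a residue group in one frame
#'
#' Unweighted arithmetic mean of the selected atom coordinates (no mass
#' weighting); all distance and angle measurements in the package are built
#' on these centers.
#'
#' @param traj A [trajectory()].
#' @param group A [residue_group()].
#' @param frame Frame index (1-based).
#' @return Numeric length-3 vector (Angstrom).
#' @export
geometric_center <- function(traj, group, frame) {
  stopifnot(inherits(traj, "trajectory"))
  if (frame < 1 || frame > n_frames(traj)) {
    stop("frame ", frame, " out of range 1..", n_frames(traj))
  }
  idx <- resolve_group(traj$topology, group)
  colMeans(matrix(traj$coords[frame, idx, ], ncol = 3))
}

#' Per-frame geometric centers of a residue group
#'
#' @param traj A [trajectory()].
#' @param group A [residue_group()].
#' @return nframes x 3 matrix of centers (Angstrom).
#' @export
center_series <- function(traj, group) {
  idx <- resolve_group(traj$topology, group)
  sub <- traj$coords[, idx, , drop = FALSE]
  apply(sub, c(1, 3), mean)
}

#' Superpose a trajectory onto a reference frame
#'
#' Rigid-body (rotation + translation) least-squares fit of every frame to a
#' chosen reference frame, minimizing the RMSD of the fit group's atoms; the
#' transform is applied to all atoms so internal geometry is unchanged.
#'
#' @param traj A [trajectory()].
#' @param reference_frame Frame index used as the fixed reference (default 1).
#' @param fit_group [residue_group()] whose atoms define the fit.
#' @return A new [trajectory()] with transformed coordinates.
#' @export
superpose <- function(traj, reference_frame = 1, fit_group) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- resolve_group(traj$topology, fit_group)
  if (length(idx) < 3) stop("need at least 3 fit atoms, got ", length(idx))
  ref_xyz <- matrix(traj$coords[reference_frame, idx, ], ncol = 3)
  if (qr(sweep(ref_xyz, 2, colMeans(ref_xyz)))$rank < 2) {
    stop("fit atoms are collinear; superposition is underdetermined")
  }
  xyz <- .traj_xyz(traj)
  inds <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  fitted <- bio3d::fit.xyz(
    fixed = xyz[reference_frame, ], mobile = xyz,
    fixed.inds = inds, mobile.inds = inds
  )
  trajectory(traj$topology, .xyz_to_array(fitted),
             timestep = traj$timestep, temperature = traj$temperature,
             boost = traj$boost)
}
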