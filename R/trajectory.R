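#' Construct a trajectory
#'
#' Carrier of per-frame coordinates together with a topology and, for boosted
#' (Gaussian-accelerated) runs, the per-frame boost potential Delta-V.
#'
#' @param top A [topology()].
#' @param coords Numeric array frames x atoms x 3 (Angstrom), or a single
#'   natoms x 3 matrix for a one-frame trajectory.
#' @param timestep Time between stored frames, ns. Must be positive.
#' @param temperature Simulation temperature in K (default 310).
#' @param boost Optional per-frame boost potential Delta-V (kcal/mol, >= 0).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(top, coords, timestep = 1, temperature = 310,
                       boost = NULL) {
  stopifnot(inherits(top, "topology"))
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] != nrow(top)) {
    stop(sprintf("coordinate array has %d atoms but topology has %d",
                 dim(coords)[2], nrow(top)))
  }
  if (!is.numeric(timestep) || timestep <= 0) stop("timestep must be > 0")
  if (!is.null(boost)) {
    if (length(boost) != dim(coords)[1]) {
      stop("boost length must equal the number of frames")
    }
    if (any(boost < 0)) stop("boost potential must be >= 0")
  }
  structure(
    list(topology = top, coords = coords, timestep = timestep,
         temperature = temperature, boost = boost),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d frames x %d atoms, dt = %g ns, T = %g K%s\n",
    n_frames(x), nrow(x$topology), x$timestep, x$temperature,
    if (is.null(x$boost)) "" else ", boosted (GaMD-style)"
  ))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Frame times in ns
#' @param traj A [trajectory()].
#' @return Numeric vector, `(0:(n-1)) * timestep`.
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$timestep

#' Read a coordinate trajectory (DCD)
#'
#' Reads a CHARMM/NAMD-style binary DCD file against a known topology.
#'
#' @param top A [topology()] whose atom count must match the file.
#' @param path Path to a DCD file.
#' @param format Only "dcd" is supported.
#' @param timestep Time between stored frames in ns (DCD headers carry the
#'   integrator step, not the save interval, so this is supplied explicitly).
#' @param temperature Simulation temperature in K.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(top, path, format = c("dcd"), timestep = 1,
                            temperature = 310) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  xyz <- tryCatch(
    bio3d::read.dcd(path, verbose = FALSE),
    error = function(e) stop("failed to read DCD '", path, "': ",
                             conditionMessage(e))
  )
  natom <- ncol(xyz) / 3
  if (natom != nrow(top)) {
    stop(sprintf("DCD has %d atoms but topology has %d", natom, nrow(top)))
  }
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nf, natom, 3))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, by = 3, length.out = natom),
                                      drop = FALSE]
  trajectory(top, coords, timestep = timestep, temperature = temperature)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Minimal single-segment DCD writer (little-endian, 4-byte Fortran record
#' markers, X/Y/Z float blocks per frame), readable by standard MD tools.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  natom <- nrow(traj$topology)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: length prefix + payload + length suffix
    raw_payload <- writer
    writeBin(as.integer(length(raw_payload)), con, size = 4,
             endian = "little")
    writeBin(raw_payload, con)
    writeBin(as.integer(length(raw_payload)), con, size = 4,
             endian = "little")
  }
  # header record: 'CORD' + 20 control integers
  icntrl <- integer(20)
  icntrl[1] <- nf       # number of frames
  icntrl[2] <- 1L       # first step
  icntrl[3] <- 1L       # save interval
  icntrl[4] <- nf       # total steps
  icntrl[20] <- 24L     # CHARMM version flag
  hdr <- c(charToRaw("CORD"), writeBin(icntrl, raw(), size = 4,
                                       endian = "little"))
  rec(hdr)
  # title record: count + one 80-char line
  title <- sprintf("%-80s", "ternarymd trajectory")
  rec(c(writeBin(1L, raw(), size = 4, endian = "little"),
        charToRaw(title)))
  # natom record
  rec(writeBin(as.integer(natom), raw(), size = 4, endian = "little"))
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      rec(writeBin(as.numeric(traj$coords[f, , d]), raw(), size = 4,
                   endian = "little"))
    }
  }
  invisible(path)
}
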