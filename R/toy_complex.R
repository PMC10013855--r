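#' Build a toy receptor-ligand complex with planted poses and contacts
#'
#' Generates a self-validating fixture for the contact and pose-clustering
#' stages: receptor residues (3 heavy atoms each) on a ring, a small rigid
#' ligand visiting `n_pose_clusters` distinct pockets with intra-pose jitter
#' far smaller than the inter-pose separation, and optionally a contact
#' script that moves chosen receptor residues within contact range of the
#' ligand for a prescribed fraction of frames. The planted ground truth
#' (pose schedule, pose centers, per-residue contact table) is emitted
#' alongside and verified geometrically at construction.
#'
#' @param n_receptor_residues Number of receptor residues (default 20).
#' @param n_pose_clusters Number of distinct ligand pockets (default 5).
#' @param frames_per_pose Frames spent in each pocket (default 20).
#' @param contact_script Optional data.frame with columns `resno` and
#'   `fraction`: residue `resno` is placed in contact with the ligand in the
#'   first `round(fraction * n_frames)` frames.
#' @param pose_jitter SD of the ligand positional jitter per frame
#'   (Angstrom, default 0.25).
#' @param ring_radius Receptor ring radius (default 14).
#' @param pocket_radius Radius of the circle carrying pose centers
#'   (default 6).
#' @param contact_distance Residue-center to ligand-center distance used
#'   when a scripted residue is in contact (default 2.5).
#' @param seed RNG seed (default 1); identical seeds give identical
#'   coordinates.
#' @return List of class `toy_complex`: `trajectory`, groups `receptor` and
#'   `ligand`, `pose_id` (per frame), `pose_centers` (k x 3), and
#'   `contact_truth` (data.frame resno, fraction, n_contact_frames).
#' @export
make_toy_complex <- function(n_receptor_residues = 20, n_pose_clusters = 5,
                             frames_per_pose = 20, contact_script = NULL,
                             pose_jitter = 0.25, ring_radius = 14,
                             pocket_radius = 6, contact_distance = 2.5,
                             seed = 1) {
  stopifnot(n_receptor_residues >= 4, n_pose_clusters >= 1,
            frames_per_pose >= 1, pose_jitter >= 0)
  set.seed(seed)
  n_frames <- n_pose_clusters * frames_per_pose
  # receptor homes: residues on a ring, 3 heavy atoms each (N, CA, C)
  ang <- 2 * pi * (seq_len(n_receptor_residues) - 1) / n_receptor_residues
  homes <- cbind(ring_radius * cos(ang), ring_radius * sin(ang), 0)
  atom_off <- rbind(c(0, 0, 0.7), c(0, 0, 0), c(0.7, 0, -0.7))
  lig_off <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(0.7, 1.2, 0))
  # pose centers on an inner circle at irregular angles and radii
  # (regular polygons make Ward merge costs degenerate in k): separation >>
  # jitter, and far enough from the ring that no unscripted residue is ever
  # within contact range
  ki <- seq_len(n_pose_clusters)
  w <- 1 + 0.12 * sin(2.7 * ki)
  pang <- 2 * pi * cumsum(w) / sum(w) + pi / 7
  prad <- pocket_radius * (1 + 0.06 * cos(1.9 * ki))
  pose_centers <- cbind(prad * cos(pang), prad * sin(pang), 0)
  pose_id <- rep(seq_len(n_pose_clusters), each = frames_per_pose)

  # contact script bookkeeping
  if (!is.null(contact_script)) {
    stopifnot(all(c("resno", "fraction") %in% names(contact_script)))
    if (anyDuplicated(contact_script$resno)) {
      stop("contact script lists a residue twice")
    }
    if (any(contact_script$fraction < 0 | contact_script$fraction > 1)) {
      stop("contact fractions must lie in [0, 1]")
    }
    if (!all(contact_script$resno %in% seq_len(n_receptor_residues))) {
      stop("contact script names residues outside the receptor")
    }
    n_contact <- round(contact_script$fraction * n_frames)
  } else {
    contact_script <- data.frame(resno = integer(0), fraction = numeric(0))
    n_contact <- integer(0)
  }

  nR <- 3 * n_receptor_residues
  top <- topology(
    atom_id = seq_len(nR + 3),
    atom_name = c(rep(c("N", "CA", "C"), n_receptor_residues),
                  c("C1", "C2", "C3")),
    element = c(rep(c("N", "C", "C"), n_receptor_residues),
                rep("C", 3)),
    resno = c(rep(seq_len(n_receptor_residues), each = 3), rep(1L, 3)),
    resname = c(rep("ALA", nR), rep("LIG", 3)),
    chain = c(rep("R", nR), rep("L", 3))
  )
  coords <- array(NA_real_, dim = c(n_frames, nR + 3, 3))
  lig_centers <- pose_centers[pose_id, , drop = FALSE] +
    matrix(stats::rnorm(3 * n_frames, sd = pose_jitter), ncol = 3)
  # scripted residues dock from distinct directions on an upper-hemisphere
  # cone so simultaneous contacts never collide with each other or the
  # (planar) ligand
  n_script <- length(contact_script$resno)
  if (n_script > 0) {
    theta <- 50 * pi / 180
    phi <- 2 * pi * (seq_len(n_script) - 1) / n_script
    dock_dir <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi),
                      rep(cos(theta), n_script))
  }
  for (f in seq_len(n_frames)) {
    res_pos <- homes
    for (si in seq_len(n_script)) {
      if (f <= n_contact[si]) {
        r <- contact_script$resno[si]
        res_pos[r, ] <- lig_centers[f, ] + contact_distance * dock_dir[si, ]
      }
    }
    rec_atoms <- res_pos[rep(seq_len(n_receptor_residues), each = 3), ] +
      atom_off[rep(1:3, n_receptor_residues), ]
    lig_atoms <- matrix(lig_centers[f, ], 3, 3, byrow = TRUE) + lig_off
    coords[f, , ] <- rbind(rec_atoms, lig_atoms)
  }
  traj <- trajectory(top, coords, timestep = 1)
  receptor <- residue_group("receptor", seq_len(n_receptor_residues),
                            chain = "R")
  ligand <- residue_group("ligand", 1L, chain = "L")

  # self-validation: the scripted contact table must be geometrically true
  tc <- structure(
    list(trajectory = traj, receptor = receptor, ligand = ligand,
         pose_id = pose_id, pose_centers = pose_centers,
         contact_truth = data.frame(resno = contact_script$resno,
                                    fraction = contact_script$fraction,
                                    n_contact_frames = n_contact)),
    class = "toy_complex")
  .validate_toy_complex(tc)
  tc
}

.validate_toy_complex <- function(tc, cutoff = 3.0) {
  traj <- tc$trajectory
  truth <- tc$contact_truth
  if (nrow(truth) == 0) return(invisible(tc))
  prof_frames <- seq_len(n_frames(traj))
  for (si in seq_len(nrow(truth))) {
    grp <- residue_group("scripted", truth$resno[si], chain = "R")
    hit <- vapply(prof_frames, function(f) {
      nrow(frame_contacts(traj, f, tc$ligand, grp, cutoff)) > 0
    }, logical(1))
    expect_frames <- seq_len(truth$n_contact_frames[si])
    other_frames <- setdiff(prof_frames, expect_frames)
    ok <- all(hit[expect_frames]) && !any(hit[other_frames])
    if (!ok) {
      stop("infeasible contact script: residue ", truth$resno[si],
           " contact geometry could not be realized")
    }
  }
  # scripted residues must not collide with each other or the ligand
  for (f in prof_frames) {
    d <- .cross_dist(matrix(traj$coords[f, , ], ncol = 3),
                     matrix(traj$coords[f, , ], ncol = 3))
    diag(d) <- Inf
    if (min(d) < 0.5) {
      stop("infeasible contact script: atom collision in frame ", f)
    }
  }
  invisible(tc)
}

#' Write a toy complex as PDB + DCD + ground-truth JSON
#'
#' @param tc A [make_toy_complex()] result.
#' @param dir Output directory (created if absent).
#' @param name Basename for the three files (default "toy_complex").
#' @return Named list of the written paths, invisibly.
#' @export
write_toy_complex <- function(tc, dir, name = "toy_complex") {
  stopifnot(inherits(tc, "toy_complex"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pdb <- file.path(dir, paste0(name, ".pdb"))
  dcd <- file.path(dir, paste0(name, ".dcd"))
  json <- file.path(dir, paste0(name, "_truth.json"))
  write_structure(tc$trajectory$topology,
                  matrix(tc$trajectory$coords[1, , ], ncol = 3), pdb)
  write_dcd(tc$trajectory, dcd)
  jsonlite::write_json(
    list(pose_id = tc$pose_id,
         pose_centers = tc$pose_centers,
         contact_truth = tc$contact_truth),
    json, auto_unbox = TRUE, digits = NA)
  invisible(list(pdb = pdb, dcd = dcd, truth = json))
}
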