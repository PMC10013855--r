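# pairwise distance matrix between two coordinate blocks (rows = atoms)
.cross_dist <- function(A, B) {
  # |a-b|^2 = |a|^2 + |b|^2 - 2 a.b  (clamped for rounding)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Residues of a target group in contact with a probe in one frame
#'
#' A target residue is in contact when the minimum atom-pair distance between
#' any of its atoms and any probe atom is within the cutoff (boundary counts
#' as contact). Residues belonging to the probe group are never reported.
#'
#' @param traj A [trajectory()].
#' @param frame Frame index.
#' @param probe,target [residue_group()] selections (heavy atoms by default).
#' @param cutoff Contact cutoff in Angstrom (default 3.0).
#' @return data.frame with columns `chain`, `resno`, `resname`, `min_dist`
#'   for the residues in contact.
#' @export
frame_contacts <- function(traj, frame, probe, target, cutoff = 3.0) {
  prof <- .contact_fractions(traj, probe, target, cutoff, frames = frame)
  prof[prof$contact_fraction > 0,
       c("chain", "resno", "resname", "min_dist")]
}

# core: per-residue contact fractions over a set of frames
.contact_fractions <- function(traj, probe, target, cutoff,
                               frames = seq_len(n_frames(traj))) {
  stopifnot(inherits(traj, "trajectory"), cutoff > 0)
  top <- traj$topology
  ip <- resolve_group(top, probe)
  it <- resolve_group(top, target)
  # self-contact exclusion: drop target residues present in the probe group
  probe_res <- unique(paste(top$chain[ip], top$resno[ip]))
  t_res_key <- paste(top$chain[it], top$resno[it])
  it <- it[!(t_res_key %in% probe_res)]
  if (length(it) == 0) {
    stop("no target residues remain after excluding probe residues ",
         "(probe and target fully overlap)")
  }
  t_key <- paste(top$chain[it], top$resno[it])
  res_keys <- unique(t_key)
  res_rows <- match(res_keys, t_key)
  nres <- length(res_keys)
  hits <- integer(nres)
  min_d <- rep(Inf, nres)
  grp <- factor(t_key, levels = res_keys)
  for (f in frames) {
    P <- matrix(traj$coords[f, ip, ], ncol = 3)
    Tm <- matrix(traj$coords[f, it, ], ncol = 3)
    dmin_atom <- apply(.cross_dist(Tm, P), 1, min)
    dmin_res <- tapply(dmin_atom, grp, min)
    hits <- hits + as.integer(dmin_res <= cutoff)
    min_d <- pmin(min_d, as.numeric(dmin_res))
  }
  data.frame(
    chain = top$chain[it][res_rows],
    resno = top$resno[it][res_rows],
    resname = top$resname[it][res_rows],
    contact_fraction = hits / length(frames),
    min_dist = min_d,
    stringsAsFactors = FALSE
  )
}

#' Persistent-contact profile of a target relative to a probe
#'
#' Computes, for every target residue, the fraction of frames in which it is
#' within `cutoff` of the probe; the persistent set is the residues whose
#' fraction is strictly greater than `persistence` ("more than half of the
#' frames" at the default 0.5).
#'
#' @inheritParams frame_contacts
#' @param persistence Persistence threshold in \[0, 1\) (default 0.5).
#' @param frames Optional frame indices to restrict the analysis window.
#' @return Object of class `contact_profile`: a data.frame
#'   (`chain, resno, resname, contact_fraction, persistent`) with the
#'   cutoff/persistence settings as attributes.
#' @export
persistent_contacts <- function(traj, probe, target, cutoff = 3.0,
                                persistence = 0.5,
                                frames = seq_len(n_frames(traj))) {
  if (length(frames) < 1) stop("need at least one frame")
  prof <- .contact_fractions(traj, probe, target, cutoff, frames)
  prof$persistent <- prof$contact_fraction > persistence
  attr(prof, "cutoff") <- cutoff
  attr(prof, "persistence") <- persistence
  attr(prof, "n_frames") <- length(frames)
  class(prof) <- c("contact_profile", "data.frame")
  prof
}

#' Mean percentage interaction time over a residue subset
#'
#' 100 x the mean contact fraction over the chosen residues; by default the
#' persistent set of the profile (the "average percentage interaction time"
#' of an interface).
#'
#' @param profile A `contact_profile`.
#' @param subset Optional integer vector of residue numbers; default: the
#'   persistent residues.
#' @return Percentage in \[0, 100\].
#' @export
mean_interaction_time <- function(profile, subset = NULL) {
  stopifnot(inherits(profile, "contact_profile"))
  keep <- if (is.null(subset)) profile$persistent else profile$resno %in% subset
  if (!any(keep)) stop("empty residue subset for interaction time")
  100 * mean(profile$contact_fraction[keep])
}

#' Number of persistent interface residues
#'
#' Size of the persistent-contact set of `target` relative to `probe` over a
#' frame window; the per-interface residue counts of the
#' protein-protein-interface summaries.
#'
#' @inheritParams persistent_contacts
#' @return Integer count.
#' @export
interface_residue_count <- function(traj, probe, target, cutoff = 3.0,
                                    persistence = 0.5,
                                    frames = seq_len(n_frames(traj))) {
  prof <- persistent_contacts(traj, probe, target, cutoff, persistence,
                              frames)
  sum(prof$persistent)
}

#' Write a contact profile as CSV
#'
#' @param profile A `contact_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
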