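#' Synthetic open-state G-alpha CA-trace model
#'
#' Builds a synthetic (not experimentally derived) CA-only model of a
#' G-alpha subunit in the open state: two compact domains -- an alpha-helical
#' domain (residues 88-202, carrying the A161 anchor) and a Ras-like domain
#' (residues 1-87 and 203-394, carrying the E299 anchor) -- as confined
#' CA random walks with 3.8 Angstrom virtual bonds, positioned so the
#' A161-E299 CA separation equals `open_distance`. It exercises the
#' structure pathway (PDB round trip, residue-group resolution, center
#' distances, state classification) without any downloaded coordinates; it
#' is a geometric stand-in, not a model of the real fold.
#'
#' @param open_distance Target A161-E299 distance (Angstrom, default 62).
#' @param seed RNG seed (default 42).
#' @return List with `topology` ([topology()]) and `coords` (natoms x 3).
#' @export
make_synthetic_gsa_open <- function(open_distance = 62, seed = 42) {
  set.seed(seed)
  ah_res <- 88:202
  ras_res <- c(1:87, 203:394)
  blob <- function(n, radius) {
    # CA random walk with 3.8 A steps, reflected into a sphere
    pos <- matrix(0, n, 3)
    for (i in 2:n) {
      repeat {
        step <- stats::rnorm(3)
        cand <- pos[i - 1, ] + 3.8 * step / sqrt(sum(step^2))
        if (sqrt(sum(cand^2)) <= radius) break
      }
      pos[i, ] <- cand
    }
    sweep(pos, 2, colMeans(pos))
  }
  ah <- blob(length(ah_res), 16)
  ras <- blob(length(ras_res), 20)
  # translate the Ras domain along x so the anchor CA pair sits at the
  # requested open-state separation
  ca161 <- ah[match(161, ah_res), ]
  ca299_0 <- ras[match(299, ras_res), ]
  f <- function(t) sqrt(sum((ca299_0 + c(t, 0, 0) - ca161)^2)) - open_distance
  t_star <- stats::uniroot(f, c(0, open_distance + 80))$root
  ras <- sweep(ras, 2, c(t_star, 0, 0), "+")
  resno <- c(ah_res, ras_res)
  ord <- order(resno)
  coords <- rbind(ah, ras)[ord, ]
  resno <- resno[ord]
  n <- length(resno)
  top <- topology(
    atom_id = seq_len(n), atom_name = rep("CA", n),
    element = rep("C", n), resno = resno,
    resname = rep("ALA", n), chain = rep("A", n)
  )
  list(topology = top, coords = coords)
}
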