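#' Read a per-frame energy-component table
#'
#' CSV schema: `frame,time_ns,elec,vdw,polar,nonpolar[,gas_interaction][,deltaV]`.
#' The four components are the MM-PBSA enthalpy terms (gas-phase
#' electrostatics, van der Waals, polar solvation, nonpolar solvation) in
#' kcal/mol; `gas_interaction` feeds the interaction-entropy estimator and
#' `deltaV` is the per-frame boost for reweighted averages.
#'
#' @param path CSV path.
#' @return data.frame of class `energy_series` with a `timestep` attribute.
#' @export
read_energy_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_ns", "elec", "vdw", "polar", "nonpolar")
  if (!all(need %in% names(df))) {
    stop("energy csv must have columns: ", paste(need, collapse = ", "))
  }
  num_cols <- setdiff(names(df), "frame")
  if (any(!vapply(df[num_cols], is.numeric, logical(1))) ||
      any(!is.finite(as.matrix(df[num_cols])))) {
    stop("energy components must be finite numerics")
  }
  attr(df, "timestep") <- if (nrow(df) > 1) df$time_ns[2] - df$time_ns[1] else 1
  class(df) <- c("energy_series", "data.frame")
  df
}

# restrict an energy table to a time window [t0, t1] (ns, inclusive)
.energy_window <- function(series, window) {
  if (is.null(window)) return(series)
  keep <- series$time_ns >= window[1] - 1e-9 & series$time_ns <= window[2] + 1e-9
  if (!any(keep)) stop("empty energy window")
  series[keep, , drop = FALSE]
}

#' Mean enthalpy from an energy-component table
#'
#' Mean over frames of the sum of the four MM-PBSA components.
#'
#' @param series An `energy_series` (see [read_energy_csv()]).
#' @param window Optional `c(t0, t1)` time window in ns.
#' @return Mean enthalpy dH in kcal/mol.
#' @export
mean_enthalpy <- function(series, window = NULL) {
  s <- .energy_window(series, window)
  mean(s$elec + s$vdw + s$polar + s$nonpolar)
}

#' Interaction entropy, -T dS, from interaction-energy fluctuations
#'
#' -T dS = kB T ln < exp(beta dE) > with dE the fluctuation of the gas-phase
#' interaction energy about its mean. The exponential average is evaluated
#' with log-sum-exp stabilization; the result is non-negative by Jensen's
#' inequality and exactly zero for a constant series.
#'
#' @param gas_interaction Per-frame gas-phase interaction energies (kcal/mol).
#' @param temperature Temperature in K (default 310).
#' @return -T dS in kcal/mol (>= 0).
#' @export
interaction_entropy <- function(gas_interaction, temperature = 310) {
  x <- as.numeric(gas_interaction)
  if (length(x) < 2) stop("need at least 2 frames for interaction entropy")
  if (any(!is.finite(x))) stop("interaction energies must be finite")
  kT <- kt_kcalmol(temperature)
  f <- (x - mean(x)) / kT
  val <- kT * (logsumexp(f) - log(length(f)))
  max(val, 0)
}

#' Assemble a binding free energy
#'
#' dG = dH + (-T dS), the end-point MM-PBSA decomposition; the identity is
#' exact by construction.
#'
#' @param dH Enthalpy, kcal/mol.
#' @param minus_TdS Entropic term -T dS, kcal/mol.
#' @param sem Optional block-average standard error for dG.
#' @return Object of class `binding_energy`: list(dH, minus_TdS, dG, sem).
#' @export
assemble_dG <- function(dH, minus_TdS, sem = NA_real_) {
  stopifnot(is.finite(dH), is.finite(minus_TdS))
  structure(list(dH = dH, minus_TdS = minus_TdS, dG = dH + minus_TdS,
                 sem = sem),
            class = "binding_energy")
}

#' @export
print.binding_energy <- function(x, ...) {
  cat(sprintf("dH = %.2f  -TdS = %.2f  dG = %.2f%s kcal/mol\n",
              x$dH, x$minus_TdS, x$dG,
              if (is.finite(x$sem)) sprintf(" +/- %.2f", x$sem) else ""))
  invisible(x)
}

#' Block-average standard error of the mean
#'
#' Splits the series into `n_blocks` contiguous equal blocks (any trailing
#' remainder is dropped), and reports SD(block means) / sqrt(n_blocks).
#'
#' @param x Numeric series.
#' @param n_blocks Number of blocks (default 5).
#' @return SEM of the series mean.
#' @export
block_sem <- function(x, n_blocks = 5) {
  x <- as.numeric(x)
  if (n_blocks < 2) stop("need at least 2 blocks")
  if (length(x) < n_blocks) stop("series shorter than the block count")
  bs <- length(x) %/% n_blocks
  means <- vapply(seq_len(n_blocks), function(b) {
    mean(x[((b - 1) * bs + 1):(b * bs)])
  }, numeric(1))
  stats::sd(means) / sqrt(n_blocks)
}

#' Reweighted mean energy from a boosted ensemble
#'
#' Histograms the per-frame energies (bin width 0.5 kcal/mol by default),
#' recovers each bin's unbiased free energy W through the cumulant-expansion
#' reweighting of [pmf_reweighted()] applied to the energy coordinate, forms
#' bin probabilities P = exp(-beta W), and returns
#' sum(P * Ebin) / sum(P) with Ebin the mean biased-ensemble energy of the
#' bin. With a uniform (or absent) boost this equals the count-weighted mean
#' of bin means, i.e. the plain mean up to the histogram discretization.
#'
#' @param energies Per-frame energies (kcal/mol).
#' @param deltaV Per-frame boost potential (kcal/mol); `NULL` for unbiased.
#' @param temperature Temperature in K (default 310).
#' @param bin_width Energy bin width, kcal/mol (default 0.5).
#' @return Reweighted mean energy, kcal/mol.
#' @export
reweight_energy <- function(energies, deltaV = NULL, temperature = 310,
                            bin_width = 0.5) {
  energies <- as.numeric(energies)
  if (length(energies) == 0) stop("empty energy series")
  pmf <- pmf_reweighted(energies, deltaV, bin_width = bin_width,
                        count_cutoff = 1, temperature = temperature)
  kT <- kt_kcalmol(temperature)
  edges <- pmf$edges[[1]]
  bins <- .bin_index(energies, edges)
  ebin <- tapply(energies, factor(bins, levels = seq_along(pmf$W)), mean)
  keep <- !pmf$mask & pmf$counts > 0
  P <- exp(-pmf$W[keep] / kT)
  sum(P * as.numeric(ebin[keep])) / sum(P)
}

#' Toy gas-phase interaction energy between two atom groups
#'
#' Coulomb (332.0636 q_i q_j / r, kcal/mol with charges in e and r in
#' Angstrom) plus 12-6 Lennard-Jones with Lorentz-Berthelot combination,
#' summed over all inter-group pairs with no cutoff. A self-contained
#' evaluator for end-to-end tests of the entropy/averaging machinery.
#'
#' @param coordsA,coordsB natoms x 3 coordinate matrices (Angstrom).
#' @param chargesA,chargesB Per-atom charges (e).
#' @param ljA,ljB data.frames with columns `epsilon` (kcal/mol) and `sigma`
#'   (Angstrom), one row per atom.
#' @return List with `electrostatic` and `van_der_waals` (kcal/mol).
#' @export
toy_interaction_energy <- function(coordsA, coordsB, chargesA, chargesB,
                                   ljA, ljB) {
  stopifnot(nrow(coordsA) == length(chargesA), nrow(ljA) == length(chargesA),
            nrow(coordsB) == length(chargesB), nrow(ljB) == length(chargesB))
  r <- .cross_dist(as.matrix(coordsA), as.matrix(coordsB))
  if (any(r < 0.01)) stop("overlapping atoms (r < 0.01 A)")
  qq <- outer(chargesA, chargesB)
  elec <- COULOMB_KCALMOL * sum(qq / r)
  eps <- sqrt(outer(ljA$epsilon, ljB$epsilon))
  sig <- outer(ljA$sigma, ljB$sigma, function(a, b) (a + b) / 2)
  sr6 <- (sig / r)^6
  vdw <- sum(4 * eps * (sr6^2 - sr6))
  list(electrostatic = elec, van_der_waals = vdw)
}
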