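#' Overdamped Langevin (Brownian) dynamics on a 1D potential
#'
#' Euler-Maruyama integration of overdamped Langevin dynamics,
#' x <- x - beta D V'(x) dt + sqrt(2 D dt) xi, whose stationary density is
#' the Boltzmann distribution exp(-V/kBT)/Z. Only equilibrium populations
#' and correlation structure matter for testing the estimators, so inertial
#' (underdamped) kinetics are deliberately not modelled. With a
#' [gamd_boost()] the dynamics run on the boosted potential V + Delta-V and
#' the per-frame boost energy is recorded, emulating a
#' Gaussian-accelerated run.
#'
#' @param potential A [potential1d()].
#' @param temperature Temperature in K (default 310).
#' @param diffusion Diffusion coefficient D of the collective variable
#'   (Angstrom^2/ns, default 50).
#' @param dt Integration/sampling timestep (ns). Stability requires
#'   dt <= 2 / (beta D kmax) for the stiffest curvature kmax; violating it
#'   is an error reporting the largest admissible dt.
#' @param n_steps Number of recorded steps.
#' @param x0 Initial position; defaults to the domain midpoint.
#' @param boost Optional [gamd_boost()] specification.
#' @param seed Optional RNG seed; identical seeds give identical series.
#' @return A [cv_series()] named "langevin-cv" (units Angstrom) with, when
#'   boosted, the per-frame Delta-V attached as attribute `deltaV`.
#' @export
simulate_langevin <- function(potential, temperature = 310, diffusion = 50,
                              dt = 0.01, n_steps = 1e5, x0 = NULL,
                              boost = NULL, seed = NULL) {
  stopifnot(inherits(potential, "potential1d"), dt > 0, n_steps >= 1)
  if (!is.null(boost)) stopifnot(inherits(boost, "boost_spec"))
  kT <- kt_kcalmol(temperature)
  beta <- 1 / kT
  grad <- if (is.null(boost)) {
    potential$dV
  } else {
    function(x) potential$dV(x) + boost$ddeltaV(x)
  }
  # stability: estimate the stiffest curvature of the effective potential
  grid <- seq(potential$domain[1], potential$domain[2], length.out = 2001)
  h <- grid[2] - grid[1]
  kmax <- max(abs(diff(grad(grid)) / h))
  dt_max <- 2 / (beta * diffusion * kmax)
  if (dt > dt_max) {
    stop(sprintf(
      "unstable timestep: dt = %g ns exceeds the stability limit %.4g ns for this potential/diffusion; reduce dt",
      dt, dt_max))
  }
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n_steps)
  xi <- stats::rnorm(n_steps)
  amp <- sqrt(2 * diffusion * dt)
  drift <- beta * diffusion * dt
  pos <- x0 %||% mean(potential$domain)
  for (i in seq_len(n_steps)) {
    pos <- pos - drift * grad(pos) + amp * xi[i]
    x[i] <- pos
  }
  out <- cv_series("langevin-cv", x, units = "A", timestep = dt)
  if (!is.null(boost)) attr(out, "deltaV") <- boost$deltaV(x)
  out
}

#' Generate a pair of CV series with prescribed correlation (and lag)
#'
#' `gaussian_iid`: y = rho x + sqrt(1 - rho^2) e with iid standard normals,
#' so the population correlation is exactly rho. `ou`: both series are
#' Ornstein-Uhlenbeck processes with correlation time `tau_ns`; y mixes the
#' lag-shifted x with an independent OU innovation, so the cross-correlation
#' peaks at the requested lag with peak height rho.
#'
#' @param rho Target correlation in (-1, 1).
#' @param n Series length.
#' @param process "gaussian_iid" or "ou".
#' @param lag Lag of y behind x in ns (OU only; default 0).
#' @param timestep Sample spacing in ns (default 1).
#' @param tau_ns OU correlation time (default 10 ns).
#' @param seed Optional RNG seed.
#' @return List with elements `x` and `y`, both [cv_series()].
#' @export
correlated_cv_pair <- function(rho, n, process = c("gaussian_iid", "ou"),
                               lag = 0, timestep = 1, tau_ns = 10,
                               seed = NULL) {
  process <- match.arg(process)
  if (abs(rho) >= 1) stop("rho must be in (-1, 1)")
  if (!is.null(seed)) set.seed(seed)
  L <- round(lag / timestep)
  if (process == "gaussian_iid") {
    if (L != 0) stop("lag is only supported for the OU process")
    xv <- stats::rnorm(n)
    yv <- rho * xv + sqrt(1 - rho^2) * stats::rnorm(n)
  } else {
    phi <- exp(-timestep / tau_ns)
    innov_sd <- sqrt(1 - phi^2)
    ou <- function(m) {
      z <- numeric(m)
      e <- stats::rnorm(m, sd = innov_sd)
      z[1] <- stats::rnorm(1)
      for (i in 2:m) z[i] <- phi * z[i - 1] + e[i]
      z
    }
    xf <- ou(n + L)
    ef <- ou(n)
    xv <- xf[(L + 1):(L + n)]
    yv <- rho * xf[seq_len(n)] + sqrt(1 - rho^2) * ef
  }
  list(x = cv_series("cv-x", xv, units = "A", timestep = timestep),
       y = cv_series("cv-y", yv, units = "A", timestep = timestep))
}
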