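#' Construct a 1D potential
#'
#' Container for an analytic 1D potential: energy and gradient functions, a
#' recommended domain, and the defining parameters. Used by the Langevin
#' generator and as the ground truth for PMF parameter-recovery tests.
#'
#' @param kind "harmonic", "double_well" or "tabulated".
#' @param V Vectorized energy function (kcal/mol).
#' @param dV Vectorized gradient function (kcal/mol/Angstrom).
#' @param domain Length-2 numeric, the simulation domain (Angstrom).
#' @param params Named list of defining parameters.
#' @return Object of class `potential1d`.
#' @export
potential1d <- function(kind, V, dV, domain, params = list()) {
  stopifnot(is.function(V), is.function(dV), length(domain) == 2,
            domain[1] < domain[2])
  structure(list(kind = kind, V = V, dV = dV, domain = domain,
                 params = params),
            class = "potential1d")
}

#' @export
print.potential1d <- function(x, ...) {
  cat(sprintf("potential1d (%s) on [%.1f, %.1f]\n", x$kind,
              x$domain[1], x$domain[2]))
  if (length(x$params)) utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

#' Harmonic potential
#'
#' V(x) = k/2 (x - center)^2.
#'
#' @param center Minimum position (Angstrom).
#' @param k Force constant (kcal/mol/Angstrom^2).
#' @param width Domain half-width around the center (default 10).
#' @return A [potential1d()].
#' @export
potential_harmonic <- function(center = 0, k = 1, width = 10) {
  force(center); force(k)
  potential1d("harmonic",
              V = function(x) 0.5 * k * (x - center)^2,
              dV = function(x) k * (x - center),
              domain = c(center - width, center + width),
              params = list(center = center, k = k))
}

#' Calibrated double-well opening potential
#'
#' Quartic double well with minima pinned exactly at the closed and open
#' positions of the G-alpha opening coordinate (defaults 34 and 62 Angstrom,
#' the endpoints observed for the opening transition), a saddle `barrier`
#' kcal/mol above the lower minimum, and a well-depth difference `asymmetry`
#' (positive = open well lower, the energetically favored state). The
#' gradient is the cubic c (x-a)(x-s)(x-b); the saddle position s and scale
#' c are solved so the barrier and asymmetry are met exactly, which requires
#' barrier > |asymmetry|.
#'
#' @param closed_pos,open_pos Minima positions (Angstrom), closed < open.
#' @param barrier Saddle height above the lower minimum (kcal/mol, > 0).
#' @param asymmetry V(closed) - V(open) (kcal/mol); 0 gives symmetric wells.
#' @return A [potential1d()] with params `closed_pos, open_pos, saddle_pos,
#'   barrier, asymmetry, c`.
#' @export
make_opening_double_well <- function(closed_pos = 34, open_pos = 62,
                                     barrier = 2.5, asymmetry = 1.0) {
  a <- closed_pos; b <- open_pos
  if (!(b > a)) stop("open_pos must exceed closed_pos")
  if (barrier <= 0) stop("barrier must be positive")
  if (barrier <= abs(asymmetry)) {
    stop("infeasible parameters: barrier must exceed |asymmetry| ",
         "(the saddle must sit above both wells)")
  }
  # antiderivative of (t-a)(t-s)(t-b), anchored at a
  P <- function(x, s) {
    Q <- function(t) t^4 / 4 - (a + s + b) * t^3 / 3 +
      (a * b + a * s + s * b) * t^2 / 2 - a * s * b * t
    Q(x) - Q(a)
  }
  mid <- (a + b) / 2
  eps <- (b - a) * 1e-6
  if (abs(asymmetry) < 1e-12) {
    s <- mid
    cc <- barrier / P(s, s)
  } else if (asymmetry > 0) {
    # open well lower: saddle left of midpoint; ratio matches barrier/asym
    g <- function(s) (P(s, s) - P(b, s)) / (-P(b, s)) - barrier / asymmetry
    s <- stats::uniroot(g, c(a + eps, mid - eps), tol = 1e-12)$root
    cc <- asymmetry / (-P(b, s))
  } else {
    g <- function(s) P(s, s) / P(b, s) - barrier / (-asymmetry)
    s <- stats::uniroot(g, c(mid + eps, b - eps), tol = 1e-12)$root
    cc <- (-asymmetry) / P(b, s)
  }
  pad <- 0.15 * (b - a)
  potential1d(
    "double_well",
    V = function(x) cc * P(x, s),
    dV = function(x) cc * (x - a) * (x - s) * (x - b),
    domain = c(a - pad, b + pad),
    params = list(closed_pos = a, open_pos = b, saddle_pos = s,
                  barrier = barrier, asymmetry = asymmetry, c = cc)
  )
}

#' Tabulated potential from samples
#'
#' Monotone-free spline interpolation of tabulated (x, V) values.
#'
#' @param x,V Equal-length numeric vectors.
#' @return A [potential1d()].
#' @export
potential_tabulated <- function(x, V) {
  stopifnot(length(x) == length(V), length(x) >= 4)
  f <- stats::splinefun(x, V, method = "natural")
  potential1d("tabulated",
              V = function(z) f(z),
              dV = function(z) f(z, deriv = 1),
              domain = range(x))
}

#' GaMD-style harmonic boost specification
#'
#' Boost Delta-V(x) = k/2 (E - V(x))^2 for V(x) < E, else 0 -- the harmonic
#' boost form of Gaussian-accelerated MD with the reference energy at the
#' lower bound: E is set to the maximum of V over the domain and
#' k = k0 / (E - Vmin) with k0 in (0, 1].
#'
#' @param potential A [potential1d()].
#' @param k0 Effective harmonic constant fraction in (0, 1] (default 1).
#' @param domain Optional domain override for locating Vmin/Vmax.
#' @return Object of class `boost_spec` with fields `E`, `k`, `deltaV(x)`
#'   and `ddeltaV(x)` (gradient of the boost).
#' @export
gamd_boost <- function(potential, k0 = 1, domain = NULL) {
  stopifnot(inherits(potential, "potential1d"))
  if (k0 <= 0 || k0 > 1) stop("k0 must be in (0, 1]")
  dom <- domain %||% potential$domain
  grid <- seq(dom[1], dom[2], length.out = 2001)
  Vg <- potential$V(grid)
  E <- max(Vg)
  k <- k0 / (E - min(Vg))
  V <- potential$V; dV <- potential$dV
  structure(list(
    E = E, k = k, k0 = k0,
    deltaV = function(x) {
      v <- V(x)
      ifelse(v < E, 0.5 * k * (E - v)^2, 0)
    },
    ddeltaV = function(x) {
      v <- V(x)
      ifelse(v < E, -k * (E - v) * dV(x), 0)
    }
  ), class = "boost_spec")
}
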