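#' Physical constants
#'
#' Boltzmann constant in kcal/mol/K and the Coulomb conversion factor in
#' kcal mol^-1 A e^-2, the conventional molecular-mechanics values.
#'
#' @format Named numeric scalars.
#' @name constants
NULL

#' @rdname constants
#' @export
KB_KCALMOL <- 0.0019872041

#' @rdname constants
#' @export
COULOMB_KCALMOL <- 332.0636

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.
#' @return kB * T in kcal/mol. At 310 K this is about 0.616 kcal/mol.
#' @export
kt_kcalmol <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB_KCALMOL * temperature
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
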