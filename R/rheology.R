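#' Blood rheology (Carreau shear-thinning model)
#'
#' Parameter set for the Carreau apparent-viscosity law used by the flow
#' solver: density plus the zero-shear viscosity `mu0`, infinite-shear
#' viscosity `mu_inf`, relaxation time `lambda` and power index `n`.
#' Defaults are standard whole-blood values.
#'
#' @param density kg/m^3.
#' @param mu0 zero-shear viscosity, Pa s.
#' @param mu_inf infinite-shear viscosity, Pa s.
#' @param lambda relaxation time, s.
#' @param n power index (0 < n < 1).
#' @return object of class `blood_rheology`.
#' @export
blood_rheology <- function(density = 1057, mu0 = 0.056, mu_inf = 0.0035,
                           lambda = 3.313, n = 0.3568) {
  stopifnot(mu_inf < mu0, lambda > 0, n > 0, n < 1, density > 0)
  structure(list(density = density, mu0 = mu0, mu_inf = mu_inf,
                 lambda = lambda, n = n), class = "blood_rheology")
}

#' Carreau apparent viscosity
#'
#' `mu = mu_inf + (mu0 - mu_inf) * (1 + (lambda * gdot)^2)^((n - 1) / 2)`,
#' continuous and monotone decreasing in the shear rate.
#'
#' @param shear_rate shear rate gamma-dot, 1/s (vectorized, must be >= 0).
#' @param rheology a [blood_rheology()].
#' @return apparent viscosity, Pa s.
#' @examples
#' carreau_viscosity(0, blood_rheology())     # zero-shear limit 0.056
#' carreau_viscosity(1e9, blood_rheology())   # -> 0.0035
#' @export
carreau_viscosity <- function(shear_rate, rheology = blood_rheology()) {
  if (any(shear_rate < 0)) stop("shear_rate must be >= 0", call. = FALSE)
  rheology$mu_inf + (rheology$mu0 - rheology$mu_inf) *
    (1 + (rheology$lambda * shear_rate)^2)^((rheology$n - 1) / 2)
}
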