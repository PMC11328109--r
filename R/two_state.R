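#' Two-state denaturation parameters
#'
#' Bundle of the three thermodynamic parameters that define a reversible
#' two-state unfolding transition N <-> D: the denaturation temperature
#' \eqn{T_d}, the denaturation enthalpy at \eqn{T_d}, and the (temperature
#' independent) heat-capacity change upon denaturation.
#'
#' @param td denaturation temperature. Kelvin unless `celsius = TRUE`.
#' @param dhd denaturation enthalpy change at `td`, kJ/mol. Must be positive.
#' @param dcp heat-capacity change upon denaturation, kJ/(K mol). Must be
#'   non-negative.
#' @param celsius if `TRUE`, `td` is given in Celsius and converted.
#' @return an object of class `two_state_params`.
#' @examples
#' two_state_params(102.6, 470, 5.2, celsius = TRUE)
#' @export
two_state_params <- function(td, dhd, dcp = 0, celsius = FALSE) {
  if (celsius) td <- celsius_to_kelvin(td)
  stopifnot(is.numeric(td), length(td) == 1L, is.finite(td),
            is.numeric(dhd), length(dhd) == 1L, is.finite(dhd),
            is.numeric(dcp), length(dcp) == 1L, is.finite(dcp))
  if (td <= 0) stop("td must be positive (Kelvin)")
  if (dhd <= 0) stop("dhd must be positive")
  if (dcp < 0) stop("dcp must be non-negative")
  structure(list(td = td, dhd = dhd, dcp = dcp), class = "two_state_params")
}

#' @export
print.two_state_params <- function(x, ...) {
  cat(sprintf("Two-state parameters: Td = %.2f K (%.2f C), dHd = %.1f kJ/mol, dCp = %.2f kJ/(K mol)\n",
              x$td, kelvin_to_celsius(x$td), x$dhd, x$dcp))
  invisible(x)
}

#' Gibbs free energy of denaturation
#'
#' Gibbs-Helmholtz form with temperature-independent \eqn{\Delta C_p}:
#' \deqn{\Delta G_d(T) = \Delta H_d (1 - T/T_d) +
#'   \Delta C_p [(T - T_d) - T \ln(T/T_d)]}
#' It is zero at \eqn{T_d} by construction and its slope there is
#' \eqn{-\Delta H_d / T_d}.
#'
#' @param temperature temperatures in Kelvin (vectorized).
#' @param params a [two_state_params()] object.
#' @return \eqn{\Delta G_d(T)} in kJ/mol.
#' @examples
#' p <- two_state_params(375.75, 470)
#' delta_g(375.75, p)       # 0 at Td
#' delta_g(365.75, p)       # ~12.5 kJ/mol
#' @export
delta_g <- function(temperature, params) {
  stopifnot(inherits(params, "two_state_params"))
  if (any(temperature <= 0)) stop("temperature must be positive (Kelvin)")
  td <- params$td
  params$dhd * (1 - temperature / td) +
    params$dcp * ((temperature - td) - temperature * log(temperature / td))
}

#' Equilibrium denatured fraction
#'
#' Two-state population of the denatured state,
#' \eqn{f_D = K / (1 + K)} with \eqn{K = \exp(-\Delta G_d / RT)}.
#' Equals 1/2 at \eqn{T_d} and increases strictly with temperature.
#'
#' @inheritParams delta_g
#' @return fraction in \[0, 1\] (vectorized).
#' @export
denatured_fraction <- function(temperature, params) {
  dg <- delta_g(temperature, params)
  # plogis is the numerically stable logistic: K/(1+K) = 1/(1+exp(dG/RT))
  stats::plogis(-dg / (.R_kJ * temperature))
}

#' Excess molar heat capacity of a two-state transition
#'
#' Analytic temperature derivative of the excess enthalpy
#' \eqn{f_D(T)\,\Delta H_d(T)} with \eqn{\Delta H_d(T) = \Delta H_d +
#' \Delta C_p (T - T_d)}:
#' \deqn{C_{p,ex}(T) = \frac{\Delta H_d(T)^2 f (1-f)}{R T^2} + f \Delta C_p}
#' The first term is the transition peak (height
#' \eqn{\Delta H_d^2 / 4 R T_d^2} at \eqn{T_d} when \eqn{\Delta C_p = 0});
#' the second is the sigmoidal heat-capacity shift that the progress baseline
#' removes before peak integration.
#'
#' @inheritParams delta_g
#' @return excess heat capacity in kJ/(K mol) (vectorized).
#' @examples
#' p <- two_state_params(375.75, 470)
#' excess_cp(375.75, p)  # peak height ~47 kJ/(K mol)
#' @export
excess_cp <- function(temperature, params) {
  f <- denatured_fraction(temperature, params)
  dh_t <- params$dhd + params$dcp * (temperature - params$td)
  dh_t^2 * f * (1 - f) / (.R_kJ * temperature^2) + f * params$dcp
}
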