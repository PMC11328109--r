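#' Read a cosolute-condition table
#'
#' One row per DSC condition: cosolute label, concentration, transition
#' temperature (Celsius on disk) and denaturation enthalpy, with optional
#' van't Hoff enthalpy. An optional `part` column groups conditions
#' (e.g. single denaturants vs denaturant + stabilizer mixtures).
#'
#' @param path CSV with header
#'   `cosolute,conc_M,td_C,dh_kJ_mol[,dhvh_kJ_mol][,part]`; `#` comments.
#' @return a data.frame of class `condition_table` with `td_K` added.
#' @export
read_conditions_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("cosolute", "conc_M", "td_C", "dh_kJ_mol")
  if (!all(need %in% names(df)))
    stop("conditions CSV must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$td_C)) || any(!is.finite(df$dh_kJ_mol)))
    stop("td_C and dh_kJ_mol must be numeric and complete")
  if (any(df$dh_kJ_mol <= 0)) stop("dh_kJ_mol must be positive")
  df$td_K <- celsius_to_kelvin(df$td_C)
  class(df) <- c("condition_table", "data.frame")
  df
}

#' Packaged condition table for the TmArgBP D2 domain
#'
#' The DSC parameter table for the 92-residue D2 domain of the
#' Thermotoga maritima arginine-binding protein: buffer plus KSCN (part A),
#' GdmSCN (part B), GdmCl (part C) and GdmSCN + stabilizer mixtures
#' (part D). Transcribed printed values; `dhvh_kJ_mol` are the
#' instrument-reported van't Hoff enthalpies.
#'
#' @param regression_subset if `TRUE` (default `FALSE`), return only the
#'   rows that enter the heat-capacity regression: buffer and the pure
#'   denaturant series A-C, excluding the stabilizer mixtures of part D.
#' @return a `condition_table` data.frame.
#' @examples
#' fit_dcp(d2_conditions(regression_subset = TRUE))
#' @export
d2_conditions <- function(regression_subset = FALSE) {
  path <- system.file("extdata", "d2_conditions.csv", package = "cosolv",
                      mustWork = TRUE)
  df <- read_conditions_csv(path)
  if (regression_subset) {
    df <- df[df$part %in% c("buffer", "A", "B", "C"), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Heat-capacity change from cross-condition regression
#'
#' Under Kirchhoff's relation, the denaturation enthalpy measured at the
#' (cosolute-shifted) transition temperature varies linearly with that
#' temperature, with slope equal to the heat-capacity change upon
#' denaturation. This fits an ordinary least-squares line of
#' \eqn{\Delta H_d(T_d)} on \eqn{T_d} across conditions; the slope is the
#' \eqn{\Delta C_{p,d}} estimate. The slope is invariant to the
#' Celsius/Kelvin choice since the two scales differ by a shift.
#'
#' @param conditions a `condition_table` (or any data.frame with `td_K` and
#'   `dh_kJ_mol`), at least 3 rows.
#' @return a `dcp_regression` list: `slope` (kJ/(K mol)), `slope_se`,
#'   `intercept` (kJ/mol, at 0 K), `r_squared`, `n_points`, `residuals`.
#' @examples
#' fit_dcp(d2_conditions(regression_subset = TRUE))  # slope ~5.2
#' @export
fit_dcp <- function(conditions) {
  stopifnot(is.data.frame(conditions),
            all(c("td_K", "dh_kJ_mol") %in% names(conditions)))
  if (nrow(conditions) < 3L) stop("need at least 3 conditions")
  if (sd(conditions$td_K) == 0) stop("zero variance in Td across conditions")
  fit <- lm(dh_kJ_mol ~ td_K, data = conditions)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 slope_se = sm$coefficients[2, 2],
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 n_points = nrow(conditions),
                 residuals = unname(resid(fit))),
            class = "dcp_regression")
}

#' @export
print.dcp_regression <- function(x, ...) {
  cat(sprintf("dCp regression: slope = %.2f +- %.2f kJ/(K mol), r^2 = %.4f, n = %d\n",
              x$slope, x$slope_se, x$r_squared, x$n_points))
  invisible(x)
}

#' Extrapolate a denaturation enthalpy to another temperature
#'
#' Kirchhoff extrapolation with temperature-independent heat capacity
#' change: \eqn{\Delta H(T) = \Delta H_d(T_d) + \Delta C_p (T - T_d)}.
#'
#' @param dhd enthalpy at the transition temperature, kJ/mol.
#' @param td transition temperature, Kelvin unless `celsius = TRUE`.
#' @param dcp heat-capacity change, kJ/(K mol).
#' @param t_target target temperature, same unit convention as `td`.
#' @param celsius interpret `td` and `t_target` as Celsius (the difference
#'   is unit-free, so the result is identical either way).
#' @return \eqn{\Delta H(T_{target})} in kJ/mol.
#' @examples
#' extrapolate_dh(470, 102.6, 5.2, 60, celsius = TRUE)  # ~248.5
#' @export
extrapolate_dh <- function(dhd, td, dcp, t_target, celsius = FALSE) {
  stopifnot(is.numeric(dhd), is.numeric(td), is.numeric(dcp),
            is.numeric(t_target))
  dhd + dcp * (t_target - td)
}

#' Per-residue enthalpy normalization
#'
#' Divides an unfolding enthalpy by the number of residues, the standard
#' scale on which thermophilic and mesophilic proteins are compared.
#'
#' @param dh enthalpy, kJ/mol.
#' @param n_residues residue count (> 0).
#' @return kJ/mol per residue.
#' @examples
#' per_residue_dh(extrapolate_dh(470, 102.6, 5.2, 60, celsius = TRUE), 92)
#' @export
per_residue_dh <- function(dh, n_residues) {
  if (any(n_residues <= 0)) stop("n_residues must be positive")
  dh / n_residues
}

#' Protein stability curve
#'
#' Gibbs-Helmholtz \eqn{\Delta G_d(T)} over a temperature grid for one
#' condition, from its \eqn{(T_d, \Delta H_d)} and a shared heat-capacity
#' change. The curve is zero at \eqn{T_d} and, for \eqn{\Delta C_p > 0},
#' has a unique maximum at the temperature where the denaturation entropy
#' vanishes.
#'
#' @param dhd,td,dcp as in [extrapolate_dh()] (`td` in Kelvin unless
#'   `celsius = TRUE`, in which case `t_grid` is Celsius too).
#' @param t_grid temperatures at which to evaluate the curve.
#' @param celsius Celsius I/O flag.
#' @return data.frame with `temperature` (as supplied) and `dg_kJ_mol`.
#' @export
stability_curve <- function(dhd, td, dcp, t_grid, celsius = FALSE) {
  tk <- if (celsius) celsius_to_kelvin(td) else td
  gk <- if (celsius) celsius_to_kelvin(t_grid) else t_grid
  p <- two_state_params(tk, dhd, dcp)
  data.frame(temperature = t_grid, dg_kJ_mol = delta_g(gk, p))
}
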