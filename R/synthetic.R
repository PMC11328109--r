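#' Synthetic DSC dataset with known ground truth
#'
#' Simulates a thermogram from two-state parameters (defaults: the aqueous
#' buffer condition of the D2 domain, transition at 102.6 C with 470 kJ/mol,
#' and the cross-condition heat-capacity change 5.2 kJ/(K mol)) over a
#' 25-115 C grid, optionally with an instrument baseline and Gaussian
#' noise.
#'
#' @param td_C,dhd,dcp generating two-state parameters (Celsius, kJ/mol,
#'   kJ/(K mol)).
#' @param tmin_C,tmax_C,step_C simulation grid, Celsius.
#' @param baseline a [dsc_baseline()] or `NULL`.
#' @param noise_sd Gaussian noise sd, kJ/(K mol).
#' @param seed integer seed.
#' @return list with `trace` (a [dsc_trace()]) and `truth` (the generating
#'   [two_state_params()]).
#' @examples
#' ds <- make_dsc_dataset(noise_sd = 0)
#' find_td(ds$trace) - ds$truth$td   # ~0
#' @export
make_dsc_dataset <- function(td_C = 102.6, dhd = 470, dcp = 5.2,
                             tmin_C = 25, tmax_C = 115, step_C = 0.1,
                             baseline = NULL, noise_sd = 0, seed = 1) {
  p <- two_state_params(td_C, dhd, dcp, celsius = TRUE)
  grid <- celsius_to_kelvin(seq(tmin_C, tmax_C, by = step_C))
  trace <- simulate_trace(p, grid, baseline = baseline, noise_sd = noise_sd,
                          seed = seed, label = "synthetic DSC")
  list(trace = trace, truth = p)
}

#' Synthetic ITC dataset with known ground truth
#'
#' Simulates per-injection heats from the equal-and-independent-sites
#' isotherm on the standard schedule (25 x 10 uL of 300 mM ligand into
#' 961 uL of 42 uM protein) with defaults matching the thiocyanate-binding
#' parameters n = 30 sites, Kb = 6.3 1/M, total binding enthalpy
#' -14.9 kJ/mol of protein. Optionally adds a constant per-injection
#' dilution heat and Gaussian noise; the matching dilution-blank series is
#' returned so that [subtract_dilution()] can be exercised.
#'
#' @param n,kb,dh_total generating binding parameters.
#' @param schedule a [titration_schedule()].
#' @param dilution_heat_uJ constant dilution heat per injection, uJ.
#' @param noise_sd Gaussian noise sd on per-injection heats, uJ.
#' @param seed integer seed.
#' @return list with `data` (a `titration_data` including dilution and
#'   noise), `dilution_heats` (the blank series, uJ), and `truth` (the
#'   generating [binding_params()]).
#' @export
make_itc_dataset <- function(n = 30, kb = 6.3, dh_total = -14.9,
                             schedule = titration_schedule(),
                             dilution_heat_uJ = 0, noise_sd = 0, seed = 1) {
  p <- binding_params(n, kb, dh_total)
  dil <- rep(dilution_heat_uJ, schedule$n_injections)
  data <- simulate_titration(p, schedule, noise_sd = noise_sd, seed = seed,
                             dilution_heats = if (dilution_heat_uJ != 0) dil
                                              else NULL)
  list(data = data, dilution_heats = dil, truth = p)
}
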