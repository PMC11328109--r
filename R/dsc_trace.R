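#' DSC excess-heat-capacity trace
#'
#' A thermogram after buffer subtraction: a strictly increasing temperature
#' grid with one excess molar heat capacity value per grid point.
#'
#' @param temperature grid, Kelvin unless `celsius = TRUE`; strictly
#'   increasing.
#' @param cp_excess excess molar heat capacity, kJ/(K mol); same length.
#' @param celsius interpret `temperature` as Celsius.
#' @param label scan label.
#' @param cosolute free-text cosolute description.
#' @return a `dsc_trace` object (list with `temperature` in Kelvin,
#'   `cp_excess`, `label`, `cosolute`).
#' @export
dsc_trace <- function(temperature, cp_excess, celsius = FALSE,
                      label = "", cosolute = "") {
  if (celsius) temperature <- celsius_to_kelvin(temperature)
  stopifnot(is.numeric(temperature), is.numeric(cp_excess))
  if (length(temperature) != length(cp_excess))
    stop("temperature and cp_excess must have equal length")
  if (length(temperature) < 2L) stop("a trace needs at least two points")
  if (any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing")
  structure(list(temperature = as.numeric(temperature),
                 cp_excess = as.numeric(cp_excess),
                 label = label, cosolute = cosolute),
            class = "dsc_trace")
}

#' @export
print.dsc_trace <- function(x, ...) {
  cat(sprintf("DSC trace%s: %d points, %.2f-%.2f C, peak %.2f kJ/(K mol)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$temperature),
              kelvin_to_celsius(min(x$temperature)),
              kelvin_to_celsius(max(x$temperature)),
              max(x$cp_excess)))
  invisible(x)
}

#' Instrument baseline model for DSC traces
#'
#' Linear pre- and post-transition segments joined by a progress baseline:
#' the baseline under the transition is the pre segment weighted by the folded
#' fraction plus the post segment weighted by the denatured fraction, which is
#' the conventional sigmoidal interpolation used before peak integration.
#'
#' @param pre numeric `c(intercept, slope)` of the pre-transition segment,
#'   kJ/(K mol) and kJ/(K^2 mol); intercept is taken at the temperature
#'   origin used for evaluation (Kelvin).
#' @param post numeric `c(intercept, slope)` of the post-transition segment.
#' @param progress if `TRUE` the two segments are blended by the denatured
#'   fraction; if `FALSE` only the pre segment is used everywhere.
#' @return a `dsc_baseline` object.
#' @seealso [simulate_trace()], [subtract_baseline()]
#' @export
dsc_baseline <- function(pre = c(0, 0), post = c(0, 0), progress = TRUE) {
  stopifnot(length(pre) == 2L, length(post) == 2L)
  structure(list(pre = as.numeric(pre), post = as.numeric(post),
                 progress = isTRUE(progress)),
            class = "dsc_baseline")
}

#' Evaluate a baseline model on a temperature grid
#'
#' @param baseline a [dsc_baseline()] object.
#' @param temperature Kelvin grid.
#' @param fraction denatured fraction on the grid, used as the blending
#'   weight when `baseline$progress` is `TRUE`.
#' @return baseline values, kJ/(K mol).
#' @keywords internal
eval_baseline <- function(baseline, temperature, fraction = NULL) {
  stopifnot(inherits(baseline, "dsc_baseline"))
  pre <- baseline$pre[1] + baseline$pre[2] * temperature
  if (!baseline$progress) return(pre)
  post <- baseline$post[1] + baseline$post[2] * temperature
  if (is.null(fraction)) stop("progress baseline needs the denatured fraction")
  (1 - fraction) * pre + fraction * post
}

#' Simulate a DSC trace from two-state parameters
#'
#' Evaluates the forward two-state excess heat capacity on a grid, adds an
#' optional instrument baseline (blended by the true denatured fraction) and
#' optional i.i.d. Gaussian noise.
#'
#' @param params a [two_state_params()] object.
#' @param grid temperature grid in Kelvin (strictly increasing), inside
#'   `(0, 2 * Td)`.
#' @param baseline a [dsc_baseline()] or `NULL` for no baseline.
#' @param noise_sd Gaussian noise standard deviation, kJ/(K mol).
#' @param seed integer seed for reproducible noise; `NULL` leaves the RNG
#'   state alone.
#' @param label,cosolute passed to [dsc_trace()].
#' @return a [dsc_trace()] object.
#' @examples
#' p <- two_state_params(375.75, 470, 5.2)
#' tr <- simulate_trace(p, seq(330, 390, by = 0.1))
#' find_td(tr)
#' @export
simulate_trace <- function(params, grid, baseline = NULL, noise_sd = 0,
                           seed = NULL, label = "simulated", cosolute = "") {
  stopifnot(inherits(params, "two_state_params"))
  if (length(grid) == 0L) stop("empty temperature grid")
  if (any(grid <= 0) || any(grid >= 2 * params$td))
    stop("grid must lie inside (0, 2*Td)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  cp <- excess_cp(grid, params)
  if (!is.null(baseline)) {
    f <- denatured_fraction(grid, params)
    cp <- cp + eval_baseline(baseline, grid, f)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    cp <- cp + rnorm(length(grid), sd = noise_sd)
  }
  dsc_trace(grid, cp, label = label, cosolute = cosolute)
}

#' Read and write the DSC trace CSV dialect
#'
#' Two columns, `temperature_C,cp_excess_kJ_per_K_mol`, comment lines start
#' with `#`, decimal point only. Temperatures are Celsius on disk and Kelvin
#' in memory.
#'
#' @param path file path.
#' @param label,cosolute metadata attached to the trace on read.
#' @return `read_dsc_csv()` returns a [dsc_trace()]; `write_dsc_csv()`
#'   returns `path` invisibly.
#' @export
read_dsc_csv <- function(path, label = basename(path), cosolute = "") {
  df <- read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("temperature_C", "cp_excess_kJ_per_K_mol")
  if (!all(need %in% names(df)))
    stop("DSC CSV must have columns: ", paste(need, collapse = ", "))
  dsc_trace(df$temperature_C, df$cp_excess_kJ_per_K_mol, celsius = TRUE,
            label = label, cosolute = cosolute)
}

#' @rdname read_dsc_csv
#' @param trace a [dsc_trace()] to write.
#' @export
write_dsc_csv <- function(trace, path) {
  stopifnot(inherits(trace, "dsc_trace"))
  df <- data.frame(temperature_C = kelvin_to_celsius(trace$temperature),
                   cp_excess_kJ_per_K_mol = trace$cp_excess)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
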