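#' Binding parameters for the equal-and-independent-sites model
#'
#' @param n number of equivalent sites per protein molecule (> 0).
#' @param kb per-site binding constant, 1/M (> 0).
#' @param dh_total total binding enthalpy change at saturation, kJ per mol of
#'   protein. The per-site enthalpy is the derived quantity `dh_total / n`.
#' @return a `binding_params` object.
#' @examples
#' binding_params(30, 6.3, -14.9)
#' @export
binding_params <- function(n, kb, dh_total) {
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(kb), length(kb) == 1L, is.finite(kb),
            is.numeric(dh_total), length(dh_total) == 1L, is.finite(dh_total))
  if (n <= 0) stop("n must be positive")
  if (kb <= 0) stop("kb must be positive")
  structure(list(n = n, kb = kb, dh_total = dh_total),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("Binding parameters: n = %.3g sites, Kb = %.3g 1/M, dHb(total) = %.3g kJ/mol (%.3g per site)\n",
              x$n, x$kb, x$dh_total, x$dh_total / x$n))
  invisible(x)
}

#' ITC titration schedule
#'
#' Geometry and concentrations of a titration: an overfilled cell of fixed
#' sensitive volume receiving equal ligand injections from a syringe.
#' Defaults follow a 25 x 10 uL titration of 300 mM ligand into 961 uL of
#' 42 uM protein.
#'
#' @param cell_volume_ul cell volume, uL.
#' @param injection_volume_ul volume per injection, uL (< cell volume).
#' @param n_injections number of injections.
#' @param syringe_conc_M ligand concentration in the syringe, M.
#' @param protein_conc_M initial protein concentration in the cell, M.
#' @return a `titration_schedule` object.
#' @export
titration_schedule <- function(cell_volume_ul = 961,
                               injection_volume_ul = 10,
                               n_injections = 25,
                               syringe_conc_M = 0.300,
                               protein_conc_M = 42e-6) {
  vals <- c(cell_volume_ul, injection_volume_ul, n_injections,
            syringe_conc_M, protein_conc_M)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all schedule fields must be positive and finite")
  if (injection_volume_ul >= cell_volume_ul)
    stop("injection volume must be smaller than the cell volume")
  structure(list(cell_volume_ul = cell_volume_ul,
                 injection_volume_ul = injection_volume_ul,
                 n_injections = as.integer(n_injections),
                 syringe_conc_M = syringe_conc_M,
                 protein_conc_M = protein_conc_M),
            class = "titration_schedule")
}

#' Cell concentrations after the k-th injection
#'
#' Overfilled-cell displacement bookkeeping: each injection of volume v into
#' a cell of volume V displaces an equal volume of cell content, so after k
#' injections
#' \deqn{[P_0]_k = P_{init} (1 - v/V)^k, \quad
#'       [L_0]_k = C_{syr} (1 - (1 - v/V)^k)}
#' `dilution = "none"` disables the displacement factor (ligand simply
#' accumulates as `k v C_syr / V` with constant protein).
#'
#' @param schedule a [titration_schedule()].
#' @param k injection index (vectorized); `k = 0` is the pre-titration state.
#' @param dilution `"displacement"` (default) or `"none"`.
#' @return a data.frame with columns `k`, `P0`, `L0` (molar).
#' @examples
#' s <- titration_schedule()
#' concentrations_after_injection(s, c(1, 25))
#' @export
concentrations_after_injection <- function(schedule, k,
                                           dilution = c("displacement", "none")) {
  stopifnot(inherits(schedule, "titration_schedule"))
  dilution <- match.arg(dilution)
  if (any(k < 0) || any(k > schedule$n_injections) || any(k != floor(k)))
    stop("injection index k must be an integer in [0, n_injections]")
  r <- schedule$injection_volume_ul / schedule$cell_volume_ul
  if (dilution == "displacement") {
    fk <- (1 - r)^k
    data.frame(k = k,
               P0 = schedule$protein_conc_M * fk,
               L0 = schedule$syringe_conc_M * (1 - fk))
  } else {
    data.frame(k = k,
               P0 = rep(schedule$protein_conc_M, length(k)),
               L0 = schedule$syringe_conc_M * k * r)
  }
}

#' Fraction of binding-site saturation
#'
#' Closed-form solution of the mass-action balance for n equal and
#' independent sites. With \eqn{a = n K_b}, \eqn{b = 1 + n P_0 K_b + L_0 K_b},
#' \eqn{c = L_0 P_0 K_b}, the physically meaningful root is
#' \deqn{\theta = \frac{b - \sqrt{b^2 - 4ac}}{2 a P_0}}
#' which equals the bound-ligand concentration divided by the site
#' concentration \eqn{n P_0} and lies in \[0, 1\]. The small root is
#' evaluated as \eqn{2c / (b + \sqrt{b^2 - 4ac})} for numerical stability.
#'
#' @param L0 total ligand concentration, M (vectorized).
#' @param P0 total protein concentration, M (vectorized or scalar).
#' @param params a [binding_params()].
#' @return saturation fraction in \[0, 1\].
#' @examples
#' bound_fraction(0.05, 42e-6, binding_params(30, 6.3, -14.9))
#' @export
bound_fraction <- function(L0, P0, params) {
  stopifnot(inherits(params, "binding_params"))
  if (any(L0 < 0)) stop("L0 must be non-negative")
  if (any(P0 <= 0)) stop("P0 must be positive")
  n <- params$n; kb <- params$kb
  a <- n * kb
  b <- 1 + n * P0 * kb + L0 * kb
  cc <- L0 * P0 * kb
  disc <- b^2 - 4 * a * cc
  if (any(disc < 0)) stop("negative discriminant in binding isotherm")
  # small root of a x^2 - b x + c = 0, stable form
  x <- 2 * cc / (b + sqrt(disc))
  x / P0
}

#' Cumulative heat of the binding isotherm
#'
#' The model cumulative heat after reaching composition `(L0, P0)`:
#' \eqn{Q = \Delta H_{b,tot} \cdot \theta(L_0, P_0)} in kJ per mol of
#' protein, where \eqn{\theta} is [bound_fraction()]. At saturation the
#' cumulative heat equals the total binding enthalpy change. With
#' `per_cell = TRUE` the heat is scaled by the moles of protein in the cell
#' and returned in microjoules, the scale on which per-injection heats are
#' recorded.
#'
#' @inheritParams bound_fraction
#' @param per_cell return microjoules for the cell contents instead of
#'   kJ per mol of protein.
#' @param cell_volume_ul cell volume used when `per_cell = TRUE`.
#' @return cumulative heat (kJ/mol of protein, or uJ if `per_cell`).
#' @export
cumulative_heat <- function(L0, P0, params, per_cell = FALSE,
                            cell_volume_ul = 961) {
  q <- params$dh_total * bound_fraction(L0, P0, params)
  if (!per_cell) return(q)
  moles <- P0 * cell_volume_ul * 1e-6
  q * moles * 1e9   # kJ -> uJ
}

#' Subtract ligand dilution heats from titration heats
#'
#' Element-wise subtraction of a dilution (blank) titration from a binding
#' titration recorded on the same schedule.
#'
#' @param heats per-injection heats, uJ.
#' @param dilution_heats per-injection dilution heats, uJ; same length.
#' @return corrected per-injection heats.
#' @export
subtract_dilution <- function(heats, dilution_heats) {
  if (length(heats) != length(dilution_heats))
    stop("heats and dilution_heats must have equal length")
  heats - dilution_heats
}

#' Simulate an ITC titration
#'
#' Per-injection heats are first differences of the model cumulative heat
#' ([cumulative_heat()], per cell, uJ) along the injection schedule, plus an
#' optional per-injection dilution-heat series and optional i.i.d. Gaussian
#' noise.
#'
#' @param params a [binding_params()].
#' @param schedule a [titration_schedule()].
#' @param noise_sd Gaussian noise sd on per-injection heats, uJ.
#' @param seed integer seed; `NULL` leaves the RNG alone.
#' @param dilution_heats optional per-injection dilution heats (uJ) added to
#'   the simulated heats (length `n_injections`).
#' @param dilution concentration bookkeeping passed to
#'   [concentrations_after_injection()].
#' @return a `titration_data` data.frame with columns `injection`, `heat_uJ`,
#'   `P0`, `L0`, `cumulative_uJ`; the generating parameters and schedule are
#'   attached as attributes `params` and `schedule`.
#' @examples
#' sim <- simulate_titration(binding_params(30, 6.3, -14.9),
#'                           titration_schedule(), noise_sd = 0)
#' head(sim)
#' @export
simulate_titration <- function(params, schedule, noise_sd = 0, seed = NULL,
                               dilution_heats = NULL,
                               dilution = "displacement") {
  stopifnot(inherits(params, "binding_params"),
            inherits(schedule, "titration_schedule"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  k <- seq_len(schedule$n_injections)
  conc <- concentrations_after_injection(schedule, c(0L, k),
                                         dilution = dilution)
  qcum <- cumulative_heat(conc$L0, conc$P0, params, per_cell = TRUE,
                          cell_volume_ul = schedule$cell_volume_ul)
  heats <- diff(qcum)
  if (!is.null(dilution_heats)) {
    if (length(dilution_heats) != length(heats))
      stop("dilution_heats must have one value per injection")
    heats <- heats + dilution_heats
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    heats <- heats + rnorm(length(heats), sd = noise_sd)
  }
  out <- data.frame(injection = k,
                    heat_uJ = heats,
                    P0 = conc$P0[-1],
                    L0 = conc$L0[-1],
                    cumulative_uJ = cumsum(heats))
  attr(out, "params") <- params
  attr(out, "schedule") <- schedule
  class(out) <- c("titration_data", "data.frame")
  out
}

#' Fit the equal-and-independent-sites model to titration data
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) of the model
#' cumulative heat against the measured cumulative heats versus total ligand
#' concentration. Initialization is deterministic: `kb` from the reciprocal
#' of the ligand concentration at half-maximal cumulative heat, `dh_total`
#' from the final cumulative heat corrected by the initial saturation guess,
#' `n` from the schedule's site-to-protein heat balance; on failure a grid of
#' `kb` starting values spanning 0.1-100 1/M is tried.
#'
#' @param data a `titration_data` object ([simulate_titration()] or
#'   [read_itc_csv()] joined with a schedule), with dilution-corrected heats.
#' @param init optional [binding_params()] starting point.
#' @return a `binding_fit` list: `params` ([binding_params()]), `se` (named
#'   asymptotic standard errors), `rss`, `fitted` cumulative heats (uJ),
#'   `n_injections`.
#' @export
fit_binding <- function(data, init = NULL) {
  stopifnot(inherits(data, "data.frame"),
            all(c("heat_uJ", "P0", "L0") %in% names(data)))
  if (nrow(data) < 5L) stop("need at least 5 injections to fit")
  sched <- attr(data, "schedule")
  vcell <- if (!is.null(sched)) sched$cell_volume_ul else 961
  qcum <- cumsum(data$heat_uJ)
  if (max(abs(qcum)) < .Machine$double.eps^0.5 * max(1, max(data$L0)))
    stop("flat (zero-heat) titration: binding parameters are not identifiable")
  L0 <- data$L0; P0 <- data$P0
  model <- function(n, kb, dh) {
    a <- n * kb
    b <- 1 + n * P0 * kb + L0 * kb
    cc <- L0 * P0 * kb
    x <- 2 * cc / (b + sqrt(pmax(b^2 - 4 * a * cc, 0)))
    dh * (x / P0) * (P0 * vcell * 1e-6) * 1e9
  }
  starts <- list()
  if (!is.null(init)) {
    stopifnot(inherits(init, "binding_params"))
    starts[[1]] <- list(n = init$n, kb = init$kb, dh = init$dh_total)
  } else {
    qn <- qcum[length(qcum)]
    half <- which(abs(qcum) >= abs(qn) / 2)[1]
    kb0 <- 1 / max(L0[half], .Machine$double.eps)
    sat0 <- kb0 * L0[length(L0)] / (1 + kb0 * L0[length(L0)])
    dh0 <- qn / (P0[length(P0)] * vcell * 1e-6 * 1e9) / max(sat0, 0.1)
    starts[[1]] <- list(n = 10, kb = kb0, dh = dh0)
    for (kbg in c(0.1, 1, 10, 100))
      starts[[length(starts) + 1L]] <- list(n = 10, kb = kbg, dh = dh0)
  }
  fit <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(qcum ~ model(n, kb, dh), start = s,
                        lower = c(n = 1e-3, kb = 1e-6, dh = -Inf),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("binding fit did not converge from any deterministic start")
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(
    params = binding_params(est[["n"]], est[["kb"]], est[["dh"]]),
    se = setNames(se, c("n", "kb", "dh_total")),
    rss = sum(resid(fit)^2),
    fitted = fitted(fit),
    n_injections = nrow(data)
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  se: n %.3g, Kb %.3g, dHb %.3g;  RSS = %.4g over %d injections\n",
              x$se[["n"]], x$se[["kb"]], x$se[["dh_total"]], x$rss,
              x$n_injections))
  invisible(x)
}

#' Read and write the ITC heats CSV dialect and its schedule sidecar
#'
#' Heats: two columns `injection,heat_uJ`, comment lines start with `#`.
#' Schedule sidecar: a YAML file with keys `cell_volume_ul`,
#' `injection_volume_ul`, `n_injections`, `syringe_conc_M`,
#' `protein_conc_M`.
#'
#' @param path CSV (heats) or YAML (schedule) path.
#' @param schedule an optional [titration_schedule()]; when supplied,
#'   per-injection concentrations are attached so the result can go straight
#'   into [fit_binding()].
#' @return `read_itc_csv()` returns a `titration_data` data.frame;
#'   `read_schedule()` a [titration_schedule()]; writers return the path
#'   invisibly.
#' @export
read_itc_csv <- function(path, schedule = NULL) {
  df <- read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("injection", "heat_uJ")
  if (!all(need %in% names(df)))
    stop("ITC CSV must have columns: ", paste(need, collapse = ", "))
  df <- df[order(df$injection), , drop = FALSE]
  out <- data.frame(injection = df$injection, heat_uJ = df$heat_uJ)
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "titration_schedule"))
    if (nrow(out) != schedule$n_injections)
      stop("heats rows (", nrow(out), ") do not match schedule n_injections (",
           schedule$n_injections, ")")
    conc <- concentrations_after_injection(schedule, out$injection)
    out$P0 <- conc$P0
    out$L0 <- conc$L0
    out$cumulative_uJ <- cumsum(out$heat_uJ)
    attr(out, "schedule") <- schedule
  }
  class(out) <- c("titration_data", "data.frame")
  out
}

#' @rdname read_itc_csv
#' @param data a `titration_data` data.frame to write.
#' @export
write_itc_csv <- function(data, path) {
  write.csv(data.frame(injection = data$injection, heat_uJ = data$heat_uJ),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_itc_csv
#' @export
read_schedule <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("cell_volume_ul", "injection_volume_ul", "n_injections",
            "syringe_conc_M", "protein_conc_M")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("schedule file missing keys: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(cfg), need)
  if (length(extra))
    stop("unknown schedule keys: ", paste(extra, collapse = ", "))
  do.call(titration_schedule, cfg[need])
}

#' @rdname read_itc_csv
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "titration_schedule"))
  yaml::write_yaml(unclass(schedule), path)
  invisible(path)
}
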