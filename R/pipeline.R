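.REPORT_SCHEMA <- "cosolv-report/1"

#' Write a JSON analysis report
#'
#' All pipeline stages report JSON with a schema version stamp so that
#' downstream consumers can detect format changes.
#'
#' @param x a named list of results.
#' @param path output path; `NULL` returns the report list invisibly
#'   without writing.
#' @return the report list (with `schema` added), invisibly.
#' @export
write_report <- function(x, path = NULL) {
  rep <- c(list(schema = .REPORT_SCHEMA), x)
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(rep)
}

#' Reproduce the packaged cross-condition stability analysis
#'
#' Runs the full stability-regression stage on the packaged condition table
#' for the D2 domain: ordinary least squares of the denaturation enthalpy
#' versus transition temperature over the buffer + pure-denaturant
#' conditions (the heat-capacity change estimate), Kirchhoff extrapolation
#' of the buffer-condition enthalpy to a reference temperature, and
#' per-residue normalization.
#'
#' @param t_ref_C reference temperature for the extrapolation, Celsius.
#' @param n_residues residue count for normalization (92 for the D2
#'   domain).
#' @param dcp heat-capacity change used for the extrapolation; `NULL`
#'   (default) uses the regression slope rounded to the reported precision
#'   of 0.1 kJ/(K mol).
#' @param path optional JSON report path.
#' @return report list with `dcp_slope`, `dcp_slope_se`, `r_squared`,
#'   `n_points`, `dh_at_tref`, `dh_per_residue`, `t_ref_C`, `n_residues`.
#' @examples
#' repro_conditions()$dh_per_residue  # ~2.70
#' @export
repro_conditions <- function(t_ref_C = 60, n_residues = 92, dcp = NULL,
                         path = NULL) {
  cond <- d2_conditions(regression_subset = TRUE)
  reg <- fit_dcp(cond)
  dcp_use <- if (is.null(dcp)) round(reg$slope, 1) else dcp
  buffer <- cond[cond$part == "buffer", ]
  dh_ref <- extrapolate_dh(buffer$dh_kJ_mol, buffer$td_C, dcp_use, t_ref_C,
                           celsius = TRUE)
  out <- list(dcp_slope = reg$slope,
              dcp_slope_se = reg$slope_se,
              r_squared = reg$r_squared,
              n_points = reg$n_points,
              dcp_used = dcp_use,
              dh_at_tref = dh_ref,
              dh_per_residue = per_residue_dh(dh_ref, n_residues),
              t_ref_C = t_ref_C,
              n_residues = n_residues)
  write_report(out, path)
  out
}

.PIPELINE_STAGES <- c("dsc_sim", "dsc_fit", "itc_sim", "itc_fit",
                      "dcp_regress", "md_shell", "md_contacts",
                      "md_mindist", "repro")

#' Run a configured analysis pipeline stage
#'
#' Dispatches one named stage with a validated configuration list (unknown
#' keys are rejected), writes a JSON report when `report` is given, and
#' returns the stage result. This is the programmatic surface behind the
#' `cosolv` command-line script.
#'
#' Supported stages and their keys:
#' * `dsc_sim`: `td_C`, `dhd`, `dcp`, `tmin_C`, `tmax_C`, `step_C`,
#'   `noise_sd`, `seed`, `out` (trace CSV).
#' * `dsc_fit`: `input` (trace CSV), `report`.
#' * `itc_sim`: `n`, `kb`, `dh_total`, `schedule` (YAML path), `noise_sd`,
#'   `seed`, `out` (heats CSV).
#' * `itc_fit`: `input` (heats CSV), `schedule` (YAML path), `dilution`
#'   (optional blank CSV), `report`.
#' * `dcp_regress`: `input` (conditions CSV; defaults to the packaged
#'   table), `t_ref_C`, `n_residues`, `report`.
#' * `md_shell` / `md_contacts` / `md_mindist`: `input` (multi-model PDB),
#'   `cutoff`, `species`, `ion_atom`, `bin_width`, `per_atom`, `out`,
#'   `report`.
#' * `repro`: `t_ref_C`, `n_residues`, `report`.
#'
#' @param stage stage name.
#' @param config named list of stage keys.
#' @return the stage result, invisibly.
#' @export
run_pipeline <- function(stage, config = list()) {
  stage <- match.arg(stage, .PIPELINE_STAGES)
  allowed <- switch(stage,
    dsc_sim = c("td_C", "dhd", "dcp", "tmin_C", "tmax_C", "step_C",
                "noise_sd", "seed", "out"),
    dsc_fit = c("input", "report"),
    itc_sim = c("n", "kb", "dh_total", "schedule", "noise_sd", "seed",
                "out"),
    itc_fit = c("input", "schedule", "dilution", "report"),
    dcp_regress = c("input", "t_ref_C", "n_residues", "report"),
    md_shell = c("input", "cutoff", "species", "out", "report"),
    md_contacts = c("input", "cutoff", "species", "per_atom", "report"),
    md_mindist = c("input", "ion_atom", "bin_width", "species", "out",
                   "report"),
    repro = c("t_ref_C", "n_residues", "report"))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config keys for stage '", stage, "': ",
         paste(unknown, collapse = ", "))
  get_in <- function() {
    if (is.null(config$input))
      stop("stage '", stage, "' requires an 'input' path")
    if (!file.exists(config$input))
      stop("input file not found: ", config$input)
    config$input
  }
  res <- switch(stage,
    dsc_sim = {
      args <- config[intersect(names(config),
                               names(formals(make_dsc_dataset)))]
      ds <- do.call(make_dsc_dataset, args)
      if (!is.null(config$out)) write_dsc_csv(ds$trace, config$out)
      ds
    },
    dsc_fit = {
      trace <- read_dsc_csv(get_in())
      corrected <- subtract_baseline(trace)
      ana <- analyze_trace(corrected)
      fit <- fit_two_state(corrected)
      out <- list(td_C = kelvin_to_celsius(ana$td),
                  dh_cal = ana$dh_cal, dh_vh = ana$dh_vh,
                  ratio = ana$ratio, rss = fit$rss,
                  n_points = fit$n_points)
      write_report(out, config$report)
      out
    },
    itc_sim = {
      sched <- if (is.null(config$schedule)) titration_schedule()
               else read_schedule(config$schedule)
      ds <- make_itc_dataset(
        n = config$n %||% 30, kb = config$kb %||% 6.3,
        dh_total = config$dh_total %||% -14.9, schedule = sched,
        noise_sd = config$noise_sd %||% 0, seed = config$seed %||% 1)
      if (!is.null(config$out)) write_itc_csv(ds$data, config$out)
      ds
    },
    itc_fit = {
      sched <- if (is.null(config$schedule)) titration_schedule()
               else read_schedule(config$schedule)
      data <- read_itc_csv(get_in(), schedule = sched)
      if (!is.null(config$dilution)) {
        dil <- read_itc_csv(config$dilution)
        data$heat_uJ <- subtract_dilution(data$heat_uJ, dil$heat_uJ)
        data$cumulative_uJ <- cumsum(data$heat_uJ)
      }
      fit <- fit_binding(data)
      out <- list(n = fit$params$n, kb = fit$params$kb,
                  dh_total = fit$params$dh_total,
                  se = as.list(fit$se), rss = fit$rss,
                  n_injections = fit$n_injections)
      write_report(out, config$report)
      fit
    },
    dcp_regress = {
      cond <- if (is.null(config$input)) d2_conditions(regression_subset = TRUE)
              else read_conditions_csv(config$input)
      reg <- fit_dcp(cond)
      out <- list(dcp_slope = reg$slope, dcp_slope_se = reg$slope_se,
                  r_squared = reg$r_squared, n_points = reg$n_points)
      if (!is.null(config$t_ref_C) || !is.null(config$n_residues)) {
        nres <- config$n_residues %||% 92
        tref <- config$t_ref_C %||% 60
        row1 <- cond[which.max(cond$td_K), ]
        dh <- extrapolate_dh(row1$dh_kJ_mol, row1$td_C, round(reg$slope, 1),
                             tref, celsius = TRUE)
        out$dh_at_tref <- dh
        out$dh_per_residue <- per_residue_dh(dh, nres)
      }
      write_report(out, config$report)
      out
    },
    md_shell = {
      fr <- read_frames(get_in())
      occ <- occupancy_series(fr, cutoff = config$cutoff %||% 4.0,
                              species = config$species %||% "SCN")
      if (!is.null(config$out)) write_histogram_tsv(occ, config$out)
      write_report(list(mean = occ$mean, n_frames = length(occ$counts)),
                   config$report)
      occ
    },
    md_contacts = {
      fr <- read_frames(get_in())
      st <- contact_stats(fr, cutoff = config$cutoff %||% 4.0,
                          species = config$species %||% "SCN",
                          per_atom = isTRUE(config$per_atom))
      write_report(split(st[, c("min", "max", "mean")], st$class),
                   config$report)
      st
    },
    md_mindist = {
      fr <- read_frames(get_in())
      md <- min_distance_distribution(
        fr, ion_atom = config$ion_atom %||% "N",
        bin_width = config$bin_width %||% 0.05,
        species = config$species %||% "SCN")
      if (!is.null(config$out)) write_histogram_tsv(md, config$out)
      write_report(list(n_distances = length(md$distances),
                        mode_bin_A = if (nrow(md$histogram))
                          md$histogram$bin_left_A[which.max(md$histogram$count)]
                        else NA),
                   config$report)
      md
    },
    repro = repro_conditions(t_ref_C = config$t_ref_C %||% 60,
                         n_residues = config$n_residues %||% 92,
                         path = config$report))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
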