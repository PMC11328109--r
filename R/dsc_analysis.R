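# Unvalidated forward model used inside optimizer loops; the exported
# excess_cp() is the validated surface.
.cpex_raw <- function(temperature, td, dhd, dcp) {
  dg <- dhd * (1 - temperature / td) +
    dcp * ((temperature - td) - temperature * log(temperature / td))
  f <- stats::plogis(-dg / (.R_kJ * temperature))
  dh_t <- dhd + dcp * (temperature - td)
  dh_t^2 * f * (1 - f) / (.R_kJ * temperature^2) + f * dcp
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Quadratic refinement of the grid maximum: a parabola is fitted over the
# top quarter of the peak's half-height width around the grid maximum (at
# least the two nearest neighbours), which averages grid noise instead of
# trusting three raw points. Returns the refined Td and peak height.
.peak_quad <- function(trace) {
  cp <- trace$cp_excess
  tt <- trace$temperature
  n <- length(cp)
  i <- which.max(cp)
  if (i == 1L || i == n)
    stop("transition maximum lies at a grid boundary (truncated transition)")
  half <- min(cp) + (cp[i] - min(cp)) / 2
  above <- which(cp >= half)
  hw_pts <- max(2L, round(0.25 * (max(above) - min(above))))
  win <- max(1L, i - hw_pts):min(n, i + hw_pts)
  x <- tt[win] - tt[i]
  y <- cp[win]
  co <- unname(coef(lm(y ~ x + I(x^2))))
  if (!is.finite(co[3]) || co[3] >= 0) {
    # degenerate neighbourhood (plateau); keep the grid point
    return(list(td = tt[i], cp_peak = cp[i]))
  }
  dx <- -co[2] / (2 * co[3])
  dx <- max(min(dx, max(x)), min(x))
  list(td = tt[i] + dx, cp_peak = co[1] + co[2] * dx + co[3] * dx^2)
}

#' Transition temperature of a DSC trace
#'
#' The denaturation temperature is the temperature of the maximum of the
#' excess-heat-capacity profile, refined by a three-point quadratic
#' interpolation around the grid maximum (thermograms are recorded on ~0.1 K
#' grids, so the refinement recovers sub-grid precision).
#'
#' @param trace a [dsc_trace()], normally baseline-subtracted.
#' @return the transition temperature in Kelvin.
#' @examples
#' p <- two_state_params(375.75, 470)
#' find_td(simulate_trace(p, seq(340, 400, by = 0.1)))
#' @export
find_td <- function(trace) {
  stopifnot(inherits(trace, "dsc_trace"))
  .peak_quad(trace)$td
}

#' Subtract the instrument baseline from a DSC trace
#'
#' Fits linear segments to the pre- and post-transition windows (the outer
#' `window_frac` of the grid on each side) and joins them with a progress
#' baseline: the chemical baseline under the peak is the pre segment weighted
#' by the folded fraction plus the post segment weighted by the reaction
#' progress, with the progress estimated from the running integral of the
#' baseline-corrected trace and refined by fixed-point iteration.
#'
#' The fitting windows default to the outer 15% of the grid, clipped away
#' from the transition: first geometrically (the peak's full width at half
#' maximum expanded by half a width on each side), then by state purity —
#' after the progress weights converge, window points must have progress
#' below `purity` (pre) or above `1 - purity` (post), the conventional
#' requirement that baseline segments represent essentially pure folded or
#' unfolded states. A trace whose transition is not resolved well enough to
#' leave such windows (e.g. a scan truncated inside the transition tail, or
#' a broad transition overlapping cold denaturation) is refused with an
#' error; such traces can still be analyzed with the model-based
#' [fit_two_state()].
#'
#' @param trace a [dsc_trace()].
#' @param window_frac fraction of grid points in each fitting window
#'   (default 0.15).
#' @param progress use the sigmoidal progress interpolation (`TRUE`) or the
#'   pre-transition line alone (`FALSE`).
#' @param max_iter fixed-point iterations for the progress weight.
#' @param purity maximum progress allowed inside the pre-transition window
#'   (and `1 - purity` minimum in the post window) after refinement.
#' @return a baseline-subtracted [dsc_trace()]; the fitted [dsc_baseline()]
#'   and final progress weights are attached as attributes `baseline` and
#'   `progress_weight`.
#' @export
subtract_baseline <- function(trace, window_frac = 0.15, progress = TRUE,
                              max_iter = 8L, purity = 1e-3) {
  stopifnot(inherits(trace, "dsc_trace"), window_frac > 0, window_frac < 0.5)
  tt <- trace$temperature
  cp <- trace$cp_excess
  n <- length(tt)
  nw <- max(2L, ceiling(window_frac * n))
  imax <- which.max(cp)
  if (imax == 1L || imax == n)
    stop("transition maximum lies at a grid boundary (truncated transition)")
  # transition span: full width at half maximum, expanded by half a width
  half <- min(cp) + (cp[imax] - min(cp)) / 2
  above <- which(cp >= half)
  t_lo <- tt[min(above)]; t_hi <- tt[max(above)]
  w <- max(t_hi - t_lo, 2 * mean(diff(tt)))
  pre_idx <- intersect(seq_len(nw), which(tt < t_lo - w / 2))
  post_idx <- intersect(seq(n - nw + 1L, n), which(tt > t_hi + w / 2))
  if (length(pre_idx) < 2L || length(post_idx) < 2L)
    stop("transition region overlaps the baseline windows; no flat segments to fit")
  fit_lines <- function(pi, qi) {
    list(pre = unname(coef(lm(cp[pi] ~ tt[pi]))),
         post = unname(coef(lm(cp[qi] ~ tt[qi]))))
  }
  # The blending weight is the denatured fraction f, which satisfies
  # df = dCp_peak dT / dH(T): progress increments are divided by the
  # running transition enthalpy, not accumulated as raw area (the raw
  # area sigmoid is biased when dCp shifts dH across the transition).
  iterate_alpha <- function(pre, post) {
    pre_v <- pre[1] + pre[2] * tt
    post_v <- post[1] + post[2] * tt
    t_pk <- tt[imax]
    dcp_est <- (post[1] + post[2] * t_pk) - (pre[1] + pre[2] * t_pk)
    alpha <- rep(0.5, n)
    for (it in seq_len(max_iter)) {
      base <- (1 - alpha) * pre_v + alpha * post_v
      resid <- pmax(cp - base, 0)
      h0 <- .trapz(tt, resid)
      if (h0 <= 0) stop("no transition area above the baseline")
      dh_t <- pmax(h0 + dcp_est * (tt - t_pk), 0.05 * h0)
      wts <- resid / dh_t
      cum <- cumsum(c(0, diff(tt) * (head(wts, -1) + tail(wts, -1)) / 2))
      alpha <- cum / cum[n]
    }
    alpha
  }
  ln <- fit_lines(pre_idx, post_idx)
  if (!progress) {
    out <- cp - (ln$pre[1] + ln$pre[2] * tt)
    alpha <- NULL
    model <- dsc_baseline(pre = ln$pre, post = ln$pre, progress = FALSE)
  } else {
    alpha <- iterate_alpha(ln$pre, ln$post)
    # purity refinement: windows restricted to essentially pure states
    pre_idx2 <- intersect(pre_idx, which(alpha < purity))
    post_idx2 <- intersect(post_idx, which(alpha > 1 - purity))
    if (length(pre_idx2) < 2L || length(post_idx2) < 2L)
      stop("transition not resolved within the trace: no pure-state ",
           "baseline windows (progress purity ", purity, "); consider ",
           "fit_two_state() for truncated or overlapping transitions")
    ln <- fit_lines(pre_idx2, post_idx2)
    alpha <- iterate_alpha(ln$pre, ln$post)
    model <- dsc_baseline(pre = ln$pre, post = ln$post, progress = TRUE)
    out <- cp - ((1 - alpha) * (ln$pre[1] + ln$pre[2] * tt) +
                   alpha * (ln$post[1] + ln$post[2] * tt))
    # self-consistency: the measured (Td, dHcal, dCp) must predict pure
    # states at the grid edges, otherwise the scan truncates the
    # transition (or it overlaps cold denaturation) and the integral is
    # not trustworthy
    dh_est <- .trapz(tt, out)
    if (dh_est > 0) {
      t_pk <- tt[imax]
      dcp_chk <- max(0, (ln$post[1] + ln$post[2] * t_pk) -
                       (ln$pre[1] + ln$pre[2] * t_pk))
      p_est <- two_state_params(t_pk, dh_est, dcp_chk)
      f_edges <- denatured_fraction(tt[c(1L, n)], p_est)
      if (f_edges[1] > purity || f_edges[2] < 1 - purity)
        stop("transition not resolved within the trace (predicted ",
             "denatured fraction at the grid edges: ",
             signif(f_edges[1], 2), ", ", signif(f_edges[2], 3),
             "); the scan truncates the transition or it overlaps cold ",
             "denaturation; consider fit_two_state()")
    }
  }
  res <- dsc_trace(tt, out, label = trace$label, cosolute = trace$cosolute)
  attr(res, "baseline") <- model
  attr(res, "progress_weight") <- alpha
  res
}

#' Calorimetric enthalpy of a DSC peak
#'
#' The model-free transition enthalpy: the total integrated area below the
#' baseline-subtracted DSC peak, by the trapezoidal rule on the native grid
#' (no resampling).
#'
#' @param trace a baseline-subtracted [dsc_trace()].
#' @return \eqn{\Delta H_{cal}} in kJ/mol.
#' @export
calorimetric_enthalpy <- function(trace) {
  stopifnot(inherits(trace, "dsc_trace"))
  area <- .trapz(trace$temperature, trace$cp_excess)
  if (area <= 0)
    stop("non-positive peak area: baseline subtraction failed")
  area
}

#' Van't Hoff enthalpy of a DSC peak
#'
#' Transition enthalpy inferred from the sharpness of the peak under the
#' two-state assumption, using the Privalov relation at the transition
#' midpoint:
#' \deqn{\Delta H_{vH} = \frac{4 R T_{1/2}^2\, C_{p,ex}(T_{1/2})}{\Delta H_{cal}}}
#' For an ideal two-state transition this equals the calorimetric enthalpy;
#' the ratio of the two ([cooperativity_ratio()]) is the standard test that
#' the protein unfolds as a single cooperative unit.
#'
#' When the trace carries the progress weights attached by
#' [subtract_baseline()], the midpoint is taken where the progress crosses
#' one half (the temperature at which the folded and unfolded states are
#' equally populated); otherwise the peak maximum is used. The two coincide
#' when the heat-capacity change is zero, and differ by a fraction of a
#' Kelvin otherwise.
#'
#' @param trace a baseline-subtracted [dsc_trace()].
#' @param td,dh_cal optionally precomputed transition temperature and
#'   calorimetric enthalpy; computed from the trace when `NULL`.
#' @return \eqn{\Delta H_{vH}} in kJ/mol.
#' @export
vant_hoff_enthalpy <- function(trace, td = NULL, dh_cal = NULL) {
  stopifnot(inherits(trace, "dsc_trace"))
  if (is.null(dh_cal)) dh_cal <- calorimetric_enthalpy(trace)
  if (dh_cal <= 0) stop("dh_cal must be positive")
  alpha <- attr(trace, "progress_weight")
  if (!is.null(alpha)) {
    tt <- trace$temperature
    t_half <- stats::approx(alpha, tt, xout = 0.5, ties = "ordered")$y
    cp_half <- stats::approx(tt, trace$cp_excess, xout = t_half)$y
    return(4 * .R_kJ * t_half^2 * cp_half / dh_cal)
  }
  pk <- .peak_quad(trace)
  if (is.null(td)) td <- pk$td
  4 * .R_kJ * td^2 * pk$cp_peak / dh_cal
}

#' Cooperativity ratio
#'
#' Ratio of calorimetric to van't Hoff enthalpy,
#' \eqn{\Delta H_{cal} / \Delta H_{vH}}. Values close to one indicate a
#' single cooperative two-state transition; values above one suggest
#' independently melting subdomains.
#'
#' @param dh_cal calorimetric enthalpy, kJ/mol; positive.
#' @param dh_vh van't Hoff enthalpy, kJ/mol; positive.
#' @return the dimensionless ratio.
#' @examples
#' cooperativity_ratio(470, 490)  # 0.96
#' @export
cooperativity_ratio <- function(dh_cal, dh_vh) {
  if (any(dh_vh == 0)) stop("dh_vh must be non-zero")
  if (any(dh_cal <= 0) || any(dh_vh <= 0))
    stop("enthalpies must be positive")
  dh_cal / dh_vh
}

#' Analyze a baseline-subtracted DSC trace
#'
#' Convenience wrapper returning the four quantities conventionally reported
#' per scan: transition temperature, calorimetric enthalpy, van't Hoff
#' enthalpy and their ratio.
#'
#' @param trace a baseline-subtracted [dsc_trace()].
#' @return a `dsc_result` list with fields `td` (K), `dh_cal`, `dh_vh`
#'   (kJ/mol) and `ratio`.
#' @export
analyze_trace <- function(trace) {
  td <- find_td(trace)
  dh_cal <- calorimetric_enthalpy(trace)
  dh_vh <- vant_hoff_enthalpy(trace, td = td, dh_cal = dh_cal)
  structure(list(td = td, dh_cal = dh_cal, dh_vh = dh_vh,
                 ratio = cooperativity_ratio(dh_cal, dh_vh)),
            class = "dsc_result")
}

#' @export
print.dsc_result <- function(x, ...) {
  cat(sprintf("Td = %.2f C  dHcal = %.1f kJ/mol  dHvH = %.1f kJ/mol  ratio = %.3f\n",
              kelvin_to_celsius(x$td), x$dh_cal, x$dh_vh, x$ratio))
  invisible(x)
}

#' Fit the two-state model to a DSC trace
#'
#' Unweighted nonlinear least squares of the forward excess-heat-capacity
#' model ([excess_cp()]) against a baseline-subtracted trace, via
#' Levenberg-Marquardt. Initialization is deterministic: `Td` from
#' [find_td()], `dHd` from [calorimetric_enthalpy()], `dCp` from the offset
#' between the post- and pre-transition window means.
#'
#' @param trace a baseline-subtracted [dsc_trace()] covering the transition.
#' @param init optional [two_state_params()] starting point.
#' @return a `two_state_fit` list: `params` (a [two_state_params()]), `rss`,
#'   `fitted`, `residuals`, `n_points`, and `se` (asymptotic standard
#'   errors).
#' @examples
#' p <- two_state_params(375.75, 470, 5.2)
#' tr <- simulate_trace(p, seq(340, 400, by = 0.1))
#' fit_two_state(tr)$params
#' @export
fit_two_state <- function(trace, init = NULL) {
  stopifnot(inherits(trace, "dsc_trace"))
  tt <- trace$temperature
  cp <- trace$cp_excess
  if (is.null(init)) {
    start <- tryCatch({
      td0 <- find_td(trace)
      dh0 <- .trapz(tt, cp)
      nw <- max(2L, ceiling(0.15 * length(tt)))
      dcp0 <- max(0, mean(tail(cp, nw)) - mean(head(cp, nw)))
      if (dh0 <= 0) stop("non-positive initial enthalpy")
      list(td = td0, dhd = dh0, dcp = dcp0)
    }, error = function(e) {
      stop("cannot initialize two-state fit (degenerate trace): ",
           conditionMessage(e))
    })
  } else {
    stopifnot(inherits(init, "two_state_params"))
    start <- list(td = init$td, dhd = init$dhd, dcp = init$dcp)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      cp ~ .cpex_raw(tt, td, dhd, dcp),
      start = start,
      lower = c(td = 1, dhd = 1e-3, dcp = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) {
      stop("two-state fit did not converge (last start: Td=",
           signif(start$td, 6), ", dHd=", signif(start$dhd, 6),
           ", dCp=", signif(start$dcp, 6), "): ", conditionMessage(e))
    })
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(
    params = two_state_params(est[["td"]], est[["dhd"]], max(0, est[["dcp"]])),
    rss = sum(resid(fit)^2),
    fitted = fitted(fit),
    residuals = resid(fit),
    n_points = length(tt),
    se = setNames(se, c("td", "dhd", "dcp"))
  ), class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  RSS = %.4g over %d points\n", x$rss, x$n_points))
  invisible(x)
}
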