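buffer_params <- function() two_state_params(375.75, 470, 5.2)

test_that("simulated traces reproduce the forward model and are seeded", {
  p <- buffer_params()
  grid <- dsc_grid(p)
  tr <- simulate_trace(p, grid)
  expect_equal(tr$cp_excess, excess_cp(grid, p))
  n1 <- simulate_trace(p, grid, noise_sd = 0.5, seed = 11)
  n2 <- simulate_trace(p, grid, noise_sd = 0.5, seed = 11)
  expect_identical(n1$cp_excess, n2$cp_excess)
  n3 <- simulate_trace(p, grid, noise_sd = 0.5, seed = 12)
  expect_false(identical(n1$cp_excess, n3$cp_excess))
  expect_equal(sd(n1$cp_excess - tr$cp_excess), 0.5, tolerance = 0.1)
  expect_error(simulate_trace(p, numeric(0)), "empty")
  expect_error(simulate_trace(p, c(100, 900)), "inside")
})

test_that("baseline subtraction inverts a known linear instrument baseline", {
  p <- two_state_params(375.75, 470, 0)
  grid <- dsc_grid(p, widths = 35)
  base <- dsc_baseline(pre = c(-30, 0.1), post = c(-30, 0.1),
                       progress = FALSE)
  tr <- simulate_trace(p, grid, baseline = base)
  rec <- subtract_baseline(tr, progress = FALSE)
  expect_lt(max(abs(rec$cp_excess - excess_cp(grid, p))), 1e-8)
  # null baseline: subtraction is the identity up to fit noise
  tr0 <- simulate_trace(p, grid)
  rec0 <- subtract_baseline(tr0, progress = FALSE)
  expect_lt(max(abs(rec0$cp_excess - tr0$cp_excess)), 1e-8)
})

test_that("the peak area equals the generating enthalpy after progress
           baseline subtraction", {
  # instrument baseline plus the intrinsic f*dCp shift, both removed
  p <- buffer_params()
  grid <- dsc_grid(p)
  base <- dsc_baseline(pre = c(5, 0.02), post = c(9, 0.015))
  tr <- simulate_trace(p, grid, baseline = base)
  sb <- subtract_baseline(tr)
  expect_equal(calorimetric_enthalpy(sb), 470, tolerance = 5e-3)
})

test_that("scans that truncate the transition are refused by the integral
           route but handled by the model fit", {
  # the aqueous-buffer transition (102.6 C) ends ~12 K before a 115 C scan
  # limit: the unfolded baseline never becomes pure
  ds <- make_dsc_dataset()
  expect_error(subtract_baseline(ds$trace), "not resolved")
  fit <- fit_two_state(ds$trace)
  expect_equal(fit$params$td, ds$truth$td, tolerance = 1e-3)
  expect_equal(fit$params$dhd, ds$truth$dhd, tolerance = 1e-3)
})

test_that("find_td locates the transition and ignores offsets", {
  p <- two_state_params(375.75, 470, 0)
  grid <- dsc_grid(p)
  tr <- simulate_trace(p, grid)
  expect_equal(find_td(tr), 375.75, tolerance = 0.1)
  shifted <- dsc_trace(tr$temperature, tr$cp_excess + 3.7)
  expect_equal(find_td(shifted), find_td(tr))
  # truncated transition: maximum on the boundary is refused
  cut <- dsc_trace(grid[grid <= 375.75], excess_cp(grid[grid <= 375.75], p))
  expect_error(find_td(cut), "boundary")
})

test_that("find_td is accurate to 0.2 K under 1% peak noise", {
  p <- two_state_params(375.75, 470, 0)
  grid <- dsc_grid(p)
  peak <- max(excess_cp(grid, p))
  tds <- vapply(1:100, function(i) {
    find_td(simulate_trace(p, grid, noise_sd = 0.01 * peak, seed = i))
  }, numeric(1))
  expect_lt(max(abs(tds - 375.75)), 0.2)
})

test_that("calorimetric enthalpy integrates the peak", {
  p <- two_state_params(375.75, 470, 0)
  grid <- dsc_grid(p)
  tr <- simulate_trace(p, grid)
  a <- calorimetric_enthalpy(tr)
  expect_equal(a, 470, tolerance = 1e-3)
  doubled <- dsc_trace(grid, 2 * tr$cp_excess)
  expect_equal(calorimetric_enthalpy(doubled), 2 * a, tolerance = 1e-12)
  # halving the grid density changes the trapezoid value only within its
  # discretization error bound
  coarse <- dsc_trace(grid[c(TRUE, FALSE)], tr$cp_excess[c(TRUE, FALSE)])
  expect_equal(calorimetric_enthalpy(coarse), a, tolerance = 1e-4)
  expect_error(calorimetric_enthalpy(dsc_trace(grid, -tr$cp_excess - 1)),
               "non-positive")
})

test_that("van't Hoff enthalpy is self-consistent for two-state traces and
           detects independent transitions", {
  p <- two_state_params(375.75, 470, 0)
  grid <- dsc_grid(p)
  tr <- simulate_trace(p, grid)
  vh <- vant_hoff_enthalpy(tr)
  expect_equal(vh, 470, tolerance = 5e-3)
  # peak height halved at fixed reported area -> halved vH enthalpy
  halved <- dsc_trace(grid, tr$cp_excess / 2)
  expect_equal(vant_hoff_enthalpy(halved, dh_cal = calorimetric_enthalpy(tr)),
               vh / 2, tolerance = 1e-6)
  # two well-separated independent transitions: the calorimetric area sums
  # but the apparent sharpness reflects one domain -> ratio > 1
  p2 <- two_state_params(345, 470, 0)
  g2 <- seq(315, 406, by = 0.1)
  two <- dsc_trace(g2, excess_cp(g2, two_state_params(375.75, 470, 0)) +
                         excess_cp(g2, p2))
  dh_cal <- calorimetric_enthalpy(two)
  dh_vh <- vant_hoff_enthalpy(two)
  expect_gt(dh_cal, 900)
  expect_lt(dh_vh, dh_cal)
  expect_gt(cooperativity_ratio(dh_cal, dh_vh), 1)
})

test_that("cooperativity ratio reproduces reported scan ratios", {
  expect_equal(round(cooperativity_ratio(470, 490), 2), 0.96)
  expect_equal(round(cooperativity_ratio(425, 435), 2), 0.98)
  expect_equal(cooperativity_ratio(123.4, 123.4), 1)
  expect_error(cooperativity_ratio(470, 0), "non-zero")
})

test_that("two-state fits recover generating parameters", {
  p <- buffer_params()
  grid <- dsc_grid(p)
  fit <- fit_two_state(simulate_trace(p, grid))
  expect_equal(fit$params$td, p$td, tolerance = 1e-3)
  expect_equal(fit$params$dhd, p$dhd, tolerance = 1e-3)
  expect_equal(fit$params$dcp, p$dcp, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10)
  expect_error(fit_two_state(dsc_trace(grid, rep(1, length(grid)))),
               "degenerate|converge")
})

test_that("noisy two-state fits are unbiased within Monte-Carlo error", {
  p <- two_state_params(375.75, 470, 5.2)
  grid <- dsc_grid(p, step = 0.2)
  peak <- max(excess_cp(grid, p))
  est <- vapply(1:100, function(i) {
    f <- fit_two_state(simulate_trace(p, grid, noise_sd = 0.01 * peak,
                                      seed = 500 + i))
    c(f$params$td, f$params$dhd)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - p$td), 0.1)
  expect_lt(abs(mean(est[2, ]) - p$dhd) / p$dhd, 0.02)
  # bias within ~2 Monte-Carlo standard errors of zero
  for (j in 1:2) {
    se <- sd(est[j, ]) / sqrt(ncol(est))
    expect_lt(abs(mean(est[j, ]) - c(p$td, p$dhd)[j]), 3 * se)
  }
})

test_that("DSC CSV dialect round-trips in Celsius", {
  p <- two_state_params(350, 400, 2)
  tr <- simulate_trace(p, dsc_grid(p, step = 0.5), noise_sd = 0.2, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dsc_csv(tr, path)
  expect_match(readLines(path, n = 1), "temperature_C,cp_excess_kJ_per_K_mol")
  back <- read_dsc_csv(path)
  expect_equal(back$temperature, tr$temperature, tolerance = 1e-10)
  expect_equal(back$cp_excess, tr$cp_excess, tolerance = 1e-10)
})
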