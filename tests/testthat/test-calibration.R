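test_that("linear fits recover exact lines and flag bad input", {
  cv <- fit_linear(c(0, 1, 2), c(1, 3, 5))
  expect_equal(unname(cv$coefficients), c(1, 2))
  expect_equal(cv$r_squared, 1)
  expect_equal(predict(cv, c(0, 1, 2)), c(1, 3, 5))
  expect_error(fit_linear(c(1, 2), c(1, 2)), "3 distinct")
  expect_error(fit_linear(c(2, 2, 2), c(1, 2, 3)), "3 distinct")
})

test_that("simulated PCT calibrations recover the generator slope", {
  # parameter recovery under the reported intra-assay noise: the median
  # fitted slope over 200 seeded calibrations is within 2% of truth
  p <- test_params()
  slopes <- vapply(1:200, function(s) {
    panel <- generate_calibration_panel(analyte = "pct", params = p,
                                        noise_cv = 0.09, seed = s)
    means <- tapply(panel$truth$intensity, panel$truth$true_conc, mean)
    fit <- fit_linear(as.numeric(names(means)), as.numeric(means))
    fit$coefficients[["slope"]]
  }, numeric(1))
  expect_lt(abs(median(slopes) - p$alpha_pct) / p$alpha_pct, 0.02)
  # and individual recoveries stay within 5%
  expect_lt(median(abs(slopes - p$alpha_pct) / p$alpha_pct), 0.05)
})

test_that("r_squared matches its definition", {
  x <- c(2, 4, 9, 1)
  expect_equal(r_squared(x, x), 1)
  expect_equal(r_squared(x, rep(mean(x), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(3, 3, 3), c(1, 2, 3)), "no variance")
})

test_that("the Akima fit interpolates its knots and controls overshoot", {
  p <- test_params()
  curve <- default_crp_curve(p)
  # interpolation contract: knots reproduced exactly
  expect_equal(predict(curve, curve$knots_conc), curve$knots_intensity,
               tolerance = 1e-12)
  expect_equal(curve$r_squared, 1)
  # replicate-level R2 below 1 under scatter
  ladder <- default_ladder("crp")
  reps <- data.frame(conc = rep(ladder, each = 3),
                     intensity = rep(crp_signal(ladder, p), each = 3) *
                       rep(c(0.95, 1, 1.05), length(ladder)))
  noisy <- fit_akima(ladder, crp_signal(ladder, p), replicates = reps)
  expect_lt(noisy$r_squared, 1)
  expect_gt(noisy$r_squared, 0.9)
  # unsorted and duplicated calibrators are handled
  shuf <- c(5, 0.05, 1, 0.5, 10, 0.25, 0.1, 2.5, 2.5)
  dup <- fit_akima(shuf, crp_signal(shuf, p))
  expect_equal(predict(dup, ladder), predict(curve, ladder),
               tolerance = 1e-12)
  expect_error(fit_akima(c(1, 2, 3, 4), 1:4), "5 distinct")
  expect_error(fit_akima(c(0, 1, 2, 3, 4), 0:4), "> 0")
  # monotone calibrators (ascending branch) give a monotone interpolant
  asc <- c(0.05, 0.1, 0.25, 0.5, 1)
  mono <- fit_akima(asc, crp_signal(asc, p))
  g <- 10^seq(log10(0.05), 0, length.out = 2001)
  expect_true(all(diff(predict(mono, g)) > -1e-9))
  expect_true(is.na(mono$hook_apex))  # no interior maximum, no hook
})

test_that("the fitted hook apex matches the dense-grid oracle", {
  # frozen oracle: argmax of the modified-Akima interpolant through the
  # noiseless default ladder on the 10,001-point log grid (cross-checked
  # against an independent implementation of the same slope rule)
  curve <- default_crp_curve()
  expect_equal(curve$hook_apex, 0.9707035, tolerance = 1e-6)
  expect_true(curve$hook_apex > curve$conc_range[1] &&
                curve$hook_apex < curve$conc_range[2])
  # the apex value is the interpolant maximum on that grid
  g <- 10^seq(log10(0.05), log10(10), length.out = 10001)
  expect_equal(curve$apex_intensity, max(predict(curve, g)))
})

test_that("the original-Akima mode reproduces pracma exactly", {
  set.seed(9)
  for (i in 1:5) {
    n <- sample(5:9, 1)
    x <- sort(runif(n, 0.5, 10))
    y <- rnorm(n)
    xi <- seq(min(x), max(x), length.out = 101)
    mine <- lfaquant:::hermite_eval(
      x, y, lfaquant:::akima_slopes(x, y, "akima"), xi)
    expect_equal(mine, pracma::akimaInterp(x, y, xi), tolerance = 1e-12)
  }
})

test_that("linear inversion is the exact inverse of evaluation", {
  cv <- fit_linear(c(0.5, 1, 5, 10, 50, 100),
                   pct_signal(c(0.5, 1, 5, 10, 50, 100)))
  set.seed(4)
  c_true <- runif(100, 0.5, 100)
  back <- invert_linear(cv, predict(cv, c_true))
  expect_lt(max(abs(as.numeric(back) - c_true)), 1e-9 * 100)
  expect_false(any(attr(back, "extrapolated")))
  # intensity at the intercept maps to zero concentration (flagged
  # extrapolated: 0 lies below the calibrated range)
  at0 <- invert_linear(cv, cv$coefficients[["intercept"]])
  expect_equal(as.numeric(at0), 0)
  expect_true(attr(at0, "extrapolated"))
  bad <- structure(list(model = "linear",
                        coefficients = c(intercept = 1, slope = 0),
                        conc_range = c(0, 1)), class = "lfa_curve")
  expect_error(invert_linear(bad, 5), "zero slope")
})

test_that("hooked inversion finds both branches to tolerance", {
  p <- test_params()
  curve <- default_crp_curve(p)
  fmax <- curve$apex_intensity
  # candidates reproduce the queried intensity within 1e-6 of its scale
  for (frac in c(0.15, 0.4, 0.7, 0.9)) {
    cand <- invert_hooked(curve, frac * fmax)
    expect_false(cand$degenerate)
    expect_lt(cand$c_low, curve$hook_apex)
    expect_gt(cand$c_high, curve$hook_apex)
    expect_lt(abs(predict(curve, cand$c_low) - frac * fmax), 1e-6 * fmax)
    expect_lt(abs(predict(curve, cand$c_high) - frac * fmax), 1e-6 * fmax)
  }
  # a known ascending-branch point round-trips, the descending candidate
  # matches the brute-force grid-scan oracle
  i25 <- predict(curve, 0.25)
  cand <- invert_hooked(curve, i25)
  expect_equal(cand$c_low, 0.25, tolerance = 1e-6)
  expect_equal(cand$c_high, grid_scan_root(curve, i25, "high"),
               tolerance = 1e-4)
  # the apex intensity is degenerate; above-maximum and non-positive error
  at_apex <- invert_hooked(curve, fmax)
  expect_true(at_apex$degenerate)
  expect_equal(at_apex$c_low, curve$hook_apex)
  expect_error(invert_hooked(curve, 1.05 * fmax), "exceeds")
  expect_error(invert_hooked(curve, 0), "below range")
  lin <- fit_linear(c(0, 1, 2), c(1, 3, 5))
  expect_error(invert_hooked(lin, 2), "Akima")
})

test_that("below-range evaluation continues linearly through the origin", {
  curve <- default_crp_curve()
  c1 <- curve$knots_conc[1]
  y1 <- curve$knots_intensity[1]
  expect_equal(predict(curve, c1 / 4), y1 / 4, tolerance = 1e-12)
  expect_equal(predict(curve, 0), 0)
})

test_that("LoD follows the blank mean + 3 SD convention", {
  # hand case on an exact line I = 5 + 20 c with blanks mean 10, SD 2
  lin <- fit_linear(c(0, 1, 2), c(5, 25, 45))
  expect_equal(estimate_lod(c(8, 10, 12), lin), (16 - 5) / 20)
  # zero-variance blanks at the curve value of c* give LoD = c*
  curve <- default_crp_curve()
  c_star <- 0.2
  blanks <- rep(predict(curve, c_star), 5)
  expect_equal(estimate_lod(blanks, curve), c_star, tolerance = 1e-9)
  # noisy blanks agree with a brute-force threshold inversion
  set.seed(12)
  noisy <- 100 * exp(rnorm(10, 0, 0.1))
  thr <- mean(noisy) + 3 * sd(noisy)
  oracle <- grid_scan_root(curve, thr, "low")
  expect_lt(abs(estimate_lod(noisy, curve) - oracle) / oracle, 1e-3)
  expect_error(estimate_lod(c(1, 2), lin), "3 blank")
  expect_error(estimate_lod(rep(2 * curve$apex_intensity, 4), curve),
               "LoD undefined")
})

test_that("curves serialise to JSON and back without loss", {
  dir <- withr::local_tempdir()
  lin <- fit_linear(c(0.5, 1, 5, 10, 50, 100),
                    pct_signal(c(0.5, 1, 5, 10, 50, 100)))
  ak <- default_crp_curve()
  for (curve in list(lin, ak)) {
    path <- file.path(dir, paste0(curve$model, ".json"))
    write_curve(curve, path)
    back <- read_curve(path)
    g <- seq(curve$conc_range[1], curve$conc_range[2], length.out = 50)
    expect_equal(predict(back, g), predict(curve, g), tolerance = 1e-12)
    expect_equal(back$r_squared, curve$r_squared)
  }
})
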