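test_that("brightness conversion follows the documented mapping", {
  raw <- matrix(c(0, 1000, 30000, 65535), 2)
  # gain chosen so the brightest pixel maps to 255 exactly: no clipping
  out <- apply_brightness(raw, gain = 1)
  expect_identical(out[2, 2], 255L)
  expect_equal(out, matrix(as.integer(round(raw * 255 / 65535)), 2),
               ignore_attr = TRUE)
  # pixelwise non-decreasing in gain
  g <- sort(runif(6, 0.5, 40))
  imgs <- lapply(g, function(gg) apply_brightness(raw, gg))
  for (i in seq_len(length(g) - 1))
    expect_true(all(imgs[[i + 1]] >= imgs[[i]]))
  expect_error(apply_brightness(raw, 0), "gain")
})

test_that("band areas saturate once the brightest pixel clips", {
  lay <- test_layout()
  img <- render_strip(c(crp = 0, pct = 4000, control = 0), lay,
                      test_params())
  area_at <- function(gain) {
    quantify_strip(img, roi = lay$roi, layout = lay, gain = gain)$area_pct
  }
  # the brightest band pixel (blank 300 + peak ~319 raw counts) clips at
  # gain ~105; below that the area tracks the gain, beyond it saturates
  gains <- c(20, 40, 80, 105, 120)
  areas <- vapply(gains, area_at, numeric(1))
  expect_gt(areas[2] / areas[1], 1.9)
  expect_gt(areas[3] / areas[2], 1.9)
  expect_lt(areas[5], areas[4] * 1.02)
})

test_that("profiles are averaged over the ROI and baseline-corrected", {
  roi <- test_roi()
  v <- 87
  uniform <- matrix(v, roi$height_px, roi$width_px)
  prof <- extract_profile(uniform, roi)
  expect_equal(prof$raw_values, rep(v, roi$height_px))
  expect_equal(prof$values, rep(0, roi$height_px))
  expect_equal(prof$values, prof$raw_values - prof$baseline)
  expect_equal(length(prof$positions), roi$height_px)
  # a linear illumination ramp is removed by the baseline
  ramp <- matrix(rep(seq(10, 40, length.out = roi$height_px),
                     roi$width_px), roi$height_px)
  expect_lt(max(abs(extract_profile(ramp, roi)$values)), 1e-9)
  # single-band strip: corrected profile peaks at the band row
  lay <- test_layout()
  img <- render_strip(c(pct = 3000), lay, test_params())
  prof2 <- extract_profile(apply_brightness(img, 60), roi)
  expect_lt(abs(prof2$positions[which.max(prof2$values)] -
                  lay$line_centers_px[["pct"]]), 1.5)
  expect_error(extract_profile(uniform, roi_spec(height_px = 400)),
               "bounds")
})

test_that("line windows track the bands and fall back when blank", {
  lay <- test_layout()
  p <- test_params()
  img <- render_strip(c(crp = 3000, pct = 3000, control = 8000), lay, p)
  prof <- extract_profile(apply_brightness(img, 60), lay$roi)
  win <- locate_lines(prof, lay)
  expect_identical(win$line, c("crp", "pct", "control"))
  for (line in win$line)
    expect_lt(abs(win[line, "center"] - lay$line_centers_px[[line]]), 1.5)
  # blank strip: no peak above noise, windows sit at the expected centres
  blank <- extract_profile(matrix(50, lay$roi$height_px, lay$roi$width_px),
                           lay$roi)
  win0 <- locate_lines(blank, lay)
  expect_equal(win0$center, as.numeric(round(lay$line_centers_px)))
  # a global shift within the search range moves all windows with it
  shift <- 5
  shifted <- prof
  shifted$values <- c(rep(0, shift),
                      prof$values[seq_len(length(prof$values) - shift)])
  win5 <- locate_lines(shifted, lay)
  expect_equal(win5$center, win$center + shift)
})

test_that("Simpson's 3/8 rule is exact on cubics and matches a fine-grid
           trapezoid oracle", {
  # constant value v over L = 3k intervals integrates to v * L
  expect_equal(simpson38(rep(4.5, 61)), 4.5 * 60)
  # exact for random cubics (closed-form oracle)
  set.seed(31)
  for (i in 1:10) {
    cf <- rnorm(4)
    x <- 0:36
    y <- cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3
    analytic <- function(t) cf[1] * t + cf[2] * t^2 / 2 +
      cf[3] * t^3 / 3 + cf[4] * t^4 / 4
    expect_equal(simpson38(y), analytic(36) - analytic(0),
                 tolerance = 1e-12)
  }
  # smooth profile: agree with a 10x-resampled trapezoid oracle
  for (i in 1:5) {
    ctr <- runif(1, 20, 40)
    sg <- runif(1, 4, 8)
    f <- function(t) 40 * exp(-(t - ctr)^2 / (2 * sg^2)) +
      5 * sin(t / 9) + 10
    coarse <- f(0:60)
    fine_x <- seq(0, 60, by = 0.1)
    oracle <- pracma::trapz(fine_x, f(fine_x))
    expect_lt(abs(simpson38(coarse) - oracle) / abs(oracle), 0.005)
  }
  expect_error(simpson38(1:3), "3k intervals")
  expect_error(simpson38(1:6), "3k intervals")
})

test_that("peak integration trims to the 3/8 rule and floors at zero", {
  roi <- test_roi()
  prof <- extract_profile(matrix(20, roi$height_px, roi$width_px), roi)
  # a constant profile carries no peak: the local flanking baseline
  # removes it entirely
  prof$values <- rep(2, roi$height_px)
  expect_equal(integrate_peak(prof, list(lo = 100, hi = 160)), 0)
  # Gaussian band: area matches the closed form amp * sigma * sqrt(2*pi)
  prof$values <- 50 * exp(-(prof$positions - 130)^2 / (2 * 5^2))
  truth <- 50 * 5 * sqrt(2 * pi)
  expect_equal(integrate_peak(prof, list(lo = 105, hi = 155)), truth,
               tolerance = 0.01)
  # a window whose interval count is not divisible by 3 is trimmed
  # symmetrically, losing only tail mass
  expect_equal(integrate_peak(prof, list(lo = 105, hi = 154)), truth,
               tolerance = 0.01)
  # negative corrected values floor at zero
  prof$values <- rep(0, roi$height_px)
  prof$values[121:141] <- -6
  expect_equal(integrate_peak(prof, list(lo = 110, hi = 152)), 0)
  expect_error(integrate_peak(prof, list(lo = 10, hi = 12)), ">= 4")
})

test_that("strip quantification handles the canonical detection scenarios", {
  lay <- test_layout()
  p <- test_params()
  # negative control: control line only, test areas ~ 0, strip valid
  blank <- quantify_rendered(c(crp = 0, pct = 0, control = 8000))
  expect_true(blank$control_valid)
  expect_lt(blank$area_crp, 20)
  expect_lt(blank$area_pct, 20)
  # malfunction: no control band -> invalid reading
  broken <- quantify_rendered(c(crp = 3000, pct = 3000, control = 0))
  expect_false(broken$control_valid)
  # co-detection: three positive areas proportional to the intensities
  co <- quantify_rendered(c(crp = 4000, pct = 2000, control = 8000))
  expect_true(co$control_valid)
  expect_equal(co$area_crp / co$area_pct, 2, tolerance = 0.02)
  expect_equal(co$area_ctrl / co$area_pct, 4, tolerance = 0.02)
  # determinism: quantifying the same image twice gives identical readings
  img <- render_strip(c(crp = 1000, pct = 500, control = 8000), lay, p,
                      noise_seed = 3, read_noise_sd = 3)
  r1 <- quantify_strip(img, roi = lay$roi, layout = lay, gain = 60)
  r2 <- quantify_strip(img, roi = lay$roi, layout = lay, gain = 60)
  expect_identical(unclass(r1), unclass(r2))
})

test_that("areas are linear in band intensity and offset-invariant", {
  lay <- test_layout()
  ints <- c(500, 1000, 2000, 3000, 4000)
  areas <- vapply(ints, function(i) {
    quantify_rendered(c(pct = i, control = 8000))$area_pct
  }, numeric(1))
  fit <- lm(areas ~ ints)
  expect_gt(summary(fit)$r.squared, 0.999)
  # adding a constant background offset leaves areas unchanged
  lo <- quantify_rendered(c(pct = 2000, control = 8000),
                          params = test_params(blank_level = 300))
  hi <- quantify_rendered(c(pct = 2000, control = 8000),
                          params = test_params(blank_level = 800))
  expect_equal(hi$area_pct, lo$area_pct, tolerance = 0.02)
})

test_that("batches enforce a single brightness gain", {
  lay <- test_layout()
  imgs <- list(render_strip(c(control = 8000), lay, test_params()),
               render_strip(c(control = 8000), lay, test_params()))
  expect_error(quantify_batch(imgs, roi = lay$roi, layout = lay,
                              gain = c(40, 60)), "one gain per batch")
  out <- quantify_batch(imgs, roi = lay$roi, layout = lay, gain = 60)
  expect_equal(nrow(out), 2)
  expect_true(all(out$gain == 60))
  expect_true(all(out$control_valid))
})
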