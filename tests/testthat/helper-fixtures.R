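# Shared fixtures: a compact strip geometry for fast image tests (coarser
# pixel pitch than the production default, same physical layout) and the
# default forward model.

test_roi <- function() roi_spec(width_px = 40, height_px = 300)

test_layout <- function(band_sigma_px = 5, roi = test_roi()) {
  strip_layout(pixel_pitch_mm = 0.05, band_sigma_px = band_sigma_px,
               roi = roi)
}

test_params <- function(...) forward_model_params(...)

# Render one noiseless strip and quantify it with matching geometry.
quantify_rendered <- function(intensities, gain = 60,
                              layout = test_layout(), params = test_params(),
                              ...) {
  img <- render_strip(intensities, layout = layout, params = params,
                      gain = gain, ...)
  quantify_strip(img, roi = layout$roi, layout = layout, gain = gain)
}

# Noiseless buffer calibration curve for the hooked analyte.
default_crp_curve <- function(params = test_params(), ...) {
  ladder <- default_ladder("crp")
  fit_akima(ladder, crp_signal(ladder, params), ...)
}

# Dense grid-scan inversion oracle: nearest concentration on one branch of
# a curve whose value matches the target intensity.
grid_scan_root <- function(curve, intensity, branch = c("low", "high"),
                           n = 1e6) {
  branch <- match.arg(branch)
  apex <- curve$hook_apex
  r <- curve$conc_range
  g <- if (branch == "low") {
    10^seq(log10(r[1] / 100), log10(apex), length.out = n)
  } else {
    # cover the log-axis continuation beyond the last knot as well
    10^seq(log10(apex), log10(r[2] * 100), length.out = n)
  }
  g[which.min(abs(predict(curve, g) - intensity))]
}
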