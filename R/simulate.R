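#' Render a synthetic raw strip image
#'
#' Emulates the raw 16-bit single-channel sensor output of the fluorescence
#' reader for one strip. The image is `blank_level` counts everywhere plus
#' one Gaussian band per line whose column-integrated amplitude equals the
#' requested line intensity (so a noiseless rendered band carries exactly
#' `intensity` counts.px per column), an optional linear background ramp,
#' and optional Gaussian read noise. Row 1 of the matrix is the strip
#' bottom.
#'
#' @param intensities Named numeric vector of line intensities with names
#'   among `"crp"`, `"pct"`, `"control"`; missing lines are rendered at 0
#'   (absent band). All values must be >= 0.
#' @param layout A [strip_layout()].
#' @param params A [forward_model_params()]; supplies `blank_level`.
#' @param gain Display gain recorded in the metadata (used later by
#'   [apply_brightness()]); must be > 0.
#' @param noise_seed Integer seed for the pixel noise, or `NULL`. The same
#'   seed and parameters give a bit-identical image.
#' @param read_noise_sd Gaussian pixel noise SD in raw counts (default 0).
#' @param background_gradient Amplitude (raw counts) of a linear bottom-to-
#'   top background ramp added to the blank level (default 0).
#' @param strip_id Identifier stored in the metadata.
#' @return An object of class `strip_image`: a list with the integer `raw`
#'   matrix (rows = positions along the strip, bottom first) and `meta`.
#' @examples
#' img <- render_strip(c(crp = 4000, pct = 2000, control = 8000))
#' dim(img$raw)
#' @export
render_strip <- function(intensities, layout = strip_layout(),
                         params = forward_model_params(), gain = 60,
                         noise_seed = NULL, read_noise_sd = 0,
                         background_gradient = 0, strip_id = "strip") {
  stopifnot(inherits(layout, "strip_layout"), gain > 0, read_noise_sd >= 0)
  if (is.null(names(intensities)) ||
      !all(names(intensities) %in% c("crp", "pct", "control")))
    stop("intensities must be named with lines among crp/pct/control")
  if (any(intensities < 0)) stop("line intensities must be non-negative")
  roi <- layout$roi
  height <- roi$y0 + roi$height_px
  width <- roi$x0 + roi$width_px
  rows <- seq_len(height) - 1          # 0-based image positions
  sigma <- layout$band_sigma_px
  profile <- rep(params$blank_level, height)
  if (background_gradient != 0)
    profile <- profile + background_gradient * rows / (height - 1)
  for (line in names(intensities)) {
    center <- roi$y0 + layout$line_centers_px[[line]]
    if (center - 3 * sigma < 0 || center + 3 * sigma > height - 1)
      stop("band for line '", line, "' falls off the image")
    amp <- intensities[[line]] / (sigma * sqrt(2 * pi))
    profile <- profile + amp * exp(-(rows - center)^2 / (2 * sigma^2))
  }
  raw <- matrix(profile, nrow = height, ncol = width)
  if (read_noise_sd > 0)
    raw <- raw + with_seed(noise_seed,
                           matrix(stats::rnorm(length(raw), 0, read_noise_sd),
                                  nrow = height))
  raw <- matrix(pmin(pmax(round(raw), 0), 65535), nrow = height)
  storage.mode(raw) <- "integer"
  structure(list(raw = raw,
                 meta = list(strip_id = strip_id, gain = gain,
                             seed = noise_seed, bit_depth = 16L,
                             pixel_pitch_mm = layout$pixel_pitch_mm,
                             excitation_nm = 380, longpass_nm = 530)),
            class = "strip_image")
}

#' @export
print.strip_image <- function(x, ...) {
  cat(sprintf("<strip_image '%s': %d x %d, %d-bit, gain %g>\n",
              x$meta$strip_id, nrow(x$raw), ncol(x$raw), x$meta$bit_depth,
              x$meta$gain))
  invisible(x)
}

# Replicate intensities for one analyte/concentration under the lognormal
# replicate noise model; control line gets the same multiplicative factor
# scaled draw independently.
#' @noRd
replicate_intensities <- function(conc, analyte, params, replicates, cv,
                                  matrix_scale = 1) {
  base <- analyte_signal(conc, analyte, params) * matrix_scale
  base * lognorm_factors(replicates, cv)
}

#' Generate a synthetic calibration panel
#'
#' Simulates the spiked-buffer calibration experiment: for each calibrator
#' concentration, `replicates` strips whose test-line intensity is the
#' forward-model signal times a lognormal factor with coefficient of
#' variation `noise_cv`. By default the panel is returned in intensity
#' space; with `render = TRUE` each replicate is also rendered to a
#' [render_strip()] image.
#'
#' @param concs Calibrator concentrations (default [default_ladder()] for
#'   the analyte); PCT in ng/mL, CRP in mg/dL.
#' @param replicates Replicates per concentration (default 3).
#' @param analyte `"pct"` or `"crp"`.
#' @param params A [forward_model_params()].
#' @param seed Integer seed; panels are fully reproducible.
#' @param matrix `"buffer"` (default) or `"serum"` (applies the serum
#'   matrix scale).
#' @param noise_cv Replicate CV; default [default_noise_cv()] for the
#'   analyte/matrix unless `params$noise_cv` is set.
#' @param render If `TRUE`, also render one strip image per replicate.
#' @param layout,gain Rendering geometry and display gain (when `render`).
#' @return A list of class `lfa_panel` with `truth` (data frame:
#'   `sample_id`, `analyte`, `true_conc`, `units`, `replicate`,
#'   `dilution_factor`, `intensity`) and, when rendered, `images` (list of
#'   `strip_image` in `truth` row order).
#' @export
generate_calibration_panel <- function(concs = NULL, replicates = 3,
                                       analyte = c("pct", "crp"),
                                       params = forward_model_params(),
                                       seed = 1,
                                       matrix = c("buffer", "serum"),
                                       noise_cv = NULL, render = FALSE,
                                       layout = strip_layout(), gain = 60) {
  analyte <- match.arg(analyte)
  matrix <- match.arg(matrix)
  if (is.null(concs)) concs <- default_ladder(analyte)
  if (length(concs) == 0) stop("concs must be non-empty")
  if (any(concs < 0)) stop("concentrations must be non-negative")
  stopifnot(replicates >= 1)
  cv <- noise_cv %||% params$noise_cv %||% default_noise_cv(analyte, matrix)
  mscale <- if (matrix == "serum") params$serum_scale else 1
  truth <- with_seed(seed, {
    do.call(rbind, lapply(seq_along(concs), function(i) {
      ints <- replicate_intensities(concs[i], analyte, params, replicates,
                                    cv, mscale)
      data.frame(sample_id = sprintf("cal_%s_%02d", analyte, i),
                 analyte = analyte, true_conc = concs[i],
                 units = analyte_units(analyte),
                 replicate = seq_len(replicates), dilution_factor = 1,
                 intensity = ints)
    }))
  })
  panel <- structure(list(truth = truth, analyte = analyte, matrix = matrix,
                          params = params, noise_cv = cv, seed = seed),
                     class = "lfa_panel")
  if (render) panel$images <- render_panel_images(truth, analyte, params,
                                                  layout, gain)
  panel
}

#' @noRd
render_panel_images <- function(truth, analyte, params, layout, gain) {
  lapply(seq_len(nrow(truth)), function(i) {
    ints <- c(control = params$control_level, crp = 0, pct = 0)
    ints[[analyte]] <- truth$intensity[i]
    render_strip(ints, layout = layout, params = params, gain = gain,
                 strip_id = sprintf("%s_r%d", truth$sample_id[i],
                                    truth$replicate[i]))
  })
}

#' Generate a synthetic serum sample panel
#'
#' Simulates a clinical validation panel: `n` true concentrations drawn
#' log-uniformly over `conc_range`, each measured in triplicate with
#' lognormal replicate noise. For CRP (the hooked analyte) every sample
#' additionally gets a 1:10-diluted companion set of readings whose true
#' concentration is exactly `true_conc / dilution_factor`, as used by the
#' serial-dilution disambiguation protocol. PCT is never diluted.
#'
#' Default ranges reflect the clinical panel: 0.22--24.94 ng/mL PCT and
#' 0.05--25 mg/dL CRP (spanning local infection through septic shock, and
#' the hook region for CRP).
#'
#' @param n Number of samples (>= 2).
#' @param analyte `"pct"` or `"crp"`.
#' @param conc_range `c(low, high)` with `0 < low < high`.
#' @param params A [forward_model_params()].
#' @param seed Integer seed.
#' @param replicates Replicates per strip condition (default 3).
#' @param noise_cv Replicate CV; default [default_noise_cv()] for serum.
#' @param dilution_factor Fold-dilution of the CRP companion strips.
#' @param render If `TRUE`, also render strip images.
#' @param layout,gain Rendering geometry and display gain.
#' @return An `lfa_panel` list: `truth` (one row per sample: `sample_id`,
#'   `analyte`, `true_conc`, `units`), `readings` (one row per replicate
#'   per dilution: adds `replicate`, `dilution_factor`, `intensity`), and
#'   optionally `images`.
#' @export
generate_serum_panel <- function(n = 24, analyte = c("pct", "crp"),
                                 conc_range = NULL,
                                 params = forward_model_params(), seed = 1,
                                 replicates = 3, noise_cv = NULL,
                                 dilution_factor = 10, render = FALSE,
                                 layout = strip_layout(), gain = 60) {
  analyte <- match.arg(analyte)
  stopifnot(n >= 2, replicates >= 1, dilution_factor >= 1)
  if (is.null(conc_range))
    conc_range <- switch(analyte, pct = c(0.22, 24.94), crp = c(0.05, 25))
  if (conc_range[1] <= 0 || conc_range[1] >= conc_range[2])
    stop("conc_range must satisfy 0 < low < high")
  cv <- noise_cv %||% params$noise_cv %||% default_noise_cv(analyte, "serum")
  res <- with_seed(seed, {
    true_conc <- sort(exp(stats::runif(n, log(conc_range[1]),
                                       log(conc_range[2]))))
    truth <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                        analyte = analyte, true_conc = true_conc,
                        units = analyte_units(analyte))
    dils <- if (analyte == "crp") c(1, dilution_factor) else 1
    readings <- do.call(rbind, lapply(seq_len(n), function(i) {
      do.call(rbind, lapply(dils, function(d) {
        ints <- replicate_intensities(true_conc[i] / d, analyte, params,
                                      replicates, cv, params$serum_scale)
        data.frame(sample_id = truth$sample_id[i], analyte = analyte,
                   true_conc = true_conc[i], units = truth$units[i],
                   replicate = seq_len(replicates), dilution_factor = d,
                   intensity = ints)
      }))
    }))
    list(truth = truth, readings = readings)
  })
  panel <- structure(list(truth = res$truth, readings = res$readings,
                          analyte = analyte, matrix = "serum",
                          params = params, noise_cv = cv, seed = seed,
                          dilution_factor = dilution_factor),
                     class = "lfa_panel")
  if (render) panel$images <- render_panel_images(
    transform(res$readings,
              sample_id = paste0(res$readings$sample_id, "_d",
                                 res$readings$dilution_factor)),
    analyte, params, layout, gain)
  panel
}

#' @export
print.lfa_panel <- function(x, ...) {
  tab <- if (!is.null(x$readings)) x$readings else x$truth
  cat(sprintf("<lfa_panel: %s in %s, %d readings, noise CV %.1f%%, seed %s>\n",
              toupper(x$analyte), x$matrix, nrow(tab), 100 * x$noise_cv,
              format(x$seed)))
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
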