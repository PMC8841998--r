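#' Convert raw 16-bit sensor counts to an 8-bit display image
#'
#' The reader stores unprocessed raw data and renders 8-bit images at a
#' chosen brightness: `out = clip(round(gain * raw * 255 / 65535), 0, 255)`.
#' The same gain must be applied to every strip of a batch to avoid
#' background disparity (see [quantify_batch()], which enforces this); as
#' the gain grows, band pixels eventually clip at 255 and the integrated
#' line intensity saturates.
#'
#' @param raw A `strip_image` or a raw counts matrix (0..65535).
#' @param gain Brightness gain, > 0.
#' @return An integer matrix of 8-bit grey values with attribute `gain`.
#' @export
apply_brightness <- function(raw, gain) {
  stopifnot(is.numeric(gain), length(gain) == 1, gain > 0)
  m <- if (inherits(raw, "strip_image")) raw$raw else raw
  stopifnot(is.matrix(m))
  out <- pmin(pmax(round(gain * m * 255 / 65535), 0), 255)
  storage.mode(out) <- "integer"
  attr(out, "gain") <- gain
  out
}

#' Extract a baseline-corrected lane profile from a strip image
#'
#' Averages the ROI across its width (after unweighted channel averaging
#' for RGB input) into one grey value per row, bottom row first, and
#' subtracts an estimated background baseline. The baseline is a straight
#' line fitted by least squares to the rows at or below the median profile
#' value — the line regions occupy a minority of the ROI, so the lower half
#' of the grey distribution is background — which removes constant offsets
#' and linear illumination ramps. A uniform image therefore yields a
#' corrected profile that is identically zero.
#'
#' @param image An 8-bit matrix from [apply_brightness()], a `strip_image`
#'   (its raw matrix is used as-is), or an H x W x 3 array.
#' @param roi An [roi_spec()]; must fit inside the image.
#' @return An object of class `lane_profile` with fields `positions`
#'   (0-based, bottom to top), `values` (corrected), `raw_values`, and
#'   `baseline` (`values = raw_values - baseline` elementwise).
#' @export
extract_profile <- function(image, roi = roi_spec()) {
  stopifnot(inherits(roi, "roi_spec"))
  m <- if (inherits(image, "strip_image")) image$raw else image
  if (is.array(m) && length(dim(m)) == 3) {
    m <- (m[, , 1] + m[, , 2] + m[, , 3]) / 3  # unweighted channel mean
  }
  stopifnot(is.matrix(m))
  if (roi$y0 + roi$height_px > nrow(m) || roi$x0 + roi$width_px > ncol(m))
    stop("ROI extends beyond the image bounds")
  sub <- m[roi$y0 + seq_len(roi$height_px), roi$x0 + seq_len(roi$width_px),
           drop = FALSE]
  raw_values <- rowMeans(sub)
  positions <- seq_len(roi$height_px) - 1
  bg <- raw_values <= stats::median(raw_values)
  fit <- stats::lm.fit(cbind(1, positions[bg]), raw_values[bg])
  baseline <- fit$coefficients[1] + fit$coefficients[2] * positions
  structure(list(positions = positions, values = raw_values - baseline,
                 raw_values = raw_values, baseline = baseline),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("<lane_profile: %d rows, corrected range [%.2f, %.2f]>\n",
              length(x$positions), min(x$values), max(x$values)))
  invisible(x)
}

# Robust noise SD of a corrected profile.
#' @noRd
profile_noise_sd <- function(profile) stats::mad(profile$values)

#' Locate the three line windows on a profile
#'
#' For each expected line centre from the layout (CRP below PCT below
#' control), searches the corrected profile for a local maximum within
#' `search_mm` of the expected position and centres a fixed-width
#' integration window of `window_mm` on it. If no peak rises above 3x the
#' robust profile noise in the search range (e.g. a blank test line), the
#' window falls back to the expected centre unshifted. Windows must come
#' out ordered and non-overlapping.
#'
#' @param profile A [extract_profile()] result.
#' @param layout A [strip_layout()]; expected centres and the pixel pitch.
#' @param window_mm Integration window width (default 1.2 mm = 60 px at the
#'   default pitch).
#' @param search_mm Search half-width around the expected centre (default
#'   0.6 mm = 30 px).
#' @param min_peak Absolute grey-level floor a peak must clear in addition
#'   to 3x the robust noise (default 1, the 8-bit quantisation step).
#' @return A data frame with one row per line: `line`, `center`, `lo`,
#'   `hi` (0-based profile positions), `found` (peak above noise?).
#' @export
locate_lines <- function(profile, layout = strip_layout(),
                         window_mm = 1.2, search_mm = 0.6, min_peak = 1) {
  stopifnot(inherits(profile, "lane_profile"),
            inherits(layout, "strip_layout"))
  npos <- length(profile$positions)
  window_px <- max(4, round(window_mm / layout$pixel_pitch_mm))
  search_px <- max(1, round(search_mm / layout$pixel_pitch_mm))
  noise <- profile_noise_sd(profile)
  half <- floor(window_px / 2)
  rows <- lapply(names(layout$line_centers_px), function(line) {
    expected <- round(layout$line_centers_px[[line]])
    span <- max(0, expected - search_px):min(npos - 1, expected + search_px)
    vals <- profile$values[span + 1]
    found <- max(vals) > max(3 * noise, min_peak)
    center <- if (found) span[which.max(vals)] else expected
    data.frame(line = line, center = center,
               lo = max(0, center - half),
               hi = min(npos - 1, center + half), found = found)
  })
  windows <- do.call(rbind, rows)
  windows <- windows[order(windows$center), ]
  if (!identical(windows$line, layout$line_order))
    stop("located line windows are not in the expected bottom-to-top order")
  if (any(diff(windows$center) < window_px))
    stop("line integration windows overlap; check layout or window width")
  rownames(windows) <- windows$line
  windows
}

#' Composite Simpson's 3/8 rule on equally spaced samples
#'
#' Integrates `y` sampled at spacing `h` with the composite 3/8 rule.
#' The number of intervals (`length(y) - 1`) must be divisible by 3. The
#' rule is exact for cubic polynomials.
#'
#' @param y Sample values.
#' @param h Sample spacing (default 1, i.e. pixel rows).
#' @return The integral estimate.
#' @export
simpson38 <- function(y, h = 1) {
  n <- length(y) - 1
  if (n < 3 || n %% 3 != 0)
    stop("simpson38 needs 3k intervals (3k + 1 samples), k >= 1")
  w <- rep(3, n + 1)
  w[seq(1, n + 1, by = 3)] <- 2
  w[c(1, n + 1)] <- 1
  3 * h / 8 * sum(w * y)
}

#' Integrate one line's peak area from a profile
#'
#' Takes the corrected profile over the window, subtracts a local linear
#' baseline through the means of the two 10-px segments just outside the
#' window (robust to residual background ramps), symmetrically trims the
#' window to the largest interval count divisible by 3, and integrates with
#' the composite Simpson's 3/8 rule at unit row spacing. A negative result
#' is floored at 0 (intensity is physically non-negative).
#'
#' @param profile A [extract_profile()] result.
#' @param window A one-row data frame (or list) with 0-based `lo`, `hi`.
#' @param flank_px Width of the flanking baseline segments (default 10).
#' @return The peak area in grey.px.
#' @export
integrate_peak <- function(profile, window, flank_px = 10) {
  stopifnot(inherits(profile, "lane_profile"))
  lo <- window$lo
  hi <- window$hi
  npos <- length(profile$positions)
  if (hi - lo + 1 < 4) stop("integration window must hold >= 4 samples")
  left <- max(0, lo - flank_px):(lo - 1)
  right <- (hi + 1):min(npos - 1, hi + flank_px)
  left <- left[left >= 0]
  right <- right[right <= npos - 1 & right > hi]
  vals <- profile$values[(lo:hi) + 1]
  if (length(left) > 0 && length(right) > 0) {
    x1 <- mean(left); y1 <- mean(profile$values[left + 1])
    x2 <- mean(right); y2 <- mean(profile$values[right + 1])
    slope <- (y2 - y1) / (x2 - x1)
    vals <- vals - (y1 + slope * ((lo:hi) - x1))
  } else if (length(left) + length(right) > 0) {
    vals <- vals - mean(profile$values[c(left, right) + 1])
  }
  n_int <- length(vals) - 1
  r <- n_int %% 3
  if (r > 0) {  # symmetric trim to 3k intervals, bias to the left edge
    drop_lo <- floor(r / 2)
    drop_hi <- r - drop_lo
    vals <- vals[(1 + drop_lo):(length(vals) - drop_hi)]
  }
  max(0, simpson38(vals, h = 1))
}

#' Per-strip line reading
#'
#' Record of the three integrated peak areas of one strip. `control_valid`
#' marks whether the control line rose above the validity threshold; a
#' reading with an invalid control line must be discarded (the control line
#' only validates the strip's function and is never used for
#' quantification).
#'
#' @param area_crp,area_pct,area_ctrl Integrated areas (grey.px), >= 0.
#' @param control_valid Logical.
#' @param gain_used Display gain applied before quantification.
#' @param strip_id Identifier.
#' @return An object of class `line_reading`.
#' @export
line_reading <- function(area_crp, area_pct, area_ctrl,
                         control_valid = TRUE, gain_used = NA_real_,
                         strip_id = "strip") {
  stopifnot(area_crp >= 0, area_pct >= 0, area_ctrl >= 0)
  structure(list(area_crp = area_crp, area_pct = area_pct,
                 area_ctrl = area_ctrl, control_valid = control_valid,
                 gain_used = gain_used, strip_id = strip_id),
            class = "line_reading")
}

#' @export
print.line_reading <- function(x, ...) {
  cat(sprintf(paste0("<line_reading '%s': CRP %.1f, PCT %.1f, control %.1f",
                     " [%s]>\n"),
              x$strip_id, x$area_crp, x$area_pct, x$area_ctrl,
              if (isTRUE(x$control_valid)) "valid" else "INVALID"))
  invisible(x)
}

#' Quantify one strip image into a line reading
#'
#' Full image-processing pipeline: brightness conversion (16-bit raw ->
#' 8-bit at `gain`), ROI profile extraction with baseline correction, line
#' localisation, and Simpson's 3/8 peak integration for the three lines.
#' The control line is valid when its area reaches
#' `5 * robust_noise_SD * window_length` (and at least `min_ctrl_area`,
#' so a flat noiseless profile never validates); readings from strips whose
#' control line failed must not be used downstream.
#'
#' @param image A `strip_image` (raw 16-bit) or an already-converted 8-bit
#'   matrix (then `gain` may be `NULL` and is taken from its attribute).
#' @param roi An [roi_spec()].
#' @param layout A [strip_layout()].
#' @param gain Brightness gain; required for raw input.
#' @param min_ctrl_area Absolute floor of the control-validity threshold in
#'   grey.px (default 10).
#' @param ... Passed to [locate_lines()].
#' @return A [line_reading()].
#' @export
quantify_strip <- function(image, roi = roi_spec(), layout = strip_layout(),
                           gain = NULL, min_ctrl_area = 10, ...) {
  if (inherits(image, "strip_image")) {
    if (is.null(gain)) gain <- image$meta$gain
    strip_id <- image$meta$strip_id
    img8 <- apply_brightness(image, gain)
  } else {
    img8 <- image
    gain <- gain %||% attr(image, "gain") %||% NA_real_
    strip_id <- attr(image, "strip_id") %||% "strip"
  }
  profile <- extract_profile(img8, roi)
  windows <- locate_lines(profile, layout, ...)
  areas <- vapply(c("crp", "pct", "control"), function(line) {
    integrate_peak(profile, windows[line, ])
  }, numeric(1))
  win_len <- windows["control", "hi"] - windows["control", "lo"] + 1
  threshold <- max(5 * profile_noise_sd(profile) * win_len, min_ctrl_area)
  line_reading(area_crp = areas[["crp"]], area_pct = areas[["pct"]],
               area_ctrl = areas[["control"]],
               control_valid = areas[["control"]] >= threshold,
               gain_used = gain, strip_id = strip_id)
}

#' Quantify a batch of strips with one shared gain
#'
#' Applies [quantify_strip()] to every image using a single brightness
#' gain, the batch-consistency requirement of the reader protocol (passing
#' more than one gain is an error).
#'
#' @param images List of `strip_image` objects.
#' @param roi,layout,gain,... As in [quantify_strip()]; `gain` must have
#'   length 1.
#' @return A data frame with one row per strip: `strip_id`, `area_crp`,
#'   `area_pct`, `area_ctrl`, `control_valid`, `gain`.
#' @export
quantify_batch <- function(images, roi = roi_spec(),
                           layout = strip_layout(), gain = 60, ...) {
  if (length(gain) != 1)
    stop("one gain per batch: all strips of a calibration batch must use ",
         "the same brightness setting")
  rows <- lapply(images, function(img) {
    r <- quantify_strip(img, roi = roi, layout = layout, gain = gain, ...)
    data.frame(strip_id = r$strip_id, area_crp = r$area_crp,
               area_pct = r$area_pct, area_ctrl = r$area_ctrl,
               control_valid = r$control_valid, gain = gain)
  })
  do.call(rbind, rows)
}
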