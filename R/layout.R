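#' Region-of-interest specification
#'
#' Pixel window within which the strip profile is extracted. Position 0 is
#' the bottom of the ROI and `height_px - 1` its top; the default
#' 500 x 1500 window (positions 0..1499) matches the fixed ROI used by the
#' reader protocol. The same ROI must be applied to every strip image of a
#' batch for consistency.
#'
#' @param x0,y0 Pixel origin of the ROI inside the image (0-based offsets).
#' @param width_px ROI width in pixels (default 500).
#' @param height_px ROI height in pixels (default 1500).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x0 = 0, y0 = 0, width_px = 500, height_px = 1500) {
  stopifnot(x0 >= 0, y0 >= 0, width_px >= 1, height_px >= 4)
  structure(list(x0 = x0, y0 = y0, width_px = width_px,
                 height_px = height_px),
            class = "roi_spec")
}

#' Strip layout geometry
#'
#' Geometry of the printed lines of the duplex strip: three parallel lines
#' 3 mm apart on a 4 mm-wide membrane, ordered CRP (bottom), PCT (middle),
#' control (top). The layout maps line positions to ROI pixel rows: the
#' middle (PCT) line sits at the ROI mid-height and the other two lines one
#' spacing below/above. Bands are rendered as Gaussians of half-width
#' `band_sigma_px`.
#'
#' @param line_order Bottom-to-top line identities.
#' @param line_spacing_mm Distance between adjacent lines (default 3 mm).
#' @param strip_width_mm Strip width (default 4 mm); metadata only.
#' @param pixel_pitch_mm mm per pixel (default 0.02, so 3 mm = 150 px).
#' @param band_sigma_px Gaussian band half-width in pixels.
#' @param roi An [roi_spec()].
#' @return An object of class `strip_layout` with computed `spacing_px` and
#'   0-based `line_centers_px` (named by line, within the ROI).
#' @export
strip_layout <- function(line_order = c("crp", "pct", "control"),
                         line_spacing_mm = 3.0, strip_width_mm = 4.0,
                         pixel_pitch_mm = 0.02, band_sigma_px = 8,
                         roi = roi_spec()) {
  stopifnot(length(line_order) == 3,
            setequal(line_order, c("crp", "pct", "control")),
            line_spacing_mm > 0, pixel_pitch_mm > 0, band_sigma_px > 0,
            inherits(roi, "roi_spec"))
  if (line_spacing_mm <= 2 * band_sigma_px * pixel_pitch_mm)
    stop("line spacing must exceed 2 * band_sigma_px * pixel_pitch_mm ",
         "so that adjacent bands are resolvable")
  spacing_px <- line_spacing_mm / pixel_pitch_mm
  mid <- (roi$height_px - 1) / 2
  centers <- mid + (-1:1) * spacing_px
  names(centers) <- line_order
  if (any(centers < 0 | centers > roi$height_px - 1))
    stop("line positions fall outside the ROI; enlarge the ROI or reduce ",
         "the pixel pitch")
  structure(list(line_order = line_order,
                 line_spacing_mm = line_spacing_mm,
                 strip_width_mm = strip_width_mm,
                 pixel_pitch_mm = pixel_pitch_mm,
                 band_sigma_px = band_sigma_px,
                 roi = roi, spacing_px = spacing_px,
                 line_centers_px = centers),
            class = "strip_layout")
}
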