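#' Default run configuration
#'
#' @return Nested list of all documented defaults: ROI (500 x 1500),
#'   layout (3 mm spacing, 0.02 mm/px), gain, per-analyte units and
#'   ranges, dilution volumes, solver tolerances, seed, and reader
#'   metadata (380 nm excitation, 530 nm long-pass — informational only;
#'   no computation depends on them).
#' @export
default_config <- function() {
  list(
    roi = list(x0 = 0, y0 = 0, width_px = 500, height_px = 1500),
    layout = list(line_spacing_mm = 3.0, strip_width_mm = 4.0,
                  pixel_pitch_mm = 0.02, band_sigma_px = 8),
    gain = 60,
    analytes = list(
      pct = list(units = "ng/mL", conc_range = c(0.5, 100)),
      crp = list(units = "mg/dL", conc_range = c(0.05, 10))),
    dilution = list(factor = 10, specimen_volume_neat = 25,
                    specimen_volume_diluted = 2.5, diluent_volume = 22.5),
    solver = list(tau_accept = 0.35, rho = 0.10, apex_band = 0.05,
                  grid_n = 10001),
    seed = 1,
    reader = list(excitation_nm = 380, longpass_nm = 530))
}

# Recursive merge of user values into defaults; unknown keys are rejected
# with their full path.
#' @noRd
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    here <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", here)
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        stop("configuration key ", here, " must be a mapping")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], here)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, applies the documented defaults for every
#' omitted field, rejects unknown keys (with the offending field path),
#' and validates the result. An empty or missing-fields file yields the
#' full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated configuration list of class `lfa_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  structure(cfg, class = "lfa_config")
}

#' @noRd
validate_config <- function(cfg) {
  if (cfg$gain <= 0) stop("config error at gain: must be > 0")
  with(cfg$roi, {
    if (width_px < 1 || height_px < 4 || x0 < 0 || y0 < 0)
      stop("config error at roi: invalid geometry")
  })
  with(cfg$layout, {
    if (line_spacing_mm <= 0 || pixel_pitch_mm <= 0 || band_sigma_px <= 0)
      stop("config error at layout: dimensions must be positive")
  })
  with(cfg$solver, {
    if (tau_accept <= 0 || rho <= 0 || apex_band < 0 || grid_n < 101)
      stop("config error at solver: tolerances must be positive")
  })
  with(cfg$dilution, {
    if (abs(dilution_factor(specimen_volume_diluted, diluent_volume) -
              factor) > 1e-9 * factor)
      stop("config error at dilution: volumes do not match the factor")
  })
  invisible(cfg)
}

#' Configuration fingerprint
#'
#' MD5 hash of the canonical JSON serialisation; recorded in every report
#' so results can be traced to the exact configuration.
#'
#' @param config A configuration list.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA, pretty = FALSE)
  unname(tools::md5sum(tmp))
}

#' Write a results report
#'
#' Writes the results table as CSV next to a JSON sidecar recording the
#' schema version, the configuration hash and the seed, so identical
#' inputs always produce byte-identical artifacts.
#'
#' @param results Non-empty data frame of results.
#' @param dir Output directory (created if needed).
#' @param config Configuration used (default [default_config()]).
#' @param seed Seed used for the run.
#' @return Invisibly, the paths written (`csv`, `json`).
#' @export
write_report <- function(results, dir, config = default_config(),
                         seed = NA_integer_) {
  if (!is.data.frame(results) || nrow(results) == 0)
    stop("results must be a non-empty data frame")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "results.csv")
  json <- file.path(dir, "report.json")
  utils::write.csv(results, csv, row.names = FALSE)
  jsonlite::write_json(list(schema_version = "1.0",
                            config_hash = config_hash(config),
                            seed = seed, n_results = nrow(results),
                            columns = names(results)),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(csv = csv, json = json))
}

#' Read back a results report
#'
#' @param dir Directory written by [write_report()].
#' @return List with `results` (data frame) and `meta` (report sidecar).
#' @export
read_report <- function(dir) {
  list(results = utils::read.csv(file.path(dir, "results.csv")),
       meta = jsonlite::read_json(file.path(dir, "report.json"),
                                  simplifyVector = TRUE))
}

#' Write a strip image to PNG (8-bit) or TIFF (16-bit raw)
#'
#' The 16-bit raw counts are stored losslessly as TIFF; PNG output stores
#' the 8-bit rendering after [apply_brightness()] at the image's gain. On
#' disk the first pixel row is the top of the image, so rows are flipped
#' relative to the bottom-first in-memory orientation; [read_strip_image()]
#' restores it.
#'
#' @param image A `strip_image`.
#' @param path Output path ending in `.png` or `.tif`/`.tiff`.
#' @return Invisibly, `path`.
#' @export
write_strip_image <- function(image, path) {
  stopifnot(inherits(image, "strip_image"))
  m <- image$raw[rev(seq_len(nrow(image$raw))), , drop = FALSE]
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img8 <- apply_brightness(m, image$meta$gain)
    png::writePNG(img8 / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Read a strip image from PNG or TIFF
#'
#' TIFF input is interpreted as 16-bit raw counts; PNG as an already
#' brightness-converted 8-bit image (its `bit_depth` metadata is 8 and
#' [quantify_strip()] will skip the brightness step). RGB content is
#' reduced by unweighted channel averaging. Rows are flipped so row 1 is
#' the strip bottom.
#'
#' @param path Image path.
#' @param strip_id Identifier to store (default: file name).
#' @param gain Gain to record for 8-bit input (metadata only).
#' @return A `strip_image`.
#' @export
read_strip_image <- function(path, strip_id = NULL, gain = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop("unsupported image format: .", ext))
  if (length(dim(m)) == 3) m <- (m[, , 1] + m[, , 2] + m[, , 3]) / 3
  scale <- if (ext == "png") 255 else 65535
  raw <- round(m[rev(seq_len(nrow(m))), , drop = FALSE] * scale)
  storage.mode(raw) <- "integer"
  structure(list(raw = raw,
                 meta = list(strip_id = strip_id %||% basename(path),
                             gain = gain,
                             bit_depth = if (ext == "png") 8L else 16L,
                             pixel_pitch_mm = NA_real_,
                             excitation_nm = 380, longpass_nm = 530)),
            class = "strip_image")
}

#' Serialise a calibration curve to JSON
#'
#' @param curve An `lfa_curve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "lfa_curve"))
  obj <- unclass(curve)
  if (!is.null(obj$coefficients))  # keep coefficient names in the JSON
    obj$coefficients <- as.list(obj$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a calibration curve from JSON
#'
#' @param path Path written by [write_curve()].
#' @return An `lfa_curve`.
#' @export
read_curve <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$coefficients))
    obj$coefficients <- unlist(obj$coefficients)
  if (length(obj$blank_stats) == 0) obj$blank_stats <- NULL
  for (f in c("hook_apex", "apex_intensity"))
    if (is.null(obj[[f]])) obj[[f]] <- NA_real_
  new_lfa_curve(obj)
}

#' Write line readings to CSV
#'
#' @param readings Data frame from [quantify_batch()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_readings <- function(readings, path) {
  utils::write.csv(readings, path, row.names = FALSE)
  invisible(path)
}

#' Read line readings from CSV
#'
#' @param path CSV written by [write_readings()].
#' @return Data frame of readings.
#' @export
read_readings <- function(path) utils::read.csv(path)
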