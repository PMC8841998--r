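#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`. For calibration fits the package computes R2
#' against replicate-level intensities (not the fitted means): an
#' interpolating spline reproduces its means exactly, so only replicate
#' scatter makes its R2 meaningful.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @return R-squared.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("R-squared undefined: observations have no variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

# Shared constructor/validator for fitted curves.
#' @noRd
new_lfa_curve <- function(fields) {
  structure(fields, class = "lfa_curve")
}

#' Fit a linear calibration curve (PCT)
#'
#' Ordinary least squares of mean test-line intensity on concentration.
#' The PCT response of this platform is linear over 0.5--100 ng/mL.
#'
#' @param concs Calibrator concentrations (>= 3 distinct, positive spread).
#' @param mean_intensities Mean intensity per calibrator.
#' @param replicates Optional data frame with columns `conc` and
#'   `intensity` of replicate-level measurements; when given, R2 is
#'   computed against these replicates.
#' @param analyte,matrix Curve labels (default PCT in buffer).
#' @param blank_intensities Optional blank replicate intensities; their
#'   mean/SD are stored for limit-of-detection estimation.
#' @return An object of class `lfa_curve` with `model = "linear"`,
#'   coefficients, `conc_range`, `r_squared`, units, and blank statistics.
#' @examples
#' cv <- fit_linear(c(0, 1, 2), c(1, 3, 5))
#' cv$coefficients  # intercept 1, slope 2
#' @export
fit_linear <- function(concs, mean_intensities, replicates = NULL,
                       analyte = "pct", matrix = c("buffer", "serum"),
                       blank_intensities = NULL) {
  matrix <- match.arg(matrix)
  if (length(unique(concs)) < 3)
    stop("linear calibration needs at least 3 distinct concentrations ",
         "with non-zero spread")
  stopifnot(length(concs) == length(mean_intensities))
  fit <- stats::lm.fit(cbind(1, concs), mean_intensities)
  coefs <- c(intercept = unname(fit$coefficients[1]),
             slope = unname(fit$coefficients[2]))
  curve <- new_lfa_curve(list(
    analyte = analyte, model = "linear", matrix = matrix,
    coefficients = coefs, conc_range = range(concs),
    units = analyte_units(analyte), hook_apex = NA_real_,
    blank_stats = blank_stats(blank_intensities), r_squared = NA_real_))
  curve$r_squared <- fit_r2(curve, concs, mean_intensities, replicates)
  curve
}

#' Fit an Akima-spline calibration curve (CRP)
#'
#' Local cubic (Akima-family) interpolation of mean test-line intensity
#' against log10 concentration — the standard axis for decade-spanning
#' dose-response ladders. The interpolant passes exactly through the
#' calibrator means; replicate scatter determines R2. The hook apex is the
#' argmax of the interpolant over a dense log-spaced grid and is reported
#' only when it falls strictly inside the calibrated range (a monotone
#' curve has no hook).
#'
#' The default slope rule is the modified-Akima ("makima") variant, which
#' tempers the overshoot of the original rule between unevenly spaced
#' calibrators; `method = "akima"` selects Akima's original weights.
#'
#' @param concs Calibrator concentrations (> 0, >= 5 distinct; duplicates
#'   are averaged, unsorted input is sorted).
#' @param mean_intensities Mean intensity per calibrator.
#' @param replicates Optional replicate-level data frame (`conc`,
#'   `intensity`) for R2.
#' @param analyte,matrix Curve labels (default CRP in buffer).
#' @param method Slope rule, `"makima"` (default) or `"akima"`.
#' @param grid_n Dense-grid resolution for the apex search (default 10001
#'   log-spaced points over the calibrated range).
#' @param blank_intensities Optional blank replicates for LoD estimation.
#' @return An `lfa_curve` with `model = "akima"`, knots and node slopes,
#'   `hook_apex`, `apex_intensity`, `conc_range`, and `r_squared`.
#' @export
fit_akima <- function(concs, mean_intensities, replicates = NULL,
                      analyte = "crp", matrix = c("buffer", "serum"),
                      method = c("makima", "akima"), grid_n = 10001,
                      blank_intensities = NULL) {
  matrix <- match.arg(matrix)
  method <- match.arg(method)
  stopifnot(length(concs) == length(mean_intensities))
  if (any(concs <= 0))
    stop("Akima calibration uses a log-concentration axis; ",
         "concentrations must be > 0")
  means <- tapply(mean_intensities, concs, mean)
  x <- as.numeric(names(means))
  y <- as.numeric(means)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (length(x) < 5)
    stop("Akima calibration needs at least 5 distinct concentrations")
  u <- log10(x)
  d <- akima_slopes(u, y, method = method)
  curve <- new_lfa_curve(list(
    analyte = analyte, model = "akima", matrix = matrix,
    knots_conc = x, knots_intensity = y, knots_log10 = u, slopes = d,
    method = method, conc_range = range(x), grid_n = grid_n,
    units = analyte_units(analyte),
    blank_stats = blank_stats(blank_intensities), r_squared = NA_real_))
  grid <- curve_grid(curve)
  vals <- predict(curve, grid)
  imax <- which.max(vals)
  curve$apex_intensity <- vals[imax]
  curve$hook_apex <- if (imax > 1 && imax < length(grid)) grid[imax]
                     else NA_real_
  curve$r_squared <- fit_r2(curve, x, y, replicates)
  curve
}

#' @noRd
blank_stats <- function(blank_intensities) {
  if (is.null(blank_intensities)) return(NULL)
  list(mean = mean(blank_intensities), sd = stats::sd(blank_intensities),
       n = length(blank_intensities))
}

#' @noRd
fit_r2 <- function(curve, concs, means, replicates) {
  if (!is.null(replicates)) {
    stopifnot(all(c("conc", "intensity") %in% names(replicates)))
    r_squared(replicates$intensity, predict(curve, replicates$conc))
  } else {
    r_squared(means, predict(curve, concs))
  }
}

# Dense log-spaced evaluation grid over the calibrated range, clipped to
# stay inside it despite floating-point endpoints.
#' @noRd
curve_grid <- function(curve) {
  r <- curve$conc_range
  g <- 10^seq(log10(r[1]), log10(r[2]), length.out = curve$grid_n)
  pmin(pmax(g, r[1]), r[2])
}

#' Evaluate a fitted calibration curve
#'
#' Linear curves evaluate the fitted line everywhere. Akima curves
#' evaluate the Hermite interpolant inside the calibrated range; below the
#' lowest knot the curve continues linearly through the origin and the
#' first knot (the signal is physically anchored at zero), which the
#' dilution protocol relies on for 1:10-diluted predictions; above the
#' highest knot the end slope continues on the log axis. Evaluations are
#' floored at 0.
#'
#' @param object An `lfa_curve`.
#' @param conc Concentration(s) at which to evaluate (>= 0).
#' @param ... Unused.
#' @return Intensity value(s).
#' @export
predict.lfa_curve <- function(object, conc, ...) {
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (object$model == "linear")
    return(object$coefficients[["intercept"]] +
             object$coefficients[["slope"]] * conc)
  out <- numeric(length(conc))
  c1 <- object$knots_conc[1]
  lo <- conc < c1
  out[lo] <- object$knots_intensity[1] * conc[lo] / c1
  if (any(!lo))
    out[!lo] <- hermite_eval(object$knots_log10, object$knots_intensity,
                             object$slopes, log10(conc[!lo]))
  pmax(out, 0)
}

#' @export
print.lfa_curve <- function(x, ...) {
  apex <- if (is.finite(x$hook_apex))
    sprintf(", hook apex %.3g %s", x$hook_apex, x$units) else ""
  cat(sprintf("<lfa_curve %s/%s (%s): range %.3g-%.3g %s, R2 %.4f%s>\n",
              toupper(x$analyte), x$matrix, x$model, x$conc_range[1],
              x$conc_range[2], x$units, x$r_squared, apex))
  invisible(x)
}

#' Invert a linear calibration curve
#'
#' `(intensity - intercept) / slope`, floored at 0; values outside the
#' calibrated concentration range are flagged as extrapolated in the
#' `"extrapolated"` attribute.
#'
#' @param curve A linear `lfa_curve`.
#' @param intensity Intensity value(s).
#' @return Concentration(s) with logical attribute `extrapolated`.
#' @export
invert_linear <- function(curve, intensity) {
  stopifnot(inherits(curve, "lfa_curve"))
  if (curve$model != "linear") stop("invert_linear needs a linear curve")
  slope <- curve$coefficients[["slope"]]
  if (slope == 0) stop("cannot invert a curve with zero slope")
  conc <- (intensity - curve$coefficients[["intercept"]]) / slope
  extra <- conc < curve$conc_range[1] | conc > curve$conc_range[2]
  out <- pmax(conc, 0)
  attr(out, "extrapolated") <- extra
  out
}

# Root of predict(curve, c) == intensity on the ascending branch
# (0, apex]; works through the below-range origin-anchored extrapolation.
#' @noRd
ascending_root <- function(curve, intensity, apex) {
  f <- function(u) predict(curve, 10^u) - intensity
  u_hi <- log10(apex)
  u_lo <- u_hi - 1
  while (f(u_lo) > 0 && u_lo > u_hi - 30) u_lo <- u_lo - 1
  if (f(u_lo) > 0) return(NA_real_)
  10^stats::uniroot(f, c(u_lo, u_hi), tol = 1e-12)$root
}

# Root on the descending branch [apex, c_max], extended by the log-axis
# end-slope continuation up to two decades beyond the last knot.
#' @noRd
descending_root <- function(curve, intensity, apex) {
  f <- function(u) predict(curve, 10^u) - intensity
  u_lo <- log10(apex)
  u_hi <- log10(curve$conc_range[2])
  if (f(u_hi) > 0) {  # dimmer than the last knot: extrapolate beyond it
    u_ext <- u_hi + 2
    if (f(u_ext) > 0) return(NA_real_)
    u_lo <- u_hi
    u_hi <- u_ext
  }
  10^stats::uniroot(f, c(u_lo, u_hi), tol = 1e-12)$root
}

#' Invert a hooked (Akima) calibration curve
#'
#' A hooked curve maps one intensity to up to two concentrations: one on
#' the ascending branch below the hook apex and one on the descending
#' branch above it. Both are found by bracketed root-finding on the two
#' branches separately. The pair is degenerate when the intensity is
#' within tolerance of the apex intensity (single solution at the apex) or
#' when only one branch holds a root in range.
#'
#' @param curve An Akima `lfa_curve` with a finite `hook_apex`.
#' @param intensity Queried intensity (scalar, > 0).
#' @param rel_tol Relative tolerance on the intensity scale for the
#'   apex-degeneracy and above-maximum checks (default 1e-6).
#' @return An object of class `candidate_pair`: `c_low`, `c_high`,
#'   `degenerate`, `intensity`, and branch extrapolation flags.
#' @export
invert_hooked <- function(curve, intensity, rel_tol = 1e-6) {
  stopifnot(inherits(curve, "lfa_curve"), length(intensity) == 1)
  if (curve$model != "akima" || !is.finite(curve$hook_apex))
    stop("invert_hooked needs an Akima curve with a hook apex")
  fmax <- curve$apex_intensity
  apex <- curve$hook_apex
  if (intensity > fmax * (1 + rel_tol))
    stop("no solution: intensity exceeds the fitted curve maximum")
  if (intensity <= 0)
    stop("intensity below range: no concentration maps to it")
  if (abs(intensity - fmax) <= rel_tol * fmax)
    return(structure(list(c_low = apex, c_high = apex, degenerate = TRUE,
                          intensity = intensity, extrapolated = FALSE),
                     class = "candidate_pair"))
  c_low <- ascending_root(curve, intensity, apex)
  c_high <- descending_root(curve, intensity, apex)
  if (is.na(c_low) && is.na(c_high))
    stop("intensity below both branch minima: out of curve range")
  degenerate <- is.na(c_low) || is.na(c_high)
  if (is.na(c_low)) c_low <- c_high
  if (is.na(c_high)) c_high <- c_low
  structure(list(c_low = c_low, c_high = c_high, degenerate = degenerate,
                 intensity = intensity,
                 extrapolated = c_low < curve$conc_range[1] ||
                   c_high > curve$conc_range[2]),
            class = "candidate_pair")
}

#' @export
print.candidate_pair <- function(x, ...) {
  cat(sprintf("<candidate_pair: %.4g / %.4g%s at intensity %.4g>\n",
              x$c_low, x$c_high, if (x$degenerate) " (degenerate)" else "",
              x$intensity))
  invisible(x)
}

#' Estimate the limit of detection from blank replicates
#'
#' Analytical LoD by the standard blank-based convention: the
#' concentration whose curve value equals `mean(blank) + 3 * SD(blank)`,
#' solved on the ascending branch of the calibration curve.
#'
#' @param blank_intensities At least 3 blank replicate intensities (or
#'   `NULL` to use the blank statistics stored in the curve).
#' @param curve An `lfa_curve`.
#' @return The LoD concentration in the curve's units.
#' @export
estimate_lod <- function(blank_intensities = NULL, curve) {
  stopifnot(inherits(curve, "lfa_curve"))
  bs <- if (is.null(blank_intensities)) curve$blank_stats
        else blank_stats(blank_intensities)
  if (is.null(bs) || bs$n < 3)
    stop("LoD estimation needs at least 3 blank replicate intensities")
  threshold <- bs$mean + 3 * bs$sd
  if (curve$model == "linear") {
    conc <- (threshold - curve$coefficients[["intercept"]]) /
      curve$coefficients[["slope"]]
    return(max(conc, 0))
  }
  apex <- if (is.finite(curve$hook_apex)) curve$hook_apex
          else curve$conc_range[2]
  if (threshold > predict(curve, apex))
    stop("LoD undefined: blank threshold exceeds the curve maximum")
  ascending_root(curve, threshold, apex)
}
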