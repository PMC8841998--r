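#' Forward signal model parameters for the duplex assay
#'
#' Bundles the parameters of the noiseless intensity models for the two
#' analytes together with the replicate noise model and the rendering
#' constants shared by the synthetic strip generator.
#'
#' The PCT test line responds linearly over its working range
#' (0.5--100 ng/mL), so its model is affine:
#' `I_pct(c) = beta_pct + alpha_pct * c`.
#'
#' The CRP test line shows a high-dose hook: the signal rises up to an apex
#' concentration and falls beyond it as excess unlabeled analyte occupies the
#' capture sites. The model is the simplest unimodal single-apex curve
#' through the origin,
#' `I_crp(c) = alpha_crp * (c/h) / (1 + (c/h)^2)`,
#' with maximum `alpha_crp / 2` exactly at `c = h` (default 1 mg/dL).
#'
#' Replicate-to-replicate variability is multiplicative lognormal with a
#' coefficient of variation `noise_cv`; intra-assay variability of these
#' assays is reported as a CV, which is scale-free, hence the multiplicative
#' form. When `noise_cv` is `NULL` a context default from the reported
#' intra-assay CV ranges is used (see [default_noise_cv()]).
#'
#' @param alpha_pct PCT slope, intensity units per ng/mL. Must be > 0.
#' @param beta_pct PCT intercept: test-line intensity at zero PCT.
#' @param alpha_crp CRP intensity scale; the hook maximum is `alpha_crp / 2`.
#' @param hook_apex Apex concentration `h` of the CRP hook, mg/dL.
#' @param blank_level Background level of an analyte-free strip, raw 16-bit
#'   sensor counts.
#' @param control_level Control-line intensity of a functional strip.
#' @param serum_scale Multiplicative matrix factor applied to serum-panel
#'   signals relative to buffer (serum suppresses the response).
#' @param noise_cv Replicate coefficient of variation (fraction), or `NULL`
#'   to use the per-analyte context default.
#'
#' @return An object of class `lfa_params`.
#' @examples
#' p <- forward_model_params()
#' pct_signal(10, p)
#' crp_signal(1, p)  # the hook maximum, alpha_crp / 2
#' @export
forward_model_params <- function(alpha_pct = 120, beta_pct = 200,
                                 alpha_crp = 12000, hook_apex = 1.0,
                                 blank_level = 300, control_level = 8000,
                                 serum_scale = 0.85, noise_cv = NULL) {
  stopifnot(alpha_pct > 0, alpha_crp > 0, hook_apex > 0,
            blank_level >= 0, control_level >= 0, serum_scale > 0)
  if (!is.null(noise_cv)) stopifnot(noise_cv >= 0)
  structure(list(alpha_pct = alpha_pct, beta_pct = beta_pct,
                 alpha_crp = alpha_crp, hook_apex = hook_apex,
                 blank_level = blank_level, control_level = control_level,
                 serum_scale = serum_scale, noise_cv = noise_cv),
            class = "lfa_params")
}

#' Default replicate CVs by analyte and matrix
#'
#' Midpoints of the intra-assay CV ranges measured for this platform:
#' buffer 6.8--11.0% (PCT) and 3.7--15.1% (CRP); clinical serum 1.3--16.9%
#' (PCT) and 3.1--11.1% (CRP).
#'
#' @param analyte `"pct"` or `"crp"`.
#' @param matrix `"buffer"` or `"serum"`.
#' @return The default CV as a fraction.
#' @export
default_noise_cv <- function(analyte = c("pct", "crp"),
                             matrix = c("buffer", "serum")) {
  analyte <- match.arg(analyte)
  matrix <- match.arg(matrix)
  switch(matrix,
         buffer = c(pct = 0.089, crp = 0.094)[[analyte]],
         serum  = c(pct = 0.091, crp = 0.071)[[analyte]])
}

#' Noiseless PCT test-line intensity
#'
#' Affine response `beta_pct + alpha_pct * c`; the response of this assay is
#' linear through 100 ng/mL.
#'
#' @param conc PCT concentration(s), ng/mL; must be >= 0.
#' @param params An [forward_model_params()] object.
#' @return Intensity value(s), same length as `conc`.
#' @export
pct_signal <- function(conc, params = forward_model_params()) {
  stopifnot(inherits(params, "lfa_params"))
  if (any(conc < 0)) stop("PCT concentration must be non-negative")
  params$beta_pct + params$alpha_pct * conc
}

#' Noiseless CRP test-line intensity (hooked response)
#'
#' `alpha_crp * (c/h) / (1 + (c/h)^2)`: strictly increasing below the apex
#' `h`, maximal (`alpha_crp/2`) at `h`, strictly decreasing beyond. The form
#' is symmetric on a log-concentration axis: `crp_signal(h*x) ==
#' crp_signal(h/x)`.
#'
#' @param conc CRP concentration(s), mg/dL; must be >= 0.
#' @param params An [forward_model_params()] object.
#' @return Intensity value(s), same length as `conc`.
#' @export
crp_signal <- function(conc, params = forward_model_params()) {
  stopifnot(inherits(params, "lfa_params"))
  if (any(conc < 0)) stop("CRP concentration must be non-negative")
  x <- conc / params$hook_apex
  params$alpha_crp * x / (1 + x^2)
}

#' @noRd
analyte_signal <- function(conc, analyte, params) {
  switch(analyte, pct = pct_signal(conc, params),
         crp = crp_signal(conc, params),
         stop("unknown analyte: ", analyte))
}

#' Analyte units used throughout the package
#'
#' Units are fixed per analyte (PCT in ng/mL, CRP in mg/dL, matching the
#' thousandfold difference in physiological range) and carried in every
#' record; no implicit conversion is ever performed.
#'
#' @param analyte `"pct"` or `"crp"`.
#' @return `"ng/mL"` or `"mg/dL"`.
#' @export
analyte_units <- function(analyte = c("pct", "crp")) {
  analyte <- match.arg(analyte)
  c(pct = "ng/mL", crp = "mg/dL")[[analyte]]
}

#' Default calibration ladders
#'
#' Serial-dilution ladders spanning the working ranges: 0.5--100 ng/mL for
#' PCT and 0.05--10 mg/dL for CRP (the CRP ladder straddles the 1 mg/dL
#' hook apex).
#'
#' @param analyte `"pct"` or `"crp"`.
#' @return Numeric vector of calibrator concentrations.
#' @export
default_ladder <- function(analyte = c("pct", "crp")) {
  analyte <- match.arg(analyte)
  switch(analyte,
         pct = c(0.5, 1, 5, 10, 50, 100),
         crp = c(0.05, 0.1, 0.25, 0.5, 1, 2.5, 5, 10))
}

# Lognormal replicate factors with unit mean and coefficient of variation cv.
#' @noRd
lognorm_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# Evaluate expr with a locally-set RNG seed, restoring global state after.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
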