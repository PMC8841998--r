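#' Triplicate summary statistics
#'
#' Mean, sample SD (n - 1 denominator) and intra-assay coefficient of
#' variation `100 * sd / mean` of same-run replicates.
#'
#' @param values At least 2 replicate values.
#' @return A list: `mean`, `sd`, `cv_percent` (`NA` with `cv_defined =
#'   FALSE` when the mean is 0), `n`.
#' @examples
#' summarize_triplicates(c(9, 10, 11))  # CV 10%
#' @export
summarize_triplicates <- function(values) {
  if (length(values) < 2)
    stop("replicate summary needs at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  defined <- m != 0
  list(mean = m, sd = s,
       cv_percent = if (defined) 100 * s / m else NA_real_,
       cv_defined = defined, n = length(values))
}

#' Select calibrator samples covering the measured range
#'
#' Mirrors the serum-calibration step: from a panel with reference-method
#' concentrations, pick `k` samples spanning the whole detection range.
#' Samples are sorted by reference concentration and split into `k`
#' near-equal rank bins; the lowest and highest bins contribute their
#' extreme member (so the selection always brackets the full range, as a
#' calibration set must) and each interior bin contributes one random
#' member.
#'
#' @param reference_concs Reference concentrations, one per sample.
#' @param k Number of calibrators (default 5); `k <= n`.
#' @param seed Optional seed for the interior draws.
#' @return Integer indices into `reference_concs`, sorted by
#'   concentration.
#' @export
select_calibrators <- function(reference_concs, k = 5, seed = NULL) {
  n <- length(reference_concs)
  if (k > n) stop("cannot select more calibrators than samples")
  if (k == n) return(order(reference_concs))
  ord <- order(reference_concs)
  bins <- split(ord, cut(seq_len(n), breaks = k, labels = FALSE))
  with_seed(seed, {
    picks <- vapply(seq_along(bins), function(b) {
      idx <- bins[[b]]
      if (b == 1) idx[1]
      else if (b == length(bins)) idx[length(idx)]
      else idx[sample.int(length(idx), 1)]
    }, integer(1))
    picks
  })
}

#' Method-comparison statistics
#'
#' Compares platform-predicted concentrations against a reference
#' (gold-standard) method: Pearson correlation with its two-sided p-value,
#' Spearman rank correlation, and the least-squares regression of
#' predicted on reference. Both correlation flavours are reported because
#' published comparisons quote either.
#'
#' @param predicted,reference Paired vectors, n >= 3.
#' @return A list of class `method_comparison`: `pearson_r`, `p_value`,
#'   `spearman_rho`, `slope`, `intercept`, `r_squared`
#'   (`= pearson_r^2`), `n`.
#' @export
compare_methods <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference))
  if (length(predicted) < 3)
    stop("method comparison needs at least 3 paired samples")
  if (stats::sd(predicted) == 0 || stats::sd(reference) == 0)
    stop("method comparison undefined for zero-variance input")
  ct <- stats::cor.test(predicted, reference, method = "pearson")
  rho <- suppressWarnings(
    stats::cor(predicted, reference, method = "spearman"))
  fit <- stats::lm.fit(cbind(1, reference), predicted)
  structure(list(pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, spearman_rho = rho,
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = unname(ct$estimate)^2,
                 n = length(predicted)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf(paste0("<method_comparison: n = %d, Pearson r = %.3f ",
                     "(p = %.2g), Spearman rho = %.3f, R2 = %.3f,\n",
                     "  predicted = %.3f + %.3f * reference>\n"),
              x$n, x$pearson_r, x$p_value, x$spearman_rho, x$r_squared,
              x$intercept, x$slope))
  invisible(x)
}

#' Sepsis stage from a PCT concentration
#'
#' Clinical staging intervals on serum PCT (ng/mL), right-closed as used
#' in sepsis work-ups: local infection (0.05-0.5], sepsis (0.5-2], severe
#' sepsis (2-10], septic shock (> 10). Concentrations at or below
#' 0.05 ng/mL are below the staging scale (healthy/indeterminate).
#'
#' @param pct_conc PCT concentration(s) in ng/mL, > 0.
#' @return A factor with levels `below_staging`, `local_infection`,
#'   `sepsis`, `severe_sepsis`, `septic_shock`.
#' @examples
#' classify_sepsis_stage(c(0.3, 0.5, 24.94))
#' @export
classify_sepsis_stage <- function(pct_conc) {
  if (any(pct_conc <= 0)) stop("PCT concentration must be positive")
  cut(pct_conc, breaks = c(0, 0.05, 0.5, 2, 10, Inf), right = TRUE,
      labels = c("below_staging", "local_infection", "sepsis",
                 "severe_sepsis", "septic_shock"))
}

#' End-to-end serum validation experiment
#'
#' Reproduces the clinical validation workflow on a synthetic serum panel:
#' optionally excludes samples whose reference concentration exceeds the
#' validated range (an explicit, logged filter — never silent), selects
#' `k` calibrators covering the range, fits a matrix-specific calibration
#' curve (linear for PCT, Akima for CRP) against the reference
#' concentrations, predicts every non-calibrator sample from its
#' triplicate-mean intensity (CRP through the serial-dilution resolver),
#' and compares predictions with the reference values.
#'
#' @param panel An `lfa_panel` from [generate_serum_panel()] (intensity
#'   space).
#' @param k_calibrators Number of calibrator samples (default 5).
#' @param seed Seed for the calibrator draw.
#' @param resolve_hook For CRP: use the dilution pair to pick the branch
#'   (`TRUE`, the protocol) or naively report the ascending-branch
#'   candidate (`FALSE`, ablation).
#' @param exclude_above Reference concentration above which samples are
#'   excluded (e.g. 100 ng/mL, the validated PCT range), or `NULL`.
#' @param tau_accept,rho,apex_band Passed to [resolve()].
#' @return A list of class `lfa_validation`: `comparison`
#'   ([compare_methods()] on the non-calibrator samples), `samples` (per-
#'   sample table: reference, predicted, role, branch, flags, stage for
#'   PCT), and `curve`.
#' @export
run_validation_experiment <- function(panel, k_calibrators = 5, seed = 1,
                                      resolve_hook = TRUE,
                                      exclude_above = NULL,
                                      tau_accept = 0.35, rho = 0.10,
                                      apex_band = 0.05) {
  stopifnot(inherits(panel, "lfa_panel"), !is.null(panel$readings))
  analyte <- panel$analyte
  truth <- panel$truth
  if (nrow(truth) < k_calibrators + 3)
    stop("panel needs at least k_calibrators + 3 samples")
  excluded <- if (!is.null(exclude_above)) truth$true_conc > exclude_above
              else rep(FALSE, nrow(truth))
  usable <- truth[!excluded, ]
  neat <- panel$readings[panel$readings$dilution_factor == 1, ]
  mean_by_sample <- tapply(neat$intensity, neat$sample_id, mean)
  means <- as.numeric(mean_by_sample[usable$sample_id])
  cal_idx <- select_calibrators(usable$true_conc, k_calibrators, seed)
  is_cal <- seq_len(nrow(usable)) %in% cal_idx
  reps <- data.frame(
    conc = usable$true_conc[match(neat$sample_id, usable$sample_id)],
    intensity = neat$intensity)
  reps <- reps[neat$sample_id %in% usable$sample_id[is_cal], ]
  curve <- if (analyte == "pct") {
    fit_linear(usable$true_conc[is_cal], means[is_cal], replicates = reps,
               analyte = "pct", matrix = "serum")
  } else {
    fit_akima(usable$true_conc[is_cal], means[is_cal], replicates = reps,
              analyte = "crp", matrix = "serum")
  }
  pred <- rep(NA_real_, nrow(usable))
  branch <- rep(NA_character_, nrow(usable))
  flags <- rep("", nrow(usable))
  for (i in which(!is_cal)) {
    sid <- usable$sample_id[i]
    if (analyte == "pct") {
      pred[i] <- invert_linear(curve, means[i])
    } else {
      dil <- panel$readings[panel$readings$sample_id == sid &
                              panel$readings$dilution_factor != 1, ]
      res <- predict_crp_sample(means[i], mean(dil$intensity),
                                dil$dilution_factor[1], curve,
                                resolve_hook, tau_accept, rho, apex_band)
      pred[i] <- res$concentration
      branch[i] <- res$branch
      flags[i] <- paste(res$flags, collapse = ";")
    }
  }
  test <- !is_cal
  comparison <- compare_methods(pred[test], usable$true_conc[test])
  samples <- data.frame(
    sample_id = usable$sample_id, reference = usable$true_conc,
    units = usable$units, predicted = pred,
    role = ifelse(is_cal, "calibrator", "test"),
    branch = branch, flags = flags)
  if (analyte == "pct") {
    ok <- !is.na(pred) & pred > 0
    samples$stage <- NA_character_
    samples$stage[ok] <-
      as.character(classify_sepsis_stage(pred[ok]))
  }
  if (any(excluded)) {
    exc <- truth[excluded, ]
    message(sprintf("excluded %d sample(s) above %g %s: %s", nrow(exc),
                    exclude_above, exc$units[1],
                    paste(exc$sample_id, collapse = ", ")))
    exc_rows <- data.frame(sample_id = exc$sample_id,
                           reference = exc$true_conc, units = exc$units,
                           predicted = NA_real_, role = "excluded",
                           branch = NA_character_, flags = "excluded")
    if (analyte == "pct") exc_rows$stage <- NA_character_
    samples <- rbind(samples, exc_rows)
  }
  structure(list(comparison = comparison, samples = samples,
                 curve = curve, analyte = analyte,
                 k_calibrators = k_calibrators, seed = seed),
            class = "lfa_validation")
}

# Predict one CRP sample from its neat/diluted mean intensities.
#' @noRd
predict_crp_sample <- function(i_neat, i_dil, d, curve, resolve_hook,
                               tau_accept, rho, apex_band) {
  if (resolve_hook) {
    pr <- dilution_pair(
      line_reading(area_crp = i_neat, area_pct = 0, area_ctrl = 1e6),
      line_reading(area_crp = i_dil, area_pct = 0, area_ctrl = 1e6),
      dilution_factor = d, specimen_volume_diluted = 2.5,
      diluent_volume = 2.5 * (d - 1))
    resolve(pr, curve, tau_accept = tau_accept, rho = rho,
            apex_band = apex_band)
  } else {
    # ablation: no dilution information, report the ascending candidate
    fmax <- curve$apex_intensity
    cand <- invert_hooked(curve, min(i_neat, fmax * (1 - 1e-9)))
    list(concentration = cand$c_low, branch = "ascending",
         flags = "no_resolution")
  }
}

#' @export
print.lfa_validation <- function(x, ...) {
  cat(sprintf("<lfa_validation: %s, %d calibrators>\n",
              toupper(x$analyte), x$k_calibrators))
  print(x$comparison)
  invisible(x)
}

#' Repeated-seed correlation recovery experiment
#'
#' Runs [generate_serum_panel()] + [run_validation_experiment()] across
#' many seeds and collects the Pearson correlation between predicted and
#' reference concentrations, the figure of merit of the clinical method
#' comparison (24 samples: 5 calibrators + 19 predicted, triplicates).
#'
#' @param n_seeds Number of replicate experiments.
#' @param analyte `"pct"` or `"crp"`.
#' @param n_samples Panel size (default 24).
#' @param k_calibrators Calibrators per panel (default 5).
#' @param params Forward model.
#' @param noise_cv Replicate CV (default: serum [default_noise_cv()]).
#' @param resolve_hook Passed to [run_validation_experiment()].
#' @param base_seed Offset added to the per-replicate seed.
#' @return Numeric vector of Pearson r values, one per seed.
#' @export
correlation_recovery_experiment <- function(n_seeds = 200,
                                            analyte = c("pct", "crp"),
                                            n_samples = 24,
                                            k_calibrators = 5,
                                            params = forward_model_params(),
                                            noise_cv = NULL,
                                            resolve_hook = TRUE,
                                            base_seed = 0) {
  analyte <- match.arg(analyte)
  vapply(seq_len(n_seeds), function(s) {
    panel <- generate_serum_panel(n = n_samples, analyte = analyte,
                                  params = params, noise_cv = noise_cv,
                                  seed = base_seed + s)
    val <- run_validation_experiment(panel, k_calibrators = k_calibrators,
                                     seed = base_seed + s,
                                     resolve_hook = resolve_hook)
    val$comparison$pearson_r
  }, numeric(1))
}
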