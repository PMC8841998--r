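#' Fold-dilution from pipetted volumes
#'
#' `(v_specimen + v_diluent) / v_specimen`: mixing 2.5 uL of specimen with
#' 22.5 uL of buffer gives a 1:10 dilution.
#'
#' @param v_specimen Specimen volume, uL (> 0).
#' @param v_diluent Diluent volume, uL (>= 0).
#' @return The fold-dilution factor.
#' @examples
#' dilution_factor(2.5, 22.5)  # 10
#' @export
dilution_factor <- function(v_specimen, v_diluent) {
  if (any(v_specimen <= 0)) stop("specimen volume must be positive")
  if (any(v_diluent < 0)) stop("diluent volume must be non-negative")
  (v_specimen + v_diluent) / v_specimen
}

#' Neat + diluted strip pair for hook disambiguation
#'
#' The serial-dilution protocol measures each CRP specimen on two strips:
#' a neat strip (25 uL of specimen) and a companion diluted
#' `dilution_factor`-fold (by default 2.5 uL of specimen + 22.5 uL of
#' buffer, i.e. 1:10). Both readings must have a valid control line.
#'
#' @param neat,diluted [line_reading()]s of the neat and diluted strips.
#' @param dilution_factor Fold dilution `D` (default 10); must equal
#'   `(specimen_volume_diluted + diluent_volume) / specimen_volume_diluted`.
#' @param specimen_volume_neat uL of specimen on the neat strip (25).
#' @param specimen_volume_diluted uL of specimen in the dilution (2.5).
#' @param diluent_volume uL of diluent (22.5).
#' @return An object of class `dilution_pair`.
#' @export
dilution_pair <- function(neat, diluted, dilution_factor = 10,
                          specimen_volume_neat = 25,
                          specimen_volume_diluted = 2.5,
                          diluent_volume = 22.5) {
  stopifnot(inherits(neat, "line_reading"), inherits(diluted, "line_reading"))
  implied <- dilution_factor(specimen_volume_diluted, diluent_volume)
  if (abs(implied - dilution_factor) > 1e-9 * dilution_factor)
    stop(sprintf("volumes imply a %.4g-fold dilution, not %.4g-fold",
                 implied, dilution_factor))
  if (!isTRUE(neat$control_valid) || !isTRUE(diluted$control_valid))
    stop("both strips of a dilution pair must have a valid control line")
  structure(list(neat = neat, diluted = diluted,
                 dilution_factor = dilution_factor,
                 specimen_volume_neat = specimen_volume_neat,
                 specimen_volume_diluted = specimen_volume_diluted,
                 diluent_volume = diluent_volume),
            class = "dilution_pair")
}

#' Total specimen volume of a two-strip measurement
#'
#' Specimen consumed by the neat strip plus specimen in the dilution
#' (diluent does not count): 25 + 2.5 = 27.5 uL with the defaults.
#'
#' @param pair A [dilution_pair()].
#' @return Volume in uL.
#' @export
total_specimen_volume <- function(pair) {
  stopifnot(inherits(pair, "dilution_pair"))
  pair$specimen_volume_neat + pair$specimen_volume_diluted
}

#' Resolve the hooked-curve ambiguity with a dilution pair
#'
#' Selects the correct branch of a hooked calibration curve. The neat
#' reading is inverted into its (up to) two candidate concentrations; for
#' each candidate `c` the expected diluted intensity `curve(c / D)` is
#' computed, and the candidate whose prediction best matches the observed
#' diluted reading (smallest relative deviation) is selected. The reported
#' concentration is always the selected neat-strip candidate — the diluted
#' strip only verifies the branch.
#'
#' Readings within `apex_band` of the fitted maximum (including noisy
#' readings slightly above it) carry almost no branch information of their
#' own; for these the two branch candidates are taken at the band-edge
#' intensity `(1 - apex_band) * max` and the dilution reading decides
#' the branch (flag `"near_apex"`). When the two branch deviations are
#' indistinguishable (difference < `rho`) the result is flagged
#' `"ambiguous"`; in the near-apex band this returns the apex itself with
#' branch `"degenerate"`. A best deviation above `tau_accept` flags the
#' pair `"inconsistent"` (or errors when `strict = TRUE`).
#'
#' @param pair A [dilution_pair()].
#' @param curve A hooked Akima `lfa_curve`.
#' @param tau_accept Maximum accepted relative deviation (default 0.35;
#'   must exceed plausible replicate CVs yet reject gross inconsistency).
#' @param rho Ambiguity margin between the two branch deviations (0.10).
#' @param apex_band Relative intensity band below the fitted maximum
#'   treated as near-apex (default 0.05).
#' @param strict Error on an inconsistent pair instead of flagging.
#' @return An object of class `lfa_resolved`: `concentration`, `branch`
#'   (`"ascending"`, `"descending"` or `"degenerate"`),
#'   `consistency_score`, `flags`, the candidate pair and the per-branch
#'   deviations.
#' @export
resolve <- function(pair, curve, tau_accept = 0.35, rho = 0.10,
                    apex_band = 0.05, strict = FALSE) {
  stopifnot(inherits(pair, "dilution_pair"), inherits(curve, "lfa_curve"),
            tau_accept > 0, rho > 0, apex_band >= 0)
  if (curve$model != "akima" || !is.finite(curve$hook_apex))
    stop("resolve needs a hooked (Akima) calibration curve")
  area_field <- paste0("area_", curve$analyte)
  i_neat <- pair$neat[[area_field]]
  i_dil <- pair$diluted[[area_field]]
  fmax <- curve$apex_intensity
  d <- pair$dilution_factor
  flags <- character(0)
  if (abs(i_neat - fmax) <= 1e-6 * fmax) {
    # exactly at the fitted maximum: single solution, the apex itself
    cand <- invert_hooked(curve, fmax)
    return(new_resolved(cand$c_low, "degenerate", NA_real_, "degenerate",
                        cand, NULL, i_dil))
  }
  if (i_neat > fmax || i_neat >= fmax * (1 - apex_band)) {
    # near (or noisily above) the maximum the neat inversion is
    # ill-conditioned: take branch candidates at the band edge and let the
    # dilution reading decide
    flags <- c(flags, "near_apex")
    cand <- invert_hooked(curve, fmax * (1 - max(apex_band, 1e-6)))
  } else {
    cand <- invert_hooked(curve, i_neat)
  }
  preds <- c(ascending = predict(curve, cand$c_low / d),
             descending = predict(curve, cand$c_high / d))
  eps <- 1e-8 * max(fmax, 1)
  devs <- abs(preds - i_dil) / max(i_dil, eps)
  if (cand$degenerate) {
    # only one branch held a root: its side relative to the apex is known
    branch <- if (cand$c_low < curve$hook_apex) "ascending" else "descending"
    score <- unname(devs[[branch]])
    flags <- c(flags, "single_branch",
               if (score > tau_accept) "inconsistent")
    return(new_resolved(cand$c_low, branch, score, flags, cand, preds,
                        i_dil))
  }
  best <- which.min(devs)
  ambiguous <- abs(devs[1] - devs[2]) < rho
  if (ambiguous) flags <- c(flags, "ambiguous")
  if ("near_apex" %in% flags && ambiguous) {
    # dilution cannot separate the band-edge candidates either: report the
    # apex rather than an arbitrary branch
    return(new_resolved(curve$hook_apex, "degenerate", unname(min(devs)),
                        flags, cand, preds, i_dil))
  }
  if (devs[best] > tau_accept) {
    if (strict)
      stop(sprintf(paste0("unresolved pair: best dilution deviation %.2f ",
                          "exceeds tau_accept = %.2f"),
                   devs[best], tau_accept))
    flags <- c(flags, "inconsistent")
  }
  conc <- if (best == 1) cand$c_low else cand$c_high
  new_resolved(conc, names(devs)[best], unname(devs[best]), flags, cand,
               preds, i_dil)
}

#' @noRd
new_resolved <- function(conc, branch, score, flags, candidates, preds,
                         observed_diluted) {
  structure(list(concentration = conc, branch = branch,
                 consistency_score = score, flags = flags,
                 candidates = candidates, predicted_diluted = preds,
                 observed_diluted = observed_diluted),
            class = "lfa_resolved")
}

#' @export
print.lfa_resolved <- function(x, ...) {
  fl <- if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
        else ""
  cat(sprintf("<resolved: %.4g (%s branch, score %.3g)%s>\n",
              x$concentration, x$branch, x$consistency_score, fl))
  invisible(x)
}

#' Monte-Carlo branch-recovery experiment
#'
#' Measures how often the serial-dilution protocol selects the correct
#' branch of a hooked curve. True concentrations are drawn log-uniformly
#' over `conc_range`, excluding a `exclude_frac` band around the hook
#' apex where the branches merge; neat and diluted readings are simulated
#' from the forward model with lognormal noise of coefficient of variation
#' `cv` and resolved against `curve`. A selection is correct when the
#' chosen branch matches the side of the apex the truth lies on.
#'
#' @param n_pairs Number of simulated pairs.
#' @param cv Replicate CV of each reading.
#' @param curve Hooked calibration curve to resolve against (default: fit
#'   to the noiseless default CRP ladder).
#' @param params Forward model generating the readings.
#' @param conc_range True-concentration range (default 0.05--25 mg/dL).
#' @param exclude_frac Excluded relative band around the apex (0.2 =
#'   truths within +/-20% of the apex are not drawn).
#' @param seed Integer seed.
#' @param ... Passed to [resolve()].
#' @return A list: `fraction_correct`, and `results` data frame with
#'   `true_conc`, `selected`, `branch`, `correct`, `flagged`.
#' @export
branch_recovery_experiment <- function(n_pairs = 1000, cv = 0.10,
                                       curve = NULL,
                                       params = forward_model_params(),
                                       conc_range = c(0.05, 25),
                                       exclude_frac = 0.2, seed = 1, ...) {
  if (is.null(curve)) {
    ladder <- default_ladder("crp")
    curve <- fit_akima(ladder, crp_signal(ladder, params))
  }
  apex <- params$hook_apex
  res <- with_seed(seed, {
    truths <- numeric(0)
    while (length(truths) < n_pairs) {
      draw <- exp(stats::runif(2 * n_pairs, log(conc_range[1]),
                               log(conc_range[2])))
      draw <- draw[draw < apex * (1 - exclude_frac) |
                     draw > apex * (1 + exclude_frac)]
      truths <- c(truths, draw)
    }
    truths <- truths[seq_len(n_pairs)]
    rows <- lapply(truths, function(tc) {
      i_neat <- crp_signal(tc, params) * lognorm_factors(1, cv)
      i_dil <- crp_signal(tc / 10, params) * lognorm_factors(1, cv)
      pr <- dilution_pair(line_reading(i_neat, 0, 1e6),
                          line_reading(i_dil, 0, 1e6))
      r <- resolve(pr, curve, ...)
      truth_branch <- if (tc < apex) "ascending" else "descending"
      data.frame(true_conc = tc, selected = r$concentration,
                 branch = r$branch, correct = r$branch == truth_branch,
                 flagged = length(r$flags) > 0)
    })
    do.call(rbind, rows)
  })
  list(fraction_correct = mean(res$correct), results = res)
}
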