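# Inverse problem: grid-search SSR minimization against a measured
# spectrum (calibration of tissue parameters at known hemoglobin, then
# hemoglobin/oxygenation prediction), leave-one-out cross-validation and
# clinical agreement statistics.

.default_calib_ranges <- function() {
  list(h_tp = c(1.0, 1.25, 1.5),          # tarsal plate thickness, mm
       s = seq(0.2, 0.9, by = 0.1),        # oxygenation parameter
       c_blood_tp = seq(0.1, 0.9, by = 0.2))  # tarsal blood fraction
}

.stack_with <- function(stack, h_tp = NULL, c_blood_tp = NULL) {
  l <- stack$layers$TP
  if (!is.null(h_tp)) l$thickness_mm <- h_tp
  if (!is.null(c_blood_tp)) l$c_blood <- c_blood_tp
  # search ranges may push the blood fraction past the volume left by
  # water; the baseline weight then clamps at zero
  l$allow_oversum <- TRUE
  stack$layers$TP <- do.call(optical_layer, l)
  stack
}

#' Calibrate tissue parameters against a measured spectrum
#'
#' The calibration stage of the combined forward/inverse method: with the
#' subject's hemoglobin fixed at its known (CBC) value, forward spectra are
#' simulated on an exhaustive grid over tarsal-plate thickness, the
#' oxygenation parameter `S` and tarsal blood volume fraction, and the
#' parameter set minimizing the sum of squared residuals against the
#' measured spectrum over the fitting band is returned. All grid points
#' share one root seed (common random numbers) so the argmin is
#' well-defined at reduced photon counts.
#'
#' @param measured a [conj_spectrum()] covering the fitting band.
#' @param hgb_known the subject's hemoglobin, g/dL (`> 0`).
#' @param ranges named list with numeric grids `h_tp` (mm), `s`,
#'   `c_blood_tp`; defaults cover the published search ranges
#'   (1--1.5 mm, 0.2--0.9, 0.1--0.9).
#' @param stack baseline `tissue_stack` providing all non-searched
#'   parameters.
#' @param grid simulation wavelength grid, nm.
#' @param config a [run_config()].
#' @param band fitting band, nm.
#' @return object of class `conj_calib`: best parameters, best SSR, the
#'   full SSR grid, and the calibrated stack.
#' @export
conj_calibrate <- function(measured, hgb_known,
                           ranges = .default_calib_ranges(),
                           stack = default_eyelid_stack(),
                           grid = default_grid(400, 660, 20),
                           config = run_config(), band = c(400, 660)) {
  stopifnot(inherits(measured, "conj_spectrum"), hgb_known > 0)
  for (nm in c("h_tp", "s", "c_blood_tp"))
    if (!length(ranges[[nm]])) stop("empty calibration grid for ", nm)
  pts <- expand.grid(h_tp = ranges$h_tp, s = ranges$s,
                     c_blood_tp = ranges$c_blood_tp,
                     KEEP.OUT.ATTRS = FALSE)
  pts$ssr <- vapply(seq_len(nrow(pts)), function(i) {
    st <- .stack_with(stack, pts$h_tp[i], pts$c_blood_tp[i])
    bl <- blood_state(hgb_known, pts$s[i])
    sim <- simulate_spectrum(st, bl, grid, config)
    ssr(sim, measured, band)
  }, numeric(1))
  best <- which.min(pts$ssr)
  pars <- c(h_tp = pts$h_tp[best], s = pts$s[best],
            c_blood_tp = pts$c_blood_tp[best])
  structure(list(coefficients = pars, best_ssr = pts$ssr[best],
                 ssr_grid = pts, ranges = ranges,
                 stack = .stack_with(stack, pars[["h_tp"]],
                                     pars[["c_blood_tp"]]),
                 hgb_known = hgb_known, measured = measured,
                 sim_grid = grid, band = band, config = config),
            class = "conj_calib")
}

#' @export
coef.conj_calib <- function(object, ...) object$coefficients

#' @export
print.conj_calib <- function(x, ...) {
  cat("conjunctiva model calibration (SSR grid search)\n")
  cat(sprintf("  known Hgb: %.2f g/dL; fitting band %g-%g nm\n",
              x$hgb_known, x$band[1], x$band[2]))
  cat(sprintf("  best fit: h_TP = %.3g mm, S = %.3g, C_blood(TP) = %.3g\n",
              x$coefficients[["h_tp"]], x$coefficients[["s"]],
              x$coefficients[["c_blood_tp"]]))
  cat(sprintf("  best SSR = %.5g over %d grid points\n", x$best_ssr,
              nrow(x$ssr_grid)))
  invisible(x)
}

#' @export
summary.conj_calib <- function(object, ...) {
  print(object)
  cat("\nSSR quartiles over the search grid:\n")
  print(quantile(object$ssr_grid$ssr))
  invisible(object)
}

#' @export
simulate.conj_calib <- function(object, nsim = 1, seed = NULL,
                                blood = NULL, ...) {
  cfg <- object$config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(blood))
    blood <- blood_state(object$hgb_known, object$coefficients[["s"]])
  simulate_spectrum(object$stack, blood, object$sim_grid, cfg)
}

#' @export
residuals.conj_calib <- function(object, ...) {
  sim <- simulate.conj_calib(object)
  wl <- sim$wavelength_nm
  in_band <- wl >= object$band[1] & wl <= object$band[2]
  meas <- approx(object$measured$wavelength_nm,
                 object$measured$reflectance, xout = wl[in_band])$y
  setNames(sim$reflectance[in_band] - meas, wl[in_band])
}

#' @export
plot.conj_calib <- function(x, ...) {
  sim <- simulate.conj_calib(x)
  wl <- sim$wavelength_nm
  meas <- approx(x$measured$wavelength_nm, x$measured$reflectance,
                 xout = wl)$y
  graphics::matplot(wl, cbind(sim$reflectance, meas), type = "l", lty = 1:2,
                    col = c("black", "red"), xlab = "wavelength (nm)",
                    ylab = "reflectance", main = "calibrated fit", ...)
  graphics::legend("topleft", c("simulated", "measured"), lty = 1:2,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Predict hemoglobin and oxygenation from a measured spectrum
#'
#' The prediction stage: holding the calibrated tissue parameters fixed,
#' forward spectra are simulated for every `(Hgb, S)` pair on the search
#' grids (hematocrit tracking hemoglobin through [ht_from_hgb()]) and the
#' pair minimizing the SSR over the fitting band is returned. Ties are
#' broken toward the lower hemoglobin value.
#'
#' @param object a `conj_calib` fit.
#' @param newdata the measured [conj_spectrum()] to invert.
#' @param hgb_grid hemoglobin search grid, g/dL (default 5--20 by 0.3).
#' @param s_grid oxygenation search grid (default 0.2--0.99 by 0.05,
#'   the published parameter range).
#' @param config optional [run_config()] (defaults to the calibration's).
#' @param ... unused.
#' @return object of class `conj_pred`: `hgb`, `s`, `best_ssr` and the
#'   full SSR grid.
#' @export
predict.conj_calib <- function(object, newdata,
                               hgb_grid = seq(5, 20, by = 0.3),
                               s_grid = seq(0.2, 0.99, by = 0.05),
                               config = NULL, ...) {
  stopifnot(inherits(newdata, "conj_spectrum"),
            length(hgb_grid) >= 1, length(s_grid) >= 1)
  cfg <- if (is.null(config)) object$config else config
  pts <- expand.grid(hgb = hgb_grid, s = s_grid, KEEP.OUT.ATTRS = FALSE)
  pts$ssr <- vapply(seq_len(nrow(pts)), function(i) {
    bl <- blood_state(pts$hgb[i], pts$s[i])
    sim <- simulate_spectrum(object$stack, bl, object$sim_grid, cfg)
    ssr(sim, newdata, object$band)
  }, numeric(1))
  ord <- order(pts$ssr, pts$hgb)  # ties toward lower Hgb
  best <- ord[1]
  structure(list(hgb = pts$hgb[best], s = pts$s[best],
                 best_ssr = pts$ssr[best], ssr_grid = pts,
                 calibration = object$coefficients),
            class = "conj_pred")
}

#' @export
print.conj_pred <- function(x, ...) {
  cat(sprintf(
    "predicted Hgb = %.2f g/dL, S = %.2f (best SSR = %.5g, %d grid points)\n",
    x$hgb, x$s, x$best_ssr, nrow(x$ssr_grid)))
  invisible(x)
}

# ---- clinical statistics --------------------------------------------------

#' Anemia classification (WHO thresholds)
#'
#' Hemoglobin strictly below 13 g/dL for men or 12 g/dL for women is
#' classified anemic.
#'
#' @param hgb hemoglobin, g/dL.
#' @param sex `"male"` or `"female"` (recycled).
#' @return character vector, `"anemic"` or `"non-anemic"`.
#' @export
anemia_classify <- function(hgb, sex) {
  sex <- rep_len(as.character(sex), length(hgb))
  if (!all(sex %in% c("male", "female")))
    stop("sex must be \"male\" or \"female\"")
  thr <- ifelse(sex == "male", 13, 12)
  ifelse(hgb < thr, "anemic", "non-anemic")
}

#' Bland-Altman agreement statistics
#'
#' Mean difference between predicted and reference values and the limits
#' of agreement at mean +/- 2 SD of the differences (the 2x multiplier as
#' used in the clinical comparison; SD with the sample n-1 convention).
#'
#' @param predicted,reference equal-length numeric vectors (length >= 2).
#' @return list with `mean_difference`, `lower_limit`, `upper_limit`,
#'   `sd_difference`.
#' @export
bland_altman <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference lengths differ")
  if (length(predicted) < 2) stop("need at least 2 pairs")
  d <- predicted - reference
  m <- mean(d); s <- sd(d)
  list(mean_difference = m, lower_limit = m - 2 * s,
       upper_limit = m + 2 * s, sd_difference = s)
}

#' Plausibility band for the tissue oxygen saturation parameter
#'
#' Assuming oxygenated (arterial) and deoxygenated (venous) blood are
#' present in equal parts in the tissue layer, the plausible tissue
#' saturation is the equal-parts average of the arterial mean and each
#' venous bound.
#'
#' @param sao2_mean mean arterial oxygen saturation, percent.
#' @param svo2_low,svo2_high venous saturation bounds, percent.
#' @return named numeric vector `c(low, high)`, percent.
#' @export
saturation_plausibility <- function(sao2_mean, svo2_low, svo2_high) {
  v <- c(sao2_mean, svo2_low, svo2_high)
  if (any(v < 0 | v > 100)) stop("saturations must lie in [0, 100] percent")
  c(low = (sao2_mean + svo2_low) / 2, high = (sao2_mean + svo2_high) / 2)
}

# ---- leave-one-out cross-validation --------------------------------------

#' Leave-one-out cross-validation of hemoglobin prediction
#'
#' For each held-out subject, the tissue hyperparameters are set from the
#' remaining subjects and [predict.conj_calib()] inverts the held-out
#' spectrum for hemoglobin and oxygenation. Two modes of propagating the
#' training calibrations are provided: `"median"` (default) calibrates
#' each training subject once against its own spectrum at its known
#' hemoglobin and uses the median tissue parameters
#' (deterministic and invariant to subject order), while `"global"`
#' reuses one calibration of the full cohort's first subject for every
#' fold. Aggregates RMSECV, the Pearson correlation between predicted and
#' reference hemoglobin, anemia sensitivity/specificity at the WHO
#' thresholds, and Bland-Altman agreement statistics.
#'
#' @param cohort a cohort list as returned by [generate_cohort()] /
#'   [read_cohort()]: `metadata` data.frame (columns `subject_id`, `sex`,
#'   `hgb_g_dl`) and `spectra`, a named list (per subject) of
#'   [conj_spectrum()]s or lists of replicate spectra (replicates are
#'   averaged).
#' @param ranges,stack,grid,config,band as in [conj_calibrate()].
#' @param hgb_grid,s_grid prediction grids, as in [predict.conj_calib()].
#' @param calibration_mode `"median"` or `"global"`.
#' @return object of class `conj_cv`.
#' @export
conj_loocv <- function(cohort, ranges = .default_calib_ranges(),
                       stack = default_eyelid_stack(),
                       grid = default_grid(400, 660, 20),
                       config = run_config(), band = c(400, 660),
                       hgb_grid = seq(5, 20, by = 0.3),
                       s_grid = seq(0.2, 0.99, by = 0.05),
                       calibration_mode = c("median", "global")) {
  calibration_mode <- match.arg(calibration_mode)
  md <- cohort$metadata
  stopifnot(is.data.frame(md),
            all(c("subject_id", "hgb_g_dl") %in% names(md)))
  n <- nrow(md)
  if (n < 3) stop("leave-one-out cross-validation needs at least 3 subjects")
  ids <- as.character(md$subject_id)

  subj_spectrum <- function(id) {
    sp <- cohort$spectra[[id]]
    if (inherits(sp, "conj_spectrum")) return(sp)
    wl <- sp[[1]]$wavelength_nm
    conj_spectrum(wl, rowMeans(vapply(sp, `[[`,
                                      numeric(length(wl)), "reflectance")))
  }
  spectra <- lapply(ids, subj_spectrum)
  names(spectra) <- ids

  # per-subject calibration is fold-independent: calibrate once per subject
  calibs <- lapply(seq_len(n), function(i) {
    conj_calibrate(spectra[[i]], md$hgb_g_dl[i], ranges = ranges,
                   stack = stack, grid = grid, config = config, band = band)
  })

  fold_fit <- function(i) {
    train <- setdiff(seq_len(n), i)
    if (calibration_mode == "global") return(calibs[[train[1]]])
    pars <- vapply(calibs[train], coef, numeric(3))
    med <- apply(pars, 1, median)
    base <- calibs[[train[1]]]
    base$coefficients <- med
    base$stack <- .stack_with(stack, med[["h_tp"]], med[["c_blood_tp"]])
    base
  }

  preds <- lapply(seq_len(n), function(i) {
    predict(fold_fit(i), spectra[[i]], hgb_grid = hgb_grid,
            s_grid = s_grid, config = config)
  })
  hgb_pred <- vapply(preds, `[[`, numeric(1), "hgb")
  s_pred <- vapply(preds, `[[`, numeric(1), "s")
  hgb_ref <- md$hgb_g_dl

  rmsecv <- sqrt(mean((hgb_pred - hgb_ref)^2))
  pearson <- if (var(hgb_pred) > 0 && var(hgb_ref) > 0)
    cor(hgb_pred, hgb_ref) else NA_real_

  sens <- spec <- NA_real_
  if ("sex" %in% names(md) && !anyNA(md$sex)) {
    truth <- anemia_classify(hgb_ref, md$sex) == "anemic"
    call_ <- anemia_classify(hgb_pred, md$sex) == "anemic"
    if (any(truth)) sens <- mean(call_[truth])
    if (any(!truth)) spec <- mean(!call_[!truth])
  }

  structure(list(
    predictions = data.frame(subject_id = ids, hgb_ref = hgb_ref,
                             hgb_pred = hgb_pred, s_pred = s_pred),
    rmsecv = rmsecv, pearson = pearson,
    anemia_sensitivity = sens, anemia_specificity = spec,
    bland_altman = bland_altman(hgb_pred, hgb_ref),
    calibration_mode = calibration_mode, seed = config$seed),
    class = "conj_cv")
}

#' @export
print.conj_cv <- function(x, ...) {
  cat(sprintf(
    "leave-one-out cross-validation, %d subjects (seed %d, %s calibration)\n",
    nrow(x$predictions), x$seed, x$calibration_mode))
  cat(sprintf("  RMSECV = %.3f g/dL; Pearson r = %.3f\n", x$rmsecv,
              x$pearson))
  if (!is.na(x$anemia_sensitivity))
    cat(sprintf("  anemia sensitivity = %.2f, specificity = %.2f\n",
                x$anemia_sensitivity, x$anemia_specificity))
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman: mean diff %.2f g/dL, limits [%.2f, %.2f]\n",
              ba$mean_difference, ba$lower_limit, ba$upper_limit))
  invisible(x)
}

#' @export
summary.conj_cv <- function(object, ...) {
  print(object)
  cat("\nper-subject predictions:\n")
  print(object$predictions)
  invisible(object)
}

#' @export
plot.conj_cv <- function(x, ...) {
  p <- x$predictions
  graphics::plot(p$hgb_ref, p$hgb_pred, xlab = "CBC hemoglobin (g/dL)",
                 ylab = "predicted hemoglobin (g/dL)",
                 main = "LOOCV prediction", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
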