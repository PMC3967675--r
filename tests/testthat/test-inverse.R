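# Inverse fitting: calibration, prediction, cross-validation and the
# clinical agreement statistics.

calib_ranges <- function() {
  list(h_tp = c(1.0, 1.25), s = c(0.8, 0.9), c_blood_tp = c(0.1, 0.3))
}

test_that("calibration recovers on-grid generating parameters exactly", {
  st <- default_eyelid_stack()
  grid <- coarse_grid()
  cfg <- fast_config(1500)
  truth_stack <- conjspec:::.stack_with(st, h_tp = 1.25, c_blood_tp = 0.3)
  measured <- simulate_spectrum(truth_stack, blood_state(13, 0.8),
                                grid, cfg)
  fit <- conj_calibrate(measured, 13, ranges = calib_ranges(), stack = st,
                        grid = grid, config = cfg)
  expect_s3_class(fit, "conj_calib")
  expect_equal(unname(coef(fit)), c(1.25, 0.8, 0.3))
  expect_equal(fit$best_ssr, 0)
  # argmin bookkeeping: reported best is the grid minimum
  expect_equal(fit$best_ssr, min(fit$ssr_grid$ssr))
  g <- fit$ssr_grid
  row <- g[g$h_tp == 1.25 & g$s == 0.8 & g$c_blood_tp == 0.3, ]
  expect_equal(row$ssr, fit$best_ssr)

  # degenerate one-point grid returns that point
  fit1 <- conj_calibrate(measured, 13,
                         ranges = list(h_tp = 1.0, s = 0.9,
                                       c_blood_tp = 0.1),
                         stack = st, grid = grid, config = cfg)
  expect_equal(unname(coef(fit1)), c(1.0, 0.9, 0.1))
  expect_error(conj_calibrate(measured, 13,
                              ranges = list(h_tp = numeric(0), s = 0.9,
                                            c_blood_tp = 0.1),
                              stack = st, grid = grid, config = cfg),
               "empty")
})

test_that("prediction recovers on-grid hemoglobin and saturation", {
  st <- default_eyelid_stack()
  grid <- coarse_grid()
  cfg <- fast_config(1500)
  truth_stack <- conjspec:::.stack_with(st, h_tp = 1.0, c_blood_tp = 0.3)
  fit <- conj_calibrate(
    simulate_spectrum(truth_stack, blood_state(12, 0.8), grid, cfg), 12,
    ranges = list(h_tp = 1.0, s = c(0.8, 0.9), c_blood_tp = 0.3),
    stack = st, grid = grid, config = cfg)

  target <- simulate_spectrum(fit$stack, blood_state(14, 0.9), grid, cfg)
  pred <- predict(fit, target, hgb_grid = seq(10, 16, 2),
                  s_grid = c(0.8, 0.9))
  expect_equal(pred$hgb, 14)
  expect_equal(pred$s, 0.9)
  expect_equal(pred$best_ssr, 0)

  # deeper hemoglobin absorption maps to higher predicted hemoglobin
  weak <- simulate_spectrum(fit$stack, blood_state(10, 0.9), grid, cfg)
  pred_weak <- predict(fit, weak, hgb_grid = seq(10, 16, 2),
                       s_grid = c(0.8, 0.9))
  expect_lt(pred_weak$hgb, pred$hgb)
})

test_that("prediction is exact for a seeded batch of on-grid truths", {
  st <- default_eyelid_stack()
  grid <- coarse_grid()
  cfg <- fast_config(1200)
  fit <- conj_calibrate(
    simulate_spectrum(st, blood_state(13, 0.9), grid, cfg), 13,
    ranges = list(h_tp = 0.1, s = 0.9, c_blood_tp = 0.45),
    stack = st, grid = grid, config = cfg)
  hgbs <- seq(8, 17, by = 1)
  set.seed(5)
  cases <- data.frame(hgb = sample(hgbs, 20, replace = TRUE),
                      s = sample(c(0.8, 0.9), 20, replace = TRUE))
  for (i in seq_len(nrow(cases))) {
    sp <- simulate_spectrum(fit$stack,
                            blood_state(cases$hgb[i], cases$s[i]),
                            grid, cfg)
    pr <- predict(fit, sp, hgb_grid = hgbs, s_grid = c(0.8, 0.9))
    expect_equal(pr$hgb, cases$hgb[i])
    expect_equal(pr$s, cases$s[i])
  }
})

test_that("anemia classification applies the sex-specific thresholds", {
  expect_equal(anemia_classify(12.9, "male"), "anemic")
  expect_equal(anemia_classify(12.0, "female"), "non-anemic")
  expect_equal(anemia_classify(12.5, "female"), "non-anemic")
  expect_equal(anemia_classify(12.5, "male"), "anemic")
  expect_equal(anemia_classify(c(11, 14), c("female", "male")),
               c("anemic", "non-anemic"))
  expect_error(anemia_classify(12, "other"), "sex")
})

test_that("Bland-Altman limits bracket the mean difference at two SD", {
  ba0 <- bland_altman(c(10, 12, 14), c(10, 12, 14))
  expect_equal(ba0$mean_difference, 0)
  expect_equal(ba0$lower_limit, 0)
  expect_equal(ba0$upper_limit, 0)

  ba <- bland_altman(c(11, 9), c(10, 10))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, sd(c(1, -1)))
  expect_equal(ba$upper_limit, 2 * sqrt(2))
  expect_equal(ba$lower_limit, -2 * sqrt(2))

  set.seed(2)
  p <- rnorm(10); r <- rnorm(10)
  bb <- bland_altman(p, r)
  expect_equal(bb$upper_limit - bb$mean_difference,
               bb$mean_difference - bb$lower_limit)
  expect_error(bland_altman(1:3, 1:4), "lengths differ")
})

test_that("tissue saturation plausibility is the equal-parts average", {
  out <- saturation_plausibility(98.3, 72, 75)
  expect_equal(unname(out), c(85.15, 86.65))
  expect_equal(unname(saturation_plausibility(100, 100, 100)), c(100, 100))
  expect_equal(unname(saturation_plausibility(80, 80, 80)), c(80, 80))
  expect_error(saturation_plausibility(110, 70, 75), "\\[0, 100\\]")
})

test_that("leave-one-out cross-validation recovers a noise-free cohort", {
  st <- default_eyelid_stack()
  grid <- coarse_grid()
  cfg <- fast_config(1500)
  ranges <- list(h_tp = c(1.0, 1.25), s = c(0.8, 0.9),
                 c_blood_tp = c(0.1, 0.3))
  gen_stack <- conjspec:::.stack_with(st, h_tp = 1.0, c_blood_tp = 0.3)

  hgb <- c(10, 12, 14, 16)
  s <- c(0.9, 0.8, 0.9, 0.8)
  sex <- c("female", "male", "female", "male")
  ids <- paste0("P", 1:4)
  spectra <- lapply(1:4, function(i)
    simulate_spectrum(gen_stack, blood_state(hgb[i], s[i]), grid, cfg))
  names(spectra) <- ids
  cohort <- list(metadata = data.frame(subject_id = ids, sex = sex,
                                       hgb_g_dl = hgb),
                 spectra = spectra)

  cv <- conj_loocv(cohort, ranges = ranges, stack = st, grid = grid,
                   config = cfg, hgb_grid = seq(8, 18, 2),
                   s_grid = c(0.8, 0.9))
  expect_s3_class(cv, "conj_cv")
  expect_equal(nrow(cv$predictions), 4)
  expect_equal(cv$predictions$hgb_pred, hgb)
  expect_equal(cv$rmsecv, 0)
  expect_equal(cv$pearson, 1)
  expect_equal(cv$anemia_sensitivity, 1)
  expect_equal(cv$anemia_specificity, 1)
  expect_equal(cv$bland_altman$mean_difference, 0)

  # invariant to subject ordering
  perm <- c(3, 1, 4, 2)
  cohort2 <- list(metadata = cohort$metadata[perm, ],
                  spectra = cohort$spectra[perm])
  cv2 <- conj_loocv(cohort2, ranges = ranges, stack = st, grid = grid,
                    config = cfg, hgb_grid = seq(8, 18, 2),
                    s_grid = c(0.8, 0.9))
  expect_equal(cv2$rmsecv, cv$rmsecv)
  expect_equal(sort(cv2$predictions$hgb_pred),
               sort(cv$predictions$hgb_pred))

  # minimal three-subject cohort executes
  cohort3 <- list(metadata = cohort$metadata[1:3, ],
                  spectra = cohort$spectra[1:3])
  cv3 <- conj_loocv(cohort3, ranges = ranges, stack = st, grid = grid,
                    config = cfg, hgb_grid = seq(8, 18, 2),
                    s_grid = c(0.8, 0.9))
  expect_equal(nrow(cv3$predictions), 3)
  expect_error(conj_loocv(list(metadata = cohort$metadata[1:2, ],
                               spectra = cohort$spectra[1:2]),
                          ranges = ranges, stack = st, grid = grid,
                          config = cfg), "at least 3")
})
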