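# Spectral sweeps, sensitivity machinery, SSR and spectrum file I/O.

test_that("the default grid covers 400-700 nm at 2 nm", {
  g <- default_grid()
  expect_length(g, 151)
  expect_equal(g[1], 400)
  expect_equal(g[151], 700)
})

test_that("simulated spectra are reproducible, bounded, and Hgb-ordered", {
  st <- default_eyelid_stack()
  grid <- coarse_grid()
  cfg <- fast_config(3000)
  sp1 <- simulate_spectrum(st, default_blood(), grid, cfg)
  sp2 <- simulate_spectrum(st, default_blood(), grid, cfg)
  expect_identical(sp1$reflectance, sp2$reflectance)
  expect_true(all(sp1$reflectance >= 0 & sp1$reflectance <= 1))

  # common random numbers: higher hemoglobin absorbs more in the
  # 500-580 nm hemoglobin bands
  band <- seq(500, 580, by = 20)
  lo <- simulate_spectrum(st, blood_state(8.1, 0.9), band, cfg)
  hi <- simulate_spectrum(st, blood_state(16.7, 0.9), band, cfg)
  expect_true(all(hi$reflectance <= lo$reflectance))
})

test_that("relative variation summarizes spread against the baseline", {
  wl <- c(500, 550, 600)
  mk <- function(v) conj_spectrum(wl, rep(v, 3))
  # identical curves -> zero
  rv0 <- relative_variation(list(mk(0.5), mk(0.5), mk(0.5)),
                            band = c(500, 600))
  expect_equal(rv0$max_percent, 0)
  # two flat spectra around a flat baseline
  rv <- relative_variation(list(mk(0.45), mk(0.5), mk(0.55)),
                           band = c(500, 600))
  expect_equal(rv$max_percent, 20)
  # explicit baseline
  rv2 <- relative_variation(list(mk(0.45), mk(0.55)), baseline = mk(0.5),
                            band = c(500, 600))
  expect_equal(rv2$max_percent, 20)
  expect_error(relative_variation(list(mk(0.4), mk(0.5)),
                                  baseline = mk(0)), "positive")
})

test_that("sensitivity scans isolate parameter effects from MC noise", {
  st <- default_eyelid_stack()
  bl <- default_blood()
  grid <- coarse_grid()
  cfg <- fast_config(4000)

  # single-value sweep has zero variation by definition
  one <- sensitivity_scan(st, bl, "c_mel_LE", 0.05, grid, cfg)
  expect_equal(one$relative_variation$max_percent, 0)

  # a sensitive parameter (tarsal blood) moves the curves far beyond the
  # per-curve MC noise; melanin below 580 nm does not
  tp <- sensitivity_scan(st, bl, "c_blood_TP", c(0.08, 0.19, 0.30),
                         grid, cfg)
  expect_gt(tp$relative_variation$max_percent, 10)
  mel <- sensitivity_scan(st, bl, "c_mel_LE", c(0.01, 0.055, 0.10),
                          grid, cfg, band = c(420, 580))
  expect_lt(mel$relative_variation$max_percent,
            tp$relative_variation$max_percent / 5)

  # raising oxygen saturation reshapes the 540-580 nm doublet region
  sat <- sensitivity_scan(st, bl, "S", c(0.3, 0.6, 0.9),
                          seq(520, 600, 20), cfg)
  expect_gt(sat$relative_variation$max_percent, 0)

  # tarsal blood matters more than dermal blood
  d <- sensitivity_scan(st, bl, "c_blood_D", c(0.15, 0.30, 0.45),
                        grid, cfg)
  expect_gt(tp$relative_variation$max_percent,
            d$relative_variation$max_percent)

  expect_error(sensitivity_scan(st, bl, "c_blood_TP", c(-0.1, 0.5),
                                grid, cfg), "bounds")
  expect_error(sensitivity_scan(st, bl, "nonsense", 1, grid, cfg),
               "unknown sweep parameter")
})

test_that("SSR measures squared spectral mismatch over the band", {
  wl <- c(500, 550, 600)
  a <- conj_spectrum(wl, c(0.2, 0.3, 0.4))
  expect_equal(ssr(a, a, band = c(400, 660)), 0)
  b <- conj_spectrum(wl, c(0.3, 0.4, 0.5))
  expect_equal(ssr(a, b, band = c(400, 660)), 0.03)
  # measured resampled onto the simulation grid
  m <- conj_spectrum(c(475, 525, 575, 625), c(0.15, 0.25, 0.35, 0.45))
  expect_equal(ssr(a, m, band = c(400, 660)), 0, tolerance = 1e-12)
  expect_error(ssr(a, conj_spectrum(c(700, 710), c(0.1, 0.1))),
               "cover the fitting band")

  # objective decreases toward the generating hemoglobin
  st <- default_eyelid_stack()
  cfg <- fast_config(3000)
  grid <- coarse_grid()
  truth <- simulate_spectrum(st, blood_state(12, 0.9), grid, cfg)
  errs <- vapply(c(6, 9, 12), function(h)
    ssr(simulate_spectrum(st, blood_state(h, 0.9), grid, cfg), truth),
    numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_equal(errs[3], 0)
})

test_that("spectrum files round-trip and malformed files are rejected", {
  sp <- conj_spectrum(c(400, 402, 404), c(0.123456789, 0.2, 1.0))
  path <- tempfile(fileext = ".csv")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_equal(back$wavelength_nm, sp$wavelength_nm)
  expect_equal(back$reflectance, sp$reflectance, tolerance = 1e-9)

  # hand-written three-line file
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,reflectance", "500,0.5", "510,0.6"), p2)
  expect_equal(nrow(read_spectrum(p2)), 2)

  # descending wavelengths
  p3 <- tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,reflectance", "510,0.5", "500,0.6"), p3)
  expect_error(read_spectrum(p3), "non-ascending")

  # missing header
  p4 <- tempfile(fileext = ".csv")
  writeLines(c("400,0.1", "410,0.2"), p4)
  expect_error(read_spectrum(p4), "header")

  # out-of-range reflectance with line number
  p5 <- tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,reflectance", "500,0.5", "510,1.2"), p5)
  expect_error(read_spectrum(p5), "\\[0, 1.05\\]")
  unlink(c(path, p2, p3, p4, p5))
})
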