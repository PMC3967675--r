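# Wavelength sweeps of the transport engine, sensitivity experiments and
# spectral comparison metrics.

#' Construct a spectrum object
#'
#' @param wavelength_nm ascending wavelength grid, nm.
#' @param reflectance reflectance values (same length; `[0, 1]` for
#'   simulated spectra, small excursions above 1 tolerated for noisy
#'   measurements).
#' @param metadata optional named list (stack hash, blood state, photon
#'   count, seed, ...).
#' @return object of class `conj_spectrum` (a data.frame).
#' @export
conj_spectrum <- function(wavelength_nm, reflectance, metadata = list()) {
  if (length(wavelength_nm) != length(reflectance))
    stop("wavelength and reflectance lengths differ")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly ascending")
  if (any(reflectance < 0 | reflectance > 1.05))
    stop("reflectance outside [0, 1.05]")
  structure(data.frame(wavelength_nm = wavelength_nm,
                       reflectance = reflectance),
            metadata = metadata,
            class = c("conj_spectrum", "data.frame"))
}

#' @export
print.conj_spectrum <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("conjunctiva spectrum: %d points, %g-%g nm\n",
              nrow(x), min(x$wavelength_nm), max(x$wavelength_nm)))
  if (length(md)) {
    keys <- intersect(c("hgb", "s", "n_photons", "seed"), names(md))
    if (length(keys))
      cat("  ", paste(sprintf("%s = %s", keys,
                              vapply(md[keys], format, "")),
                      collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Default simulation wavelength grid
#'
#' 400--700 nm at 2 nm intervals (151 points).
#'
#' @param from,to,by grid limits and step, nm.
#' @return numeric vector of wavelengths.
#' @export
default_grid <- function(from = 400, to = 700, by = 2) seq(from, to, by = by)

#' Simulate a reflectance spectrum
#'
#' Runs [simulate_reflectance()] at every grid wavelength. Each wavelength
#' uses its own RNG substream derived from the root seed and the
#' wavelength index, so a run is bit-reproducible and two runs with the
#' same seed share photon streams wavelength-by-wavelength (common random
#' numbers across parameter sweeps).
#'
#' @param stack a `tissue_stack`.
#' @param blood a [blood_state()].
#' @param grid wavelength grid, nm (default [default_grid()]).
#' @param config a [run_config()].
#' @return a [conj_spectrum()] with ledger metadata.
#' @export
simulate_spectrum <- function(stack, blood, grid = default_grid(),
                              config = run_config()) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly ascending")
  refl <- vapply(seq_along(grid), function(k) {
    simulate_reflectance(stack, grid[k], blood, config,
                         stream = k)$R_diffuse
  }, numeric(1))
  conj_spectrum(grid, refl,
                metadata = list(hgb = blood$hgb, s = blood$s, ht = blood$ht,
                                n_photons = config$n_photons,
                                seed = config$seed,
                                termination = config$termination))
}

#' Relative variation of a spectrum family
#'
#' Per wavelength, `100 * (max_p R - min_p R) / R_baseline` across the
#' sweep curves; the summary is the maximum over the band. The baseline
#' defaults to the sweep's midpoint curve (`summary_mode = "vs_mid"`);
#' `"vs_mean"` uses the per-wavelength mean of the curves instead.
#'
#' @param curves list of [conj_spectrum()]s on a common grid.
#' @param baseline baseline spectrum; default the middle curve of `curves`.
#' @param band wavelength interval for the summary, nm.
#' @param summary_mode `"vs_mid"` or `"vs_mean"`.
#' @return list: `per_wavelength` data.frame and `max_percent` summary.
#' @export
relative_variation <- function(curves, baseline = NULL, band = c(400, 660),
                               summary_mode = c("vs_mid", "vs_mean")) {
  summary_mode <- match.arg(summary_mode)
  stopifnot(length(curves) >= 1)
  wl <- curves[[1]]$wavelength_nm
  for (cv in curves)
    if (!isTRUE(all.equal(cv$wavelength_nm, wl)))
      stop("all spectra must share one wavelength grid")
  R <- vapply(curves, `[[`, numeric(length(wl)), "reflectance")
  R <- matrix(R, nrow = length(wl))
  base <- if (!is.null(baseline)) {
    if (!isTRUE(all.equal(baseline$wavelength_nm, wl)))
      stop("baseline grid differs from the curves")
    baseline$reflectance
  } else if (summary_mode == "vs_mean") {
    rowMeans(R)
  } else {
    R[, ceiling(ncol(R) / 2)]
  }
  in_band <- wl >= band[1] & wl <= band[2]
  if (any(base[in_band] <= 0))
    stop("baseline reflectance must be positive over the band")
  rv <- 100 * (apply(R, 1, max) - apply(R, 1, min)) / base
  list(per_wavelength = data.frame(wavelength_nm = wl,
                                   relative_variation_pct = rv),
       max_percent = max(rv[in_band]),
       band = band)
}

# parameter spec -> stack/blood modifier for sensitivity sweeps
.apply_sweep_value <- function(stack, blood, parameter, value) {
  if (identical(parameter, "S")) {
    blood <- blood_state(blood$hgb, value, ht = blood$ht)
    return(list(stack = stack, blood = blood))
  }
  m <- regmatches(parameter,
                  regexec("^(thickness|c_blood|c_mel)_([A-Z]{1,2})$",
                          parameter))[[1]]
  if (!length(m)) stop("unknown sweep parameter: ", parameter)
  field <- switch(m[2], thickness = "thickness_mm", c_blood = "c_blood",
                  c_mel = "c_mel")
  lay <- m[3]
  if (!lay %in% names(stack$layers)) stop("unknown layer: ", lay)
  if (value < 0 || (field != "thickness_mm" && value > 1))
    stop("sweep value outside physical bounds")
  if (field == "thickness_mm" && value <= 0)
    stop("sweep thickness must be positive")
  l <- stack$layers[[lay]]
  l[[field]] <- value
  l$allow_oversum <- TRUE
  stack$layers[[lay]] <- do.call(optical_layer, l)
  list(stack = stack, blood = blood)
}

#' Sensitivity scan over one model parameter
#'
#' Simulates one spectrum per sweep value with common random numbers
#' (shared root seed, so differences between curves isolate the parameter
#' effect from Monte Carlo noise) and attaches the [relative_variation()]
#' summary. Parameters are named `thickness_<LAYER>` (mm),
#' `c_blood_<LAYER>`, `c_mel_<LAYER>` or `"S"`, e.g. `"c_blood_TP"`.
#'
#' @param stack baseline `tissue_stack`.
#' @param blood baseline [blood_state()].
#' @param parameter parameter name (see Details).
#' @param values sweep values (ascending recommended; the middle value is
#'   the relative-variation baseline).
#' @param grid wavelength grid, nm.
#' @param config a [run_config()].
#' @param band summary band, nm.
#' @return object of class `sensitivity_result`.
#' @export
sensitivity_scan <- function(stack, blood, parameter, values,
                             grid = default_grid(), config = run_config(),
                             band = c(400, 660)) {
  stopifnot(length(values) >= 1)
  curves <- lapply(values, function(v) {
    sw <- .apply_sweep_value(stack, blood, parameter, v)
    simulate_spectrum(sw$stack, sw$blood, grid, config)
  })
  rv <- if (length(values) > 1) relative_variation(curves, band = band)
        else list(per_wavelength = NULL, max_percent = 0, band = band)
  structure(list(parameter = parameter, values = values, curves = curves,
                 relative_variation = rv, band = band),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("sensitivity of reflectance to %s over [%s]\n", x$parameter,
              paste(format(x$values), collapse = ", ")))
  cat(sprintf("  band-maximum relative variation (%g-%g nm): %.2f%%\n",
              x$band[1], x$band[2], x$relative_variation$max_percent))
  invisible(x)
}

#' @export
plot.sensitivity_result <- function(x, ...) {
  wl <- x$curves[[1]]$wavelength_nm
  R <- vapply(x$curves, `[[`, numeric(length(wl)), "reflectance")
  graphics::matplot(wl, R, type = "l", lty = 1,
                    xlab = "wavelength (nm)", ylab = "reflectance",
                    main = paste("sweep of", x$parameter), ...)
  graphics::legend("topleft", legend = format(x$values),
                   col = seq_along(x$values), lty = 1, bty = "n")
  invisible(x)
}

#' Sum of squared residuals between spectra
#'
#' `SSR = sum_lambda (R_sim - R_meas)^2` over the fitting band. The
#' measured spectrum is linearly resampled onto the simulation grid; the
#' two grids must overlap the band.
#'
#' @param simulated,measured [conj_spectrum()]s.
#' @param band fitting band, nm (default 400--660).
#' @return non-negative SSR value.
#' @export
ssr <- function(simulated, measured, band = c(400, 660)) {
  wl <- simulated$wavelength_nm
  in_band <- wl >= band[1] & wl <= band[2]
  wl <- wl[in_band]
  if (!length(wl)) stop("simulation grid has no points in the band")
  if (min(measured$wavelength_nm) > min(wl) ||
      max(measured$wavelength_nm) < max(wl))
    stop("measured spectrum does not cover the fitting band")
  rm_i <- approx(measured$wavelength_nm, measured$reflectance, xout = wl)$y
  sum((simulated$reflectance[in_band] - rm_i)^2)
}

# ---- spectrum file I/O ----------------------------------------------------

#' Read / write a spectrum CSV
#'
#' The on-disk dialect is a UTF-8 CSV with header
#' `wavelength_nm,reflectance`, one row per grid point, decimal points and
#' no thousands separators. Writing keeps 10 significant digits so a
#' write/read round trip is lossless at that precision. Reading validates
#' the header, strict wavelength monotonicity and the reflectance range
#' `[0, 1.05]`, reporting offending line numbers.
#'
#' @param path file path.
#' @param spectrum a [conj_spectrum()].
#' @return `read_spectrum` returns a [conj_spectrum()].
#' @export
read_spectrum <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!identical(trimws(hdr), "wavelength_nm,reflectance"))
    stop("missing or malformed header in ", path,
         " (expected \"wavelength_nm,reflectance\")")
  df <- read.csv(path, header = TRUE)
  bad <- which(!is.finite(df$wavelength_nm) | !is.finite(df$reflectance))
  if (length(bad))
    stop("malformed rows in ", path, " at lines: ",
         paste(bad + 1L, collapse = ", "))
  nd <- which(diff(df$wavelength_nm) <= 0)
  if (length(nd))
    stop("non-ascending wavelengths in ", path, " at lines: ",
         paste(nd + 2L, collapse = ", "))
  oob <- which(df$reflectance < 0 | df$reflectance > 1.05)
  if (length(oob))
    stop("reflectance outside [0, 1.05] in ", path, " at lines: ",
         paste(oob + 1L, collapse = ", "))
  conj_spectrum(df$wavelength_nm, df$reflectance,
                metadata = list(source = path))
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "conj_spectrum"))
  df <- data.frame(wavelength_nm = signif(spectrum$wavelength_nm, 10),
                   reflectance = signif(spectrum$reflectance, 10))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
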