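#' @useDynLib conjspec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef lm median predict quantile rnorm runif sd
#'   setNames var cor
#' @importFrom utils read.delim write.table read.csv write.csv
NULL

# ---- constants ------------------------------------------------------------

#' Physical and model constants
#'
#' Named constants used throughout the optical model: the hemoglobin gram
#' molecular weight (64500 g/mol); the hemoglobin mass concentration of the
#' hemoglobin-occupied volume (850 g/L), chosen so that with the
#' within-erythrocyte hemoglobin volume fraction `phi_Hb = 0.4` the
#' intracellular mass concentration `phi_Hb * rho` equals the standard
#' value of 340 g/L (mean corpuscular hemoglobin concentration); and the
#' default adult hemoglobin-to-hematocrit slope (0.40 fractional
#' hematocrit per 13.9 g/dL, from cohort means).
#'
#' @format A named list.
#' @export
conjspec_constants <- list(
  m_hgb_g_per_mol   = 64500,
  rho_hgb_g_per_l   = 850,
  ht_slope_per_gdl  = 0.40 / 13.9,
  ht_intercept      = 0,
  melanin_prefactor = 6.6e10,   # 1/mm when lambda in nm
  melanin_exponent  = 3.33,
  baseline_prefactor = 7.84e7,  # 1/mm when lambda in nm
  baseline_exponent  = 3.255
)

# conjunctival-epithelium polynomial fits, highest degree first, 1/mm
.ce_mua_coef <- c(5.76328e-13, -5.05681e-9, 1.09816e-5, -0.00905007, 2.607)
.ce_mus_coef <- c(2.63396e-13, -2.81535e-10, -1.10282e-6, 0.00236644,
                  -1.62947, 392.569)
.ce_range <- c(400, 700)

# ---- bundled tables -------------------------------------------------------

.chromo_env <- new.env(parent = emptyenv())

.table_file <- function(species) {
  fname <- switch(species,
    HbO2  = "hbo2_extinction_synthetic.tsv",
    Hb    = "hb_extinction_synthetic.tsv",
    water = "water_mua_synthetic.tsv",
    stop("unknown chromophore species: ", species))
  system.file("extdata", fname, package = "conjspec", mustWork = TRUE)
}

#' Bundled chromophore table
#'
#' Returns the bundled wavelength-resolved table for one chromophore
#' species: molar extinction in L/(cm mol) for oxy- and deoxyhemoglobin, or
#' the absorption coefficient in 1/mm for water. Tables are tabulated on a
#' 2 nm grid over 380--820 nm; values between grid points are obtained by
#' linear interpolation. The bundled hemoglobin and water tables are
#' synthetic tabulations constructed to reproduce the canonical spectral
#' features of the standard literature compilations (band positions,
#' isosbestic crossings, relative magnitudes); they are not transcriptions
#' of any published dataset. A replacement table with columns
#' `wavelength_nm` and a value column can be supplied via `path`.
#'
#' @param species one of `"HbO2"`, `"Hb"`, `"water"`.
#' @param path optional path to a replacement two-column table.
#' @return data.frame with columns `wavelength_nm`, `value`.
#' @export
chromophore_table <- function(species = c("HbO2", "Hb", "water"), path = NULL) {
  species <- match.arg(species)
  key <- if (is.null(path)) species else paste0(species, ":", path)
  if (!is.null(.chromo_env[[key]])) return(.chromo_env[[key]])
  f <- if (is.null(path)) .table_file(species) else path
  tab <- read.delim(f, header = TRUE)
  if (ncol(tab) < 2L) stop("chromophore table must have two columns")
  tab <- data.frame(wavelength_nm = tab[[1]], value = tab[[2]])
  if (any(diff(tab$wavelength_nm) <= 0))
    stop("chromophore table wavelengths must be strictly ascending")
  if (any(tab$value < 0)) stop("chromophore table values must be >= 0")
  .chromo_env[[key]] <- tab
  tab
}

.interp_table <- function(tab, lambda_nm, what) {
  rng <- range(tab$wavelength_nm)
  if (any(lambda_nm < rng[1] | lambda_nm > rng[2]))
    stop(sprintf("wavelength outside the %s table range [%g, %g] nm",
                 what, rng[1], rng[2]))
  approx(tab$wavelength_nm, tab$value, xout = lambda_nm)$y
}

# ---- absorption building blocks ------------------------------------------

#' Hemoglobin absorption coefficient
#'
#' Converts tabulated molar extinction `e(lambda)` (L/(cm mol)) into an
#' absorption coefficient for a hemoglobin mass concentration `x` (g/L):
#' `mu_a = ln(10) * e * x / M_Hgb` in 1/cm, returned in 1/mm. The `ln(10)`
#' factor follows the extinction-table convention (base-10 extinction);
#' set `log10_factor = FALSE` for tables already in natural-log form.
#'
#' @param lambda_nm wavelength(s), nm; must lie inside the bundled table.
#' @param species `"HbO2"` (oxy) or `"Hb"` (deoxy).
#' @param x hemoglobin mass concentration, g/L; must be `>= 0`.
#' @param log10_factor include the `ln(10)` conversion factor (default).
#' @return absorption coefficient(s), 1/mm; exactly linear in `x`.
#' @export
hgb_mu_a <- function(lambda_nm, species = c("HbO2", "Hb"), x,
                     log10_factor = TRUE) {
  species <- match.arg(species)
  if (any(x < 0)) stop("hemoglobin concentration x must be >= 0")
  e <- .interp_table(chromophore_table(species), lambda_nm, "extinction")
  fac <- if (log10_factor) log(10) else 1
  fac * e * x / conjspec_constants$m_hgb_g_per_mol / 10  # 1/cm -> 1/mm
}

#' Water absorption coefficient
#'
#' @param lambda_nm wavelength(s), nm.
#' @return absorption coefficient(s), 1/mm, from the bundled table.
#' @export
water_mu_a <- function(lambda_nm) {
  .interp_table(chromophore_table("water"), lambda_nm, "water")
}

#' Melanin absorption coefficient
#'
#' Power-law melanosome absorption `C * lambda^-p` with the standard
#' prefactor/exponent stored in [conjspec_constants] (6.6e10 / 3.33 for
#' `mu_a` in 1/mm and `lambda` in nm); both are overridable.
#'
#' @param lambda_nm wavelength(s), nm, `> 0`.
#' @param prefactor,exponent power-law parameters.
#' @return absorption coefficient(s), 1/mm; strictly decreasing in lambda.
#' @export
melanin_mu_a <- function(lambda_nm,
                         prefactor = conjspec_constants$melanin_prefactor,
                         exponent = conjspec_constants$melanin_exponent) {
  if (any(lambda_nm <= 0)) stop("wavelength must be positive")
  prefactor * lambda_nm^(-exponent)
}

#' Hemoglobin- and water-free baseline tissue absorption
#'
#' Power-law baseline absorption of bloodless, water-free tissue,
#' `C' * lambda^-p'` (defaults 7.84e7 / 3.255, 1/mm, lambda in nm).
#'
#' @inheritParams melanin_mu_a
#' @return absorption coefficient(s), 1/mm.
#' @export
baseline_mu_a <- function(lambda_nm,
                          prefactor = conjspec_constants$baseline_prefactor,
                          exponent = conjspec_constants$baseline_exponent) {
  if (any(lambda_nm <= 0)) stop("wavelength must be positive")
  prefactor * lambda_nm^(-exponent)
}

.polyval <- function(coef, x) {
  out <- rep(0, length(x))
  for (c_k in coef) out <- out * x + c_k
  out
}

#' Conjunctival-epithelium absorption coefficient
#'
#' Quartic least-squares fit to measured conjunctival-epithelium absorption,
#' evaluated with the published coefficients (1/mm, lambda in nm). The fit
#' is valid over 400--700 nm; outside that window the polynomial diverges
#' and evaluation raises an error unless `check_range = FALSE`.
#'
#' @param lambda_nm wavelength(s), nm.
#' @param check_range enforce the 400--700 nm validity window.
#' @return absorption coefficient(s), 1/mm.
#' @export
ce_mu_a <- function(lambda_nm, check_range = TRUE) {
  if (check_range &&
      any(lambda_nm < .ce_range[1] | lambda_nm > .ce_range[2]))
    stop("lambda outside the conjunctival-epithelium fit window [400, 700] nm")
  .polyval(.ce_mua_coef, lambda_nm)
}

#' Conjunctival-epithelium scattering coefficient
#'
#' Quintic least-squares fit to measured conjunctival-epithelium scattering
#' (1/mm, lambda in nm), valid over 400--700 nm.
#'
#' @inheritParams ce_mu_a
#' @return scattering coefficient(s), 1/mm.
#' @export
ce_mu_s <- function(lambda_nm, check_range = TRUE) {
  if (check_range &&
      any(lambda_nm < .ce_range[1] | lambda_nm > .ce_range[2]))
    stop("lambda outside the conjunctival-epithelium fit window [400, 700] nm")
  .polyval(.ce_mus_coef, lambda_nm)
}

# ---- polynomial fitting ---------------------------------------------------

#' Least-squares polynomial fit via the normal equations
#'
#' Fits `mu = a_1 lambda^d + ... + a_{d+1}` by solving the normal equations
#' `a = (L^T L)^-1 L^T mu` for the Vandermonde design `L`. The design
#' columns are rescaled to unit norm before the solve (a diagonal
#' preconditioner that leaves the solution unchanged but keeps the Gram
#' matrix well-conditioned for wavelength-scale predictors). Used to refit
#' the epithelium polynomials or a hematocrit--hemoglobin regression from
#' user data.
#'
#' @param lambda_nm predictor values (distinct; at least `degree + 1`).
#' @param mu response values.
#' @param degree polynomial degree.
#' @return object of class `poly_fit`: list with `coefficients`
#'   (highest degree first), `r_squared`, `degree`, `range`.
#' @export
polyfit_normal_equations <- function(lambda_nm, mu, degree) {
  stopifnot(length(lambda_nm) == length(mu), degree >= 0)
  if (length(lambda_nm) < degree + 1)
    stop("need at least degree + 1 points")
  if (anyDuplicated(lambda_nm)) stop("lambda values must be distinct")
  L <- outer(lambda_nm, degree:0, `^`)
  if (qr(L)$rank < degree + 1)
    stop("rank-deficient design: normal equations are singular")
  scl <- sqrt(colSums(L^2))
  Ls <- sweep(L, 2, scl, `/`)
  a <- solve(crossprod(Ls), crossprod(Ls, mu)) / scl
  fitted <- drop(L %*% a)
  ss_res <- sum((mu - fitted)^2)
  ss_tot <- sum((mu - mean(mu))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(coefficients = drop(a), r_squared = r2, degree = degree,
                 range = range(lambda_nm)),
            class = "poly_fit")
}

#' @export
predict.poly_fit <- function(object, newdata, ...) {
  .polyval(object$coefficients, newdata)
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("polynomial fit, degree %d (R^2 = %.6g)\n", x$degree,
              x$r_squared))
  cat("coefficients (highest degree first):\n")
  print(x$coefficients)
  invisible(x)
}

#' Isosbestic wavelengths of the bundled hemoglobin tables
#'
#' Wavelengths at which the bundled oxy- and deoxyhemoglobin extinction
#' curves cross (equal absorption regardless of oxygen saturation), located
#' by sign changes of their difference with linear refinement.
#'
#' @param band wavelength interval to search, nm.
#' @return numeric vector of crossing wavelengths, nm.
#' @export
isosbestic_points <- function(band = c(450, 620)) {
  oxy <- chromophore_table("HbO2")
  deo <- chromophore_table("Hb")
  wl <- oxy$wavelength_nm
  keep <- wl >= band[1] & wl <= band[2]
  wl <- wl[keep]
  d <- oxy$value[keep] - deo$value[keep]
  idx <- which(d[-1] * d[-length(d)] < 0)
  vapply(idx, function(i) {
    wl[i] + (wl[i + 1] - wl[i]) * abs(d[i]) / (abs(d[i]) + abs(d[i + 1]))
  }, numeric(1))
}
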