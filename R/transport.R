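# R surface over the compiled photon-transport kernel, plus the sampling
# primitives the kernel is built from.

#' Monte Carlo run configuration
#'
#' @param n_photons photon packets per wavelength (`>= 1`).
#' @param w_th termination weight threshold, `0 < w_th < 1`.
#' @param roulette_m Russian-roulette survival factor (`>= 2`): a packet
#'   falling below `w_th` survives with probability `1/m` at weight `m w`.
#' @param seed integer root seed; all randomness derives from it.
#' @param termination `"roulette"` (unbiased, default) or `"hard"`
#'   (literal threshold termination; the discarded weight is booked in the
#'   ledger's `leak` bin).
#' @param max_events per-photon event cap guarding against runaway packets.
#' @return object of class `run_config`.
#' @export
run_config <- function(n_photons = 20000, w_th = 1e-4, roulette_m = 10,
                       seed = 1, termination = c("roulette", "hard"),
                       max_events = 1e6) {
  termination <- match.arg(termination)
  stopifnot(n_photons >= 1, w_th > 0, w_th < 1, roulette_m >= 2)
  structure(list(n_photons = as.integer(n_photons), w_th = w_th,
                 roulette_m = as.integer(roulette_m),
                 seed = as.integer(seed), termination = termination,
                 max_events = max_events),
            class = "run_config")
}

# ---- sampling primitives (same code path as the kernel) -------------------

#' Sample a free-flight step length
#'
#' `s = -ln(xi1) / mu_t` with `xi1` uniform on `(0, 1]`; `mu_t = 0`
#' returns `Inf`, signalling ballistic traversal to the caller.
#'
#' @param xi1 uniform random number(s) on `(0, 1]`.
#' @param mu_t total attenuation coefficient, 1/mm.
#' @return step length(s), mm.
#' @export
sample_step <- function(xi1, mu_t) {
  if (any(xi1 <= 0 | xi1 > 1)) stop("xi1 must lie in (0, 1]")
  if (mu_t < 0) stop("mu_t must be >= 0")
  if (mu_t == 0) return(rep(Inf, length(xi1)))
  -log(xi1) / mu_t
}

#' Attenuate a photon packet's weight
#'
#' Survival share `w mu_s / mu_t` stays with the packet; the absorbed share
#' is the exact complement, credited to the current layer's absorption bin
#' (so deposited + retained equals the incoming weight to the last bit).
#'
#' @param w incoming weight(s).
#' @param mu_s,mu_a scattering/absorption coefficients, 1/mm.
#' @return list with `weight` (retained) and `absorbed`.
#' @export
attenuate <- function(w, mu_s, mu_a) {
  if (any(w < 0) || mu_s < 0 || mu_a < 0) stop("negative input")
  mu_t <- mu_s + mu_a
  if (mu_t <= 0) stop("mu_s + mu_a must be positive")
  w_new <- w * (mu_s / mu_t)
  list(weight = w_new, absorbed = w - w_new)
}

#' Sample a scattering deflection
#'
#' Henyey-Greenstein polar angle via the inverse CDF (isotropic
#' `cos theta = 2 xi3 - 1` at `g = 0`) and uniform azimuth
#' `phi = 2 pi xi2`.
#'
#' @param g anisotropy factor, `|g| < 1`.
#' @param xi2,xi3 uniform random numbers on `[0, 1)`.
#' @return list with `cos_theta` and `phi`.
#' @export
sample_scatter <- function(g, xi2, xi3) {
  if (abs(g) >= 1) stop("|g| must be < 1")
  stopifnot(length(xi2) == length(xi3))
  ct <- vapply(xi3, function(x) .cpp_hg_cos(g, x), numeric(1))
  list(cos_theta = ct, phi = 2 * pi * xi2)
}

#' Rotate a direction vector by a scattering deflection
#'
#' Standard local-frame rotation: the new unit vector makes an angle with
#' cosine `cos_theta` against the old one, at azimuth `phi`; a dedicated
#' formula is used when the direction is near the z axis.
#'
#' @param direction unit 3-vector.
#' @param cos_theta deflection cosine, `[-1, 1]`.
#' @param phi azimuth, radians.
#' @return new unit 3-vector.
#' @export
update_direction <- function(direction, cos_theta, phi) {
  stopifnot(length(direction) == 3, abs(cos_theta) <= 1)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6)
    stop("direction must be a unit vector")
  .cpp_spin(direction, cos_theta, phi)
}

#' Unpolarized Fresnel reflection at a planar interface
#'
#' Average of the s- and p-polarized Fresnel reflectances; incidence beyond
#' the critical angle returns probability 1 (total internal reflection).
#' Also returns the transmitted direction cosine from Snell's law.
#'
#' @param n1,n2 refractive indices on the incident/transmitted side.
#' @param cos_incident cosine of the incidence angle, `[0, 1]`.
#' @return list with `reflectance` and `cos_transmitted`.
#' @export
fresnel <- function(n1, n2, cos_incident) {
  stopifnot(n1 >= 1, n2 >= 1, cos_incident >= 0, cos_incident <= 1)
  v <- .cpp_fresnel(n1, n2, cos_incident)
  list(reflectance = v[1], cos_transmitted = v[2])
}

# ---- engine ---------------------------------------------------------------

.stack_optics <- function(stack, lambda_nm, blood,
                          baseline_mode = "residual") {
  lays <- stack$layers
  list(mua = vapply(lays, function(l)
         layer_mu_a(l, lambda_nm, blood, baseline_mode), numeric(1)),
       mus = vapply(lays, function(l) layer_mu_s(l, lambda_nm), numeric(1)),
       g = vapply(lays, `[[`, numeric(1), "g"),
       n = vapply(lays, `[[`, numeric(1), "n"),
       thickness = vapply(lays, `[[`, numeric(1), "thickness_mm"))
}

#' Simulate diffuse reflectance at one wavelength
#'
#' Traces `n_photons` packets through the stack at the given wavelength and
#' blood state and returns the diffuse reflectance (total reflected weight
#' over total incident weight) with the full transport ledger: specular and
#' diffuse reflectance, transmittance, per-layer absorption, and the
#' roulette/leak bookkeeping bin that closes the per-photon energy
#' identity exactly.
#'
#' @param stack a `tissue_stack`.
#' @param lambda_nm wavelength, nm.
#' @param blood a [blood_state()].
#' @param config a [run_config()].
#' @param stream integer substream id (used to derive independent
#'   per-wavelength streams from one root seed).
#' @return object of class `transport_ledger`; element `R_diffuse` is the
#'   scored reflectance.
#' @export
simulate_reflectance <- function(stack, lambda_nm, blood,
                                 config = run_config(), stream = 0L) {
  stopifnot(inherits(stack, "tissue_stack"), inherits(config, "run_config"))
  op <- .stack_optics(stack, lambda_nm, blood)
  res <- .mc_run(op$mua, op$mus, op$g, op$n, op$thickness,
                 stack$n_above, stack$n_below,
                 config$n_photons, config$seed, stream,
                 config$w_th, config$roulette_m,
                 as.integer(config$termination == "hard"),
                 config$max_events, FALSE)
  res$wavelength_nm <- lambda_nm
  class(res) <- "transport_ledger"
  res
}

#' @export
print.transport_ledger <- function(x, ...) {
  cat(sprintf("transport ledger (%d photons%s)\n", x$n_photons,
              if (!is.null(x$wavelength_nm))
                sprintf(", %g nm", x$wavelength_nm) else ""))
  cat(sprintf("  R_specular = %.5f  R_diffuse = %.5f  T = %.5f\n",
              x$R_specular, x$R_diffuse, x$T))
  cat(sprintf("  absorption by layer: %s\n",
              paste(sprintf("%.4f", x$A_per_layer), collapse = " ")))
  cat(sprintf("  roulette net = %.3e  leak = %.3e  max photon residual = %.2e\n",
              x$roulette_net, x$leak, x$max_photon_residual))
  invisible(x)
}

#' Trace photons and return per-photon ledgers
#'
#' Same walk as [simulate_reflectance()] but returns the per-photon ledger
#' matrix (specular, diffuse, transmitted, roulette/leak, per-layer
#' absorbed weight) for energy-conservation auditing.
#'
#' @inheritParams simulate_reflectance
#' @return list: summary ledger fields plus `per_photon` matrix with one
#'   row per packet.
#' @export
trace_photons <- function(stack, lambda_nm, blood, config = run_config(),
                          stream = 0L) {
  stopifnot(inherits(stack, "tissue_stack"), inherits(config, "run_config"))
  op <- .stack_optics(stack, lambda_nm, blood)
  res <- .mc_run(op$mua, op$mus, op$g, op$n, op$thickness,
                 stack$n_above, stack$n_below,
                 config$n_photons, config$seed, stream,
                 config$w_th, config$roulette_m,
                 as.integer(config$termination == "hard"),
                 config$max_events, TRUE)
  colnames(res$per_photon) <- c("R_specular", "R_diffuse", "T",
                                "roulette_or_leak",
                                paste0("A_", names(stack$layers)),
                                "exit_phi")
  res
}

# low-level entry for arbitrary layer optics (used by tests and oracles)
.mc_run_raw <- function(mua, mus, g, n, thickness, n_above = 1, n_below = 1,
                        n_photons = 1e4, seed = 1, stream = 0,
                        w_th = 1e-4, roulette_m = 10, hard = FALSE,
                        max_events = 1e6, per_photon = FALSE) {
  .mc_run(mua, mus, g, n, thickness, n_above, n_below,
          as.integer(n_photons), seed, stream, w_th,
          as.integer(roulette_m), as.integer(hard), max_events, per_photon)
}
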