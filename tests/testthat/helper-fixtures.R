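# Shared fixtures: small stacks, fast run configs, and the independent
# plain-R single-slab Monte Carlo oracle used to cross-check the engine.

fast_config <- function(n_photons = 2000, seed = 7, ...) {
  run_config(n_photons = n_photons, seed = seed, ...)
}

coarse_grid <- function() seq(420, 620, by = 40)

default_blood <- function(hgb = 15.4, s = 0.9) blood_state(hgb, s)

# single uniform slab expressed as a one-layer "stack" for the raw engine
slab_run <- function(mu_a, mu_s, g, thickness_mm, n = 1, n_photons = 1e4,
                     seed = 1, ...) {
  conjspec:::.mc_run_raw(mua = mu_a, mus = mu_s, g = g, n = n,
                         thickness = thickness_mm, n_above = 1, n_below = 1,
                         n_photons = n_photons, seed = seed, ...)
}

# Independent brute-force Monte Carlo for a single slab with matched
# refractive indices: written in plain R against base R's RNG, sharing no
# code with the compiled engine. Returns diffuse reflectance and
# transmittance with their per-photon standard errors.
oracle_slab_mc <- function(mu_a, mu_s, g, thickness_mm, n_photons, seed,
                           w_th = 1e-4, m = 10) {
  set.seed(seed)
  mu_t <- mu_a + mu_s
  albedo <- mu_s / mu_t
  r_contrib <- numeric(n_photons)
  t_contrib <- numeric(n_photons)
  for (ph in seq_len(n_photons)) {
    z <- 0; uz <- 1; ux <- 0; uy <- 0; w <- 1
    repeat {
      s <- -log(runif(1)) / mu_t
      z_new <- z + uz * s
      if (z_new < 0) { r_contrib[ph] <- w; break }
      if (z_new > thickness_mm) { t_contrib[ph] <- w; break }
      z <- z_new
      w <- w * albedo
      # Henyey-Greenstein deflection
      xi <- runif(1)
      ct <- if (abs(g) < 1e-12) 2 * xi - 1 else {
        f <- (1 - g^2) / (1 - g + 2 * g * xi)
        (1 + g^2 - f^2) / (2 * g)
      }
      st <- sqrt(max(0, 1 - ct^2))
      phi <- 2 * pi * runif(1)
      if (abs(uz) > 0.99999) {
        ux <- st * cos(phi); uy <- st * sin(phi); uz <- sign(uz) * ct
      } else {
        den <- sqrt(1 - uz^2)
        ux_n <- st * (ux * uz * cos(phi) - uy * sin(phi)) / den + ux * ct
        uy_n <- st * (uy * uz * cos(phi) + ux * sin(phi)) / den + uy * ct
        uz_n <- -den * st * cos(phi) + uz * ct
        nrm <- sqrt(ux_n^2 + uy_n^2 + uz_n^2)
        ux <- ux_n / nrm; uy <- uy_n / nrm; uz <- uz_n / nrm
      }
      if (w < w_th) {
        if (runif(1) < 1 / m) w <- w * m else break
      }
    }
  }
  list(R = mean(r_contrib), T = mean(t_contrib),
       se_R = sd(r_contrib) / sqrt(n_photons),
       se_T = sd(t_contrib) / sqrt(n_photons))
}

# analytic Henyey-Greenstein CDF of cos(theta)
hg_cdf <- function(ct, g) {
  if (abs(g) < 1e-12) return((ct + 1) / 2)
  (1 - g^2) / (2 * g) * (1 / sqrt(1 + g^2 - 2 * g * ct) - 1 / (1 + g))
}
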