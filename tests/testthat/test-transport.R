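# Monte Carlo transport: sampling primitives, boundary physics, ledger
# accounting and agreement with the independent single-slab oracle.

test_that("free-flight step sampling inverts the exponential law", {
  expect_equal(sample_step(exp(-1), 10), 0.1)
  expect_equal(sample_step(1, 3), 0)
  expect_identical(sample_step(0.5, 0), Inf)
  expect_error(sample_step(0, 1), "\\(0, 1\\]")

  set.seed(11)
  s <- sample_step(runif(1e5, .Machine$double.eps, 1), 4)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 1 / 4), 3 * se)
})

test_that("weight attenuation conserves weight exactly", {
  a <- attenuate(1, 9, 1)
  expect_equal(a$weight, 0.9)
  expect_equal(a$absorbed, 0.1)
  expect_equal(attenuate(0.42, 5, 0)$weight, 0.42)
  w <- runif(50)
  out <- attenuate(w, 3.7, 1.3)
  expect_identical(out$weight + out$absorbed, w)
})

test_that("Henyey-Greenstein sampling reproduces the phase function", {
  set.seed(21)
  # isotropic limit
  iso <- sample_scatter(0, runif(1e5), runif(1e5))
  expect_lt(abs(mean(iso$cos_theta)),
            3 * sd(iso$cos_theta) / sqrt(1e5))
  expect_true(all(iso$phi >= 0 & iso$phi < 2 * pi))

  # mean cosine equals g
  hg <- sample_scatter(0.9, runif(1e5), runif(1e5))
  expect_lt(abs(mean(hg$cos_theta) - 0.9),
            3 * sd(hg$cos_theta) / sqrt(1e5))

  # empirical CDF against the analytic HG CDF at g = 0.75
  ct <- sample_scatter(0.75, runif(2e4), runif(2e4))$cos_theta
  grid <- seq(-0.95, 0.95, by = 0.05)
  emp <- ecdf(ct)(grid)
  expect_lt(max(abs(emp - hg_cdf(grid, 0.75))), 0.015)
})

test_that("direction update preserves unit norm and the deflection angle", {
  u <- c(0, 0, 1)
  expect_equal(update_direction(u, 1, 1.3), u, tolerance = 1e-12)
  expect_equal(update_direction(u, -1, 0.4), -u, tolerance = 1e-9)

  set.seed(31)
  for (i in 1:200) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    ct <- runif(1, -1, 1); phi <- runif(1, 0, 2 * pi)
    w <- update_direction(v, ct, phi)
    expect_equal(sum(w^2), 1, tolerance = 1e-9)
    expect_equal(sum(v * w), ct, tolerance = 1e-9)
  }
})

test_that("Fresnel boundaries follow the unpolarized average and Snell", {
  expect_equal(fresnel(1.4, 1.4, 0.3)$reflectance, 0)
  expect_equal(fresnel(1, 1.5, 1)$reflectance, 0.04)
  # beyond the critical angle: total internal reflection
  expect_equal(fresnel(1.5, 1.0, cos(80 * pi / 180))$reflectance, 1)
  # Snell at 45 degrees into glass
  out <- fresnel(1, 1.5, cos(pi / 4))
  expect_equal(out$cos_transmitted,
               sqrt(1 - (sin(pi / 4) / 1.5)^2), tolerance = 1e-12)
})

test_that("the ledger identity closes exactly and runs are deterministic", {
  st <- default_eyelid_stack()
  bl <- default_blood()
  tr <- trace_photons(st, 560, bl, fast_config(5000))
  pp <- tr$per_photon
  sums <- rowSums(pp[, setdiff(colnames(pp), "exit_phi")])
  expect_lt(max(abs(sums - 1)), 1e-12)

  # hard mode closes through the leak bin
  trh <- trace_photons(st, 560, bl, fast_config(3000, termination = "hard"))
  expect_lt(trh$max_photon_residual, 1e-12)
  expect_gt(trh$leak, 0)

  # bit-identical reruns with one seed; different seeds differ
  r1 <- simulate_reflectance(st, 560, bl, fast_config(4000, seed = 5))
  r2 <- simulate_reflectance(st, 560, bl, fast_config(4000, seed = 5))
  r3 <- simulate_reflectance(st, 560, bl, fast_config(4000, seed = 6))
  expect_identical(r1$R_diffuse, r2$R_diffuse)
  expect_false(identical(r1$R_diffuse, r3$R_diffuse))
})

test_that("degenerate slabs behave physically", {
  # absorbing-only semi-infinite slab, matched indices: nothing returns
  res <- slab_run(mu_a = 1, mu_s = 0, g = 0, thickness_mm = 1e6,
                  n_photons = 2000)
  expect_equal(res$R_diffuse, 0)
  expect_equal(res$T, 0)
  # opaque deep floor kills transmission
  res2 <- conjspec:::.mc_run_raw(mua = c(0.01, 1e5), mus = c(1, 1),
                                 g = c(0.5, 0.5), n = c(1.4, 1.4),
                                 thickness = c(1, 5), n_photons = 2000)
  expect_equal(res2$T, 0)
  # non-absorbing index-matched scattering slab: all weight exits, and a
  # deep slab returns nearly everything upward
  res3 <- slab_run(mu_a = 0, mu_s = 10, g = 0, thickness_mm = 20,
                   n_photons = 2000)
  expect_equal(res3$R_diffuse + res3$T, 1, tolerance = 1e-12)
  expect_gt(res3$R_diffuse, 0.95)
})

test_that("reflectance error shrinks as one over root photon count", {
  ns <- c(100, 1000, 10000)
  sds <- vapply(ns, function(n) {
    r <- vapply(1:24, function(k)
      slab_run(0.1, 0.9, 0.75, 2, n_photons = n, seed = 1000 + k)$R_diffuse,
      numeric(1))
    sd(r)
  }, numeric(1))
  slope <- coef(lm(log(sds) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.15)
})

test_that("adding absorption never increases diffuse reflectance (CRN)", {
  r <- vapply(c(0.05, 0.2, 0.8, 2), function(mua)
    slab_run(mua, 5, 0.8, 3, n_photons = 5000, seed = 99)$R_diffuse,
    numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("exit azimuths are uniform for isotropic scattering", {
  st <- default_eyelid_stack()
  tr <- trace_photons(st, 640, default_blood(), fast_config(20000, seed = 3))
  phi <- tr$per_photon[, "exit_phi"]
  phi <- phi[is.finite(phi)]
  expect_gt(length(phi), 500)
  bins <- cut(phi, breaks = seq(-pi, pi, length.out = 9))
  p <- chisq.test(table(bins))$p.value
  expect_gt(p, 0.001)
})

test_that("the engine matches the independent single-slab oracle", {
  mu_a <- 0.1; mu_s <- 0.9; g <- 0.75; d <- 2
  eng <- conjspec:::.mc_run_raw(mua = mu_a, mus = mu_s, g = g, n = 1,
                                thickness = d, n_photons = 1e4, seed = 12,
                                per_photon = TRUE)
  pp <- eng$per_photon
  se_R <- sd(pp[, 2]) / sqrt(nrow(pp))
  se_T <- sd(pp[, 3]) / sqrt(nrow(pp))
  orc <- oracle_slab_mc(mu_a, mu_s, g, d, n_photons = 1e4, seed = 12)
  expect_lt(abs(eng$R_diffuse - orc$R), 3 * sqrt(se_R^2 + orc$se_R^2))
  expect_lt(abs(eng$T - orc$T), 3 * sqrt(se_T^2 + orc$se_T^2))
})
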