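---
title: "Methods: Monte Carlo reflectance modeling of the palpebral conjunctiva"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo reflectance modeling of the palpebral conjunctiva}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Anemia screening requires a hemoglobin (Hgb) measurement, normally obtained
invasively from a complete blood count. The palpebral (tarsal) conjunctiva —
the vascular mucosa lining the inner eyelid — is an attractive optical
window: its epithelium is thin, transparent, and melanin-free, so its
visible reflectance spectrum carries a strong, pigmentation-independent
hemoglobin signature. `conjspec` implements the combined forward/inverse
approach to exploiting that window: a seven-layer Monte Carlo (MC) model of
light transport in eyelid tissue simulates conjunctival reflectance spectra,
and an iterative sum-of-squared-residuals (SSR) search inverts measured
spectra for hemoglobin concentration and blood oxygenation.

# The tissue model

The lower eyelid is modeled as seven homogeneous plane-parallel strata,
listed from the illuminated (conjunctival) side: conjunctival epithelium
(CE), tarsal plate (TP), orbicularis oculi (OO), subcutaneous tissue (ST),
dermis (D), living epidermis (LE) and stratum corneum (SC), with air on
both sides. Each layer carries a thickness $h$, scattering coefficient
$\mu_s$ (mm$^{-1}$), anisotropy $g$, refractive index $n$, and chromophore
volume fractions (melanin, water, blood). Layer absorption is assembled as

$$
\mu_a(\lambda) \;=\; \gamma\, C_{blood}\!\left[S\,\mu_a^{HbO_2}(\lambda)
 + (1-S)\,\mu_a^{Hb}(\lambda)\right]
 + C_{mel}\,\mu_a^{mel}(\lambda) + C_{H_2O}\,\mu_a^{H_2O}(\lambda)
 + w_0\,\mu_a^{base}(\lambda),
$$

where $S$ is the oxygen saturation parameter, $\gamma = \varphi_{Hb}\,Ht$
is the hemoglobin volume fraction of whole blood ($\varphi_{Hb} = 0.4$ the
hemoglobin volume fraction of an erythrocyte, $Ht$ the hematocrit), and
$w_0$ weights the hemoglobin- and water-free baseline. Hemoglobin
absorption follows the extinction-table convention
$\mu_a = \ln(10)\, e(\lambda)\, x / M_{Hgb}$ with $M_{Hgb} = 64500$ g/mol
and $x$ the hemoglobin mass concentration where the light meets hemoglobin
— inside the erythrocyte — taken as
$x = \varphi_{Hb}\,\rho_{Hgb} = 0.4 \times 850 = 340$ g/L, the standard
intracellular (mean corpuscular) hemoglobin concentration. The patient's
systemic hemoglobin level enters only through the hematocrit, via the
affine cohort relation $Ht = 0.40/13.9 \times \mathrm{Hgb}$ (fractional
hematocrit per g/dL, through the origin; refittable from any CBC panel
with `polyfit_normal_equations()` at degree 1). This deliberately avoids
counting hemoglobin twice through both $x$ and $\gamma$; the alternative
reading, in which $x$ also tracks the patient level, would make the blood
term quadratic in Hgb and is not used.

Design choices in this assembly that were genuinely open:

* **Baseline weighting.** The published form of the mixing rule does not
  state how the chromophore-free baseline is weighted. The default weights
  it by the residual volume $w_0 = \max(0, 1 - \sum_i C_i)$, the
  convention of layered-skin models, preventing double-counting of
  occupied volume; a pure-additive mode ($w_0 = 1$) is available via
  `baseline_mode = "additive"`.
* **Melanin and baseline power laws.** The melanosome and baseline
  absorption formulas are adopted from the standard skin-optics
  literature: $\mu_a^{mel} = 6.6\times10^{10}\,\lambda^{-3.33}$ and
  $\mu_a^{base} = 7.84\times10^{7}\,\lambda^{-3.255}$ (mm$^{-1}$,
  $\lambda$ in nm); prefactor and exponent are arguments.
* **Chromophore sums above unity.** Some published sweep ranges push one
  fraction beyond the volume left by the others (dermal blood 0.45 against
  water 0.6; tarsal blood up to 0.9 against water 0.3). Layer construction
  rejects such sums by default; sweep and search paths explicitly allow
  them, with the baseline weight clamped at zero.
* **Units.** All optical coefficients are mm$^{-1}$ internally. The bare
  scattering values of the tissue table (5, 35, 45, 100) are read as
  mm$^{-1}$; conversions happen only at the chromophore-database boundary.

The conjunctival epithelium is special-cased: its absorption and
scattering are measured-fit polynomials (quartic and quintic in
$\lambda$, valid 400--700 nm) evaluated with the published coefficients
(`ce_mu_a()`, `ce_mu_s()`); outside the validity window they diverge and
raise an error unless explicitly overridden.

Default thicknesses are the calibrated headline set (20, 100, 2000, 1000,
300, 200, 7 µm). Two of these (dermis 300 µm, living epidermis 200 µm)
sit far outside the histology-derived ranges of the published parameter
table (30--40 µm and 10--20 µm); the calibrated values are used as
defaults and the histology ranges are retained as soft validation bounds
that warn — not fail — on user overrides. Blood volume fractions default
to the parameter table's mid-range (TP and OO 0.45, ST 0.06, D 0.30);
melanin to 0.055.

The bundled oxy-/deoxyhemoglobin extinction and water absorption tables
are **synthetic tabulations**: smooth curves constructed to reproduce the
canonical spectral anatomy of the standard literature compilations (Soret
bands near 414/430 nm at $\sim 5\times10^5$ L cm$^{-1}$ mol$^{-1}$, the
oxyhemoglobin Q-band doublet at ~541/577 nm against the single deoxy band
at ~555 nm, isosbestic crossings near 500/545/570/585 nm, weak red-region
absorption with deoxy above oxy beyond 600 nm). They are not
transcriptions of any published dataset — the originals are not
redistributable here — and files carry `_synthetic` in their names. Every
table-derived expectation in the test suite is defined against the
bundled tables themselves, so the package is self-consistent; absolute
agreement with any particular published compilation is explicitly out of
scope, and users can drop in replacement tables via
`chromophore_table(path = ...)`.

# The transport engine

Photon packets are traced through the stack MCML-style (compiled C++
kernel): launch at normal incidence with a one-time specular deduction;
hop with exponential free paths against $\mu_t = \mu_a + \mu_s$; at layer
boundaries, take the partial step to the interface, decide reflection
versus refraction with the unpolarized Fresnel average and Snell's law
(total internal reflection handled exactly), and rescale the unused
optical path by the $\mu_t$ ratio across the interface; drop weight with
the absorbed share credited to the current layer's bin as the *exact*
floating-point complement of the surviving weight; spin by a
Henyey–Greenstein deflection (inverse-CDF sampling; isotropic limit
$\cos\theta = 2\xi - 1$ at $g = 0$) and uniform azimuth. Diffuse
reflectance is the total weight escaping the conjunctival surface over
the total launched weight.

Numerical and accounting choices:

* **Termination.** Literal hard termination at a weight threshold
  discards energy, which would poison conservation checks. The default is
  Russian roulette ($w_{th} = 10^{-4}$, survival factor $m = 10$):
  unbiased in expectation. Because a single roulette decision creates or
  destroys weight, the ledger carries an explicit `roulette_net` bin
  (killed weight minus survivor boosts) so the per-photon identity
  $R_{spec} + R_{diff} + T + \sum_l A_l + \text{roulette}_{net} = 1$
  closes to better than $10^{-12}$ for every packet; the bin's
  expectation is zero. Hard mode is available (`termination = "hard"`)
  and closes the identity through a `leak` bin instead. The threshold and
  survival factor are this package's documented defaults, not transcribed
  values.
* **RNG.** One root seed; each (wavelength, photon) pair gets its own
  xoshiro256++ stream seeded through splitmix64, so results are
  bit-reproducible and independent of execution order, and sweeps that
  share a seed share photon streams (common random numbers, CRN).
* **Geometry.** $z$ increases downward from the conjunctival surface;
  layers are half-open intervals; lateral extent is unbounded; photons
  crossing the stratum corneum are scored as transmittance. The scored
  quantity is total diffuse reflectance — reflected weight over launched
  weight, an aperture-free definition; no detector cone is applied by
  default.
* **Degenerate inputs.** $\mu_t = 0$ signals ballistic traversal;
  grazing incidence reflects; a configurable per-photon event cap
  (default $10^6$) turns runaway packets into errors rather than hangs.

# Forward spectra and sensitivity

`simulate_spectrum()` sweeps the engine over a wavelength grid (default
400--700 nm at 2 nm; sensitivity and inversion work uses 400--660 nm at
20 nm — the standard fitting band at desk-scale resolution).
`sensitivity_scan()` simulates one curve per parameter value under CRN
and summarizes with `relative_variation()`: per wavelength,
$100\,(\max_p R - \min_p R)/R_{baseline}$, maximized over the band.
"Relative variation" has no single standard definition; the default
baseline is the sweep's midpoint curve, with a per-wavelength mean
alternative (`summary_mode = "vs_mean"`).

A consequence of the parameter set above that users should understand:
with $\mu_s' = \mu_s(1-g) = 0.25$--$0.5$ mm$^{-1}$ and blood-band
absorption of several mm$^{-1}$ in the tarsal plate and orbicularis, the
model's baseline reflectance over 400--600 nm is of order $10^{-2}$ or
below, while red light penetrates millimetres. Relative variations
against that near-zero green baseline are therefore large for any
superficial-layer change, and deep layers (and epidermal melanin) are
reachable at red wavelengths. The *ordering* of sensitivities under the
shipped defaults — tarsal/orbicularis blood and upper-layer thicknesses
dominant; deep-layer blood, deep thicknesses and melanin minor, with
melanin inert below 580 nm — is verified by the test suite; the absolute
percentages depend on the assumed baseline blood fractions (see Known
limitations) and are reported by `scripts/acceptance.R` exactly as
computed.

# Inverse method

`conj_calibrate()` is the fitting function: with the subject's hemoglobin
fixed at its known CBC value, it grid-searches tarsal-plate thickness
(default 1--1.5 mm), oxygenation $S$ (0.2--0.9) and tarsal blood fraction
(0.1--0.9), minimizing
$\mathrm{SSR} = \sum_\lambda (R_{sim} - R_{meas})^2$ over 400--660 nm.
All SSR evaluations inside one search reuse common random numbers so the
argmin is well defined at reduced photon counts. The result is a classed
model object with `print`, `coef`, `summary`, `plot`, `simulate`,
`residuals` and `predict` methods.

`predict()` then holds the calibrated tissue parameters fixed and
searches (Hgb, $S$) — defaults 5--20 g/dL by 0.3 and 0.2--0.99 by 0.05,
hematocrit tracking hemoglobin — for the SSR minimum; ties break toward
the lower hemoglobin value (conservative for anemia screening).

`conj_loocv()` runs leave-one-out cross-validation. How the training
spectra should inform the held-out prediction is genuinely open; the
default calibrates each training subject once against its own spectrum
and uses the *median* tissue parameters — deterministic, order-invariant,
and fold-independent (a subject's calibration does not depend on which
subject is held out, so each is computed once). A `"global"` mode reusing
a single calibration is provided for comparison. Aggregates: RMSECV,
Pearson correlation, anemia sensitivity/specificity at the WHO thresholds
(< 13 g/dL men, < 12 g/dL women, strict inequalities), and Bland–Altman
agreement with limits at mean ± 2 SD (a deliberate 2× multiplier rather
than 1.96, sample SD). Clinical-cohort validation requires measured
patient spectra, which are not included; nothing in this package asserts
clinical performance.

# Synthetic cohorts

`generate_cohort()` emulates the study population so the whole pipeline
is testable without patient data: 30 subjects (14 male / 16 female),
hemoglobin $\mathcal{N}(13.9, 2.1^2)$ g/dL truncated to [5, 20], three
replicate spectra each. Observation noise is multiplicative log-normal
with band-structured covariance — one shared factor per band per
replicate, relative SD 0.15 below 580 nm (the reported 10--20% replicate
variation band) and 0.05 above, perfectly correlated within a band and
independent across bands — since only banded magnitudes are reported.
Between-subject anatomy is modeled as ±30% tarsal-plate thickness jitter
(histology suggests 30--70%); within-subject replicate variation
additionally re-jitters the tarsal blood fraction by ±10%, modeling the
small sampling-location shifts to which intrapatient variation is
attributed. What this generator does *not* emulate: instrument stray
light, wavelength miscalibration, spatial heterogeneity within layers,
and real between-subject covariance of optical properties — so passing
end-to-end tests demonstrates internal consistency of the method, not
clinical performance.

# Problem sizes used by the tests

The test and acceptance runs use desk-scale sizes chosen as this
package's own defaults for routine verification: $10^4$ photons per
wavelength and 20 nm grid steps for sensitivity work (production-grade
runs use $10^5$--$10^6$ photons at 2 nm), 1200--4000 photons for
inverse-recovery
tests on 4--6-wavelength grids, $10^5$ photons for conservation and
sampling-law checks, and cohorts of 3--8 subjects for cross-validation
plumbing. Monte Carlo standard error scales as $1/\sqrt{n}$ (verified
over three decades), so production analyses should raise `n_photons`
accordingly; the CLI default is $2\times10^4$ per wavelength.

# Known limitations

* Plane-parallel homogeneous layers; no curved boundaries, vessels, or
  within-layer heterogeneity.
* No polarization, fluorescence, or time-resolved transport; no detector
  aperture by default.
* The bundled chromophore tables are synthetic reconstructions (above);
  swap in measured tables for quantitative spectroscopy.
* Absolute sensitivity percentages depend strongly on the assumed
  baseline blood fractions, which the source does not unambiguously
  specify; treat the shipped defaults as a documented reference
  configuration, not anatomy.
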