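# Synthetic "measured" cohorts with the statistical structure of the
# clinical study, so the full calibration/prediction pipeline can be
# exercised without patient data.

#' Synthetic cohort specification
#'
#' Defaults mirror the study population: 30 subjects (14 male, 16 female),
#' hemoglobin normal with mean 13.9 and SD 2.1 g/dL truncated to
#' `[5, 20]`, three replicate spectra per subject, multiplicative
#' log-normal observation noise with a relative SD of 0.15 below 580 nm
#' (the reported 10--20% replicate band) and 0.05 above, subject-level
#' tissue jitter of +/-30% on the tarsal-plate thickness (histology
#' suggests 30--70% between-subject thickness variation) and +/-10%
#' re-jitter of the tarsal blood fraction per replicate (modeling small
#' shifts in sampling location between takes).
#'
#' @param n_subjects number of subjects.
#' @param hgb_mean,hgb_sd,hgb_range truncated-normal hemoglobin
#'   distribution, g/dL.
#' @param n_male number of male subjects (rest female); default keeps the
#'   study's 14:16 ratio.
#' @param replicates replicate spectra per subject.
#' @param noise_sd_below,noise_sd_above relative observation-noise SD
#'   below/above `noise_split_nm`.
#' @param noise_split_nm band boundary, nm.
#' @param thickness_jitter relative half-width of the subject-level
#'   tarsal-plate thickness jitter.
#' @param replicate_jitter relative half-width of the per-replicate
#'   tarsal blood-fraction jitter.
#' @param s_range subject oxygenation parameter range (uniform draw).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 30, hgb_mean = 13.9, hgb_sd = 2.1,
                        hgb_range = c(5, 20),
                        n_male = round(n_subjects * 14 / 30),
                        replicates = 3,
                        noise_sd_below = 0.15, noise_sd_above = 0.05,
                        noise_split_nm = 580, thickness_jitter = 0.30,
                        replicate_jitter = 0.10, s_range = c(0.8, 0.95),
                        seed = 1) {
  stopifnot(n_subjects >= 1, hgb_sd >= 0, replicates >= 1,
            noise_sd_below >= 0, noise_sd_above >= 0,
            n_male >= 0, n_male <= n_subjects)
  structure(as.list(environment()), class = "cohort_spec")
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Generate a synthetic cohort
#'
#' Per subject: draws hemoglobin from the truncated normal, assigns sex,
#' jitters the tarsal-plate thickness, forward-simulates the clean
#' spectrum, then emits replicates with a per-replicate re-jittered
#' tarsal blood fraction and band-structured multiplicative log-normal
#' noise (one shared log-normal factor per band per replicate: perfectly
#' correlated within a band, independent across bands). When `dir` is
#' given the cohort tree (`metadata.csv`, `truth.csv`,
#' `spectra/<subject>_<rep>.csv`) is written; the cohort is also returned
#' invisibly for in-memory use.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory.
#' @param stack baseline `tissue_stack` shared by the cohort.
#' @param grid wavelength grid, nm.
#' @param config a [run_config()] (its seed is taken from `spec$seed`).
#' @return list with `metadata` (data.frame: `subject_id`, `sex`,
#'   `hgb_g_dl`, `hematocrit_pct`, `spo2_pct`), `spectra` (per subject, a
#'   list of replicate [conj_spectrum()]s), and `truth` (generating
#'   parameters per subject).
#' @export
generate_cohort <- function(spec = cohort_spec(), dir = NULL,
                            stack = default_eyelid_stack(),
                            grid = default_grid(400, 660, 20),
                            config = run_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  config$seed <- as.integer(spec$seed)
  set.seed(spec$seed)
  n <- spec$n_subjects
  ids <- sprintf("S%02d", seq_len(n))
  sex <- sample(c(rep("male", spec$n_male),
                  rep("female", n - spec$n_male)))
  hgb <- .rtruncnorm(n, spec$hgb_mean, spec$hgb_sd,
                     spec$hgb_range[1], spec$hgb_range[2])
  s_subj <- runif(n, spec$s_range[1], spec$s_range[2])
  h_tp0 <- stack$layers$TP$thickness_mm
  cb0 <- stack$layers$TP$c_blood
  h_tp <- h_tp0 * runif(n, 1 - spec$thickness_jitter,
                        1 + spec$thickness_jitter)

  below <- grid < spec$noise_split_nm
  spectra <- vector("list", n)
  names(spectra) <- ids
  for (i in seq_len(n)) {
    reps <- vector("list", spec$replicates)
    for (r in seq_len(spec$replicates)) {
      cb <- cb0 * runif(1, 1 - spec$replicate_jitter,
                        1 + spec$replicate_jitter)
      st <- .stack_with(stack, h_tp = h_tp[i], c_blood_tp = cb)
      bl <- blood_state(hgb[i], s_subj[i])
      cfg <- config
      cfg$seed <- as.integer((spec$seed * 1000L + i * 10L + r) %% .Machine$integer.max)
      clean <- simulate_spectrum(st, bl, grid, cfg)
      fac <- rep(NA_real_, length(grid))
      fac[below] <- exp(rnorm(1, 0, 1) * sqrt(log(1 + spec$noise_sd_below^2))
                        - log(1 + spec$noise_sd_below^2) / 2)
      fac[!below] <- exp(rnorm(1, 0, 1) * sqrt(log(1 + spec$noise_sd_above^2))
                         - log(1 + spec$noise_sd_above^2) / 2)
      refl <- pmin(1.05, clean$reflectance * fac)
      reps[[r]] <- conj_spectrum(grid, refl,
                                 metadata = list(subject = ids[i],
                                                 replicate = r,
                                                 hgb = hgb[i],
                                                 s = s_subj[i]))
    }
    spectra[[i]] <- reps
  }

  metadata <- data.frame(
    subject_id = ids, sex = sex, hgb_g_dl = round(hgb, 2),
    hematocrit_pct = round(100 * ht_from_hgb(hgb), 1),
    spo2_pct = round(runif(n, 94, 100), 1))
  truth <- data.frame(subject_id = ids, hgb_g_dl = hgb, s = s_subj,
                      h_tp_mm = h_tp, c_blood_tp = cb0)

  cohort <- list(metadata = metadata, spectra = spectra, truth = truth,
                 spec = spec)
  if (!is.null(dir)) write_cohort(cohort, dir)
  invisible(cohort)
}

#' Write / read a cohort tree
#'
#' On-disk layout: `metadata.csv` (columns `subject_id`, `sex`,
#' `hgb_g_dl`, `hematocrit_pct`, `spo2_pct`, `spectrum_file`),
#' `truth.csv` (generating parameters) and one spectrum CSV per replicate
#' under `spectra/<subject>_<rep>.csv`.
#'
#' @param cohort a cohort list (see [generate_cohort()]).
#' @param dir directory path.
#' @return `read_cohort` returns a cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "spectra"), recursive = TRUE,
             showWarnings = FALSE)
  md <- cohort$metadata
  first_files <- character(nrow(md))
  for (i in seq_len(nrow(md))) {
    id <- md$subject_id[i]
    reps <- cohort$spectra[[id]]
    for (r in seq_along(reps)) {
      f <- file.path("spectra", sprintf("%s_%d.csv", id, r))
      write_spectrum(reps[[r]], file.path(dir, f))
      if (r == 1L) first_files[i] <- f
    }
  }
  md$spectrum_file <- first_files
  write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE,
            quote = FALSE)
  if (!is.null(cohort$truth))
    write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE,
              quote = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  md <- read.csv(file.path(dir, "metadata.csv"))
  spectra <- vector("list", nrow(md))
  names(spectra) <- md$subject_id
  for (id in md$subject_id) {
    files <- sort(list.files(file.path(dir, "spectra"),
                             pattern = paste0("^", id, "_[0-9]+\\.csv$"),
                             full.names = TRUE))
    spectra[[id]] <- lapply(files, read_spectrum)
  }
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) read.csv(truth_path) else NULL
  list(metadata = md, spectra = spectra, truth = truth)
}
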