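#' Simulation configuration for synthetic serum Raman cohorts
#'
#' Bundles the acquisition-grid and noise parameters used by
#' [simulate_spectrum()] and [simulate_cohort()]. Defaults emulate the
#' reference cohort design: 2330-point spectra on 400--1800 cm^-1
#' (~0.6 cm^-1 resolution) and three classes (breast 160, cervical 150,
#' leukemia 42 spectra from 16/21/7 patients).
#'
#' @param n_points Number of points of the uniform wavenumber grid.
#' @param wn_min,wn_max Grid bounds in cm^-1.
#' @param n_spectra_per_class Named integer vector, spectra per class in
#'   cohort order (breast, cervical, leukemia).
#' @param n_patients_per_class Integer vector, patients per class.
#' @param baseline_degree Degree of the random fluorescence baseline
#'   polynomial.
#' @param baseline_scale Baseline magnitude relative to the tallest Raman
#'   band (the normalized peak scale); the fluorescence background of serum
#'   typically dwarfs the Raman signal.
#' @param noise_sd Standard deviation of additive Gaussian shot-like noise,
#'   relative intensity units.
#' @param spike_rate Expected number of cosmic-ray spikes per spectrum
#'   (Poisson).
#' @param spike_scale Unit amplitude of cosmic-ray spikes (relative
#'   intensity); each spike is 5--10 times this scale, so with the default
#'   (the shot-noise scale) spikes are sharp narrow artifacts that
#'   Savitzky-Golay smoothing suppresses to below the noise floor, matching
#'   serum spectra whose cosmic-ray shot noise is removed by smoothing.
#' @param patient_effect_sd Standard deviation (log scale) of the per
#'   (patient, band) multiplicative amplitude factor; induces within-class
#'   substructure.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_points = 2330L,
                       wn_min = 400, wn_max = 1800,
                       n_spectra_per_class = c(breast = 160L, cervical = 150L, leukemia = 42L),
                       n_patients_per_class = c(breast = 16L, cervical = 21L, leukemia = 7L),
                       baseline_degree = 5L,
                       baseline_scale = 2,
                       noise_sd = 0.04,
                       spike_rate = 0.2,
                       spike_scale = 0.02,
                       patient_effect_sd = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_points = as.integer(n_points), wn_min = wn_min, wn_max = wn_max,
    n_spectra_per_class = as.integer(n_spectra_per_class),
    n_patients_per_class = as.integer(n_patients_per_class),
    baseline_degree = as.integer(baseline_degree),
    baseline_scale = baseline_scale,
    noise_sd = noise_sd, spike_rate = spike_rate, spike_scale = spike_scale,
    patient_effect_sd = patient_effect_sd, seed = as.integer(seed)
  )
  names(cfg$n_spectra_per_class) <- names(cfg$n_patients_per_class) <- c("breast", "cervical", "leukemia")
  if (cfg$n_points < 2L) stop("sim_config: n_points must be >= 2", call. = FALSE)
  if (!(cfg$wn_min < cfg$wn_max)) stop("sim_config: wn_min must be < wn_max", call. = FALSE)
  if (any(cfg$n_spectra_per_class < 1L) || any(cfg$n_patients_per_class < 1L))
    stop("sim_config: all class counts must be >= 1", call. = FALSE)
  if (cfg$noise_sd < 0) stop("sim_config: noise_sd must be >= 0", call. = FALSE)
  if (cfg$spike_rate < 0) stop("sim_config: spike_rate must be >= 0", call. = FALSE)
  if (cfg$baseline_degree < 0L) stop("sim_config: baseline_degree must be >= 0", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Class templates for the three serum cohorts
#'
#' Returns one band template per class (breast, cervical, leukemia). All
#' three share a common catalog of serum Raman bands; class identity is
#' encoded as attenuation of specific bands, mirroring the qualitative
#' differences between the mean spectra of the three cancers:
#' * leukemia lacks the amide I band at 1654 cm^-1 and its neighbors
#'   (1620, 1603, 1556, 1523) as well as the 1447 cm^-1 phospholipid band;
#' * breast and cervical lack the left amide III shoulder (~1230 cm^-1)
#'   and the 938 cm^-1 skeletal region;
#' * cervical additionally lacks the 714 cm^-1 polysaccharide band;
#' * breast flattens the bulged 1040--1100 cm^-1 region.
#'
#' Band intensities are free parameters of the simulator (chosen so the
#' 1002 cm^-1 phenylalanine band is globally maximal, matching the
#' peak-normalization convention); only the presence/absence pattern is
#' class-informative.
#'
#' @return Named list of three `class_template` objects, each with fields
#'   `class_name`, `bands` (data frame: center, width, amplitude,
#'   assignment) and `suppressed` (data frame: lo, hi, factor).
#' @export
default_templates <- function() {
  shared <- data.frame(
    center = c(509, 622, 642, 714, 760, 828, 853, 938, 1002, 1028, 1063,
               1070, 1103, 1160, 1208, 1230, 1282, 1447, 1523, 1556, 1603,
               1620, 1654),
    width = c(8, 8, 8, 8, 8, 8, 8, 8, 8, 8, 8,
              40, 8, 8, 8, 25, 25, 8, 8, 8, 8,
              8, 12),
    amplitude = c(0.20, 0.30, 0.25, 0.35, 0.30, 0.25, 0.30, 0.25, 1.00, 0.35, 0.40,
                  0.50, 0.30, 0.25, 0.30, 0.35, 0.40, 0.45, 0.25, 0.30, 0.35,
                  0.35, 0.55),
    assignment = c("tryptophan", "phenylalanine", "tyrosine", "polysaccharides",
                   "tryptophan", "tyrosine", "tyrosine", "skeletal str alpha",
                   "phenylalanine", "phenylalanine", "phenylalanine/phospholipid",
                   "phenylalanine/phospholipid bulge", "phenylalanine",
                   "beta-carotene", "tryptophan", "amide III (left shoulder)",
                   "amide III (right shoulder)", "phospholipid", "beta-carotene",
                   "tryptophan", "tyrosine", "tryptophan", "amide I"),
    stringsAsFactors = FALSE
  )
  supp <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(lo = m[, 1], hi = m[, 2], factor = m[, 3])
  }
  # breast/cervical both lose the low-wavenumber amide III shoulder and 938
  bc_common <- c(1220, 1245, 0.15,
                 928, 948, 0.15)
  templates <- list(
    breast = class_template("breast", shared,
                            supp(bc_common, 1040, 1100, 0.25)),
    cervical = class_template("cervical", shared,
                              supp(bc_common, 705, 723, 0.05)),
    leukemia = class_template("leukemia", shared,
                              supp(1640, 1670, 0.00,
                                   1612, 1628, 0.05,
                                   1595, 1610, 0.05,
                                   1548, 1564, 0.05,
                                   1515, 1531, 0.05,
                                   1439, 1455, 0.10))
  )
  templates
}

#' Construct a class template
#'
#' @param class_name One of `"breast"`, `"cervical"`, `"leukemia"` (other
#'   labels are allowed for toy data).
#' @param bands Data frame with columns `center`, `width`, `amplitude`,
#'   `assignment` (Lorentzian band parameters; width is FWHM in cm^-1).
#' @param suppressed Data frame with columns `lo`, `hi`, `factor`: bands
#'   whose center falls in `[lo, hi]` have their amplitude multiplied by
#'   `factor` in `[0, 1]`.
#' @return A `class_template` object.
#' @export
class_template <- function(class_name, bands, suppressed = NULL) {
  if (is.null(suppressed))
    suppressed <- data.frame(lo = numeric(0), hi = numeric(0), factor = numeric(0))
  stopifnot(is.data.frame(bands),
            all(c("center", "width", "amplitude") %in% names(bands)))
  if (any(bands$width <= 0)) stop("class_template: band widths must be > 0", call. = FALSE)
  if (any(bands$amplitude < 0)) stop("class_template: amplitudes must be >= 0", call. = FALSE)
  if (any(bands$center < 400 | bands$center > 1800))
    stop("class_template: band centers must lie in [400, 1800] cm^-1", call. = FALSE)
  if (nrow(suppressed) && any(suppressed$factor < 0 | suppressed$factor > 1))
    stop("class_template: suppression factors must lie in [0, 1]", call. = FALSE)
  structure(list(class_name = class_name, bands = bands, suppressed = suppressed),
            class = "class_template")
}

#' Effective band amplitudes of a template after suppression
#'
#' @param template A `class_template`.
#' @return Numeric vector of per-band amplitudes with suppression factors
#'   applied.
#' @export
effective_amplitudes <- function(template) {
  amp <- template$bands$amplitude
  sup <- template$suppressed
  if (nrow(sup)) {
    for (r in seq_len(nrow(sup))) {
      hit <- template$bands$center >= sup$lo[r] & template$bands$center <= sup$hi[r]
      amp[hit] <- amp[hit] * sup$factor[r]
    }
  }
  amp
}

# Lorentzian line with unit peak height; w is FWHM
lorentzian <- function(x, center, w) {
  hw2 <- (w / 2)^2
  hw2 / ((x - center)^2 + hw2)
}

#' Simulate one serum-like Raman spectrum
#'
#' Signal model: sum of Lorentzian bands (template amplitudes times a
#' per-patient multiplicative factor), plus a smooth random polynomial
#' fluorescence baseline, additive Gaussian noise, and Poisson-placed
#' cosmic-ray spikes; intensities are clipped at zero. Randomness is drawn
#' from R's global RNG stream: seed it (or let [simulate_cohort()] do so)
#' for reproducibility.
#'
#' @param template A `class_template`.
#' @param patient_id Identifier stored on the record.
#' @param config A `sim_config`.
#' @param patient_factors Optional numeric vector, one multiplicative
#'   amplitude factor per band of the template (defaults to all 1).
#' @param cohort_index Optional 1-based index stored on the record.
#' @return A `spectrum` object: list with `wavenumber`, `intensity`,
#'   `class_label`, `patient_id`, `cohort_index`.
#' @export
simulate_spectrum <- function(template, patient_id, config = sim_config(),
                              patient_factors = NULL, cohort_index = NA_integer_) {
  if (!inherits(config, "sim_config")) stop("simulate_spectrum: config must be a sim_config", call. = FALSE)
  wn <- seq(config$wn_min, config$wn_max, length.out = config$n_points)
  amp <- effective_amplitudes(template)
  if (is.null(patient_factors)) patient_factors <- rep(1, length(amp))
  stopifnot(length(patient_factors) == length(amp))
  signal <- numeric(config$n_points)
  for (b in seq_along(amp)) {
    a <- amp[b] * patient_factors[b]
    if (a > 0)
      signal <- signal + a * lorentzian(wn, template$bands$center[b], template$bands$width[b])
  }
  # fluorescence baseline: random polynomial of the configured degree,
  # rescaled to [0, baseline_scale] so it is smooth, positive and dominant
  baseline <- numeric(config$n_points)
  if (config$baseline_scale > 0) {
    xs <- seq(-1, 1, length.out = config$n_points)
    co <- stats::runif(config$baseline_degree + 1L, -1, 1)
    raw <- drop(outer(xs, 0:config$baseline_degree, `^`) %*% co)
    rng <- diff(range(raw))
    if (rng < 1e-12) raw[] <- 0 else raw <- (raw - min(raw)) / rng
    baseline <- config$baseline_scale * raw
  }
  y <- signal + baseline
  if (config$noise_sd > 0)
    y <- y + stats::rnorm(config$n_points, 0, config$noise_sd)
  if (config$spike_rate > 0) {
    n_spikes <- stats::rpois(1L, config$spike_rate)
    if (n_spikes > 0) {
      for (k in seq_len(n_spikes)) {
        pos <- sample.int(config$n_points, 1L)
        w <- sample.int(3L, 1L)
        a <- stats::runif(1L, 5, 10) * config$spike_scale
        idx <- pos:min(config$n_points, pos + w - 1L)
        y[idx] <- y[idx] + a
      }
    }
  }
  spectrum(wn, pmax(y, 0), class_label = template$class_name,
           patient_id = patient_id, cohort_index = cohort_index)
}

#' Simulate a labeled cohort of serum-like spectra
#'
#' Spectra are ordered breast, then cervical, then leukemia, with 1-based
#' cohort indices matching that order (indices 1--160 breast, 161--310
#' cervical, 311--352 leukemia under the default design). Each class's
#' spectra are split near-evenly over its patients; each (patient, band)
#' pair receives one log-normal amplitude factor, so all spectra from one
#' patient share a band-intensity fingerprint.
#'
#' @param config A `sim_config`.
#' @param templates List of three `class_template`s, as from
#'   [default_templates()].
#' @return List of `spectrum` objects (class `raman_cohort`).
#' @export
simulate_cohort <- function(config = sim_config(), templates = default_templates()) {
  if (!inherits(config, "sim_config")) stop("simulate_cohort: config must be a sim_config", call. = FALSE)
  stopifnot(length(templates) == 3L)
  set.seed(config$seed)
  out <- vector("list", sum(config$n_spectra_per_class))
  idx <- 0L
  for (ci in 1:3) {
    tpl <- templates[[ci]]
    n_sp <- config$n_spectra_per_class[ci]
    n_pat <- config$n_patients_per_class[ci]
    n_bands <- nrow(tpl$bands)
    pf <- matrix(exp(stats::rnorm(n_pat * n_bands, 0, config$patient_effect_sd)),
                 nrow = n_pat)
    # near-even partition of the class's spectra over its patients
    pat_of <- sort(rep_len(seq_len(n_pat), n_sp))
    for (s in seq_len(n_sp)) {
      idx <- idx + 1L
      p <- pat_of[s]
      out[[idx]] <- simulate_spectrum(
        tpl, patient_id = sprintf("%s_p%02d", tpl$class_name, p),
        config = config, patient_factors = pf[p, ], cohort_index = idx)
    }
  }
  class(out) <- c("raman_cohort", "list")
  out
}

#' Write a cohort as CSV files
#'
#' Writes one two-column CSV (`wavenumber_cm-1`, `intensity`) per spectrum
#' plus a manifest (`index`, `class`, `patient_id`, `filename`), or a single
#' wide-matrix CSV (first column wavenumber, one column per spectrum).
#'
#' @param cohort List of `spectrum` objects.
#' @param dir Output directory (created if needed).
#' @param wide If `TRUE` write `spectra_matrix.csv` instead of per-spectrum
#'   files.
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir, wide = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (wide) {
    m <- sapply(cohort, function(s) s$intensity)
    colnames(m) <- sprintf("spec_%03d", seq_along(cohort))
    df <- data.frame(`wavenumber_cm-1` = cohort[[1]]$wavenumber, m, check.names = FALSE)
    path <- file.path(dir, "spectra_matrix.csv")
    utils::write.csv(df, path, row.names = FALSE)
    paths <- path
  } else {
    paths <- character(length(cohort))
    for (i in seq_along(cohort)) {
      s <- cohort[[i]]
      fn <- sprintf("spectrum_%03d.csv", i)
      utils::write.csv(
        data.frame(`wavenumber_cm-1` = s$wavenumber, intensity = s$intensity,
                   check.names = FALSE),
        file.path(dir, fn), row.names = FALSE)
      paths[i] <- file.path(dir, fn)
    }
  }
  manifest <- data.frame(
    index = seq_along(cohort),
    class = vapply(cohort, function(s) s$class_label %||% NA_character_, character(1)),
    patient_id = vapply(cohort, function(s) s$patient_id %||% NA_character_, character(1)),
    filename = if (wide) "spectra_matrix.csv" else basename(paths)
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(c(paths, file.path(dir, "manifest.csv")))
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir Directory containing `manifest.csv` and the spectrum CSVs (or
#'   `spectra_matrix.csv`).
#' @return List of `spectrum` objects (class `raman_cohort`).
#' @export
read_cohort_csv <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  wide <- all(man$filename == "spectra_matrix.csv")
  out <- vector("list", nrow(man))
  if (wide) {
    m <- utils::read.csv(file.path(dir, "spectra_matrix.csv"), check.names = FALSE)
    wn <- m[[1]]
    for (i in seq_len(nrow(man)))
      out[[i]] <- spectrum(wn, m[[i + 1L]], class_label = man$class[i],
                           patient_id = man$patient_id[i], cohort_index = man$index[i])
  } else {
    for (i in seq_len(nrow(man))) {
      df <- utils::read.csv(file.path(dir, man$filename[i]), check.names = FALSE)
      out[[i]] <- spectrum(df[[1]], df[[2]], class_label = man$class[i],
                           patient_id = man$patient_id[i], cohort_index = man$index[i])
    }
  }
  class(out) <- c("raman_cohort", "list")
  out
}
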