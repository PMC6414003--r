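#' Preprocessing configuration
#'
#' @param baseline_degree Polynomial degree of the fluorescence baseline fit
#'   (default 5).
#' @param sg_polyorder Savitzky-Golay polynomial order (default 2).
#' @param sg_window Savitzky-Golay window length, odd, greater than
#'   `sg_polyorder` (default 11 points, about 6.6 cm^-1 on the reference
#'   grid).
#' @param norm_peak Reference band for normalization, cm^-1 (default 1002,
#'   the phenylalanine band).
#' @param norm_window Half-width of the search window around `norm_peak`
#'   (default 5 cm^-1).
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(baseline_degree = 5L, sg_polyorder = 2L,
                              sg_window = 11L, norm_peak = 1002,
                              norm_window = 5) {
  cfg <- list(baseline_degree = as.integer(baseline_degree),
              sg_polyorder = as.integer(sg_polyorder),
              sg_window = as.integer(sg_window),
              norm_peak = norm_peak, norm_window = norm_window)
  if (cfg$baseline_degree < 0L)
    stop("preprocess_config: baseline_degree must be >= 0", call. = FALSE)
  if (cfg$sg_window %% 2L == 0L || cfg$sg_window <= cfg$sg_polyorder)
    stop("preprocess_config: sg_window must be odd and > sg_polyorder", call. = FALSE)
  class(cfg) <- "preprocess_config"
  cfg
}

#' Iterative polynomial baseline correction
#'
#' Removes background fluorescence by an iteratively re-fitted polynomial:
#' fit a degree-`degree` polynomial by least squares, clip the working
#' signal to `min(signal, fit + dev)` where `dev` is the standard
#' deviation of the current residuals, and refit until the fit changes by
#' less than `tol` (relative) or `max_iter` iterations. The clipping step
#' makes the fit hug the valleys between peaks — so peaks are not
#' subtracted away as a single least-squares fit would do — while the
#' `dev` allowance keeps the fit from chasing the noise floor, so
#' re-running the correction on an already-corrected spectrum is a
#' near-no-op.
#'
#' @param s A `spectrum`.
#' @param degree Polynomial degree (default 5).
#' @param max_iter,tol Convergence controls.
#' @return The baseline-subtracted `spectrum` (negative residuals are kept).
#' @export
correct_baseline <- function(s, degree = 5L, max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(s, "spectrum"))
  n <- length(s$intensity)
  if (n <= degree + 1L)
    stop("correct_baseline: spectrum shorter than degree + 2 points", call. = FALSE)
  # orthogonal polynomial basis on the grid, QR factored once
  x <- s$wavenumber
  basis <- matrix(1, n, 1)
  if (degree > 0L) basis <- cbind(basis, stats::poly(x, degree = degree))
  qrb <- qr(basis)
  y <- s$intensity
  scale <- max(abs(y), 1e-12)
  fit <- drop(basis %*% qr.coef(qrb, y))
  for (it in seq_len(max_iter)) {
    dev <- stats::sd(y - fit)
    y <- pmin(y, fit + dev)
    new_fit <- drop(basis %*% qr.coef(qrb, y))
    if (max(abs(new_fit - fit)) < tol * scale) {
      fit <- new_fit
      break
    }
    fit <- new_fit
  }
  set_intensity(s, s$intensity - fit)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing; reproduces polynomial signals
#' up to `polyorder` exactly while attenuating narrow spikes such as
#' cosmic-ray artifacts.
#'
#' @param s A `spectrum`.
#' @param polyorder Fit order (default 2).
#' @param window Odd window length greater than `polyorder` (default 11).
#' @return The smoothed `spectrum`.
#' @export
sg_smooth <- function(s, polyorder = 2L, window = 11L) {
  stopifnot(inherits(s, "spectrum"))
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window <= polyorder || window < 3L)
    stop("sg_smooth: window must be odd, >= 3 and > polyorder", call. = FALSE)
  if (length(s$intensity) < window)
    stop("sg_smooth: spectrum shorter than the filter window", call. = FALSE)
  set_intensity(s, signal::sgolayfilt(s$intensity, p = polyorder, n = window))
}

#' Normalize a spectrum to a reference band
#'
#' Divides intensities by the maximum found within `norm_peak +-
#' norm_window`, so the reference band (phenylalanine at 1002 cm^-1 by
#' default, the tallest band of serum spectra) becomes 1. A windowed rather
#' than global maximum keeps the normalization robust to residual spikes.
#'
#' @param s A `spectrum`.
#' @param norm_peak Reference wavenumber (cm^-1).
#' @param norm_window Half-width of the search window (cm^-1).
#' @return The normalized `spectrum`.
#' @export
normalize_spectrum <- function(s, norm_peak = 1002, norm_window = 5) {
  stopifnot(inherits(s, "spectrum"))
  win <- s$wavenumber >= norm_peak - norm_window & s$wavenumber <= norm_peak + norm_window
  if (!any(win))
    stop("normalize_spectrum: no grid point within the normalization window", call. = FALSE)
  ref <- max(s$intensity[win])
  if (!is.finite(ref) || ref <= 0)
    stop("normalize_spectrum: non-positive reference maximum (degenerate spectrum)",
         call. = FALSE)
  set_intensity(s, s$intensity / ref)
}

#' Full preprocessing pipeline for one spectrum
#'
#' Baseline correction, Savitzky-Golay smoothing, then peak normalization,
#' in that order.
#'
#' @param s A `spectrum`.
#' @param config A `preprocess_config`.
#' @return The processed `spectrum`.
#' @export
preprocess_spectrum <- function(s, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  s <- correct_baseline(s, degree = config$baseline_degree)
  s <- sg_smooth(s, polyorder = config$sg_polyorder, window = config$sg_window)
  normalize_spectrum(s, norm_peak = config$norm_peak, norm_window = config$norm_window)
}

#' Preprocess every spectrum of a cohort
#'
#' @param cohort List of `spectrum` objects.
#' @param config A `preprocess_config`.
#' @return List of processed spectra (class `raman_cohort`).
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  out <- lapply(cohort, preprocess_spectrum, config = config)
  class(out) <- c("raman_cohort", "list")
  out
}

#' Pointwise mean spectrum
#'
#' @param spectra Non-empty list of spectra on a common grid.
#' @return A `spectrum` holding the arithmetic mean intensity; class label
#'   is kept if all inputs agree.
#' @export
mean_spectrum <- function(spectra) {
  if (length(spectra) == 0L) stop("mean_spectrum: empty input", call. = FALSE)
  if (!same_grid(spectra)) stop("mean_spectrum: spectra are not on a common grid", call. = FALSE)
  m <- rowMeans(sapply(spectra, function(s) s$intensity))
  labs <- unique(vapply(spectra, function(s) s$class_label %||% NA_character_, character(1)))
  spectrum(spectra[[1]]$wavenumber, m,
           class_label = if (length(labs) == 1L && !is.na(labs)) labs else NULL)
}

#' Catalog of serum Raman band assignments
#'
#' The 21 vibrational assignments used to annotate serum spectra:
#' phenylalanine (622, 1002, 1028, 1063, 1103), tyrosine (642, 828, 853,
#' 1603), amide III (1230--1282, one entry), phospholipid (1447),
#' beta-carotene (1160, 1523), tryptophan (509, 760, 1208, 1556, 1620),
#' polysaccharides (714), skeletal str alpha (938) and amide I (1654).
#'
#' @return Data frame with columns `lo`, `hi` (band window, cm^-1) and
#'   `assignment`.
#' @export
band_catalog <- function() {
  b <- function(center, assignment, half = 5)
    data.frame(lo = center - half, hi = center + half, assignment = assignment)
  rbind(
    b(509, "tryptophan"), b(622, "phenylalanine"), b(642, "tyrosine"),
    b(714, "polysaccharides"), b(760, "tryptophan"), b(828, "tyrosine"),
    b(853, "tyrosine"), b(938, "skeletal str alpha"), b(1002, "phenylalanine"),
    b(1028, "phenylalanine"), b(1063, "phenylalanine"), b(1103, "phenylalanine"),
    b(1160, "beta-carotene"), b(1208, "tryptophan"),
    data.frame(lo = 1230, hi = 1282, assignment = "amide III"),
    b(1447, "phospholipid"), b(1523, "beta-carotene"), b(1556, "tryptophan"),
    b(1603, "tyrosine"), b(1620, "tryptophan"), b(1654, "amide I")
  )
}

#' Annotate catalog bands on a normalized spectrum
#'
#' Reports the maximum intensity inside each catalog band window.
#'
#' @param s A (normalized) `spectrum`.
#' @param catalog Band windows, as from [band_catalog()].
#' @return Data frame: `band` (window center), `assignment`, `intensity`.
#' @export
annotate_bands <- function(s, catalog = band_catalog()) {
  stopifnot(inherits(s, "spectrum"))
  intensity <- vapply(seq_len(nrow(catalog)), function(r) {
    win <- s$wavenumber >= catalog$lo[r] & s$wavenumber <= catalog$hi[r]
    if (!any(win)) NA_real_ else max(s$intensity[win])
  }, numeric(1))
  data.frame(band = (catalog$lo + catalog$hi) / 2,
             assignment = catalog$assignment,
             intensity = intensity)
}
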