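`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a spectrum record
#'
#' @param wavenumber Strictly increasing numeric grid (cm^-1).
#' @param intensity Numeric vector of the same length.
#' @param class_label,patient_id,cohort_index Optional metadata.
#' @return A `spectrum` object.
#' @export
spectrum <- function(wavenumber, intensity, class_label = NULL,
                     patient_id = NULL, cohort_index = NA_integer_) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("spectrum: wavenumber and intensity must have equal length", call. = FALSE)
  if (any(diff(wavenumber) <= 0))
    stop("spectrum: wavenumber grid must be strictly increasing", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("spectrum: intensities must be finite", call. = FALSE)
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 class_label = class_label, patient_id = patient_id,
                 cohort_index = cohort_index),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.1f-%.1f cm^-1%s\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              if (!is.null(x$class_label)) paste0(", class ", x$class_label) else ""))
  invisible(x)
}

# replace intensities, keeping grid and metadata
set_intensity <- function(s, y) {
  s$intensity <- as.numeric(y)
  s
}

# all spectra of a list share one grid?
same_grid <- function(spectra) {
  g <- spectra[[1]]$wavenumber
  all(vapply(spectra, function(s)
    length(s$wavenumber) == length(g) && all(s$wavenumber == g), logical(1)))
}
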