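#' Principal component analysis of a spectra matrix
#'
#' Treats spectra (columns of the data matrix) as observations and
#' wavenumbers as variables; observations are mean-centered, not scaled
#' (all intensities already share the peak-normalized scale). Component
#' signs are fixed so the largest-magnitude loading of each component is
#' positive, making results deterministic.
#'
#' @param sm A `spectra_matrix` (or plain points x spectra matrix).
#' @param k Number of components to keep.
#' @return An `spc_pca`: list with `scores` (spectra x k), `loadings`
#'   (points x k, unit norm per column), `explained_variance` (fraction per
#'   component), `grid`.
#' @export
run_pca <- function(sm, k = 3L) {
  values <- if (inherits(sm, "spectra_matrix")) sm$values else as.matrix(sm)
  grid <- if (inherits(sm, "spectra_matrix")) sm$grid else seq_len(nrow(values))
  n <- ncol(values)
  p <- nrow(values)
  k <- as.integer(k)
  if (k < 1L || k > min(n, p))
    stop("run_pca: k must satisfy 1 <= k <= min(n_spectra, n_points)", call. = FALSE)
  pr <- stats::prcomp(t(values), center = TRUE, scale. = FALSE)
  total_var <- sum(pr$sdev^2)
  if (total_var <= .Machine$double.eps) {
    warning("run_pca: data matrix has zero variance (all spectra identical)")
    ev <- rep(0, k)
  } else {
    ev <- (pr$sdev^2 / total_var)[seq_len(k)]
    ev[is.na(ev)] <- 0
  }
  kk <- min(k, ncol(pr$rotation))
  loadings <- pr$rotation[, seq_len(kk), drop = FALSE]
  scores <- pr$x[, seq_len(kk), drop = FALSE]
  for (c in seq_len(kk)) {
    if (loadings[which.max(abs(loadings[, c])), c] < 0) {
      loadings[, c] <- -loadings[, c]
      scores[, c] <- -scores[, c]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev, grid = grid, center = pr$center),
            class = "spc_pca")
}

#' Loading curve of one principal component
#'
#' Pairs a component's loadings with the wavenumber grid; the positions of
#' the largest |loading| values indicate the spectral regions that drive
#' the differences between spectra.
#'
#' @param pca An `spc_pca`.
#' @param component Component index.
#' @param n_peaks How many |loading| local maxima to report.
#' @return Data frame (`wavenumber`, `loading`) with attribute `peaks`: the
#'   wavenumbers of the top local maxima of |loading|, strongest first.
#' @export
loading_curve <- function(pca, component = 1L, n_peaks = 5L) {
  stopifnot(inherits(pca, "spc_pca"))
  if (component < 1L || component > ncol(pca$loadings))
    stop("loading_curve: component out of range", call. = FALSE)
  v <- pca$loadings[, component]
  a <- abs(v)
  n <- length(a)
  is_peak <- c(FALSE, a[2:(n - 1)] >= a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n], FALSE)
  pk <- which(is_peak)
  pk <- pk[order(-a[pk])]
  pk <- utils::head(pk, n_peaks)
  out <- data.frame(wavenumber = pca$grid, loading = v)
  attr(out, "peaks") <- pca$grid[pk]
  out
}

#' Write PCA scores and loadings as CSV
#'
#' @param pca An `spc_pca`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_pca_csv <- function(pca, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "pca_scores.csv")
  utils::write.csv(data.frame(spectrum = seq_len(nrow(pca$scores)), pca$scores),
                   p1, row.names = FALSE)
  p2 <- file.path(dir, "pca_loadings.csv")
  utils::write.csv(data.frame(wavenumber = pca$grid, pca$loadings),
                   p2, row.names = FALSE)
  invisible(c(p1, p2))
}
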