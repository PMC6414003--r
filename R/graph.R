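#' Assemble the data matrix from a cohort
#'
#' Columns are spectra (ordered by cohort index when available), rows are
#' Raman shifts; for the reference design this is the 2330 x 352 matrix.
#'
#' @param spectra List of preprocessed spectra on a shared grid.
#' @return A `spectra_matrix`: list with `values` (points x spectra),
#'   `grid`, `classes`, `patients`, `index`.
#' @export
build_matrix <- function(spectra) {
  if (length(spectra) == 0L) stop("build_matrix: empty cohort", call. = FALSE)
  if (!same_grid(spectra)) stop("build_matrix: spectra are not on a common grid", call. = FALSE)
  idx <- vapply(spectra, function(s) s$cohort_index %||% NA_integer_, numeric(1))
  ord <- if (all(!is.na(idx))) order(idx) else seq_along(spectra)
  spectra <- spectra[ord]
  values <- sapply(spectra, function(s) s$intensity)
  structure(list(
    values = values,
    grid = spectra[[1]]$wavenumber,
    classes = vapply(spectra, function(s) s$class_label %||% NA_character_, character(1)),
    patients = vapply(spectra, function(s) s$patient_id %||% NA_character_, character(1)),
    index = if (all(!is.na(idx))) sort(idx) else seq_along(spectra)
  ), class = "spectra_matrix")
}

#' Euclidean distance matrix between spectra
#'
#' @param sm A `spectra_matrix` (or a plain points-x-spectra matrix).
#' @return Full symmetric matrix of pairwise Euclidean distances between
#'   columns (spectra); for the reference design, 352 x 352.
#' @export
distance_matrix <- function(sm) {
  values <- if (inherits(sm, "spectra_matrix")) sm$values else as.matrix(sm)
  as.matrix(stats::dist(t(values)))
}

#' Build the interacting-neighbor graph
#'
#' Edges are mutual K-nearest-neighbor pairs (kept iff i is among j's K
#' nearest and j among i's K nearest; ties broken by lower index),
#' augmented with the minimum-spanning-tree edges of the distance matrix so
#' the graph is connected and the ferromagnetic phase is a single cluster.
#' `d_bar` (mean edge distance) and `k_hat` (mean number of interacting
#' neighbors, 2|E|/n) are computed from the final edge set.
#'
#' @param d Symmetric distance matrix.
#' @param k Neighborhood size (default 10).
#' @return A `coupling_graph`: list with `n`, `edges` (data frame `i`, `j`,
#'   `d`, and `J` once [compute_couplings()] has run), `d_bar`, `k_hat`.
#' @export
build_neighbor_graph <- function(d, k = 10L) {
  d <- as.matrix(d)
  n <- nrow(d)
  k <- as.integer(k)
  if (n < 2L) stop("build_neighbor_graph: need at least 2 points", call. = FALSE)
  if (k < 1L || k >= n)
    stop("build_neighbor_graph: k must satisfy 1 <= k < n", call. = FALSE)
  # K nearest neighbors of each point, ties broken by lower index
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    nn[i, ] <- ord[seq_len(k)]
  }
  is_nn <- matrix(FALSE, n, n)
  for (i in seq_len(n)) is_nn[i, nn[i, ]] <- TRUE
  mutual <- is_nn & t(is_nn)
  # minimum-spanning-tree augmentation for connectivity
  g_full <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
  mst_el <- igraph::as_edgelist(igraph::mst(g_full), names = FALSE)
  adj <- mutual
  adj[mst_el] <- TRUE
  adj[mst_el[, 2:1, drop = FALSE]] <- TRUE
  diag(adj) <- FALSE
  wh <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(i = wh[, 1], j = wh[, 2], d = d[wh])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(n = n, edges = edges,
                 d_bar = mean(edges$d),
                 k_hat = 2 * nrow(edges) / n),
            class = "coupling_graph")
}

#' Populate ferromagnetic couplings
#'
#' Sets, for every edge, the short-range ferromagnetic coupling
#' \deqn{J_{ij} = \frac{1}{\hat K} \exp\left\{-\frac{1}{2}
#'   \left(\frac{d_{ij}}{\bar d}\right)^2\right\},}
#' a positive, monotonically decreasing function of the distance; couplings
#' between non-neighbors are implicitly zero.
#'
#' @param graph A `coupling_graph` from [build_neighbor_graph()].
#' @return The graph with `edges$J` populated.
#' @export
compute_couplings <- function(graph) {
  stopifnot(inherits(graph, "coupling_graph"))
  if (!is.finite(graph$d_bar) || graph$d_bar <= 0)
    stop("compute_couplings: mean neighbor distance is zero (all points coincide)",
         call. = FALSE)
  if (graph$k_hat <= 0) stop("compute_couplings: k_hat must be > 0", call. = FALSE)
  graph$edges$J <- exp(-0.5 * (graph$edges$d / graph$d_bar)^2) / graph$k_hat
  graph
}

#' Distance matrix to coupling graph in one step
#'
#' @param d Symmetric distance matrix.
#' @param k Neighborhood size.
#' @return A `coupling_graph` with couplings populated.
#' @export
spc_graph <- function(d, k = 10L) compute_couplings(build_neighbor_graph(d, k))

#' Build a coupling graph directly from an edge list
#'
#' Utility for toy systems and tests: takes explicit edges and couplings
#' without any neighbor search.
#'
#' @param n Number of points.
#' @param i,j Integer endpoint vectors (1-based, i != j).
#' @param J Coupling strengths (> 0).
#' @param d Optional edge distances.
#' @return A `coupling_graph`.
#' @export
coupling_graph_from_edges <- function(n, i, j, J, d = NA_real_) {
  stopifnot(length(i) == length(j), length(J) == length(i))
  if (any(i == j)) stop("coupling_graph_from_edges: self-loops not allowed", call. = FALSE)
  if (any(J <= 0)) stop("coupling_graph_from_edges: couplings must be > 0", call. = FALSE)
  sw <- i > j
  tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp
  edges <- data.frame(i = as.integer(i), j = as.integer(j), d = d, J = J)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(n = as.integer(n), edges = edges,
                 d_bar = if (all(is.finite(edges$d))) mean(edges$d) else NA_real_,
                 k_hat = 2 * nrow(edges) / n),
            class = "coupling_graph")
}

#' Export a coupling graph as an edge-list CSV
#'
#' @param graph A `coupling_graph`.
#' @param path Output CSV path (columns i, j, d, J).
#' @return Invisibly, `path`.
#' @export
write_graph_csv <- function(graph, path) {
  utils::write.csv(graph$edges, path, row.names = FALSE)
  invisible(path)
}
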