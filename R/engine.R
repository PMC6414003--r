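#' Potts / Swendsen-Wang sampler configuration
#'
#' @param q Number of Potts spin states (default 20; results are
#'   insensitive to q once it is ~10 or larger).
#' @param n_sweeps Monte Carlo sweeps per temperature, including burn-in.
#' @param n_burnin Discarded sweeps per temperature.
#' @param t_min Lowest temperature of the sweep (default `t_step`).
#' @param t_max Highest temperature; `NULL` (default) extends the grid
#'   automatically until the largest data cluster has stayed below
#'   `stop_frac` of the points for `stop_runs` consecutive steps.
#' @param t_step Temperature grid step (default 0.001).
#' @param g_threshold Spin-spin correlation threshold above which two
#'   neighbors are assigned to the same data cluster (default 0.5).
#' @param estimator `"sw"` for the variance-reduced SW-cluster
#'   co-membership estimator (default) or `"delta"` for plain counting of
#'   equal-spin sweeps.
#' @param stop_frac,stop_runs,max_steps Automatic sweep-termination
#'   controls (see `t_max`); `max_steps` caps the grid length.
#' @param seed Optional integer seed applied at the start of a sweep.
#' @return A `potts_config` object.
#' @export
potts_config <- function(q = 20L, n_sweeps = 1000L, n_burnin = 200L,
                         t_min = NULL, t_max = NULL, t_step = 0.001,
                         g_threshold = 0.5,
                         estimator = c("sw", "delta"),
                         stop_frac = 0.05, stop_runs = 20L, max_steps = 2000L,
                         seed = NULL) {
  cfg <- list(q = as.integer(q), n_sweeps = as.integer(n_sweeps),
              n_burnin = as.integer(n_burnin),
              t_min = if (is.null(t_min)) t_step else t_min,
              t_max = t_max, t_step = t_step,
              g_threshold = g_threshold,
              estimator = match.arg(estimator),
              stop_frac = stop_frac, stop_runs = as.integer(stop_runs),
              max_steps = as.integer(max_steps),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (cfg$q < 2L) stop("potts_config: q must be >= 2", call. = FALSE)
  if (cfg$t_step <= 0) stop("potts_config: t_step must be > 0", call. = FALSE)
  if (cfg$g_threshold <= 0 || cfg$g_threshold >= 1)
    stop("potts_config: g_threshold must lie in (0, 1)", call. = FALSE)
  if (cfg$n_sweeps <= cfg$n_burnin)
    stop("potts_config: n_sweeps must exceed n_burnin", call. = FALSE)
  if (!is.null(cfg$t_max) && cfg$t_max < cfg$t_min)
    stop("potts_config: t_max must be >= t_min", call. = FALSE)
  class(cfg) <- "potts_config"
  cfg
}

#' Potts Hamiltonian of a spin configuration
#'
#' Energy \eqn{H = \sum_{(i,j)} J_{ij} (1 - \delta_{s_i, s_j})}, summed over
#' interacting neighbor pairs: each edge whose endpoints carry different
#' spins contributes its coupling.
#'
#' @param state Integer vector of spin labels, one per graph vertex.
#' @param graph A `coupling_graph` with couplings populated.
#' @return Non-negative energy.
#' @export
hamiltonian <- function(state, graph) {
  stopifnot(inherits(graph, "coupling_graph"))
  if (length(state) != graph$n || any(is.na(state)))
    stop("hamiltonian: state must label every vertex", call. = FALSE)
  e <- graph$edges
  sum(e$J[state[e$i] != state[e$j]])
}

#' One Swendsen-Wang update
#'
#' Freezes each satisfied edge (equal endpoint spins) independently with
#' probability \eqn{p_{ij} = 1 - \exp(-J_{ij}/T)}, forms the connected
#' components of frozen edges (the SW clusters) and assigns each component
#' a fresh uniform label in 1..q. This move satisfies detailed balance with
#' respect to \eqn{\exp(-H/T)}.
#'
#' @param state Integer spin vector (labels in 1..q).
#' @param graph A `coupling_graph` with couplings.
#' @param temperature Temperature T > 0.
#' @param q Number of spin states.
#' @return The successor spin vector.
#' @export
sw_step <- function(state, graph, temperature, q = 20L) {
  stopifnot(inherits(graph, "coupling_graph"))
  if (temperature <= 0) stop("sw_step: temperature must be > 0", call. = FALSE)
  res <- .sw_chain_cpp(graph$n, graph$edges$i, graph$edges$j, graph$edges$J,
                       as.integer(q), temperature, 1L, 0L, as.integer(state))
  res$state
}

#' Magnetic susceptibility from magnetization samples
#'
#' \eqn{\chi = (N/T)(\langle m^2\rangle - \langle m\rangle^2)} with the
#' per-sweep magnetization \eqn{m = (q N_{max} - N) / ((q-1) N)}, where
#' \eqn{N_{max}} is the size of the largest spin-value class.
#'
#' @param m Numeric vector of per-sweep magnetization samples.
#' @param temperature Temperature at which they were drawn.
#' @param n_points Number of points N of the system.
#' @return Non-negative susceptibility.
#' @export
susceptibility <- function(m, temperature, n_points) {
  if (length(m) < 2L) stop("susceptibility: need at least 2 samples", call. = FALSE)
  (n_points / temperature) * max(0, mean(m^2) - mean(m)^2)
}

#' Estimate spin-spin correlations at one temperature
#'
#' Runs a Swendsen-Wang chain (burn-in, then retained sweeps) and estimates
#' the edge correlations \eqn{g_{ij} = \langle\delta_{s_i,s_j}\rangle}. The
#' default estimator uses SW-cluster co-membership,
#' \eqn{g_{ij} = ((q-1) c_{ij} + 1)/q} with \eqn{c_{ij}} the fraction of
#' sweeps in which i and j share a frozen cluster — an unbiased,
#' variance-reduced form of the plain equal-spin frequency, which is also
#' available (`estimator = "delta"`).
#'
#' @param graph A `coupling_graph` with couplings.
#' @param temperature Temperature T > 0.
#' @param config A `potts_config`.
#' @param state Optional initial spin vector (warm start); defaults to all
#'   spins equal.
#' @return A `sweep_point`: list with `T`, `g` (per-edge correlations),
#'   `chi`, `m` (magnetization samples), `partition` (integer cluster
#'   membership from [clusters_at_T()]), `state` (final spins).
#' @export
estimate_correlations <- function(graph, temperature, config = potts_config(),
                                  state = NULL) {
  stopifnot(inherits(graph, "coupling_graph"), inherits(config, "potts_config"))
  if (is.null(graph$edges$J)) stop("estimate_correlations: couplings not computed", call. = FALSE)
  if (is.null(state)) state <- rep(1L, graph$n)
  res <- .sw_chain_cpp(graph$n, graph$edges$i, graph$edges$j, graph$edges$J,
                       config$q, temperature, config$n_sweeps, config$n_burnin,
                       as.integer(state))
  n_kept <- res$n_kept
  g <- if (config$estimator == "sw") {
    c_ij <- res$co_count / n_kept
    ((config$q - 1) * c_ij + 1) / config$q
  } else {
    res$delta_count / n_kept
  }
  pt <- list(T = temperature, g = g,
             chi = susceptibility(res$m, temperature, graph$n),
             m = res$m, state = res$state)
  pt$partition <- clusters_at_T(g, graph, config$g_threshold)
  class(pt) <- "sweep_point"
  pt
}

#' Data clusters from thresholded correlations
#'
#' Keeps only edges whose estimated correlation exceeds the threshold and
#' returns the connected components: every point belongs to exactly one
#' cluster (singletons allowed).
#'
#' @param g Per-edge correlation vector (aligned with `graph$edges`).
#' @param graph A `coupling_graph`.
#' @param g_threshold Correlation cut (default 0.5).
#' @return Integer membership vector of length `graph$n` (component ids
#'   numbered by decreasing component size, ties by smallest member).
#' @export
clusters_at_T <- function(g, graph, g_threshold = 0.5) {
  stopifnot(inherits(graph, "coupling_graph"), length(g) == nrow(graph$edges))
  keep <- g > g_threshold
  ig <- igraph::graph_from_edgelist(
    cbind(graph$edges$i[keep], graph$edges$j[keep]), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, graph$n - igraph::vcount(ig)))
  memb <- igraph::components(ig)$membership
  relabel_partition(memb)
}

# canonical cluster ids: decreasing size, ties by smallest member index
relabel_partition <- function(memb) {
  sizes <- table(memb)
  firsts <- tapply(seq_along(memb), memb, min)
  ord <- order(-as.vector(sizes), as.vector(firsts))
  new_id <- integer(length(sizes))
  new_id[ord] <- seq_along(ord)
  as.integer(new_id[match(memb, as.integer(names(sizes)))])
}

#' Temperature sweep of the Potts system
#'
#' Anneals a Swendsen-Wang chain over an increasing temperature grid
#' (`t_min`, `t_min + t_step`, ...), carrying the spin state across
#' adjacent temperatures, and records at each temperature the estimated
#' correlations, susceptibility and thresholded cluster partition. Starts
#' from all spins equal. When `t_max` is `NULL`, the grid extends until the
#' largest cluster has occupied less than `stop_frac` of the points for
#' `stop_runs` consecutive steps (capped at `max_steps` temperatures).
#'
#' @param graph A `coupling_graph` with couplings populated.
#' @param config A `potts_config`.
#' @return An `spc_sweep`: list with `points` (list of `sweep_point`s) and
#'   `summary` (data frame: T, chi, n_clusters, largest_cluster_size).
#' @export
temperature_sweep <- function(graph, config = potts_config()) {
  stopifnot(inherits(graph, "coupling_graph"), inherits(config, "potts_config"))
  if (is.null(graph$edges$J)) stop("temperature_sweep: couplings not computed", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  temps <- if (!is.null(config$t_max)) {
    seq(config$t_min, config$t_max, by = config$t_step)
  } else NULL
  if (!is.null(temps) && length(temps) == 0L)
    stop("temperature_sweep: empty temperature grid", call. = FALSE)
  auto <- is.null(temps)
  small_thresh <- max(2, config$stop_frac * graph$n)
  points <- list()
  state <- rep(1L, graph$n)
  t_cur <- config$t_min
  run <- 0L
  step <- 0L
  repeat {
    step <- step + 1L
    if (!auto && step > length(temps)) break
    if (auto && step > config$max_steps) {
      warning("temperature_sweep: max_steps reached before the paramagnetic phase")
      break
    }
    temperature <- if (auto) t_cur else temps[step]
    pt <- estimate_correlations(graph, temperature, config, state = state)
    state <- pt$state
    points[[step]] <- pt
    if (auto) {
      largest <- max(tabulate(pt$partition))
      run <- if (largest < small_thresh) run + 1L else 0L
      if (run >= config$stop_runs) break
      t_cur <- t_cur + config$t_step
    }
  }
  summary <- data.frame(
    T = vapply(points, `[[`, numeric(1), "T"),
    chi = vapply(points, `[[`, numeric(1), "chi"),
    n_clusters = vapply(points, function(p) max(p$partition), numeric(1)),
    largest_cluster_size = vapply(points, function(p) max(tabulate(p$partition)), numeric(1))
  )
  structure(list(points = points, summary = summary, t_step = config$t_step),
            class = "spc_sweep")
}

#' Write the sweep summary and partitions as CSV
#'
#' @param sweep An `spc_sweep`.
#' @param dir Output directory; writes `sweep_summary.csv` and
#'   `partitions.csv` (columns T, point_index, cluster_id).
#' @return Invisibly, the paths written.
#' @export
write_sweep_csv <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "sweep_summary.csv")
  utils::write.csv(sweep$summary, p1, row.names = FALSE)
  parts <- do.call(rbind, lapply(sweep$points, function(p)
    data.frame(T = p$T, point_index = seq_along(p$partition),
               cluster_id = p$partition)))
  p2 <- file.path(dir, "partitions.csv")
  utils::write.csv(parts, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
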