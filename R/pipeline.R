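#' Full pipeline configuration
#'
#' Nests the per-stage configurations and propagates one global seed into
#' deterministic per-stage sub-seeds.
#'
#' @param sim A `sim_config` (the synthetic cohort definition).
#' @param preprocess A `preprocess_config`.
#' @param potts A `potts_config`.
#' @param tree A `tree_config`.
#' @param k_neighbors Mutual nearest-neighbor count of the coupling graph.
#' @param pca_k Number of principal components.
#' @param seed Global integer seed; overrides the nested stage seeds.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(sim = sim_config(), preprocess = preprocess_config(),
                            potts = potts_config(), tree = tree_config(),
                            k_neighbors = 10L, pca_k = 3L, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), inherits(preprocess, "preprocess_config"),
            inherits(potts, "potts_config"), inherits(tree, "tree_config"))
  seed <- as.integer(seed)
  # deterministic per-stage sub-seeds, kept well below 2^31
  sim$seed <- (seed * 1000L + 1L) %% 2147480000L
  potts$seed <- (seed * 1000L + 2L) %% 2147480000L
  cfg <- list(sim = sim, preprocess = preprocess, potts = potts, tree = tree,
              k_neighbors = as.integer(k_neighbors), pca_k = as.integer(pca_k),
              seed = seed)
  if (cfg$k_neighbors < 1L) stop("pipeline_config: k_neighbors must be >= 1", call. = FALSE)
  if (sum(sim$n_spectra_per_class) < 2L)
    stop("pipeline_config: cohort must contain at least 2 spectra", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

# polynomial rolling hash of the serialized config (hex string)
config_fingerprint <- function(config) {
  js <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
  bytes <- utf8ToInt(as.character(js))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a cohort, preprocess it, build the data/distance
#' matrices and coupling graph, run the Potts temperature sweep, extract
#' the natural-cluster tree, and cross-check with PCA. All stage outputs
#' are written under `out_dir` (sweep summary and partitions, chi(T)
#' curve, tree JSON, membership table, PCA scores/loadings) together with
#' a manifest recording the config fingerprint, seed and stage timings.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param cohort Optional pre-made list of `spectrum` objects; when given,
#'   the simulation stage is skipped.
#' @return Invisibly, a list with `cohort`, `processed`, `matrix`, `dist`,
#'   `graph`, `sweep`, `lineages`, `tree`, `report`, `pca`,
#'   `natural_partition`, `fingerprint`, `timings`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  fingerprint <- config_fingerprint(config)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    val <- force(expr)
    timings[[name]] <<- round(tic() - t0, 3)
    message(sprintf("[ramanspc] stage %-10s %7.2fs", name, timings[[name]]))
    val
  }
  if (is.null(cohort))
    cohort <- stage("simulate", simulate_cohort(config$sim))
  if (length(cohort) < 2L)
    stop("run_pipeline: cohort must contain at least 2 spectra", call. = FALSE)
  processed <- stage("preprocess", preprocess_cohort(cohort, config$preprocess))
  sm <- stage("matrix", build_matrix(processed))
  d <- stage("distance", distance_matrix(sm))
  graph <- stage("graph", spc_graph(d, k = min(config$k_neighbors, ncol(sm$values) - 1L)))
  sweep <- stage("sweep", temperature_sweep(graph, config$potts))
  lineages <- stage("track", track_clusters(sweep, config$tree))
  tree <- stage("tree", extract_natural_clusters(lineages, config$tree))
  labels <- vapply(processed, function(s) s$class_label %||% NA_character_, character(1))
  report <- membership_report(tree, if (all(!is.na(labels))) labels else NULL)
  pca <- stage("pca", run_pca(sm, k = min(config$pca_k, ncol(sm$values))))
  result <- list(cohort = cohort, processed = processed, matrix = sm, dist = d,
                 graph = graph, sweep = sweep, lineages = lineages, tree = tree,
                 report = report, pca = pca,
                 natural_partition = natural_leaf_partition(tree),
                 fingerprint = fingerprint, timings = timings)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sweep_csv(sweep, out_dir)
    write_graph_csv(graph, file.path(out_dir, "coupling_graph.csv"))
    write_tree_json(tree, file.path(out_dir, "tree.json"))
    utils::write.csv(report, file.path(out_dir, "membership.csv"), row.names = FALSE)
    write_pca_csv(pca, out_dir)
    jsonlite::write_json(
      list(config_fingerprint = fingerprint, seed = config$seed,
           n_spectra = length(cohort), timings = as.list(timings)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(result)
}
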