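#' Cluster-tree configuration
#'
#' @param s_theta Stability threshold for natural-cluster extraction
#'   (default 0.5); the main control parameter of the sequential procedure.
#' @param match_jaccard Coverage floor for cluster identity across
#'   temperatures (default 0.8): a tracked cluster survives singleton
#'   evaporation while at least this fraction of its members still share
#'   one cluster; below it the node is considered dissolved.
#' @param min_cluster_size Smallest cluster tracked as a tree node and
#'   reportable as natural (default 2; singletons are never natural
#'   clusters). Set to 1 to track singleton lineages in toy analyses.
#' @param persistence Number of consecutive grid steps a split or
#'   dissolution must persist before it is recorded (default 3); guards the
#'   tree against single-temperature Monte Carlo flicker.
#' @param direction `"ge"` (default) marks a node stable when
#'   `s_t >= s_theta`; `"lt"` inverts the comparison.
#' @return A `tree_config` object.
#' @export
tree_config <- function(s_theta = 0.5, match_jaccard = 0.8,
                        min_cluster_size = 2L, persistence = 3L,
                        direction = c("ge", "lt")) {
  cfg <- list(s_theta = s_theta, match_jaccard = match_jaccard,
              min_cluster_size = as.integer(min_cluster_size),
              persistence = as.integer(persistence),
              direction = match.arg(direction))
  if (cfg$s_theta <= 0 || cfg$s_theta > 1)
    stop("tree_config: s_theta must lie in (0, 1]", call. = FALSE)
  if (cfg$match_jaccard <= 0 || cfg$match_jaccard > 1)
    stop("tree_config: match_jaccard must lie in (0, 1]", call. = FALSE)
  if (cfg$min_cluster_size < 1L)
    stop("tree_config: min_cluster_size must be >= 1", call. = FALSE)
  if (cfg$persistence < 1L)
    stop("tree_config: persistence must be >= 1", call. = FALSE)
  class(cfg) <- "tree_config"
  cfg
}

# sizes of the pieces into which the full partition at index t cuts the
# member set S (decreasing); used by the restricted tracker
restricted_pieces <- function(part, S) {
  pieces <- split(S, part[S])
  pieces[order(-lengths(pieces), vapply(pieces, min, numeric(1)))]
}

#' Track cluster lineages across the temperature sweep
#'
#' Follows each cluster from its birth upward in temperature with its
#' member set fixed at birth (as in the printed cluster tables, where each
#' cluster has one definitive member list). At every temperature the full
#' partition cuts the member set into pieces:
#' * the lineage survives while one piece of at least
#'   `match_jaccard * size` members holds together — members that
#'   evaporate as singletons (Monte Carlo flicker, outliers approaching
#'   their own transition) do not end a lineage;
#' * it *splits* when at least two pieces of size `min_cluster_size` or
#'   more persist for `persistence` consecutive steps; those pieces become
#'   child lineages;
#' * it *dissolves* (no children) when coverage drops below the floor.
#'
#' Lineages start from the clusters of the first (lowest-temperature)
#' partition; clusters smaller than `min_cluster_size` there are treated
#' as background.
#'
#' @param sweep An `spc_sweep` from [temperature_sweep()], ordered by
#'   increasing temperature.
#' @param config A `tree_config`.
#' @return A `lineage_set`: list with `lineages` (each: id, parent,
#'   birth_idx, last_idx, members, size, birth_T, death_T, lifetime,
#'   death_reason), `t_grid`, `partitions`, `n`, `root_id`.
#' @export
track_clusters <- function(sweep, config = tree_config()) {
  stopifnot(inherits(sweep, "spc_sweep"), inherits(config, "tree_config"))
  parts <- lapply(sweep$points, `[[`, "partition")
  if (length(parts) == 0L) stop("track_clusters: empty sweep", call. = FALSE)
  t_grid <- vapply(sweep$points, `[[`, numeric(1), "T")
  n_t <- length(parts)
  n <- length(parts[[1]])
  min_sz <- config$min_cluster_size
  lineages <- list()
  next_id <- 0L

  split_now <- function(S, t) {
    pieces <- restricted_pieces(parts[[t]], S)
    length(pieces) >= 2L && length(pieces[[2L]]) >= min_sz
  }
  dissolved_now <- function(S, t) {
    pieces <- restricted_pieces(parts[[t]], S)
    length(pieces[[1L]]) < config$match_jaccard * length(S)
  }
  persists <- function(test, S, t) {
    horizon <- min(n_t, t + config$persistence - 1L)
    all(vapply(t:horizon, function(u) test(S, u), logical(1)))
  }

  follow <- function(S, birth_idx, parent) {
    next_id <<- next_id + 1L
    id <- next_id
    last_idx <- birth_idx
    death_reason <- "survived"
    death_at <- NA_integer_
    t <- birth_idx + 1L
    while (t <= n_t) {
      if (split_now(S, t) && persists(split_now, S, t)) {
        death_reason <- "split"
        death_at <- t
        break
      }
      if (dissolved_now(S, t) && persists(dissolved_now, S, t)) {
        death_reason <- "dissolved"
        death_at <- t
        break
      }
      last_idx <- t
      t <- t + 1L
    }
    lineages[[id]] <<- list(
      id = id, parent = parent, birth_idx = birth_idx, last_idx = last_idx,
      members = sort(S), size = length(S),
      birth_T = t_grid[birth_idx], death_T = t_grid[last_idx],
      lifetime = t_grid[last_idx] - t_grid[birth_idx],
      death_reason = death_reason)
    if (death_reason == "split") {
      pieces <- restricted_pieces(parts[[death_at]], S)
      for (p in pieces)
        if (length(p) >= min_sz) follow(p, death_at, id)
    }
    id
  }

  roots <- restricted_pieces(parts[[1L]], seq_len(n))
  root_ids <- integer(0)
  for (r in roots)
    if (length(r) >= min_sz) root_ids <- c(root_ids, follow(r, 1L, NA_integer_))
  if (length(root_ids) == 0L)
    stop("track_clusters: no cluster of min_cluster_size at the lowest temperature",
         call. = FALSE)
  primary <- root_ids[which.max(vapply(lineages[root_ids], `[[`, numeric(1), "size"))]
  structure(list(lineages = lineages, t_grid = t_grid, partitions = parts,
                 n = n, root_id = primary, root_ids = root_ids),
            class = "lineage_set")
}

#' Relative stability of a lineage
#'
#' `s_T` expresses the stability of a cluster relative to the stability of
#' the whole set: the ratio of the lineage's temperature-range lifetime to
#' the reference lifetime of the root, clipped to `[0, 1]`.
#'
#' @param lineage A lineage (list with `lifetime`) or a numeric lifetime.
#' @param root_lineage The root lineage or its numeric reference lifetime.
#' @return `s_t` in `[0, 1]`.
#' @export
stability <- function(lineage, root_lineage) {
  lt <- if (is.list(lineage)) lineage$lifetime else lineage
  rt <- if (is.list(root_lineage)) root_lineage$lifetime else root_lineage
  if (!is.finite(rt) || rt <= 0)
    stop("stability: root lineage has zero lifetime (degenerate sweep)", call. = FALSE)
  min(1, max(0, lt / rt))
}

# first grid index at which the majority of `members` are singletons
majority_singleton_idx <- function(partitions, members) {
  for (t in seq_along(partitions)) {
    sz <- tabulate(partitions[[t]])
    if (mean(sz[partitions[[t]][members]] == 1) > 0.5) return(t)
  }
  NA_integer_
}

#' Extract the natural-cluster tree from tracked lineages
#'
#' Assembles the lineages into the temperature hierarchy (children ordered
#' by decreasing size and labeled hierarchically: root "0", its children
#' "1", "2", grandchildren "1 1", ...) and flags the natural clusters.
#'
#' Each node's relative stability `s_t` is its lifetime divided by the
#' root's ordered-regime span — from the root's birth at the lowest
#' temperature to its paramagnetic transition (`t_max`, where its members
#' become majority singletons). A node is *stable* when `s_t` passes the
#' `s_theta` threshold and its size reaches `min_cluster_size`; the
#' *natural* clusters are the deepest stable nodes — stable nodes with no
#' stable substructure — so extracted natural clusters sit on right
#' branches with residual structure on the left, as in the sequential
#' procedure. The whole-set root is never itself natural.
#'
#' Per node, `t_ferro` is the temperature range from birth to first split
#' (the node's ferromagnetic phase), `t_cl` the largest child lifetime
#' (the T-range of its most stable cluster), and `t_max` its paramagnetic
#' transition temperature.
#'
#' @param lineage_set A `lineage_set` from [track_clusters()].
#' @param config A `tree_config`.
#' @return A `cluster_tree`: list with `root` (nested `cluster_node`s;
#'   when the lowest-temperature partition has several tracked clusters, a
#'   synthetic root "0" spans them), `t_grid`, `root_lifetime`, `n`.
#' @export
extract_natural_clusters <- function(lineage_set, config = tree_config()) {
  stopifnot(inherits(lineage_set, "lineage_set"), inherits(config, "tree_config"))
  lin <- lineage_set$lineages
  t_grid <- lineage_set$t_grid
  root_id <- lineage_set$root_id
  # reference span: root birth to its paramagnetic transition
  rmax <- majority_singleton_idx(lineage_set$partitions, lin[[root_id]]$members)
  ref_end <- if (is.na(rmax)) t_grid[length(t_grid)] else t_grid[rmax]
  ref_span <- max(ref_end - lin[[root_id]]$birth_T,
                  if (length(t_grid) > 1L) diff(t_grid[1:2]) else 1)
  cond <- function(s) if (config$direction == "ge") s >= config$s_theta else s < config$s_theta

  kids_of <- function(id) {
    k <- which(vapply(lin, function(l) identical(l$parent, id), logical(1)))
    k[order(-vapply(lin[k], `[[`, numeric(1), "size"),
            vapply(lin[k], function(l) min(l$members), numeric(1)))]
  }
  build <- function(id, hier_id, is_primary_root) {
    l <- lin[[id]]
    kid_ids <- kids_of(id)
    s_t <- stability(l, ref_span)
    t_ferro <- if (l$death_reason == "split")
      t_grid[min(vapply(lin[kid_ids], `[[`, numeric(1), "birth_idx"))] - l$birth_T
    else l$lifetime
    t_cl <- if (length(kid_ids)) max(vapply(lin[kid_ids], `[[`, numeric(1), "lifetime")) else NA_real_
    tm <- majority_singleton_idx(lineage_set$partitions, l$members)
    t_max <- if (is.na(tm)) NA_real_ else t_grid[tm]
    child_prefix <- if (hier_id == "0") "" else paste0(hier_id, " ")
    children <- vector("list", length(kid_ids))
    for (k in seq_along(kid_ids))
      children[[k]] <- build(kid_ids[k], paste0(child_prefix, k), FALSE)
    has_stable_desc <- any(vapply(children, function(ch)
      isTRUE(attr(ch, "stable")) || isTRUE(attr(ch, "has_stable_desc")), logical(1)))
    stable <- !is_primary_root && l$size >= config$min_cluster_size && cond(s_t)
    node <- structure(list(
      id = hier_id, lineage_id = id, members = l$members, size = l$size,
      birth_T = l$birth_T, death_T = l$death_T, lifetime = l$lifetime,
      death_reason = l$death_reason,
      t_ferro = t_ferro, t_cl = t_cl, t_max = t_max, s_t = s_t,
      is_natural = stable && !has_stable_desc,
      children = children
    ), class = "cluster_node")
    attr(node, "stable") <- stable
    attr(node, "has_stable_desc") <- has_stable_desc
    node
  }
  root_ids <- lineage_set$root_ids
  if (length(root_ids) == 1L) {
    # a single root spanning the data is the whole-set cluster and can
    # never itself be natural; coexisting top-level clusters are ordinary
    # candidates
    root <- build(root_id, "0", TRUE)
  } else {
    # several coexisting clusters at the lowest temperature: wrap them in a
    # synthetic whole-set root so hierarchical ids stay well-formed
    ord <- root_ids[order(-vapply(lin[root_ids], `[[`, numeric(1), "size"))]
    children <- vector("list", length(ord))
    for (k in seq_along(ord))
      children[[k]] <- build(ord[k], as.character(k), FALSE)
    members <- sort(unlist(lapply(lin[ord], `[[`, "members")))
    root <- structure(list(
      id = "0", lineage_id = NA_integer_, members = members,
      size = length(members), birth_T = t_grid[1],
      death_T = t_grid[1], lifetime = 0, death_reason = "split",
      t_ferro = 0, t_cl = max(vapply(lin[ord], `[[`, numeric(1), "lifetime")),
      t_max = NA_real_, s_t = NA_real_, is_natural = FALSE,
      children = children), class = "cluster_node")
  }
  structure(list(root = root, t_grid = t_grid,
                 root_lifetime = ref_span, n = lineage_set$n),
            class = "cluster_tree")
}

# preorder flatten of the node hierarchy
flatten_tree <- function(tree) {
  out <- list()
  rec <- function(node) {
    out[[length(out) + 1L]] <<- node
    for (ch in node$children) rec(ch)
  }
  rec(tree$root)
  out
}

#' Natural clusters of a tree
#'
#' @param tree A `cluster_tree`.
#' @return List of the `cluster_node`s flagged natural.
#' @export
natural_clusters <- function(tree) {
  Filter(function(nd) isTRUE(nd$is_natural), flatten_tree(tree))
}

#' Point partition induced by the natural clusters
#'
#' Members of each natural cluster share a label; the natural clusters are
#' pairwise disjoint by construction, and remaining points become
#' singletons.
#'
#' @param tree A `cluster_tree`.
#' @param n Number of points (defaults to the tree's).
#' @return Integer membership vector of length `n`.
#' @export
natural_leaf_partition <- function(tree, n = tree$n) {
  nat <- natural_clusters(tree)
  memb <- integer(n)
  for (k in seq_along(nat)) memb[nat[[k]]$members] <- k
  free <- which(memb == 0L)
  memb[free] <- length(nat) + seq_along(free)
  relabel_partition(memb)
}

#' Membership and composition report
#'
#' Flattens the cluster tree into a table with one row per node:
#' hierarchical id, size, temperature statistics, stability, natural flag,
#' the sorted member list, and (when class labels are supplied) per-class
#' composition counts.
#'
#' @param tree A `cluster_tree`.
#' @param class_labels Optional character vector of per-point class labels
#'   (position = point index).
#' @return Data frame, one row per tree node.
#' @export
membership_report <- function(tree, class_labels = NULL) {
  nodes <- flatten_tree(tree)
  df <- data.frame(
    id = vapply(nodes, `[[`, character(1), "id"),
    size = vapply(nodes, `[[`, numeric(1), "size"),
    t_ferro = vapply(nodes, function(nd) nd$t_ferro %||% NA_real_, numeric(1)),
    t_cl = vapply(nodes, function(nd) nd$t_cl %||% NA_real_, numeric(1)),
    s_t = vapply(nodes, function(nd) nd$s_t %||% NA_real_, numeric(1)),
    is_natural = vapply(nodes, function(nd) isTRUE(nd$is_natural), logical(1)),
    members = vapply(nodes, function(nd) paste(nd$members, collapse = " "), character(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(class_labels)) {
    for (cl in unique(class_labels)) {
      df[[paste0("n_", cl)]] <- vapply(nodes, function(nd)
        sum(class_labels[nd$members] == cl), numeric(1))
    }
  }
  df
}

#' Serialize a cluster tree to JSON
#'
#' @param tree A `cluster_tree`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tree_json <- function(tree, path) {
  strip <- function(node) {
    list(id = node$id, size = node$size, members = node$members,
         t_ferro = node$t_ferro, t_cl = node$t_cl, t_max = node$t_max,
         s_t = node$s_t, is_natural = node$is_natural,
         children = lapply(node$children, strip))
  }
  jsonlite::write_json(strip(tree$root), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Text rendering of the cluster tree
#'
#' @param x A `cluster_tree`.
#' @param ... Unused.
#' @export
print.cluster_tree <- function(x, ...) {
  rec <- function(node, indent) {
    cat(sprintf("%s[%s] n=%d T_ferro=%.4g%s%s%s\n",
                strrep("  ", indent), node$id, node$size, node$t_ferro,
                if (!is.na(node$t_cl)) sprintf(" T_cl=%.4g", node$t_cl) else "",
                if (!is.na(node$s_t)) sprintf(" s_T=%.4g", node$s_t) else "",
                if (isTRUE(node$is_natural)) " *natural*" else ""))
    for (ch in node$children) rec(ch, indent + 1L)
  }
  rec(x$root, 0L)
  invisible(x)
}
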