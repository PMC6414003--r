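#' Reference cohort design
#'
#' The 1-based cohort index ranges of the reference study design: spectra
#' 1--160 breast cancer (16 patients), 161--310 cervical cancer (21
#' patients), 311--352 leukemia (7 patients).
#'
#' @return Data frame with columns `start`, `end`, `class`, `n_patients`.
#' @export
cohort_design <- function() {
  data.frame(start = c(1L, 161L, 311L), end = c(160L, 310L, 352L),
             class = c("breast", "cervical", "leukemia"),
             n_patients = c(16L, 21L, 7L), stringsAsFactors = FALSE)
}

#' Load the cohort design fixture
#'
#' Reads the packaged transcription of the study design table and checks
#' that its ranges are disjoint, contiguous and start at 1.
#'
#' @return Data frame like [cohort_design()].
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "ramanspc", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- d[order(d$start), , drop = FALSE]
  if (d$start[1] != 1L || any(d$start[-1] != utils::head(d$end, -1) + 1L))
    stop("load_table1: corrupted fixture (ranges not contiguous from 1)", call. = FALSE)
  d
}

#' Class of a cohort index
#'
#' @param index 1-based spectrum index (vectorized).
#' @param design Cohort design data frame.
#' @return Class name(s).
#' @export
class_of <- function(index, design = cohort_design()) {
  if (any(index < min(design$start)) || any(index > max(design$end)))
    stop("class_of: index out of the design range", call. = FALSE)
  vapply(index, function(i)
    design$class[design$start <= i & i <= design$end], character(1))
}

#' Per-point class labels of a design
#'
#' @param design Cohort design data frame.
#' @return Character vector of length `max(design$end)`.
#' @export
design_labels <- function(design = cohort_design()) {
  class_of(seq_len(max(design$end)), design)
}

#' Load the printed cluster table fixture
#'
#' Reads the packaged transcription of the published cluster tree: leaf
#' clusters "1 1 1", "1 1 2", "1 2" and "2" with full member lists, and
#' internal nodes "0", "1" and "1 1" with sizes and temperature statistics
#' only. Integrity checks guard the transcription: every leaf's member
#' count must equal its printed size, leaves must be pairwise disjoint with
#' union 1..352, and each internal node's printed size must equal the union
#' of its descendant leaves.
#'
#' @return List of cluster records (fields `id`, `size`, `t_ferro`, `t_cl`,
#'   `s_t`, `members`; `members` is `NULL` on internal nodes).
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2.json", package = "ramanspc", mustWork = TRUE)
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  clusters <- lapply(seq_along(recs$id), function(r) {
    list(id = recs$id[r], size = as.integer(recs$size[r]),
         t_ferro = recs$t_ferro[r], t_cl = recs$t_cl[r], s_t = recs$s_t[r],
         members = if (is.null(recs$members[[r]])) NULL else as.integer(recs$members[[r]]))
  })
  names(clusters) <- recs$id
  leaves <- Filter(function(cl) !is.null(cl$members), clusters)
  for (cl in leaves)
    if (length(cl$members) != cl$size)
      stop("load_table2: corrupted fixture (member count != size for '",
           cl$id, "')", call. = FALSE)
  all_members <- sort(unname(unlist(lapply(leaves, `[[`, "members"))))
  if (anyDuplicated(all_members) || !identical(all_members, seq_len(352L)))
    stop("load_table2: corrupted fixture (leaves not a partition of 1..352)",
         call. = FALSE)
  for (cl in clusters) {
    if (!is.null(cl$members)) next
    pre <- if (cl$id == "0") "" else paste0(cl$id, " ")
    below <- Filter(function(lf) cl$id == "0" || startsWith(lf$id, pre), leaves)
    if (sum(vapply(below, `[[`, integer(1), "size")) != cl$size)
      stop("load_table2: corrupted fixture (internal node '", cl$id,
           "' size mismatch)", call. = FALSE)
  }
  clusters
}

#' Cluster tree from the printed cluster table
#'
#' Reassembles the published cluster hierarchy as a `cluster_tree`
#' (bypassing the Monte Carlo stage), so that [membership_report()] and
#' composition checks run on the printed partition directly. Internal
#' nodes inherit their member sets from the union of their descendant
#' leaves; leaves with printed member lists are flagged natural.
#'
#' @param clusters As returned by [load_table2()].
#' @return A `cluster_tree`.
#' @export
table2_tree <- function(clusters = load_table2()) {
  ids <- names(clusters)
  members_of <- function(id) {
    cl <- clusters[[id]]
    if (!is.null(cl$members)) return(sort(cl$members))
    pre <- if (id == "0") "" else paste0(id, " ")
    leaves <- Filter(function(c2) !is.null(c2$members) &&
                       (id == "0" || startsWith(c2$id, pre)), clusters)
    sort(unlist(lapply(leaves, `[[`, "members")))
  }
  children_ids <- function(id) {
    pre <- if (id == "0") "" else paste0(id, " ")
    kids <- ids[ids != "0" & startsWith(ids, pre) &
                  !grepl(" ", substring(ids, nchar(pre) + 1L))]
    kids[order(-vapply(kids, function(k) clusters[[k]]$size, numeric(1)))]
  }
  build <- function(id) {
    cl <- clusters[[id]]
    kids <- children_ids(id)
    structure(list(
      id = id, members = members_of(id), size = cl$size,
      birth_T = NA_real_, death_T = NA_real_, lifetime = NA_real_,
      t_ferro = cl$t_ferro, t_cl = cl$t_cl, t_max = NA_real_, s_t = cl$s_t,
      is_natural = !is.null(cl$members),
      children = lapply(kids, build)
    ), class = "cluster_node")
  }
  structure(list(root = build("0"), t_grid = NA_real_,
                 root_lifetime = NA_real_, n = clusters[["0"]]$size),
            class = "cluster_tree")
}
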