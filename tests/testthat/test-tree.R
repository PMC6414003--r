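toy_cfg <- function(...) tree_config(min_cluster_size = 1L, persistence = 1L, ...)

test_that("a static partition yields one lineage spanning the sweep", {
  sw <- make_sweep(rep(list(rep(1L, 5)), 10), temps = seq(0.001, 0.010, by = 0.001))
  lin <- track_clusters(sw, toy_cfg())
  expect_length(lin$lineages, 1)
  expect_equal(lin$lineages[[1]]$lifetime, 0.009)
  expect_equal(lin$lineages[[1]]$members, 1:5)
  expect_equal(lin$lineages[[1]]$death_reason, "survived")
})

test_that("the {ABC},{AB|C},{A|B|C} sequence yields 5 lineages with correct parentage", {
  # points 1 = A, 2 = B, 3 = C
  sw <- make_sweep(list(c(1L, 1L, 1L), c(1L, 1L, 2L), c(1L, 2L, 3L)))
  lin <- track_clusters(sw, toy_cfg())
  members <- lapply(lin$lineages, `[[`, "members")
  parents <- vapply(lin$lineages, function(l) l$parent %||% NA_integer_, integer(1))
  expect_length(lin$lineages, 5)
  expect_setequal(vapply(members, paste, character(1), collapse = ","),
                  c("1,2,3", "1,2", "3", "1", "2"))
  find <- function(m) which(vapply(members, identical, logical(1), m))
  expect_true(is.na(parents[find(c(1L, 2L, 3L))]))
  expect_equal(parents[find(c(1L, 2L))], find(c(1L, 2L, 3L)))
  expect_equal(parents[find(3L)], find(c(1L, 2L, 3L)))
  expect_equal(parents[find(1L)], find(c(1L, 2L)))
  expect_equal(parents[find(2L)], find(c(1L, 2L)))
})

test_that("lineage tracking ignores cluster label identities", {
  p1 <- list(c(1L, 1L, 1L, 1L), c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L))
  p2 <- list(c(1L, 1L, 1L, 1L), c(2L, 2L, 1L, 1L), c(2L, 2L, 1L, 1L))
  l1 <- track_clusters(make_sweep(p1), toy_cfg())
  l2 <- track_clusters(make_sweep(p2), toy_cfg())
  strip <- function(ls) lapply(ls$lineages, function(l)
    l[c("members", "parent", "birth_idx", "last_idx")])
  expect_identical(strip(l1), strip(l2))
})

test_that("singleton flicker does not break a lineage", {
  # one member drops out for two steps and returns; same lineage throughout
  base <- rep(1L, 6)
  flick <- c(1L, 1L, 1L, 1L, 1L, 2L)
  sw <- make_sweep(list(base, base, flick, flick, base, base))
  lin <- track_clusters(sw, tree_config(min_cluster_size = 2))
  expect_length(lin$lineages, 1)
  expect_equal(lin$lineages[[1]]$lifetime, 0.005)
})

test_that("stability is a clipped lifetime ratio", {
  expect_equal(stability(30, 45), 2 / 3, tolerance = 1e-12)
  expect_equal(stability(45, 45), 1)
  expect_equal(stability(90, 45), 1)  # clipped
  expect_equal(stability(list(lifetime = 5), list(lifetime = 10)), 0.5)
  expect_error(stability(1, 0), "zero lifetime")
})

test_that("natural clusters are the deepest stable nodes", {
  # root (20 pts) holds 5 steps, splits into 12 + 8 that persist 30 steps,
  # then everything is singletons
  n <- 20
  root_p <- rep(1L, n)
  split_p <- c(rep(1L, 12), rep(2L, 8))
  singl_p <- seq_len(n)
  parts <- c(rep(list(root_p), 5), rep(list(split_p), 30), rep(list(singl_p), 5))
  sw <- make_sweep(parts)
  lin <- track_clusters(sw, tree_config())
  tree <- extract_natural_clusters(lin, tree_config())

  expect_equal(tree$root$id, "0")
  expect_equal(tree$root$size, n)
  expect_false(tree$root$is_natural)
  kids <- tree$root$children
  expect_length(kids, 2)
  expect_equal(kids[[1]]$id, "1")
  expect_equal(kids[[1]]$size, 12)  # children ordered by size
  expect_equal(kids[[2]]$size, 8)
  expect_true(kids[[1]]$is_natural)
  expect_true(kids[[2]]$is_natural)

  # natural clusters partition their union; residual is disjoint
  nat <- natural_clusters(tree)
  all_m <- unlist(lapply(nat, `[[`, "members"))
  expect_false(any(duplicated(all_m)))
  part <- natural_leaf_partition(tree)
  expect_length(part, n)
  expect_equal(sort(unique(part[1:12])), part[1])
})

test_that("an unsplit root yields a single node and no natural clusters", {
  sw <- make_sweep(rep(list(rep(1L, 8)), 12))
  tree <- extract_natural_clusters(track_clusters(sw, tree_config()), tree_config())
  expect_length(tree$root$children, 0)
  expect_length(natural_clusters(tree), 0)
})

test_that("hierarchical ids are consistent with parentage", {
  # 24 -> {12, 12}; first 12 -> {8, 4}; all pieces persist
  n <- 24
  p1 <- rep(1L, n)
  p2 <- rep(c(1L, 2L), each = 12)
  p3 <- c(rep(1L, 8), rep(3L, 4), rep(2L, 12))
  parts <- c(rep(list(p1), 5), rep(list(p2), 10), rep(list(p3), 20),
             list(seq_len(n)))
  tree <- extract_natural_clusters(track_clusters(make_sweep(parts), tree_config()),
                                   tree_config())
  ids <- vapply(flatten_tree_for_test(tree), `[[`, character(1), "id")
  expect_true(all(c("0", "1", "2", "1 1", "1 2") %in% ids))
  node1 <- tree$root$children[[1]]
  expect_equal(node1$id, "1")
  expect_equal(vapply(node1$children, `[[`, character(1), "id"), c("1 1", "1 2"))
  expect_equal(node1$children[[1]]$size, 8)
  expect_true(all(node1$children[[1]]$members %in% node1$members))
})

test_that("tree_config validates its parameters", {
  expect_error(tree_config(s_theta = 0), "s_theta")
  expect_error(tree_config(match_jaccard = 1.2), "match_jaccard")
  expect_error(tree_config(min_cluster_size = 0), "min_cluster_size")
  expect_error(tree_config(persistence = 0), "persistence")
})

test_that("membership_report flattens the tree with composition counts", {
  n <- 12
  parts <- c(rep(list(rep(1L, n)), 4),
             rep(list(rep(c(1L, 2L), each = 6)), 10),
             list(seq_len(n)))
  tree <- extract_natural_clusters(track_clusters(make_sweep(parts), tree_config()),
                                   tree_config())
  labs <- rep(c("x", "y"), each = 6)
  rep_df <- membership_report(tree, labs)
  expect_setequal(c("id", "size", "t_ferro", "t_cl", "s_t", "is_natural",
                    "members", "n_x", "n_y"), names(rep_df))
  expect_equal(rep_df$n_x[rep_df$id == "0"], 6)
  expect_equal(rep_df$size[rep_df$id == "1"], 6)
  # composition columns omitted without labels
  expect_false(any(grepl("^n_", names(membership_report(tree)))))
})
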