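# Independent oracles used across tests: exact Boltzmann enumeration for
# tiny Potts systems, brute-force graph algorithms, and a constructor for
# hand-made sweeps.

# exact thermal averages of a q-state Potts system by full enumeration
potts_exact <- function(graph, q, temperature) {
  n <- graph$n
  edges <- graph$edges
  states <- as.matrix(expand.grid(rep(list(seq_len(q)), n)))
  energy <- apply(states, 1, function(s) sum(edges$J[s[edges$i] != s[edges$j]]))
  w <- exp(-energy / temperature)
  w <- w / sum(w)
  e_delta <- vapply(seq_len(nrow(edges)), function(e)
    sum(w * (states[, edges$i[e]] == states[, edges$j[e]])), numeric(1))
  m_of <- function(s) {
    n_max <- max(tabulate(s, nbins = q))
    (q * n_max - n) / ((q - 1) * n)
  }
  m <- apply(states, 1, m_of)
  e_m <- sum(w * m)
  e_m2 <- sum(w * m^2)
  list(delta = e_delta, m = e_m, m2 = e_m2,
       chi = (n / temperature) * (e_m2 - e_m^2))
}

# batched SW estimates with batch-mean standard errors; the chain is
# carried across batches after one burn-in run
potts_mc_batches <- function(graph, q, temperature, n_batches = 40L,
                             batch_len = 500L, burnin = 500L) {
  cfg0 <- potts_config(q = q, n_sweeps = burnin + batch_len, n_burnin = burnin)
  pt <- estimate_correlations(graph, temperature, cfg0)
  g <- matrix(NA_real_, n_batches, nrow(graph$edges))
  m <- chi <- numeric(n_batches)
  g[1, ] <- pt$g
  m[1] <- mean(pt$m)
  chi[1] <- pt$chi
  cfgb <- potts_config(q = q, n_sweeps = batch_len, n_burnin = 0L)
  for (b in 2:n_batches) {
    pt <- estimate_correlations(graph, temperature, cfgb, state = pt$state)
    g[b, ] <- pt$g
    m[b] <- mean(pt$m)
    chi[b] <- pt$chi
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  list(g = colMeans(g), g_se = apply(g, 2, se),
       m = mean(m), m_se = se(m),
       chi = mean(chi), chi_se = se(chi))
}

# 4-node path with unit couplings
path4_graph <- function() coupling_graph_from_edges(4, 1:3, 2:4, rep(1, 3))

# brute-force connected components of a thresholded edge set
components_oracle <- function(n, i, j, keep) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (e in which(keep)) {
      a <- comp[i[e]]; b <- comp[j[e]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# wrap a list of membership vectors into a minimal spc_sweep object
make_sweep <- function(partitions, temps = seq_along(partitions) * 0.001) {
  points <- lapply(seq_along(partitions), function(t)
    structure(list(T = temps[t], partition = as.integer(partitions[[t]]),
                   chi = 0, g = numeric(0), m = numeric(0)),
              class = "sweep_point"))
  summary <- data.frame(
    T = temps,
    chi = 0,
    n_clusters = vapply(partitions, max, numeric(1)),
    largest_cluster_size = vapply(partitions, function(p) max(tabulate(p)), numeric(1)))
  structure(list(points = points, summary = summary,
                 t_step = if (length(temps) > 1) diff(temps[1:2]) else 0.001),
            class = "spc_sweep")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
flatten_tree_for_test <- function(tree) ramanspc:::flatten_tree(tree)
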