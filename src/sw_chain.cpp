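#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving
static inline int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static inline void uf_union(std::vector<int> &parent, std::vector<int> &rank_,
                            int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a == b) return;
  if (rank_[a] < rank_[b]) std::swap(a, b);
  parent[b] = a;
  if (rank_[a] == rank_[b]) rank_[a]++;
}

// Swendsen-Wang chain at fixed temperature.
//
// One sweep: freeze each satisfied edge (s_i == s_j) with probability
// p_ij = 1 - exp(-J_ij / T); form connected components of frozen edges
// (the SW clusters); assign each component a fresh uniform label in 1..q.
//
// After n_burnin sweeps, each retained sweep accumulates
//   co_count[e]    - i, j in the same SW cluster (variance-reduced
//                    correlation estimator),
//   delta_count[e] - s_i == s_j in the new state (plain estimator),
//   m[t]           - magnetization (q*N_max - N) / ((q-1)*N) with N_max the
//                    size of the largest spin-value class of the new state.
//
// Uses R's RNG stream, so set.seed() makes runs reproducible.
// [[Rcpp::export(name = ".sw_chain_cpp")]]
List sw_chain_cpp(int n, IntegerVector edge_i, IntegerVector edge_j,
                  NumericVector J, int q, double temperature,
                  int n_sweeps, int n_burnin, IntegerVector init_state) {
  if (temperature <= 0.0) stop("sw_chain: temperature must be > 0");
  if (q < 2) stop("sw_chain: q must be >= 2");
  const int m_edges = edge_i.size();
  if (edge_j.size() != m_edges || J.size() != m_edges)
    stop("sw_chain: edge vectors must have equal length");
  if (init_state.size() != n) stop("sw_chain: init_state must have length n");

  std::vector<int> s(n);
  for (int v = 0; v < n; ++v) {
    s[v] = init_state[v];
    if (s[v] < 1 || s[v] > q) stop("sw_chain: spin labels must lie in 1..q");
  }

  std::vector<double> p(m_edges);
  for (int e = 0; e < m_edges; ++e)
    p[e] = 1.0 - std::exp(-J[e] / temperature);

  const int n_keep = n_sweeps - n_burnin;
  if (n_keep < 0) stop("sw_chain: n_sweeps must be >= n_burnin");

  IntegerVector co_count(m_edges), delta_count(m_edges);
  NumericVector m_samples(n_keep);
  std::vector<int> parent(n), rank_(n), comp_label(n), label_count(q + 1);

  RNGScope scope;
  for (int t = 0; t < n_sweeps; ++t) {
    for (int v = 0; v < n; ++v) { parent[v] = v; rank_[v] = 0; }
    for (int e = 0; e < m_edges; ++e) {
      const int a = edge_i[e] - 1, b = edge_j[e] - 1;
      if (s[a] == s[b] && unif_rand() < p[e])
        uf_union(parent, rank_, a, b);
    }
    // fresh uniform label per SW cluster
    std::fill(comp_label.begin(), comp_label.end(), 0);
    for (int v = 0; v < n; ++v) {
      const int r = uf_find(parent, v);
      if (comp_label[r] == 0) {
        int lab = 1 + (int)(unif_rand() * q);
        if (lab > q) lab = q;  // guard against unif_rand() == 1.0
        comp_label[r] = lab;
      }
      s[v] = comp_label[r];
    }
    if (t >= n_burnin) {
      const int k = t - n_burnin;
      for (int e = 0; e < m_edges; ++e) {
        const int a = edge_i[e] - 1, b = edge_j[e] - 1;
        if (uf_find(parent, a) == uf_find(parent, b)) co_count[e]++;
        if (s[a] == s[b]) delta_count[e]++;
      }
      std::fill(label_count.begin(), label_count.end(), 0);
      int n_max = 0;
      for (int v = 0; v < n; ++v) {
        const int c = ++label_count[s[v]];
        if (c > n_max) n_max = c;
      }
      m_samples[k] = ((double)q * n_max - n) / (((double)q - 1.0) * n);
    }
  }

  IntegerVector final_state(n);
  for (int v = 0; v < n; ++v) final_state[v] = s[v];
  return List::create(_["co_count"] = co_count,
                      _["delta_count"] = delta_count,
                      _["m"] = m_samples,
                      _["state"] = final_state,
                      _["n_kept"] = n_keep);
}
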