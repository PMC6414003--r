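# Memoized synthetic cohorts shared across test files (simulation and the
# temperature sweep are the expensive steps; build each once).

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# 30-spectrum, 3-class, 3-patients-per-class design used throughout
demo_config <- function(seed = 7001L, ...) {
  sim_config(n_spectra_per_class = c(breast = 10L, cervical = 10L, leukemia = 10L),
             n_patients_per_class = c(breast = 3L, cervical = 3L, leukemia = 3L),
             seed = seed, ...)
}

demo_cohort <- function() memo("demo_cohort", simulate_cohort(demo_config()))

demo_processed <- function() memo("demo_processed", preprocess_cohort(demo_cohort()))

demo_labels <- function()
  vapply(demo_processed(), function(s) s$class_label, character(1))

demo_graph <- function() memo("demo_graph", {
  spc_graph(distance_matrix(build_matrix(demo_processed())), k = 10)
})

demo_sweep <- function() memo("demo_sweep", {
  temperature_sweep(demo_graph(), potts_config(seed = 42))
})

demo_tree <- function() memo("demo_tree", {
  extract_natural_clusters(track_clusters(demo_sweep()))
})

# noise-free spectra of a given class (band structure only)
noiseless_config <- function(n = 10L, seed = 1L) {
  sim_config(n_spectra_per_class = c(breast = n, cervical = n, leukemia = n),
             n_patients_per_class = c(breast = 2L, cervical = 2L, leukemia = 2L),
             noise_sd = 0, spike_rate = 0, baseline_scale = 0,
             patient_effect_sd = 0, seed = seed)
}
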