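test_that("default templates encode the class-specific band patterns", {
  tpl <- default_templates()
  expect_named(tpl, c("breast", "cervical", "leukemia"))

  for (t in tpl) {
    amp <- effective_amplitudes(t)
    # the 1002 cm^-1 phenylalanine band is the global maximum everywhere
    expect_equal(t$bands$center[which.max(amp)], 1002)
    # every suppression window hits at least one shared band
    if (nrow(t$suppressed)) {
      for (r in seq_len(nrow(t$suppressed)))
        expect_true(any(t$bands$center >= t$suppressed$lo[r] &
                          t$bands$center <= t$suppressed$hi[r]))
    }
  }

  # leukemia: amide I fully absent
  leuk <- effective_amplitudes(tpl$leukemia)
  expect_equal(leuk[tpl$leukemia$bands$center == 1654], 0)
  # breast: bulged 1040-1100 region strictly below the other two classes
  sel <- tpl$breast$bands$center >= 1040 & tpl$breast$bands$center <= 1100
  expect_true(all(effective_amplitudes(tpl$breast)[sel] <
                    effective_amplitudes(tpl$cervical)[sel]))
  expect_true(all(effective_amplitudes(tpl$breast)[sel] <
                    effective_amplitudes(tpl$leukemia)[sel]))
  # cervical: polysaccharide 714 attenuated relative to breast
  i714 <- tpl$breast$bands$center == 714
  expect_lt(effective_amplitudes(tpl$cervical)[i714],
            effective_amplitudes(tpl$breast)[i714])
})

test_that("template validation rejects malformed bands", {
  bands <- data.frame(center = 1000, width = 8, amplitude = 1, assignment = "x")
  expect_error(class_template("t", transform(bands, width = 0)), "width")
  expect_error(class_template("t", transform(bands, amplitude = -1)), "amplitude")
  expect_error(class_template("t", transform(bands, center = 200)), "center")
  expect_error(class_template("t", bands,
                              data.frame(lo = 990, hi = 1010, factor = 2)),
               "factor")
})

test_that("noise-free simulation equals the pure band superposition", {
  cfg <- noiseless_config()
  tpl <- default_templates()$breast
  s <- simulate_spectrum(tpl, "p1", cfg)
  wn <- seq(cfg$wn_min, cfg$wn_max, length.out = cfg$n_points)
  amp <- effective_amplitudes(tpl)
  manual <- rowSums(sapply(seq_along(amp), function(b) {
    hw2 <- (tpl$bands$width[b] / 2)^2
    amp[b] * hw2 / ((wn - tpl$bands$center[b])^2 + hw2)
  }))
  expect_equal(s$intensity, manual, tolerance = 1e-12)
  expect_equal(s$wavenumber, wn)
})

test_that("simulated spectra live on the configured grid and are non-negative", {
  s <- simulate_spectrum(default_templates()$cervical, "p1", sim_config(seed = 3))
  expect_length(s$intensity, 2330)
  expect_equal(range(s$wavenumber), c(400, 1800))
  expect_true(all(is.finite(s$intensity)))
  expect_true(all(s$intensity >= 0))
})

test_that("cohort simulation is deterministic and matches the reference design", {
  cfg <- demo_config(seed = 11L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  # class blocks in order, 1-based indices, shared grid
  classes <- vapply(a, function(s) s$class_label, character(1))
  expect_equal(classes, rep(c("breast", "cervical", "leukemia"), each = 10))
  expect_equal(vapply(a, function(s) s$cohort_index, numeric(1)), 1:30)
  g <- a[[1]]$wavenumber
  for (s in a) expect_identical(s$wavenumber, g)

  # patients partition each class near-evenly
  pats <- vapply(a[1:10], function(s) s$patient_id, character(1))
  expect_true(max(table(pats)) - min(table(pats)) <= 1)
  expect_length(unique(pats), 3)
})

test_that("minimal cohort has one spectrum per class", {
  cfg <- sim_config(n_spectra_per_class = c(1L, 1L, 1L),
                    n_patients_per_class = c(1L, 1L, 1L), seed = 2)
  coh <- simulate_cohort(cfg)
  expect_length(coh, 3)
  expect_setequal(vapply(coh, function(s) s$class_label, character(1)),
                  c("breast", "cervical", "leukemia"))
})

test_that("preprocessed cohort separates classes in Euclidean distance", {
  d <- distance_matrix(build_matrix(demo_processed()))
  same <- outer(demo_labels(), demo_labels(), "==") & upper.tri(d)
  diff <- outer(demo_labels(), demo_labels(), "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff]))
})

test_that("simulation config validation catches bad inputs", {
  expect_error(sim_config(n_points = 1), "n_points")
  expect_error(sim_config(wn_min = 1800, wn_max = 400), "wn_min")
  expect_error(sim_config(n_spectra_per_class = c(10L, 0L, 10L)), "counts")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
})

test_that("cohort CSV writers round-trip both layouts", {
  cfg <- sim_config(n_points = 50L, n_spectra_per_class = c(2L, 1L, 1L),
                    n_patients_per_class = c(1L, 1L, 1L), seed = 5)
  coh <- simulate_cohort(cfg)
  for (wide in c(FALSE, TRUE)) {
    dir <- withr::local_tempdir()
    write_cohort_csv(coh, dir, wide = wide)
    back <- read_cohort_csv(dir)
    expect_length(back, 4)
    for (i in seq_along(coh)) {
      expect_equal(back[[i]]$intensity, coh[[i]]$intensity, tolerance = 1e-12)
      expect_equal(back[[i]]$class_label, coh[[i]]$class_label)
    }
  }
})
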