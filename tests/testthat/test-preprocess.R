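grid_400_1800 <- function(n = 500) seq(400, 1800, length.out = n)

test_that("baseline correction annihilates a pure polynomial background", {
  x <- grid_400_1800()
  xs <- (x - mean(x)) / diff(range(x))
  poly5 <- 3 + 2 * xs - 5 * xs^2 + xs^3 + 0.5 * xs^4 - 2 * xs^5
  s <- spectrum(x, poly5 - min(poly5) + 1)
  out <- correct_baseline(s, degree = 5)
  expect_lt(max(abs(out$intensity)), 1e-6 * diff(range(s$intensity)))
})

test_that("baseline correction recovers an injected peak on a polynomial", {
  x <- grid_400_1800(1000)
  xs <- (x - mean(x)) / diff(range(x))
  base <- 2 + xs - 0.5 * xs^2 + 0.2 * xs^5
  peak <- 0.8 * (4^2) / ((x - 1002)^2 + 4^2)  # Lorentzian, FWHM 8, height 0.8
  s <- spectrum(x, base + peak)
  out <- correct_baseline(s, degree = 5)
  got <- out$intensity[which.min(abs(x - 1002))]
  expect_lt(abs(got - 0.8) / 0.8, 0.05)
})

test_that("degree-0 correction removes a constant spectrum entirely", {
  s <- spectrum(1:100, rep(7, 100))
  expect_equal(correct_baseline(s, degree = 0)$intensity, rep(0, 100),
               tolerance = 1e-10)
  expect_error(correct_baseline(spectrum(1:3, 1:3), degree = 5), "shorter")
})

test_that("Savitzky-Golay reproduces polynomials up to its order exactly", {
  x <- seq_len(200)
  quad <- 5 + 0.3 * x - 0.002 * x^2
  out <- sg_smooth(spectrum(x, quad), polyorder = 2, window = 11)
  expect_equal(out$intensity, quad, tolerance = 1e-9)
})

test_that("Savitzky-Golay attenuates a cosmic spike as the impulse response predicts", {
  # analytic central coefficient of the quadratic SG smoother,
  # h0 = 3(3m^2 + 3m - 1) / ((2m+3)(2m+1)(2m-1)) with m = 5 for window 11
  m <- 5
  h0 <- 3 * (3 * m^2 + 3 * m - 1) / ((2 * m + 3) * (2 * m + 1) * (2 * m - 1))
  y <- rep(0, 201)
  y[101] <- 1
  out <- sg_smooth(spectrum(1:201, y), polyorder = 2, window = 11)
  expect_equal(out$intensity[101], h0, tolerance = 1e-10)
  expect_gt(1 - out$intensity[101], 0.6)  # >= 60% amplitude reduction
})

test_that("Savitzky-Golay rejects invalid windows", {
  s <- spectrum(1:50, rnorm(50))
  expect_error(sg_smooth(s, window = 1), "window")
  expect_error(sg_smooth(s, window = 10), "window")
  expect_error(preprocess_config(sg_window = 1), "sg_window")
})

test_that("normalization pins the 1002 band at 1 and is idempotent", {
  x <- grid_400_1800()
  y <- 0.4 + 2.5 * exp(-(x - 1002)^2 / 50) + 0.5 * exp(-(x - 1447)^2 / 50)
  s <- normalize_spectrum(spectrum(x, y))
  win <- abs(s$wavenumber - 1002) <= 5
  expect_equal(max(s$intensity[win]), 1)
  again <- normalize_spectrum(s)
  expect_equal(again$intensity, s$intensity)
  expect_error(normalize_spectrum(spectrum(x, rep(0, length(x)))), "degenerate")
})

test_that("mean spectrum is the pointwise average", {
  x <- 1:50
  a <- spectrum(x, rnorm(50))
  expect_equal(mean_spectrum(list(a))$intensity, a$intensity)
  b <- spectrum(x, -a$intensity + 6)
  expect_equal(mean_spectrum(list(a, b))$intensity, rep(3, 50))
  expect_error(mean_spectrum(list(a, spectrum(1:49, rnorm(49)))), "grid")
  expect_error(mean_spectrum(list()), "empty")
})

test_that("suppressed leukemia amide I is near-absent in the mean spectrum", {
  cfg <- noiseless_config()
  coh <- simulate_cohort(cfg)
  leuk <- coh[vapply(coh, function(s) s$class_label, character(1)) == "leukemia"]
  m <- normalize_spectrum(mean_spectrum(leuk))
  at <- function(s, wn) s$intensity[which.min(abs(s$wavenumber - wn))]
  expect_lt(at(m, 1654), 0.15 * at(m, 1002))
})

test_that("band annotation covers the 21-entry catalog and tracks suppression", {
  cat21 <- band_catalog()
  expect_equal(nrow(cat21), 21)
  expect_setequal(unique(cat21$assignment),
                  c("tryptophan", "phenylalanine", "tyrosine", "polysaccharides",
                    "skeletal str alpha", "beta-carotene", "amide III",
                    "phospholipid", "amide I"))

  cfg <- noiseless_config()
  coh <- simulate_cohort(cfg)
  cls <- vapply(coh, function(s) s$class_label, character(1))
  means <- lapply(split(coh, cls), function(g) normalize_spectrum(mean_spectrum(g)))
  ann <- lapply(means, annotate_bands)
  for (a in ann) expect_equal(a$intensity[a$band == 1002], 1, tolerance = 1e-9)
  i714 <- which(ann$breast$band == 714)
  expect_lt(ann$cervical$intensity[i714], ann$breast$intensity[i714])
})

test_that("the full pipeline is near-idempotent and scale-invariant", {
  cfg <- demo_config(seed = 31L)
  s <- simulate_cohort(cfg)[[4]]
  p1 <- preprocess_spectrum(s)
  p2 <- preprocess_spectrum(p1)
  # a second pass may change the spectrum by no more than the effect of
  # smoothing an already-smooth signal (plus its renormalization), which
  # for Lorentzian bands of ~13-point FWHM under an 11-point window is a
  # small peak-top bite; everything else (baseline, normalization) is a
  # near-no-op
  delta_smooth <- max(abs(sg_smooth(p1)$intensity - p1$intensity))
  expect_lt(max(abs(p2$intensity - p1$intensity)), 3 * delta_smooth + 1e-3)
  expect_lt(max(abs(p2$intensity - p1$intensity)), 0.03)

  scaled <- preprocess_spectrum(spectrum(s$wavenumber, 17.3 * s$intensity))
  expect_equal(scaled$intensity, p1$intensity, tolerance = 1e-9)
})
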