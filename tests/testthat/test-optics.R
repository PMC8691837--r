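test_that("illumination patterns are Bernoulli and reproducible", {
  p <- generate_pattern(128L, 32L, 0.5, seed = 4)
  expect_equal(dim(p$mask), c(128L, 32L))
  expect_true(all(p$mask %in% c(0, 1)))
  expect_lt(abs(mean(p$mask) - 0.5), 0.05)

  dense <- generate_pattern(64L, 64L, 0.999, seed = 4)
  expect_gt(mean(dense$mask), 0.99)

  expect_identical(generate_pattern(32L, 8L, 0.3, seed = 9)$mask,
                   generate_pattern(32L, 8L, 0.3, seed = 9)$mask)
  expect_error(generate_pattern(32L, 8L, 0), "fill_fraction")
  expect_error(generate_pattern(32L, 8L, 1), "fill_fraction")
})

test_that("gmi_waveform equals the hand-computed traversal examples", {
  cfg <- modality_config("dGMI")
  p1 <- pattern_from_mask(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(gmi_waveform(matrix(c(1, 2), 1, 2), p1, cfg)$samples,
               c(1, 2))
  p2 <- pattern_from_mask(matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE))
  expect_equal(gmi_waveform(matrix(c(2, 3), 1, 2), p2, cfg)$samples,
               c(5, 2))
  # all-zero object: background only
  cfg_bg <- modality_config("dGMI", background = 1.5)
  expect_equal(gmi_waveform(matrix(0, 3, 2), p2, cfg_bg)$samples,
               rep(1.5, 4))
  # lateral overflow refused
  expect_error(gmi_waveform(matrix(1, 1, 5), p2, cfg), "lateral")
})

test_that("gmi_waveform matches the brute-force oracle on random cases", {
  set.seed(71)
  for (case in 1:50) {
    f <- sample(2:16, 1); wm <- sample(1:16, 1)
    h <- sample(1:16, 1); w <- sample(1:16, 1)
    w <- min(w, wm)
    mask <- matrix(rbinom(f * wm, 1, 0.5), f, wm)
    map <- matrix(runif(h * w), h, w)
    got <- gmi_waveform(map, pattern_from_mask(mask),
                        modality_config("dGMI"))$samples
    want <- oracle_waveform(map, mask)
    expect_lt(max(abs(got - want)) / max(max(abs(want)), 1e-12), 1e-9)
  }
})

test_that("the forward model is linear and shift-equivariant", {
  set.seed(72)
  mask <- matrix(rbinom(20 * 6, 1, 0.5), 20, 6)
  pat <- pattern_from_mask(mask)
  cfg <- modality_config("dGMI")
  m1 <- matrix(runif(5 * 6), 5, 6)
  m2 <- matrix(runif(5 * 6), 5, 6)
  lhs <- gmi_waveform(2 * m1 + 3 * m2, pat, cfg)$samples
  rhs <- 2 * gmi_waveform(m1, pat, cfg)$samples +
    3 * gmi_waveform(m2, pat, cfg)$samples
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  # translating the object k pixels along the flow axis shifts the
  # waveform by exactly k samples
  k <- 3L
  big <- matrix(0, 5 + k, 6)
  big[1:5, ] <- m1
  shifted <- matrix(0, 5 + k, 6)
  shifted[k + (1:5), ] <- m1
  a <- gmi_waveform(big, pat, cfg)$samples
  b <- gmi_waveform(shifted, pat, cfg)$samples
  expect_equal(b[1:(length(b) - k)], a[(k + 1):length(a)])

  # an all-ones mask longer than the object plateaus at the map total
  ones <- pattern_from_mask(matrix(1, 30, 6))
  wf <- gmi_waveform(m1, ones, cfg)$samples
  inside <- wf[5:30]          # object fully inside the mask
  expect_true(all(abs(inside - sum(m1)) < 1e-9))
})

test_that("scalar channels reflect size and granularity totals", {
  # uniform 5x5 map: FSC pulse area equals the map total
  ph <- make_phantom(morphology_params(diameter = 10), pitch = 1,
                     shape = c(24L, 24L), seed = 1)
  ph$contrast_maps$transmission <- matrix(1, 5, 5)
  sc <- scalar_channels(ph, ssc_gain = 1, bsc_gain = 1)
  expect_equal(sum(sc$fsc_pulse$samples), 25)

  small <- make_phantom(morphology_params(diameter = 8),
                        shape = c(64L, 32L), seed = 5)
  large <- make_phantom(morphology_params(diameter = 16),
                        shape = c(64L, 32L), seed = 5)
  expect_gt(sum(scalar_channels(large)$fsc_pulse$samples),
            sum(scalar_channels(small)$fsc_pulse$samples))

  ph$contrast_maps$scatter <- matrix(0, 5, 5)
  z <- scalar_channels(ph)
  expect_equal(z$ssc, 0)
  expect_equal(z$bsc, 0)
})

test_that("fluorescence intensity is a linear gain on the stain total", {
  mp <- morphology_params(diameter = 10)
  none <- make_phantom(mp, shape = c(40L, 32L), seed = 2,
                       stain_amounts = c(green = 0))
  expect_equal(fluorescence_intensity(none, "green"), 0)

  one <- make_phantom(mp, shape = c(40L, 32L), seed = 2,
                      stain_amounts = c(green = 3))
  two <- make_phantom(mp, shape = c(40L, 32L), seed = 2,
                      stain_amounts = c(green = 6))
  expect_equal(fluorescence_intensity(two, "green"),
               2 * fluorescence_intensity(one, "green"))

  ph <- none
  ph$fluorescence_maps$green <- matrix(1, 3, 3)
  expect_equal(fluorescence_intensity(ph, "green", gain = 2), 18)
  expect_error(fluorescence_intensity(ph, "red"), "unknown")
})

test_that("the noise model is seeded shot + read noise", {
  s <- raw_signal(rep(100, 1e4))
  expect_identical(add_noise(s, noise_model(0, 0))$samples, s$samples)

  shot <- add_noise(s, noise_model(shot_scale = 1, read_sigma = 0,
                                   seed = 5))
  expect_lt(abs(mean(shot$samples) - 100), 3)   # Poisson CLT bound

  a <- add_noise(s, noise_model(1, 0.5, seed = 9))
  b <- add_noise(s, noise_model(1, 0.5, seed = 9))
  expect_identical(a$samples, b$samples)

  expect_error(add_noise(raw_signal(c(-1, 1)), noise_model(1, 0)),
               "nonnegative")
})

test_that("patterns round-trip through CSV export", {
  p <- generate_pattern(16L, 8L, 0.4, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pattern_csv(p, path)
  q <- read_pattern_csv(path)
  expect_equal(q$mask, p$mask)
})
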