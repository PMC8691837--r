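test_that("phantom geometry follows the morphology parameters", {
  # smooth cell: no texture, no blebbing -> flat within-support maps
  p <- make_phantom(morphology_params(diameter = 10, granularity = 0,
                                      membrane_irregularity = 0),
                    pitch = 1, shape = c(24L, 24L), seed = 3)
  sc <- p$contrast_maps$scatter
  inside <- sc[sc > 0]
  expect_lt(stats::sd(inside) / mean(inside), 0.05)

  # support major axis ~ diameter / pitch pixels along the flow axis
  tx <- p$contrast_maps$transmission
  rows_occupied <- sum(rowSums(tx) > 0)
  expect_gte(rows_occupied, 9)
  expect_lte(rows_occupied, 11)

  # unstained channel renders an all-zero fluorescence map
  expect_true(all(p$fluorescence_maps$green == 0))
  p2 <- make_phantom(morphology_params(diameter = 10), pitch = 1,
                     shape = c(24L, 24L), seed = 3,
                     stain_amounts = c(green = 5))
  expect_true(any(p2$fluorescence_maps$green > 0))

  # geometry overflow is an error, not a silent crop
  expect_error(make_phantom(morphology_params(diameter = 30), pitch = 1,
                            shape = c(16L, 16L)),
               "does not fit")
})

test_that("phantoms are deterministic and texture responds to granularity", {
  mp <- morphology_params(diameter = 10, granularity = 0.8)
  a <- make_phantom(mp, shape = c(40L, 32L), seed = 11)
  b <- make_phantom(mp, shape = c(40L, 32L), seed = 11)
  expect_identical(a, b)

  smooth <- make_phantom(morphology_params(diameter = 10,
                                           granularity = 0.1),
                         shape = c(40L, 32L), seed = 11)
  rough <- make_phantom(morphology_params(diameter = 10,
                                          granularity = 1.2),
                        shape = c(40L, 32L), seed = 11)
  cv <- function(m) {
    v <- m[m > 0]
    stats::sd(v) / mean(v)
  }
  expect_gt(cv(rough$contrast_maps$scatter),
            cv(smooth$contrast_maps$scatter))
})

test_that("expected total fluorescence increases with stain amount", {
  mp <- morphology_params(diameter = 10)
  totals <- vapply(c(1, 5, 20), function(s) {
    p <- make_phantom(mp, shape = c(40L, 32L), seed = 2,
                      stain_amounts = c(green = s))
    sum(p$fluorescence_maps$green)
  }, 0)
  expect_true(all(diff(totals) > 0))
})

test_that("population sampling is multinomial, labeled and reproducible", {
  mp <- morphology_params(diameter = 8)
  two <- population_spec(list(
    class_spec("a", mp, fraction = 0.5),
    class_spec("b", mp, fraction = 0.5)), n_events = 1000L, seed = 7)

  draws <- vapply(seq_len(1000L), function(i) {
    ghostflow:::draw_event_params(two, i)$class_name
  }, "")
  counts <- table(draws)
  # binomial(1000, 1/2) tail: P(outside [400, 600]) < 1e-9
  expect_true(all(counts >= 400 & counts <= 600))

  all_a <- population_spec(list(
    class_spec("a", mp, fraction = 1),
    class_spec("b", mp, fraction = 0)), n_events = 50L, seed = 7)
  ph <- sample_population(all_a)
  expect_true(all(vapply(ph, `[[`, "", "true_class") == "a"))

  s1 <- sample_population(two, indices = 1:20)
  s2 <- sample_population(two, indices = 1:20)
  expect_identical(s1, s2)

  expect_error(population_spec(list(), n_events = 10L))
  expect_error(population_spec(list(class_spec("a", mp, fraction = 0.6),
                                    class_spec("b", mp, fraction = 0.6)),
                               n_events = 10L),
               "sum to 1")
})

test_that("batch effects shift the generated populations as declared", {
  spec <- population_spec(list(
    class_spec("a", morphology_params(diameter = 10, granularity = 0.4),
               sd_params = c(diameter = 0.5), fraction = 1)),
    n_events = 100L, seed = 21)

  ident <- apply_batch_effect(spec, batch_effect(), "donor2",
                              seed = spec$seed)
  expect_identical(ident$classes, spec$classes)
  expect_identical(ident$batch_id, "donor2")

  gained <- apply_batch_effect(spec, batch_effect(gain_scale = 2),
                               "donor2", seed = spec$seed)
  tot <- function(s) {
    mean(vapply(sample_population(s, 1:100), function(p) {
      sum(p$contrast_maps$transmission)
    }, 0))
  }
  ratio <- tot(gained) / tot(spec)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)

  drifted <- apply_batch_effect(spec,
                                batch_effect(morphology_drift =
                                               c(diameter = 2)),
                                "donor2", seed = spec$seed)
  area <- function(s) {
    mean(vapply(sample_population(s, 1:60), function(p) {
      sum(scalar_channels(p)$fsc_pulse$samples)
    }, 0))
  }
  expect_gt(area(drifted), area(spec))
})

test_that("viability states follow their cytological correlates", {
  spec <- viability_spec(n_events = 120L, seed = 401)
  ev <- simulate_events(spec)
  cls <- ev$info$true_class
  # dead cells: collapsed optical density -> weaker FSC pulses
  expect_lt(median(ev$scalars$fsc_area[cls == "dead"]),
            median(ev$scalars$fsc_area[cls == "live"]))
  # viability dyes label dead cells PI-positive, live cells PI-negative
  pi_lab <- threshold_label(ev, label_rule("pi", 500, "dead", "other"))
  expect_gt(mean((pi_lab == "dead") == (cls == "dead")), 0.95)
})

test_that("size-matched benchmark classes have overlapping FSC areas", {
  ev <- small_benchmark_events()
  a <- ev$scalars$fsc_area[ev$info$true_class == "smooth"]
  b <- ev$scalars$fsc_area[ev$info$true_class == "granular"]
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_lt(unname(ks$statistic), 0.1)
})
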