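# Synthetic multichannel events built from deterministic class templates:
# three sine/sawtooth/pulse shapes plus small Gaussian noise, trivially
# separable so training behavior can be asserted quickly.
template_events <- function(n_per_class, seed = 1, n_classes = 3,
                            sd = 0.1, labels = NULL) {
  l <- 32L
  t <- seq(0, 2 * pi, length.out = l)
  shapes <- list(sin(t) + 1, abs((t / pi) %% 2 - 1) * 2,
                 as.numeric(t > pi) * 2,
                 cos(2 * t) + 1, (t / (2 * pi))^2 * 2,
                 exp(-((t - pi) / 0.8)^2) * 2)
  n <- n_per_class * n_classes
  cls <- rep(paste0("k", seq_len(n_classes)), each = n_per_class)
  wf <- ghostflow:::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n), function(i) {
      k <- match(cls[i], unique(cls))
      shapes[[k]] + rnorm(l, 0, sd)
    }))
  })
  isgc_events(
    waveforms = list(dGMI = wf, bsGMI = wf[, rev(seq_len(l))]),
    scalars = data.frame(fsc_height = rep(1, n), fsc_width = 1,
                         fsc_area = rowSums(wf), ssc = 1,
                         bsc = rowMeans(wf)),
    fluorescence = data.frame(green = numeric(n)),
    info = data.frame(event_id = seq_len(n),
                      true_class = if (is.null(labels)) cls else labels,
                      predicted_class = NA_character_,
                      batch_id = "batch1", stringsAsFactors = FALSE))
}

tiny_cnn_config <- function(n_classes, seed = 1, max_epochs = 60L,
                            patience = 15L) {
  cnn_config(n_classes = n_classes,
             modality_set = c("dGMI", "bsGMI"),
             scalar_set = c("fsc_area", "bsc"),
             max_epochs = max_epochs, patience = patience, seed = seed)
}

test_that("the network is built per the declared architecture", {
  cfg <- cnn_config(n_classes = 6)
  m <- build_cnn(cfg, segment_length = 128L)
  census <- layer_census(m)
  expect_equal(unname(census[c("conv", "batchnorm", "relu", "maxpool")]),
               rep(5L, 4))
  expect_equal(unname(census["fc"]), 1L)
  expect_equal(unname(census["softmax"]), 1L)

  # 128 / 2^5 = 4 temporal positions enter the flatten; scalars widen the
  # FC input by their count
  expect_equal(nrow(m$params$fc_w), 4 * 64 + 2)
  expect_equal(ncol(m$params$out_w), 6)

  expect_error(build_cnn(cnn_config(n_classes = 3), segment_length = 48L),
               "conv block")
})

test_that("prediction is a softmax with lowest-index tie-break", {
  ev <- template_events(5, seed = 2)
  cfg <- tiny_cnn_config(3)
  m <- build_cnn(cfg, segment_length = 32L)
  m$trained <- TRUE
  m$classes <- c("k1", "k2", "k3")
  xin <- ghostflow:::cnn_inputs(ev, cfg)
  m$normalizer <- xin$normalizer
  pr <- predict_cnn(m, ev)
  expect_equal(rowSums(pr$probs), rep(1, n_events(ev)), tolerance = 1e-6)

  # duplicate events predict identically
  expect_equal(pr$probs[1, ], predict_cnn(m, ev[c(1, 1)])$probs[2, ])

  # force uniform logits: zero softmax layer -> first class by tie-break
  m$params$out_w[] <- 0
  m$params$out_b[] <- 0
  pr0 <- predict_cnn(m, ev)
  expect_true(all(pr0$labels == "k1"))
  expect_equal(pr0$probs[1, ], c(k1 = 1, k2 = 1, k3 = 1) / 3,
               tolerance = 1e-12)
})

test_that("training separates template classes and early-stops", {
  ev <- template_events(30, seed = 3)
  lab <- ev$info$true_class
  sp <- fraction_split(lab, 0.7, seed = 1)
  cfg <- tiny_cnn_config(3, seed = 5)
  m <- train_cnn(ev[sp$train], ev[sp$test], cfg,
                 lab[sp$train], lab[sp$test])
  pr <- predict_cnn(m, ev[sp$test])
  res <- evaluate_multiclass(pr$labels, lab[sp$test])
  expect_equal(res$macro_f1, 1.0)
  # history recorded, best epoch corresponds to the minimum val loss
  expect_equal(m$history$val_loss[m$best_epoch],
               min(m$history$val_loss))
  # stagnant validation loss stops before max_epochs
  expect_lte(nrow(m$history), cfg$max_epochs)

  expect_error(train_cnn(ev[sp$train], ev[sp$test],
                         tiny_cnn_config(5), lab[sp$train],
                         lab[sp$test]),
               "classes")
})

test_that("permuted labels train to chance-level macro-F1", {
  ev <- template_events(30, seed = 7)
  perm <- ghostflow:::with_seed(99, sample(ev$info$true_class))
  sp <- fraction_split(perm, 0.7, seed = 2)
  cfg <- tiny_cnn_config(3, seed = 9, max_epochs = 30L, patience = 10L)
  m <- train_cnn(ev[sp$train], ev[sp$test], cfg, perm[sp$train],
                 perm[sp$test])
  pr <- predict_cnn(m, ev[sp$test])
  res <- evaluate_multiclass(pr$labels, perm[sp$test])
  expect_lt(res$macro_f1, 0.55)   # chance for K = 3 is ~ 1/3
})

test_that("multiclass metrics match hand computation", {
  perfect <- evaluate_multiclass(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(perfect$macro_f1, 1.0)
  expect_true(all(perfect$confusion == diag(3)))

  # binary confusion [[8,2],[3,7]]: F1 = 0.762 / 0.737, macro 0.749
  pred <- c(rep("x", 8), rep("y", 2), rep("x", 3), rep("y", 7))
  truth <- c(rep("x", 10), rep("y", 10))
  r <- evaluate_multiclass(pred, truth)
  expect_equal(r$macro_f1, 0.749, tolerance = 5e-4)
  expect_equal(unname(r$confusion["x", ]), c(8, 2))

  # a never-predicted class contributes F1 = 0
  r0 <- evaluate_multiclass(c("a", "a", "a"), c("a", "a", "b"))
  expect_equal(unname(r0$per_class_f1["b"]), 0)
  expect_error(evaluate_multiclass(character(0), character(0)), "empty")

  set.seed(48)
  for (case in 1:20) {
    k <- sample(2:5, 1)
    cm <- matrix(rpois(k * k, 3), k, k)
    rownames(cm) <- colnames(cm) <- paste0("c", seq_len(k))
    pred <- rep(rep(colnames(cm), k), as.vector(t(cm)))
    truth <- rep(rownames(cm), rowSums(cm))
    if (length(truth) == 0) next
    got <- evaluate_multiclass(pred, truth, classes = rownames(cm))
    expect_equal(got$macro_f1, oracle_macro_f1(cm))
  }
})

test_that("stratified cross-validation is balanced and picks best fold", {
  ev <- template_events(20, seed = 11)
  lab <- ev$info$true_class
  folds <- ghostflow:::stratified_folds(lab, 4, seed = 3)
  for (f in 1:4) {
    tab <- table(lab[folds == f])
    expect_true(all(abs(tab - 20 / 4) <= 1))
  }
  cv <- crossfold_eval(ev, tiny_cnn_config(3, seed = 13,
                                           max_epochs = 25L,
                                           patience = 8L), k = 3)
  expect_equal(cv$mean_f1, mean(cv$fold_f1))
  expect_equal(cv$best_fold, which.max(cv$fold_f1))
  expect_gt(cv$mean_f1, 0.95)   # trivially separable templates
  expect_error(crossfold_eval(ev, tiny_cnn_config(3), k = 50),
               "fewer members")
})

test_that("batch effects degrade inter-batch transfer", {
  ev_a <- template_events(25, seed = 15)
  # severe gain distortion on batch B's waveform channels
  ev_b <- template_events(25, seed = 16)
  for (m in names(ev_b$waveforms)) {
    ev_b$waveforms[[m]] <- ev_b$waveforms[[m]] * 3 + 1.5
  }
  ev_b$info$batch_id <- "batch2"
  cfg <- tiny_cnn_config(3, seed = 17, max_epochs = 30L, patience = 10L)
  tr <- transfer_eval(ev_a, ev_b, cfg)
  expect_lte(tr$inter, tr$intra)

  # matched batches transfer without loss
  ev_c <- template_events(25, seed = 18)
  tr2 <- transfer_eval(ev_a, ev_c, cfg)
  expect_lt(abs(tr2$intra - tr2$inter), 0.1)
})
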