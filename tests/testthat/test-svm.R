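test_that("featurize concatenates the declared blocks in order", {
  ev <- small_benchmark_events()
  expect_equal(ncol(featurize(ev, "dGMI")), 128)
  expect_equal(ncol(featurize(ev, c("dGMI", "ssGMI", "fsc_area", "ssc"))),
               258)
  expect_equal(ncol(featurize(ev, c("fsc_area", "ssc"))), 2)
  expect_error(featurize(ev, "nope"), "not found")

  x <- featurize(ev, c("fsc_area", "ssc"))
  nz <- fit_normalizer(x)
  xs <- featurize(ev, c("fsc_area", "ssc"), nz)
  expect_equal(colMeans(xs), c(0, 0), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(apply(xs, 2, sd), c(1, 1), ignore_attr = TRUE)
})

test_that("the grid-searched SVM separates blobs and is deterministic", {
  set.seed(41)
  n <- 100
  ev <- scalar_only_events(c(rnorm(n, 0), rnorm(n, 8)),
                           c(rnorm(n, 0), rnorm(n, 8)))
  lab <- rep(c("neg", "pos"), each = n)
  cfg <- svm_config(kernel = "linear", modality_set = c("fsc_area", "ssc"),
                    seed = 6)
  m <- train_svm(ev, lab, cfg, positive = "pos")
  expect_equal(roc_auc(svm_score(m, ev), lab, "pos")$auc, 1.0)

  m2 <- train_svm(ev, lab, cfg, positive = "pos")
  expect_identical(c(m$cost, m$gamma), c(m2$cost, m2$gamma))

  expect_error(train_svm(ev, rep("pos", 2 * n), cfg),
               "two classes")
})

test_that("permuted labels give chance-level inner-CV AUC", {
  set.seed(42)
  n <- 200
  ev <- scalar_only_events(rnorm(2 * n), rnorm(2 * n))
  lab <- sample(rep(c("a", "b"), each = n))
  cfg <- svm_config(kernel = "linear", C_grid = c(0.1, 1),
                    modality_set = c("fsc_area", "ssc"), seed = 8)
  m <- train_svm(ev, lab, cfg, positive = "b")
  expect_gte(m$cv_auc, 0.4)
  expect_lte(m$cv_auc, 0.6)
})

test_that("linear models export a scorer that reproduces svm_score", {
  set.seed(43)
  n <- 80
  ev <- scalar_only_events(c(rnorm(n, 0), rnorm(n, 3)),
                           c(rnorm(n, 0), rnorm(n, 3)))
  lab <- rep(c("neg", "pos"), each = n)
  cfg <- svm_config(kernel = "linear", modality_set = c("fsc_area", "ssc"),
                    seed = 6)
  m <- train_svm(ev, lab, cfg, positive = "pos")
  wb <- export_linear_scorer(m)
  expect_length(wb$weights, 2)
  x <- featurize(ev, c("fsc_area", "ssc"))
  manual <- as.numeric(x %*% wb$weights + wb$bias)
  expect_lt(max(abs(manual - svm_score(m, ev))), 1e-9)

  # scoring is order-invariant and monotone in a single feature
  perm <- sample(2 * n)
  expect_equal(svm_score(m, ev[perm]), svm_score(m, ev)[perm])
  probe <- scalar_only_events(seq(-2, 5, length.out = 20),
                              rep(1, 20))
  sc <- svm_score(m, probe)
  expect_true(all(diff(sc) > 0) || all(diff(sc) < 0))

  mr <- train_svm(ev, lab, svm_config(kernel = "rbf",
                                      C_grid = 1, gamma_grid = 0.1,
                                      modality_set = c("fsc_area", "ssc"),
                                      seed = 6), positive = "pos")
  expect_error(export_linear_scorer(mr), "linear")
})

test_that("ROC/AUC matches the pairwise Mann-Whitney oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  expect_equal(roc_auc(c(0.8, 0.2, 0.6, 0.4),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  expect_equal(roc_auc(c(0.5, 0.5), c(TRUE, FALSE))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), "both classes")

  set.seed(44)
  for (case in 1:30) {
    n <- sample(5:40, 1)
    scores <- round(rnorm(n), sample(0:2, 1))   # force ties sometimes
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_lt(abs(r$auc - oracle_auc(scores, labels)), 1e-12)
    expect_true(all(diff(r$roc$fpr) >= 0))
    expect_true(all(diff(r$roc$tpr) >= 0))
  }
})

test_that("mean ROC averaging and recovery interpolation are linear", {
  toy <- data.frame(fpr = c(0, 0.01, 1), tpr = c(0, 0.6, 1))
  expect_equal(recovery_at_fpr(toy, 0.01), 0.6)
  expect_equal(recovery_at_fpr(toy, 1), 1.0)
  expect_equal(recovery_at_fpr(toy, 0.505), 0.8)   # halfway interpolation

  grid <- seq(0, 1, length.out = 101)
  m <- mean_roc(list(toy, toy), grid)
  single <- mean_roc(list(toy), grid)
  expect_equal(m$tpr, single$tpr)
  expect_error(mean_roc(list()), "empty")
})

test_that("repeated evaluation reports both AUC summaries honestly", {
  set.seed(45)
  n <- 60
  # degenerate features: everything identical
  ev0 <- scalar_only_events(rep(1, 2 * n), rep(1, 2 * n))
  lab <- rep(c("a", "b"), each = n)
  cfg <- svm_config(kernel = "linear", C_grid = 1,
                    modality_set = c("fsc_area", "ssc"), n_trials = 3L,
                    seed = 2)
  r0 <- repeated_eval(ev0, lab, cfg, 20, 20, positive = "b")
  expect_lt(abs(r0$mean_auc - 0.5), 0.15)

  # perfectly separated classes
  ev1 <- scalar_only_events(c(rnorm(n, 0), rnorm(n, 30)),
                            c(rnorm(n, 0), rnorm(n, 30)))
  r1 <- repeated_eval(ev1, lab, cfg, 20, 20, positive = "b")
  expect_equal(r1$mean_auc, 1.0)
  expect_equal(r1$sd_auc, 0.0)
  expect_equal(r1$auc_mean_roc, 1.0, tolerance = 0.01)
})

test_that("the sort simulator reports purity, yield and enrichment", {
  lab <- c("t", "t", "o", "o")
  perfect <- simulate_sort(NULL, scores = c(2, 1.5, -1, -2),
                           threshold = 0, target_class = "t",
                           labels = lab)
  expect_equal(perfect$purity, 1.0)
  expect_equal(perfect$yield, 1.0)

  mixed <- simulate_sort(NULL, scores = c(1, 1, 1, -1), threshold = 0,
                         target_class = "t", labels = lab)
  expect_equal(mixed$purity, 2 / 3)

  all_kept <- simulate_sort(NULL, scores = c(1, 1, 1, -1),
                            threshold = -Inf, target_class = "t",
                            labels = lab)
  expect_equal(all_kept$purity, all_kept$pre_fraction)
  expect_equal(all_kept$yield, 1.0)

  none <- simulate_sort(NULL, scores = c(-1, -1, -1, -1), threshold = 0,
                        target_class = "t", labels = lab)
  expect_true(is.na(none$purity))
})

test_that("the normalizer is fitted on training data only", {
  set.seed(46)
  ev <- scalar_only_events(c(rnorm(50, 0), rnorm(50, 4)),
                           c(rnorm(50), rnorm(50, 4)))
  lab <- rep(c("a", "b"), each = 50)
  idx_train <- c(1:30, 51:80)
  cfg <- svm_config(kernel = "linear", C_grid = 1,
                    modality_set = c("fsc_area", "ssc"), seed = 3)
  m <- train_svm(ev[idx_train], lab[idx_train], cfg, positive = "b")
  x_train <- featurize(ev[idx_train], c("fsc_area", "ssc"))
  expect_equal(m$normalizer$center, colMeans(x_train),
               tolerance = 1e-12, ignore_attr = TRUE)
  x_all <- featurize(ev, c("fsc_area", "ssc"))
  expect_false(isTRUE(all.equal(m$normalizer$center, colMeans(x_all),
                                check.attributes = FALSE)))
})

test_that("throughput is the inverse acquisition time", {
  expect_equal(estimate_throughput(100e-6), 10000)
  expect_equal(estimate_throughput(1), 1)
  expect_equal(estimate_throughput(50e-6), 20000)
  expect_error(estimate_throughput(0), "> 0")
  expect_error(estimate_throughput(-1), "> 0")
})
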