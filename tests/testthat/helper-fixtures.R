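# Shared fixtures, built in code and cached across test files within one
# test run so expensive simulations happen once.

fixture_cache <- local({
  env_name <- ".ghostflow_test_cache"
  if (!exists(env_name, envir = globalenv(), inherits = FALSE)) {
    assign(env_name, new.env(parent = emptyenv()), envir = globalenv())
  }
  get(env_name, envir = globalenv())
})

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

# Moderate-size realization of the shipped two-class texture benchmark.
small_benchmark_events <- function() {
  cached_fixture("small_benchmark", {
    simulate_events(benchmark_two_class_spec(n_per_class = 250,
                                             seed = 101))
  })
}

# Tiny illumination pattern helper for exact-arithmetic tests.
pattern_from_mask <- function(mask, pitch = 0.5, seed = NA_integer_) {
  structure(list(mask = mask, pitch = pitch,
                 fill_fraction = mean(mask), seed = seed),
            class = "illumination_pattern")
}

# Hand-built event table holding only scalar features (waveform-free),
# for classifier unit tests with controlled geometry.
scalar_only_events <- function(x1, x2, classes = NULL) {
  n <- length(x1)
  isgc_events(
    waveforms = list(),
    scalars = data.frame(fsc_height = x1, fsc_width = 1, fsc_area = x1,
                         ssc = x2, bsc = x2),
    fluorescence = data.frame(green = numeric(n)),
    info = data.frame(event_id = seq_len(n),
                      true_class = if (is.null(classes))
                        rep(NA_character_, n) else classes,
                      predicted_class = NA_character_,
                      batch_id = "batch1", stringsAsFactors = FALSE))
}

# Brute-force forward-model oracle: padded double loop over mask and the
# translated map (independent of the package's implementation).
oracle_waveform <- function(map, mask, gain = 1, background = 0) {
  f <- nrow(mask); h <- nrow(map)
  w <- ncol(map)
  out <- numeric(f + h - 1L)
  for (t in seq_len(f + h - 1L)) {
    acc <- 0
    for (r in seq_len(h)) {
      mi <- t - h + r
      if (mi >= 1 && mi <= f) {
        for (j in seq_len(w)) {
          acc <- acc + mask[mi, j] * map[r, j]
        }
      }
    }
    out[t] <- gain * acc + background
  }
  out
}

# Independent Mann-Whitney AUC oracle: pairwise comparison, ties 1/2.
oracle_auc <- function(scores, labels, positive = TRUE) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Independent point-in-polygon oracle: winding-angle accumulation with an
# explicit on-segment test (different algorithm from the implementation).
oracle_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    ang <- 0
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      ax <- vx[k] - x; ay <- vy[k] - y
      bx <- vx[k2] - x; by <- vy[k2] - y
      cross <- ax * by - ay * bx
      dot <- ax * bx + ay * by
      seg_len2 <- (vx[k2] - vx[k])^2 + (vy[k2] - vy[k])^2
      # on-segment check
      if (abs(cross) < 1e-12 && dot <= 1e-12 &&
          (ax^2 + ay^2) <= seg_len2 + 1e-9 &&
          (bx^2 + by^2) <= seg_len2 + 1e-9) {
        return(TRUE)
      }
      ang <- ang + atan2(cross, dot)
    }
    abs(ang) > pi
  }, TRUE)
}

# Hand macro-F1 oracle from a confusion matrix (rows = true).
oracle_macro_f1 <- function(cm) {
  k <- nrow(cm)
  f1 <- numeric(k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    prec <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec <- if (sum(cm[i, ]) > 0) tp / sum(cm[i, ]) else 0
    f1[i] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  mean(f1)
}
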