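#' Configuration of the 1D convolutional classifier
#'
#' The multiclass network used for leukocyte-style typing: five
#' convolutional blocks (convolution, batch normalization, ReLU, max
#' pooling) over the stacked waveform channels, one fully connected
#' layer, and a softmax layer. Scalar features join the network at the
#' fully connected stage. Training uses categorical cross-entropy with
#' the Adam optimizer, a batch size capped at 1024 (reduced to a quarter
#' of the training set when that is smaller), at most 500 epochs, and
#' early stopping that restores the best-validation-loss weights after
#' 30 stagnant epochs.
#'
#' @param n_classes Number of classes (>= 2).
#' @param modality_set Waveform modalities stacked as input channels.
#' @param scalar_set Scalar features concatenated at the FC stage.
#' @param channels Per-block output channels (length 5).
#' @param kernel Convolution kernel size.
#' @param fc_width Width of the fully connected layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size Batch-size ceiling.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs (< `max_epochs`).
#' @param scalar_concat Where scalars join: `"flatten"` concatenates them
#'   to the flattened convolutional output entering the FC layer (so the
#'   FC layer mixes waveform and scalar information); `"after_fc"`
#'   concatenates them to the FC output entering the softmax layer.
#' @param seed Integer seed for initialization and batch shuffling.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(n_classes,
                       modality_set = c("dGMI", "bsGMI", "fsGMI", "bfGMI"),
                       scalar_set = c("fsc_area", "bsc"),
                       channels = c(16L, 32L, 64L, 64L, 64L),
                       kernel = 5L, fc_width = 64L,
                       learning_rate = 1e-3, batch_size = 1024L,
                       max_epochs = 500L, patience = 30L,
                       scalar_concat = c("flatten", "after_fc"),
                       seed = 1L) {
  stop_if_not(is_count(n_classes) && n_classes >= 2,
              "n_classes must be >= 2")
  stop_if_not(length(channels) == 5L, "exactly five convolutional blocks")
  stop_if_not(is_count(patience) && is_count(max_epochs) &&
                patience < max_epochs, "patience must be < max_epochs")
  structure(list(n_classes = as.integer(n_classes),
                 modality_set = modality_set, scalar_set = scalar_set,
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 pool = 2L, fc_width = as.integer(fc_width),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 scalar_concat = match.arg(scalar_concat),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Build an untrained convolutional classifier
#'
#' Initializes all parameters (He initialization for convolution and FC
#' weights, unit-gamma/zero-beta batch norm) and precomputes the temporal
#' length entering the flatten stage, erroring if any pooling step cannot
#' halve the temporal length.
#'
#' @param config A [cnn_config()].
#' @param segment_length Waveform segment length.
#' @return An object of class `cnn_model` (untrained).
#' @export
build_cnn <- function(config, segment_length = 128L) {
  stop_if_not(inherits(config, "cnn_config"), "config must be a cnn_config")
  n_mod <- length(config$modality_set)
  n_scal <- length(config$scalar_set)
  l <- as.integer(segment_length)
  lens <- integer(5)
  for (b in 1:5) {
    if (l < 2L || l %% 2L != 0L) {
      stop("max pooling in conv block ", b,
           " cannot halve temporal length ", l, call. = FALSE)
    }
    l <- l %/% 2L
    lens[b] <- l
  }
  flat_dim <- lens[5] * config$channels[5]
  fc_in <- flat_dim + if (config$scalar_concat == "flatten") n_scal else 0L
  out_in <- config$fc_width +
    if (config$scalar_concat == "after_fc") n_scal else 0L

  params <- with_seed(config$seed, {
    p <- list()
    cin <- n_mod
    for (b in 1:5) {
      cout <- config$channels[b]
      sdw <- sqrt(2 / (config$kernel * cin))
      p[[sprintf("c%d_w", b)]] <-
        matrix(stats::rnorm(cin * config$kernel * cout, 0, sdw),
               cin * config$kernel, cout)
      p[[sprintf("c%d_gamma", b)]] <- rep(1, cout)
      p[[sprintf("c%d_beta", b)]] <- rep(0, cout)
      cin <- cout
    }
    p$fc_w <- matrix(stats::rnorm(fc_in * config$fc_width, 0,
                                  sqrt(2 / fc_in)), fc_in, config$fc_width)
    p$fc_b <- rep(0, config$fc_width)
    p$out_w <- matrix(stats::rnorm(out_in * config$n_classes, 0,
                                   sqrt(2 / out_in)),
                      out_in, config$n_classes)
    p$out_b <- rep(0, config$n_classes)
    p
  })
  bn_state <- lapply(1:5, function(b) {
    list(rmean = rep(0, config$channels[b]),
         rvar = rep(1, config$channels[b]))
  })
  structure(list(config = config, segment_length = as.integer(segment_length),
                 params = params, bn_state = bn_state,
                 classes = NULL, normalizer = NULL, trained = FALSE,
                 history = NULL, best_epoch = NA_integer_),
            class = "cnn_model")
}

#' Layer census of a convolutional model
#'
#' @param model A [build_cnn()] model.
#' @return Named integer vector counting layers by kind.
#' @export
layer_census <- function(model) {
  c(conv = 5L, batchnorm = 5L, relu = 5L, maxpool = 5L, fc = 1L,
    softmax = 1L)
}

# Forward pass. xw: [batch, L, n_modalities]; xs: [batch, n_scalars].
cnn_forward <- function(model, xw, xs, training = FALSE) {
  cfg <- model$config
  p <- model$params
  caches <- vector("list", 5)
  a <- xw
  for (b in 1:5) {
    cv <- conv1d_forward(a, p[[sprintf("c%d_w", b)]], cfg$kernel)
    bn <- bn_forward(cv$y, p[[sprintf("c%d_gamma", b)]],
                     p[[sprintf("c%d_beta", b)]], model$bn_state[[b]],
                     training)
    if (training) model$bn_state[[b]] <- bn$state
    rl <- relu_forward(bn$y)
    mp <- maxpool2_forward(rl$y, b)
    caches[[b]] <- list(cv = cv, bn = bn, rl = rl, mp = mp)
    a <- mp$y
  }
  d <- dim(a)
  flat <- a
  dim(flat) <- c(d[1], d[2] * d[3])
  fc_in <- if (cfg$scalar_concat == "flatten") cbind(flat, xs) else flat
  h_pre <- sweep(fc_in %*% p$fc_w, 2, p$fc_b, `+`)
  h_mask <- h_pre > 0
  h <- h_pre * h_mask
  out_in <- if (cfg$scalar_concat == "after_fc") cbind(h, xs) else h
  logits <- sweep(out_in %*% p$out_w, 2, p$out_b, `+`)
  list(logits = logits, probs = softmax_rows(logits), caches = caches,
       flat_dims = d, fc_in = fc_in, h_mask = h_mask, out_in = out_in,
       model = model)
}

# Backward pass from softmax cross-entropy; y_onehot: [batch, K].
cnn_backward <- function(model, fwd, y_onehot) {
  cfg <- model$config
  p <- model$params
  bsz <- nrow(y_onehot)
  grads <- list()
  dz <- (fwd$probs - y_onehot) / bsz
  grads$out_w <- crossprod(fwd$out_in, dz)
  grads$out_b <- colSums(dz)
  dout_in <- dz %*% t(p$out_w)
  n_scal <- length(cfg$scalar_set)
  dh <- if (cfg$scalar_concat == "after_fc" && n_scal > 0) {
    dout_in[, seq_len(cfg$fc_width), drop = FALSE]
  } else {
    dout_in
  }
  dh_pre <- dh * fwd$h_mask
  grads$fc_w <- crossprod(fwd$fc_in, dh_pre)
  grads$fc_b <- colSums(dh_pre)
  dfc_in <- dh_pre %*% t(p$fc_w)
  flat_width <- prod(fwd$flat_dims[2:3])
  dflat <- dfc_in[, seq_len(flat_width), drop = FALSE]
  da <- dflat
  dim(da) <- fwd$flat_dims
  for (b in 5:1) {
    cc <- fwd$caches[[b]]
    da <- maxpool2_backward(da, cc$mp)
    da <- da * cc$rl$mask
    bnb <- bn_backward(da, cc$bn, p[[sprintf("c%d_gamma", b)]])
    grads[[sprintf("c%d_gamma", b)]] <- bnb$dgamma
    grads[[sprintf("c%d_beta", b)]] <- bnb$dbeta
    cvb <- conv1d_backward(bnb$dx, cc$cv, p[[sprintf("c%d_w", b)]],
                           cfg$kernel)
    grads[[sprintf("c%d_w", b)]] <- cvb$dw
    da <- cvb$dx
  }
  grads
}

# Stack the selected waveform modalities into [n, L, n_modalities] and
# standardize with per-channel (waveforms) / per-feature (scalars) stats.
cnn_inputs <- function(events, config, normalizer = NULL) {
  mods <- config$modality_set
  stop_if_not(all(mods %in% names(events$waveforms)),
              "missing waveform modality for the CNN input")
  n <- n_events(events)
  l <- ncol(events$waveforms[[mods[1]]])
  xw <- array(0, c(n, l, length(mods)))
  for (k in seq_along(mods)) xw[, , k] <- events$waveforms[[mods[k]]]
  xs <- if (length(config$scalar_set) > 0) {
    do.call(cbind, lapply(config$scalar_set, function(f) {
      get_feature(events, f)
    }))
  } else {
    matrix(0, n, 0)
  }
  if (is.null(normalizer)) {
    wf_mean <- apply(xw, 3, mean)
    wf_sd <- pmax(apply(xw, 3, stats::sd), 1e-12)
    sc_mean <- if (ncol(xs)) colMeans(xs) else numeric(0)
    sc_sd <- if (ncol(xs)) pmax(apply(xs, 2, stats::sd), 1e-12) else
      numeric(0)
    normalizer <- list(wf_mean = wf_mean, wf_sd = wf_sd,
                       sc_mean = sc_mean, sc_sd = sc_sd)
  }
  for (k in seq_along(mods)) {
    xw[, , k] <- (xw[, , k] - normalizer$wf_mean[k]) / normalizer$wf_sd[k]
  }
  if (ncol(xs)) {
    xs <- sweep(sweep(xs, 2, normalizer$sc_mean), 2, normalizer$sc_sd, `/`)
  }
  list(xw = xw, xs = xs, normalizer = normalizer)
}

ce_loss <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_along(y_idx), y_idx)], 1e-12)))
}

#' Train the convolutional classifier
#'
#' Early-stopped Adam training on categorical cross-entropy. The
#' validation set must be disjoint from training; the returned model
#' carries the weights of the epoch with the best validation loss and the
#' full per-epoch loss history.
#'
#' @param train_events,val_events [isgc_events()] tables.
#' @param config A [cnn_config()].
#' @param train_labels,val_labels Class labels (default: the tables'
#'   `true_class`).
#' @return A trained `cnn_model`.
#' @export
train_cnn <- function(train_events, val_events, config,
                      train_labels = train_events$info$true_class,
                      val_labels = val_events$info$true_class) {
  train_labels <- as.character(train_labels)
  classes <- sort(unique(train_labels))
  stop_if_not(length(classes) == config$n_classes,
              paste0("training labels contain ", length(classes),
                     " classes; config expects ", config$n_classes))
  tr_in <- cnn_inputs(train_events, config)
  va_in <- cnn_inputs(val_events, config, tr_in$normalizer)
  y_tr <- match(train_labels, classes)
  y_va <- match(as.character(val_labels), classes)
  stop_if_not(!anyNA(y_va), "validation labels outside training classes")

  model <- build_cnn(config, segment_length = dim(tr_in$xw)[2])
  model$classes <- classes
  model$normalizer <- tr_in$normalizer
  n <- length(y_tr)
  bsz <- min(config$batch_size, max(16L, n %/% 4L))
  onehot <- diag(config$n_classes)
  adam <- adam_init(model$params)
  best_loss <- Inf
  best_params <- model$params
  best_bn <- model$bn_state
  best_epoch <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  for (epoch in seq_len(config$max_epochs)) {
    idx <- with_seed(event_seed(config$seed, 7L * epoch), sample.int(n))
    ep_loss <- 0
    n_batch <- 0L
    for (start in seq(1L, n, by = bsz)) {
      bi <- idx[start:min(start + bsz - 1L, n)]
      if (length(bi) < 2L) next
      fwd <- cnn_forward(model, tr_in$xw[bi, , , drop = FALSE],
                         tr_in$xs[bi, , drop = FALSE], training = TRUE)
      model <- fwd$model            # batch-norm running stats advance
      grads <- cnn_backward(model, fwd, onehot[y_tr[bi], , drop = FALSE])
      upd <- adam_step(model$params, grads, adam, config$learning_rate)
      model$params <- upd$params
      adam <- upd$state
      ep_loss <- ep_loss + ce_loss(fwd$probs, y_tr[bi])
      n_batch <- n_batch + 1L
    }
    va_fwd <- cnn_forward(model, va_in$xw, va_in$xs, training = FALSE)
    val_loss <- ce_loss(va_fwd$probs, y_va)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = ep_loss / max(n_batch, 1L),
                                val_loss = val_loss))
    if (val_loss < best_loss - 1e-9) {
      best_loss <- val_loss
      best_params <- model$params
      best_bn <- model$bn_state
      best_epoch <- epoch
    } else if (epoch - best_epoch >= config$patience) {
      break
    }
  }
  model$params <- best_params
  model$bn_state <- best_bn
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best_epoch
  model
}

#' Predict class probabilities and labels
#'
#' @param model A trained `cnn_model`.
#' @param events Events to classify.
#' @return List with `probs` (rows sum to 1) and `labels` (argmax, ties
#'   to the lowest class index).
#' @export
predict_cnn <- function(model, events) {
  stop_if_not(inherits(model, "cnn_model") && isTRUE(model$trained),
              "model must be a trained cnn_model")
  xin <- cnn_inputs(events, model$config, model$normalizer)
  fwd <- cnn_forward(model, xin$xw, xin$xs, training = FALSE)
  idx <- max.col(fwd$probs, ties.method = "first")
  colnames(fwd$probs) <- model$classes
  list(probs = fwd$probs, labels = model$classes[idx])
}
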