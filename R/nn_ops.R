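# Internal tensor primitives for the 1D convolutional classifier.
# Activations are 3D arrays [batch, time, channels]; because R arrays are
# column-major, flattening the first two dimensions is a free reshape.
# Convolutions run as one BLAS matmul on an im2col matrix built by a C++
# gather kernel (src/nn_kernels.cpp) and reused by the backward pass;
# batch-norm and pooling elementwise passes run in C++ as well.

# w: [cin * k, cout] (tap-major blocks of cin rows)
conv1d_forward <- function(x, w, k) {
  d <- dim(x)
  b <- d[1]; l <- d[2]; cin <- d[3]
  pad <- (k - 1L) %/% 2L
  lp <- l + 2L * pad
  xp <- array(0, c(b, lp, cin))
  xp[, pad + seq_len(l), ] <- x
  xc <- cpp_im2col(xp, b, lp, cin, k)
  y <- xc %*% w
  dim(y) <- c(b, l, ncol(w))
  list(y = y, xc = xc, dims = c(b, l, cin))
}

conv1d_backward <- function(dy, cache, w, k) {
  d <- cache$dims
  b <- d[1]; l <- d[2]; cin <- d[3]
  pad <- (k - 1L) %/% 2L
  dyf <- dy
  dim(dyf) <- c(b * l, ncol(w))
  dw <- crossprod(cache$xc, dyf)
  dxc <- tcrossprod(dyf, w)
  dxp <- cpp_col_fold(dxc, b, l + 2L * pad, cin, k)
  list(dx = dxp[, pad + seq_len(l), , drop = FALSE], dw = dw)
}

bn_forward <- function(x, gamma, beta, state, training, momentum = 0.9,
                       eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  xf <- x
  dim(xf) <- c(n, d[3])
  if (training) {
    st <- cpp_col_stats(xf)
    mu <- st$mu
    va <- st$va
    state$rmean <- momentum * state$rmean + (1 - momentum) * mu
    state$rvar <- momentum * state$rvar + (1 - momentum) * va
  } else {
    mu <- state$rmean
    va <- state$rvar
  }
  istd <- 1 / sqrt(va + eps)
  ap <- cpp_bn_apply(xf, mu, istd, gamma, beta)
  y <- ap$y
  dim(y) <- d
  list(y = y, xhat = ap$xhat, istd = istd, state = state, dims = d)
}

bn_backward <- function(dy, cache, gamma) {
  d <- cache$dims
  dyf <- dy
  dim(dyf) <- c(d[1] * d[2], d[3])
  bk <- cpp_bn_backward(dyf, cache$xhat, cache$istd, gamma)
  dx <- bk$dx
  dim(dx) <- d
  list(dx = dx, dgamma = bk$dgamma, dbeta = bk$dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

maxpool2_forward <- function(x, layer_index = NA) {
  d <- dim(x)
  if (d[2] < 2L || d[2] %% 2L != 0L) {
    stop("max pooling in conv block ", layer_index,
         " cannot halve temporal length ", d[2], call. = FALSE)
  }
  mp <- cpp_maxpool2(x, d[1], d[2], d[3])
  list(y = mp$y, take_odd = mp$take_odd, dims = d)
}

maxpool2_backward <- function(dy, cache) {
  d <- cache$dims
  cpp_maxpool2_backward(dy, cache$take_odd, d[1], d[2], d[3])
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adam over a flat named list of arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
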