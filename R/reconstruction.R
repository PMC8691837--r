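#' Build the linear sensing system of a set of patterns
#'
#' Stacks, for every pattern and every flow translation, the mask entries
#' overlapping the object, so that `matrix %*% vec(object)` reproduces the
#' concatenated noise-free [gmi_waveform()] outputs exactly (unit gain,
#' zero background). This certifies that the compressive waveforms are a
#' linear image measurement.
#'
#' @param patterns List of [generate_pattern()] results.
#' @param object_shape Object dimensions `c(flow, lateral)` in pixels;
#'   lateral size must not exceed any pattern's lateral size.
#' @return An object of class `sensing_system` with elements `patterns`,
#'   `object_shape`, `matrix` (rows = total waveform samples, columns =
#'   object pixels, vec in column-major order).
#' @export
sensing_matrix <- function(patterns, object_shape) {
  stop_if_not(length(patterns) > 0, "at least one pattern required")
  object_shape <- as.integer(object_shape)
  h <- object_shape[1]
  w <- object_shape[2]
  rows <- lapply(patterns, function(p) {
    stop_if_not(inherits(p, "illumination_pattern"),
                "patterns must be illumination_pattern objects")
    if (w > ncol(p$mask)) {
      stop("object lateral size (", w, ") exceeds pattern lateral size (",
           ncol(p$mask), ")", call. = FALSE)
    }
    f <- nrow(p$mask)
    a <- matrix(0, f + h - 1L, h * w)
    for (t in seq_len(f + h - 1L)) {
      for (r in seq_len(h)) {
        mi <- t - h + r
        if (mi >= 1L && mi <= f) {
          a[t, r + (seq_len(w) - 1L) * h] <- p$mask[mi, seq_len(w)]
        }
      }
    }
    a
  })
  structure(list(patterns = patterns, object_shape = object_shape,
                 matrix = do.call(rbind, rows)),
            class = "sensing_system")
}

#' Reconstruct an object image from compressive waveforms
#'
#' Solves the (optionally ridge-regularized) least-squares problem
#' `min ||A x - b||^2 + ridge ||x||^2` for the vectorized object, using a
#' dense QR solve for `ridge = 0` and the normal equations otherwise.
#'
#' @param waveforms Stacked measurement vector (concatenated waveform
#'   samples in pattern order), or a list of [raw_signal()]s / numeric
#'   vectors to concatenate.
#' @param system A [sensing_matrix()] result.
#' @param ridge Tikhonov regularization weight (>= 0).
#' @return Matrix of `system$object_shape` with the reconstructed image.
#' @export
reconstruct_image <- function(waveforms, system, ridge = 0) {
  stop_if_not(inherits(system, "sensing_system"),
              "system must be a sensing_system")
  stop_if_not(is_number(ridge) && ridge >= 0, "ridge must be >= 0")
  if (is.list(waveforms)) {
    waveforms <- unlist(lapply(waveforms, function(s) {
      if (inherits(s, "raw_signal")) s$samples else s
    }))
  }
  a <- system$matrix
  stop_if_not(length(waveforms) == nrow(a),
              "stacked waveform length must equal the sensing matrix rows")
  if (ridge == 0) {
    qa <- qr(a)
    if (qa$rank < ncol(a)) {
      stop("sensing matrix is rank deficient (rank ", qa$rank, " < ",
           ncol(a), " pixels); add patterns or use ridge > 0",
           call. = FALSE)
    }
    x <- qr.coef(qa, waveforms)
  } else {
    ata <- crossprod(a) + diag(ridge, ncol(a))
    x <- solve(ata, crossprod(a, waveforms))
  }
  matrix(x, system$object_shape[1], system$object_shape[2])
}
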