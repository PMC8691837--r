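#' Raw single-channel signal
#'
#' @param samples Numeric vector of finite samples.
#' @param sample_period Sampling period in seconds.
#' @param channel Channel name.
#' @return An object of class `raw_signal`.
#' @export
raw_signal <- function(samples, sample_period = 1e-6, channel = "chan") {
  stop_if_not(is.numeric(samples) && all(is.finite(samples)),
              "samples must be finite numeric")
  structure(list(samples = as.numeric(samples),
                 sample_period = sample_period,
                 channel = channel),
            class = "raw_signal")
}

#' Generate a structured-illumination pattern
#'
#' The static binary mask the flowing cell traverses. Entries are i.i.d.
#' Bernoulli(`fill_fraction`); the flow axis is the first index.
#'
#' @param flow_extent,lateral_extent Pattern dimensions in pixels (>= 1).
#' @param fill_fraction Probability that a pixel is illuminated, in (0, 1).
#' @param seed Integer seed; the mask is deterministic given the seed.
#' @param pitch Pixel pitch in micrometres per pixel.
#' @return An object of class `illumination_pattern` with elements `mask`,
#'   `pitch`, `fill_fraction`, `seed`.
#' @export
generate_pattern <- function(flow_extent = 128L, lateral_extent = 32L,
                             fill_fraction = 0.5, seed = 1L, pitch = 0.5) {
  stop_if_not(is_count(flow_extent) && flow_extent >= 1,
              "flow_extent must be >= 1")
  stop_if_not(is_count(lateral_extent) && lateral_extent >= 1,
              "lateral_extent must be >= 1")
  stop_if_not(is_number(fill_fraction) && fill_fraction > 0 &&
                fill_fraction < 1, "fill_fraction must be in (0, 1)")
  mask <- with_seed(seed, {
    matrix(stats::rbinom(flow_extent * lateral_extent, 1L, fill_fraction),
           flow_extent, lateral_extent)
  })
  structure(list(mask = mask, pitch = pitch, fill_fraction = fill_fraction,
                 seed = as.integer(seed)),
            class = "illumination_pattern")
}

#' Modality configuration for one compressive channel
#'
#' Each ghost-motion-imaging (GMI) modality reads one phantom contrast map
#' through its own structured pattern: `dGMI` (diffracted) and `fsGMI`
#' (forward-scatter) read the transmission map, `ssGMI`/`bsGMI` the scatter
#' map, and `bfGMI` (bright field) the absorption map. Modalities differ by
#' detection geometry, not by the measurement mathematics.
#'
#' @param modality One of `dGMI`, `ssGMI`, `bsGMI`, `fsGMI`, `bfGMI`.
#' @param contrast_source Phantom map read by this modality; defaults to
#'   the field convention above.
#' @param gain Detector gain (dimensionless).
#' @param background Additive background in signal units.
#' @param flow_speed Flow speed in micrometres per second.
#' @param sample_period Sampling period in seconds. The default,
#'   `pitch / flow_speed`, gives exactly one pixel of object translation
#'   per sample so the waveform is a pure discrete correlation.
#' @param n_fringes Number of detector sub-apertures (independent
#'   sub-masks) summed into the signal (>= 1).
#' @param pitch Pixel pitch in micrometres per pixel.
#' @return An object of class `modality_config`.
#' @export
modality_config <- function(modality = c("dGMI", "ssGMI", "bsGMI", "fsGMI",
                                         "bfGMI"),
                            contrast_source = NULL, gain = 1,
                            background = 0, flow_speed = 6.4e5,
                            sample_period = NULL, n_fringes = 1L,
                            pitch = 0.5) {
  modality <- match.arg(modality)
  if (is.null(contrast_source)) {
    contrast_source <- switch(modality,
                              dGMI = "transmission", fsGMI = "transmission",
                              ssGMI = "scatter", bsGMI = "scatter",
                              bfGMI = "absorption")
  }
  stop_if_not(is_number(flow_speed) && flow_speed > 0,
              "flow_speed must be > 0")
  if (is.null(sample_period)) sample_period <- pitch / flow_speed
  stop_if_not(is_number(sample_period) && sample_period > 0,
              "sample_period must be > 0")
  stop_if_not(is_count(n_fringes) && n_fringes >= 1,
              "n_fringes must be >= 1")
  structure(list(modality = modality, contrast_source = contrast_source,
                 gain = gain, background = background,
                 flow_speed = flow_speed, sample_period = sample_period,
                 n_fringes = as.integer(n_fringes)),
            class = "modality_config")
}

# Core discrete correlation: object map (h x w) translated one pixel per
# sample along the flow axis of mask (F x W), zero-padded entry/exit.
# out[t] = sum_{r,j} mask[t - h + r, j] * map[r, j],  t = 1 .. F + h - 1.
correlate_traversal <- function(map, mask) {
  h <- nrow(map)
  f <- nrow(mask)
  m <- mask %*% t(map)                     # F x h row-overlap products
  out <- numeric(f + h - 1L)
  for (r in seq_len(h)) {
    idx <- (h - r + 1L):(h - r + f)
    out[idx] <- out[idx] + m[, r]
  }
  out
}

#' Compressive motion-imaging waveform of a phantom map
#'
#' Forward model of ghost motion imaging: the object map translates one
#' pixel per sample through the static mask and a single-pixel detector
#' records the total overlap, yielding a waveform of `F + h - 1` samples
#' (mask flow extent `F`, map flow extent `h`), equal per sample to
#' `gain * sum(mask * translated map) + background`. With `n_fringes > 1`
#' the signals from that many independent sub-masks (derived from the
#' pattern's seed) are summed.
#'
#' @param map 2D nonnegative contrast matrix (flow axis first).
#' @param pattern An [generate_pattern()] result.
#' @param cfg A [modality_config()].
#' @return A [raw_signal()] of length `nrow(pattern$mask) + nrow(map) - 1`.
#' @export
gmi_waveform <- function(map, pattern, cfg = modality_config("dGMI")) {
  stop_if_not(inherits(pattern, "illumination_pattern"),
              "pattern must be an illumination_pattern")
  stop_if_not(is.matrix(map) && all(is.finite(map)),
              "map must be a finite matrix")
  if (ncol(map) > ncol(pattern$mask)) {
    stop("map lateral width (", ncol(map), ") exceeds pattern lateral ",
         "width (", ncol(pattern$mask), ")", call. = FALSE)
  }
  if (ncol(map) < ncol(pattern$mask)) {
    pad <- matrix(0, nrow(map), ncol(pattern$mask) - ncol(map))
    map <- cbind(map, pad)
  }
  acc <- correlate_traversal(map, pattern$mask)
  if (cfg$n_fringes > 1L) {
    for (k in seq_len(cfg$n_fringes - 1L)) {
      sub <- generate_pattern(nrow(pattern$mask), ncol(pattern$mask),
                              pattern$fill_fraction,
                              seed = event_seed(pattern$seed, k),
                              pitch = pattern$pitch)
      acc <- acc + correlate_traversal(map, sub$mask)
    }
  }
  raw_signal(cfg$gain * acc + cfg$background, cfg$sample_period,
             cfg$modality)
}

#' Conventional scatter channels of a phantom
#'
#' The forward-scatter (FSC) pulse is the flow-axis sliding row-sum of the
#' transmission map through a uniform illumination strip, so its area is
#' proportional to projected cell size; side scatter (SSC) and back scatter
#' (BSC) are gain-scaled totals of the scatter map (BSC with an independent
#' gain; the two are interchangeable in practice).
#'
#' @param phantom A [make_phantom()] result.
#' @param fsc_gain,ssc_gain,bsc_gain Channel gains.
#' @param strip_rows Flow extent of the uniform FSC strip in pixels.
#' @param sample_period Sampling period in seconds.
#' @return List with `fsc_pulse` (a [raw_signal()]), `ssc`, `bsc`.
#' @export
scalar_channels <- function(phantom, fsc_gain = 1, ssc_gain = 1,
                            bsc_gain = 0.9, strip_rows = 1L,
                            sample_period = 1e-6) {
  stop_if_not(inherits(phantom, "cell_phantom"),
              "phantom must be a cell_phantom")
  tx <- phantom$contrast_maps$transmission
  strip <- matrix(1, strip_rows, ncol(tx))
  pulse <- fsc_gain * correlate_traversal(tx, strip)
  sc <- phantom$contrast_maps$scatter
  list(fsc_pulse = raw_signal(pulse, sample_period, "FSC"),
       ssc = ssc_gain * sum(sc),
       bsc = bsc_gain * sum(sc))
}

#' Total fluorescence intensity of a phantom channel
#'
#' @param phantom A [make_phantom()] result.
#' @param channel Fluorescence channel name.
#' @param gain Detector gain.
#' @param noise Optional [noise_model()] applied to the scalar intensity.
#' @return Scalar intensity.
#' @export
fluorescence_intensity <- function(phantom, channel, gain = 1,
                                   noise = NULL) {
  stop_if_not(inherits(phantom, "cell_phantom"),
              "phantom must be a cell_phantom")
  if (!channel %in% names(phantom$fluorescence_maps)) {
    stop("unknown fluorescence channel '", channel, "'", call. = FALSE)
  }
  x <- gain * sum(phantom$fluorescence_maps[[channel]])
  if (!is.null(noise)) {
    x <- add_noise(raw_signal(x, channel = channel), noise)$samples
  }
  x
}

#' Acquisition noise model
#'
#' Shot noise as scaled Poisson resampling (`Poisson(shot_scale * x) /
#' shot_scale`, so larger `shot_scale` means more collected photons and
#' relatively less noise), followed by additive Gaussian read noise.
#'
#' @param shot_scale Poisson intensity scaling (>= 0; 0 disables shot
#'   noise).
#' @param read_sigma Standard deviation of additive Gaussian noise (>= 0).
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(shot_scale = 0, read_sigma = 0, seed = 1L) {
  stop_if_not(is_number(shot_scale) && shot_scale >= 0,
              "shot_scale must be >= 0")
  stop_if_not(is_number(read_sigma) && read_sigma >= 0,
              "read_sigma must be >= 0")
  structure(list(shot_scale = shot_scale, read_sigma = read_sigma,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Add detector noise to a signal
#'
#' @param signal A [raw_signal()].
#' @param model A [noise_model()]; the output is deterministic given
#'   `model$seed`.
#' @return A noisy [raw_signal()].
#' @export
add_noise <- function(signal, model) {
  stop_if_not(inherits(signal, "raw_signal"), "signal must be a raw_signal")
  stop_if_not(inherits(model, "noise_model"), "model must be a noise_model")
  x <- signal$samples
  if (model$shot_scale > 0 && any(x < 0)) {
    stop("shot noise requires nonnegative signal values", call. = FALSE)
  }
  y <- with_seed(model$seed, {
    out <- x
    if (model$shot_scale > 0) {
      out <- stats::rpois(length(x), model$shot_scale * x) / model$shot_scale
    }
    if (model$read_sigma > 0) {
      out <- out + stats::rnorm(length(x), 0, model$read_sigma)
    }
    out
  })
  raw_signal(y, signal$sample_period, signal$channel)
}

#' Write or read an illumination pattern as CSV
#'
#' Plain-text export of the mask matrix for reproducibility and external
#' inspection.
#'
#' @param pattern An [generate_pattern()] result.
#' @param path File path.
#' @return `write_pattern_csv` returns `path` invisibly;
#'   `read_pattern_csv` returns an `illumination_pattern`.
#' @export
write_pattern_csv <- function(pattern, path) {
  utils::write.table(pattern$mask, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @param pitch,fill_fraction,seed Metadata to attach on read.
#' @export
read_pattern_csv <- function(path, pitch = 0.5, fill_fraction = NA,
                             seed = NA_integer_) {
  mask <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(mask) <- NULL
  structure(list(mask = mask, pitch = pitch, fill_fraction = fill_fraction,
                 seed = seed),
            class = "illumination_pattern")
}
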