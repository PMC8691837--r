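#' Acquisition configuration
#'
#' Parameters of the digitizer-side signal chain: AC coupling (single-pole
#' high-pass), the forward-scatter trigger condition, the fixed segment
#' window cut from every channel, and the pulse-width fraction.
#'
#' @param highpass_alpha Pole of the recursive high-pass filter, in (0, 1);
#'   values near 1 remove only the DC component.
#' @param trigger_threshold Trigger level in signal units on the filtered
#'   FSC channel.
#' @param trigger_min_run Number of consecutive supra-threshold samples
#'   required to fire the trigger (>= 1).
#' @param segment_length Samples per extracted segment (default 128, so a
#'   waveform carries over 100 points).
#' @param pre_trigger Samples kept before the trigger index (>= 0, less
#'   than `segment_length`).
#' @param width_fraction Fraction of pulse height at which pulse width is
#'   measured, in (0, 1).
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(highpass_alpha = 0.995,
                               trigger_threshold = 3,
                               trigger_min_run = 3L,
                               segment_length = 128L,
                               pre_trigger = 8L,
                               width_fraction = 0.5) {
  stop_if_not(is_number(highpass_alpha) && highpass_alpha > 0 &&
                highpass_alpha < 1, "highpass_alpha must be in (0, 1)")
  stop_if_not(is_count(trigger_min_run) && trigger_min_run >= 1,
              "trigger_min_run must be >= 1")
  stop_if_not(is_count(segment_length) && segment_length >= 1,
              "segment_length must be >= 1")
  stop_if_not(is_count(pre_trigger) && pre_trigger >= 0 &&
                pre_trigger < segment_length,
              "pre_trigger must be in [0, segment_length)")
  stop_if_not(is_number(width_fraction) && width_fraction > 0 &&
                width_fraction < 1, "width_fraction must be in (0, 1)")
  structure(list(highpass_alpha = highpass_alpha,
                 trigger_threshold = trigger_threshold,
                 trigger_min_run = as.integer(trigger_min_run),
                 segment_length = as.integer(segment_length),
                 pre_trigger = as.integer(pre_trigger),
                 width_fraction = width_fraction),
            class = "acquisition_config")
}

#' Single-pole recursive high-pass filter
#'
#' AC coupling: `y[t] = alpha * (y[t-1] + x[t] - x[t-1])`, initialized with
#' `x[0] = x[1]` and `y[0] = 0` so a constant signal maps to exactly zero
#' from the first sample.
#'
#' @param signal A [raw_signal()].
#' @param alpha Filter pole in (0, 1).
#' @return Filtered [raw_signal()].
#' @export
highpass <- function(signal, alpha) {
  stop_if_not(inherits(signal, "raw_signal"), "signal must be a raw_signal")
  stop_if_not(is_number(alpha) && alpha > 0 && alpha < 1,
              "alpha must be in (0, 1)")
  x <- signal$samples
  stop_if_not(length(x) > 0, "empty signal")
  # y = alpha-discounted cumulated first difference; stats::filter runs the
  # recursion y[t] = alpha * y[t-1] + alpha * dx[t] in C
  dx <- c(0, diff(x))
  y <- as.numeric(stats::filter(alpha * dx, alpha, method = "recursive"))
  raw_signal(y, signal$sample_period, signal$channel)
}

#' Detect the forward-scatter trigger
#'
#' Returns the first index starting a run of at least `min_run` consecutive
#' samples strictly above `threshold`, or `NA` if the condition never
#' holds.
#'
#' @param fsc_signal A [raw_signal()] (or numeric vector).
#' @param threshold Trigger level.
#' @param min_run Required run length (>= 1).
#' @return 1-based sample index, or `NA_integer_`.
#' @export
detect_trigger <- function(fsc_signal, threshold, min_run = 1L) {
  stop_if_not(is_count(min_run) && min_run >= 1, "min_run must be >= 1")
  x <- if (inherits(fsc_signal, "raw_signal")) fsc_signal$samples
       else fsc_signal
  r <- rle(x > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_run)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(starts[hit[1L]])
}

#' Extract a fixed-length segment around a trigger
#'
#' Cuts `cfg$segment_length` samples starting `cfg$pre_trigger` samples
#' before the trigger index, zero-padding outside the recorded range. The
#' same window is applied to every channel of an event, so channels remain
#' time-aligned.
#'
#' @param signal A [raw_signal()] or numeric vector.
#' @param trigger_index 1-based trigger sample index.
#' @param cfg An [acquisition_config()].
#' @return Numeric vector of length `cfg$segment_length`.
#' @export
extract_segment <- function(signal, trigger_index, cfg) {
  x <- if (inherits(signal, "raw_signal")) signal$samples else signal
  stop_if_not(is_count(trigger_index), "trigger_index must be an integer")
  idx <- seq.int(trigger_index - cfg$pre_trigger,
                 length.out = cfg$segment_length)
  out <- numeric(cfg$segment_length)
  ok <- idx >= 1L & idx <= length(x)
  out[ok] <- x[idx[ok]]
  out
}

#' Pulse height, width and area
#'
#' Height is the segment maximum, width the number of samples above
#' `width_fraction * height`, and area the segment sum. An all-zero
#' segment yields `(0, 0, 0)`.
#'
#' @param fsc_segment Numeric vector (an extracted FSC segment).
#' @param width_fraction Fraction of height defining the width level.
#' @return Named list `height`, `width`, `area`.
#' @export
pulse_features <- function(fsc_segment, width_fraction = 0.5) {
  stop_if_not(length(fsc_segment) > 0, "empty segment")
  h <- max(fsc_segment)
  if (h <= 0) return(list(height = 0, width = 0L, area = sum(fsc_segment)))
  list(height = h,
       width = sum(fsc_segment > width_fraction * h),
       area = sum(fsc_segment))
}

#' Assemble one event from per-channel signals
#'
#' Applies the high-pass filter to every channel, fires the trigger on the
#' FSC channel, cuts the common segment window from all waveform channels,
#' and attaches pulse features, scatter scalars and fluorescence
#' intensities. Returns `NULL` when the trigger condition is never met
#' (the caller counts the dropout).
#'
#' @param signals Named list of [raw_signal()] objects; must contain
#'   `FSC`, other entries are treated as waveform modalities.
#' @param scalars Named list with `ssc` and `bsc` scalar intensities.
#' @param fluorescence Named numeric vector of fluorescence intensities.
#' @param cfg An [acquisition_config()].
#' @param event_id Integer event identifier.
#' @param true_class,batch_id Labels carried on the event.
#' @return A one-row [isgc_events()] or `NULL` (no trigger).
#' @export
assemble_event <- function(signals, scalars, fluorescence, cfg,
                           event_id = 1L, true_class = NA_character_,
                           batch_id = NA_character_) {
  stop_if_not("FSC" %in% names(signals), "signals must contain FSC")
  filtered <- lapply(signals, highpass, alpha = cfg$highpass_alpha)
  trig <- detect_trigger(filtered$FSC, cfg$trigger_threshold,
                         cfg$trigger_min_run)
  if (is.na(trig)) return(NULL)
  fsc_seg <- extract_segment(filtered$FSC, trig, cfg)
  pf <- pulse_features(fsc_seg, cfg$width_fraction)
  mods <- setdiff(names(filtered), "FSC")
  wf <- lapply(filtered[mods], function(s) {
    matrix(extract_segment(s, trig, cfg), nrow = 1)
  })
  names(wf) <- mods
  isgc_events(
    waveforms = wf,
    scalars = data.frame(fsc_height = pf$height, fsc_width = pf$width,
                         fsc_area = pf$area, ssc = scalars$ssc,
                         bsc = scalars$bsc),
    fluorescence = as.data.frame(as.list(fluorescence)),
    info = data.frame(event_id = as.integer(event_id),
                      true_class = true_class,
                      predicted_class = NA_character_,
                      batch_id = batch_id,
                      stringsAsFactors = FALSE)
  )
}
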