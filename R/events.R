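#' Construct an event table
#'
#' The per-cell record set of one acquisition run: fixed-length compressive
#' waveforms per modality, conventional scalar channels, fluorescence
#' intensities and labels, aligned row-by-row.
#'
#' @param waveforms Named list of `n x segment_length` matrices, one per
#'   modality.
#' @param scalars Data frame with columns `fsc_height`, `fsc_width`,
#'   `fsc_area`, `ssc`, `bsc`.
#' @param fluorescence Data frame of per-channel intensities.
#' @param info Data frame with columns `event_id`, `true_class`,
#'   `predicted_class`, `batch_id`.
#' @param meta List of run metadata (dropout counts, configuration,
#'   provenance).
#' @return An object of class `isgc_events`.
#' @export
isgc_events <- function(waveforms, scalars, fluorescence, info,
                        meta = list()) {
  n <- nrow(info)
  stop_if_not(all(vapply(waveforms, nrow, 0L) == n),
              "waveform matrices must have one row per event")
  lens <- vapply(waveforms, ncol, 0L)
  stop_if_not(length(unique(lens)) <= 1L,
              "all waveforms must share segment_length")
  stop_if_not(nrow(scalars) == n && nrow(fluorescence) == n,
              "scalars and fluorescence must have one row per event")
  structure(list(waveforms = waveforms, scalars = scalars,
                 fluorescence = fluorescence, info = info, meta = meta),
            class = "isgc_events")
}

#' Number of events in an event table
#' @param events An `isgc_events` object.
#' @return Integer count.
#' @export
n_events <- function(events) {
  nrow(events$info)
}

#' @export
print.isgc_events <- function(x, ...) {
  cat("<isgc_events> ", n_events(x), " events, ",
      length(x$waveforms), " waveform modalities (",
      paste(names(x$waveforms), collapse = ", "), "), segment length ",
      if (length(x$waveforms)) ncol(x$waveforms[[1]]) else 0, "\n", sep = "")
  cat("  classes: ", paste(utils::head(unique(x$info$true_class), 8),
                           collapse = ", "), "\n", sep = "")
  if (!is.null(x$meta$n_dropouts)) {
    cat("  dropouts: ", x$meta$n_dropouts, "\n", sep = "")
  }
  invisible(x)
}

#' Subset an event table by row
#' @param x An `isgc_events` object.
#' @param i Row indices or logical mask.
#' @param ... Unused.
#' @return An `isgc_events` with the selected events.
#' @export
`[.isgc_events` <- function(x, i, ...) {
  isgc_events(lapply(x$waveforms, function(w) w[i, , drop = FALSE]),
              x$scalars[i, , drop = FALSE],
              x$fluorescence[i, , drop = FALSE],
              x$info[i, , drop = FALSE],
              x$meta)
}

#' Combine event tables row-wise
#' @param ... `isgc_events` objects with identical modality sets.
#' @return A combined `isgc_events`.
#' @export
bind_events <- function(...) {
  parts <- list(...)
  stop_if_not(length(parts) > 0, "nothing to bind")
  mods <- names(parts[[1]]$waveforms)
  wf <- lapply(mods, function(m) {
    do.call(rbind, lapply(parts, function(p) p$waveforms[[m]]))
  })
  names(wf) <- mods
  isgc_events(wf,
              do.call(rbind, lapply(parts, `[[`, "scalars")),
              do.call(rbind, lapply(parts, `[[`, "fluorescence")),
              do.call(rbind, lapply(parts, `[[`, "info")),
              parts[[1]]$meta)
}
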