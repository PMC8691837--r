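#' Optics configuration for a simulated acquisition
#'
#' Defines which compressive modalities are measured, the shared pattern
#' geometry (each modality gets its own independent Bernoulli mask derived
#' from `pattern_seed`), the scalar-channel gains, and the per-channel
#' noise model applied during acquisition.
#'
#' @param modalities Character vector of GMI modalities to record.
#' @param pattern_flow Pattern flow extent in pixels. With the default 128
#'   and a 64-pixel phantom canvas, raw waveforms carry
#'   `128 + 64 - 1 = 191` samples before segmentation.
#' @param pattern_lateral Pattern lateral extent in pixels (defaults to
#'   the population canvas width at simulation time).
#' @param fill_fraction Bernoulli fill of the masks.
#' @param pattern_seed Seed from which per-modality mask seeds derive.
#' @param gains Named numeric vector of per-modality gains (default 1).
#' @param fsc_gain,ssc_gain,bsc_gain,strip_rows,fluor_gain Scalar-channel
#'   settings; see [scalar_channels()].
#' @param noise A [noise_model()] applied to every channel (its seed is
#'   re-derived per event and channel; the population's `noise_scale`
#'   rescales it).
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(modalities = c("dGMI", "ssGMI", "bsGMI", "fsGMI",
                                         "bfGMI"),
                          pattern_flow = 128L, pattern_lateral = NULL,
                          fill_fraction = 0.5, pattern_seed = 20L,
                          gains = NULL, fsc_gain = 1, ssc_gain = 1,
                          bsc_gain = 0.9, strip_rows = 1L, fluor_gain = 1,
                          noise = noise_model(shot_scale = 10,
                                              read_sigma = 0.5)) {
  stop_if_not(length(modalities) >= 1, "at least one modality required")
  stop_if_not(all(modalities %in% c("dGMI", "ssGMI", "bsGMI", "fsGMI",
                                    "bfGMI")),
              "unknown modality name")
  if (is.null(gains)) gains <- stats::setNames(rep(1, length(modalities)),
                                               modalities)
  structure(list(modalities = modalities,
                 pattern_flow = as.integer(pattern_flow),
                 pattern_lateral = pattern_lateral,
                 fill_fraction = fill_fraction,
                 pattern_seed = as.integer(pattern_seed),
                 gains = gains, fsc_gain = fsc_gain, ssc_gain = ssc_gain,
                 bsc_gain = bsc_gain, strip_rows = as.integer(strip_rows),
                 fluor_gain = fluor_gain, noise = noise),
            class = "optics_config")
}

# One illumination pattern per modality, independent but reproducible.
modality_patterns <- function(optics, lateral) {
  pats <- lapply(seq_along(optics$modalities), function(k) {
    generate_pattern(optics$pattern_flow, lateral, optics$fill_fraction,
                     seed = event_seed(optics$pattern_seed, 131L * k))
  })
  names(pats) <- optics$modalities
  pats
}

# Per-event, per-channel noise model with a counter-derived seed; the
# population's noise_scale multiplies read noise and divides the Poisson
# intensity scale (both raise the noise floor).
scaled_noise <- function(base, noise_scale, seed) {
  noise_model(shot_scale = base$shot_scale / noise_scale^2,
              read_sigma = base$read_sigma * noise_scale,
              seed = seed)
}

#' Simulate a full acquisition run
#'
#' The end-to-end simulated instrument: draws phantoms from the population
#' specification, measures every configured compressive modality through
#' its own structured pattern plus the conventional FSC/SSC/BSC and
#' fluorescence channels, adds detector noise, and runs the acquisition
#' signal chain (high-pass, FSC trigger, fixed-length aligned segments).
#' Phantoms that never meet the trigger condition are counted as dropouts.
#'
#' @param spec A [population_spec()].
#' @param optics An [optics_config()].
#' @param acq An [acquisition_config()].
#' @return An [isgc_events()] table; `meta` records dropout count, the
#'   configuration and the seeds used.
#' @export
simulate_events <- function(spec, optics = optics_config(),
                            acq = acquisition_config()) {
  stop_if_not(inherits(spec, "population_spec"),
              "spec must be a population_spec")
  lateral <- if (is.null(optics$pattern_lateral)) spec$shape[2]
             else optics$pattern_lateral
  pats <- modality_patterns(optics, lateral)
  cfgs <- lapply(optics$modalities, function(m) {
    modality_config(m, gain = optics$gains[[m]], pitch = spec$pitch)
  })
  names(cfgs) <- optics$modalities
  raw_len <- optics$pattern_flow + spec$shape[1] - 1L

  n <- spec$n_events
  rows <- vector("list", n)
  n_drop <- 0L
  n_chan <- length(optics$modalities) + 4L   # + FSC, SSC/BSC, fluorescence
  for (i in seq_len(n)) {
    d <- draw_event_params(spec, i)
    phantom <- make_phantom(d$params, pitch = spec$pitch,
                            shape = spec$shape,
                            seed = event_seed(spec$seed, 2L * i + 1L),
                            stain_amounts = d$stain_amounts,
                            true_class = d$class_name,
                            batch_id = spec$batch_id)
    chan_seed <- function(k) {
      event_seed(spec$seed, 7919.0 * i + 61L * k + 17L)
    }
    signals <- list()
    for (k in seq_along(optics$modalities)) {
      m <- optics$modalities[k]
      map <- phantom$contrast_maps[[cfgs[[m]]$contrast_source]]
      wf <- gmi_waveform(map, pats[[m]], cfgs[[m]])
      signals[[m]] <- add_noise(wf, scaled_noise(optics$noise,
                                                 spec$noise_scale,
                                                 chan_seed(k)))
    }
    sc <- scalar_channels(phantom, optics$fsc_gain, optics$ssc_gain,
                          optics$bsc_gain, optics$strip_rows)
    fsc <- c(sc$fsc_pulse$samples,
             numeric(raw_len - length(sc$fsc_pulse$samples)))
    signals$FSC <- add_noise(raw_signal(fsc, channel = "FSC"),
                             scaled_noise(optics$noise, spec$noise_scale,
                                          chan_seed(n_chan - 3L)))
    nm_sc <- scaled_noise(optics$noise, spec$noise_scale,
                          chan_seed(n_chan - 2L))
    sb <- add_noise(raw_signal(c(sc$ssc, sc$bsc), channel = "SC"), nm_sc)
    fluo <- vapply(names(phantom$fluorescence_maps), function(ch) {
      fluorescence_intensity(phantom, ch, optics$fluor_gain)
    }, 0)
    fluo_noisy <- add_noise(raw_signal(pmax(fluo, 0), channel = "FL"),
                            scaled_noise(optics$noise, spec$noise_scale,
                                         chan_seed(n_chan - 1L)))$samples
    names(fluo_noisy) <- names(phantom$fluorescence_maps)
    ev <- assemble_event(signals,
                         scalars = list(ssc = sb$samples[1],
                                        bsc = sb$samples[2]),
                         fluorescence = fluo_noisy, cfg = acq,
                         event_id = i, true_class = phantom$true_class,
                         batch_id = phantom$batch_id)
    if (is.null(ev)) n_drop <- n_drop + 1L else rows[[i]] <- ev
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  stop_if_not(length(rows) > 0, "no event met the trigger condition")
  out <- collect_event_rows(rows)
  out$meta <- list(n_dropouts = n_drop,
                   n_simulated = n,
                   seed = spec$seed,
                   pattern_seed = optics$pattern_seed,
                   segment_length = acq$segment_length)
  out
}

# Fast row-wise collection of single-event tables (avoids repeated rbind
# of data frames at n ~ 10^3).
collect_event_rows <- function(rows) {
  mods <- names(rows[[1]]$waveforms)
  wf <- lapply(mods, function(m) {
    do.call(rbind, lapply(rows, function(r) r$waveforms[[m]]))
  })
  names(wf) <- mods
  bind_df <- function(field) {
    do.call(rbind, lapply(rows, `[[`, field))
  }
  isgc_events(wf, bind_df("scalars"), bind_df("fluorescence"),
              bind_df("info"))
}

#' Merge two phantoms into a doublet
#'
#' Sums the maps of two phantoms on the first phantom's canvas, the second
#' shifted along the flow axis — the footprint of two cells traversing the
#' interrogation region together.
#'
#' @param p1,p2 `cell_phantom` objects with identical canvas shapes.
#' @param offset_rows Flow-axis shift of the second phantom in pixels.
#' @return A `cell_phantom` whose `true_class` is `"doublet"`.
#' @export
merge_phantoms <- function(p1, p2, offset_rows) {
  stop_if_not(inherits(p1, "cell_phantom") && inherits(p2, "cell_phantom"),
              "p1 and p2 must be cell_phantom objects")
  d1 <- dim(p1$contrast_maps[[1]])
  stop_if_not(identical(d1, dim(p2$contrast_maps[[1]])),
              "phantom canvases must match")
  offset_rows <- as.integer(offset_rows)
  shift_add <- function(a, b) {
    out <- a
    src <- seq_len(max(0L, nrow(b) - abs(offset_rows)))
    if (offset_rows >= 0L) {
      out[src + offset_rows, ] <- out[src + offset_rows, ] + b[src, ]
    } else {
      out[src, ] <- out[src, ] + b[src - offset_rows, ]
    }
    out
  }
  p1$contrast_maps <- Map(shift_add, p1$contrast_maps, p2$contrast_maps)
  common <- intersect(names(p1$fluorescence_maps),
                      names(p2$fluorescence_maps))
  p1$fluorescence_maps <- Map(shift_add, p1$fluorescence_maps[common],
                              p2$fluorescence_maps[common])
  p1$true_class <- "doublet"
  p1
}
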