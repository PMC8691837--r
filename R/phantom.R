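#' Morphology parameters for a synthetic cell phantom
#'
#' Describes the stain-free morphological content of one cell: overall size,
#' nuclear size, internal granularity (speckle texture amplitude, the main
#' source of scatter contrast), elongation, membrane irregularity (blebbing,
#' a cytological correlate of apoptosis) and optical density.
#'
#' @param diameter Cell diameter in micrometres (> 0).
#' @param nucleus_fraction Fraction of the projected cell area occupied by
#'   the nucleus, in `[0, 1]`.
#' @param granularity Dimensionless speckle-texture amplitude (>= 0). Zero
#'   gives an optically smooth cell; values around 1 give strong internal
#'   texture such as cytoplasmic granules.
#' @param eccentricity Eccentricity of the elliptical cell outline, in
#'   `[0, 1)`.
#' @param membrane_irregularity Amplitude (>= 0) of low-order angular
#'   perturbations of the membrane radius (blebbing).
#' @param optical_density Mean optical density of the cytoplasm (>= 0).
#' @param texture_seed Integer mixed into the per-phantom seed so that two
#'   phantoms with identical parameters can still carry independent texture.
#' @return An object of class `morphology_params`.
#' @export
morphology_params <- function(diameter,
                              nucleus_fraction = 0.4,
                              granularity = 0.3,
                              eccentricity = 0,
                              membrane_irregularity = 0,
                              optical_density = 1,
                              texture_seed = 0L) {
  stop_if_not(is_number(diameter) && diameter > 0, "diameter must be > 0")
  stop_if_not(is_number(nucleus_fraction) && nucleus_fraction >= 0 &&
                nucleus_fraction <= 1, "nucleus_fraction must be in [0, 1]")
  stop_if_not(is_number(granularity) && granularity >= 0,
              "granularity must be >= 0")
  stop_if_not(is_number(eccentricity) && eccentricity >= 0 &&
                eccentricity < 1, "eccentricity must be in [0, 1)")
  stop_if_not(is_number(membrane_irregularity) && membrane_irregularity >= 0,
              "membrane_irregularity must be >= 0")
  stop_if_not(is_number(optical_density) && optical_density >= 0,
              "optical_density must be >= 0")
  structure(list(diameter = diameter,
                 nucleus_fraction = nucleus_fraction,
                 granularity = granularity,
                 eccentricity = eccentricity,
                 membrane_irregularity = membrane_irregularity,
                 optical_density = optical_density,
                 texture_seed = as.integer(texture_seed)),
            class = "morphology_params")
}

#' Generate one cell phantom
#'
#' Renders a 2D projected cell on a pixel canvas: an elliptical support
#' (major axis along the flow axis, index 1) perturbed by membrane
#' irregularity, a denser nucleus, and mean-preserving multiplicative
#' speckle texture whose amplitude is `granularity`. Three stain-free
#' contrast maps are produced (`transmission`, `scatter`, `absorption`)
#' plus one fluorescence map per stain channel, scaling linearly with
#' `stain_amounts`.
#'
#' @param params A [morphology_params()] object.
#' @param pitch Pixel pitch in micrometres per pixel.
#' @param shape Canvas dimensions `c(flow, lateral)` in pixels.
#' @param seed Integer seed; the phantom is deterministic given
#'   `(params, seed)`.
#' @param stain_amounts Named numeric vector of stain amounts per
#'   fluorescence channel (>= 0); the fluorescence map of a channel is
#'   `stain_amount` over the cell support.
#' @param true_class,batch_id Optional labels carried on the phantom.
#' @return An object of class `cell_phantom` with elements `pixel_pitch`,
#'   `contrast_maps`, `fluorescence_maps`, `true_class`, `batch_id`.
#' @export
make_phantom <- function(params, pitch = 0.5, shape = c(64L, 32L),
                         seed = 1L, stain_amounts = c(green = 0),
                         true_class = NA_character_,
                         batch_id = NA_character_) {
  stop_if_not(inherits(params, "morphology_params"),
              "params must be a morphology_params object")
  stop_if_not(is_number(pitch) && pitch > 0, "pitch must be > 0")
  shape <- as.integer(shape)
  stop_if_not(length(shape) == 2L && all(shape >= 1L),
              "shape must be two positive pixel dimensions")

  a <- params$diameter / (2 * pitch)                    # semi-major, flow axis
  b <- a * sqrt(1 - params$eccentricity^2)              # semi-minor, lateral
  margin <- 1 + params$membrane_irregularity
  if (2 * a * margin > shape[1] || 2 * b * margin > shape[2]) {
    stop("phantom (diameter ", params$diameter, " um at pitch ", pitch,
         " um/px) does not fit the ", shape[1], "x", shape[2], " canvas",
         call. = FALSE)
  }

  with_seed(event_seed(seed, params$texture_seed), {
    cx <- (shape[1] + 1) / 2
    cy <- (shape[2] + 1) / 2
    x <- (seq_len(shape[1]) - cx) / a
    y <- (seq_len(shape[2]) - cy) / b
    xx <- matrix(x, shape[1], shape[2])
    yy <- matrix(y, shape[1], shape[2], byrow = TRUE)
    rho <- sqrt(xx^2 + yy^2)

    # membrane blebbing: low-order angular modulation of the normalized radius
    if (params$membrane_irregularity > 0) {
      theta <- atan2(yy, xx)
      modes <- 3:6
      amp <- stats::runif(length(modes), 0.5, 1)
      amp <- amp / sum(amp) * params$membrane_irregularity
      phase <- stats::runif(length(modes), 0, 2 * pi)
      bleb <- Reduce(`+`, lapply(seq_along(modes), function(k) {
        amp[k] * cos(modes[k] * theta + phase[k])
      }))
      support <- rho <= 1 + bleb
    } else {
      support <- rho <= 1
    }
    nucleus <- support & (rho <= sqrt(params$nucleus_fraction))

    n_px <- length(rho)
    # mean-one lognormal speckle; granularity blends it in without moving
    # the mean, so total intensity (hence FSC/SSC totals) is size-driven
    sdlog <- 0.7
    speckle <- function() {
      matrix(stats::rlnorm(n_px, meanlog = -sdlog^2 / 2, sdlog = sdlog),
             shape[1], shape[2])
    }
    textured <- function(base, g) {
      pmax(base * (1 + g * (speckle() - 1)), 0)
    }

    g <- params$granularity
    dens <- params$optical_density
    base_tx <- dens * (support + 0.8 * nucleus)        # nucleus 1.8x denser
    transmission <- textured(base_tx, g) * support
    scatter <- textured(0.5 * dens * support, g) * support
    absorption <- textured(0.6 * dens * (support + 0.4 * nucleus), 0.5 * g) *
      support

    stain_amounts <- unlist(stain_amounts)
    stop_if_not(all(stain_amounts >= 0), "stain_amounts must be >= 0")
    fluo <- lapply(stain_amounts, function(s) s * (support * 1))
    names(fluo) <- names(stain_amounts)

    structure(list(pixel_pitch = pitch,
                   contrast_maps = list(transmission = transmission,
                                        scatter = scatter,
                                        absorption = absorption),
                   fluorescence_maps = fluo,
                   true_class = true_class,
                   batch_id = batch_id),
              class = "cell_phantom")
  })
}

#' Batch (donor) effect
#'
#' Systematic differences between acquisition batches or donors: a
#' multiplicative detector/stain gain, additive drifts of morphology
#' parameters, and a noise-level scaling. Used to emulate inter-donor
#' transfer experiments.
#'
#' @param gain_scale Multiplicative gain (> 0) applied to optical density
#'   and stain amounts.
#' @param morphology_drift Named numeric vector of additive shifts to
#'   morphology-parameter means (e.g. `c(diameter = 2)`).
#' @param noise_scale Multiplicative factor (> 0) on acquisition noise.
#' @return An object of class `batch_effect`.
#' @export
batch_effect <- function(gain_scale = 1, morphology_drift = numeric(),
                         noise_scale = 1) {
  stop_if_not(is_number(gain_scale) && gain_scale > 0,
              "gain_scale must be > 0")
  stop_if_not(is_number(noise_scale) && noise_scale > 0,
              "noise_scale must be > 0")
  structure(list(gain_scale = gain_scale,
                 morphology_drift = morphology_drift,
                 noise_scale = noise_scale),
            class = "batch_effect")
}

#' Specify one class of a phantom population
#'
#' @param name Class name.
#' @param mean_params [morphology_params()] giving per-field means.
#' @param sd_params Named numeric vector of per-field Gaussian spreads
#'   (fields absent default to 0).
#' @param stain_amounts Named numeric vector of stain amounts per channel.
#' @param fraction Mixing fraction of this class.
#' @return An object of class `phantom_class_spec`.
#' @export
class_spec <- function(name, mean_params, sd_params = numeric(),
                       stain_amounts = c(green = 0), fraction = 1) {
  stop_if_not(inherits(mean_params, "morphology_params"),
              "mean_params must be a morphology_params object")
  stop_if_not(is_number(fraction) && fraction >= 0, "fraction must be >= 0")
  structure(list(name = name, mean_params = mean_params,
                 sd_params = sd_params,
                 stain_amounts = unlist(stain_amounts),
                 fraction = fraction),
            class = "phantom_class_spec")
}

#' Specify a mixed phantom population
#'
#' @param classes List of [class_spec()] objects; mixing fractions must sum
#'   to 1.
#' @param n_events Number of cells to draw (> 0).
#' @param seed Integer seed; per-event seeds are derived by a counter scheme
#'   (`seed + event index`), so streams are reproducible and extendable.
#' @param pitch Pixel pitch in micrometres per pixel.
#' @param shape Phantom canvas `c(flow, lateral)` in pixels.
#' @param batch_id Batch (donor) identifier tagged on every event.
#' @param noise_scale Multiplier on acquisition noise for this population
#'   (set by [apply_batch_effect()]).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(classes, n_events, seed = 1L, pitch = 0.5,
                            shape = c(64L, 32L), batch_id = "batch1",
                            noise_scale = 1) {
  stop_if_not(length(classes) > 0, "classes must be a nonempty list")
  stop_if_not(all(vapply(classes, inherits, TRUE, "phantom_class_spec")),
              "classes must be class_spec objects")
  fr <- vapply(classes, `[[`, 0, "fraction")
  stop_if_not(abs(sum(fr) - 1) < 1e-9, "mixing fractions must sum to 1")
  stop_if_not(is_count(n_events) && n_events > 0, "n_events must be > 0")
  structure(list(classes = classes, n_events = as.integer(n_events),
                 seed = as.integer(seed), pitch = pitch,
                 shape = as.integer(shape), batch_id = batch_id,
                 noise_scale = noise_scale),
            class = "population_spec")
}

# Draw one event's class index and perturbed morphology, deterministically.
draw_event_params <- function(spec, i) {
  fr <- vapply(spec$classes, `[[`, 0, "fraction")
  with_seed(event_seed(spec$seed, i), {
    ci <- sample.int(length(spec$classes), 1L, prob = fr)
    cl <- spec$classes[[ci]]
    m <- cl$mean_params
    sd <- cl$sd_params
    # truncated-normal jitter (+/- 2.5 sd) keeps draws near the class mean
    # and phantoms on-canvas
    jitter <- function(field, lo, hi) {
      s <- if (field %in% names(sd)) sd[[field]] else 0
      dv <- if (s > 0) max(min(stats::rnorm(1, 0, s), 2.5 * s),
                           -2.5 * s) else 0
      min(max(m[[field]] + dv, lo), hi)
    }
    p <- morphology_params(
      diameter = jitter("diameter", 0.5, Inf),
      nucleus_fraction = jitter("nucleus_fraction", 0, 1),
      granularity = jitter("granularity", 0, Inf),
      eccentricity = jitter("eccentricity", 0, 0.99),
      membrane_irregularity = jitter("membrane_irregularity", 0, Inf),
      optical_density = jitter("optical_density", 0, Inf),
      texture_seed = m$texture_seed
    )
    list(class_index = ci, class_name = cl$name, params = p,
         stain_amounts = cl$stain_amounts)
  })
}

#' Sample a population of cell phantoms
#'
#' Draws `spec$n_events` phantoms: class membership is multinomial in the
#' mixing fractions and each phantom's morphology is drawn from its class
#' distribution. Fully reproducible given `spec$seed`.
#'
#' @param spec A [population_spec()].
#' @param indices Optional subset of event indices to realize (1-based);
#'   defaults to all events. Because seeds are per-event, realizing a
#'   subset yields the same phantoms as realizing the full stream.
#' @return List of `cell_phantom` objects with `true_class` and `batch_id`
#'   set.
#' @export
sample_population <- function(spec, indices = NULL) {
  stop_if_not(inherits(spec, "population_spec"),
              "spec must be a population_spec")
  if (is.null(indices)) indices <- seq_len(spec$n_events)
  lapply(indices, function(i) {
    d <- draw_event_params(spec, i)
    make_phantom(d$params, pitch = spec$pitch, shape = spec$shape,
                 seed = event_seed(spec$seed, 2L * i + 1L),
                 stain_amounts = d$stain_amounts,
                 true_class = d$class_name, batch_id = spec$batch_id)
  })
}

#' Apply a batch (donor) effect to a population specification
#'
#' Returns a new specification tagged with `batch_id` whose class means are
#' shifted by `morphology_drift`, whose optical densities and stain amounts
#' are scaled by `gain_scale`, and whose acquisition noise is scaled by
#' `noise_scale`.
#'
#' @param spec A [population_spec()].
#' @param effect A [batch_effect()].
#' @param batch_id New batch identifier.
#' @param seed Optional new seed for the batch (defaults to the spec's seed
#'   plus a fixed offset so two batches are statistically independent).
#' @return A modified [population_spec()].
#' @export
apply_batch_effect <- function(spec, effect, batch_id,
                               seed = event_seed(spec$seed, 104729L)) {
  stop_if_not(inherits(spec, "population_spec"),
              "spec must be a population_spec")
  stop_if_not(inherits(effect, "batch_effect"),
              "effect must be a batch_effect")
  classes <- lapply(spec$classes, function(cl) {
    m <- unclass(cl$mean_params)
    for (field in names(effect$morphology_drift)) {
      stop_if_not(field %in% names(m),
                  paste0("unknown morphology field '", field, "'"))
      m[[field]] <- m[[field]] + effect$morphology_drift[[field]]
    }
    m$optical_density <- m$optical_density * effect$gain_scale
    mp <- morphology_params(
      diameter = max(m$diameter, 0.5),
      nucleus_fraction = min(max(m$nucleus_fraction, 0), 1),
      granularity = max(m$granularity, 0),
      eccentricity = min(max(m$eccentricity, 0), 0.99),
      membrane_irregularity = max(m$membrane_irregularity, 0),
      optical_density = max(m$optical_density, 0),
      texture_seed = m$texture_seed
    )
    class_spec(cl$name, mp, cl$sd_params,
               cl$stain_amounts * effect$gain_scale, cl$fraction)
  })
  population_spec(classes, spec$n_events, seed = seed, pitch = spec$pitch,
                  shape = spec$shape, batch_id = batch_id,
                  noise_scale = spec$noise_scale * effect$noise_scale)
}
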