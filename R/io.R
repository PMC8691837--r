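EVENT_SCHEMA_VERSION <- "1.0"

# Stable content hash of a plain-list configuration (via its YAML form).
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(rapply(x, unclass, how = "replace")), tmp)
  unname(tools::md5sum(tmp))
}

#' Write an event table to an event-store container
#'
#' Serializes the full table (waveform matrices, scalars, fluorescence,
#' labels) with a schema version and a provenance block (configuration
#' hash, seeds, package version). Optionally writes plain-text CSV
#' mirrors of the scalar and label tables alongside.
#'
#' @param events An [isgc_events()] table.
#' @param path Output path (conventionally `.rds`).
#' @param config Optional configuration list hashed into provenance.
#' @param csv_mirror Write `<path>.scalars.csv` and `<path>.labels.csv`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, config = NULL, csv_mirror = FALSE) {
  stop_if_not(inherits(events, "isgc_events"),
              "events must be an isgc_events table")
  stop_if_not(n_events(events) > 0, "refusing to write an empty table")
  obj <- list(schema_version = EVENT_SCHEMA_VERSION,
              waveforms = events$waveforms,
              scalars = events$scalars,
              fluorescence = events$fluorescence,
              info = events$info,
              meta = events$meta,
              provenance = list(
                config_hash = if (is.null(config)) NA_character_
                              else config_hash(config),
                seed = events$meta$seed,
                package_version =
                  as.character(utils::packageVersion("ghostflow")),
                r_version = R.version.string,
                created = format(Sys.time(), tz = "UTC")))
  saveRDS(obj, path)
  if (csv_mirror) {
    utils::write.csv(cbind(events$info, events$scalars,
                           events$fluorescence),
                     paste0(path, ".scalars.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read an event table from an event-store container
#'
#' Verifies the schema version and the cross-group event-count
#' invariant before returning the table.
#'
#' @param path Path written by [write_events()].
#' @return An [isgc_events()] table; provenance is available under
#'   `$meta$provenance`.
#' @export
read_events <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema_version, EVENT_SCHEMA_VERSION)) {
    stop("event store schema version '", obj$schema_version,
         "' does not match supported version '", EVENT_SCHEMA_VERSION,
         "'", call. = FALSE)
  }
  n <- nrow(obj$info)
  counts <- c(vapply(obj$waveforms, nrow, 0L), nrow(obj$scalars),
              nrow(obj$fluorescence))
  if (!all(counts == n)) {
    stop("corrupt event store: group event counts disagree (",
         paste(counts, collapse = ", "), " vs ", n, ")", call. = FALSE)
  }
  meta <- obj$meta
  meta$provenance <- obj$provenance
  isgc_events(obj$waveforms, obj$scalars, obj$fluorescence, obj$info,
              meta)
}

#' Export scalar channels as an FCS 3.1 file
#'
#' Writes the conventional-cytometry view of an event table (FSC
#' height/width/area, SSC, BSC, and the fluorescence channels) as a
#' single-dataset FCS 3.1 file with 32-bit float data, readable by
#' standard cytometry software.
#'
#' @param events An [isgc_events()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_fcs <- function(events, path) {
  stop_if_not(inherits(events, "isgc_events"),
              "events must be an isgc_events table")
  dat <- cbind(`FSC-H` = events$scalars$fsc_height,
               `FSC-W` = events$scalars$fsc_width,
               `FSC-A` = events$scalars$fsc_area,
               SSC = events$scalars$ssc,
               BSC = events$scalars$bsc)
  if (ncol(events$fluorescence) > 0) {
    fl <- as.matrix(events$fluorescence)
    colnames(fl) <- paste0("FL-", colnames(events$fluorescence))
    dat <- cbind(dat, fl)
  }
  n <- nrow(dat)
  p <- ncol(dat)
  delim <- "/"
  kv <- c("$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = "1,2,3,4",
          "$NEXTDATA" = "0", "$TOT" = as.character(n),
          "$PAR" = as.character(p),
          "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$CYT" = "ghostflow simulated cytometer")
  for (j in seq_len(p)) {
    kv[paste0("$P", j, "N")] <- colnames(dat)[j]
    kv[paste0("$P", j, "B")] <- "32"
    kv[paste0("$P", j, "E")] <- "0,0"
    kv[paste0("$P", j, "R")] <- format(ceiling(max(dat[, j], 1)),
                                       scientific = FALSE)
  }
  # fixed-width offsets so the TEXT segment length is stable
  data_bytes <- 4L * n * p
  make_text <- function(begin_data, end_data) {
    kv2 <- c(kv, "$BEGINDATA" = formatC(begin_data, width = 10, flag = "0"),
             "$ENDDATA" = formatC(end_data, width = 10, flag = "0"))
    paste0(delim, paste0(names(kv2), delim, unname(kv2), delim,
                         collapse = ""))
  }
  header_len <- 58L
  text_len <- nchar(make_text(0L, 0L), type = "bytes")
  begin_text <- header_len
  end_text <- begin_text + text_len - 1L
  begin_data <- end_text + 1L
  end_data <- begin_data + data_bytes - 1L
  text <- make_text(begin_data, end_data)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", begin_text, end_text,
                    if (begin_data <= 99999999) begin_data else 0L,
                    if (end_data <= 99999999) end_data else 0L, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(dat)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Parse a time value with unit suffix
#'
#' Accepts `us`, `ms` and `s` suffixes (e.g. `"100us"`) or plain numbers
#' interpreted as seconds; returns seconds.
#'
#' @param x Character or numeric scalar.
#' @return Time in seconds.
#' @export
parse_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  m <- regmatches(x, regexec("^([0-9.eE+-]+)\\s*(us|ms|s)?$", trimws(x)))[[1]]
  stop_if_not(length(m) >= 2 && nzchar(m[2]),
              paste0("cannot parse time '", x, "'"))
  val <- as.numeric(m[2])
  stop_if_not(is.finite(val), paste0("cannot parse time '", x, "'"))
  unit <- if (length(m) >= 3 && nzchar(m[3])) m[3] else "s"
  val * switch(unit, us = 1e-6, ms = 1e-3, s = 1)
}

run_config_sections <- c("population", "optics", "acquisition", "gating",
                         "classifier", "seed")

#' Read and validate a run configuration file
#'
#' A YAML file with sections `population`, `optics`, `acquisition`,
#' `gating`, `classifier` and a global `seed`; unknown top-level keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return Named list of validated sections (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  extra <- setdiff(names(cfg), run_config_sections)
  if (length(extra) > 0) {
    stop("unknown configuration section(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  stop_if_not(!is.null(cfg$population), "configuration needs a population")
  structure(cfg, class = "run_config")
}

#' Write a run configuration file
#' @param cfg A `run_config` (or plain list of sections).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(rapply(unclass(cfg), unclass, how = "replace"), path)
  invisible(path)
}

morph_fields <- c("diameter", "nucleus_fraction", "granularity",
                  "eccentricity", "membrane_irregularity",
                  "optical_density")

#' Build a population specification from a configuration section
#'
#' @param pop The `population` section of a [read_run_config()] result:
#'   `n_events`, `seed`, optional `pitch`/`shape`/`batch_id`, and
#'   `classes`, each with `name`, `fraction`, optional `stain` map,
#'   and `params` (morphology means plus optional `<field>_sd` spreads).
#' @param seed Optional seed overriding the section's.
#' @return A [population_spec()].
#' @export
population_from_config <- function(pop, seed = NULL) {
  stop_if_not(!is.null(pop$classes) && length(pop$classes) > 0,
              "population needs classes")
  classes <- lapply(pop$classes, function(cl) {
    pars <- cl$params
    known <- c(morph_fields, paste0(morph_fields, "_sd"), "texture_seed")
    extra <- setdiff(names(pars), known)
    if (length(extra) > 0) {
      stop("unknown morphology field(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    mean_args <- pars[intersect(names(pars), morph_fields)]
    mp <- do.call(morphology_params, mean_args)
    sd_names <- grep("_sd$", names(pars), value = TRUE)
    sds <- stats::setNames(as.numeric(unlist(pars[sd_names])),
                           sub("_sd$", "", sd_names))
    stain <- if (is.null(cl$stain)) c(green = 0) else unlist(cl$stain)
    class_spec(cl$name, mp, sds, stain, cl$fraction)
  })
  population_spec(classes,
                  n_events = pop$n_events,
                  seed = if (!is.null(seed)) seed else
                    (if (is.null(pop$seed)) 1L else pop$seed),
                  pitch = if (is.null(pop$pitch)) 0.5 else pop$pitch,
                  shape = if (is.null(pop$shape)) c(64L, 32L) else
                    as.integer(pop$shape),
                  batch_id = if (is.null(pop$batch_id)) "batch1" else
                    pop$batch_id)
}

#' Build an optics configuration from a configuration section
#' @param opt The `optics` section (may be `NULL` for defaults).
#' @return An [optics_config()].
#' @export
optics_from_config <- function(opt) {
  if (is.null(opt)) return(optics_config())
  noise <- if (is.null(opt$noise)) noise_model(10, 0.5) else
    noise_model(shot_scale = opt$noise$shot_scale %||% 10,
                read_sigma = opt$noise$read_sigma %||% 0.5)
  optics_config(
    modalities = opt$modalities %||% c("dGMI", "ssGMI", "bsGMI", "fsGMI",
                                       "bfGMI"),
    pattern_flow = opt$pattern_flow %||% 128L,
    fill_fraction = opt$fill_fraction %||% 0.5,
    pattern_seed = opt$pattern_seed %||% 20L,
    noise = noise)
}

#' Build an acquisition configuration from a configuration section
#' @param acq The `acquisition` section (may be `NULL` for defaults).
#' @return An [acquisition_config()].
#' @export
acquisition_from_config <- function(acq) {
  if (is.null(acq)) return(acquisition_config())
  acquisition_config(
    highpass_alpha = acq$highpass_alpha %||% 0.995,
    trigger_threshold = acq$trigger_threshold %||% 3,
    trigger_min_run = acq$trigger_min_run %||% 3L,
    segment_length = acq$segment_length %||% 128L,
    pre_trigger = acq$pre_trigger %||% 8L,
    width_fraction = acq$width_fraction %||% 0.5)
}
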