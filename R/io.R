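## Delimited-text trace format: '#'-prefixed metadata header, then a CSV body
## with columns time_s, voltage_V at full double precision.

#' Write an acquisition trace to delimited text
#'
#' Metadata go first as `# key: value` lines, followed by a `time_s,voltage_V`
#' CSV body serialized at full precision (`%.17g`), so write-then-read is a
#' bit-identical round trip.
#'
#' @param trace An [acquisition_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "acquisition_trace"))
  meta <- c(list(sample_id = trace$sample_id, repeat_index = trace$repeat_index),
            trace$meta)
  hdr <- vapply(names(meta), function(k) {
    v <- meta[[k]]
    sprintf("# %s: %s", k, if (is.numeric(v)) sprintf("%.17g", v) else as.character(v))
  }, character(1))
  body <- sprintf("%.17g,%.17g", trace$time, trace$voltage)
  writeLines(c(hdr, "time_s,voltage_V", body), path)
  invisible(path)
}

#' Read an acquisition trace from delimited text
#'
#' Parses the `#`-metadata header and CSV body written by [write_trace()],
#' validating that the body is numeric, the time grid uniform, and (when fs
#' and duration metadata are present) that the sample count equals
#' `fs * duration`. Malformed rows raise an error naming the line.
#'
#' @param path File path.
#' @return An [acquisition_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  head_lines <- readLines(path, n = 200L)
  n_meta <- sum(cumprod(startsWith(head_lines, "#")))
  meta <- list()
  for (ln in head_lines[seq_len(n_meta)]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[trimws(key)]] <- if (!is.na(num)) num else val
  }
  dat <- data.table::fread(path, skip = n_meta, header = TRUE, sep = ",",
                           colClasses = "character", data.table = FALSE)
  if (ncol(dat) != 2L) {
    stop(sprintf("%s: expected 2 columns (time_s, voltage_V), found %d",
                 path, ncol(dat)), call. = FALSE)
  }
  tt <- suppressWarnings(as.numeric(dat[[1L]]))
  vv <- suppressWarnings(as.numeric(dat[[2L]]))
  bad <- which(is.na(tt) | is.na(vv))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric row at line %d", path,
                 n_meta + 1L + bad[1L]), call. = FALSE)
  }
  if (length(tt) > 1L) {
    dt <- diff(tt)
    if (any(abs(dt - dt[1L]) > 1e-9 * abs(dt[1L]))) {
      stop(sprintf("%s: non-uniform time grid", path), call. = FALSE)
    }
  }
  sample_id <- if (!is.null(meta$sample_id)) meta$sample_id else basename(path)
  repeat_index <- if (!is.null(meta$repeat_index)) as.integer(meta$repeat_index) else 1L
  meta$sample_id <- NULL
  meta$repeat_index <- NULL
  acquisition_trace(time = tt, voltage = vv, sample_id = sample_id,
                    repeat_index = repeat_index, meta = meta)
}

## ---- run configuration (YAML) -------------------------------------------

.check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

#' Default run configuration
#'
#' The full pipeline configuration with the reference defaults: 9 mT / 5 kHz
#' drive, 1 MS/s for 0.1 s, gain 10, 10 repeats, the seven-group panel, and
#' the default classification bands.
#'
#' @return A named list (class `run_config`) accepted by [write_run_config()]
#'   and the CLI.
#' @export
default_run_config <- function() {
  panel <- default_tissue_panel()
  structure(list(
    seed = 1L,
    physics = list(
      ensemble = list(moment = panel$ensemble$moment,
                      concentration = panel$ensemble$concentration,
                      granulometry = NULL),
      drive = list(amplitude_T = panel$drive$amplitude_T,
                   frequency_Hz = panel$drive$frequency_Hz),
      environment = list(temperature_K = panel$env$temperature_K)),
    instrument = list(
      coil = list(sensitivity = panel$coil$sensitivity,
                  sample_volume = panel$coil$sample_volume,
                  gain = panel$coil$gain,
                  feedthrough_amplitude = panel$coil$feedthrough_amplitude),
      acquisition = list(fs = panel$acq$fs, duration = panel$acq$duration,
                         n_repeats = panel$acq$n_repeats,
                         noise_sigma = panel$acq$noise_sigma)),
    panel = list(groups = lapply(seq_len(nrow(panel$groups)), function(i) {
      list(label = panel$groups$label[i],
           target_ratio = panel$groups$target_ratio[i],
           n_samples = panel$groups$n_samples[i])
    })),
    analysis = list(thresholds = list(benign_max = threshold_config()$benign_max,
                                      malignant_min = threshold_config()$malignant_min),
                    noise_floor = 0)),
    class = "run_config")
}

#' Write a run configuration as YAML
#'
#' @param config A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys, validates every field
#' through the type constructors, and returns the assembled configuration
#' objects. Omitted sections fall back to the defaults of
#' [default_run_config()].
#'
#' @param path YAML file path.
#' @return List with `panel` (a [tissue_panel_config()]), `thresholds`,
#'   `noise_floor` and `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  base <- unclass(default_run_config())
  .check_keys(raw, c(names(base), "output_dir"), "config")
  cfg <- modifyList(base, raw, keep.null = TRUE)
  if (!is.null(raw$panel)) cfg$panel <- raw$panel  # group lists replace, not merge

  .check_keys(cfg$physics, c("ensemble", "drive", "environment"), "physics")
  .check_keys(cfg$physics$ensemble, c("moment", "concentration", "granulometry"),
              "physics.ensemble")
  .check_keys(cfg$physics$drive, c("amplitude_T", "frequency_Hz"), "physics.drive")
  .check_keys(cfg$physics$environment, c("temperature_K"), "physics.environment")
  .check_keys(cfg$instrument, c("coil", "acquisition"), "instrument")
  .check_keys(cfg$instrument$coil,
              c("sensitivity", "sample_volume", "gain", "feedthrough_amplitude"),
              "instrument.coil")
  .check_keys(cfg$instrument$acquisition,
              c("fs", "duration", "n_repeats", "noise_sigma"),
              "instrument.acquisition")
  .check_keys(cfg$panel, "groups", "panel")
  .check_keys(cfg$analysis, c("thresholds", "noise_floor"), "analysis")
  .check_keys(cfg$analysis$thresholds, c("benign_max", "malignant_min"),
              "analysis.thresholds")

  gran <- cfg$physics$ensemble$granulometry
  if (!is.null(gran)) {
    .check_keys(gran, c("median_diameter", "log_sigma", "Ms"),
                "physics.ensemble.granulometry")
    gran <- lognormal_granulometry(gran$median_diameter, gran$log_sigma, gran$Ms)
  }
  ensemble <- particle_ensemble(moment = cfg$physics$ensemble$moment,
                                concentration = cfg$physics$ensemble$concentration,
                                granulometry = gran)
  drive <- drive_field(cfg$physics$drive$amplitude_T, cfg$physics$drive$frequency_Hz)
  env <- mps_environment(cfg$physics$environment$temperature_K, 0)
  coil <- do.call(coil_model, cfg$instrument$coil)
  acq <- do.call(acquisition_config,
                 c(cfg$instrument$acquisition, list(seed = cfg$seed)))
  groups <- do.call(rbind, lapply(cfg$panel$groups, function(g) {
    .check_keys(g, c("label", "target_ratio", "n_samples"), "panel.groups[]")
    data.frame(label = g$label, target_ratio = g$target_ratio,
               n_samples = if (is.null(g$n_samples)) 1L else g$n_samples)
  }))
  panel <- tissue_panel_config(groups, ensemble = ensemble, drive = drive,
                               env = env, coil = coil, acq = acq)
  thresholds <- threshold_config(cfg$analysis$thresholds$benign_max,
                                 cfg$analysis$thresholds$malignant_min)
  list(panel = panel, thresholds = thresholds,
       noise_floor = cfg$analysis$noise_floor, seed = as.integer(cfg$seed))
}
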