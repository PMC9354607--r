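# File formats: versioned JSON recording schema, truth side-car, flat
# key/value run configuration.

.SCHEMA_VERSION <- "1.0"

burst_to_list <- function(st) {
  list(freq_hz = st$freq_hz, duration_ms = st$duration_ms,
       ramp_ms = st$ramp_ms, level_db_spl = st$level_db_spl,
       phase = st$phase)
}

burst_from_list <- function(x) {
  tone_burst(x$freq_hz, x$duration_ms, x$ramp_ms,
             if (is.null(x$level_db_spl)) NA_real_ else x$level_db_spl,
             x$phase)
}

pair_to_list <- function(pair) {
  list(cond = pair$cond$samples, rare = pair$rare$samples)
}

pair_from_list <- function(x, stimulus, fs_hz, prestim_ms) {
  sc <- stimulus; sc$phase <- "condensation"
  sr <- stimulus; sr$phase <- "rarefaction"
  list(cond = epoch_recording(unlist(x$cond), fs_hz, prestim_ms, sc),
       rare = epoch_recording(unlist(x$rare), fs_hz, prestim_ms, sr))
}

#' Write a simulation's recordings to the JSON recording schema
#'
#' Serialises an insertion or sweep simulation (metadata, stimuli, geometry,
#' per-step or per-electrode sample arrays in microvolts, noise recordings)
#' to a schema-versioned JSON document. Numeric fields round-trip at full
#' double precision.
#'
#' @param sim An `insertion_simulation` or `sweep_simulation`.
#' @param path Output file path.
#' @param case_id Optional case identifier embedded in the file.
#' @return `path`, invisibly.
#' @seealso [read_recording_json()], [write_truth_json()]
#' @export
write_recording_json <- function(sim, path, case_id = "sim") {
  stopifnot(inherits(sim, c("insertion_simulation", "sweep_simulation")))
  doc <- list(
    schema_version = .SCHEMA_VERSION,
    kind = sim$kind,
    case_id = case_id,
    seed = sim$seed,
    fs_hz = sim$fs_hz,
    prestim_ms = sim$prestim_ms,
    epoch_ms = sim$epoch_ms,
    noise_sd_uv = sim$noise_sd_uv,
    stimuli = lapply(sim$stimuli, burst_to_list),
    geometry = list(
      diameter_mm = sim$geometry$diameter_mm,
      apical_angle_deg = sim$geometry$apical_angle_deg,
      basal_angle_deg = sim$geometry$basal_angle_deg,
      n_electrodes = sim$geometry$n_electrodes
    )
  )
  if (sim$kind == "insertion") {
    doc$steps <- lapply(sim$steps, function(st) lapply(st, pair_to_list))
    doc$noise_pairs <- lapply(sim$noise_pairs,
                              function(np) lapply(np, pair_to_list))
  } else {
    set_to_list <- function(set) {
      list(cond = lapply(set$cond, function(e) e$samples),
           rare = lapply(set$rare, function(e) e$samples))
    }
    doc$electrodes <- lapply(sim$electrodes,
                             function(e) lapply(e, set_to_list))
    doc$noise_sets <- lapply(sim$noise_sets,
                             function(ns) lapply(ns, set_to_list))
    doc$n_reps <- sim$n_reps
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

stop_schema <- function(field) {
  stop(sprintf("recording file violates schema: missing/invalid `%s`",
               field), call. = FALSE)
}

#' Read a JSON recording file
#'
#' Validates the schema and reconstructs the simulation-shaped object that
#' [build_insertion_trace()] / [sweep_from_recordings()] consume.
#'
#' @param path Path to a file written by [write_recording_json()].
#' @return A list shaped like an `insertion_simulation` or
#'   `sweep_simulation` (with the matching class).
#' @export
read_recording_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("schema_version", "kind", "fs_hz", "prestim_ms", "epoch_ms",
              "stimuli")) {
    if (is.null(doc[[f]])) stop_schema(f)
  }
  if (!doc$kind %in% c("insertion", "sweep")) stop_schema("kind")
  stimuli <- lapply(doc$stimuli, burst_from_list)
  names(stimuli) <- names(doc$stimuli)
  fs <- doc$fs_hz
  prestim <- doc$prestim_ms
  n_epoch <- round(doc$epoch_ms * fs / 1000)

  check_pair <- function(p, where) {
    if (is.null(p$cond) || is.null(p$rare) ||
        length(p$cond) != n_epoch || length(p$rare) != n_epoch) {
      stop(sprintf("recording file violates schema: %s sample arrays", where),
           call. = FALSE)
    }
  }

  out <- list(kind = doc$kind, fs_hz = fs, prestim_ms = prestim,
              epoch_ms = doc$epoch_ms, seed = doc$seed,
              noise_sd_uv = doc$noise_sd_uv, stimuli = stimuli,
              case_id = doc$case_id)
  if (!is.null(doc$geometry)) {
    out$geometry <- cochlear_geometry(
      doc$geometry$diameter_mm, doc$geometry$apical_angle_deg,
      doc$geometry$basal_angle_deg, doc$geometry$n_electrodes)
  }
  if (doc$kind == "insertion") {
    if (is.null(doc$steps)) stop_schema("steps")
    out$steps <- lapply(seq_along(doc$steps), function(i) {
      st <- doc$steps[[i]]
      pair <- lapply(names(stimuli), function(f) {
        check_pair(st[[f]], sprintf("step %d / %s Hz", i, f))
        pair_from_list(st[[f]], stimuli[[f]], fs, prestim)
      })
      names(pair) <- names(stimuli)
      pair
    })
    out$noise_pairs <- lapply(doc$noise_pairs, function(np) {
      pair <- lapply(names(stimuli), function(f) {
        pair_from_list(np[[f]], stimuli[[f]], fs, prestim)
      })
      names(pair) <- names(stimuli)
      pair
    })
    class(out) <- "insertion_simulation"
  } else {
    if (is.null(doc$electrodes)) stop_schema("electrodes")
    set_from_list <- function(x, stimulus) {
      sc <- stimulus; sc$phase <- "condensation"
      sr <- stimulus; sr$phase <- "rarefaction"
      list(
        cond = lapply(x$cond, function(s) {
          epoch_recording(unlist(s), fs, prestim, sc)
        }),
        rare = lapply(x$rare, function(s) {
          epoch_recording(unlist(s), fs, prestim, sr)
        })
      )
    }
    out$electrodes <- lapply(doc$electrodes, function(e) {
      per_freq <- lapply(names(stimuli), function(f) {
        set_from_list(e[[f]], stimuli[[f]])
      })
      names(per_freq) <- names(stimuli)
      per_freq
    })
    names(out$electrodes) <- names(doc$electrodes)
    out$noise_sets <- lapply(doc$noise_sets, function(ns) {
      per_freq <- lapply(names(stimuli), function(f) {
        set_from_list(ns[[f]], stimuli[[f]])
      })
      names(per_freq) <- names(stimuli)
      per_freq
    })
    out$n_reps <- doc$n_reps
    class(out) <- "sweep_simulation"
  }
  out
}

#' Write the simulation ground-truth side-car
#'
#' @param truth A `sim_truth` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = I(17), dataframe = "columns")
  invisible(path)
}

#' Default run configuration
#'
#' Collects the pipeline's fixed analysis constants (30% relative drop
#' criterion, 2-uV count threshold, 3-SD significance, the 9.5-mm/350-degree
#' risk rule) together with simulation parameters and the seed.
#'
#' @param seed Integer seed recorded in all outputs (default 1).
#' @return Named list of configuration values.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    rel_drop_threshold = 0.30,
    count_abs_uv = 2.0,
    significance_n_sd = 3,
    risk_diameter_mm = 9.5,
    risk_angle_deg = 350,
    diameter_mm = 9.2,
    apical_angle_deg = 396,
    basal_angle_deg = 20,
    n_steps = 200L,
    n_reps = 30L,
    noise_sd_uv = default_noise_sd(),
    peak_uv = 10
  )
}

#' Read a flat key/value configuration file
#'
#' Parses lines of the form `key = value` (strings, numbers, or
#' true/false), ignoring blank lines and `#` comments, and merges them over
#' [default_run_config()]. Unknown keys are kept.
#'
#' @param path Path to the configuration file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_run_config()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("invalid config line (expected `key = value`): ", ln,
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    parsed <- suppressWarnings(as.numeric(val))
    if (!is.na(parsed)) {
      cfg[[key]] <- parsed
    } else if (tolower(val) %in% c("true", "false")) {
      cfg[[key]] <- tolower(val) == "true"
    } else {
      cfg[[key]] <- val
    }
  }
  cfg
}

# Short md5 hash of a configuration, embedded in outputs for provenance.
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(substr(tools::md5sum(tmp), 1, 12))
}
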