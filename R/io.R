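#' @title CSV and JSON dialects
#' @name rlrpaco2_io
#' @description
#' Trial recordings are written as long-format CSV (`animal_id`, `time_s`
#' with 3 decimals, `channel`, `value`, `unit`); blood gases as CSV
#' (`animal_id`, `minute_iso8601`, `paco2_mmHg`, `ph`, `pao2_mmHg`); fitted
#' models as versioned JSON. Times inside the package are seconds from trial
#' start; ISO-8601 is used only for blood-gas minutes, anchored at a fixed
#' UTC origin to avoid timezone ambiguity in synthetic data.
NULL

.time_origin <- function() as.POSIXct("2026-01-01 00:00:00", tz = "UTC")
.model_schema_version <- 1L

#' Write a trial recording and its blood gases to CSV
#'
#' @param animal A `list(recording, bga)` pair as produced by
#'   [generate_population()].
#' @param trial_path,bga_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_trial <- function(animal, trial_path, bga_path) {
  rec <- animal$recording
  units <- channel_units(rec$channel_specs)
  long <- do.call(rbind, lapply(names(rec$channels), function(nm) {
    ch <- rec$channels[[nm]]
    data.frame(animal_id = rec$animal_id,
               time_s = sprintf("%.3f", ch$time),
               channel = nm, value = ch$value, unit = units[[nm]],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, trial_path, row.names = FALSE)
  bga <- animal$bga
  out <- data.frame(
    animal_id = bga$animal_id,
    minute_iso8601 = format(.time_origin() + bga$minute,
                            "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    paco2_mmHg = bga$paco2, ph = bga$ph, pao2_mmHg = bga$pao2,
    stringsAsFactors = FALSE)
  utils::write.csv(out, bga_path, row.names = FALSE)
  invisible(c(trial_path, bga_path))
}

#' Load a trial recording and its blood gases from CSV
#'
#' Channels must belong to the canonical catalogue; unknown channel names
#' and unit mismatches are rejected with classed errors. Blood-gas
#' timestamps with a non-zero seconds component are normalised to the
#' documented minute with a warning (documentation is minute-resolved).
#'
#' @param trial_path,bga_path CSV paths written by [write_trial()].
#' @param channel_specs Channel catalogue used for validation.
#' @return A `list(recording, bga)` pair.
#' @export
load_trial <- function(trial_path, bga_path,
                       channel_specs = default_channel_specs()) {
  long <- utils::read.csv(trial_path, stringsAsFactors = FALSE)
  need <- c("animal_id", "time_s", "channel", "value", "unit")
  if (!all(need %in% names(long)))
    stop_parse(paste0("trial CSV must have columns: ",
                      paste(need, collapse = ", ")))
  unknown <- setdiff(unique(long$channel), names(channel_specs))
  if (length(unknown))
    stop_parse(paste0("unknown channel(s): ", paste(unknown, collapse = ", ")))
  units <- channel_units(channel_specs)
  channels <- list()
  for (nm in intersect(names(channel_specs), unique(long$channel))) {
    sub <- long[long$channel == nm, , drop = FALSE]
    bad_unit <- unique(sub$unit[sub$unit != units[[nm]]])
    if (length(bad_unit))
      stop_unit(sprintf("channel '%s': expected unit '%s', found '%s'",
                        nm, units[[nm]], bad_unit[1]))
    tt <- as.numeric(sub$time_s)
    if (any(is.na(tt)))
      stop_parse(sprintf("channel '%s': malformed time_s at line %d", nm,
                         which(is.na(tt))[1]))
    o <- order(tt)
    channels[[nm]] <- data.frame(time = tt[o], value = sub$value[o])
  }
  bga_raw <- utils::read.csv(bga_path, stringsAsFactors = FALSE)
  bneed <- c("animal_id", "minute_iso8601", "paco2_mmHg", "ph", "pao2_mmHg")
  if (!all(bneed %in% names(bga_raw)))
    stop_parse(paste0("BGA CSV must have columns: ",
                      paste(bneed, collapse = ", ")))
  ts <- as.POSIXct(bga_raw$minute_iso8601, format = "%Y-%m-%dT%H:%M:%SZ",
                   tz = "UTC")
  if (any(is.na(ts)))
    stop_parse(sprintf("BGA CSV: malformed timestamp at line %d",
                       which(is.na(ts))[1] + 1L))
  secs <- as.numeric(ts - .time_origin(), units = "secs")
  if (any(secs %% 60 != 0)) {
    warning("BGA timestamps with seconds component normalised to the documented minute")
    secs <- floor(secs / 60) * 60
  }
  bga <- data.frame(animal_id = bga_raw$animal_id, minute = secs,
                    paco2 = bga_raw$paco2_mmHg, ph = bga_raw$ph,
                    pao2 = bga_raw$pao2_mmHg, stringsAsFactors = FALSE)
  recording <- structure(
    list(animal_id = bga$animal_id[1] %||% long$animal_id[1],
         start_time = 0, channels = channels, capnogram = NULL,
         channel_specs = channel_specs),
    class = "trial_recording")
  recording$animal_id <- long$animal_id[1]
  list(recording = recording, bga = bga)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a[1])) b else a

#' Save / load a fitted model as JSON
#'
#' The JSON schema (version 1) stores the intercept, the term list
#' (`base`, `transform`, `coefficient`), the robust scale, convergence
#' information and a provenance block. Coefficients survive the round trip
#' at full double precision.
#'
#' @param model A `paco2_model`.
#' @param path JSON file path.
#' @param seed Optional seed recorded in the provenance block.
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   `paco2_model`.
#' @export
save_model <- function(model, path, seed = NULL) {
  obj <- list(
    schema_version = .model_schema_version,
    intercept = model$intercept,
    terms = model$terms[, c("base", "transform", "coefficient")],
    scale = model$scale, n_iter = model$n_iter,
    converged = model$converged, method = model$method,
    provenance = list(
      tool = "rlrpaco2",
      version = as.character(utils::packageVersion("rlrpaco2")),
      seed = seed))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) ||
      obj$schema_version != .model_schema_version)
    stop_schema(sprintf("unsupported model schema version: %s",
                        obj$schema_version %||% "<missing>"))
  if (is.null(obj$intercept))
    stop_schema("model JSON lacks an intercept")
  terms <- if (is.null(obj$terms) || length(obj$terms) == 0L)
    data.frame(base = character(), transform = character(),
               coefficient = numeric()) else as.data.frame(obj$terms)
  paco2_model(intercept = obj$intercept, terms = terms,
              scale = obj$scale %||% NA_real_,
              n_iter = obj$n_iter %||% 0L,
              converged = isTRUE(obj$converged),
              method = obj$method %||% "loaded")
}

#' Write averaged samples / estimate streams as CSV
#'
#' @param samples Data frame from [collect_design_samples()] (optionally
#'   filtered).
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @param estimates Estimate record data frame.
#' @param animal_id Animal identifier column value.
#' @export
write_estimates <- function(estimates, path, animal_id = "animal01") {
  out <- data.frame(animal_id = animal_id,
                    time_s = sprintf("%.3f", estimates$time),
                    method = estimates$method,
                    value_mmHg = estimates$value,
                    withheld_reason = estimates$withheld_reason,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a run configuration as JSON
#'
#' Serialises the generator, filter, fit and online configurations together
#' with the seed, so a full run is reproducible from one file.
#'
#' @param config Named list of configuration objects (e.g.
#'   `list(trial = trial_config(), filter = filter_config())`).
#' @param path JSON path.
#' @return `write_config` invisibly returns `path`; `read_config` the list.
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    if (inherits(x, "paco2_model"))
      return(list(intercept = x$intercept,
                  terms = x$terms[, c("base", "transform", "coefficient")]))
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
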