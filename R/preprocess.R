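#' Window policy
#'
#' The design-phase regression averages every variable over a centred 2-min
#' window around the documented minute of the blood-gas analysis (only the
#' minute, not the exact instant, is documented by hand). The online
#' estimator instead uses a short trailing 20-s window that includes only
#' measurements preceding the estimation instant, so no delay is created by
#' waiting for data.
#'
#' @param mode `"centred"` or `"trailing"`.
#' @param width Window width in seconds; defaults to 120 (centred) or 20
#'   (trailing).
#' @param min_coverage Minimum fraction of expected samples a channel must
#'   provide to count as covered.
#' @return Object of class `window_policy`.
#' @export
window_policy <- function(mode = c("centred", "trailing"), width = NULL,
                          min_coverage = 0.5) {
  mode <- match.arg(mode)
  if (is.null(width)) width <- if (mode == "centred") 120 else 20
  if (!is.numeric(width) || width <= 0)
    stop_invalid_config("window width must be > 0")
  if (min_coverage <= 0 || min_coverage > 1)
    stop_invalid_config("min_coverage must lie in (0, 1]")
  structure(list(mode = mode, width = width, min_coverage = min_coverage),
            class = "window_policy")
}

#' Extract end-tidal CO2 from a capnogram window
#'
#' The end-tidal CO2 is the maximum CO2 partial pressure in the last
#' `window` seconds of the waveform (default 4 s, giving the 0.25 Hz etCO2
#' cadence when applied on a stream).
#'
#' @param capnogram Data frame with columns `time` (s) and `value` (mmHg),
#'   ending at the evaluation instant.
#' @param window Lookback in seconds.
#' @return etCO2 in mmHg, or `NA_real_` when the window holds no samples
#'   (missing-data signal, not an error).
#' @export
extract_etco2 <- function(capnogram, window = 4) {
  if (is.null(capnogram) || nrow(capnogram) == 0L) return(NA_real_)
  t_end <- max(capnogram$time)
  v <- capnogram$value[capnogram$time > t_end - window]
  if (!length(v)) return(NA_real_)
  max(v)
}

#' @rdname extract_etco2
#' @param cadence Seconds between emitted etCO2 values (default 4 s).
#' @return For `extract_etco2_stream`, a data frame `time`/`value` with one
#'   etCO2 value per cadence tick, each the maximum over `(t - window, t]`.
#' @export
extract_etco2_stream <- function(capnogram, window = 4, cadence = 4) {
  if (is.null(capnogram) || nrow(capnogram) == 0L)
    return(data.frame(time = numeric(), value = numeric()))
  ticks <- seq(cadence * ceiling(min(capnogram$time + window) / cadence),
               max(capnogram$time), by = cadence)
  val <- vapply(ticks, function(t) {
    v <- capnogram$value[capnogram$time > t - window & capnogram$time <= t]
    if (length(v)) max(v) else NA_real_
  }, 0)
  data.frame(time = ticks, value = val)
}

# Mean and coverage of one channel over a half-open window.
# centred: [lo, hi); trailing: (lo, hi].
window_stats <- function(channel, lo, hi, mode, rate, min_coverage) {
  inside <- if (mode == "centred")
    channel$time >= lo & channel$time < hi
  else
    channel$time > lo & channel$time <= hi
  v <- channel$value[inside]
  v <- v[is.finite(v)]
  expected <- max(1, round((hi - lo) * rate))
  coverage <- min(1, length(v) / expected)
  list(mean = if (coverage >= min_coverage) mean(v) else NA_real_,
       coverage = coverage)
}

average_window <- function(trial, reference_time, lo, hi, mode, min_coverage) {
  specs <- trial$channel_specs
  nms <- names(trial$channels)
  values <- coverage <- stats::setNames(rep(NA_real_, length(nms)), nms)
  for (nm in nms) {
    st <- window_stats(trial$channels[[nm]], lo, hi, mode,
                       specs[[nm]]$sampling_rate, min_coverage)
    values[nm] <- st$mean
    coverage[nm] <- st$coverage
  }
  structure(
    list(animal_id = trial$animal_id, reference_time = reference_time,
         values = values, coverage = coverage,
         complete = all(coverage >= min_coverage), paco2 = NA_real_),
    class = "averaged_sample")
}

#' Centred window average for one blood-gas analysis
#'
#' Averages every channel over `[minute - 60 s, minute + 60 s)` around the
#' documented minute `m` of the blood-gas record; since only the minute is
#' documented, the true sampling instant is guaranteed to lie inside this
#' window. Channels providing fewer than `min_coverage` of their expected
#' samples are marked uncovered (value `NA`); the sample is `complete` only
#' when every channel is covered.
#'
#' @param trial A `trial_recording`.
#' @param bga One blood-gas record (list or one-row data frame with at least
#'   `minute` and `paco2`).
#' @param policy A centred [window_policy()].
#' @return Object of class `averaged_sample`: `animal_id`,
#'   `reference_time`, named `values` and `coverage` vectors, `complete`,
#'   `paco2`.
#' @export
centred_average <- function(trial, bga, policy = window_policy("centred")) {
  if (policy$mode != "centred")
    stop_invalid_config("centred_average requires a centred window policy")
  m <- bga$minute
  out <- average_window(trial, m, m - policy$width / 2, m + policy$width / 2,
                        "centred", policy$min_coverage)
  out$paco2 <- if (!is.null(bga$paco2)) bga$paco2 else NA_real_
  out
}

#' Trailing window average at an instant
#'
#' Averages every channel over `(t - width, t]`; strictly causal (samples
#' after `t` are never used).
#'
#' @param trial A `trial_recording`.
#' @param t Evaluation instant in seconds from trial start.
#' @param policy A trailing [window_policy()].
#' @return An `averaged_sample` (see [centred_average()]).
#' @export
trailing_average <- function(trial, t, policy = window_policy("trailing")) {
  if (policy$mode != "trailing")
    stop_invalid_config("trailing_average requires a trailing window policy")
  average_window(trial, t, t - policy$width, t, "trailing",
                 policy$min_coverage)
}

#' Collect design samples for a population
#'
#' Applies [centred_average()] to every blood-gas record of every animal and
#' assembles one table: one row per blood-gas analysis with the averaged
#' channel values, per-channel coverage, the completeness flag and the PaCO2
#' reference. Derived oxygenation indices are appended from the averaged
#' FiO2 and SpO2.
#'
#' @param population A `paco2_population` (or list of
#'   `list(recording, bga)` pairs).
#' @param policy Centred [window_policy()].
#' @return Data frame of averaged samples.
#' @export
collect_design_samples <- function(population,
                                   policy = window_policy("centred")) {
  rows <- list()
  for (animal in population) {
    trial <- animal$recording
    bga <- animal$bga
    for (k in seq_len(nrow(bga))) {
      s <- centred_average(trial, bga[k, ], policy)
      row <- c(list(animal_id = s$animal_id, minute = s$reference_time,
                    paco2 = s$paco2, complete = s$complete),
               as.list(s$values),
               stats::setNames(as.list(s$coverage),
                               paste0("coverage_", names(s$coverage))))
      rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- !is.na(out$FiO2) & !is.na(out$SpO2)
  out$O2diff <- out$O2quot <- NA_real_
  if (any(ok)) {
    idx <- derive_oxygen_indices(out$FiO2[ok], out$SpO2[ok])
    out$O2diff[ok] <- idx$O2diff
    out$O2quot[ok] <- idx$O2quot
  }
  out
}

#' Exclusion filter configuration
#'
#' The study excludes blood-gas analyses with PaCO2 above 75 mmHg (etCO2
#' becomes increasingly imprecise there) and with a simultaneous expiratory
#' tidal volume below 12 mL (end-tidal measurement unreliable under the high
#' apparatus dead space). Both boundaries are inclusive-keep: PaCO2 = 75 and
#' Vte = 12 are retained.
#'
#' @param paco2_max PaCO2 inclusion ceiling in mmHg (default 75).
#' @param vte_min Minimum expiratory tidal volume in mL (default 12).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(paco2_max = 75, vte_min = 12) {
  if (!is.numeric(paco2_max) || paco2_max <= 0 ||
      !is.numeric(vte_min) || vte_min <= 0)
    stop_invalid_config("paco2_max and vte_min must be positive")
  structure(list(paco2_max = paco2_max, vte_min = vte_min),
            class = "filter_config")
}

#' Apply the study exclusion filters
#'
#' Keeps samples with `paco2 <= paco2_max`, averaged `Vte >= vte_min` and a
#' complete covariate set. Each excluded sample is counted once, under the
#' first failing rule in the fixed order PaCO2 ceiling, Vte floor,
#' completeness, so the report is deterministic.
#'
#' @param samples Data frame of averaged samples (needs columns `paco2`,
#'   `Vte`, `complete`).
#' @param cfg A [filter_config()].
#' @param include_high_paco2 If `TRUE`, the PaCO2 ceiling is not applied
#'   (extended-evaluation variant).
#' @return List with `kept` (filtered data frame) and `report` (class
#'   `filter_report`: `n_input`, `n_kept`, `n_excluded_paco2`,
#'   `n_excluded_vte`, `n_excluded_incomplete`).
#' @export
apply_filters <- function(samples, cfg = filter_config(),
                          include_high_paco2 = FALSE) {
  samples <- as.data.frame(samples)
  n <- nrow(samples)
  if (n == 0L) {
    report <- filter_report(0L, 0L, 0L, 0L, 0L)
    return(list(kept = samples, report = report))
  }
  complete <- if (!is.null(samples$complete)) samples$complete else
    rep(TRUE, n)
  fail_paco2 <- if (include_high_paco2) rep(FALSE, n) else
    !is.na(samples$paco2) & samples$paco2 > cfg$paco2_max
  fail_vte <- !is.na(samples$Vte) & samples$Vte < cfg$vte_min
  fail_comp <- !complete | is.na(samples$Vte) | is.na(samples$paco2)
  kept <- !fail_paco2 & !fail_vte & !fail_comp
  report <- filter_report(
    n_input = n, n_kept = sum(kept),
    n_excluded_paco2 = sum(fail_paco2),
    n_excluded_vte = sum(!fail_paco2 & fail_vte),
    n_excluded_incomplete = sum(!fail_paco2 & !fail_vte & fail_comp))
  list(kept = samples[kept, , drop = FALSE], report = report)
}

filter_report <- function(n_input, n_kept, n_excluded_paco2, n_excluded_vte,
                          n_excluded_incomplete) {
  structure(
    list(n_input = as.integer(n_input), n_kept = as.integer(n_kept),
         n_excluded_paco2 = as.integer(n_excluded_paco2),
         n_excluded_vte = as.integer(n_excluded_vte),
         n_excluded_incomplete = as.integer(n_excluded_incomplete)),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "<filter_report> %d in, %d kept (excluded: %d PaCO2 ceiling, %d low Vte, %d incomplete)\n",
    x$n_input, x$n_kept, x$n_excluded_paco2, x$n_excluded_vte,
    x$n_excluded_incomplete))
  invisible(x)
}
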