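#' Online estimation configuration
#'
#' @param window Trailing averaging window in seconds (default 20 s: short
#'   enough for a low reaction delay, long enough to suppress single-sample
#'   outliers).
#' @param vte_min Minimum trailing-averaged expiratory tidal volume in mL;
#'   estimates are withheld below it (default 12 mL).
#' @param cadence Seconds between estimates (default 4 s, the etCO2 cadence).
#' @param offset_initial Initial offset of the offset-corrected baseline in
#'   mmHg, used before the first blood-gas result (default 0).
#' @param bga_delay Seconds between a blood gas' documented minute ending and
#'   its result being available to the offset baseline (default 0).
#' @param min_coverage Minimum per-channel coverage of the trailing window.
#' @return Object of class `online_config`.
#' @export
online_config <- function(window = 20, vte_min = 12, cadence = 4,
                          offset_initial = 0, bga_delay = 0,
                          min_coverage = 0.5) {
  if (window <= 0 || cadence <= 0)
    stop_invalid_config("window and cadence must be > 0")
  structure(list(window = window, vte_min = vte_min, cadence = cadence,
                 offset_initial = offset_initial, bga_delay = bga_delay,
                 min_coverage = min_coverage),
            class = "online_config")
}

# Vectorised trailing means over (t - window, t] for one channel at many
# ticks, via cumulative sums on the sorted sample grid.
trailing_means <- function(channel, ticks, window, rate, min_coverage) {
  tt <- channel$time
  vv <- channel$value
  cs <- cumsum(ifelse(is.finite(vv), vv, 0))
  cn <- cumsum(as.numeric(is.finite(vv)))
  hi <- findInterval(ticks, tt)                      # count of times <= t
  lo <- findInterval(ticks - window, tt)             # count of times <= t - w
  cnt <- ifelse(hi > 0, cn[pmax(hi, 1)], 0) - ifelse(lo > 0, cn[pmax(lo, 1)], 0)
  sm <- ifelse(hi > 0, cs[pmax(hi, 1)], 0) - ifelse(lo > 0, cs[pmax(lo, 1)], 0)
  expected <- max(1, round(window * rate))
  coverage <- pmin(1, cnt / expected)
  mean_ <- ifelse(coverage >= min_coverage & cnt > 0, sm / cnt, NA_real_)
  list(mean = mean_, coverage = coverage)
}

# Trailing-averaged covariates for the given channels at every tick.
online_covariates <- function(trial, ticks, channels, cfg) {
  out <- list()
  cov <- list()
  for (nm in channels) {
    ch <- trial$channels[[nm]]
    if (is.null(ch))
      stop_missing_parameters(sprintf("trial lacks channel '%s'", nm))
    st <- trailing_means(ch, ticks, cfg$window,
                         trial$channel_specs[[nm]]$sampling_rate,
                         cfg$min_coverage)
    out[[nm]] <- st$mean
    cov[[nm]] <- st$coverage
  }
  list(values = as.data.frame(out), coverage = as.data.frame(cov))
}

required_channels <- function(model) {
  bases <- unique(model$terms$base)
  derived <- intersect(bases, .derived_variable_names)
  bases <- setdiff(bases, derived)
  if (length(derived)) bases <- union(bases, c("FiO2", "SpO2"))
  union(bases, "Vte")
}

make_estimates <- function(ticks, method, values, covariates, cfg) {
  vte <- covariates$values$Vte
  vte_cov <- covariates$coverage$Vte
  low_vte <- !is.na(vte) & vte < cfg$vte_min
  missing <- !low_vte & (is.na(values) |
                           apply(is.na(covariates$values), 1, any))
  reason <- rep("none", length(ticks))
  reason[missing] <- "missing_parameters"
  reason[low_vte] <- "low_vte"
  data.frame(
    time = ticks, method = method,
    value = ifelse(reason == "none", values, NA_real_),
    withheld_reason = reason,
    above_range = reason == "none" & !is.na(values) & values > 75,
    stringsAsFactors = FALSE)
}

online_ticks <- function(trial, cfg) {
  dur <- max(vapply(trial$channels, function(ch) max(ch$time), 0))
  seq(cfg$cadence, dur, by = cfg$cadence)
}

#' Run the online estimator over a recording
#'
#' At every cadence tick the covariates are averaged over the trailing
#' window (strictly causal: only measurements preceding the tick), the
#' estimate is withheld with reason `low_vte` when the averaged expiratory
#' tidal volume falls below `vte_min`, or `missing_parameters` when any
#' required covariate window is uncovered; otherwise the model prediction is
#' emitted. Estimates above 75 mmHg are emitted but flagged `above_range`
#' (the estimator is not validated there).
#'
#' @param trial A `trial_recording`.
#' @param model A `paco2_model`; default the frozen [published_model()].
#' @param cfg An [online_config()].
#' @return Data frame of estimate records: `time`, `method` (`"rlr"`),
#'   `value` (mmHg, `NA` when withheld), `withheld_reason` (`"none"`,
#'   `"low_vte"` or `"missing_parameters"`), `above_range`.
#' @export
run_online <- function(trial, model = published_model(),
                       cfg = online_config()) {
  ticks <- online_ticks(trial, cfg)
  covs <- online_covariates(trial, ticks, required_channels(model), cfg)
  vals <- rep(NA_real_, length(ticks))
  ok <- !apply(is.na(covs$values), 1, any)
  if (!is.null(covs$values$Vte)) ok <- ok & covs$values$Vte > 0
  if (any(ok)) vals[ok] <- eval_model(model, covs$values[ok, , drop = FALSE])
  make_estimates(ticks, "rlr", vals, covs, cfg)
}

#' Unaltered etCO2 baseline
#'
#' The trailing-averaged etCO2 itself taken as the PaCO2 estimate, under the
#' same withholding rules as [run_online()].
#'
#' @inheritParams run_online
#' @return Estimate record data frame with method `"etco2"`.
#' @export
etco2_baseline <- function(trial, cfg = online_config()) {
  ticks <- online_ticks(trial, cfg)
  covs <- online_covariates(trial, ticks, c("etCO2", "Vte"), cfg)
  make_estimates(ticks, "etco2", covs$values$etCO2, covs, cfg)
}

#' Offset-corrected etCO2 baseline
#'
#' Estimates PaCO2 as trailing-averaged etCO2 plus a piecewise-constant
#' offset. The offset starts at `cfg$offset_initial` and, each time a
#' blood-gas result becomes available, becomes that blood gas' PaCO2 minus
#' the trailing-averaged etCO2 at the end of its documented minute. A result
#' is available `cfg$bga_delay` seconds after its documented minute ends, so
#' estimates inside blood gas k's own minute still carry the offset derived
#' from blood gas k-1 (no look-ahead when scoring).
#'
#' @inheritParams run_online
#' @param bgas Blood-gas data frame (columns `minute`, `paco2`), sorted by
#'   time.
#' @return Estimate record data frame with method `"etco2_offset"`.
#' @export
offset_baseline <- function(trial, bgas, cfg = online_config()) {
  ticks <- online_ticks(trial, cfg)
  covs <- online_covariates(trial, ticks, c("etCO2", "Vte"), cfg)
  et <- covs$values$etCO2

  bgas <- bgas[order(bgas$minute), , drop = FALSE]
  # offset updates: value and the time from which it applies
  upd_time <- numeric(0)
  upd_val <- numeric(0)
  for (k in seq_len(nrow(bgas))) {
    t_eval <- bgas$minute[k] + 60
    st <- trailing_means(trial$channels[["etCO2"]], t_eval, cfg$window,
                         trial$channel_specs[["etCO2"]]$sampling_rate,
                         cfg$min_coverage)
    if (is.na(st$mean)) next   # no etCO2 window: offset unchanged
    upd_time <- c(upd_time, t_eval + cfg$bga_delay)
    upd_val <- c(upd_val, bgas$paco2[k] - st$mean)
  }
  offs <- rep(cfg$offset_initial, length(ticks))
  if (length(upd_time)) {
    idx <- findInterval(ticks, upd_time)   # updates strictly in the past or now
    offs[idx > 0] <- upd_val[idx[idx > 0]]
  }
  make_estimates(ticks, "etco2_offset", et + offs, covs, cfg)
}
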