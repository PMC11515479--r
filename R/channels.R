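#' Channel specification
#'
#' Describes one recorded channel of a ventilation trial: its name, unit,
#' plausible physiological range and sampling rate. Ventilator and vital
#' channels are sampled at 0.5 Hz; the end-tidal CO2 channel is derived from
#' the capnogram at 0.25 Hz (one value per 4-s waveform window).
#'
#' @param name Channel identifier (one of [base_variables()] minus the two
#'   derived oxygenation indices).
#' @param unit Unit string, e.g. `"mmHg"`.
#' @param low,high Lower and upper bound of the channel in its unit
#'   (`low < high`).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(name, unit, low, high, sampling_rate) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_invalid_config("channel name must be a non-empty string")
  if (!is.numeric(low) || !is.numeric(high) || low >= high)
    stop_invalid_config(sprintf("channel '%s': low must be < high", name))
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop_invalid_config(sprintf("channel '%s': sampling_rate must be > 0", name))
  structure(
    list(name = name, unit = unit, low = as.numeric(low),
         high = as.numeric(high), sampling_rate = as.numeric(sampling_rate)),
    class = "channel_spec"
  )
}

# Canonical variable catalogue. The 15 recorded channels plus the two derived
# oxygenation indices give the 17 base variables that enter the candidate
# catalogue. Order is fixed and used everywhere (column order, tie-breaking).
.recorded_channel_names <- c(
  "etCO2", "FiO2", "PEEP", "Ppeak", "Pmean", "f", "fSpont", "pctSpont",
  "MV", "SpO2", "Vti", "Vte", "Compl", "Leak", "Resist"
)
.derived_variable_names <- c("O2diff", "O2quot")

#' Base variable names
#'
#' The canonical, ordered catalogue of regression base variables: the 15
#' recorded ventilator/vital channels followed by the two derived oxygenation
#' indices `O2diff = FiO2 - SpO2` and `O2quot = SpO2 / FiO2`.
#'
#' @param recorded_only If `TRUE`, return only the 15 recorded channel names.
#' @return Character vector of variable names in canonical order.
#' @export
base_variables <- function(recorded_only = FALSE) {
  if (recorded_only) .recorded_channel_names
  else c(.recorded_channel_names, .derived_variable_names)
}

#' Default channel specifications
#'
#' Ranges follow the design-population ventilation statistics of the ovine
#' trials (ranges of FiO2, PEEP, Ppeak, Pmean, respiratory rate, SpO2, minute
#' volume and expiratory tidal volume); channels without a published range
#' (Vti, Compl, Leak, Resist, etCO2) use clinically plausible neonatal spans.
#' All channels are 0.5 Hz except etCO2 (0.25 Hz).
#'
#' @return Named list of [channel_spec()] objects in canonical order.
#' @export
default_channel_specs <- function() {
  sp <- list(
    channel_spec("etCO2",    "mmHg",      15,    75,   0.25),
    channel_spec("FiO2",     "%",         20,    100,  0.5),
    channel_spec("PEEP",     "mbar",      0.9,   9.7,  0.5),
    channel_spec("Ppeak",    "mbar",      9,     36,   0.5),
    channel_spec("Pmean",    "mbar",      4.8,   17.1, 0.5),
    channel_spec("f",        "b/min",     18,    101,  0.5),
    channel_spec("fSpont",   "b/min",     0,     101,  0.5),
    channel_spec("pctSpont", "%",         0,     100,  0.5),
    channel_spec("MV",       "mL/min",    254,   4758, 0.5),
    channel_spec("SpO2",     "%",         68,    100,  0.5),
    channel_spec("Vti",      "mL",        12,    90,   0.5),
    channel_spec("Vte",      "mL",        12.1,  84.9, 0.5),
    channel_spec("Compl",    "mL/mbar",   0.2,   3,    0.5),
    channel_spec("Leak",     "%",         0,     95,   0.5),
    channel_spec("Resist",   "mbar/L/s",  20,    400,  0.5)
  )
  names(sp) <- vapply(sp, `[[`, character(1), "name")
  sp
}

channel_units <- function(specs = default_channel_specs()) {
  vapply(specs, `[[`, character(1), "unit")
}
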