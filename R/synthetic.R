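#' Trial generator configuration
#'
#' Conditions for the synthetic ovine-style ventilation trials: per-animal
#' multichannel recordings (15 channels: 14 ventilator/vital channels at
#' 0.5 Hz plus etCO2 at 0.25 Hz) with intermittent blood-gas analyses whose
#' PaCO2 is linked to the concurrent covariates through the structural form
#' of the published estimation equation plus Gaussian noise and an optional
#' outlier contamination.
#'
#' @param n_animals Number of animals (>= 1).
#' @param duration Recording duration per animal in seconds (> 0).
#' @param bga_interval_range Two-element numeric, minimum and maximum spacing
#'   in seconds between consecutive blood-gas analyses; defaults to 15 min to
#'   180 min.
#' @param noise_sd SD of the Gaussian PaCO2 noise in mmHg (>= 0); default
#'   3 mmHg.
#' @param outlier_fraction Probability that a blood-gas PaCO2 receives an
#'   additional gross shift, in `[0, 1)`; default 0.05.
#' @param outlier_shift Magnitude of the gross shift in mmHg (sign random);
#'   default 15 mmHg.
#' @param channel_specs Named list of [channel_spec()]s;
#'   default [default_channel_specs()].
#' @param seed Integer seed; every generator draw derives from it.
#' @param model Structural model linking PaCO2 to the covariates; default
#'   [published_model()].
#' @param spont_burst_rate Expected number of spontaneous-breathing bursts per
#'   hour; the spontaneous percentage is 0 outside bursts, matching the trial
#'   populations' median of 0. Default 0 (no bursts).
#' @param spont_burst_duration Two-element range of burst durations (s).
#' @param spont_burst_level Two-element range of burst spontaneous
#'   percentages.
#' @param capnogram If `TRUE`, also synthesize a raw capnogram waveform whose
#'   4-s end-tidal maxima reproduce the etCO2 channel.
#' @param capnogram_rate Capnogram sampling rate in Hz (>= 10).
#' @return Object of class `trial_config`.
#' @export
trial_config <- function(n_animals = 6L,
                         duration = 14400,
                         bga_interval_range = c(900, 10800),
                         noise_sd = 3,
                         outlier_fraction = 0.05,
                         outlier_shift = 15,
                         channel_specs = default_channel_specs(),
                         seed = 1L,
                         model = published_model(),
                         spont_burst_rate = 0,
                         spont_burst_duration = c(300, 900),
                         spont_burst_level = c(20, 80),
                         capnogram = FALSE,
                         capnogram_rate = 50) {
  if (!is.numeric(n_animals) || length(n_animals) != 1L || n_animals < 1)
    stop_invalid_config("n_animals must be a positive integer")
  if (!is.numeric(duration) || duration <= 0)
    stop_invalid_config("duration must be > 0 seconds")
  if (length(bga_interval_range) != 2L ||
      bga_interval_range[1] <= 0 ||
      bga_interval_range[1] > bga_interval_range[2])
    stop_invalid_config("bga_interval_range must be increasing and positive")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_invalid_config("noise_sd must be >= 0")
  if (!is.numeric(outlier_fraction) || outlier_fraction < 0 ||
      outlier_fraction >= 1)
    stop_invalid_config("outlier_fraction must lie in [0, 1)")
  if (capnogram && capnogram_rate < 10)
    stop_invalid_config("capnogram_rate must be >= 10 Hz")
  structure(
    list(n_animals = as.integer(n_animals), duration = as.numeric(duration),
         bga_interval_range = as.numeric(bga_interval_range),
         noise_sd = noise_sd, outlier_fraction = outlier_fraction,
         outlier_shift = outlier_shift, channel_specs = channel_specs,
         seed = as.integer(seed), model = model,
         spont_burst_rate = spont_burst_rate,
         spont_burst_duration = spont_burst_duration,
         spont_burst_level = spont_burst_level,
         capnogram = isTRUE(capnogram), capnogram_rate = capnogram_rate),
    class = "trial_config"
  )
}

# Run expr with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Structural PaCO2 value
#'
#' Evaluates the structural model on a covariate vector and adds measurement
#' noise: a Normal(0, `noise_sd`) draw, plus (with probability
#' `outlier_fraction`) a gross shift of `outlier_shift` mmHg with random
#' sign. Uses the current RNG state; seed externally for reproducibility.
#'
#' @param covariates Named list/data frame with the model's base variables
#'   (O2diff may be given directly or derived from FiO2 and SpO2). Vte must
#'   be strictly positive (its logarithm enters the published model).
#' @param model Structural model; default [published_model()].
#' @param noise_sd,outlier_fraction,outlier_shift Noise parameters as in
#'   [trial_config()].
#' @return For `structural_paco2`, a numeric vector of PaCO2 values (mmHg).
#'   Attribute `outlier` flags which values received a gross shift.
#' @examples
#' structural_paco2(list(etCO2 = 40, FiO2 = 21, SpO2 = 91, pctSpont = 0,
#'                       Pmean = 12, Vte = 20))   # 45.689
#' @export
structural_paco2 <- function(covariates, model = published_model(),
                             noise_sd = 0, outlier_fraction = 0,
                             outlier_shift = 15) {
  data <- as.data.frame(covariates)
  if (!is.null(data$Vte) && any(data$Vte <= 0, na.rm = TRUE))
    stop_domain("Vte must be > 0 (log(Vte) undefined otherwise)")
  mu <- eval_model(model, data)
  n <- length(mu)
  noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  is_out <- if (outlier_fraction > 0)
    stats::runif(n) < outlier_fraction else rep(FALSE, n)
  shift <- ifelse(is_out, sample(c(-1, 1), n, replace = TRUE) * outlier_shift, 0)
  structure(mu + noise + shift, outlier = is_out)
}

#' Synthesize a capnogram waveform
#'
#' Generates a periodic breath-shaped CO2 partial-pressure signal: a low
#' inspiratory baseline, an expiratory upstroke and an alveolar plateau whose
#' sampled maximum equals `plateau` exactly. Morphological realism beyond
#' plateau/baseline is deliberately not attempted.
#'
#' @param plateau End-tidal plateau value in mmHg (> 0).
#' @param respiratory_rate Breaths per minute (> 0).
#' @param duration Signal duration in seconds.
#' @param rate Sampling rate in Hz (>= 10).
#' @param baseline Inspiratory baseline in mmHg (<= 5).
#' @return Data frame with columns `time` (s) and `value` (mmHg).
#' @export
synthesize_capnogram <- function(plateau, respiratory_rate, duration,
                                 rate = 50, baseline = 0.5) {
  if (!is.numeric(plateau) || plateau <= 0)
    stop_invalid_config("plateau must be > 0 mmHg")
  if (!is.numeric(respiratory_rate) || respiratory_rate <= 0)
    stop_invalid_config("respiratory_rate must be > 0 breaths/min")
  if (rate < 10) stop_invalid_config("rate must be >= 10 Hz")
  if (baseline > 5) stop_invalid_config("baseline must be <= 5 mmHg")
  period <- 60 / respiratory_rate
  t <- seq(0, duration, by = 1 / rate)
  phase <- (t %% period) / period
  # 0-0.35 inspiration (baseline), 0.35-0.55 upstroke, 0.55-1 plateau
  v <- ifelse(phase < 0.35, baseline,
         ifelse(phase < 0.55,
                baseline + (plateau - baseline) * (phase - 0.35) / 0.2,
                plateau))
  data.frame(time = t, value = v)
}

# Bounded reflected random walk on a regular grid.
bounded_walk <- function(n, low, high, step_sd) {
  x0 <- stats::runif(1, low, high)
  x <- x0 + c(0, cumsum(stats::rnorm(n - 1L, 0, step_sd)))
  span <- high - low
  y <- (x - low) %% (2 * span)
  low + ifelse(y > span, 2 * span - y, y)
}

# Freeze a channel inside hold windows: every sample with time in
# [a, b] takes the value of the last sample at or before a.
freeze_windows <- function(time, value, holds) {
  for (k in seq_len(nrow(holds))) {
    idx <- which(time >= holds$a[k] & time <= holds$b[k])
    if (!length(idx)) next
    anchor <- which(time <= holds$a[k])
    v <- if (length(anchor)) value[max(anchor)] else value[idx[1L]]
    value[idx] <- v
  }
  value
}

#' Generate a synthetic trial population
#'
#' Produces `n_animals` paired (recording, blood-gas table) datasets. Each
#' channel evolves as a bounded random walk reflecting at its specification
#' bounds, so 20-s and 2-min windows exercise the averaging logic
#' non-trivially. Around every blood-gas draw the channels are held at their
#' current value over `[minute - 60 s, minute + 120 s]` (ventilation is not
#' being actively changed while a gas is drawn); within that window the
#' centred 2-min design average and the trailing 20-s online average both
#' equal the held covariate value exactly, which pins the generator's
#' structural PaCO2 to what the downstream pipelines recompute.
#'
#' Blood-gas PaCO2 is the structural model value of the held covariates plus
#' Normal(0, `noise_sd`) noise and optional gross outlier shifts. Only the
#' floor-to-minute `minute` is documented (results are recorded by hand at
#' minute resolution); the exact draw instant is retained as `true_time` for
#' testing only.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Object of class `paco2_population`: a list with one element per
#'   animal, each a list with `recording` (class `trial_recording`: channels
#'   as data frames of `time`/`value`, optional `capnogram`) and `bga` (data
#'   frame: `animal_id`, `minute`, `paco2`, `ph`, `pao2`, `true_time`,
#'   `outlier`).
#' @export
generate_population <- function(config = trial_config(), seed = config$seed) {
  if (!inherits(config, "trial_config"))
    stop_invalid_config("config must be a trial_config")
  with_seed(seed, {
    lapply(seq_len(config$n_animals), function(i) {
      generate_animal(config, sprintf("animal%02d", i))
    })
  }) -> animals
  structure(animals, class = "paco2_population",
            config = config, seed = seed)
}

generate_animal <- function(config, animal_id) {
  dur <- config$duration
  rng <- config$bga_interval_range
  # BGA times: an early gas after stabilisation, then spacing within range.
  t_first_max <- min(rng[1], max(121, dur - 180))
  times <- numeric(0)
  t <- stats::runif(1, min(120, t_first_max), t_first_max)
  while (t <= dur - 180) {
    times <- c(times, t)
    t <- t + stats::runif(1, rng[1], rng[2])
  }
  minutes <- floor(times / 60) * 60
  holds <- data.frame(a = minutes - 60, b = minutes + 120)

  specs <- config$channel_specs
  channels <- list()
  pct_spont <- NULL
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    tt <- seq(0, dur, by = 1 / sp$sampling_rate)
    v <- switch(nm,
      pctSpont = spont_series(tt, config),
      fSpont = NULL,  # derived below from f and pctSpont
      bounded_walk(length(tt), sp$low, sp$high,
                   step_sd = (sp$high - sp$low) / 400)
    )
    if (is.null(v)) { channels[[nm]] <- tt; next }  # placeholder, fixed below
    v <- freeze_windows(tt, v, holds)
    channels[[nm]] <- data.frame(time = tt, value = v)
  }
  # fSpont is physically tied to f and the spontaneous percentage.
  if ("fSpont" %in% names(specs)) {
    tt <- channels[["fSpont"]]
    channels[["fSpont"]] <- data.frame(
      time = tt,
      value = channels[["f"]]$value * channels[["pctSpont"]]$value / 100)
  }

  capno <- NULL
  if (config$capnogram)
    capno <- capnogram_from_etco2(channels[["etCO2"]], channels[["f"]],
                                  config$capnogram_rate)

  recording <- structure(
    list(animal_id = animal_id, start_time = 0, channels = channels,
         capnogram = capno, channel_specs = specs),
    class = "trial_recording")

  # Covariates at each BGA: the held value (any sample inside the centred
  # window; use the sample at the documented minute).
  cov <- lapply(base_variables(recorded_only = TRUE), function(nm) {
    ch <- channels[[nm]]
    vapply(minutes, function(m) ch$value[max(which(ch$time <= m))], 0)
  })
  names(cov) <- base_variables(recorded_only = TRUE)
  cov <- as.data.frame(cov)
  paco2 <- if (nrow(cov)) structural_paco2(
    cov, model = config$model, noise_sd = config$noise_sd,
    outlier_fraction = config$outlier_fraction,
    outlier_shift = config$outlier_shift) else structure(numeric(0),
                                                         outlier = logical(0))
  bga <- data.frame(
    animal_id = rep(animal_id, length(times)),
    minute = minutes,
    paco2 = as.numeric(paco2),
    ph = round(stats::rnorm(length(times), 7.30, 0.08), 3),
    pao2 = round(pmax(5, stats::rnorm(length(times), 50, 12)), 1),
    true_time = times,
    outlier = attr(paco2, "outlier"),
    stringsAsFactors = FALSE
  )
  list(recording = recording, bga = bga)
}

spont_series <- function(tt, config) {
  v <- numeric(length(tt))
  if (config$spont_burst_rate > 0) {
    n_burst <- stats::rpois(1, config$spont_burst_rate * max(tt) / 3600)
    for (k in seq_len(n_burst)) {
      s <- stats::runif(1, 0, max(tt))
      d <- stats::runif(1, config$spont_burst_duration[1],
                        config$spont_burst_duration[2])
      lv <- stats::runif(1, config$spont_burst_level[1],
                         config$spont_burst_level[2])
      v[tt >= s & tt <= s + d] <- lv
    }
  }
  v
}

# Piece a capnogram together from the 0.25 Hz etCO2 channel: each 4-s window
# ending at an etCO2 sample is a breath train whose plateau is that sample.
capnogram_from_etco2 <- function(etco2, f, rate) {
  segs <- lapply(seq_len(nrow(etco2))[-1], function(k) {
    rr <- max(15, f$value[max(which(f$time <= etco2$time[k]))])
    w <- synthesize_capnogram(etco2$value[k], rr, duration = 4 - 1 / rate,
                              rate = rate)
    w$time <- w$time + etco2$time[k] - 4 + 1 / rate
    w
  })
  do.call(rbind, segs)
}

#' @rdname structural_paco2
#' @param n Number of samples to draw.
#' @param channel_specs Channel ranges used for the independent uniform draws.
#' @param seed Optional integer seed.
#' @details
#' `simulate_design_samples()` draws `n` independent covariate vectors, each
#' channel uniform over its specification range (spanning the design
#' population's observed ranges), and sets PaCO2 to the structural model
#' value plus noise/outliers. This covariate-level generator is the input for
#' model-recovery studies where the full time-series machinery is not needed.
#' @return For `simulate_design_samples`, a data frame with one row per
#'   sample: the 15 channel values, the derived oxygenation indices, `paco2`,
#'   `outlier`, plus `animal_id`/`minute`/`complete` bookkeeping columns.
#' @export
simulate_design_samples <- function(n, model = published_model(),
                                    noise_sd = 3, outlier_fraction = 0.05,
                                    outlier_shift = 15,
                                    channel_specs = default_channel_specs(),
                                    seed = NULL) {
  if (!is.numeric(n) || n < 1) stop_invalid_config("n must be >= 1")
  with_seed(seed, {
    cov <- lapply(channel_specs, function(sp) stats::runif(n, sp$low, sp$high))
    names(cov) <- names(channel_specs)
    cov <- as.data.frame(cov)
    # keep fSpont physically consistent with f and pctSpont
    if (all(c("f", "pctSpont", "fSpont") %in% names(cov)))
      cov$fSpont <- cov$f * cov$pctSpont / 100
    paco2 <- structural_paco2(cov, model = model, noise_sd = noise_sd,
                              outlier_fraction = outlier_fraction,
                              outlier_shift = outlier_shift)
    out <- add_oxygen_indices(cov)
    out$paco2 <- as.numeric(paco2)
    out$outlier <- attr(paco2, "outlier")
    out$animal_id <- "design"
    out$minute <- 60 * seq_len(n)
    out$complete <- TRUE
    out
  })
}
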