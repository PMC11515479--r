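# Fixture builders: everything is generated in code at test time.

# A trial recording whose channels are constant at the given values.
make_constant_trial <- function(values = list(), duration = 600,
                                animal_id = "t01") {
  defaults <- list(etCO2 = 45, FiO2 = 21, PEEP = 7.5, Ppeak = 21, Pmean = 12,
                   f = 55, fSpont = 0, pctSpont = 0, MV = 1100, SpO2 = 94,
                   Vti = 22, Vte = 20, Compl = 1.2, Leak = 5, Resist = 150)
  defaults[names(values)] <- values
  specs <- default_channel_specs()
  channels <- lapply(names(specs), function(nm) {
    tt <- seq(0, duration, by = 1 / specs[[nm]]$sampling_rate)
    data.frame(time = tt, value = rep(defaults[[nm]], length(tt)))
  })
  names(channels) <- names(specs)
  structure(list(animal_id = animal_id, start_time = 0, channels = channels,
                 capnogram = NULL, channel_specs = specs),
            class = "trial_recording")
}

# Replace one channel's values over a time interval.
set_channel_interval <- function(trial, name, from, to, value) {
  ch <- trial$channels[[name]]
  ch$value[ch$time >= from & ch$time <= to] <- value
  trial$channels[[name]] <- ch
  trial
}

# The worked covariate vector used throughout: evaluates to 45.689 mmHg.
worked_covariates <- function() {
  data.frame(etCO2 = 40, FiO2 = 21, SpO2 = 91, pctSpont = 0,
             Pmean = 12, Vte = 20)
}

# One-row-per-sample frame with all 17 base variables, strictly positive
# except where overridden; used for catalogue-counting tests.
make_base_fixture <- function(n = 4, overrides = list()) {
  base <- list(etCO2 = 45, FiO2 = 30, PEEP = 7, Ppeak = 20, Pmean = 12,
               f = 50, fSpont = 10, pctSpont = 20, MV = 1000, SpO2 = 95,
               Vti = 22, Vte = 20, Compl = 1, Leak = 4, Resist = 100)
  df <- as.data.frame(lapply(base, function(v) rep(v, n)))
  df$paco2 <- rep(50, n)
  for (nm in names(overrides)) df[[nm]] <- overrides[[nm]]
  df
}

# Scale a draw to an exact sample standard deviation (and zero mean).
vector_with_sd <- function(n, target_sd, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  x <- x - mean(x)
  x * target_sd / stats::sd(x)
}
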