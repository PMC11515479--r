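test_that("the frozen published model carries its five terms exactly", {
  m <- published_model()
  expect_equal(nrow(m$terms), 5L)
  co <- coef(m)
  expect_equal(co[["(Intercept)"]], 31.8164)
  expect_equal(co[["etCO2"]], 0.8892)
  expect_equal(co[["O2diff^2"]], -0.0019)
  expect_equal(co[["pctSpont"]], -0.0854)
  expect_equal(co[["Pmean^3"]], 0.002)
  expect_equal(co[["log(Vte)"]], -5.2879)
})

test_that("prediction evaluates the linear form and flags missing covariates", {
  m <- published_model()
  expect_equal(predict(m, worked_covariates()), 45.689, tolerance = 1e-3)
  zero <- data.frame(etCO2 = 0, O2diff = 0, pctSpont = 0, Pmean = 0, Vte = 1)
  expect_equal(predict(m, zero), 31.8164)

  nospo2 <- worked_covariates()
  nospo2$SpO2 <- NULL
  expect_error(predict(m, nospo2), class = "paco2_missing_parameters")
})

test_that("online estimation reproduces constant covariates and withholds on low Vte", {
  trial <- make_constant_trial(duration = 600)
  est <- run_online(trial)
  settled <- est[est$time >= 20, ]
  expect_true(all(settled$withheld_reason == "none"))
  want <- predict(published_model(),
                  data.frame(etCO2 = 45, FiO2 = 21, SpO2 = 94, pctSpont = 0,
                             Pmean = 12, Vte = 20))
  expect_equal(unique(round(settled$value, 10)), round(want, 10))

  # Vte drops to 10 mL during [300, 360]: withheld exactly while the
  # trailing mean is below 12 (oracle recomputes the window means directly)
  trial2 <- set_channel_interval(make_constant_trial(duration = 600),
                                 "Vte", 300, 360, 10)
  est2 <- run_online(trial2)
  ch <- trial2$channels$Vte
  for (t in seq(292, 400, by = 4)) {
    mean_vte <- mean(ch$value[ch$time > t - 20 & ch$time <= t])
    row <- est2[est2$time == t, ]
    if (mean_vte < 12) expect_equal(row$withheld_reason, "low_vte")
    else expect_equal(row$withheld_reason, "none")
  }
  expect_true(any(est2$withheld_reason == "low_vte"))
})

test_that("every online method is invariant to future perturbations", {
  trial <- make_constant_trial(duration = 400)
  bga <- data.frame(minute = 180, paco2 = 50)
  cut <- 240
  crop <- function(df) df[df$time <= cut, ]
  ref <- list(rlr = crop(run_online(trial)),
              etco2 = crop(etco2_baseline(trial)),
              off = crop(offset_baseline(trial, bga)))
  pert <- trial
  for (nm in names(pert$channels))
    pert <- set_channel_interval(pert, nm, cut + 0.001, 400,
                                 pert$channel_specs[[nm]]$high)
  got <- list(rlr = crop(run_online(pert)),
              etco2 = crop(etco2_baseline(pert)),
              off = crop(offset_baseline(pert, bga)))
  expect_identical(got, ref)
})

test_that("etCO2 baseline equals the identity model run online", {
  trial <- make_constant_trial(list(etCO2 = 45), duration = 300)
  bl <- etco2_baseline(trial)
  expect_true(all(bl$value[bl$time >= 20] == 45))

  ident <- paco2_model(0, data.frame(base = "etCO2", transform = "identity",
                                     coefficient = 1))
  ol <- run_online(trial, ident)
  expect_equal(bl$value, ol$value)
  expect_equal(bl$withheld_reason, ol$withheld_reason)

  # missing etCO2 stream -> missing_parameters once Vte is fine
  trial2 <- make_constant_trial(duration = 300)
  trial2$channels$etCO2 <- trial2$channels$etCO2[
    trial2$channels$etCO2$time < 100, ]
  bl2 <- etco2_baseline(trial2)
  late <- bl2[bl2$time >= 130, ]
  expect_true(all(late$withheld_reason == "missing_parameters"))
})

test_that("offset baseline updates piecewise at blood-gas availability", {
  trial <- make_constant_trial(list(etCO2 = 44), duration = 900)
  bga <- data.frame(minute = 300, paco2 = 50)
  est <- offset_baseline(trial, bga)
  before <- est$value[est$time >= 20 & est$time < 360]
  after <- est$value[est$time >= 360]
  expect_true(all(before == 44))        # offset_initial = 0
  expect_true(all(after == 50))         # offset = 50 - 44 = 6

  # two gases: piecewise-constant offset, scored with the pre-update offset
  bga2 <- data.frame(minute = c(300, 600), paco2 = c(50, 41))
  est2 <- offset_baseline(trial, bga2)
  expect_true(all(est2$value[est2$time < 360 & est2$time >= 20] == 44))
  expect_true(all(est2$value[est2$time >= 360 & est2$time < 660] == 50))
  expect_true(all(est2$value[est2$time >= 660] == 41))
  # the pair scored against gas 2 (minute 600) still uses offset from gas 1
  pr <- pair_estimates(est2, bga2)
  expect_equal(pr$estimate[pr$minute == 600], 50)
})

test_that("zero-noise populations give exact rlr estimates and a structural etCO2 gap", {
  cfg <- trial_config(n_animals = 1, duration = 7200, noise_sd = 0,
                      outlier_fraction = 0, seed = 31)
  a <- generate_population(cfg)[[1]]
  est <- run_online(a$recording)
  bl <- etco2_baseline(a$recording)
  pr <- pair_estimates(est, a$bga)
  expect_equal(nrow(pr), nrow(a$bga))
  expect_lt(max(abs(pr$estimate - pr$paco2)), 1e-9)

  # etCO2 baseline error equals the generator's structural etCO2-PaCO2 gap
  prb <- pair_estimates(bl, a$bga)
  samples <- collect_design_samples(list(a))
  gap <- samples$etCO2 - samples$paco2
  expect_equal(prb$estimate - prb$paco2, gap, tolerance = 1e-9)
})

test_that("model serialisation round-trips exactly and validates its schema", {
  m <- published_model()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path, seed = 7)
  m2 <- load_model(path)
  expect_identical(coef(m2), coef(m))

  intercept_only <- paco2_model(40, data.frame())
  save_model(intercept_only, path)
  expect_equal(coef(load_model(path)), c("(Intercept)" = 40))

  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$intercept <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(load_model(path), class = "paco2_schema_error")
  obj$schema_version <- 99
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(load_model(path), class = "paco2_schema_error")
})
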