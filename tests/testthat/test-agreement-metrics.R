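test_that("pairing picks the latest usable estimate inside the documented minute", {
  est <- data.frame(time = seq(4, 900, by = 4), method = "rlr",
                    value = seq(4, 900, by = 4) / 10,
                    withheld_reason = "none")
  bga <- data.frame(minute = 600, paco2 = 50)
  pr <- pair_estimates(est, bga)
  expect_equal(pr$estimate_time, 656)   # latest tick in [600, 660)
  expect_equal(pr$estimate, 65.6)

  # all estimates withheld inside that minute -> blood gas dropped
  est2 <- est
  est2$withheld_reason[est2$time >= 600 & est2$time < 660] <- "low_vte"
  pr2 <- pair_estimates(est2, bga)
  expect_equal(nrow(pr2), 0L)
  expect_equal(attr(pr2, "n_dropped"), 1L)

  empty <- pair_estimates(est, bga[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_dropped"), 0L)
})

test_that("error metrics follow the difference conventions", {
  two <- data.frame(estimate = c(51, 49), paco2 = c(50, 50))
  m <- error_metrics(two)
  expect_equal(m$mae, 1)
  expect_equal(m$sd, sqrt(2))
  expect_equal(round(m$sd, 2), 1.41)
  expect_equal(m$se, 1)
  expect_equal(m$mean_diff, 0)
  expect_error(error_metrics(two[1, ]), class = "paco2_insufficient_data")
})

test_that("printed standard errors are reproduced from printed SD and n", {
  # evaluation population (n = 246): SD 3.66 / 5.44 / 4.92 -> SE .23/.35/.31
  cases246 <- list(c(3.66, 0.23), c(5.44, 0.35), c(4.92, 0.31))
  for (cs in cases246) {
    d <- vector_with_sd(246, cs[1])
    m <- error_metrics(data.frame(estimate = d, paco2 = 0))
    expect_equal(sd(d), cs[1], tolerance = 1e-12)
    expect_equal(round(m$se, 2), cs[2])
  }
  # design population (n = 863): SD 6.53 / 4.70 -> SE 0.22 / 0.16
  for (cs in list(c(6.53, 0.22), c(4.70, 0.16))) {
    d <- vector_with_sd(863, cs[1])
    m <- error_metrics(data.frame(estimate = d, paco2 = 0))
    expect_equal(round(m$se, 2), cs[2])
  }
})

test_that("quantile limits of agreement interpolate order statistics", {
  d <- 1:40
  rpt <- bland_altman(data.frame(estimate = d, paco2 = 0))
  expect_equal(rpt$loa_low, 1.975)
  expect_equal(rpt$loa_high, 39.025)
  expect_true(rpt$loa_low <= rpt$mean_diff & rpt$mean_diff <= rpt$loa_high)

  same <- bland_altman(data.frame(estimate = rep(7, 10), paco2 = 0))
  expect_equal(same$loa_low, 7)
  expect_equal(same$loa_high, 7)

  expect_error(bland_altman(data.frame(estimate = d, paco2 = 0),
                            q_low = 0.9, q_high = 0.1),
               class = "paco2_invalid_config")
})

test_that("limits of agreement cover about 95% of differences", {
  set.seed(77)
  for (i in 1:8) {
    n <- sample(100:800, 1)
    d <- rnorm(n) + rexp(n)   # skewed, non-normal differences
    rpt <- bland_altman(data.frame(estimate = d, paco2 = 0))
    inside <- mean(d >= rpt$loa_low & d <= rpt$loa_high)
    # order-statistic counting: the number of differences inside the
    # interpolated [q(.025), q(.975)] limits is
    # floor(.975(n-1)+1) - ceil(.025(n-1)+1) + 1 in [.95n - 1.95, .95n + 2]
    expect_gte(inside, 0.95 - 1.95 / n)
    expect_lte(inside, 0.95 + 2 / n)
    expect_equal(rpt$se * sqrt(rpt$n), rpt$sd, tolerance = 1e-12)
  }
})

test_that("relative reduction reproduces the headline arithmetic", {
  red <- relative_reduction(5.15, 3.80)
  expect_equal(red$abs, 1.35)
  expect_equal(red$rel, 26.21)
  expect_equal(relative_reduction(4, 4), list(abs = 0, rel = 0))
  expect_equal(relative_reduction(10, 5), list(abs = 5, rel = 50))
  expect_error(relative_reduction(0, 1), class = "paco2_domain_error")
})

test_that("method comparison shares one blood-gas set across methods", {
  cfg <- trial_config(n_animals = 1, duration = 10800, noise_sd = 2,
                      outlier_fraction = 0, seed = 19)
  a <- generate_population(cfg)[[1]]
  streams <- list(rlr = run_online(a$recording),
                  etco2 = etco2_baseline(a$recording),
                  etco2_offset = offset_baseline(a$recording, a$bga))
  cmp <- compare_methods(streams, a$recording, a$bga)
  ns <- vapply(cmp$reports, `[[`, 0L, "n")
  expect_true(all(ns == cmp$n))
  expect_equal(cmp$mae_reduction_abs,
               round(cmp$reports$etco2$mae - cmp$reports$rlr$mae, 2))

  # identical streams under different labels give identical reports
  ident <- paco2_model(0, data.frame(base = "etCO2", transform = "identity",
                                     coefficient = 1))
  id_stream <- run_online(a$recording, ident)
  cmp2 <- compare_methods(list(etco2 = streams$etco2, rlr = id_stream),
                          a$recording, a$bga)
  expect_equal(cmp2$reports$rlr$mae, cmp2$reports$etco2$mae)
  expect_equal(cmp2$mae_reduction_rel, 0)

  # supply order must not matter
  cmp3 <- compare_methods(rev(streams), a$recording, a$bga)
  expect_equal(cmp3$reports$rlr$mae, cmp$reports$rlr$mae)
  expect_equal(cmp3$n, cmp$n)
})

test_that("the high-PaCO2 toggle adds exactly the gases above the ceiling", {
  cfg <- trial_config(n_animals = 1, duration = 14400,
                      bga_interval_range = c(900, 1800), noise_sd = 8,
                      outlier_fraction = 0, seed = 23)
  a <- generate_population(cfg)[[1]]
  streams <- list(rlr = run_online(a$recording),
                  etco2 = etco2_baseline(a$recording))
  base_cmp <- compare_methods(streams, a$recording, a$bga)
  ext_cmp <- compare_methods(streams, a$recording, a$bga,
                             include_high_paco2 = TRUE)
  n_high <- sum(a$bga$paco2 > 75)   # all gases pass the Vte filter here
  expect_gte(n_high, 1L)
  expect_equal(ext_cmp$n - base_cmp$n, n_high)
})
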