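test_that("pearson correlation matches hand computation and handles degeneracy", {
  x <- c(1, 2, 3)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  # hand oracle: cov = 1.5, sd_x = 1, sd_y = sqrt(7/3)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 1.5 / sqrt(7 / 3),
               tolerance = 1e-12)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 0.9820, tolerance = 1e-4)

  set.seed(1)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(pearson(a, b), cor(a, b), tolerance = 1e-12)

  expect_true(is.na(pearson(rep(5, 10), rnorm(10))))
  expect_error(pearson(1:4, 1:5), class = "paco2_invalid_config")
  expect_error(pearson(1:2, 1:2), class = "paco2_insufficient_data")
})

test_that("huber weights and robust scale follow their definitions", {
  expect_equal(huber_weights(1.345, scale = 1), 1)
  expect_equal(huber_weights(2.69, scale = 1), 0.5)
  expect_equal(huber_weights(0, scale = 1), 1)
  expect_equal(huber_weights(c(-2.69, 1.3, 0), scale = 1),
               c(0.5, 1, 1))
  expect_error(huber_weights(1, scale = 0), class = "paco2_degenerate_scale")

  expect_equal(robust_scale(c(-1, 0, 1)), 1.4826)
  expect_error(robust_scale(rep(3, 5)), class = "paco2_degenerate_scale")
  expect_error(robust_scale(c(0, 0, 0, 10)),
               class = "paco2_degenerate_scale")
  expect_error(robust_scale(1), class = "paco2_insufficient_data")
})

test_that("huber IRLS recovers exact linear data and resists gross outliers", {
  set.seed(5)
  X <- cbind(a = runif(30, 0, 10), b = runif(30, -5, 5))
  y <- 3 + 2 * X[, "a"] - 0.5 * X[, "b"]
  fit <- fit_huber(X, y)
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 3L)
  expect_equal(unname(coef(fit)), c(3, 2, -0.5), tolerance = 1e-9)

  # one gross outlier: huber slope closer to truth than closed-form OLS
  set.seed(8)
  x <- runif(20, 0, 10)
  yy <- 2 * x
  yy[7] <- yy[7] + 100
  ols_slope <- sum((x - mean(x)) * (yy - mean(yy))) / sum((x - mean(x))^2)
  hub <- fit_huber(matrix(x, dimnames = list(NULL, "x")), yy)
  expect_lt(abs(coef(hub)[["x"]] - 2), abs(ols_slope - 2))

  Xdup <- cbind(a = x, b = x)
  expect_error(fit_huber(Xdup, yy), class = "paco2_singular_design")
})

test_that("huber agrees with an independent robust regression on noisy data", {
  set.seed(13)
  n <- 200
  X <- cbind(u = runif(n, 0, 20), v = rnorm(n))
  y <- 10 + 1.5 * X[, "u"] - 2 * X[, "v"] + rnorm(n)
  y[sample(n, 10)] <- y[sample(n, 10)] + 40
  ours <- coef(fit_huber(X, y))
  ref <- MASS::rlm(y ~ X, k = 1.345, maxit = 100)$coefficients
  expect_equal(unname(ours), unname(ref), tolerance = 0.02)
})

test_that("with a large tuning constant huber reduces to least squares", {
  set.seed(21)
  for (i in 1:5) {
    n <- 40
    X <- cbind(p = runif(n), q = runif(n))
    y <- 1 + X[, "p"] - 3 * X[, "q"] + rnorm(n, 0, 0.5)
    hub <- coef(fit_huber(X, y, fit_config(huber_k = 1e6)))
    ols <- qr.coef(qr(cbind(1, X)), y)
    expect_equal(unname(hub), unname(ols), tolerance = 1e-9)
  }
})

test_that("iterative selection recovers the structural terms on clean data", {
  s <- simulate_design_samples(2000, noise_sd = 0, outlier_fraction = 0,
                               seed = 42)
  flt <- apply_filters(s)
  dm <- build_design_matrix(flt$kept, enumerate_candidates(flt$kept))
  sel <- select_iteratively(dm)
  expect_setequal(sel$trace$steps$label,
                  c("O2diff^2", "pctSpont", "Pmean^3", "log(Vte)"))
  expect_equal(sel$trace$stop_reason, "threshold")
  truth <- coef(published_model())
  got <- coef(sel$model)[names(truth)]
  expect_equal(got, truth, tolerance = 1e-6)
  # monotone growth and threshold clearance along the trace
  expect_identical(sel$trace$steps$step, 1:4)
  expect_true(all(sel$trace$steps$max_abs_r > 0.2))
  term_counts <- vapply(sel$trace$models, function(m) nrow(m$terms), 0L)
  expect_identical(term_counts, 2:5)   # etCO2 + k selected terms
})

test_that("selection adds nothing when etCO2 already explains the response", {
  set.seed(99)
  n <- 5000
  et <- runif(n, 20, 70)
  y <- 30 + 0.9 * et
  X <- sapply(1:10, function(i) rnorm(n))
  colnames(X) <- sprintf("noise%02d", seq_len(10))
  dm <- structure(list(
    forced = matrix(et, ncol = 1, dimnames = list(NULL, "etCO2")),
    X = X, y = y,
    catalogue = data.frame(base = colnames(X), transform = "identity",
                           label = colnames(X))),
    class = "design_matrix")
  sel <- select_iteratively(dm)
  expect_equal(nrow(sel$trace$steps), 0L)
  expect_equal(sel$trace$stop_reason, "threshold")
  expect_equal(unname(coef(sel$model)), c(30, 0.9), tolerance = 1e-9)

  # a high threshold likewise stops immediately
  s <- simulate_design_samples(300, noise_sd = 3, outlier_fraction = 0,
                               seed = 4)
  dmf <- build_design_matrix(s, enumerate_candidates(s))
  self <- select_iteratively(dmf, fit_config(corr_threshold = 0.999))
  expect_equal(nrow(self$trace$steps), 0L)
  expect_equal(self$trace$stop_reason, "threshold")
})

test_that("ties between candidates resolve to canonical catalogue order", {
  set.seed(17)
  n <- 200
  et <- runif(n, 20, 70)
  z <- rnorm(n)
  y <- 30 + 0.9 * et + 2 * z
  X <- cbind(z, z)
  colnames(X) <- c("PEEP", "Ppeak^2")   # identical columns, PEEP earlier
  dm <- structure(list(
    forced = matrix(et, ncol = 1, dimnames = list(NULL, "etCO2")),
    X = X, y = y,
    catalogue = data.frame(base = c("PEEP", "Ppeak"),
                           transform = c("identity", "square"),
                           label = colnames(X))),
    class = "design_matrix")
  sel <- select_iteratively(dm)
  expect_equal(sel$trace$steps$label[1], "PEEP")
  expect_false("Ppeak^2" %in% sel$trace$steps$label)
})

test_that("fit configuration validates its parameters", {
  expect_error(fit_config(huber_k = 0), class = "paco2_invalid_config")
  expect_error(fit_config(corr_threshold = 1), class = "paco2_invalid_config")
  X <- matrix(rnorm(12), 4, 3)   # needs rows > columns + 1
  expect_error(fit_huber(X, rnorm(4)), class = "paco2_insufficient_data")
})
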