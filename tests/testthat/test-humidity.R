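test_that("observed correction factors are neph/grav ratios, below-LOD excluded", {
  s <- data.frame(sample_id = c("A", "B", "C"),
                  neph_pm = c(2000, 500, 1000),
                  grav_pm = c(1000, 1000, 1000),
                  rh = c(0.7, 0.3, 0.5),
                  below_lod = c(FALSE, FALSE, TRUE))
  expect_message(obs <- observed_cf(s), "excluded 1")
  expect_equal(obs$cf, c(2, 0.5))

  s$below_lod <- TRUE
  expect_error(suppressMessages(observed_cf(s)), "below the gravimetric LOD")
})

test_that("correction-factor prediction matches hand arithmetic", {
  chak <- cf_preset("1a")   # a = 1, b = 0.25
  expect_equal(predict(chak, 0), 1.0)
  expect_equal(predict(chak, 0.8), 1 + 0.25 * 0.64 / 0.2)   # 1.8

  rich <- cf_preset("2a")   # a = -0.72, b = -0.82
  expect_equal(predict(rich, 0.5), exp(-0.72 - 0.82 * log(0.5)),
               tolerance = 1e-12)

  # threshold rule: no adjustment at or below 60% RH
  for (m in list(chak, rich)) {
    expect_equal(predict(m, 0.5, use_threshold = TRUE), 1.0)
    expect_equal(predict(m, 0.61, use_threshold = TRUE),
                 predict(m, 0.61, use_threshold = FALSE))
  }
  expect_error(predict(chak, 1.0), "fraction")
  expect_error(predict(chak, 0.995), "0.99")
})

test_that("fitting recovers generating parameters exactly on noiseless data", {
  rh <- seq(0.15, 0.92, length.out = 20)
  obs_c <- data.frame(rh = rh, cf = 0.72 + 0.38 * rh^2 / (1 - rh))
  m_c <- fit_cf(obs_c, "chakrabarti")
  expect_equal(unname(coef(m_c)), c(0.72, 0.38), tolerance = 1e-8)

  obs_r <- data.frame(rh = rh, cf = exp(-0.72 - 0.82 * log(1 - rh)))
  m_r <- fit_cf(obs_r, "richards_log")
  expect_equal(unname(coef(m_r)), c(-0.72, -0.82), tolerance = 1e-8)

  # fit/predict round trip reproduces the generating curve at training points
  expect_equal(predict(m_r, rh), obs_r$cf, tolerance = 1e-10)
  expect_equal(predict(m_c, rh), obs_c$cf, tolerance = 1e-10)

  expect_error(fit_cf(data.frame(rh = c(0.5, 0.5, 0.5), cf = c(1, 2, 3)),
                      "chakrabarti"), "degenerate")
  expect_error(fit_cf(obs_r[1:2, ], "richards_log"), "at least 3")
})

test_that("fitted parameters equal the closed-form normal-equation solution", {
  set.seed(11)
  rh <- runif(40, 0.2, 0.9)
  cf <- exp(-0.6 - 0.9 * log(1 - rh) + rnorm(40, 0, 0.3))
  obs <- data.frame(rh = rh, cf = cf)

  m_r <- fit_cf(obs, "richards_log")
  beta_r <- oracle_ols(cbind(1, log(1 - rh)), log(cf))
  expect_equal(unname(coef(m_r)), unname(beta_r), tolerance = 1e-12)

  m_c <- fit_cf(obs, "chakrabarti")
  beta_c <- oracle_ols(cbind(1, rh^2 / (1 - rh)), cf)
  expect_equal(unname(coef(m_c)), unname(beta_c), tolerance = 1e-12)
})

test_that("humidity adjustment divides by CF and honours the threshold", {
  rich <- cf_preset("2a")
  ident <- cf_model("richards_log", a = 0, b = 0)   # CF = 1 everywhere
  expect_equal(adjust_pm(1000, 0.7, ident), 1000)
  expect_equal(adjust_pm(1000, 0.4, rich, use_threshold = TRUE), 1000)
  expect_equal(adjust_pm(1000, 0.3, rich),
               1000 / exp(-0.72 - 0.82 * log(0.7)), tolerance = 1e-12)
  # vectorised over a series
  pm <- c(100, 1000, 10000); rh <- c(0.2, 0.5, 0.9)
  expect_equal(adjust_pm(pm, rh, rich), pm / predict(rich, rh))
  expect_error(adjust_pm(-1, 0.5, rich), ">= 0")
})

test_that("CF is strictly increasing in RH for the standard parameter signs", {
  grid <- seq(0, 0.99, by = 0.001)
  for (m in list(cf_preset("1a"), cf_preset("1b"), cf_preset("2a"))) {
    expect_true(all(diff(predict(m, grid)) > 0), info = m$form)
  }
})

test_that("thresholded adjustment is identity below 60% RH and unchanged above", {
  set.seed(21)
  pm <- exp(runif(200, log(100), log(50000)))
  rh <- runif(200, 0, 0.99)
  for (m in list(cf_preset("1a"), cf_preset("2a"))) {
    adj_thr <- adjust_pm(pm, rh, m, use_threshold = TRUE)
    adj_no <- adjust_pm(pm, rh, m, use_threshold = FALSE)
    expect_identical(adj_thr[rh <= 0.6], pm[rh <= 0.6])
    expect_identical(adj_thr[rh > 0.6], adj_no[rh > 0.6])
  }
})

test_that("non-positive correction factors are a model-validity error", {
  expect_error(cf_model("chakrabarti", a = 0.5, b = -2), "not positive")
  # richards form is positive by construction
  m <- cf_model("richards_log", a = -5, b = 3)
  expect_true(all(predict(m, seq(0, 0.99, 0.01)) > 0))
})

test_that("parameter estimates concentrate on the truth under lognormal noise", {
  # 60 replicate campaigns at n = 65, sigma = 0.3 (full study in acceptance)
  reps <- simulate(cf_preset("2a"), nsim = 60, seed = 101, noise_sigma = 0.3)
  est <- t(vapply(reps, function(d) coef(fit_cf(d, "richards_log")),
                  numeric(2)))
  mc_se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - (-0.72)), 3 * mc_se[1])
  expect_lt(abs(mean(est[, 2]) - (-0.82)), 3 * mc_se[2])
})
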