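test_that("noiseless data reproduce generating parameters for every form", {
  set.seed(2)
  han <- exp(runif(40, 6.4, 11.1))

  m_ll <- fit_gravimetric(han, exp(2.5 + 0.72 * log(han)), "loglog")
  expect_equal(unname(coef(m_ll))[1:2], c(2.5, 0.72), tolerance = 1e-9)

  m_lin <- fit_gravimetric(han, 0.8 * han, "linear_origin")
  expect_equal(unname(coef(m_lin)), c(0, 0.8), tolerance = 1e-10)

  grav_q <- exp(-4.9 + 2.5 * log(han) - 0.105 * log(han)^2)
  m_q <- fit_gravimetric(han, grav_q, "loglog_quadratic")
  expect_equal(unname(coef(m_q)), c(-4.9, 2.5, -0.105), tolerance = 1e-8)
})

test_that("the hinge knot is recovered exactly from noiseless hinge data", {
  set.seed(7)
  lx <- runif(65, 6.4, 11.1)
  han <- exp(lx)
  grav <- exp(0.9 + 0.95 * lx - 0.45 * pmax(lx - 9.0, 0))
  m <- fit_gravimetric(han, grav, "loglog_spline")
  expect_equal(m$d, 9.0, tolerance = 1e-9)
  expect_equal(unname(coef(m)), c(0.9, 0.95, -0.45, 9.0), tolerance = 1e-7)
})

test_that("predictions match hand arithmetic, presets included", {
  m <- grav_model("loglog", a = 2.5, b = 0.72)
  expect_equal(predict(m, 1000), exp(2.5 + 0.72 * log(1000)), tolerance = 1e-12)

  # published through-origin slope for humidity equation 1a with threshold
  p <- grav_preset("1a", threshold = TRUE, form = "linear_origin")
  expect_equal(predict(p, 1000), 848)

  # hinge inactive below the knot: identical to plain log-log
  ms <- grav_model("loglog_spline", a = 2.5, b = 0.72, c = -0.4, d = 9)
  han_lo <- exp(seq(6.5, 8.9, length.out = 20))
  expect_identical(predict(ms, han_lo, range_warning = FALSE),
                   predict(m, han_lo, range_warning = FALSE))
})

test_that("nested forms collapse to log-log when the extra coefficient is 0", {
  han <- exp(seq(6.5, 11, length.out = 25))
  m0 <- grav_model("loglog", a = 2.2, b = 0.75)
  ms <- grav_model("loglog_spline", a = 2.2, b = 0.75, c = 0, d = 9)
  mq <- grav_model("loglog_quadratic", a = 2.2, b = 0.75, c = 0)
  expect_equal(predict(ms, han, range_warning = FALSE),
               predict(m0, han, range_warning = FALSE), tolerance = 1e-14)
  expect_equal(predict(mq, han, range_warning = FALSE),
               predict(m0, han, range_warning = FALSE), tolerance = 1e-14)
})

test_that("spline predictions are continuous and monotone at the knot", {
  m <- grav_model("loglog_spline", a = 0.9, b = 0.95, c = -0.45, d = 9)
  h <- exp(9) * (1 + c(-1e-12, 0, 1e-12))
  pr <- predict(m, h, range_warning = FALSE)
  expect_equal(pr[1], pr[2], tolerance = 1e-9)
  expect_equal(pr[3], pr[2], tolerance = 1e-9)

  # b > 0 and b + c > 0: strictly increasing in HAN
  grid <- exp(seq(6.5, 11, length.out = 400))
  expect_true(all(diff(predict(m, grid, range_warning = FALSE)) > 0))
})

test_that("knot selection equals an independently coded exhaustive CV loop", {
  set.seed(31)
  lx <- runif(20, 6.8, 11)
  han <- exp(lx)
  grav <- exp(0.8 + 0.9 * lx - 0.5 * pmax(lx - 9.3, 0) + rnorm(20, 0, 0.25))
  m <- fit_gravimetric(han, grav, "loglog_spline")

  grid <- seq(7.5, 12, by = 0.1)
  best_d <- NA; best_cv <- Inf
  for (d in grid) {
    if (sum(lx > d) < 2 || sum(lx <= d) < 2) next
    pr <- numeric(20)
    for (j in 1:20) {
      cf <- coef(lm(log(grav[-j]) ~ lx[-j] + pmax(lx[-j] - d, 0)))
      pr[j] <- exp(cf[1] + cf[2] * lx[j] + cf[3] * max(lx[j] - d, 0))
    }
    cv <- sqrt(mean((pr - grav)^2))
    if (cv < best_cv) { best_cv <- cv; best_d <- d }
  }
  expect_equal(m$d, best_d)
  expect_equal(m$cv_rmse, best_cv, tolerance = 1e-9)
})

test_that("degenerate spline grids fall back to the plain log-log fit", {
  han <- exp(seq(2, 4, length.out = 10))   # far below the default grid
  grav <- exp(1 + 0.9 * log(han))
  expect_warning(m <- fit_gravimetric(han, grav, "loglog_spline"),
                 "outside the data range")
  expect_equal(m$c, 0)
  expect_equal(unname(coef(m))[1:2], c(1, 0.9), tolerance = 1e-9)
})

test_that("predictions warn outside the 600-66000 ug/m3 applicability range", {
  m <- grav_model("loglog", a = 2.5, b = 0.72)
  expect_warning(predict(m, 100), "applicability range")
  expect_warning(predict(m, 70000), "applicability range")
  expect_silent(predict(m, 1000))
  expect_error(predict(m, -5), "> 0")
  expect_error(fit_gravimetric(1:3, 1:3, "loglog"), "at least 4")
})
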