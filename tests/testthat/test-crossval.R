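loo_grav_fit <- function(form) {
  function(d) fit_gravimetric(d$neph_pm, d$grav_pm, form)
}
loo_grav_pred <- function(m, d) predict(m, d$neph_pm, range_warning = FALSE)

test_that("LOO-CV RMSE is zero for data lying exactly on the model", {
  s <- data.frame(neph_pm = exp(seq(6.6, 10.8, length.out = 12)))
  s$grav_pm <- exp(2.5 + 0.72 * log(s$neph_pm))
  cv <- loo_cv(s, loo_grav_fit("loglog"), loo_grav_pred)
  expect_lt(cv$rmse / mean(s$grav_pm), 1e-6)
  expect_equal(cv$n_folds, 12)
})

test_that("LOO-CV equals an independently coded fold loop", {
  set.seed(17)
  s <- data.frame(neph_pm = exp(runif(5, 7, 10)))
  s$grav_pm <- 0.8 * s$neph_pm * exp(rnorm(5, 0, 0.2))
  cv <- loo_cv(s, loo_grav_fit("linear_origin"), loo_grav_pred)
  # hand loop: through-origin slope on the four training points
  preds <- sapply(1:5, function(i) {
    b <- sum(s$neph_pm[-i] * s$grav_pm[-i]) / sum(s$neph_pm[-i]^2)
    b * s$neph_pm[i]
  })
  expect_equal(cv$rmse, sqrt(mean((preds - s$grav_pm)^2)), tolerance = 1e-12)
  expect_equal(cv$predictions, preds, tolerance = 1e-12)
})

test_that("CV RMSE is invariant to sample ordering", {
  s <- oracle_fixture(n = 12, seed = 23)
  cv1 <- loo_cv(s, loo_grav_fit("loglog"), loo_grav_pred)
  perm <- sample(nrow(s))
  cv2 <- loo_cv(s[perm, ], loo_grav_fit("loglog"), loo_grav_pred)
  expect_equal(cv1$rmse, cv2$rmse, tolerance = 1e-12)
})

test_that("two-step CV is exact on compatible noiseless data and degrades under misspecification", {
  camp <- generate_campaign(campaign_config(n_samples = 20, noise_sigma = 0,
                                            dry_bias = c(0.35, 1), seed = 29))
  cv_match <- two_step_cv(camp, cf_form = "richards_log", grav_form = "loglog")
  expect_lt(cv_match$rmse / mean(camp$grav_pm), 1e-6)
  expect_equal(cv_match$n_folds, 20)

  cv_wrong <- two_step_cv(camp, cf_form = "chakrabarti", grav_form = "loglog")
  expect_gt(cv_wrong$rmse, 1e3 * cv_match$rmse)
})

test_that("two-step CV equals the brute-force nested loop", {
  s <- oracle_fixture(n = 10, seed = 37)
  for (cf in c("richards_log", "chakrabarti")) {
    got <- two_step_cv(s, cf_form = cf, grav_form = "loglog")$rmse
    want <- oracle_two_step(s, cf, use_threshold = FALSE, grav_form = "loglog")
    expect_equal(got, want, tolerance = 1e-9, info = cf)
  }
  # fixed published CF parameters, with the threshold rule
  got_fx <- two_step_cv(s, use_threshold = TRUE, grav_form = "loglog",
                        cf_fixed = cf_preset("1a"))$rmse
  want_fx <- oracle_two_step(s, c(1, 0.25), use_threshold = TRUE,
                             grav_form = "loglog")
  expect_equal(got_fx, want_fx, tolerance = 1e-9)
})

test_that("in-sample fit never worsens when the hinge is added (fitting scale)", {
  s <- oracle_fixture(n = 30, seed = 41)
  m0 <- fit_gravimetric(s$neph_pm, s$grav_pm, "loglog")
  m1 <- fit_gravimetric(s$neph_pm, s$grav_pm, "loglog_spline")
  rss0 <- sum(residuals(m0)^2)
  rss1 <- sum(residuals(m1)^2)
  expect_lte(rss1, rss0 + 1e-12)
})

test_that("the comparison enumerates 3 combined and 18 two-step approaches", {
  camp <- generate_campaign(campaign_config(n_samples = 20, seed = 43))
  tab <- comparison_table(camp)
  expect_equal(nrow(tab), 21)
  expect_equal(sum(tab$type == "two_step"), 18)
  expect_equal(sum(tab$type == "combined"), 3)
  expect_equal(tab$approach, 1:21)
  expect_true(all(tab$n_folds == 20))
  expect_true(all(is.finite(tab$cv_rmse)))
  # humidity x threshold x conversion grid is complete
  ts <- tab[tab$type == "two_step", ]
  expect_equal(as.vector(table(ts$humidity)), c(6L, 6L, 6L))
  expect_equal(sum(ts$threshold), 9)

  sub <- comparison_table(camp, approaches = c(1, 4, 9))
  expect_equal(sub$approach, c(1, 4, 9))
})

test_that("the generating approach wins on noiseless generative-match data", {
  camp <- generate_campaign(campaign_config(n_samples = 20, noise_sigma = 0,
                                            dry_bias = c(0.35, 1), seed = 47))
  tab <- comparison_table(camp)
  scale <- mean(camp$grav_pm)
  # approach 6: humidity 2a (no threshold) + log-log conversion
  rmse6 <- tab$cv_rmse[tab$approach == 6]
  expect_lt(rmse6 / scale, 1e-6)
  expect_lte(rmse6, min(tab$cv_rmse) + 1e-6 * scale)
})
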