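# Independent brute-force oracles: every fit is a direct lm()/arithmetic
# call and every cross-validation is an explicit nested loop, coded without
# reference to the package internals.

oracle_fit_predict_grav <- function(h, g, h_new, form,
                                    grid = seq(7.5, 12, by = 0.1)) {
  lx <- log(h); ly <- log(g)
  lxn <- log(h_new)
  if (form == "linear_origin") {
    return(sum(h * g) / sum(h * h) * h_new)
  }
  if (form == "loglog") {
    cf <- coef(lm(ly ~ lx))
    return(exp(cf[1] + cf[2] * lxn))
  }
  if (form == "loglog_quadratic") {
    cf <- coef(lm(ly ~ lx + I(lx^2)))
    return(exp(cf[1] + cf[2] * lxn + cf[3] * lxn^2))
  }
  # loglog_spline: knot chosen by explicit nested LOO, ties to smallest knot
  best_d <- NA_real_; best_cv <- Inf
  for (d in grid) {
    if (sum(lx > d) < 2 || sum(lx <= d) < 2) next
    pr <- numeric(length(h))
    for (j in seq_along(h)) {
      cf <- coef(lm(ly[-j] ~ lx[-j] + pmax(lx[-j] - d, 0)))
      pr[j] <- exp(cf[1] + cf[2] * lx[j] + cf[3] * max(lx[j] - d, 0))
    }
    cv <- sqrt(mean((pr - g)^2))
    if (cv < best_cv) { best_cv <- cv; best_d <- d }
  }
  cf <- coef(lm(ly ~ lx + pmax(lx - best_d, 0)))
  exp(cf[1] + cf[2] * lxn + cf[3] * max(lxn - best_d, 0))
}

oracle_loo_grav <- function(han, grav, form, grid = seq(7.5, 12, by = 0.1)) {
  preds <- vapply(seq_along(han), function(i) {
    oracle_fit_predict_grav(han[-i], grav[-i], han[i], form, grid)
  }, numeric(1))
  sqrt(mean((preds - grav)^2))
}

oracle_fit_predict_combined <- function(train, test, form,
                                        grid = seq(7.5, 12, by = 0.1)) {
  ly <- log(train$grav_pm)
  z1 <- log(1 - train$rh); z2 <- log(train$neph_pm)
  t1 <- log(1 - test$rh); t2 <- log(test$neph_pm)
  if (form == "loglinear") {
    cf <- coef(lm(ly ~ z1 + z2))
    return(exp(cf[1] + cf[2] * t1 + cf[3] * t2))
  }
  if (form == "loglinear_quadratic") {
    cf <- coef(lm(ly ~ z1 + z2 + I(z2^2)))
    return(exp(cf[1] + cf[2] * t1 + cf[3] * t2 + cf[4] * t2^2))
  }
  best_f <- NA_real_; best_cv <- Inf
  for (d in grid) {
    if (sum(z2 > d) < 2 || sum(z2 <= d) < 2) next
    pr <- numeric(nrow(train))
    for (j in seq_len(nrow(train))) {
      cf <- coef(lm(ly[-j] ~ z1[-j] + z2[-j] + pmax(z2[-j] - d, 0)))
      pr[j] <- exp(cf[1] + cf[2] * z1[j] + cf[3] * z2[j] +
                     cf[4] * max(z2[j] - d, 0))
    }
    cv <- sqrt(mean((pr - train$grav_pm)^2))
    if (cv < best_cv) { best_cv <- cv; best_f <- d }
  }
  cf <- coef(lm(ly ~ z1 + z2 + pmax(z2 - best_f, 0)))
  exp(cf[1] + cf[2] * t1 + cf[3] * t2 + cf[4] * max(t2 - best_f, 0))
}

oracle_loo_combined <- function(samples, form, grid = seq(7.5, 12, by = 0.1)) {
  preds <- vapply(seq_len(nrow(samples)), function(i) {
    oracle_fit_predict_combined(samples[-i, ], samples[i, ], form, grid)
  }, numeric(1))
  sqrt(mean((preds - samples$grav_pm)^2))
}

# cf_spec: "chakrabarti" / "richards_log" to refit per fold, or a numeric
# c(a, b) of fixed chakrabarti parameters.
oracle_two_step <- function(samples, cf_spec, use_threshold, grav_form,
                            grid = seq(7.5, 12, by = 0.1)) {
  n <- nrow(samples)
  cf_of <- function(a, b, form, rh) {
    cf <- if (form == "chakrabarti") a + b * rh^2 / (1 - rh)
          else exp(a + b * log(1 - rh))
    if (use_threshold) cf[rh <= 0.6] <- 1
    cf
  }
  preds <- numeric(n)
  for (i in seq_len(n)) {
    tr <- samples[-i, ]; te <- samples[i, ]
    cfr <- tr$neph_pm / tr$grav_pm
    if (is.numeric(cf_spec)) {
      a <- cf_spec[1]; b <- cf_spec[2]; form <- "chakrabarti"
    } else if (cf_spec == "chakrabarti") {
      co <- coef(lm(cfr ~ I(tr$rh^2 / (1 - tr$rh))))
      a <- co[1]; b <- co[2]; form <- "chakrabarti"
    } else {
      co <- coef(lm(log(cfr) ~ log(1 - tr$rh)))
      a <- co[1]; b <- co[2]; form <- "richards_log"
    }
    han_tr <- tr$neph_pm / cf_of(a, b, form, tr$rh)
    han_te <- te$neph_pm / cf_of(a, b, form, te$rh)
    preds[i] <- oracle_fit_predict_grav(han_tr, tr$grav_pm, han_te,
                                        grav_form, grid)
  }
  sqrt(mean((preds - samples$grav_pm)^2))
}

# Closed-form normal-equation OLS for the regression oracle checks.
oracle_ols <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# Small noisy co-location fixture for oracle comparisons.
oracle_fixture <- function(n = 15, seed = 42, sigma = 0.25) {
  set.seed(seed)
  rh <- runif(n, 0.2, 0.9)
  lC <- runif(n, log(700), log(25000))
  cf <- exp(-0.72 - 0.82 * log(1 - rh))
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             neph_pm = exp(-0.5 + 1.2 * lC) * cf,
             grav_pm = exp(lC + rnorm(n, 0, sigma)),
             rh = rh, below_lod = FALSE)
}
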