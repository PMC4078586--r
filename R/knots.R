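# Hinge-knot grid search shared by the gravimetric and combined fitters.
#
# For each candidate knot the model gains the regressor max(z - knot, 0); the
# knot is chosen to minimise the leave-one-out cross-validated RMSE on the
# original concentration scale (log-scale LOO linear predictors are
# exponentiated before computing errors). For ordinary least squares the LOO
# linear predictor has the exact closed form y_i - e_i / (1 - h_i), so the
# grid search needs only one QR factorisation per knot; the result is
# numerically identical to refitting each fold. Ties break to the smallest
# knot for determinism.

# confint() warns via summary.lm on numerically perfect fits (noiseless
# oracle data); the intervals are still what we want, so silence it.
ols_ci <- function(fit, level) suppressWarnings(stats::confint(fit, level = level))

# Exact LOO RMSE (original scale) of OLS on design X for log-response ly.
ols_loo_rmse_orig <- function(X, ly, y_orig) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) return(Inf)
  beta <- qr.coef(qrX, ly)
  e <- ly - drop(X %*% beta)
  h <- rowSums(qr.Q(qrX)^2)
  if (any(h >= 1 - 1e-10)) return(Inf)
  pred_loo <- ly - e / (1 - h)
  sqrt(mean((exp(pred_loo) - y_orig)^2))
}

# z: variable carrying the hinge; X0: base design (with intercept column).
# Returns list(knot, cv_rmse, profile).
select_knot <- function(z, X0, ly, y_orig, grid) {
  eligible <- vapply(grid, function(d) sum(z > d) >= 2L && sum(z <= d) >= 2L,
                     logical(1))
  if (!any(eligible)) {
    return(list(knot = NA_real_, cv_rmse = NA_real_,
                profile = data.frame(knot = grid, cv_rmse = NA_real_)))
  }
  cv <- rep(Inf, length(grid))
  for (k in which(eligible)) {
    cv[k] <- ols_loo_rmse_orig(cbind(X0, pmax(z - grid[k], 0)), ly, y_orig)
  }
  best <- which.min(cv)   # first minimum -> smallest knot on ties
  list(knot = grid[best], cv_rmse = cv[best],
       profile = data.frame(knot = grid, cv_rmse = ifelse(is.finite(cv), cv, NA_real_)))
}
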