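#' Fit a one-step combined humidity + gravimetric adjustment model
#'
#' A single regression that performs humidity adjustment and gravimetric
#' conversion together, with the gravimetric concentration as the only
#' response:
#' `ln(Grav PM2.5) = c0 + c1 * ln(1 - RH) + c2 * ln(Neph PM) [+ extra term]`.
#' It is the composition of the log-linear CF model with the log-log
#' conversion, so no RH threshold is used anywhere in this family. Forms:
#'
#' * `"loglinear"` — the base three-coefficient model.
#' * `"loglinear_spline"` — adds `c3 * max(ln(Neph PM) - knot, 0)`; the knot
#'   (on the `ln(Neph PM)` scale) is selected by grid search (default 7.5 to
#'   12.0 by 0.1) minimising leave-one-out CV RMSE on the original scale,
#'   ties to the smallest knot.
#' * `"loglinear_quadratic"` — adds `c3 * ln(Neph PM)^2`.
#'
#' @param samples co-location data frame with `neph_pm`, `grav_pm`, `rh` (and
#'   optional `below_lod`, excluded by default).
#' @param form model form.
#' @param spline_grid candidate knots on the `ln(Neph PM)` scale.
#' @param conf_level confidence level for parameter intervals.
#' @param include_below_lod keep below-LOD samples in the fit.
#' @return an object of class `combined_model` with coefficients `c0`..`c3`
#'   and `knot`.
#' @examples
#' s <- data.frame(neph_pm = exp(seq(6.5, 11, length.out = 30)),
#'                 rh = seq(0.2, 0.9, length.out = 30))
#' s$grav_pm <- exp(3.102 + 0.701 * log(1 - s$rh) + 0.717 * log(s$neph_pm))
#' fit_combined(s, "loglinear")
#' @export
fit_combined <- function(samples,
                         form = c("loglinear", "loglinear_spline",
                                  "loglinear_quadratic"),
                         spline_grid = seq(7.5, 12, by = 0.1),
                         conf_level = 0.95, include_below_lod = FALSE) {
  form <- match.arg(form)
  below <- samples$below_lod %||% rep(FALSE, nrow(samples))
  if (!include_below_lod && any(below)) {
    message(sprintf("fit_combined: excluded %d below-LOD sample(s)", sum(below)))
    samples <- samples[!below, , drop = FALSE]
  }
  if (nrow(samples) < 5L) stop("need at least 5 usable samples", call. = FALSE)
  assert_positive(samples$neph_pm, "neph_pm")
  assert_positive(samples$grav_pm, "grav_pm")
  assert_rh(samples$rh)

  ly <- log(samples$grav_pm)
  z1 <- log1p(-samples$rh)
  z2 <- log(samples$neph_pm)
  c3 <- NULL; knot <- NULL; cv_rmse <- NA_real_; profile <- NULL

  if (form == "loglinear") {
    fit <- stats::lm(ly ~ z1 + z2, data = data.frame(ly = ly, z1 = z1, z2 = z2))
    labs <- c("c0", "c1", "c2")
  } else if (form == "loglinear_quadratic") {
    fit <- stats::lm(ly ~ z1 + z2 + z2sq,
                     data = data.frame(ly = ly, z1 = z1, z2 = z2, z2sq = z2^2))
    labs <- c("c0", "c1", "c2", "c3")
  } else { # loglinear_spline
    sel <- select_knot(z2, cbind(1, z1, z2), ly, samples$grav_pm, spline_grid)
    if (is.na(sel$knot)) {
      warning("spline grid lies entirely outside the data range; ",
              "falling back to the plain log-linear combined fit",
              call. = FALSE)
      fit <- stats::lm(ly ~ z1 + z2, data = data.frame(ly = ly, z1 = z1, z2 = z2))
      labs <- c("c0", "c1", "c2")
      c3 <- 0; knot <- NA_real_
    } else {
      knot <- sel$knot; cv_rmse <- sel$cv_rmse; profile <- sel$profile
      fit <- stats::lm(ly ~ z1 + z2 + hinge,
                       data = data.frame(ly = ly, z1 = z1, z2 = z2,
                                         hinge = pmax(z2 - knot, 0)))
      labs <- c("c0", "c1", "c2", "c3")
    }
  }
  co <- unname(stats::coef(fit))
  if (any(is.na(co))) stop("collinear design: combined model is not estimable",
                           call. = FALSE)
  ci <- ols_ci(fit, conf_level)
  dimnames(ci)[[1]] <- labs
  if (length(co) == 4L) c3 <- co[4]

  structure(list(form = form, c0 = co[1], c1 = co[2], c2 = co[3], c3 = c3,
                 knot = knot, cv_rmse = cv_rmse, knot_profile = profile,
                 ci = ci, fit = fit, n = nrow(samples),
                 provenance = "fitted"),
            class = "combined_model")
}

#' Construct a combined adjustment model from known coefficients
#'
#' @inheritParams fit_combined
#' @param c0,c1,c2 intercept and coefficients on `ln(1 - RH)` and
#'   `ln(Neph PM)`.
#' @param c3 hinge (spline form) or quadratic coefficient.
#' @param knot hinge knot on the `ln(Neph PM)` scale (spline form).
#' @param provenance `"published"` or `"fitted"`.
#' @return a `combined_model`.
#' @export
combined_model <- function(form = c("loglinear", "loglinear_spline",
                                    "loglinear_quadratic"),
                           c0, c1, c2, c3 = NULL, knot = NULL,
                           provenance = "published") {
  form <- match.arg(form)
  structure(list(form = form, c0 = c0, c1 = c1, c2 = c2, c3 = c3, knot = knot,
                 cv_rmse = NA_real_, knot_profile = NULL, ci = NULL,
                 fit = NULL, n = NA_integer_, provenance = provenance),
            class = "combined_model")
}

#' Predict gravimetric-equivalent PM2.5 from raw nephelometric PM and RH
#'
#' Plain exponential of the linear predictor (no retransformation bias
#' correction); the hinge contributes only where `ln(pm) > knot`. Warns when
#' nephelometric readings fall outside the 600-66,000 ug/m3 applicability
#' range.
#'
#' @param object a `combined_model`.
#' @param pm raw nephelometric PM (ug/m3), > 0, vectorised.
#' @param rh relative humidity fraction in \[0, 0.99\], recycled to the
#'   length of `pm`.
#' @param range_warning warn outside the applicability range.
#' @param ... unused.
#' @return predicted gravimetric-equivalent PM2.5 (ug/m3).
#' @export
predict.combined_model <- function(object, pm, rh, range_warning = TRUE, ...) {
  assert_positive(pm, "pm")
  assert_rh(rh)
  if (anyNA(c(object$c0, object$c1, object$c2))) {
    stop("this combined preset ships without its full published coefficient set; ",
         "refit it on your data with fit_combined()", call. = FALSE)
  }
  if (range_warning) range_warn(pm, "nephelometric PM")
  predict_combined_core(object, pm, rh)
}

predict_combined_core <- function(m, pm, rh) {
  lp <- m$c0 + m$c1 * log1p(-rh) + m$c2 * log(pm)
  if (m$form == "loglinear_spline" && !is.null(m$c3) &&
      is.finite(m$knot %||% NA_real_)) {
    lp <- lp + m$c3 * pmax(log(pm) - m$knot, 0)
  } else if (m$form == "loglinear_quadratic" && !is.null(m$c3)) {
    lp <- lp + m$c3 * log(pm)^2
  }
  exp(lp)
}

#' @export
print.combined_model <- function(x, ...) {
  extra <- switch(x$form,
    loglinear = "",
    loglinear_spline = sprintf(" + %.4g max(ln(PM) - %.3g, 0)",
                               x$c3 %||% NA_real_, x$knot %||% NA_real_),
    loglinear_quadratic = sprintf(" + %.4g ln(PM)^2", x$c3 %||% NA_real_))
  cat("Combined humidity + gravimetric model (", x$form, ", ", x$provenance,
      ")\n", sprintf("  ln(Grav) = %.4g + %.4g ln(1-RH) + %.4g ln(PM)%s\n",
                     x$c0, x$c1, x$c2, extra),
      "  no RH threshold is used in this family\n", sep = "")
  if (is.finite(x$cv_rmse %||% NA_real_)) {
    cat(sprintf("  knot-selection LOO-CV RMSE: %.4g ug/m3\n", x$cv_rmse))
  }
  invisible(x)
}

#' @export
coef.combined_model <- function(object, ...) {
  out <- c(c0 = object$c0, c1 = object$c1, c2 = object$c2)
  if (!is.null(object$c3)) out <- c(out, c3 = object$c3)
  if (!is.null(object$knot)) out <- c(out, knot = object$knot)
  out
}

#' @export
summary.combined_model <- function(object, ...) {
  if (!is.null(object$fit)) summary(object$fit) else print(object)
}

#' @export
residuals.combined_model <- function(object, ...) {
  if (is.null(object$fit)) stop("no stored fit (published preset)", call. = FALSE)
  stats::residuals(object$fit)
}

#' @export
plot.combined_model <- function(x, rh = c(0.3, 0.6, 0.9), ...) {
  pm <- exp(seq(log(600), log(66000), length.out = 200))
  pred <- sapply(rh, function(r) predict_combined_core(x, pm, r))
  graphics::plot(pm, pred[, 1], type = "n", log = "xy",
                 ylim = range(pred), xlab = "nephelometric PM (ug/m3)",
                 ylab = "gravimetric-equivalent PM2.5 (ug/m3)", ...)
  for (j in seq_along(rh)) graphics::lines(pm, pred[, j], lty = j)
  graphics::legend("topleft", legend = sprintf("RH = %.0f%%", 100 * rh),
                   lty = seq_along(rh), bty = "n")
  invisible(x)
}
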