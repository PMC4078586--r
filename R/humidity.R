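#' Humidity correction-factor models
#'
#' A correction factor CF(RH) is the ratio of the humidity-influenced
#' nephelometric PM reading to the humidity-independent (gravimetric)
#' concentration; dividing the reading by CF removes the humidity bias. Two
#' empirical families are supported:
#'
#' * `"chakrabarti"` — `CF = a + b * RH^2 / (1 - RH)`, the empirical
#'   quadratic-ratio growth form; the published ambient-PM parameterisation is
#'   `a = 1`, `b = 0.25` (preset `"1a"`).
#' * `"richards_log"` — `ln(CF) = a + b * ln(1 - RH)`, a log-linear form that
#'   composes cleanly with log-scale gravimetric conversion.
#'
#' Both are conventionally applied only above a 60% RH threshold (CF fixed at
#' 1 below it); fitting and the threshold are kept separate — a model is fit
#' once on all samples and the threshold, when enabled, is applied at
#' prediction time only.
#'
#' @param form model family.
#' @param a,b model parameters.
#' @param rh_threshold RH threshold (fraction) used when prediction is asked
#'   to threshold; default 0.60.
#' @param provenance `"published"` for preset parameter sets, `"fitted"` for
#'   models estimated from data.
#' @param ci optional 2x2 matrix of 95% confidence limits (rows `a`, `b`).
#' @param fit optional underlying [stats::lm] fit.
#' @param n number of samples used in fitting.
#' @return an object of class `cf_model`.
#' @seealso [fit_cf()], [adjust_pm()], [cf_preset()]
#' @export
cf_model <- function(form = c("chakrabarti", "richards_log"), a, b,
                     rh_threshold = 0.60, provenance = "published",
                     ci = NULL, fit = NULL, n = NA_integer_) {
  form <- match.arg(form)
  stopifnot(is.finite(a), is.finite(b))
  m <- structure(list(form = form, a = a, b = b, rh_threshold = rh_threshold,
                      provenance = provenance, ci = ci, fit = fit, n = n),
                 class = "cf_model")
  if (form == "chakrabarti") {
    grid <- seq(0, 0.99, by = 0.01)
    if (any(a + b * grid^2 / (1 - grid) <= 0)) {
      stop("invalid chakrabarti parameters: CF(RH) is not positive on [0, 0.99]",
           call. = FALSE)
    }
  }
  m
}

#' Observed correction factors from co-location samples
#'
#' The per-sample observed CF is the ratio of the window-averaged
#' nephelometer reading to the co-located gravimetric PM2.5 concentration.
#' Samples flagged below the gravimetric limit of detection are excluded
#' (with a message); a table with no usable samples is an error.
#'
#' @param samples co-location data frame with columns `neph_pm`, `grav_pm`,
#'   `rh` and optionally `sample_id`, `below_lod`.
#' @param include_below_lod keep below-LOD samples (their CF is unreliable;
#'   off by default).
#' @return data frame with `sample_id`, `rh`, `cf`.
#' @export
observed_cf <- function(samples, include_below_lod = FALSE) {
  below <- samples$below_lod %||% rep(FALSE, nrow(samples))
  if (!include_below_lod && any(below)) {
    message(sprintf("observed_cf: excluded %d below-LOD sample(s)", sum(below)))
    samples <- samples[!below, , drop = FALSE]
  }
  if (nrow(samples) == 0L) {
    stop("no usable samples: all are below the gravimetric LOD", call. = FALSE)
  }
  assert_positive(samples$neph_pm, "neph_pm")
  assert_positive(samples$grav_pm, "grav_pm")
  assert_rh(samples$rh)
  data.frame(sample_id = samples$sample_id %||% paste0("S", seq_len(nrow(samples))),
             rh = samples$rh,
             cf = samples$neph_pm / samples$grav_pm)
}

#' Fit a humidity correction-factor model
#'
#' Ordinary least squares on the form's linearising scale:
#' `"chakrabarti"` regresses CF on `RH^2 / (1 - RH)` (intercept `a`, slope
#' `b`); `"richards_log"` regresses `ln(CF)` on `ln(1 - RH)`. Fitting is
#' unweighted and uses all supplied samples regardless of RH; the 60%
#' threshold only changes how the model is *applied*.
#'
#' @param obs observed correction factors from [observed_cf()] (columns `rh`,
#'   `cf`), or a co-location data frame (converted automatically).
#' @param form model family, see [cf_model()].
#' @param conf_level confidence level for the reported parameter intervals.
#' @return a `cf_model` with `provenance = "fitted"`.
#' @examples
#' obs <- data.frame(rh = seq(0.2, 0.9, length.out = 20))
#' obs$cf <- exp(-0.72 - 0.82 * log(1 - obs$rh))
#' fit_cf(obs, "richards_log")
#' @export
fit_cf <- function(obs, form = c("chakrabarti", "richards_log"),
                   conf_level = 0.95) {
  form <- match.arg(form)
  if (!is.null(obs$neph_pm)) obs <- observed_cf(obs)
  if (nrow(obs) < 3L) stop("need at least 3 observed correction factors",
                           call. = FALSE)
  assert_rh(obs$rh)
  assert_positive(obs$cf, "cf")
  if (length(unique(obs$rh)) < 2L) {
    stop("degenerate design: all RH values are equal", call. = FALSE)
  }
  if (form == "chakrabarti") {
    x <- obs$rh^2 / (1 - obs$rh)
    fit <- stats::lm(cf ~ x, data = data.frame(cf = obs$cf, x = x))
  } else {
    fit <- stats::lm(lcf ~ lx,
                     data = data.frame(lcf = log(obs$cf), lx = log1p(-obs$rh)))
  }
  cc <- unname(stats::coef(fit))
  ci <- ols_ci(fit, conf_level)
  dimnames(ci)[[1]] <- c("a", "b")
  cf_model(form, a = cc[1], b = cc[2], provenance = "fitted", ci = ci,
           fit = fit, n = nrow(obs))
}

#' Predict the correction factor at given humidities
#'
#' @param object a `cf_model`.
#' @param rh relative humidity, fraction in \[0, 0.99\] (vectorised).
#' @param use_threshold if `TRUE`, CF is 1 (no adjustment) wherever
#'   `rh <= object$rh_threshold` (the conventional 60% rule).
#' @param ... unused.
#' @return numeric vector of correction factors.
#' @export
predict.cf_model <- function(object, rh, use_threshold = FALSE, ...) {
  assert_rh(rh)
  cf <- switch(object$form,
    chakrabarti = object$a + object$b * rh^2 / (1 - rh),
    richards_log = exp(object$a + object$b * log1p(-rh)))
  if (any(cf <= 0)) {
    stop("model-validity error: correction factor <= 0 at some RH for the stored parameters",
         call. = FALSE)
  }
  if (use_threshold) {
    cf[rh <= (object$rh_threshold %||% 0.60)] <- 1
  }
  cf
}

#' Humidity-adjust nephelometric PM readings
#'
#' Divides readings by the model correction factor CF(RH), yielding
#' humidity-adjusted nephelometric (HAN) PM. Vectorised over aligned time
#' series, so a full 24-h record can be adjusted in one call.
#'
#' @param pm nephelometric PM (ug/m3), `>= 0`.
#' @param rh relative humidity fraction, same length as `pm` or length 1.
#' @param model a `cf_model`.
#' @param use_threshold apply the 60% RH threshold rule (see
#'   [predict.cf_model()]).
#' @return HAN PM (ug/m3).
#' @export
adjust_pm <- function(pm, rh, model, use_threshold = FALSE) {
  if (any(!is.finite(pm) | pm < 0)) stop("`pm` must be finite and >= 0",
                                         call. = FALSE)
  pm / predict(model, rh, use_threshold = use_threshold)
}

#' @export
print.cf_model <- function(x, ...) {
  eq <- switch(x$form,
    chakrabarti = sprintf("CF = %.4g + %.4g * RH^2/(1-RH)", x$a, x$b),
    richards_log = sprintf("ln(CF) = %.4g + %.4g * ln(1-RH)", x$a, x$b))
  cat("Humidity correction-factor model (", x$form, ", ", x$provenance, ")\n",
      "  ", eq, "\n", sep = "")
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI  a: (%.4g, %.4g)  b: (%.4g, %.4g)\n",
                x$ci[1, 1], x$ci[1, 2], x$ci[2, 1], x$ci[2, 2]))
  }
  cat(sprintf("  RH threshold (when applied): %.2f\n", x$rh_threshold))
  invisible(x)
}

#' @export
coef.cf_model <- function(object, ...) c(a = object$a, b = object$b)

#' @export
summary.cf_model <- function(object, ...) {
  if (!is.null(object$fit)) summary(object$fit) else print(object)
}

#' Simulate observed correction factors from a CF model
#'
#' Draws `cf = CF(rh) * exp(eps)` with `eps ~ N(0, noise_sigma^2)` —
#' multiplicative lognormal scatter, matching the log-scale error structure
#' of the fitted models.
#'
#' @param object a `cf_model`.
#' @param nsim number of replicate data sets.
#' @param seed RNG seed (required).
#' @param rh humidity design points (fractions).
#' @param noise_sigma SD of the log-scale noise.
#' @param ... unused.
#' @return for `nsim = 1` a data frame (`rh`, `cf`); otherwise a list of them.
#' @export
simulate.cf_model <- function(object, nsim = 1, seed = NULL,
                              rh = seq(0.15, 0.95, length.out = 65),
                              noise_sigma = 0.3, ...) {
  assert_rh(rh)
  out <- with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      mu <- predict(object, rh)
      data.frame(rh = rh,
                 cf = mu * exp(stats::rnorm(length(rh), 0, noise_sigma)))
    })
  })
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.cf_model <- function(x, obs = NULL, use_threshold = FALSE, ...) {
  rr <- seq(0.01, 0.98, by = 0.005)
  cf <- predict(x, rr, use_threshold = use_threshold)
  graphics::plot(rr, cf, type = "l", xlab = "relative humidity (fraction)",
                 ylab = "correction factor CF", ...)
  graphics::abline(h = 1, lty = 3)
  if (!is.null(obs)) graphics::points(obs$rh, obs$cf, pch = 16, cex = 0.6)
  invisible(x)
}
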