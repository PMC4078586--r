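#' Configuration for a synthetic co-location campaign
#'
#' The generator emulates a field co-location campaign between a passive
#' nephelometer and gravimetric PM2.5 filter samples during biomass cooking:
#'
#' * a latent true concentration `C` is drawn log-uniformly over `grav_range`
#'   (default 600-26,000 ug/m3, the gravimetric range such campaigns span);
#' * window-mean RH is drawn uniformly over `rh_range` (default 0.15-0.95);
#' * the nephelometer responds deterministically with a concentration-
#'   dependent "dry bias" power law and multiplicative humidity bias:
#'   `ln(neph) = alpha + beta * ln(C) + ln(CF_truth(rh))`
#'   (optionally plus a hinge `hinge_coef * max(ln(C) - hinge_knot, 0)` to
#'   exercise spline-knot recovery);
#' * the gravimetric reference carries the measurement error:
#'   `grav = C * exp(eps)`, `eps ~ N(0, noise_sigma^2)` (multiplicative
#'   lognormal — concentrations span two orders of magnitude and all models
#'   operate on the log scale).
#'
#' With this structure the implied combined-model truth is exactly
#' `c0 = -(alpha + a_cf)/beta`, `c1 = -b_cf/beta`, `c2 = 1/beta` for a
#' log-linear CF truth with parameters `(a_cf, b_cf)`. The defaults
#' (`beta = 1.4`, so `c2 ~= 0.714`; `alpha = -3.1`, so `c0 ~= 2.73`) match
#' the magnitude of published cookstove calibration slopes; `beta != 1` is
#' what makes the spline/quadratic conversion forms non-trivial on synthetic
#' data.
#'
#' @param n_samples number of co-location pairs (default 65).
#' @param grav_range range of true concentrations (ug/m3), drawn
#'   log-uniformly.
#' @param rh_range range of window-mean RH (fractions), drawn uniformly.
#' @param cf_truth a `cf_model` giving the humidity-bias truth (default the
#'   published log-linear set `"2a"`).
#' @param dry_bias numeric `c(alpha, beta)` of the dry-response power law.
#' @param noise_sigma SD of the log-scale gravimetric measurement noise.
#' @param hinge_knot,hinge_coef optional hinge in the instrument response
#'   (knot on the `ln(C)` scale), off by default.
#' @param seed RNG seed; mandatory for any stochastic call.
#' @return a list of class `campaign_config`.
#' @seealso [generate_campaign()]
#' @export
campaign_config <- function(n_samples = 65,
                            grav_range = c(600, 26000),
                            rh_range = c(0.15, 0.95),
                            cf_truth = cf_preset("2a"),
                            dry_bias = c(alpha = -3.1, beta = 1.4),
                            noise_sigma = 0.3,
                            hinge_knot = NULL, hinge_coef = 0,
                            seed = NULL) {
  stopifnot(n_samples >= 2, grav_range[1] > 0, grav_range[2] > grav_range[1],
            rh_range[1] >= 0, rh_range[2] <= 0.99, rh_range[2] > rh_range[1],
            inherits(cf_truth, "cf_model"), length(dry_bias) == 2,
            dry_bias[2] > 0, noise_sigma >= 0)
  structure(list(n_samples = n_samples, grav_range = grav_range,
                 rh_range = rh_range, cf_truth = cf_truth,
                 dry_bias = unname(dry_bias), noise_sigma = noise_sigma,
                 hinge_knot = hinge_knot, hinge_coef = hinge_coef,
                 seed = seed),
            class = "campaign_config")
}

#' Generate a synthetic co-location campaign
#'
#' Draws a full co-location sample table (see [campaign_config()] for the
#' generative model). Covariates (fuel type, home type, window/door status,
#' kitchen size) are sampled independently and carried through; they do not
#' enter the generative concentrations, mirroring their non-significance in
#' the adjustment models. The output is deterministic given the seed.
#'
#' @param config a [campaign_config()].
#' @param seed RNG seed; defaults to `config$seed` and is required.
#' @return data frame in the co-location table layout (`sample_id`,
#'   `neph_pm`, `grav_pm`, `rh`, covariates, `below_lod`) with attribute
#'   `"truth"` recording the generator parameters and the implied
#'   combined-model coefficients.
#' @examples
#' camp <- generate_campaign(campaign_config(seed = 1))
#' head(camp)
#' @export
generate_campaign <- function(config = campaign_config(), seed = config$seed) {
  cfg <- config
  alpha <- cfg$dry_bias[1]; beta <- cfg$dry_bias[2]
  n <- cfg$n_samples
  with_seed(seed, {
    lC <- stats::runif(n, log(cfg$grav_range[1]), log(cfg$grav_range[2]))
    rh <- stats::runif(n, cfg$rh_range[1], cfg$rh_range[2])
    eps <- stats::rnorm(n, 0, cfg$noise_sigma)
    fuel <- sample(c("wood", "crop_waste", "wood_mixed"), n, replace = TRUE,
                   prob = c(0.6, 0.2, 0.2))
    home <- sample(c("occupied", "mock"), n, replace = TRUE, prob = c(0.8, 0.2))
    wd <- sample(c("all_closed", "open"), n, replace = TRUE)
    kitchen <- round(stats::runif(n, 10, 40), 1)

    cf <- predict(cfg$cf_truth, rh)
    lneph <- alpha + beta * lC + log(cf)
    if (!is.null(cfg$hinge_knot)) {
      lneph <- lneph + cfg$hinge_coef * pmax(lC - cfg$hinge_knot, 0)
    }
    out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                      neph_pm = exp(lneph),
                      grav_pm = exp(lC + eps),
                      rh = rh,
                      fuel_type = fuel, home_type = home,
                      window_door_status = wd, kitchen_size = kitchen,
                      below_lod = FALSE,
                      stringsAsFactors = FALSE)
    truth <- list(alpha = alpha, beta = beta,
                  cf = coef(cfg$cf_truth), cf_form = cfg$cf_truth$form,
                  noise_sigma = cfg$noise_sigma,
                  combined = c(c0 = -(alpha + unname(coef(cfg$cf_truth)[1])) / beta,
                               c1 = -unname(coef(cfg$cf_truth)[2]) / beta,
                               c2 = 1 / beta))
    if (cfg$cf_truth$form != "richards_log") truth$combined <- NULL
    attr(out, "truth") <- truth
    out
  })
}

#' Generate a 24-h style instrument time series
#'
#' Emulates a cooking test record at 10-second resolution: a flat baseline,
#' one or more cooking events that rise exponentially toward a peak during
#' the active-flame window and decay exponentially afterwards, and an RH
#' profile evaluated per tick. Used to demonstrate and test the log formats
#' and the `apply` stage; it is a statistical stand-in, not a combustion
#' model.
#'
#' @param duration_h record length in hours; ticks run from 0 to
#'   `duration_h` hours inclusive, so a 3-h record has 1081 points.
#' @param events list of `c(start_h, end_h)` active-flame windows (hours from
#'   record start); must not overlap.
#' @param baseline,peak baseline and within-event target PM (ug/m3).
#' @param rh_fun function of time in hours returning RH fractions
#'   (vectorised); values are clamped to \[0, 0.99\].
#' @param temp_c logger temperature, recycled.
#' @param rise_min,decay_min exponential time constants (minutes) of event
#'   rise and post-event decay.
#' @param noise_sigma optional multiplicative lognormal tick noise on PM.
#' @param seed RNG seed; required when `noise_sigma > 0`.
#' @param sample_id identifier attached to both series.
#' @param start POSIXct timestamp of the first tick.
#' @return list with elements `neph` (data frame `timestamp`, `pm_ugm3`) and
#'   `rh` (data frame `timestamp`, `temp_c`, `rh`).
#' @export
generate_timeseries <- function(duration_h, events = list(),
                                baseline = 50, peak = 20000,
                                rh_fun = function(h) rep(0.6, length(h)),
                                temp_c = 25, rise_min = 3, decay_min = 20,
                                noise_sigma = 0, seed = NULL,
                                sample_id = "TS1",
                                start = as.POSIXct("2014-03-01 10:00:00",
                                                   tz = "UTC")) {
  stopifnot(duration_h > 0, baseline >= 0, peak > baseline)
  if (length(events)) {
    ev <- do.call(rbind, lapply(events, function(e) {
      stopifnot(length(e) == 2, e[1] < e[2])
      e
    }))
    ev <- ev[order(ev[, 1]), , drop = FALSE]
    if (any(ev[-1, 1] < ev[-nrow(ev), 2])) {
      stop("cooking events must not overlap", call. = FALSE)
    }
  } else ev <- matrix(numeric(0), ncol = 2)

  t_s <- seq(0, round(duration_h * 3600), by = 10)
  hrs <- t_s / 3600
  pm <- rep(baseline, length(t_s))
  for (r in seq_len(nrow(ev))) {
    s <- ev[r, 1] * 3600; e <- ev[r, 2] * 3600
    amp <- peak - baseline
    in_ev <- t_s >= s & t_s <= e
    pm[in_ev] <- pm[in_ev] + amp * (1 - exp(-(t_s[in_ev] - s) / (rise_min * 60)))
    end_val <- amp * (1 - exp(-(e - s) / (rise_min * 60)))
    post <- t_s > e
    pm[post] <- pm[post] + end_val * exp(-(t_s[post] - e) / (decay_min * 60))
  }
  if (noise_sigma > 0) {
    pm <- with_seed(seed, pm * exp(stats::rnorm(length(pm), 0, noise_sigma)))
  }
  rh <- pmin(pmax(rh_fun(hrs), 0), 0.99)
  ts <- start + t_s
  neph <- data.frame(timestamp = ts, pm_ugm3 = pm)
  rhdf <- data.frame(timestamp = ts, temp_c = rep(temp_c, length(ts)), rh = rh)
  attr(neph, "sample_id") <- sample_id
  attr(rhdf, "sample_id") <- sample_id
  list(neph = neph, rh = rhdf)
}

#' Simulate co-location samples from a combined model
#'
#' The direct route for knot-recovery and oracle studies: nephelometric PM is
#' drawn log-uniformly over `neph_range`, RH uniformly over `rh_range`, and
#' the gravimetric response is the model expectation times lognormal noise.
#'
#' @param object a `combined_model`.
#' @param nsim number of replicate campaigns.
#' @param seed RNG seed (required).
#' @param n samples per campaign.
#' @param neph_range nephelometric range (ug/m3), log-uniform.
#' @param rh_range RH range (fractions), uniform.
#' @param noise_sigma log-scale noise SD (0 for noiseless).
#' @param ... unused.
#' @return for `nsim = 1` a co-location data frame; otherwise a list of them.
#' @export
simulate.combined_model <- function(object, nsim = 1, seed = NULL, n = 65,
                                    neph_range = c(600, 66000),
                                    rh_range = c(0.15, 0.95),
                                    noise_sigma = 0, ...) {
  out <- with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      neph <- exp(stats::runif(n, log(neph_range[1]), log(neph_range[2])))
      rh <- stats::runif(n, rh_range[1], rh_range[2])
      mu <- predict_combined_core(object, neph, rh)
      data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                 neph_pm = neph,
                 grav_pm = mu * exp(stats::rnorm(n, 0, noise_sigma)),
                 rh = rh, below_lod = FALSE, stringsAsFactors = FALSE)
    })
  })
  if (nsim == 1) out[[1]] else out
}
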