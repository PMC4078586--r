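#' Leave-one-out cross-validation on the original concentration scale
#'
#' Exhaustive LOO: each sample in turn is held out, the model is refit on the
#' remainder via `fit`, and the held-out sample is predicted via `predict`.
#' Squared errors are accumulated on the original ug/m3 scale (log-scale
#' models must exponentiate inside `predict`, as the package predict methods
#' do), and the RMSE is the square root of their mean.
#'
#' @param data co-location data frame; one fold per row.
#' @param fit function of one argument (the training data frame) returning a
#'   fitted model.
#' @param predict function `(model, test_row)` returning the original-scale
#'   prediction for the single held-out row.
#' @param response name of the observed column compared against predictions.
#' @param approach_id label stored in the result.
#' @return an object of class `cv_result`: `approach_id`, `n_folds`,
#'   `predictions`, `observed`, `rmse`.
#' @examples
#' s <- data.frame(neph_pm = exp(seq(7, 10, length.out = 10)))
#' s$grav_pm <- exp(2.5 + 0.72 * log(s$neph_pm))
#' loo_cv(s,
#'        fit = function(d) fit_gravimetric(d$neph_pm, d$grav_pm, "loglog"),
#'        predict = function(m, d) predict(m, d$neph_pm, range_warning = FALSE))
#' @export
loo_cv <- function(data, fit, predict, response = "grav_pm",
                   approach_id = "custom") {
  n <- nrow(data)
  if (n < 3L) stop("need at least 3 samples for leave-one-out CV", call. = FALSE)
  obs <- data[[response]]
  preds <- numeric(n)
  for (i in seq_len(n)) {
    m <- tryCatch(fit(data[-i, , drop = FALSE]), error = function(e) {
      stop(sprintf("CV fold %d failed to fit: %s", i, conditionMessage(e)),
           call. = FALSE)
    })
    preds[i] <- predict(m, data[i, , drop = FALSE])
  }
  cv_result(approach_id, preds, obs)
}

cv_result <- function(approach_id, predictions, observed) {
  structure(list(approach_id = approach_id,
                 n_folds = length(predictions),
                 predictions = predictions,
                 observed = observed,
                 rmse = sqrt(mean((predictions - observed)^2))),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("LOO-CV [%s]: %d folds, RMSE %.4g\n",
              x$approach_id, x$n_folds, x$rmse))
  invisible(x)
}

#' Sequential two-step cross-validation (humidity then gravimetric)
#'
#' Exhaustive LOO over the co-location samples where *both* stages are
#' retrained inside every fold: (1) the CF model is fit on the training
#' observed correction factors (unless a fixed published model is supplied);
#' (2) the training nephelometer readings are humidity-adjusted with it;
#' (3) the gravimetric conversion is fit on the adjusted training pairs;
#' (4) the held-out reading is passed sequentially through both fold models.
#' RMSE is on the original ug/m3 scale.
#'
#' @param samples co-location data frame (`neph_pm`, `grav_pm`, `rh`).
#' @param cf_form CF family to refit per fold (ignored when `cf_fixed` is
#'   given).
#' @param use_threshold apply the 60% RH threshold when adjusting.
#' @param grav_form gravimetric conversion form, see [fit_gravimetric()].
#' @param cf_fixed optional fixed `cf_model` (e.g. `cf_preset("1a")`) used in
#'   every fold instead of refitting.
#' @param spline_grid knot grid for the spline conversion form.
#' @param approach_id label stored in the result.
#' @return a `cv_result`.
#' @export
two_step_cv <- function(samples, cf_form = "richards_log",
                        use_threshold = FALSE, grav_form = "loglog",
                        cf_fixed = NULL, spline_grid = seq(7.5, 12, by = 0.1),
                        approach_id = NULL) {
  n <- nrow(samples)
  if (n < 4L) stop("need at least 4 samples for two-step CV", call. = FALSE)
  if (is.null(approach_id)) {
    approach_id <- sprintf("%s+%s (%s threshold)",
                           if (is.null(cf_fixed)) cf_form else "fixed-cf",
                           grav_form, if (use_threshold) "with" else "no")
  }
  obs <- samples$grav_pm
  preds <- numeric(n)
  for (i in seq_len(n)) {
    train <- samples[-i, , drop = FALSE]
    test <- samples[i, , drop = FALSE]
    m_cf <- if (is.null(cf_fixed)) {
      suppressMessages(fit_cf(observed_cf(train), cf_form))
    } else cf_fixed
    han_tr <- adjust_pm(train$neph_pm, train$rh, m_cf,
                        use_threshold = use_threshold)
    m_g <- fit_gravimetric(han_tr, train$grav_pm, grav_form,
                           spline_grid = spline_grid)
    han_te <- adjust_pm(test$neph_pm, test$rh, m_cf,
                        use_threshold = use_threshold)
    preds[i] <- predict(m_g, han_te, range_warning = FALSE)
  }
  cv_result(approach_id, preds, obs)
}

#' Cross-validated comparison of all 21 adjustment approaches
#'
#' Enumerates the full candidate set: 3 one-step combined models (log-linear,
#' spline, quadratic — refit on the data) plus the 18 two-step combinations
#' of humidity equation \{1a fixed-published, 1b refit, 2a refit\} x \{with,
#' without 60% RH threshold\} x conversion \{log-log, log-log spline, log-log
#' quadratic\} (the through-origin linear conversions are excluded as
#' dominated). Every row reports the exhaustive LOO-CV RMSE on the original
#' scale. Approach numbering: 1-3 combined; 4-12 without threshold
#' (conversion-major, humidity 1a/1b/2a within); 13-21 the same with the
#' threshold.
#'
#' @param samples co-location data frame; below-LOD rows are excluded by
#'   default.
#' @param spline_grid knot grid shared by the spline forms.
#' @param approaches optional integer subset of approach numbers 1-21.
#' @param include_below_lod keep below-LOD samples.
#' @return a data frame of class `neph_comparison` with columns `approach`,
#'   `label`, `type`, `humidity`, `threshold`, `conversion`, `n_folds`,
#'   `cv_rmse`; per-approach predictions are stored in attribute
#'   `"cv_results"`.
#' @export
comparison_table <- function(samples, spline_grid = seq(7.5, 12, by = 0.1),
                             approaches = NULL, include_below_lod = FALSE) {
  below <- samples$below_lod %||% rep(FALSE, nrow(samples))
  if (!include_below_lod && any(below)) {
    message(sprintf("comparison_table: excluded %d below-LOD sample(s)",
                    sum(below)))
    samples <- samples[!below, , drop = FALSE]
  }
  if (nrow(samples) < 6L) stop("need at least 6 usable samples", call. = FALSE)

  defs <- comparison_defs()
  if (!is.null(approaches)) {
    if (!all(approaches %in% defs$approach)) {
      stop("`approaches` must be a subset of 1..21", call. = FALSE)
    }
    defs <- defs[defs$approach %in% approaches, , drop = FALSE]
  }

  results <- vector("list", nrow(defs))
  rmse <- rep(NA_real_, nrow(defs))
  nf <- rep(NA_integer_, nrow(defs))
  note <- rep("", nrow(defs))
  for (k in seq_len(nrow(defs))) {
    dk <- defs[k, ]
    res <- tryCatch({
      if (dk$type == "combined") {
        loo_cv(samples,
               fit = function(d) fit_combined(d, dk$conversion,
                                              spline_grid = spline_grid),
               predict = function(m, d) predict_combined_core(m, d$neph_pm, d$rh),
               approach_id = dk$label)
      } else {
        two_step_cv(samples,
                    cf_form = if (dk$humidity == "2a") "richards_log" else "chakrabarti",
                    use_threshold = dk$threshold,
                    grav_form = dk$conversion,
                    cf_fixed = if (dk$humidity == "1a") cf_preset("1a") else NULL,
                    spline_grid = spline_grid,
                    approach_id = dk$label)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      note[k] <- conditionMessage(res)
    } else {
      results[[k]] <- res
      rmse[k] <- res$rmse
      nf[k] <- res$n_folds
    }
  }
  out <- cbind(defs, n_folds = nf, cv_rmse = rmse,
               note = note, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cv_results") <- results
  class(out) <- c("neph_comparison", "data.frame")
  out
}

# The fixed 21-approach enumeration (stable numbering).
comparison_defs <- function() {
  combined <- data.frame(
    approach = 1:3,
    label = c("Combined (log-linear)", "Combined (spline)",
              "Combined (quadratic)"),
    type = "combined", humidity = NA_character_, threshold = NA,
    conversion = c("loglinear", "loglinear_spline", "loglinear_quadratic"),
    stringsAsFactors = FALSE)
  hum <- c("1a", "1b", "2a")
  conv <- c("loglog", "loglog_spline", "loglog_quadratic")
  conv_lab <- c("log-log", "log-log spline", "log-log quadratic")
  rows <- list()
  k <- 4L
  for (thr in c(FALSE, TRUE)) {
    for (j in seq_along(conv)) {
      for (h in hum) {
        rows[[length(rows) + 1L]] <- data.frame(
          approach = k,
          label = sprintf("%s (%s threshold) + %s", h,
                          if (thr) "with" else "no", conv_lab[j]),
          type = "two_step", humidity = h, threshold = thr,
          conversion = conv[j], stringsAsFactors = FALSE)
        k <- k + 1L
      }
    }
  }
  rbind(combined, do.call(rbind, rows))
}

#' @export
print.neph_comparison <- function(x, ...) {
  df <- as.data.frame(x)[, c("approach", "label", "n_folds", "cv_rmse")]
  df$cv_rmse <- signif(df$cv_rmse, 5)
  print(df, row.names = FALSE)
  ok <- which(is.finite(x$cv_rmse))
  if (length(ok)) {
    best <- ok[which.min(x$cv_rmse[ok])]
    cat(sprintf("\nLowest CV RMSE: approach %d (%s), %.4g ug/m3\n",
                x$approach[best], x$label[best], x$cv_rmse[best]))
  }
  invisible(x)
}
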