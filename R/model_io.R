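#' Write or read a model file (JSON)
#'
#' All three model classes serialise to a small JSON object carrying the
#' class, form, parameters and provenance, so fitted or preset models can be
#' shipped between the `fit` and `apply` stages of the pipeline. Confidence
#' intervals and CV RMSEs are included when available; the underlying `lm`
#' fit is not serialised.
#'
#' @param model a `cf_model`, `grav_model` or `combined_model`.
#' @param path JSON file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the reconstructed model object.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, c("cf_model", "grav_model", "combined_model")))
  out <- list(class = class(model)[1], form = model$form,
              provenance = model$provenance %||% "fitted")
  pars <- switch(class(model)[1],
    cf_model = list(a = model$a, b = model$b,
                    rh_threshold = model$rh_threshold,
                    cv_rmse = model$cv_rmse),
    grav_model = list(a = model$a, b = model$b, c = model$c, d = model$d,
                      cv_rmse = model$cv_rmse),
    combined_model = list(c0 = model$c0, c1 = model$c1, c2 = model$c2,
                          c3 = model$c3, knot = model$knot,
                          cv_rmse = model$cv_rmse))
  out <- c(out, pars[!vapply(pars, is.null, logical(1))])
  if (!is.null(model$ci)) {
    out$ci <- list(parameter = rownames(model$ci),
                   lower = unname(model$ci[, 1]),
                   upper = unname(model$ci[, 2]))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$class)) stop("not a model file: ", path, call. = FALSE)
  num <- function(v) if (is.null(v)) NULL else as.numeric(v)
  ci <- NULL
  if (!is.null(x$ci)) {
    ci <- cbind(lower = as.numeric(x$ci$lower), upper = as.numeric(x$ci$upper))
    rownames(ci) <- x$ci$parameter
  }
  m <- switch(x$class,
    cf_model = {
      g <- cf_model(x$form, a = num(x$a), b = num(x$b),
                    rh_threshold = num(x$rh_threshold) %||% 0.60,
                    provenance = x$provenance, ci = ci)
      g$cv_rmse <- num(x$cv_rmse) %||% NA_real_
      g
    },
    grav_model = {
      g <- grav_model(x$form, a = num(x$a) %||% 0, b = num(x$b),
                      c = num(x$c), d = num(x$d),
                      cv_rmse = num(x$cv_rmse) %||% NA_real_,
                      provenance = x$provenance)
      g$ci <- ci
      g
    },
    combined_model = {
      g <- combined_model(x$form, c0 = num(x$c0), c1 = num(x$c1),
                          c2 = num(x$c2), c3 = num(x$c3),
                          knot = num(x$knot), provenance = x$provenance)
      g$cv_rmse <- num(x$cv_rmse) %||% NA_real_
      g$ci <- ci
      g
    },
    stop("unknown model class in ", path, ": ", x$class, call. = FALSE))
  m
}
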