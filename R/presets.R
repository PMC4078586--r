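#' Published humidity correction-factor parameter sets
#'
#' Three named parameterisations are shipped:
#'
#' * `"1a"` — the original ambient-PM chakrabarti form, `a = 1`, `b = 0.25`
#'   (no confidence intervals were published).
#' * `"1b"` — the chakrabarti form refit to cookstove co-location data,
#'   `a = 0.72 (0.65, 0.79)`, `b = 0.38 (0.33, 0.44)`.
#' * `"2a"` — the log-linear (richards) form refit to the same data,
#'   `a = -0.72 (-0.82, -0.62)`, `b = -0.82 (-0.93, -0.71)`.
#'
#' @param id preset identifier.
#' @return a `cf_model` with `provenance = "published"`.
#' @export
cf_preset <- function(id = c("1a", "1b", "2a")) {
  id <- match.arg(id)
  switch(id,
    "1a" = cf_model("chakrabarti", a = 1, b = 0.25),
    "1b" = cf_model("chakrabarti", a = 0.72, b = 0.38,
                    ci = matrix(c(0.65, 0.79, 0.33, 0.44), 2, byrow = TRUE,
                                dimnames = list(c("a", "b"), c("lo", "hi")))),
    "2a" = cf_model("richards_log", a = -0.72, b = -0.82,
                    ci = matrix(c(-0.82, -0.62, -0.93, -0.71), 2, byrow = TRUE,
                                dimnames = list(c("a", "b"), c("lo", "hi")))))
}

# Published gravimetric-conversion parameter grid: 4 forms x 3 humidity
# equations x with/without the 60% RH threshold (24 sets). Column order within
# each threshold block: humidity equations 1a, 1b, 2a. The spline c for
# (1a, with threshold) is shipped exactly as printed (-4.051) although it is
# an order of magnitude away from its column neighbours; treat it with care.
.grav_preset_table <- local({
  g <- expand.grid(humidity = c("1a", "1b", "2a"),
                   threshold = c(TRUE, FALSE),
                   stringsAsFactors = FALSE)
  rbind(
    data.frame(form = "linear_origin", g,
               a = 0,
               b = c(0.848, 0.845, 0.831, 0.892, 0.757, 0.696),
               c = NA_real_, d = NA_real_,
               cv_rmse = c(3927, 4002, 4005, 3956, 3982, 3955)),
    data.frame(form = "loglog", g,
               a = c(2.726, 2.750, 2.753, 2.723, 2.510, 2.395),
               b = c(0.711, 0.707, 0.706, 0.715, 0.724, 0.730),
               c = NA_real_, d = NA_real_,
               cv_rmse = c(2889, 2977, 2969, 2932, 3001, 2990)),
    data.frame(form = "loglog_spline", g,
               a = c(0.859, 0.872, 0.822, 0.565, 0.921, 0.868),
               b = c(0.949, 0.948, 0.953, 0.995, 0.921, 0.917),
               c = c(-4.051, -0.411, -0.416, -0.430, -0.471, -0.502),
               d = c(8.4, 8.4, 8.4, 8.2, 8.9, 9.1),
               cv_rmse = c(2703, 2768, 2773, 2742, 2650, 2620)),
    data.frame(form = "loglog_quadratic", g,
               a = c(-4.867, -4.945, -4.951, -4.994, -6.049, -6.607),
               b = c(2.502, 2.527, 2.522, 2.544, 2.722, 2.809),
               c = c(-0.105, -0.106, -0.106, -0.107, -0.115, -0.119),
               d = NA_real_,
               cv_rmse = c(2682, 2750, 2759, 2715, 2652, 2619)))
})

#' Published gravimetric-conversion parameter sets
#'
#' `grav_preset_table()` returns all 24 published parameter sets (4
#' conversion forms x 3 humidity equations x threshold on/off) with their
#' cross-validated RMSEs (ug/m3). `grav_preset()` picks one as a
#' `grav_model`.
#'
#' @param humidity humidity equation the HAN PM was produced with
#'   (`"1a"`, `"1b"`, `"2a"`).
#' @param threshold whether the 60% RH threshold was applied during humidity
#'   adjustment.
#' @param form conversion form.
#' @return `grav_preset_table()`: a data frame; `grav_preset()`: a
#'   `grav_model` with `provenance = "published"`.
#' @export
grav_preset_table <- function() .grav_preset_table

#' @rdname grav_preset_table
#' @export
grav_preset <- function(humidity = c("1a", "1b", "2a"), threshold = FALSE,
                        form = c("loglog", "linear_origin", "loglog_spline",
                                 "loglog_quadratic")) {
  humidity <- match.arg(humidity)
  form <- match.arg(form)
  tab <- .grav_preset_table
  row <- tab[tab$form == form & tab$humidity == humidity &
               tab$threshold == threshold, ]
  stopifnot(nrow(row) == 1L)
  m <- grav_model(form, a = row$a, b = row$b,
                  c = if (is.na(row$c)) NULL else row$c,
                  d = if (is.na(row$d)) NULL else row$d,
                  cv_rmse = row$cv_rmse, provenance = "published")
  m
}

#' Published combined adjustment models
#'
#' * `"eq7"` — the full log-linear combined model
#'   `ln(Grav) = 3.102 + 0.701 ln(1 - RH) + 0.717 ln(Neph PM)`.
#' * `"eq8"` — the spline variant; only the knot (8.1 on the `ln(Neph PM)`
#'   scale) and hinge coefficient (-0.254) were published, so the remaining
#'   coefficients are `NA` and the preset must be refit on data before it can
#'   predict.
#'
#' @param id preset identifier.
#' @return a `combined_model` with `provenance = "published"`.
#' @export
combined_preset <- function(id = c("eq7", "eq8")) {
  id <- match.arg(id)
  switch(id,
    eq7 = combined_model("loglinear", c0 = 3.102, c1 = 0.701, c2 = 0.717),
    eq8 = combined_model("loglinear_spline", c0 = NA_real_, c1 = NA_real_,
                         c2 = NA_real_, c3 = -0.254, knot = 8.1))
}
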