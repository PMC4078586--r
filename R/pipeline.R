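#' Pipeline configuration
#'
#' One configuration object drives the four pipeline commands
#' ([cmd_simulate()], [cmd_fit()], [cmd_crossval()], [cmd_apply()]). Defaults
#' can be overridden from a YAML file and/or named arguments (arguments win).
#' Unknown keys are an error naming the offending key. Every command writes a
#' provenance block (`run_info.txt`: config hash, package version, seed,
#' timestamp) to the output directory; timestamps appear only there, so data
#' outputs are byte-stable under a fixed seed.
#'
#' @param file optional YAML config path.
#' @param ... named overrides of the defaults listed below.
#' @return a list of class `pipeline_config`.
#' @section Keys:
#' `out_dir` (output directory), `seed`, `n_samples`, `noise_sigma`,
#' `threshold` (use the 60% RH threshold in two-step stages), `cf_form`,
#' `grav_form`, `combined_form`, `spline_grid` (`c(from, to, by)`),
#' `approaches` (integer subset for crossval), `campaign` (campaign CSV
#' path), `model` (model JSON path for apply), `neph_log`, `rh_log`,
#' `tolerance` (alignment, seconds), `n_logs` (instrument logs written by
#' simulate), `preset` (published preset id for fit's preset mode).
#' @export
pipeline_config <- function(file = NULL, ...) {
  defaults <- list(out_dir = ".", seed = 1L, n_samples = 65,
                   noise_sigma = 0.3, threshold = FALSE,
                   cf_form = "richards_log", grav_form = "loglog_spline",
                   combined_form = "loglinear_spline",
                   spline_grid = c(7.5, 12, 0.1), approaches = NULL,
                   campaign = "campaign.csv", model = NULL,
                   neph_log = NULL, rh_log = NULL, tolerance = 5,
                   n_logs = 3, preset = NULL)
  cfg <- defaults
  apply_over <- function(cfg, over, src) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) {
      stop(sprintf("unknown configuration key `%s` (%s)", bad[1], src),
           call. = FALSE)
    }
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    if (!is.list(y)) stop("config file is not a YAML mapping: ", file,
                          call. = FALSE)
    cfg <- apply_over(cfg, y, file)
  }
  over <- list(...)
  over <- over[!vapply(over, is.null, logical(1))]
  if (length(over)) cfg <- apply_over(cfg, over, "argument")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

spline_grid_of <- function(cfg) {
  g <- cfg$spline_grid
  if (length(g) == 3 && g[2] > g[1]) seq(g[1], g[2], by = g[3]) else as.numeric(g)
}

as_config <- function(config) {
  if (inherits(config, "pipeline_config")) config
  else do.call(pipeline_config, as.list(config))
}

write_run_info <- function(cfg, command) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  hash <- unname(tools::md5sum(tmp))
  lines <- c(sprintf("command: %s", command),
             sprintf("nephqc version: %s", as.character(utils::packageVersion("nephqc"))),
             sprintf("seed: %d", cfg$seed),
             sprintf("config md5: %s", hash),
             sprintf("run at: %s", format(Sys.time(), tz = "UTC")))
  writeLines(lines, file.path(cfg$out_dir, "run_info.txt"))
}

#' Simulate a campaign and write it in the documented formats
#'
#' Writes the co-location table CSV (`campaign` key) and, for the first
#' `n_logs` samples, paired nephelometer and T/RH instrument logs whose
#' active-flame window reproduces the sample's window-average reading.
#'
#' @param config a [pipeline_config()] (or list/YAML path coercible to one).
#' @return invisibly, a list of written paths.
#' @export
cmd_simulate <- function(config = pipeline_config()) {
  cfg <- as_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  camp <- generate_campaign(campaign_config(n_samples = cfg$n_samples,
                                            noise_sigma = cfg$noise_sigma,
                                            seed = cfg$seed))
  camp_path <- file.path(cfg$out_dir, cfg$campaign)
  write_campaign(camp, camp_path)
  paths <- list(campaign = camp_path, logs = character(0))
  n_logs <- min(cfg$n_logs, nrow(camp))
  for (i in seq_len(n_logs)) {
    ts <- generate_timeseries(duration_h = 3,
                              events = list(c(0.5, 1.0)),
                              baseline = 50, peak = 1.2 * camp$neph_pm[i],
                              rh_fun = function(h) rep(camp$rh[i], length(h)),
                              noise_sigma = 0.1,
                              seed = cfg$seed + i,
                              sample_id = camp$sample_id[i])
    np <- file.path(cfg$out_dir, sprintf("%s_neph.csv", camp$sample_id[i]))
    rp <- file.path(cfg$out_dir, sprintf("%s_rh.csv", camp$sample_id[i]))
    write_neph_log(ts$neph, np)
    write_rh_log(ts$rh, rp)
    paths$logs <- c(paths$logs, np, rp)
  }
  write_run_info(cfg, "simulate")
  message(sprintf("cmd_simulate: wrote %d-sample campaign to %s",
                  nrow(camp), camp_path))
  invisible(paths)
}

#' Fit CF, gravimetric and combined models and write model files
#'
#' Reads the campaign table, drops below-LOD samples (an error if fewer than
#' 4 usable remain), fits both CF families, all four gravimetric conversion
#' forms (on HAN PM produced by the configured CF form and threshold rule)
#' and all three combined forms, and writes one JSON model file per fit to
#' `out_dir/models/`, each with confidence intervals and its LOO-CV RMSE.
#' When `preset` is set (e.g. `"eq7"`), fitting is skipped and the published
#' preset is copied to a model file instead.
#'
#' @inheritParams cmd_simulate
#' @return invisibly, named list of model file paths.
#' @export
cmd_fit <- function(config = pipeline_config()) {
  cfg <- as_config(config)
  dir.create(file.path(cfg$out_dir, "models"), recursive = TRUE,
             showWarnings = FALSE)
  if (!is.null(cfg$preset)) {
    m <- combined_preset(cfg$preset)
    path <- file.path(cfg$out_dir, "models",
                      sprintf("combined_%s.json", cfg$preset))
    write_model(m, path)
    write_run_info(cfg, "fit")
    message("cmd_fit: copied published preset ", cfg$preset)
    return(invisible(list(preset = path)))
  }
  camp <- read_campaign(file.path(cfg$out_dir, cfg$campaign))
  usable <- !camp$below_lod
  if (sum(usable) < 4L) stop("fewer than 4 usable (above-LOD) samples",
                             call. = FALSE)
  camp <- camp[usable, , drop = FALSE]
  grid <- spline_grid_of(cfg)
  obs <- observed_cf(camp)
  paths <- list()

  for (form in c("chakrabarti", "richards_log")) {
    m <- fit_cf(obs, form)
    # CF-model CV RMSE is on the dimensionless CF scale
    cvr <- loo_cv(obs,
                  fit = function(d) fit_cf(d, form),
                  predict = function(mm, d) predict(mm, d$rh),
                  response = "cf", approach_id = form)$rmse
    m$cv_rmse <- cvr
    p <- file.path(cfg$out_dir, "models", sprintf("cf_%s.json", form))
    write_model(m, p)
    paths[[paste0("cf_", form)]] <- p
  }

  m_cf <- fit_cf(obs, cfg$cf_form)
  han <- adjust_pm(camp$neph_pm, camp$rh, m_cf, use_threshold = cfg$threshold)
  for (form in c("linear_origin", "loglog", "loglog_spline",
                 "loglog_quadratic")) {
    m <- fit_gravimetric(han, camp$grav_pm, form, spline_grid = grid)
    d2 <- cbind(camp, han = han)
    m$cv_rmse <- loo_cv(d2,
                        fit = function(d) fit_gravimetric(d$han, d$grav_pm,
                                                          form, spline_grid = grid),
                        predict = function(mm, d) predict(mm, d$han,
                                                          range_warning = FALSE))$rmse
    p <- file.path(cfg$out_dir, "models", sprintf("grav_%s.json", form))
    write_model(m, p)
    paths[[paste0("grav_", form)]] <- p
  }

  for (form in c("loglinear", "loglinear_spline", "loglinear_quadratic")) {
    m <- fit_combined(camp, form, spline_grid = grid)
    m$cv_rmse <- loo_cv(camp,
                        fit = function(d) fit_combined(d, form, spline_grid = grid),
                        predict = function(mm, d) predict_combined_core(mm, d$neph_pm, d$rh))$rmse
    p <- file.path(cfg$out_dir, "models", sprintf("combined_%s.json", form))
    write_model(m, p)
    paths[[paste0("combined_", form)]] <- p
  }
  write_run_info(cfg, "fit")
  message(sprintf("cmd_fit: wrote %d model files to %s",
                  length(paths), file.path(cfg$out_dir, "models")))
  invisible(paths)
}

#' Run the 21-approach cross-validated comparison
#'
#' Reads the campaign, runs [comparison_table()] (optionally restricted via
#' the `approaches` key), writes `comparison.csv` to the output directory and
#' prints a summary line naming the minimum-RMSE approach.
#'
#' @inheritParams cmd_simulate
#' @return invisibly, the comparison data frame.
#' @export
cmd_crossval <- function(config = pipeline_config()) {
  cfg <- as_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  camp <- read_campaign(file.path(cfg$out_dir, cfg$campaign))
  tab <- comparison_table(camp, spline_grid = spline_grid_of(cfg),
                          approaches = cfg$approaches)
  out <- as.data.frame(tab)
  out$cv_rmse <- fmt_num(out$cv_rmse)
  utils::write.csv(out, file.path(cfg$out_dir, "comparison.csv"),
                   row.names = FALSE)
  write_run_info(cfg, "crossval")
  ok <- which(is.finite(tab$cv_rmse))
  best <- ok[which.min(tab$cv_rmse[ok])]
  message(sprintf("cmd_crossval: lowest CV RMSE is approach %d (%s), %.4g ug/m3",
                  tab$approach[best], tab$label[best], tab$cv_rmse[best]))
  invisible(tab)
}

#' Apply a model file to aligned instrument logs
#'
#' Reads a nephelometer log and a T/RH log, aligns them, applies the model
#' from the `model` JSON (a `cf_model` adds a humidity-adjusted
#' `han_pm_ugm3` column; a `combined_model` adds a gravimetric-equivalent
#' `pm25_graveq_ugm3` column) and writes `adjusted.csv` plus a per-file
#' summary: mean, max, and the percentage of ticks outside the 600-66,000
#' ug/m3 applicability range.
#'
#' @inheritParams cmd_simulate
#' @return invisibly, a list with the adjusted data frame and the summary.
#' @export
cmd_apply <- function(config = pipeline_config()) {
  cfg <- as_config(config)
  if (is.null(cfg$model) || is.null(cfg$neph_log) || is.null(cfg$rh_log)) {
    stop("cmd_apply needs `model`, `neph_log` and `rh_log` paths", call. = FALSE)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  neph <- read_neph_log(cfg$neph_log)
  rh <- read_rh_log(cfg$rh_log)
  aligned <- align_series(neph, rh, tolerance = cfg$tolerance)
  m <- read_model(cfg$model)
  if (inherits(m, "cf_model")) {
    aligned$han_pm_ugm3 <- adjust_pm(aligned$pm_ugm3, aligned$rh, m,
                                     use_threshold = cfg$threshold)
    adj_col <- "han_pm_ugm3"
  } else if (inherits(m, "combined_model")) {
    aligned$pm25_graveq_ugm3 <- predict(m, aligned$pm_ugm3, aligned$rh,
                                        range_warning = FALSE)
    adj_col <- "pm25_graveq_ugm3"
  } else {
    stop("`model` must be a cf_model or combined_model file for apply",
         call. = FALSE)
  }
  pct_out <- 100 * mean(aligned$pm_ugm3 < .neph_range[1] |
                          aligned$pm_ugm3 > .neph_range[2])
  smry <- list(n_ticks = nrow(aligned),
               mean_adjusted = mean(aligned[[adj_col]]),
               max_adjusted = max(aligned[[adj_col]]),
               pct_outside_range = pct_out)
  out <- aligned
  for (col in setdiff(names(out), "timestamp")) out[[col]] <- fmt_num(out[[col]])
  out$timestamp <- format_iso_time(out$timestamp)
  utils::write.csv(out, file.path(cfg$out_dir, "adjusted.csv"),
                   row.names = FALSE, quote = FALSE)
  write_run_info(cfg, "apply")
  message(sprintf(
    "cmd_apply: %d ticks; mean %s %.4g, max %.4g ug/m3; %.1f%% of raw ticks outside the %g-%g ug/m3 range",
    smry$n_ticks, adj_col, smry$mean_adjusted, smry$max_adjusted,
    smry$pct_outside_range, .neph_range[1], .neph_range[2]))
  invisible(list(adjusted = aligned, summary = smry))
}
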