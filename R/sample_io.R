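#' Read a nephelometer log file
#'
#' Parses an instrument log in the documented CSV dialect: header
#' `timestamp,pm_ugm3`, ISO-8601 timestamps (`YYYY-MM-DDTHH:MM:SS`, UTC), one
#' row per nominal 10-second tick. Rows whose PM cell is blank or non-numeric
#' are dropped with a message giving the count.
#'
#' @param path path to the log CSV.
#' @param sample_id identifier attached to the returned series.
#' @return a data frame of class `neph_ts` with columns `timestamp`
#'   (POSIXct, strictly increasing) and `pm_ugm3` (ug/m3), and attribute
#'   `sample_id`.
#' @seealso [read_rh_log()], [align_series()], [write_neph_log()]
#' @export
read_neph_log <- function(path, sample_id = basename(path)) {
  header <- check_log_header(path, c("timestamp", "pm_ugm3"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  ts <- parse_iso_time(df$timestamp)
  pm <- suppressWarnings(as.numeric(df$pm_ugm3))
  drop <- is.na(ts) | is.na(pm) | !is.finite(pm)
  if (any(drop)) {
    message(sprintf("read_neph_log: dropped %d row(s) with missing/non-numeric values",
                    sum(drop)))
  }
  ts <- ts[!drop]; pm <- pm[!drop]
  if (length(pm) == 0L) stop("empty nephelometer series in ", path, call. = FALSE)
  check_increasing(ts, path)
  out <- data.frame(timestamp = ts, pm_ugm3 = pm)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("neph_ts", "data.frame")
  out
}

#' Read a temperature/relative-humidity logger file
#'
#' Parses a T/RH log with header `timestamp,temp_c,rh`. The RH unit is
#' auto-detected: any value greater than 1.5 means the column is in percent
#' (0-100) and is divided by 100; otherwise it is taken as a fraction. A
#' column named `rh_pct` whose values never exceed 1.5 is ambiguous and is a
#' format error. After conversion, values are clamped to \[0, 0.99\] (the cap
#' guards the `1 - RH` singularity used downstream) with a message giving the
#' clamp count.
#'
#' @inheritParams read_neph_log
#' @return a data frame of class `rh_ts` with columns `timestamp`, `temp_c`
#'   and `rh` (fraction in \[0, 0.99\]), and attribute `sample_id`.
#' @export
read_rh_log <- function(path, sample_id = basename(path)) {
  header <- check_log_header(path, c("timestamp", "temp_c", c("rh")),
                             allow_alt = list(rh = "rh_pct"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  rh_col <- if ("rh" %in% names(df)) "rh" else "rh_pct"
  ts <- parse_iso_time(df$timestamp)
  rh <- suppressWarnings(as.numeric(df[[rh_col]]))
  temp <- suppressWarnings(as.numeric(df$temp_c))
  drop <- is.na(ts) | is.na(rh)
  if (any(drop)) {
    message(sprintf("read_rh_log: dropped %d row(s) with missing values", sum(drop)))
  }
  ts <- ts[!drop]; rh <- rh[!drop]; temp <- temp[!drop]
  if (length(rh) == 0L) stop("empty RH series in ", path, call. = FALSE)
  vmax <- max(rh)
  if (vmax > 1.5) {
    rh <- rh / 100
  } else if (rh_col == "rh_pct") {
    stop("ambiguous RH units in ", path,
         ": header says percent (`rh_pct`) but no value exceeds 1.5",
         call. = FALSE)
  }
  n_clamp <- sum(rh > 0.99 | rh < 0)
  if (n_clamp > 0L) {
    message(sprintf("read_rh_log: clamped %d RH value(s) into [0, 0.99]", n_clamp))
  }
  rh <- pmin(pmax(rh, 0), 0.99)
  check_increasing(ts, path)
  out <- data.frame(timestamp = ts, temp_c = temp, rh = rh)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("rh_ts", "data.frame")
  out
}

#' Align nephelometer and RH time series
#'
#' Nearest-timestamp join: each nephelometer tick is matched to the closest RH
#' tick within `tolerance` seconds (default 5 s, half the nominal 10-s logging
#' interval). Unmatched rows are dropped with a message; zero matches is an
#' error.
#'
#' @param neph a `neph_ts` (or data frame with `timestamp`, `pm_ugm3`).
#' @param rh a `rh_ts` (or data frame with `timestamp`, `rh`, optionally
#'   `temp_c`).
#' @param tolerance maximum timestamp mismatch, in seconds.
#' @return data frame with columns `timestamp`, `pm_ugm3`, `rh` (and `temp_c`
#'   when present in `rh`).
#' @export
align_series <- function(neph, rh, tolerance = 5) {
  if (nrow(neph) == 0L || nrow(rh) == 0L) stop("both series must be non-empty",
                                               call. = FALSE)
  tn <- as.numeric(neph$timestamp)
  tr <- as.numeric(rh$timestamp)
  idx <- findInterval(tn, tr)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(tr))
  d_lo <- abs(tn - tr[lo])
  d_hi <- abs(tn - tr[hi])
  pick <- ifelse(d_hi < d_lo, hi, lo)
  dist <- pmin(d_lo, d_hi)
  keep <- dist <= tolerance
  if (!any(keep)) {
    stop(sprintf("alignment failed: no RH reading within %g s of any PM reading",
                 tolerance), call. = FALSE)
  }
  if (any(!keep)) {
    message(sprintf("align_series: dropped %d PM row(s) with no RH match within %g s",
                    sum(!keep), tolerance))
  }
  out <- data.frame(timestamp = neph$timestamp[keep],
                    pm_ugm3 = neph$pm_ugm3[keep],
                    rh = rh$rh[pick[keep]])
  if (!is.null(rh$temp_c)) out$temp_c <- rh$temp_c[pick[keep]]
  out
}

#' Average an aligned series over a sampling window
#'
#' Arithmetic means of PM and RH over rows with `start <= t <= end` (both ends
#' inclusive). In co-location work the window is the active-flame gravimetric
#' sampling period; the pre-ignition and smoulder/decay segments are excluded
#' from calibration.
#'
#' @param aligned output of [align_series()].
#' @param start,end window bounds (POSIXct or anything comparable to the
#'   `timestamp` column).
#' @return list with `mean_pm` (ug/m3), `mean_rh` (fraction), `n_points`.
#' @export
window_average <- function(aligned, start, end) {
  if (!(start < end)) stop("`start` must precede `end`", call. = FALSE)
  in_win <- aligned$timestamp >= start & aligned$timestamp <= end
  if (!any(in_win)) stop("no data points inside the averaging window", call. = FALSE)
  list(mean_pm = mean(aligned$pm_ugm3[in_win]),
       mean_rh = mean(aligned$rh[in_win]),
       n_points = sum(in_win))
}

#' Gravimetric concentration from filter weights
#'
#' Net collected mass is `post - pre - blank` (blank correction 2 ug by
#' default); sampled air volume is `flow * duration / 1000` m3 (4 L/min
#' default). A sample is below the limit of detection when its net mass is
#' under `lod_ug` (5 ug default). A negative net mass is truncated to zero
#' concentration and flagged below-LOD.
#'
#' @param filters data frame with columns `pre_ug`, `post_ug` and optionally
#'   `blank_ug`, `flow_lpm`, `duration_min`, `lod_ug`, `filter_id` (see
#'   [read_filter_records()]), or a list/one-row data frame for a single
#'   filter.
#' @param blank_ug,flow_lpm,lod_ug defaults used where the record lacks the
#'   column.
#' @return data frame with `filter_id`, `net_ug`, `volume_m3`, `conc_ugm3`,
#'   `below_lod`.
#' @export
gravimetric_concentration <- function(filters, blank_ug = 2, flow_lpm = 4,
                                      lod_ug = 5) {
  f <- as.data.frame(filters, stringsAsFactors = FALSE)
  need <- c("pre_ug", "post_ug", "duration_min")
  miss <- setdiff(need, names(f))
  if (length(miss)) stop("filter records lack column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  blank <- f$blank_ug %||% rep(blank_ug, nrow(f))
  flow <- f$flow_lpm %||% rep(flow_lpm, nrow(f))
  lod <- f$lod_ug %||% rep(lod_ug, nrow(f))
  if (any(flow <= 0) || any(f$duration_min <= 0)) {
    stop("flow rate and duration must be positive", call. = FALSE)
  }
  net <- f$post_ug - f$pre_ug - blank
  vol <- flow * f$duration_min / 1000   # L -> m3
  below <- net < lod
  neg <- net < 0
  if (any(neg)) {
    warning(sprintf("%d filter(s) with negative net mass; concentration set to 0 and flagged below LOD",
                    sum(neg)), call. = FALSE)
  }
  conc <- ifelse(neg, 0, net / vol)
  data.frame(filter_id = f$filter_id %||% paste0("F", seq_len(nrow(f))),
             net_ug = net, volume_m3 = vol, conc_ugm3 = conc,
             below_lod = below)
}

#' Duplicate-sample precision
#'
#' For each co-located duplicate pair, precision is the paired relative
#' difference `|x1 - x2| / mean(x1, x2) * 100` (percent). Returns the mean of
#' the per-pair precisions and their standard deviation ("relative SD").
#'
#' @param x1,x2 numeric vectors of paired concentrations (ug/m3), all > 0.
#' @return list with `mean_precision_pct`, `relative_sd_pct`, and the
#'   per-pair values `precision_pct`.
#' @export
duplicate_precision <- function(x1, x2) {
  if (length(x1) == 0L || length(x1) != length(x2)) {
    stop("`x1` and `x2` must be non-empty vectors of equal length", call. = FALSE)
  }
  assert_positive(c(x1, x2), "duplicate concentrations")
  p <- abs(x1 - x2) / ((x1 + x2) / 2) * 100
  list(mean_precision_pct = mean(p),
       relative_sd_pct = if (length(p) > 1L) stats::sd(p) else NA_real_,
       precision_pct = p)
}

#' Read filter-sample records
#'
#' CSV dialect: header
#' `filter_id,pre_ug,post_ug,blank_ug,flow_lpm,duration_min`.
#'
#' @inheritParams read_neph_log
#' @return data frame of filter records suitable for
#'   [gravimetric_concentration()].
#' @export
read_filter_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("filter_id", "pre_ug", "post_ug", "duration_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("filter record file lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read or write a co-location sample table
#'
#' CSV dialect: header
#' `sample_id,neph_pm,grav_pm,rh,fuel_type,home_type,window_door_status,kitchen_size,below_lod`
#' with `rh` a fraction in \[0, 0.99\]. Numeric columns are written at full
#' precision so a write/read round trip reproduces values exactly.
#'
#' @param path CSV path.
#' @param samples co-location data frame (e.g. from [generate_campaign()]).
#' @return `read_campaign()` returns the validated data frame;
#'   `write_campaign()` returns `path` invisibly.
#' @export
read_campaign <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "neph_pm", "grav_pm", "rh")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("co-location table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$below_lod)) df$below_lod <- FALSE
  df$below_lod <- as.logical(df$below_lod)
  assert_positive(df$neph_pm, "neph_pm")
  ok <- df$below_lod | (is.finite(df$grav_pm) & df$grav_pm > 0)
  if (!all(ok)) stop("grav_pm must be > 0 for samples not flagged below_lod",
                     call. = FALSE)
  assert_rh(df$rh)
  df
}

#' @rdname read_campaign
#' @export
write_campaign <- function(samples, path) {
  df <- samples
  for (col in c("neph_pm", "grav_pm", "rh", "kitchen_size")) {
    if (!is.null(df[[col]])) df[[col]] <- fmt_num(df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write instrument logs in the documented CSV dialects
#'
#' @param x for `write_neph_log()` a data frame with `timestamp`, `pm_ugm3`;
#'   for `write_rh_log()` one with `timestamp`, `temp_c`, `rh` (fraction).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_neph_log <- function(x, path) {
  df <- data.frame(timestamp = format_iso_time(x$timestamp),
                   pm_ugm3 = fmt_num(x$pm_ugm3))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_neph_log
#' @export
write_rh_log <- function(x, path) {
  df <- data.frame(timestamp = format_iso_time(x$timestamp),
                   temp_c = fmt_num(x$temp_c),
                   rh = fmt_num(x$rh))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- internal helpers -------------------------------------------------------

parse_iso_time <- function(x) {
  ts <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  if (all(is.na(ts))) ts <- as.POSIXct(x, tz = "UTC")
  ts
}

format_iso_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

check_log_header <- function(path, expected, allow_alt = list()) {
  line1 <- readLines(path, n = 1L, warn = FALSE)
  if (length(line1) == 0L) stop("empty file: ", path, call. = FALSE)
  got <- trimws(strsplit(line1, ",", fixed = TRUE)[[1]])
  ok <- length(got) == length(expected) &&
    all(mapply(function(g, e) {
      g == e || (e %in% names(allow_alt) && g %in% allow_alt[[e]])
    }, got, expected))
  if (!ok) {
    stop(sprintf("unparseable header in %s: expected `%s`, found `%s`",
                 path, paste(expected, collapse = ","), line1), call. = FALSE)
  }
  got
}

check_increasing <- function(ts, path) {
  if (any(diff(as.numeric(ts)) <= 0)) {
    stop("timestamps must be strictly increasing in ", path, call. = FALSE)
  }
  invisible(ts)
}
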