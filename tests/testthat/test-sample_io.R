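write_tmp <- function(lines) {
  p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("nephelometer logs parse, drop bad rows, and reject bad input", {
  p <- write_tmp(c("timestamp,pm_ugm3",
                   "2014-03-01T10:00:00,100",
                   "2014-03-01T10:00:10,200",
                   "2014-03-01T10:00:20,300"))
  ts <- read_neph_log(p, "A")
  expect_equal(nrow(ts), 3)
  expect_equal(mean(ts$pm_ugm3), 200)
  expect_identical(attr(ts, "sample_id"), "A")

  p2 <- write_tmp(c("timestamp,pm_ugm3",
                    "2014-03-01T10:00:00,100",
                    "2014-03-01T10:00:10,",
                    "2014-03-01T10:00:20,300",
                    "2014-03-01T10:00:30,400"))
  expect_message(ts2 <- read_neph_log(p2), "dropped 1 row")
  expect_equal(nrow(ts2), 3)

  p3 <- write_tmp(c("time,pm", "2014-03-01T10:00:00,100"))
  expect_error(read_neph_log(p3), "unparseable header")

  p4 <- write_tmp(c("timestamp,pm_ugm3", "2014-03-01T10:00:00,"))
  expect_error(suppressMessages(read_neph_log(p4)), "empty")
})

test_that("RH logs auto-detect units, convert to fractions, and clamp", {
  p <- write_tmp(c("timestamp,temp_c,rh",
                   "2014-03-01T10:00:00,25,45",
                   "2014-03-01T10:00:10,25,60",
                   "2014-03-01T10:00:20,25,80"))
  x <- read_rh_log(p)
  expect_equal(x$rh, c(0.45, 0.60, 0.80))

  p2 <- write_tmp(c("timestamp,temp_c,rh",
                    "2014-03-01T10:00:00,25,100",
                    "2014-03-01T10:00:10,25,50"))
  expect_message(x2 <- read_rh_log(p2), "clamped 1")
  expect_equal(x2$rh, c(0.99, 0.50))

  p3 <- write_tmp(c("timestamp,temp_c,rh",
                    "2014-03-01T10:00:00,25,0.45",
                    "2014-03-01T10:00:10,25,0.60"))
  expect_equal(read_rh_log(p3)$rh, c(0.45, 0.60))

  # header claims percent but values never exceed 1.5 -> ambiguous
  p4 <- write_tmp(c("timestamp,temp_c,rh_pct",
                    "2014-03-01T10:00:00,25,0.45",
                    "2014-03-01T10:00:10,25,0.60"))
  expect_error(read_rh_log(p4), "ambiguous")
})

test_that("series alignment joins to the nearest timestamp within tolerance", {
  t0 <- as.POSIXct("2014-03-01 10:00:00", tz = "UTC")
  neph <- data.frame(timestamp = t0 + seq(0, 50, 10),
                     pm_ugm3 = c(100, 200, 300, 400, 500, 600))
  rh0 <- data.frame(timestamp = t0 + seq(0, 50, 10), temp_c = 25,
                    rh = seq(0.4, 0.65, 0.05))
  a <- align_series(neph, rh0)
  expect_equal(nrow(a), 6)
  expect_equal(a$rh, rh0$rh)

  rh3 <- rh0; rh3$timestamp <- rh3$timestamp + 3
  expect_equal(nrow(align_series(neph, rh3)), 6)

  # a lone RH reading 12 s away exceeds the 5 s tolerance: zero matches
  rh12 <- data.frame(timestamp = t0 + 12, temp_c = 25, rh = 0.5)
  expect_error(suppressMessages(align_series(neph[1, ], rh12, tolerance = 5)),
               "alignment failed")

  # symmetric in the sign of the offset
  rh_m3 <- rh0; rh_m3$timestamp <- rh_m3$timestamp - 3
  expect_equal(nrow(align_series(neph, rh3)), nrow(align_series(neph, rh_m3)))
})

test_that("window averaging is inclusive of both ends", {
  t0 <- as.POSIXct("2014-03-01 10:00:00", tz = "UTC")
  aligned <- data.frame(timestamp = t0 + seq(0, 1800, 10),
                        pm_ugm3 = rep(c(100, 300), length.out = 181),
                        rh = 0.5)
  w <- window_average(aligned, t0, t0 + 1800)
  expect_equal(w$n_points, 181)   # 30 min at 10 s, inclusive ends

  half <- window_average(aligned, t0, t0 + 900)
  expect_equal(half$n_points, 91)
  expect_equal(half$mean_pm, mean(aligned$pm_ugm3[1:91]))

  aligned2 <- data.frame(timestamp = t0 + c(0, 10), pm_ugm3 = c(100, 300),
                         rh = c(0.4, 0.6))
  w2 <- window_average(aligned2, t0, t0 + 10)
  expect_equal(w2$mean_pm, 200)
  expect_equal(w2$mean_rh, 0.5)
  expect_error(window_average(aligned2, t0 + 100, t0 + 200), "no data points")
})

test_that("gravimetric concentrations apply blank, volume, and LOD rules", {
  f <- data.frame(filter_id = c("F1", "F2", "F3"),
                  pre_ug = c(1000, 1000, 1000),
                  post_ug = c(1482, 1006, 1002),
                  blank_ug = 2, flow_lpm = 4, duration_min = 30)
  g <- gravimetric_concentration(f)
  expect_equal(g$conc_ugm3[1], 480 / 0.12)      # 4000 ug/m3
  expect_false(g$below_lod[1])
  expect_equal(g$net_ug[2], 4)
  expect_true(g$below_lod[2])                    # net 4 < LOD 5
  expect_equal(g$conc_ugm3[3], 0)
  expect_true(g$below_lod[3])

  fneg <- data.frame(pre_ug = 1000, post_ug = 1000.5, duration_min = 30)
  expect_warning(gneg <- gravimetric_concentration(fneg), "negative net mass")
  expect_equal(gneg$conc_ugm3, 0)
  expect_true(gneg$below_lod)

  expect_error(gravimetric_concentration(
    data.frame(pre_ug = 1, post_ug = 2, duration_min = 0)), "positive")
})

test_that("concentration is linear in net mass and inverse in duration", {
  set.seed(7)
  for (k in 1:20) {
    net <- runif(1, 10, 2000)
    dur <- runif(1, 10, 120)
    base <- data.frame(pre_ug = 0, post_ug = net + 2, duration_min = dur)
    g1 <- gravimetric_concentration(base)
    g2 <- gravimetric_concentration(transform(base, post_ug = 2 * net + 2))
    g3 <- gravimetric_concentration(transform(base, duration_min = 2 * dur))
    expect_equal(g2$conc_ugm3, 2 * g1$conc_ugm3)
    expect_equal(g3$conc_ugm3, g1$conc_ugm3 / 2)
  }
})

test_that("duplicate precision is the paired relative difference in percent", {
  expect_equal(duplicate_precision(100, 100)$mean_precision_pct, 0)
  expect_equal(duplicate_precision(90, 110)$mean_precision_pct, 20)
  dp <- duplicate_precision(c(100, 90), c(100, 110))
  expect_equal(dp$mean_precision_pct, 10)
  expect_equal(dp$relative_sd_pct, sd(c(0, 20)))
  expect_error(duplicate_precision(numeric(0), numeric(0)), "non-empty")
})

test_that("campaign tables and instrument logs round-trip exactly", {
  camp <- generate_campaign(campaign_config(n_samples = 20, seed = 3))
  p <- withr::local_tempfile(fileext = ".csv")
  write_campaign(camp, p)
  back <- read_campaign(p)
  expect_identical(back$neph_pm, camp$neph_pm)
  expect_identical(back$grav_pm, camp$grav_pm)
  expect_identical(back$rh, camp$rh)
  expect_identical(back$sample_id, camp$sample_id)

  ts <- generate_timeseries(1, events = list(c(0.25, 0.75)),
                            noise_sigma = 0.2, seed = 5)
  pn <- withr::local_tempfile(fileext = ".csv")
  write_neph_log(ts$neph, pn)
  back_n <- read_neph_log(pn)
  expect_identical(back_n$pm_ugm3, ts$neph$pm_ugm3)
  expect_equal(as.numeric(back_n$timestamp), as.numeric(ts$neph$timestamp))

  pr <- withr::local_tempfile(fileext = ".csv")
  write_rh_log(ts$rh, pr)
  expect_identical(read_rh_log(pr)$rh, ts$rh$rh)
})
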