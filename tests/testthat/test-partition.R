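# Builds three months of nighttime half-hours (19:00-03:00) with NEE
# attenuated below a known ustar breakpoint.
night_series <- function(breakpoint = 0.09, n_per_month = 200, noise = 0.1,
                         seed = 7) {
  set.seed(seed)
  ts <- c()
  for (m in c("2023-07-01", "2023-08-01", "2023-09-01")) {
    t0 <- as.POSIXct(paste(m, "20:00"), tz = "UTC")
    ts <- c(ts, t0 + sample(0:27, n_per_month, TRUE) * 86400 +
              sample(c(0:5, 46:47), n_per_month, TRUE) * 1800)
  }
  ts <- as.POSIXct(ts, origin = "1970-01-01", tz = "UTC")
  ustar <- runif(length(ts), 0.01, 0.4)
  nee <- 3 * pmin(1, ustar / breakpoint) + rnorm(length(ts), 0, noise)
  list(timestamp = ts, ustar = ustar, nee = nee)
}

test_that("ustar change point is recovered from a constructed breakpoint", {
  d <- night_series()
  res <- ustar_changepoint(d$nee, d$ustar, d$timestamp)
  expect_true(res$reliable)
  expect_lt(abs(res$threshold - 0.09), 0.02)
  expect_equal(nrow(res$by_month), 3)
  # removal bookkeeping: fraction below threshold matches a direct count
  frac <- mean(d$ustar < res$threshold)
  expect_gt(frac, 0)
  expect_lt(frac, 0.5)
})

test_that("no-signal and short months are handled explicitly", {
  d <- night_series()
  set.seed(1)
  flat <- rnorm(length(d$ustar), 3, 0.1)   # NEE independent of ustar
  res <- ustar_changepoint(flat, d$ustar, d$timestamp)
  expect_false(res$reliable)

  # a month with too few nighttime records is skipped with a warning
  keep <- format(d$timestamp, "%m") != "09" |
    seq_along(d$timestamp) %in% which(format(d$timestamp, "%m") == "09")[1:10]
  expect_warning(
    ustar_changepoint(d$nee[keep], d$ustar[keep], d$timestamp[keep]),
    "skipped")
})

test_that("LUT gap filling fills from similar conditions and falls back", {
  w <- clean_world()
  obs <- w$obs
  vpd <- saturation_vapor_pressure(obs$TA) - vapor_pressure(obs$TA, obs$RH)
  nee <- w$truth$NEE

  # no gaps: identity with zero flags
  gf0 <- gapfill_lut(nee, obs$timestamp, obs$SW_IN, obs$TA, vpd)
  expect_identical(gf0$filled, nee)
  expect_true(all(gf0$flag == 0))

  # single daytime gap in the smooth series: filled near truth
  g <- which(obs$SW_IN > 400)[25]
  nee2 <- nee; nee2[g] <- NA
  gf <- gapfill_lut(nee2, obs$timestamp, obs$SW_IN, obs$TA, vpd)
  expect_true(gf$flag[g] %in% 1:2)
  expect_lt(abs(gf$filled[g] - nee[g]) / abs(nee[g]), 0.10)

  # no similar conditions anywhere: diurnal-hour-mean fallback flag
  sw3 <- obs$SW_IN; sw3[g] <- 5000
  gf3 <- gapfill_lut(nee2, obs$timestamp, sw3, obs$TA, vpd)
  expect_equal(gf3$flag[g], 3L)
})

test_that("partitioning reduces to the constant case exactly", {
  n <- 200
  ts <- as.POSIXct("2023-07-01", tz = "UTC") + seq_len(n) * 1800
  night <- rep(c(TRUE, FALSE), length.out = n)
  nee <- ifelse(night, 3, -20)
  tair <- rep(20, n)
  res <- partition_nee(nee, tair, ts, night)
  expect_equal(res$data$RECO, rep(3, n), tolerance = 1e-6)
  expect_equal(res$data$GPP[!night], rep(23, sum(!night)), tolerance = 1e-6)
  expect_equal(res$data$GPP[night], rep(0, sum(night)), tolerance = 1e-6)

  expect_error(partition_nee(nee, tair, ts, rep(FALSE, n)), "nighttime")
})

test_that("Lloyd-Taylor parameters are recovered from noisy nighttime NEE", {
  set.seed(3)
  n <- 2000
  ts <- as.POSIXct("2023-07-01", tz = "UTC") + seq_len(n) * 1800
  tair <- 20 + 6 * sin(seq_len(n) / 40) + rnorm(n, 0, 1)
  night <- rep(TRUE, n)
  nee <- lloyd_taylor(tair, 2.0, 200) * (1 + rnorm(n, 0, 0.05))
  res <- partition_nee(nee, tair, ts, night)
  expect_lt(abs(res$e0 - 200) / 200, 0.15)
  expect_lt(abs(median(res$rref_windows$rref) - 2.0) / 2.0, 0.15)
})

test_that("partitioning conserves NEE + GPP - Reco on non-clipped records", {
  res <- default_run()$partition
  ok <- !is.na(res$data$NEE) & res$data$GPP_RAW >= 0
  expect_equal(res$data$NEE[ok] + res$data$GPP[ok] - res$data$RECO[ok],
               rep(0, sum(ok)), tolerance = 1e-10)
})

test_that("raising the ustar threshold never retains more nighttime data", {
  run <- default_run()
  night <- run$truth$NIGHT
  counts <- vapply(seq(0, 0.3, by = 0.05), function(thr) {
    sum(night & run$obs$USTAR >= thr)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
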