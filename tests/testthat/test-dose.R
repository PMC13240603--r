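test_that("stomatal flux splits the total by the conductance ratio", {
  r <- stomatal_o3_flux(0.5, 0.006, 1634.9)
  expect_equal(r$flux_total, 0.006 * 1634.9)
  expect_equal(r$flux_stom, 0.5 * 0.006 * 1634.9)
  expect_equal(r$flux_stom / r$flux_total, 0.5)

  r1 <- stomatal_o3_flux(1, 0.006, 1634.9)
  expect_equal(r1$flux_stom, r1$flux_total)

  r2 <- stomatal_o3_flux(1.2, 0.006, 1634.9)
  expect_true(r2$excluded)
  expect_true(is.na(r2$flux_stom))
})

test_that("diurnal centroid is the value-weighted hour with the 9-point rule", {
  h <- seq(7, 17, by = 0.5)
  expect_equal(diurnal_centroid(rep(3, length(h)), h), 12)
  v <- numeric(length(h)); v[h == 14.5] <- 2
  expect_equal(diurnal_centroid(v, h), 14.5)
  # agrees with the brute-force oracle on random days
  set.seed(14)
  for (i in 1:20) {
    vals <- runif(length(h), 0, 10)
    vals[sample(length(h), 5)] <- NA
    expect_equal(diurnal_centroid(vals, h), oracle_centroid(vals, h))
  }
  # fewer than 9 valid points: no centroid
  v8 <- c(runif(8), rep(NA, length(h) - 8))
  expect_true(is.na(diurnal_centroid(v8, h)))
  expect_true(is.na(diurnal_centroid(rep(0, length(h)), h)))
})

test_that("daily POD6 accumulates exceedance over the 6 nmol threshold", {
  expect_equal(pod6_daily(c(8, 5, 10)), oracle_pod6(c(8, 5, 10)))
  expect_equal(pod6_daily(c(8, 5, 10)), 10.8)
  expect_equal(pod6_daily(c(1, 5.9, 6)), 0)
  expect_equal(pod6_daily(6), 0)     # exactly at threshold contributes 0
  set.seed(2)
  f <- runif(30, 0, 15)
  expect_equal(pod6_daily(f), oracle_pod6(f))
})

test_that("AOT40 dialects: per-sample sums and the hourly-mean reduction", {
  expect_equal(aot40_daily(c(50, 30, 45)), oracle_aot40(c(50, 30, 45)))
  expect_equal(aot40_daily(c(50, 30, 45)), 15)
  expect_equal(aot40_daily(c(30, 40, 39)), 0)
  # paired half hours (50, 30): hourly mean 40 -> zero exceedance
  expect_equal(aot40_daily(c(50, 30), hour = c(9, 9)), 10)
  expect_equal(aot40_daily(c(50, 30), hour = c(9, 9), dialect = "hourly_mean"),
               0)
  # hourly-mean never exceeds half-hourly (Jensen for max(0, x - 40))
  set.seed(6)
  for (i in 1:50) {
    conc <- runif(20, 10, 80)
    hour <- rep(1:10, each = 2)
    hh <- aot40_daily(conc, hour)
    hm <- aot40_daily(conc, hour, dialect = "hourly_mean")
    expect_lte(hm, hh + 1e-12)
  }
  expect_equal(aot40_daily(c(50, 30), dt_weight = TRUE), 5)
})

test_that("W126 weighting matches the sigmoidal definition", {
  expect_equal(w126_weight(100), oracle_w126_weight(100), tolerance = 1e-12)
  expect_equal(w126_weight(100), 0.9854, tolerance = 1e-4)
  expect_equal(w126_weight(0), 1 / 4404, tolerance = 1e-12)
  expect_equal(w126_weight(0), 2.27e-4, tolerance = 1e-2)
  x <- seq(0, 150, by = 1)
  w <- w126_weight(x)
  expect_true(all(diff(w) > 0))
  expect_true(all(w > 0 & w < 1))
  set.seed(8)
  conc <- runif(25, 0, 90)
  expect_equal(w126_daily(conc), oracle_w126(conc))
})

test_that("metrics are monotone under pointwise increases", {
  set.seed(10)
  f <- runif(20, 0, 12)
  expect_gte(pod6_daily(f + 0.5), pod6_daily(f))
  c0 <- runif(20, 20, 60)
  expect_gte(aot40_daily(c0 + 2), aot40_daily(c0))
  expect_gte(w126_daily(c0 + 2), w126_daily(c0))
})

test_that("seasonal accumulation respects intersection-day subsets", {
  daily <- data.frame(
    date = as.Date("2023-07-01") + 0:2,
    pod6_med = c(10, 0, 8), pod6_pm = c(9, 0, 7),
    aot40 = c(50, 40, 60), w126 = c(30, 25, 35),
    n_conc = c(20, 20, 20), n_stom_med = c(15, 0, 12),
    n_stom_pm = c(15, 0, 12))
  acc <- accumulate_metrics(daily)
  all_row <- acc[acc$variant == "all", ]
  med_row <- acc[acc$variant == "intersect_med", ]
  expect_equal(all_row$n_days, 3)
  expect_equal(med_row$n_days, 2)       # day 2 lacks conductance
  expect_equal(all_row$aot40, 150 / 1000)
  expect_equal(med_row$aot40, 110 / 1000)
  expect_lte(med_row$aot40, all_row$aot40)
  expect_lte(med_row$w126, all_row$w126)

  empty <- accumulate_metrics(daily[0, ])
  expect_true(all(empty$n_days == 0))
  expect_true(all(empty$aot40 == 0))
})

test_that("accumulated POD6 tracks the truth-side accumulation", {
  run <- default_run()
  d <- run$conductance
  truth <- run$truth
  # truth-side stomatal flux on the same half-hours the pipeline retained
  fs_true <- ifelse(is.na(d$RATIO_MED), NA_real_,
                    truth$RATIO_STOM * truth$VD *
                      ppb_to_molar_density(truth$O3, run$obs$TA, run$obs$PA))
  mid <- d$timestamp - 900
  date <- as.Date(mid, tz = "UTC")
  day <- d$SZA < 90
  pod_true <- sum(vapply(split(seq_along(fs_true), date), function(ii) {
    pod6_daily(fs_true[ii][day[ii]])
  }, numeric(1))) / 1000
  acc <- run$accumulation
  pod_est <- acc$pod6_med[acc$variant == "intersect_med"]
  expect_lt(abs(pod_est - pod_true) / pod_true, 0.05)
})

test_that("the filter grid enumerates exactly 15 configurations", {
  g <- filter_grid()
  expect_equal(nrow(g), 15)
  expect_equal(nrow(unique(g[, c("rain_window_h", "rh_max")])), 15)
  expect_setequal(unique(g$rain_window_h), c(24, 36, 48, 60, 72))
  expect_setequal(unique(g$rh_max), c(70, 80, 90))
})

test_that("sensitivity grid yields 30 cells with coherent bounds", {
  run <- default_run()
  grid <- sensitivity_grid(run$deposition)
  cells <- grid$cells
  expect_equal(nrow(cells), 30)
  expect_equal(sum(cells$mode == "moving"), 15)
  expect_equal(sum(cells$mode == "fixed"), 15)

  # widening the rain window never increases the usable day count
  for (rh in c(70, 80, 90)) {
    sub <- cells[cells$rh_max == rh & cells$mode == "moving", ]
    sub <- sub[order(sub$rain_window_h), ]
    expect_true(all(diff(sub$n_days_med) <= 0))
  }

  # the default filter (36 h, 80%) is a grid member; bounds contain it
  def <- cells[cells$rain_window_h == 36 & cells$rh_max == 80 &
                 cells$mode == "moving", ]
  acc <- run$accumulation
  expect_equal(def$pod6_med, acc$pod6_med[acc$variant == "intersect_med"],
               tolerance = 1e-10)
  b <- grid$bounds
  expect_gte(def$pod6_med, b$min[b$metric == "pod6_med"])
  expect_lte(def$pod6_med, b$max[b$metric == "pod6_med"])
})
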