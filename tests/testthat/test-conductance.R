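test_that("saturation vapor pressure follows the Magnus form", {
  expect_equal(saturation_vapor_pressure(0), 0.6108)
  expect_equal(saturation_vapor_pressure(25), oracle_es(25), tolerance = 1e-12)
  expect_equal(saturation_vapor_pressure(25), 3.167, tolerance = 1e-3)
  t <- seq(-10, 45, by = 0.5)
  expect_true(all(diff(saturation_vapor_pressure(t)) > 0))
})

test_that("surface temperature responds to H through the resistances", {
  expect_equal(surface_temperature(20, 0, 1.2, 1004, 40, 20), 20)
  dt <- surface_temperature(20, 200, 1.2, 1004, 40, 20) - 20
  expect_equal(dt, 200 * 60 / (1.2 * 1004), tolerance = 1e-12)
  expect_equal(dt, 9.96, tolerance = 1e-2)
  expect_lt(surface_temperature(20, -100, 1.2, 1004, 40, 20), 20)
})

test_that("canopy VPD is surface saturation minus measured vapor pressure", {
  expect_equal(canopy_vpd(25, oracle_es(25)), 0, tolerance = 1e-12)
  expect_equal(canopy_vpd(30, 2.0), oracle_es(30) - 2.0, tolerance = 1e-12)
  expect_lt(canopy_vpd(10, 2.0), 0)  # dew-like, flagged downstream
})

test_that("PM inversion is the exact inverse of the forward formulation", {
  rho <- 1.2; cp <- 1004; gamma <- 0.066; ra <- 20; rb <- 10
  rc <- 100; vpd <- 1.5
  le_fwd <- rho * cp * vpd / (gamma * (ra + rb + rc))
  inv <- pm_inversion(le_fwd, vpd, gamma, rho, cp, ra, rb)
  expect_equal(inv$rc, 100, tolerance = 1e-10)
  expect_equal(inv$gs_ms, 0.01, tolerance = 1e-10)

  # worked arithmetic: Ra+Rb = 30, lambdaE = 210.6 -> Rc about 100
  inv2 <- pm_inversion(210.6, 1.5, 0.066, 1.2, 1004, 20, 10)
  expect_equal(inv2$rc, 1.2 * 1004 * 1.5 / (0.066 * 210.6) - 30,
               tolerance = 1e-12)
  expect_equal(inv2$rc, 100, tolerance = 0.1)

  # exclusion reasons
  expect_equal(pm_inversion(-5, 1.5, 0.066, 1.2, 1004, 20, 10)$reason, "le")
  expect_equal(pm_inversion(210.6, -0.2, 0.066, 1.2, 1004, 20, 10)$reason,
               "vpdcan")
  big <- pm_inversion(1e6, 1.5, 0.066, 1.2, 1004, 20, 10)
  expect_equal(big$reason, "rc_negative")
  expect_true(is.na(big$gs_ms))
})

test_that("validity mask enforces rain window, zenith and humidity rules", {
  ts <- as.POSIXct("2023-07-01 00:30", tz = "UTC") + (0:191) * 1800  # 4 days
  n <- length(ts)
  precip <- numeric(n)
  precip[ts == as.POSIXct("2023-07-01 12:00", tz = "UTC")] <- 2
  rh <- rep(60, n)
  sza <- rep(40, n)
  m <- stomatal_validity_mask(ts, precip, rh, sza, rain_window_h = 36)
  # 13:00 next day is within the 36 h window after the event
  i_in <- which(ts == as.POSIXct("2023-07-02 13:00", tz = "UTC"))
  expect_equal(m$reason[i_in], "rain")
  # past 36 h the mask clears
  i_out <- which(ts == as.POSIXct("2023-07-03 01:00", tz = "UTC"))
  expect_true(m$valid[i_out])

  # RH = 80 exactly is excluded (strict "< 80" rule); SZA = 85 likewise
  m2 <- stomatal_validity_mask(ts[1:2], c(0, 0), c(80, 79.9), c(40, 40))
  expect_equal(m2$reason, c("rh", ""))
  m3 <- stomatal_validity_mask(ts[1:2], c(0, 0), c(60, 60), c(85, 84.9))
  expect_equal(m3$reason, c("sza", ""))

  # exclusion accounting is conserved
  expect_equal(sum(m$counts) + sum(m$valid), n)
})

test_that("Medlyn fits recover exact parameters from noiseless model data", {
  set.seed(9)
  n <- 300
  ts <- as.POSIXct("2023-07-01", tz = "UTC") + seq_len(n) * 1800
  gpp <- runif(n, 5, 45)
  vpd <- runif(n, 0.4, 3)
  gs <- medlyn_predict(0.02, 2.5, gpp, vpd, ca = 420)
  fits <- fit_medlyn_windows(gs, gpp, vpd, ts, ca = 420, window_days = Inf)
  expect_equal(nrow(fits), 1)
  expect_lt(abs(fits$g0 - 0.02), 1e-6)
  expect_lt(abs(fits$g1 - 2.5) / 2.5, 1e-6)

  # fewer than 20 observations in a window: no fit is emitted
  f19 <- fit_medlyn_windows(gs[1:19], gpp[1:19], vpd[1:19], ts[1:19],
                            window_days = Inf)
  expect_equal(nrow(f19), 0)

  # 5% noise, 100 obs per window: slope within 10%
  gs_n <- gs * (1 + rnorm(n, 0, 0.05))
  f_n <- fit_medlyn_windows(gs_n[1:100], gpp[1:100], vpd[1:100], ts[1:100],
                            window_days = Inf)
  expect_lt(abs(f_n$g1 - 2.5) / 2.5, 0.10)
})

test_that("Medlyn prediction and unit conversion match hand arithmetic", {
  g <- medlyn_predict(0.01, 3, gpp = 30, vpdcan = 1, ca = 420)
  expect_equal(g, 0.01 + 1.6 * 4 * 30 / 420, tolerance = 1e-12)
  expect_equal(g, 0.4671, tolerance = 1e-4)
  expect_equal(medlyn_predict(0.01, 3, gpp = 0, vpdcan = 1), 0.01)
  expect_true(is.na(medlyn_predict(0.01, 3, gpp = 30, vpdcan = -0.1)))
  # mol m-2 s-1 -> m s-1 through the molar density of air
  ms <- g / molar_density_air(25, 101.325)
  expect_equal(ms, 0.01143, tolerance = 1e-3)
})

test_that("H2O conductance scales to O3 by the diffusivity ratio", {
  expect_equal(h2o_to_o3_conductance(1), 0.61)
  expect_equal(h2o_to_o3_conductance(0), 0)
  expect_equal(h2o_to_o3_conductance(3 * 0.4), 3 * h2o_to_o3_conductance(0.4))
})

test_that("noiseless conductance stage reproduces the generator exactly", {
  w <- clean_world()
  d <- w$cond$data
  ok <- !is.na(d$GS_H2O_PM_MOL)
  expect_gt(sum(ok), 100)
  rel <- abs(d$GS_H2O_PM_MOL[ok] - w$truth$GS_H2O_MOL[ok]) /
    w$truth$GS_H2O_MOL[ok]
  expect_lt(max(rel), 1e-9)
  fits <- w$cond$fits
  expect_true(all(abs(fits$g0 - w$params$g0) < 1e-6))
  expect_true(all(abs(fits$g1 - w$params$g1) / w$params$g1 < 1e-6))
  # all retained ratios live in the closed unit interval
  expect_true(all(d$RATIO_MED >= 0 & d$RATIO_MED <= 1, na.rm = TRUE))
  expect_true(all(d$RATIO_PM >= 0 & d$RATIO_PM <= 1, na.rm = TRUE))
})

test_that("windowed fits recover the Medlyn slope across noisy seasons", {
  runs <- recovery_runs()
  p <- truth_params()
  g1_err <- vapply(runs, function(r) abs(r$g1 - p$g1) / p$g1, numeric(1))
  g0_err <- vapply(runs, function(r) abs(r$g0 - p$g0), numeric(1))
  expect_lte(median(g1_err), 0.10)
  expect_lte(median(g0_err), 0.01)
})

test_that("PM and Medlyn conductances agree on the synthetic world", {
  d <- default_run()$conductance
  ok <- !is.na(d$GS_O3_PM) & !is.na(d$GS_O3_MED)
  expect_gt(sum(ok), 200)
  expect_gt(cor(d$GS_O3_PM[ok], d$GS_O3_MED[ok]), 0.9)
})
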