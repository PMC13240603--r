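make_block <- function(w, s) {
  n <- length(w)
  data.frame(t = seq_len(n) / 10, u = rep(2, n), v = rep(0, n), w = w,
             Ts = rep(25, n), c_co2 = s, c_h2o = s, c_o3 = s)
}

test_that("despiking removes constructed outliers and nothing else", {
  expect_equal(despike(rep(5, 100))$removed, 0)

  x <- sin(seq(0, 20, length.out = 500))
  med <- median(x); madv <- mad(x)
  x[250] <- med + 10 * madv
  d <- despike(x, k_mad = 6, window = 500)
  expect_equal(d$removed, 1)
  expect_true(is.na(d$values[250]))
  expect_equal(d$values[-250], x[-250])

  # 20-point toy series agrees with an independent single-window MAD filter
  y <- c(1.2, 0.8, 1.1, 0.9, 1.0, 14, 1.05, 0.95, 1.15, 0.85,
         1.0, 1.1, -12, 0.9, 1.0, 1.05, 0.95, 1.0, 1.1, 0.9)
  d2 <- despike(y, k_mad = 6, window = 20)
  expect_identical(is.na(d2$values), oracle_mad_mask(y, 6))

  expect_error(despike(numeric(0)), "empty")
  expect_error(despike(rep(NA_real_, 10)), "missing")
})

test_that("double rotation zeroes mean v and w and preserves wind magnitude", {
  set.seed(42)
  u <- 2 + rnorm(300, 0, 0.3)
  v <- rnorm(300, 0, 0.2)
  w <- rnorm(300, 0, 0.1)
  v <- v - mean(v); w <- w - mean(w)  # already aligned flow

  rot <- double_rotation(u, v, w)
  expect_equal(rot$yaw, 0, tolerance = 1e-10)
  expect_equal(rot$pitch, 0, tolerance = 1e-10)
  expect_equal(rot$u, u, tolerance = 1e-10)

  # generic block: means zeroed, per-sample magnitude preserved
  v2 <- v + 0.5; w2 <- w + 0.3
  r2 <- double_rotation(u, v2, w2)
  expect_equal(mean(r2$v), 0, tolerance = 1e-12)
  expect_equal(mean(r2$w), 0, tolerance = 1e-12)
  expect_equal(u^2 + v2^2 + w2^2, r2$u^2 + r2$v^2 + r2$w^2,
               tolerance = 1e-12)

  # idempotence: rotating rotated data is the identity
  r3 <- double_rotation(r2$u, r2$v, r2$w)
  expect_equal(r3$yaw, 0, tolerance = 1e-10)
  expect_equal(r3$pitch, 0, tolerance = 1e-10)
  expect_equal(r3$w, r2$w, tolerance = 1e-10)

  # injected pure pitch tilt is recovered
  a <- 10 * pi / 180
  um <- u * cos(a) - w * sin(a)
  wm <- u * sin(a) + w * cos(a)
  r4 <- double_rotation(um, v, wm)
  expect_equal(r4$pitch, 10, tolerance = 1e-8)

  expect_error(double_rotation(rep(0, 10), rep(0, 10), rep(0, 10)),
               "degenerate")
})

test_that("block fluxes reproduce hand-computed covariances and ustar", {
  b <- make_block(w = c(1, -1, 1, -1), s = c(2, 0, 2, 0))
  fx <- block_fluxes(b)
  expect_equal(fx$FO3, 1)   # population covariance, not the n-1 form
  expect_equal(fx$FC, 1)

  # ustar from prescribed covariances
  w <- c(1, -1, 1, -1)
  b2 <- make_block(w, s = rep(0, 4))
  b2$u <- -0.04 * w + 2
  b2$v <- 0.03 * w
  fx2 <- block_fluxes(b2)
  expect_equal(fx2$USTAR, 0.0025^0.25, tolerance = 1e-12)
  expect_equal(fx2$USTAR, 0.2236, tolerance = 1e-4)

  # ustar is invariant to a yaw rotation of (u, v)
  th <- 30 * pi / 180
  b3 <- b2
  b3$u <- b2$u * cos(th) - b2$v * sin(th)
  b3$v <- b2$u * sin(th) + b2$v * cos(th)
  expect_equal(block_fluxes(b3)$USTAR, fx2$USTAR, tolerance = 1e-12)

  # latent heat: unit-consistent micromol -> mol conversion
  air <- list(rho = 1.2, cp = 1004, lambda_v = 2.45e6)
  b4 <- make_block(w = c(1, -1, 1, -1), s = c(2, 0, 2, 0))
  fx4 <- block_fluxes(b4, air = air)
  expect_equal(fx4$LE, 2.45e6 * 0.01802 * 1 * 1e-6)
  fx4l <- block_fluxes(b4, air = air, literal_le = TRUE)
  expect_equal(fx4l$LE / fx4$LE, 1e3)
})

test_that("flux estimator is unbiased over seeded synthetic blocks", {
  ests <- vapply(1:200, function(s) {
    b <- gen_highfreq_block(cov_ws = 0.5, seed = 1000 + s, n = 2000L)
    block_fluxes(b)$FO3
  }, numeric(1))
  se_mean <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.5), 2 * se_mean)
})

test_that("SSITC flags grade stationarity and turbulence structure", {
  b <- gen_highfreq_block(cov_ws = 0.5, seed = 31)
  fl <- ssitc_flags(b)
  expect_equal(unname(fl$steady_state[["o3"]]), 0L)
  # generator default momentum flux puts sigma_w/ustar at the neutral model
  expect_equal(fl$itc, 0L)

  # opposing mean drift mid-block inflates the block covariance -> class 2
  b2 <- b
  half <- (nrow(b) / 2 + 1):nrow(b)
  b2$w[half] <- b2$w[half] + 1
  b2$c_o3[half] <- b2$c_o3[half] - 4
  expect_equal(unname(ssitc_flags(b2)$steady_state[["o3"]]), 2L)

  expect_error(ssitc_flags(b[1:5, ]), "few")
})

test_that("qc screening applies the 10% missing rule at its boundary", {
  rec <- data.frame(FC = 1, LE = 1, FO3 = 1, H = 1,
                    MISS_WIND = 0, MISS_TS = 0, MISS_CO2 = 0,
                    MISS_H2O = 0, MISS_O3 = 0,
                    SSITC_TS = 0L, SSITC_CO2 = 0L, SSITC_H2O = 0L,
                    SSITC_O3 = 0L)
  # all-clean input is untouched
  expect_equal(qc_screen(rec)$records, rec)

  r2 <- rec; r2$MISS_O3 <- 0.10   # exactly 10%: "no more than 10%" retains
  expect_false(is.na(qc_screen(r2)$records$FO3))
  r3 <- rec; r3$MISS_O3 <- 0.11
  expect_true(is.na(qc_screen(r3)$records$FO3))
  expect_false(is.na(qc_screen(r3)$records$FC))  # other fluxes untouched

  r4 <- rec; r4$SSITC_H2O <- 2L
  s4 <- qc_screen(r4)
  expect_true(is.na(s4$records$LE))
  expect_equal(unname(s4$removed["ssitc"]), 1L)
})
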