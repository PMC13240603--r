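# Independent brute-force oracles, written against the definitions rather
# than the package implementation. Deliberately loop-based and naive.

oracle_pod6 <- function(flux, threshold = 6) {
  total <- 0
  for (f in flux) {
    if (!is.na(f) && f > threshold) total <- total + (f - threshold) * 1800
  }
  total / 1000
}

oracle_aot40 <- function(conc, threshold = 40) {
  total <- 0
  for (x in conc) {
    if (!is.na(x) && x > threshold) total <- total + (x - threshold)
  }
  total
}

oracle_w126_weight <- function(conc) {
  1 / (1 + 4403 * exp(-126 * conc / 1000))
}

oracle_w126 <- function(conc) {
  total <- 0
  for (x in conc) {
    if (!is.na(x)) total <- total + x * oracle_w126_weight(x)
  }
  total
}

oracle_centroid <- function(values, hours, lo = 7, hi = 17, min_pts = 9) {
  num <- 0; den <- 0; n <- 0
  for (i in seq_along(values)) {
    if (is.na(values[i]) || hours[i] < lo || hours[i] > hi) next
    n <- n + 1
    num <- num + values[i] * hours[i]
    den <- den + values[i]
  }
  if (n < min_pts || den <= 0) return(NA_real_)
  num / den
}

# Single-window median/MAD spike mask (for series shorter than one window).
oracle_mad_mask <- function(x, k = 6) {
  med <- median(x, na.rm = TRUE)
  madv <- mad(x, na.rm = TRUE)
  !is.na(x) & abs(x - med) > k * madv
}

oracle_rb <- function(ustar, d_gas, kappa = 0.2, k = 0.4) {
  2 / (k * ustar) * (kappa / d_gas)^(2 / 3)
}

oracle_es <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
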