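# Nighttime-based carbon partitioning: friction-velocity threshold
# detection, a lookup-table gap filler, and Lloyd-Taylor extrapolation of
# nighttime respiration to the day.

# Continuous two-segment piecewise-linear fit of y on x with breakpoint c:
# y = b0 + b1 x + b2 max(0, x - c). Grid search over candidate breakpoints.
piecewise_fit <- function(x, y, n_grid = 50L) {
  qs <- stats::quantile(x, probs = seq(0.05, 0.95, length.out = n_grid),
                        names = FALSE)
  cand <- unique(qs)
  sse <- vapply(cand, function(cc) {
    X <- cbind(1, x, pmax(0, x - cc))
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }, numeric(1))
  best <- which.min(sse)
  null_sse <- sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  list(breakpoint = cand[best], sse = sse[best], null_sse = null_sse,
       at_boundary = best == 1L || best == length(cand),
       sse_reduction = 1 - sse[best] / null_sse)
}

#' Friction-velocity threshold from nighttime NEE
#'
#' Detects, per month, a change point in the relationship between nighttime
#' NEE and friction velocity using a continuous two-segment piecewise linear
#' regression over a grid of candidate breakpoints (minimizing the residual
#' sum of squares), restricted to the hours 19:00-03:00. The overall
#' threshold is the maximum of the monthly change points. A monthly fit is
#' marked unreliable when the breakpoint lands on the candidate-grid
#' boundary or when the piecewise model barely improves on a straight line.
#'
#' @param nee NEE series, micromol m-2 s-1 (micromet sign).
#' @param ustar friction velocity, m s-1.
#' @param timestamp POSIXct timestamps (end of interval, local standard).
#' @param min_n minimum nighttime records per month (months below are
#'   skipped with a warning).
#' @param n_grid number of candidate breakpoints per month.
#' @return list with \code{threshold} (m s-1), \code{by_month} (data.frame
#'   of month label, breakpoint, n, unreliable flag) and \code{reliable}
#'   (TRUE if the month providing the maximum was reliable).
#' @export
ustar_changepoint <- function(nee, ustar, timestamp, min_n = 30L,
                              n_grid = 50L) {
  hr <- as.numeric(format(timestamp, "%H", tz = "UTC"))
  in_window <- hr >= 19 | hr < 3
  ok <- in_window & !is.na(nee) & !is.na(ustar)
  month <- format(timestamp, "%Y-%m", tz = "UTC")
  res <- lapply(split(which(ok), month[ok]), function(ii) {
    if (length(ii) < min_n) return(NULL)
    fit <- piecewise_fit(ustar[ii], nee[ii], n_grid)
    data.frame(breakpoint = fit$breakpoint, n = length(ii),
               unreliable = fit$at_boundary || fit$sse_reduction < 0.05)
  })
  skipped <- names(res)[vapply(res, is.null, logical(1))]
  if (length(skipped))
    warning("months skipped (too few nighttime records): ",
            paste(skipped, collapse = ", "))
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) stop("no month has enough nighttime records")
  by_month <- do.call(rbind, res)
  by_month$month <- names(res)
  best <- which.max(by_month$breakpoint)
  list(threshold = by_month$breakpoint[best], by_month = by_month,
       reliable = !by_month$unreliable[best])
}

#' Lookup-table gap filling
#'
#' Fills gaps in a half-hourly series by the mean of records measured under
#' similar meteorological conditions (|dSWin| <= 50 W m-2, |dTair| <= 2.5
#' degC, |dVPD| <= 0.5 kPa) within a +/-7 day window, widening to +/-14
#' days, and finally falling back to the mean of the same half-hour of day
#' within +/-14 days. This is a simplified look-up-table scheme in the
#' spirit of marginal distribution sampling.
#'
#' @param x series to fill.
#' @param timestamp POSIXct timestamps.
#' @param swin,tair,vpd driver series (same length).
#' @param tol named numeric vector of similarity tolerances.
#' @param windows day half-widths to try, in order.
#' @return list with \code{filled} (series) and \code{flag} (integer per
#'   record: 0 observed, 1 filled within the first window, 2 within the
#'   second, 3 diurnal-mean fallback, -1 unfillable).
#' @export
gapfill_lut <- function(x, timestamp, swin, tair, vpd,
                        tol = c(swin = 50, tair = 2.5, vpd = 0.5),
                        windows = c(7, 14)) {
  n <- length(x)
  stopifnot(length(timestamp) == n, length(swin) == n, length(tair) == n,
            length(vpd) == n)
  filled <- x
  flag <- integer(n)
  gaps <- which(is.na(x))
  if (!length(gaps)) return(list(filled = filled, flag = flag))
  tnum <- as.numeric(timestamp)
  hod <- (as.numeric(format(timestamp, "%H", tz = "UTC")) * 60 +
            as.numeric(format(timestamp, "%M", tz = "UTC")))
  have <- !is.na(x)
  for (g in gaps) {
    done <- FALSE
    for (wi in seq_along(windows)) {
      wsec <- windows[wi] * 86400
      cand <- have & abs(tnum - tnum[g]) <= wsec
      if (!is.na(swin[g]) && !is.na(tair[g]) && !is.na(vpd[g])) {
        sim <- cand & !is.na(swin) & !is.na(tair) & !is.na(vpd) &
          abs(swin - swin[g]) <= tol[["swin"]] &
          abs(tair - tair[g]) <= tol[["tair"]] &
          abs(vpd - vpd[g]) <= tol[["vpd"]]
        if (sum(sim) >= 2) {
          filled[g] <- mean(x[sim])
          flag[g] <- wi
          done <- TRUE
          break
        }
      }
    }
    if (!done) {
      wsec <- max(windows) * 86400
      diurnal <- have & abs(tnum - tnum[g]) <= wsec & hod == hod[g]
      if (any(diurnal)) {
        filled[g] <- mean(x[diurnal])
        flag[g] <- 3L
      } else {
        flag[g] <- -1L
      }
    }
  }
  list(filled = filled, flag = flag)
}

# Least-squares Rref for fixed E0 (model linear in Rref).
fit_rref <- function(nee, tair, e0) {
  f <- lloyd_taylor(tair, 1, e0)
  sum(nee * f) / sum(f^2)
}

#' Partition NEE into GPP and ecosystem respiration
#'
#' Nighttime-based partitioning: a Lloyd-Taylor temperature response is fit
#' to nighttime NEE (temperature sensitivity E0 estimated once from all
#' nighttime data; the base rate Rref re-estimated in 15-day moving windows
#' to track seasonal change), extrapolated to all records to give Reco, and
#' GPP computed as the residual \code{GPP = Reco - NEE}. Negative GPP is
#' clipped to zero with the clip count recorded.
#'
#' @param nee gap-filled, u*-filtered NEE, micromol m-2 s-1 (micromet sign:
#'   negative = uptake).
#' @param tair air temperature, degrees C.
#' @param timestamp POSIXct timestamps.
#' @param night logical: sun below the horizon.
#' @param window_days width of the moving Rref window.
#' @param step_days spacing of window centers.
#' @param min_night minimum nighttime records per window.
#' @return list with \code{data} (data.frame: NEE, RECO, GPP, GPP_RAW),
#'   \code{e0}, \code{rref_windows} (data.frame of window centers and Rref),
#'   and \code{n_clipped}.
#' @export
partition_nee <- function(nee, tair, timestamp, night,
                          window_days = 15, step_days = 5,
                          min_night = 20L) {
  ok_n <- night & !is.na(nee) & !is.na(tair)
  if (!any(ok_n)) stop("no nighttime records: cannot partition")
  # global E0 by nonlinear least squares (bounded)
  dfn <- data.frame(y = nee[ok_n], ta = tair[ok_n])
  e0 <- tryCatch({
    fit <- minpack.lm::nlsLM(y ~ lloyd_taylor(ta, rref, e0), data = dfn,
                             start = list(rref = 2, e0 = 150),
                             lower = c(0.01, 30), upper = c(50, 450))
    stats::coef(fit)[["e0"]]
  }, error = function(e) 200)

  tnum <- as.numeric(timestamp)
  centers <- seq(min(tnum), max(tnum), by = step_days * 86400)
  half <- window_days / 2 * 86400
  wins <- lapply(centers, function(ct) {
    ii <- which(ok_n & abs(tnum - ct) <= half)
    if (length(ii) < min_night) return(NULL)
    data.frame(center = ct, rref = fit_rref(nee[ii], tair[ii], e0),
               n = length(ii))
  })
  wins <- do.call(rbind, wins[!vapply(wins, is.null, logical(1))])
  if (is.null(wins) || nrow(wins) == 0)
    stop("no window has enough nighttime records")
  rref_t <- if (nrow(wins) == 1) rep(wins$rref, length(tnum)) else
    stats::approx(wins$center, wins$rref, xout = tnum, rule = 2)$y
  reco <- lloyd_taylor(tair, rref_t, e0)
  gpp_raw <- reco - nee
  gpp <- pmax(0, gpp_raw)
  wins$center <- as.POSIXct(wins$center, origin = "1970-01-01", tz = "UTC")
  list(data = data.frame(NEE = nee, RECO = reco, GPP = gpp,
                         GPP_RAW = gpp_raw),
       e0 = e0, rref_windows = wins,
       n_clipped = sum(!is.na(gpp_raw) & gpp_raw < 0))
}
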