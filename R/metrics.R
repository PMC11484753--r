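# Oscillation metrics: peak/trough extraction with sub-sample refinement,
# period as the mean of the last ~10 inter-peak intervals, peak-trough
# amplitude, phase-unbiased temporal averages, phase lag, and a
# steady/oscillatory classification.

.get_series <- function(x, var, time_col = "time_h") {
  if (inherits(x, "per2_trajectory") || is.data.frame(x)) {
    if (!time_col %in% names(x))
      abort_domain(sprintf("no '%s' column in the series", time_col))
    if (!var %in% names(x))
      abort_domain(sprintf("no '%s' column in the series", var))
    tt <- as.numeric(x[[time_col]])
    yy <- as.numeric(x[[var]])
  } else {
    abort_domain("series must be a data frame (time + value columns)")
  }
  if (length(tt) < 3L || any(diff(tt) <= 0))
    abort_domain("series times must be strictly increasing with >= 3 samples")
  if (any(!is.finite(yy)))
    abort_domain(sprintf("series '%s' contains non-finite values", var))
  list(t = tt, y = yy)
}

.moving_average <- function(y, k) {
  # centered running mean, k odd; edges use shrinking one-sided windows
  if (k <= 1L) return(y)
  n <- length(y)
  cs <- cumsum(c(0, y))
  h <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Locate peaks and troughs of a trajectory variable
#'
#' Finds local extrema after a settling window, refines each by fitting a
#' quadratic through the three samples around the discrete extremum (the
#' period is meaningful to 0.01 h, finer than the sampling interval), and
#' enforces strict peak/trough alternation. Noisy series can be smoothed
#' with a centered moving average before detection, and shallow wiggles
#' suppressed with a prominence floor: adjacent extrema whose values differ
#' by less than `min_prominence` cancel pairwise.
#'
#' @param x A [simulate_model()] trajectory, or any data frame with a time
#'   column and the named variable.
#' @param var Name of the variable column.
#' @param settle_time Hours discarded at the start (transient from the
#'   zero pre-history); default 240 h, about ten nominal cycles.
#' @param smooth_window Moving-average window in hours (0 = none).
#' @param min_prominence Minimum value difference between neighbouring
#'   extrema (0 = keep all).
#' @param time_col Name of the time column.
#' @return Data frame with columns `time`, `value`, `type`
#'   (`"peak"`/`"trough"`), strictly alternating; zero rows if the series
#'   has no interior extrema after settling.
#' @export
find_extrema <- function(x, var, settle_time = 240, smooth_window = 0,
                         min_prominence = 0, time_col = "time_h") {
  s <- .get_series(x, var, time_col)
  dt <- stats::median(diff(s$t))
  y <- s$y
  if (smooth_window > 0) {
    k <- max(1L, as.integer(round(smooth_window / dt)))
    if (k %% 2L == 0L) k <- k + 1L
    y <- .moving_average(y, k)
  }
  keep <- s$t >= settle_time
  if (sum(keep) < 3L)
    abort_domain("fewer than 3 samples after settle_time")
  tt <- s$t[keep]; yy <- y[keep]

  d <- sign(diff(yy))
  # collapse flat runs so plateau edges count once
  nz <- which(d != 0)
  if (length(nz) < 2L) {
    ev <- data.frame(time = numeric(0), value = numeric(0),
                     type = character(0))
  } else {
    turn <- nz[-length(nz)][d[nz[-length(nz)]] != d[nz[-1L]]]
    idx <- turn + 1L
    type <- ifelse(d[turn] > 0, "peak", "trough")
    # prominence pruning: cancel the least-separated adjacent pair
    if (min_prominence > 0 && length(idx) >= 2L) {
      repeat {
        if (length(idx) < 2L) break
        dv <- abs(diff(yy[idx]))
        j <- which.min(dv)
        if (dv[j] >= min_prominence) break
        drop <- c(j, j + 1L)
        idx <- idx[-drop]; type <- type[-drop]
      }
    }
    # enforce alternation: among consecutive same-type events keep the extreme
    if (length(idx) >= 2L) {
      keep_ev <- rep(TRUE, length(idx))
      j <- 1L
      while (j < length(idx)) {
        k2 <- j + 1L
        while (k2 <= length(idx) && type[k2] == type[j]) k2 <- k2 + 1L
        run <- j:(k2 - 1L)
        if (length(run) > 1L) {
          best <- if (type[j] == "peak") run[which.max(yy[idx[run]])]
                  else run[which.min(yy[idx[run]])]
          keep_ev[setdiff(run, best)] <- FALSE
        }
        j <- k2
      }
      idx <- idx[keep_ev]; type <- type[keep_ev]
    }
    # quadratic sub-sample refinement
    ref_t <- numeric(length(idx)); ref_v <- numeric(length(idx))
    for (m in seq_along(idx)) {
      i <- idx[m]
      if (i <= 1L || i >= length(yy)) {
        ref_t[m] <- tt[i]; ref_v[m] <- yy[i]
      } else {
        y0 <- yy[i - 1L]; y1 <- yy[i]; y2 <- yy[i + 1L]
        denom <- y0 - 2 * y1 + y2
        off <- if (abs(denom) < .Machine$double.eps) 0
               else 0.5 * (y0 - y2) / denom
        off <- max(min(off, 0.5), -0.5)
        ref_t[m] <- tt[i] + off * dt
        ref_v[m] <- y1 - 0.25 * (y0 - y2) * off
      }
    }
    ev <- data.frame(time = ref_t, value = ref_v, type = type)
  }
  structure(ev, dt = dt, settle_time = settle_time, var = var)
}

.peaks <- function(ev) ev[ev$type == "peak", , drop = FALSE]

.extrema_or_stop <- function(x, var, settle_time, ...) {
  ev <- find_extrema(x, var, settle_time = settle_time, ...)
  if (sum(ev$type == "peak") < 2L)
    stop(errorCondition(
      sprintf("variable '%s': fewer than 2 peaks after settle_time (non-oscillatory or horizon too short)",
              var),
      class = c("per2as_nonoscillatory_error", "error")))
  ev
}

#' Oscillation period from inter-peak intervals
#'
#' The period is the arithmetic mean of the last `n_intervals` intervals
#' between successive peaks (after transient removal). If fewer intervals
#' are available, all of them (at least 2) are used with a warning.
#'
#' @inheritParams find_extrema
#' @param n_intervals Number of trailing peak-to-peak intervals averaged
#'   (default 10).
#' @return Period in hours.
#' @export
estimate_period <- function(x, var, n_intervals = 10, settle_time = 240,
                            smooth_window = 0, min_prominence = 0,
                            time_col = "time_h") {
  ev <- .extrema_or_stop(x, var, settle_time,
                         smooth_window = smooth_window,
                         min_prominence = min_prominence,
                         time_col = time_col)
  pk <- .peaks(ev)$time
  if (length(pk) < 3L)
    stop(errorCondition(
      sprintf("variable '%s': fewer than 3 peaks, cannot estimate a period", var),
      class = c("per2as_nonoscillatory_error", "error")))
  iv <- diff(pk)
  if (length(iv) < n_intervals)
    warning(sprintf("variable '%s': only %d inter-peak intervals available (%d requested)",
                    var, length(iv), n_intervals))
  mean(utils::tail(iv, n_intervals))
}

#' Peak-to-trough amplitude
#'
#' Mean of the last `k` peak values minus the mean of the last `k` trough
#' values, `k = min(10, available)`. A steadily converging variable has
#' amplitude 0.
#'
#' @inheritParams find_extrema
#' @param eps_amp Steady-classification threshold passed to [classify()].
#' @return Amplitude (dimensionless concentration units); 0 for a steady
#'   variable.
#' @export
amplitude <- function(x, var, settle_time = 240, eps_amp = 1e-4,
                      smooth_window = 0, min_prominence = 0,
                      time_col = "time_h") {
  if (classify(x, var, eps_amp = eps_amp, settle_time = settle_time,
               time_col = time_col) == "steady")
    return(0)
  ev <- .extrema_or_stop(x, var, settle_time,
                         smooth_window = smooth_window,
                         min_prominence = min_prominence,
                         time_col = time_col)
  pk <- ev$value[ev$type == "peak"]
  tr <- ev$value[ev$type == "trough"]
  k <- min(10L, length(pk), length(tr))
  mean(utils::tail(pk, k)) - mean(utils::tail(tr, k))
}

#' Time-weighted temporal average
#'
#' Trapezoid-rule mean of a variable over a trailing window. For an
#' oscillatory variable the window snaps to an integer number of cycles
#' (the last 5 full periods, ending at the last peak) so the mean carries
#' no phase bias; steady variables average over the last `window` hours.
#'
#' @inheritParams find_extrema
#' @param window Window length in hours for non-oscillatory series
#'   (default 200); must not exceed the post-settling span.
#' @param eps_amp Steady-classification threshold.
#' @return The temporal average (dimensionless).
#' @export
temporal_average <- function(x, var, window = 200, settle_time = 240,
                             eps_amp = 1e-4, smooth_window = 0,
                             min_prominence = 0, time_col = "time_h") {
  s <- .get_series(x, var, time_col)
  span <- s$t[length(s$t)] - s$t[1L]
  if (window > span)
    abort_domain("averaging window longer than the trajectory span")
  cls <- classify(x, var, eps_amp = eps_amp, settle_time = settle_time,
                  time_col = time_col)
  if (cls == "oscillatory") {
    ev <- .extrema_or_stop(x, var, settle_time,
                           smooth_window = smooth_window,
                           min_prominence = min_prominence,
                           time_col = time_col)
    pk <- .peaks(ev)$time
    per <- mean(utils::tail(diff(pk), 10))
    n_cyc <- min(5L, length(pk) - 1L)
    t_hi <- pk[length(pk)]
    t_lo <- t_hi - n_cyc * per
    if (t_lo < s$t[1L]) t_lo <- s$t[1L]
  } else {
    t_hi <- s$t[length(s$t)]
    t_lo <- t_hi - window
  }
  w <- s$t >= t_lo & s$t <= t_hi
  tt <- s$t[w]; yy <- s$y[w]
  sum(diff(tt) * (yy[-1L] + yy[-length(yy)]) / 2) / (tt[length(tt)] - tt[1L])
}

#' Classify a variable as oscillatory or steady
#'
#' A variable is steady if its peak-to-trough range over the trailing
#' 200 h (or the post-settling span, if shorter) falls below `eps_amp`,
#' or if fewer than 2 peaks are found there; otherwise oscillatory.
#'
#' @inheritParams find_extrema
#' @param eps_amp Range threshold below which the variable counts as
#'   converged to a steady state (default 1e-4).
#' @return `"oscillatory"` or `"steady"`.
#' @export
classify <- function(x, var, eps_amp = 1e-4, settle_time = 240,
                     time_col = "time_h") {
  s <- .get_series(x, var, time_col)
  t_hi <- s$t[length(s$t)]
  t_lo <- max(s$t[1L], t_hi - 200, settle_time)
  if (sum(s$t >= t_lo) < 10L) t_lo <- max(s$t[1L], t_hi - 200)
  w <- s$t >= t_lo
  rng <- diff(range(s$y[w]))
  if (rng < eps_amp) return("steady")
  ev <- find_extrema(x, var, settle_time = t_lo, time_col = time_col)
  if (sum(ev$type == "peak") < 2L) return("steady")
  "oscillatory"
}

#' Phase lag between two oscillatory variables
#'
#' Circular mean of the peak-time differences (variable A minus the
#' nearest preceding peak of variable B, modulo the period) over the last
#' 5 cycles. Both variables must oscillate with matching periods (within
#' 1%). Antiphasic variables give a lag near half the period.
#'
#' @inheritParams find_extrema
#' @param varA,varB Names of the two variable columns.
#' @return Lag in hours, in `[0, period)`.
#' @export
phase_lag <- function(x, varA, varB, settle_time = 240,
                      smooth_window = 0, min_prominence = 0,
                      time_col = "time_h") {
  evA <- .extrema_or_stop(x, varA, settle_time,
                          smooth_window = smooth_window,
                          min_prominence = min_prominence,
                          time_col = time_col)
  evB <- .extrema_or_stop(x, varB, settle_time,
                          smooth_window = smooth_window,
                          min_prominence = min_prominence,
                          time_col = time_col)
  pkA <- .peaks(evA)$time
  pkB <- .peaks(evB)$time
  perA <- mean(utils::tail(diff(pkA), 10))
  perB <- mean(utils::tail(diff(pkB), 10))
  if (abs(perA - perB) > 0.01 * perA)
    abort_domain(sprintf("periods of '%s' (%.3f h) and '%s' (%.3f h) differ by more than 1%%",
                         varA, perA, varB, perB))
  per <- (perA + perB) / 2
  lags <- vapply(utils::tail(pkA, 5L), function(ta) {
    prior <- pkB[pkB <= ta]
    if (length(prior) == 0L) return(NA_real_)
    (ta - prior[length(prior)]) %% per
  }, numeric(1))
  lags <- lags[!is.na(lags)]
  if (length(lags) == 0L)
    abort_domain("no overlapping peak pairs for phase lag")
  ang <- 2 * pi * lags / per
  (atan2(mean(sin(ang)), mean(cos(ang))) %% (2 * pi)) * per / (2 * pi)
}

#' Per-variable oscillation summary of a trajectory
#'
#' Computes, for each requested variable: classification, period (NA when
#' steady), peak-to-trough amplitude (0 when steady), mean of the trailing
#' peak and trough values, and the phase-unbiased temporal average.
#'
#' @inheritParams find_extrema
#' @param vars Variable columns to summarize; defaults to every non-time
#'   column.
#' @param eps_amp Steady-classification threshold.
#' @return Data frame of class `per2_summary`, one row per variable, with
#'   columns `variable`, `classification`, `period`, `amplitude`,
#'   `peak_value`, `trough_value`, `average`, `n_peaks`.
#' @export
oscillation_summary <- function(x, vars = NULL, settle_time = 240,
                                eps_amp = 1e-4, smooth_window = 0,
                                min_prominence = 0, time_col = "time_h") {
  if (is.null(vars)) vars <- setdiff(names(x), time_col)
  rows <- lapply(vars, function(v) {
    cls <- classify(x, v, eps_amp = eps_amp, settle_time = settle_time,
                    time_col = time_col)
    if (cls == "steady") {
      avg <- temporal_average(x, v, settle_time = settle_time,
                              eps_amp = eps_amp, time_col = time_col)
      data.frame(variable = v, classification = cls, period = NA_real_,
                 amplitude = 0, peak_value = NA_real_,
                 trough_value = NA_real_, average = avg, n_peaks = 0L)
    } else {
      ev <- .extrema_or_stop(x, v, settle_time,
                             smooth_window = smooth_window,
                             min_prominence = min_prominence,
                             time_col = time_col)
      pk <- ev$value[ev$type == "peak"]
      tr <- ev$value[ev$type == "trough"]
      k <- min(10L, length(pk), length(tr))
      per <- suppressWarnings(
        estimate_period(x, v, settle_time = settle_time,
                        smooth_window = smooth_window,
                        min_prominence = min_prominence,
                        time_col = time_col))
      avg <- temporal_average(x, v, settle_time = settle_time,
                              eps_amp = eps_amp,
                              smooth_window = smooth_window,
                              min_prominence = min_prominence,
                              time_col = time_col)
      data.frame(variable = v, classification = cls, period = per,
                 amplitude = mean(utils::tail(pk, k)) -
                   mean(utils::tail(tr, k)),
                 peak_value = mean(utils::tail(pk, k)),
                 trough_value = mean(utils::tail(tr, k)),
                 average = avg, n_peaks = length(pk))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("per2_summary", "data.frame")
  out
}
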