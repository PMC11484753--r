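# Independent oracles used to cross-check the implementation.

# Brute-force extrema finder: smooth the finite-difference derivative,
# take each maximal run of positive slope followed by negative slope as a
# peak window, and return the raw argmax inside it (troughs analogously).
# Deliberately different from the production path (no quadratic
# refinement, no alternation cleanup).
oracle_extrema <- function(tt, yy, deriv_smooth = 5L) {
  dy <- diff(yy)
  if (deriv_smooth > 1L) {
    k <- deriv_smooth + (1L - deriv_smooth %% 2L)
    dy <- stats::filter(dy, rep(1 / k, k), sides = 2)
    dy[is.na(dy)] <- 0
  }
  s <- sign(as.numeric(dy))
  s[s == 0] <- NA
  s <- zoo_na_locf(s)
  ch <- which(diff(s) != 0)
  if (length(ch) == 0L)
    return(data.frame(time = numeric(0), value = numeric(0),
                      type = character(0)))
  bounds <- c(1L, ch + 1L, length(yy))
  out <- lapply(seq_along(ch), function(j) {
    win <- bounds[j]:bounds[j + 2L]
    if (s[ch[j]] > 0) {
      i <- win[which.max(yy[win])]
      data.frame(time = tt[i], value = yy[i], type = "peak")
    } else {
      i <- win[which.min(yy[win])]
      data.frame(time = tt[i], value = yy[i], type = "trough")
    }
  })
  do.call(rbind, out)
}

zoo_na_locf <- function(x) {
  for (i in seq_along(x)) if (is.na(x[i]) && i > 1L) x[i] <- x[i - 1L]
  x[is.na(x)] <- 1
  x
}

# Quadrature oracle for the linear test DDE y'(t) = -y(t - tau) with
# constant history y = 1 on [-tau, 0]: trapezoid integration on a grid
# aligned with the delay, accurate to O(dt^2).
oracle_linear_dde <- function(tau, t_end, dt = tau / 2000) {
  nlag <- as.integer(round(tau / dt))
  dt <- tau / nlag
  tt <- seq(-tau, t_end, by = dt)
  y <- numeric(length(tt))
  y[tt <= 0] <- 1
  i0 <- which.min(abs(tt))
  for (i in i0:(length(tt) - 1L)) {
    y[i + 1L] <- y[i] - dt * (y[i - nlag] + y[i + 1L - nlag]) / 2
  }
  data.frame(time = tt, y = y)
}

# Session-level cache of standard 720 h reduced-system runs so the trend
# and acceptance tests never repeat an identical integration.
.traj_cache <- new.env(parent = emptyenv())

cached_traj <- function(..., t_end = 720) {
  ov <- list(...)
  key <- paste(c(t_end, unlist(ov[order(names(ov))])), collapse = "|")
  if (is.null(.traj_cache[[key]]))
    .traj_cache[[key]] <- simulate_model(do.call(default_parameters, ov),
                                         t_end = t_end)
  .traj_cache[[key]]
}
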