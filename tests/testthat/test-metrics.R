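sine_series <- function(period = 24, A = 1, mesor = 0, dt = 0.05,
                        duration = 240, phase = 0) {
  tt <- seq(0, duration, by = dt)
  data.frame(time_h = tt,
             value = mesor + A * sin(2 * pi * (tt - phase) / period))
}

test_that("pure sinusoids are measured exactly", {
  s <- sine_series(period = 24, A = 1.5, mesor = 2)
  expect_equal(suppressWarnings(estimate_period(s, "value", settle_time = 24)),
               24, tolerance = 0.01 / 24)
  expect_equal(amplitude(s, "value", settle_time = 24), 3,
               tolerance = 0.01)
  # sin peaks at t = 6 mod 24
  ev <- find_extrema(s, "value", settle_time = 24)
  pk <- ev$time[ev$type == "peak"]
  expect_true(all(abs((pk - 6) %% 24) < 0.01 | abs((pk - 6) %% 24 - 24) < 0.01))
  # peaks and troughs strictly alternate
  expect_true(all(ev$type[-1] != ev$type[-nrow(ev)]))
  # temporal average over whole cycles recovers the mesor
  expect_equal(temporal_average(s, "value", settle_time = 24), 2,
               tolerance = 1e-3)
})

test_that("constant and damped series classify as steady", {
  tt <- seq(0, 400, by = 0.1)
  const <- data.frame(time_h = tt, value = rep(1.3, length(tt)))
  expect_equal(classify(const, "value", settle_time = 100), "steady")
  expect_equal(nrow(find_extrema(const, "value", settle_time = 100)), 0L)
  expect_equal(temporal_average(const, "value", settle_time = 100), 1.3)
  expect_equal(amplitude(const, "value", settle_time = 100), 0)
  expect_error(estimate_period(const, "value", settle_time = 100),
               class = "per2as_nonoscillatory_error")
  damped <- data.frame(time_h = tt,
                       value = 0.7 + exp(-tt / 20) * sin(2 * pi * tt / 24))
  expect_equal(classify(damped, "value", settle_time = 200), "steady")
  expect_equal(temporal_average(damped, "value", settle_time = 200), 0.7,
               tolerance = 1e-4)
})

test_that("phase lag is zero for identical signals, half-period for antiphase", {
  s <- sine_series()
  s$other <- s$value
  expect_equal(phase_lag(s, "value", "other", settle_time = 24), 0,
               tolerance = 0.02)
  s$anti <- -s$value
  lag <- phase_lag(s, "value", "anti", settle_time = 24)
  expect_equal(lag, 12, tolerance = 0.05)
  # mismatched periods refuse a lag
  s$fast <- sin(2 * pi * s$time_h / 18)
  expect_error(phase_lag(s, "value", "fast", settle_time = 24),
               class = "per2as_domain_error")
})

test_that("extrema finder agrees with the brute-force oracle", {
  set.seed(11)
  for (i in 1:50) {
    per <- runif(1, 20, 28)
    A <- runif(1, 0.5, 3)
    h2 <- runif(1, 0, 0.3)
    spec <- rhythm_spec(period = per, amplitude = A, mesor = A,
                        phase = runif(1, 0, per), harmonics = h2,
                        noise_sd = 0, sampling_dt = 0.1, duration = 200,
                        seed = i)
    s <- generate_rhythm(spec)$series
    ev <- find_extrema(s, "value", settle_time = 20)
    orc <- oracle_extrema(s$time_h, s$value)
    orc <- orc[orc$time >= 20, , drop = FALSE]
    pk <- ev$time[ev$type == "peak"]
    opk <- orc$time[orc$type == "peak"]
    # same peak count (up to one boundary event) and matching times
    expect_lte(abs(length(pk) - length(opk)), 1L)
    m <- min(length(pk), length(opk))
    matched <- vapply(pk, function(t0) min(abs(opk - t0)), numeric(1))
    expect_lt(stats::median(matched), 0.11)
    # periods agree
    expect_equal(mean(diff(pk)), mean(diff(opk)), tolerance = 0.01)
  }
})

test_that("period estimates are insensitive to the sampling interval", {
  p <- default_parameters(f_S = 0.5, f_A = 0.5)
  t1 <- simulate_model(p, t_end = 400, output_dt = 0.05)
  t2 <- simulate_model(p, t_end = 400, output_dt = 0.025)
  p1 <- estimate_period(t1, "m_S", n_intervals = 5, settle_time = 200)
  p2 <- estimate_period(t2, "m_S", n_intervals = 5, settle_time = 200)
  expect_lt(abs(p1 - p2), 0.01)
})

test_that("summary table reports the per-variable rhythm structure", {
  traj <- cached_traj(f_S = 1, f_A = 1)
  sm <- oscillation_summary(traj, vars = c("m_S", "m_A", "p_S"))
  expect_s3_class(sm, "per2_summary")
  expect_equal(sm$variable, c("m_S", "m_A", "p_S"))
  expect_true(all(sm$classification == "oscillatory"))
  expect_true(all(abs(sm$period - sm$period[1]) < 0.01))
  expect_true(all(sm$amplitude > 0))
  expect_true(all(sm$amplitude <= sm$peak_value - sm$trough_value + 1e-9))
})
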