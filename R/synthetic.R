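# Seeded synthetic rhythms with known ground truth, for validating the
# oscillation metrics, plus regeneration of the deterministic reference
# trajectory bundle used by the test-suite.

#' Specification of a synthetic rhythm
#'
#' Describes a (possibly harmonically distorted) sinusoid with additive
#' Gaussian noise and a known ground truth: period, peak-to-trough
#' amplitude, mesor (rhythm-adjusted mean) and phase (time of the first
#' peak). The deterministic waveform is built from
#' `cos(2*pi*(t - phase)/period)` plus optional higher harmonics
#' `harmonics[k] * cos(2*pi*(k+1)*(t - phase)/period)`, then rescaled so
#' its peak-to-trough range is exactly `amplitude` and its time average
#' exactly `mesor`.
#'
#' @param period Period in hours, `> 0`.
#' @param amplitude Peak-to-trough amplitude, `>= 0`.
#' @param mesor Mean level (default `amplitude`, keeping the signal
#'   positive).
#' @param phase Time of the (first) waveform peak, hours.
#' @param harmonics Optional numeric weights of harmonics 2, 3, ...
#'   (asymmetric peak shapes).
#' @param noise_sd Additive Gaussian noise standard deviation, `>= 0`.
#' @param sampling_dt Sampling interval, hours.
#' @param duration Series length, hours.
#' @param seed Integer seed; fixes the noise realization.
#' @return An object of class `per2_rhythm_spec`.
#' @export
rhythm_spec <- function(period = 24, amplitude = 2, mesor = amplitude,
                        phase = 0, harmonics = NULL, noise_sd = 0,
                        sampling_dt = 0.25, duration = 240, seed = 1L) {
  if (!is.numeric(period) || period <= 0)
    abort_validation("period must be > 0")
  if (!is.numeric(amplitude) || amplitude < 0)
    abort_validation("amplitude must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    abort_validation("noise_sd must be >= 0")
  if (!is.numeric(sampling_dt) || sampling_dt <= 0 || sampling_dt >= duration)
    abort_validation("sampling_dt must be in (0, duration)")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort_validation("seed must be a single integer")
  spec <- list(period = period, amplitude = amplitude, mesor = mesor,
               phase = phase, harmonics = harmonics, noise_sd = noise_sd,
               sampling_dt = sampling_dt, duration = duration,
               seed = as.integer(seed))
  class(spec) <- "per2_rhythm_spec"
  spec
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic rhythm with known ground truth
#'
#' @param spec A [rhythm_spec()].
#' @return List with `series` (data frame `time_h`, `value`) and `truth`
#'   (the exact period, amplitude, mesor, phase, noise_sd and seed behind
#'   the realization).
#' @examples
#' r <- generate_rhythm(rhythm_spec(period = 23.5, seed = 7))
#' estimate_period(r$series, "value", settle_time = 0)
#' @export
generate_rhythm <- function(spec) {
  if (!inherits(spec, "per2_rhythm_spec")) spec <- do.call(rhythm_spec, spec)
  tt <- seq(0, spec$duration, by = spec$sampling_dt)
  shape <- function(t) {
    w <- cos(2 * pi * (t - spec$phase) / spec$period)
    if (!is.null(spec$harmonics))
      for (k in seq_along(spec$harmonics))
        w <- w + spec$harmonics[k] *
          cos(2 * pi * (k + 1) * (t - spec$phase) / spec$period)
    w
  }
  # normalize range/mean on one dense cycle
  tfine <- seq(0, spec$period, length.out = 4096L)[-4096L]
  wf <- shape(tfine)
  rng <- diff(range(wf))
  scale <- if (rng > 0) spec$amplitude / rng else 0
  w <- (shape(tt) - mean(wf)) * scale + spec$mesor
  noise <- if (spec$noise_sd > 0)
    .with_seed(spec$seed, stats::rnorm(length(tt), 0, spec$noise_sd))
  else rep(0, length(tt))
  peak_t <- tfine[which.max(wf)] %% spec$period
  list(series = data.frame(time_h = tt, value = w + noise),
       truth = list(period = spec$period, amplitude = spec$amplitude,
                    mesor = spec$mesor, phase = peak_t,
                    noise_sd = spec$noise_sd, seed = spec$seed))
}

#' Regenerate the deterministic reference-trajectory bundle
#'
#' Re-runs the standard model conditions used throughout the test-suite —
#' collision probabilities `f` in 0, 0.5, 1; the promoter mutant
#' (`K_A = 0.67`, `f = 1`); the knock-down (`alpha = 4`, `f = 1`); and a
#' 10x PER2 overexpression (`f = 1`) — with fixed solver options, so the
#' fixture set is bit-stable and never needs to be stored.
#'
#' @param param_sets Optional named list of `per2_params` replacing the
#'   default conditions.
#' @param t_end Horizon in hours.
#' @param dir Optional directory; when given, each trajectory is written
#'   as delimited text with a JSON manifest via [write_trajectory()].
#' @param ... Further arguments to [simulate_model()].
#' @return Named list of `per2_trajectory` objects, with a `manifest`
#'   attribute recording parameters and solver options per condition.
#' @export
generate_reference_trajectories <- function(param_sets = NULL, t_end = 720,
                                            dir = NULL, ...) {
  if (is.null(param_sets)) {
    param_sets <- list(
      f0 = default_parameters(f_S = 0, f_A = 0),
      f05 = default_parameters(f_S = 0.5, f_A = 0.5),
      f1 = default_parameters(f_S = 1, f_A = 1),
      mutant = default_parameters(f_S = 1, f_A = 1, K_A = 0.67),
      knockdown = default_parameters(f_S = 1, f_A = 1, alpha = 4),
      overexpression = default_parameters(f_S = 1, f_A = 1,
                                          g_S = 10 * 14 / (log(2) / 2))
    )
  }
  trajs <- lapply(param_sets, function(p)
    simulate_model(validate_parameters(p), t_end = t_end, ...))
  manifest <- lapply(trajs, function(tr)
    list(params = unclass(attr(tr, "params"))[.param_fields],
         solver = attr(tr, "solver"), system = attr(tr, "system")))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(trajs))
      write_trajectory(trajs[[nm]], file.path(dir, paste0(nm, ".csv")),
                       manifest = TRUE)
  }
  attr(trajs, "manifest") <- manifest
  trajs
}
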