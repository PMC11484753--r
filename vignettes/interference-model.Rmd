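---
title: "Modelling mutual repression of Per2 and Per2AS by transcriptional interference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mutual repression of Per2 and Per2AS by transcriptional interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(per2as)
```

## The biological problem

*Per2AS* is a long non-coding RNA transcribed antisense to the mouse core
clock gene *Period2* (*Per2*). Both transcripts are rhythmic and antiphasic,
which has long suggested mutual repression — but experiments indicate the
repression does not run through the RNA products. Instead it appears to be
**transcriptional interference**: RNA polymerases (RNAPs) transcribing the
two strands of the shared locus in opposite directions collide head-on, and
colliding polymerases can detach, killing both nascent transcripts.

`per2as` implements a deterministic model of this mechanism and the four
in-silico perturbation experiments that probe it: sweeps of the collision
probability, a Per2AS promoter mutant, a Per2 knock-down, and PER2
overexpression.

## The model

### Full system: explicit promoter switching

Transcriptional activities $X_S(t), X_A(t) \in [0,1]$ give the probability
that RNAP is recruited and transcribing the sense (Per2) or antisense
(Per2AS) strand. They switch between ON and OFF:

$$\frac{dX_S}{dt} = k_\mathrm{on}^S (1 - X_S) - k_\mathrm{off}^S\, p_S^n X_S,
\qquad
\frac{dX_A}{dt} = k_\mathrm{on}^A (1 - X_A) - k_\mathrm{off}^A X_A,$$

where $p_S$ is PER2 protein: PER2 autoinhibits its own promoter with
Hill-type nonlinearity $n$, while the Per2AS promoter switches independently
of the clock state. With both strands active (probability $X_S X_A$)
polymerases collide and detach with probabilities $f_S$ (sense) and $f_A$
(antisense), giving the concentration dynamics (dimensionless $m_S$, $m_A$,
$p_S$; time in hours):

$$\frac{1}{\mu_S}\frac{dm_S}{dt} = X_S (1 - X_A) + (1 - f_S) X_S X_A - (1+\alpha)\,m_S,$$
$$\frac{1}{\mu_S}\frac{dm_A}{dt} = v_A X_A (1 - X_S) + v_A (1 - f_A) X_A X_S - \mu_A m_A,$$
$$\frac{1}{\mu_S}\frac{dp_S}{dt} = g_S\, m_S(t - \tau) - \eta_S\, p_S.$$

The delay $\tau$ lumps together translation, post-translational maturation
and nuclear entry of repression-competent PER2. The $\alpha$ term is the
knock-down knob (below); $\alpha = 0$ is the unperturbed model.

### Reduced system: quasi-steady-state promoter activities

Promoter switching (seconds–minutes) is far faster than circadian dynamics
(hours), so setting $dX_i/dt = 0$ gives

$$X_S = \frac{1}{1 + (K_S p_S)^n}, \qquad X_A = \frac{1}{1 + K_A},$$

with $K_S^n = k_\mathrm{off}^S / k_\mathrm{on}^S$ and
$K_A = k_\mathrm{off}^A / k_\mathrm{on}^A$. Substituting yields the
three-variable delay system that all experiment runners use:

$$\frac{1}{\mu_S}\frac{dm_S}{dt} = \frac{1}{1 + (K_S p_S)^n}\left(1 - \frac{f_S}{1 + K_A}\right) - (1+\alpha) m_S,$$
$$\frac{1}{\mu_S}\frac{dm_A}{dt} = \frac{v_A}{1 + K_A}\left(1 - \frac{f_A}{1 + (K_S p_S)^n}\right) - \mu_A m_A.$$

The reduction makes the mechanism legible: PER2 *represses* Per2 but
effectively *activates* Per2AS (high PER2 silences the sense promoter, which
relieves the interference on the antisense strand). That single fact
explains the antiphasic rhythms and both counterintuitive perturbation
results.

`rhs_full()`/`rhs_reduced()` expose the two right-hand sides;
`simulate_model(system = "full")` integrates the five-variable system with
explicit kinetics from `full_kinetics()`.

### Timescale and units

The model equations carry $1/\mu_S$ on every concentration derivative. We
fold it into the right-hand side (derivatives are $\mu_S \times$ balance) so
integrations run directly in hours, the natural circadian unit. Dimensional
rate sets convert through `nondimensionalize()`, which forms the ratios
$v_A = v_{AD}/v_{SD}$, $\mu_A = \mu_{AD}/\mu_{SD}$, $g_S = g_{SD}/\mu_{SD}$,
$\eta_S = \eta_{SD}/\mu_{SD}$ and records the concentration scale
$v_{SD}/\mu_{SD}$ for back-conversion.

## Parameters

| field | default | unit | meaning |
|---|---|---|---|
| `n` | 3 | — | Hill exponent of PER2 autoinhibition |
| `f_S`, `f_A` | 0 | — | probability of collision-and-detachment per strand |
| `mu_S` | $\ln 2 / 2$ | h$^{-1}$ | Per2 mRNA degradation (2 h half-life); system timescale |
| `K_S` | 0.3684 | — | $n$-th root of $k_\mathrm{off}^S/k_\mathrm{on}^S$ |
| `v_A` | 1 | — | Per2AS transcription relative to Per2 |
| `mu_A` | 1 | — | Per2AS degradation relative to Per2 mRNA |
| `K_A` | 4.0 | — | $k_\mathrm{off}^A/k_\mathrm{on}^A$; sets peak Per2AS ≈ 1/3 of peak Per2 |
| `g_S` | $14/\mu_S$ | — | PER2 translation; 14 proteins/mRNA/h from 5 aa/s over 1257 aa |
| `eta_S` | 1 | — | PER2 degradation relative to Per2 mRNA |
| `tau` | 6.2 | h | delay to repression-competent PER2 (4–6 h mRNA→protein phase lag) |
| `alpha` | 0 | — | extra mRNA degradation from shRNA knock-down |

`default_parameters()` applies these with named overrides and strict
validation (errors, never clamping, so sweeps cannot silently leave the
model's domain). The `g_S` default is *coupled* to `mu_S`: overriding
`mu_S` alone recomputes `g_S = 14/mu_S` so the dimensional translation rate
stays 14 h$^{-1}$. The collision probabilities default to 0 — the autonomous
Per2 oscillator — because every experiment sets them explicitly.

Absolute switching rates are unconstrained by the reduction; only the
ratios matter. `full_kinetics()` defaults to $k_\mathrm{on} = 100$ h$^{-1}$
on both strands — fast against the circadian timescale but cheap to
integrate — with $k_\mathrm{off}$ derived from $K_S^n$ and $K_A$.

## Simulation protocol and numerics

All standard runs follow one protocol: zero pre-history
($m_S \equiv 0$ on $[-\tau, 0]$, $m_A(0) = p_S(0) = 0$; `constant_history()`
generalizes to any constant state), a 720 h horizon, and dense uniform
output every 0.05 h. The delay integrator (an adaptive method-of-steps
scheme with continuous interpolation of the stored solution, via deSolve's
`dede`) runs at `rtol = 1e-8`, `atol = 1e-10`. Under these settings the
reference period estimate is stable to well under 0.01 h when tolerances
are refined further, which is the accuracy contract the tests enforce; the
discontinuity the zero history injects at multiples of $\tau$ is resolved
by the adaptive step controller and is covered by the same contract. With
$\tau = 0$ the integration degrades gracefully to an ODE.

For the full system, unless a five-component history is given, promoter
activities start at their quasi-steady state for the initial PER2 level —
the configuration the fast switching relaxes to within a few multiples of
$1/k_\mathrm{on}$.

**Reduction check.** Scaling both `full_kinetics` rates by $\lambda$ at
fixed ratios drives the full system to the reduced one; at
$\lambda = 1000$ (i.e. $k_\mathrm{on} = 10^5$ h$^{-1}$) the three
concentration trajectories agree to better than $10^{-3}$ over the final
100 h of a 300 h run, and the discrepancy falls monotonically in $\lambda$.
The 300 h horizon is the shortest that discards the transient and still
leaves a 100 h comparison window; longer horizons accumulate phase drift
proportional to the $O(1/\lambda)$ period mismatch without changing the
conclusion.

## Oscillation metrics

* **Extrema** (`find_extrema`): local maxima/minima after a settling window,
  each refined by a quadratic fit through the three surrounding samples
  (the period is quoted to 0.01 h, finer than the sampling grid), with
  strict peak/trough alternation enforced.
* **Period** (`estimate_period`): arithmetic mean of the last ~10
  peak-to-peak intervals — exactly `min(10, available)` intervals, with a
  warning when fewer than 10 exist.
* **Amplitude** (`amplitude`): mean of the trailing peak values minus mean
  of the trailing trough values. Peak and trough curves are the primary
  observables of the sweep figures, so peak−trough is the reconstructible
  amplitude definition; half-amplitude conventions would scale contour
  values but none of the comparative results.
* **Temporal average** (`temporal_average`): trapezoid mean over the last 5
  full cycles (snapped to the final peak) so the window carries no phase
  bias; steady variables average over the trailing 200 h.
* **Classification** (`classify`): steady iff the trailing-200 h range falls
  below `eps_amp = 1e-4` (the solver resolves amplitudes far below this, so
  the threshold separates numerical ripple from real limit cycles) or fewer
  than 2 peaks exist.
* **Phase lag** (`phase_lag`): circular mean of peak-time offsets over the
  last 5 cycles; defined only when both periods agree within 1%.
* **Settling window**: 240 h (ten nominal cycles) by default — the zero
  history launches a large transient; trailing-window metrics must not see
  it.

For noisy series (e.g. external data through `read_series()`), detection
accepts a moving-average `smooth_window` and a `min_prominence` floor that
cancels adjacent low-contrast extrema pairwise. The validation suite uses a
4 h window — about a sixth of the shortest circadian period of interest,
attenuating a 20–28 h component by under 2% — and a prominence of 20% of
the 5–95% value range.

## Perturbation experiments

* `sweep_f(f_grid)` — wildtype sweeps with $f_S = f_A = f$ (collision
  detaches both polymerases with the same probability, the simplest
  symmetric assumption). Rising $f$ deepens Per2AS troughs at fixed peaks
  (amplitude up), clips Per2 peaks (amplitude down) and shortens the period.
* `contour_f_tau`, `contour_f_KA` — phase diagrams over delay and promoter
  strength; cells where the limit cycle dies are flagged steady with `NA`
  period. Grid resolutions are configurable (21×21 full, 5×5 coarse via the
  CLI `--coarse` flag) and affect no numerical conclusion.
* `scenario_mutant` — promoter mutant as a $K_A$ drop, 4 → 0.67, calibrated
  so the antisense activity rises $(1+4)/(1+0.67) \approx 3$-fold as
  observed in the mutant line.
* `scenario_knockdown` — shRNA action as extra first-order degradation
  $-(1+\alpha) m_S$ with $\alpha = 4$: half-life 2 h → 0.4 h. Modelling the
  knock-down as a parameter inside the right-hand side (not a separate
  model) lets every runner accept it uniformly.
* `scenario_overexpression` — exogenous PER2 as a multiplicative factor on
  `g_S` (1×, 10×, 100×), averages reported relative to the 1× arm at the
  same $f$. This mirrors what was simulated; a separate exogenous mRNA pool
  that escapes interference is *not* implemented — a known limitation, and
  the likely source of the model–experiment mismatch in endogenous Per2
  mRNA under overexpression.

## Synthetic rhythms

`generate_rhythm()` produces seeded test signals: a sinusoid with optional
higher harmonics (asymmetric peaks), rescaled so its peak-to-trough range
and time average are *exactly* the requested amplitude and mesor, plus
additive Gaussian noise. The ground-truth record suffices to recompute
every recovery expectation without rerunning generation, and the global RNG
stream is left untouched. This emulates only what the metrics need —
deterministic waveform plus white noise; it does not emulate qPCR
measurement error, replicate structure, or the relaxation-oscillator
waveform details of the model itself, so metric recovery rates on it bound
estimator quality, not real-data performance. We quote signal-to-noise as
(half peak-to-trough amplitude)/noise SD, so SNR 5 means
`noise_sd = amplitude/10`. `generate_reference_trajectories()` regenerates
the deterministic fixture bundle (f ∈ {0, 0.5, 1}, mutant, knock-down,
overexpression) bit-stably instead of vendoring data files.

## Problem sizes used by the test-suite

Deterministic headline results (golden period, fold-changes, trend
directions) use the full 720 h protocol. Runner-level unit tests shorten
the horizon to 300–400 h with a matching 150–200 h settle, and property
checks use coarse 2–5 point grids; identical integrations are cached within
a test session. The reduction-equivalence check runs 300 h as argued above.
The metrics recovery study draws 100 seeded rhythms of 240 h at 0.25 h
sampling.

## Known limitations

* Deterministic only: RNAP switching is modelled by mean activities; no
  chemical-master-equation/Gillespie counterpart.
* Two-gene circuit: no BMAL1/CRY/REV-ERB network, and no additional
  feedback factor between PER2 and Per2AS — so the observed insensitivity
  of endogenous Per2 mRNA to PER2 overexpression is *not* reproduced
  (the model predicts a strong decrease).
* Spectral period estimation (FFT/Lomb–Scargle) is deliberately absent as a
  primary method; peak-interval averaging is the definition used
  throughout.
* No bifurcation continuation; oscillation-death boundaries come from
  direct simulation grids.
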