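# Scenario runners: parameter sweeps, phase-diagram grids, and the three
# perturbation experiments (promoter mutant, knock-down, overexpression).
# Every runner is a pure function of (parameters, grids, solver options):
# re-running yields identical tables.

.run_summary <- function(params, t_end, settle_time, vars, ...) {
  traj <- simulate_model(params, t_end = t_end, ...)
  oscillation_summary(traj, vars = vars, settle_time = settle_time)
}

.check_f_grid <- function(f_grid) {
  if (!is.numeric(f_grid) || length(f_grid) < 1L || any(!is.finite(f_grid)) ||
      any(f_grid < 0 | f_grid > 1))
    abort_validation("f grid values must lie in [0, 1]")
  f_grid
}

#' Sweep the RNAP collision-and-detachment probability f
#'
#' Runs the reduced system over a grid of collision probabilities with
#' `f_S = f_A = f` (the symmetric-collision assumption) and tabulates, per
#' variable: peak and trough levels, amplitude, period and classification.
#' Increasing `f` deepens the Per2AS troughs (raising its amplitude while
#' its peak stays put), lowers the Per2 mRNA peaks, and shortens the
#' period.
#'
#' @param f_grid Collision probabilities in \[0, 1\]
#'   (default `seq(0, 1, length.out = 21)`).
#' @param params Baseline `per2_params`; `f_S`/`f_A` are overridden per
#'   grid point.
#' @param t_end,settle_time Simulation horizon and transient cut (hours).
#' @param vars Variables to summarize.
#' @param ... Further arguments to [simulate_model()].
#' @return Long-format data frame: one row per `f` x variable, with
#'   columns `f`, `variable`, `classification`, `period`, `amplitude`,
#'   `peak_value`, `trough_value`, `average`.
#' @export
sweep_f <- function(f_grid = seq(0, 1, length.out = 21),
                    params = default_parameters(),
                    t_end = 720, settle_time = 240,
                    vars = c("m_S", "m_A", "p_S"), ...) {
  .check_f_grid(f_grid)
  params <- validate_parameters(params)
  rows <- lapply(sort(f_grid), function(f) {
    p <- default_parameters(utils::modifyList(unclass(params),
                                              list(f_S = f, f_A = f)))
    sm <- .run_summary(p, t_end, settle_time, vars, ...)
    cbind(f = f, sm[, c("variable", "classification", "period", "amplitude",
                        "peak_value", "trough_value", "average")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Amplitude/period phase diagram over collision probability and delay
#'
#' Grid of reduced-system runs over `f` (with `f_S = f_A = f`) and the
#' PER2 production delay `tau`, reporting amplitude per variable plus the
#' Per2 mRNA period. Longer delays increase both the amplitudes and the
#' period at a given `f`; cells where the oscillation dies are flagged
#' steady with `period = NA`.
#'
#' @inheritParams sweep_f
#' @param tau_grid Delay values in hours, `>= 0`.
#' @return Long-format data frame with columns `f`, `tau`, `variable`,
#'   `classification`, `amplitude`, `period`, `average`.
#' @export
contour_f_tau <- function(f_grid = seq(0, 1, length.out = 21),
                          tau_grid = seq(3, 9, length.out = 21),
                          params = default_parameters(),
                          t_end = 720, settle_time = 240,
                          vars = c("m_S", "m_A", "p_S"), ...) {
  .check_f_grid(f_grid)
  if (any(!is.finite(tau_grid)) || any(tau_grid < 0))
    abort_validation("tau grid values must be >= 0")
  params <- validate_parameters(params)
  grid <- expand.grid(tau = sort(tau_grid), f = sort(f_grid),
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- default_parameters(utils::modifyList(
      unclass(params),
      list(f_S = grid$f[i], f_A = grid$f[i], tau = grid$tau[i])))
    sm <- .run_summary(p, t_end, settle_time, vars, ...)
    cbind(f = grid$f[i], tau = grid$tau[i],
          sm[, c("variable", "classification", "amplitude", "period",
                 "average")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per2 level and period over collision probability and promoter strength
#'
#' Grid of reduced-system runs over `f` (with `f_S = f_A = f`) and the
#' Per2AS RNAP detachment/recruitment ratio `K_A`, reporting the temporal
#' average and period of Per2 mRNA. Lowering `K_A` (stronger Per2AS
#' promoter) at `f > 0` lowers the average Per2 mRNA level and shortens
#' the period; at high `f` and low `K_A` the oscillation can die entirely
#' (steady cells, `period = NA`). At `f = 0` the column is independent of
#' `K_A` because interference is off.
#'
#' @inheritParams sweep_f
#' @param KA_grid `K_A` values, `>= 0`.
#' @return Data frame with columns `f`, `K_A`, `average`, `period`,
#'   `classification` (for Per2 mRNA `m_S`).
#' @export
contour_f_KA <- function(f_grid = seq(0, 1, length.out = 21),
                         KA_grid = seq(0.5, 4, length.out = 21),
                         params = default_parameters(),
                         t_end = 720, settle_time = 240, ...) {
  .check_f_grid(f_grid)
  if (any(!is.finite(KA_grid)) || any(KA_grid < 0))
    abort_validation("K_A grid values must be >= 0")
  params <- validate_parameters(params)
  grid <- expand.grid(K_A = sort(KA_grid), f = sort(f_grid),
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- default_parameters(utils::modifyList(
      unclass(params),
      list(f_S = grid$f[i], f_A = grid$f[i], K_A = grid$K_A[i])))
    sm <- .run_summary(p, t_end, settle_time, "m_S", ...)
    data.frame(f = grid$f[i], K_A = grid$K_A[i],
               average = sm$average, period = sm$period,
               classification = sm$classification)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.fold_changes <- function(ctrl_sm, pert_sm) {
  fc <- merge(ctrl_sm[, c("variable", "average", "amplitude")],
              pert_sm[, c("variable", "average", "amplitude")],
              by = "variable", suffixes = c("_control", "_perturbed"))
  fc$fold_average <- ifelse(fc$average_control > 0,
                            fc$average_perturbed / fc$average_control,
                            NA_real_)
  fc$fold_amplitude <- ifelse(fc$amplitude_control > 0,
                              fc$amplitude_perturbed / fc$amplitude_control,
                              NA_real_)
  fc
}

.new_scenario <- function(name, arms, fold_changes, extras = list()) {
  structure(c(list(name = name, arms = arms, fold_changes = fold_changes),
              extras),
            class = "per2_scenario")
}

#' @export
print.per2_scenario <- function(x, ...) {
  cat(sprintf("Per2/Per2AS scenario: %s\narms: %s\n",
              x$name, paste(names(x$arms), collapse = ", ")))
  cat("fold changes (perturbed / control):\n")
  print(x$fold_changes, digits = 4)
  invisible(x)
}

#' Per2AS promoter-mutant scenario
#'
#' Compares the wildtype promoter (`K_A = 4`) against the mutant
#' (`K_A = 0.67`), the calibration at which the Per2AS transcriptional
#' activity rises about 3-fold: the closed-form ratio is
#' `(1 + KA_wt) / (1 + KA_mut)`. At high `f` the mutant's Per2 mRNA and
#' PER2 amplitudes shrink while the Per2AS amplitude grows.
#'
#' @param f Collision probability applied to both strands.
#' @param KA_wt,KA_mut Wildtype and mutant detachment/recruitment ratios.
#' @inheritParams sweep_f
#' @return A `per2_scenario` with arms `control` / `mutant`, per-variable
#'   fold changes, and `X_A_fold` (mutant/wildtype activity ratio).
#' @export
scenario_mutant <- function(f = 1, KA_wt = 4.0, KA_mut = 0.67,
                            params = default_parameters(),
                            t_end = 720, settle_time = 240, ...) {
  .check_f_grid(f)
  params <- validate_parameters(params)
  base <- utils::modifyList(unclass(params), list(f_S = f, f_A = f))
  p_wt <- default_parameters(utils::modifyList(base, list(K_A = KA_wt)))
  p_mut <- default_parameters(utils::modifyList(base, list(K_A = KA_mut)))
  tr_wt <- simulate_model(p_wt, t_end = t_end, ...)
  tr_mut <- simulate_model(p_mut, t_end = t_end, ...)
  vars <- c("m_S", "m_A", "p_S")
  sm_wt <- oscillation_summary(tr_wt, vars = vars, settle_time = settle_time)
  sm_mut <- oscillation_summary(tr_mut, vars = vars, settle_time = settle_time)
  .new_scenario(
    "promoter_mutant",
    arms = list(control = list(params = p_wt, trajectory = tr_wt,
                               summary = sm_wt),
                mutant = list(params = p_mut, trajectory = tr_mut,
                              summary = sm_mut)),
    fold_changes = .fold_changes(sm_wt, sm_mut),
    extras = list(X_A_fold = qss_activity_antisense(p_mut) /
                    qss_activity_antisense(p_wt))
  )
}

#' Per2 knock-down scenario
#'
#' Adds shRNA-like first-order degradation `alpha * mu_S` to Per2 mRNA and
#' compares against the unperturbed control. At `alpha = 4` the mRNA
#' half-life drops from 2 h to 0.4 h, the Per2 mRNA and PER2 averages and
#' amplitudes fall to less than half of control, and — through the loss of
#' PER2-mediated relief of interference — the average Per2AS level drops
#' too, the more so the larger `f`.
#'
#' @param alpha Knock-down strength (extra degradation as a multiple of
#'   `mu_S`); default 4.
#' @param f Collision probability applied to both strands.
#' @inheritParams sweep_f
#' @return A `per2_scenario` with arms `control` / `knockdown`,
#'   fold changes, and the two mRNA `half_lives` (hours).
#' @export
scenario_knockdown <- function(alpha = 4, f = 1,
                               params = default_parameters(),
                               t_end = 720, settle_time = 240, ...) {
  .check_f_grid(f)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0)
    abort_validation("alpha must be a nonnegative number")
  params <- validate_parameters(params)
  base <- utils::modifyList(unclass(params), list(f_S = f, f_A = f))
  p_ctrl <- default_parameters(utils::modifyList(base, list(alpha = 0)))
  p_kd <- default_parameters(utils::modifyList(base, list(alpha = alpha)))
  tr_ctrl <- simulate_model(p_ctrl, t_end = t_end, ...)
  tr_kd <- simulate_model(p_kd, t_end = t_end, ...)
  vars <- c("m_S", "m_A", "p_S")
  sm_ctrl <- oscillation_summary(tr_ctrl, vars = vars,
                                 settle_time = settle_time)
  sm_kd <- oscillation_summary(tr_kd, vars = vars, settle_time = settle_time)
  .new_scenario(
    "per2_knockdown",
    arms = list(control = list(params = p_ctrl, trajectory = tr_ctrl,
                               summary = sm_ctrl),
                knockdown = list(params = p_kd, trajectory = tr_kd,
                                 summary = sm_kd)),
    fold_changes = .fold_changes(sm_ctrl, sm_kd),
    extras = list(half_lives = c(control = knockdown_half_life(p_ctrl),
                                 knockdown = knockdown_half_life(p_kd)))
  )
}

#' PER2 overexpression scenario
#'
#' Scales the PER2 translation rate `g_S` by each multiplier (the
#' reference conditions are 1x, 10x, 100x of the default `14/mu_S`) at a
#' fixed collision probability, and reports per-variable temporal averages
#' normalized to the multiplier-1 arm at the same `f`. Raising PER2
#' relieves the interference on Per2AS only weakly — for `f > 0` the
#' normalized Per2AS average stays below 1.5 even at 100x — while the
#' Per2 mRNA average drops strongly.
#'
#' @param gS_multipliers Positive multipliers on `g_S`; must include 1 or
#'   it is added as the normalization baseline.
#' @param f Collision probability applied to both strands.
#' @inheritParams sweep_f
#' @return A `per2_scenario` whose arms are named by multiplier and whose
#'   `normalized_averages` table holds averages relative to multiplier 1.
#' @export
scenario_overexpression <- function(gS_multipliers = c(1, 10, 100), f = 1,
                                    params = default_parameters(),
                                    t_end = 720, settle_time = 240, ...) {
  .check_f_grid(f)
  if (any(!is.finite(gS_multipliers)) || any(gS_multipliers <= 0))
    abort_validation("g_S multipliers must be positive")
  params <- validate_parameters(params)
  mults <- sort(unique(c(1, gS_multipliers)))
  base <- utils::modifyList(unclass(params), list(f_S = f, f_A = f))
  vars <- c("m_S", "m_A", "p_S")
  arms <- lapply(mults, function(m) {
    p <- default_parameters(utils::modifyList(
      base, list(g_S = params$g_S * m)))
    tr <- simulate_model(p, t_end = t_end, ...)
    list(params = p, trajectory = tr,
         summary = oscillation_summary(tr, vars = vars,
                                       settle_time = settle_time))
  })
  names(arms) <- paste0("x", format(mults, trim = TRUE))
  ref <- arms[[which(mults == 1)]]$summary
  norm <- do.call(rbind, lapply(seq_along(mults), function(i) {
    sm <- arms[[i]]$summary
    data.frame(multiplier = mults[i], variable = sm$variable,
               average = sm$average,
               normalized_average = sm$average /
                 ref$average[match(sm$variable, ref$variable)])
  }))
  rownames(norm) <- NULL
  ctrl <- arms[[which(mults == 1)]]$summary
  top <- arms[[length(arms)]]$summary
  .new_scenario(
    "per2_overexpression",
    arms = arms,
    fold_changes = .fold_changes(ctrl, top),
    extras = list(normalized_averages = norm, multipliers = mults)
  )
}
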