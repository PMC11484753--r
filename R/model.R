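# Right-hand sides of the interference model.
#
# Full system (five variables): promoter activities X_S, X_A switch between
# RNAP-bound (ON) and free (OFF); head-on RNAP collision detaches the
# polymerases with probabilities f_S, f_A, coupling sense and antisense
# transcription. Reduced system (three variables): X_S, X_A replaced by
# their quasi-steady-state values.
#
# Timescale convention: the model equations carry a 1/mu_S factor on the
# d/dt of every concentration; it is folded into the returned derivative
# (derivatives are mu_S times the dimensionless production/decay balance),
# so all integrations run directly in hours.

#' Quasi-steady-state transcriptional activity of the sense (Per2) strand
#'
#' Setting the RNAP on/off switching to equilibrium gives
#' `X_S = 1 / (1 + (K_S * p_S)^n)`: PER2 represses its own transcription
#' with Hill-type nonlinearity `n`. Strictly decreasing in `p_S`, equal to
#' 1 at `p_S = 0` and 1/2 at `p_S = 1/K_S`.
#'
#' @param p_S Dimensionless PER2 protein level(s), `>= 0` (vectorized).
#' @param params A `per2_params` object.
#' @return Activity value(s) in \[0, 1\].
#' @export
qss_activity_sense <- function(p_S, params) {
  params <- validate_parameters(params)
  if (!is.numeric(p_S) || any(!is.finite(p_S)))
    abort_domain("p_S must be finite numeric")
  if (any(p_S < 0))
    abort_domain("p_S must be >= 0")
  1 / (1 + (params$K_S * p_S)^params$n)
}

#' Quasi-steady-state transcriptional activity of the antisense (Per2AS) strand
#'
#' Per2AS switching does not depend on PER2, so its equilibrium activity is
#' the constant `X_A = 1 / (1 + K_A)`, where `K_A = k_off_A / k_on_A`.
#' At the wildtype `K_A = 4` this is 0.2; the promoter mutant `K_A = 0.67`
#' raises it about 3-fold.
#'
#' @param params A `per2_params` object.
#' @return A single activity value in \[0, 1\].
#' @export
qss_activity_antisense <- function(params) {
  params <- validate_parameters(params)
  1 / (1 + params$K_A)
}

# Unchecked reduced-system derivative used inside the integrator; tolerates
# the tiny negative undershoots an adaptive solver can produce.
.rhs_reduced_raw <- function(state, m_S_delayed, p) {
  X_S <- 1 / (1 + (p$K_S * max(state[[3L]], 0))^p$n)
  X_A <- 1 / (1 + p$K_A)
  c(p$mu_S * (X_S * (1 - p$f_S * X_A) - (1 + p$alpha) * state[[1L]]),
    p$mu_S * (p$v_A * X_A * (1 - p$f_A * X_S) - p$mu_A * state[[2L]]),
    p$mu_S * (p$g_S * m_S_delayed - p$eta_S * state[[3L]]))
}

.rhs_full_raw <- function(state, m_S_delayed, kin, p) {
  X_S <- state[[1L]]; X_A <- state[[2L]]
  pS <- max(state[[5L]], 0)
  c(kin$k_on_S * (1 - X_S) - kin$k_off_S * pS^p$n * X_S,
    kin$k_on_A * (1 - X_A) - kin$k_off_A * X_A,
    p$mu_S * (X_S * (1 - p$f_S * X_A) - (1 + p$alpha) * state[[3L]]),
    p$mu_S * (p$v_A * X_A * (1 - p$f_A * X_S) - p$mu_A * state[[4L]]),
    p$mu_S * (p$g_S * m_S_delayed - p$eta_S * state[[5L]]))
}

#' Time derivatives of the reduced three-variable system
#'
#' State is `(m_S, m_A, p_S)`: Per2 mRNA, Per2AS transcript, PER2 protein,
#' all dimensionless. Using the quasi-steady-state activities,
#' \deqn{dm_S/dt = \mu_S [ X_S(p_S) (1 - f_S X_A) - (1+\alpha) m_S ]}
#' \deqn{dm_A/dt = \mu_S [ v_A X_A (1 - f_A X_S(p_S)) - \mu_A m_A ]}
#' \deqn{dp_S/dt = \mu_S [ g_S m_S(t-\tau) - \eta_S p_S ]}
#' with `X_S(p_S) = 1/(1+(K_S p_S)^n)` and `X_A = 1/(1+K_A)`. The
#' knock-down term `(1+alpha)` reduces the Per2 mRNA half-life to
#' `log(2)/(mu_S (1+alpha))`.
#'
#' @param t Time in hours (unused: the system is autonomous; kept for the
#'   standard derivative signature).
#' @param state Numeric vector `(m_S, m_A, p_S)`, all `>= 0`.
#' @param m_S_delayed Value of `m_S` at `t - tau`, `>= 0`.
#' @param params A `per2_params` object.
#' @return Named numeric vector of derivatives `(m_S, m_A, p_S)` per hour.
#' @export
rhs_reduced <- function(t, state, m_S_delayed, params) {
  params <- validate_parameters(params)
  state <- .check_state(state, c("m_S", "m_A", "p_S"))
  if (any(state < 0))
    abort_domain("reduced-system state components must be >= 0")
  if (!is.numeric(m_S_delayed) || length(m_S_delayed) != 1L ||
      !is.finite(m_S_delayed) || m_S_delayed < 0)
    abort_domain("m_S_delayed must be a nonnegative number")
  d <- .rhs_reduced_raw(state, m_S_delayed, params)
  names(d) <- c("m_S", "m_A", "p_S")
  d
}

#' Time derivatives of the full five-variable system
#'
#' State is `(X_S, X_A, m_S, m_A, p_S)`. The promoter activities follow
#' explicit RNAP recruitment/detachment kinetics,
#' \deqn{dX_S/dt = k_{on}^S (1 - X_S) - k_{off}^S p_S^n X_S}
#' \deqn{dX_A/dt = k_{on}^A (1 - X_A) - k_{off}^A X_A}
#' (returned per hour as written), while the concentration equations are
#' the collision-interference balance
#' \deqn{dm_S/dt = \mu_S [ X_S (1 - X_A) + (1-f_S) X_S X_A - (1+\alpha) m_S ]}
#' and its antisense counterpart, plus the delayed PER2 production of
#' [rhs_reduced()]. Activities outside \[0, 1\] raise a domain error.
#'
#' @inheritParams rhs_reduced
#' @param state Numeric vector `(X_S, X_A, m_S, m_A, p_S)`.
#' @param kin A `per2_kinetics` object (see [full_kinetics()]).
#' @return Named numeric vector of the five derivatives per hour.
#' @export
rhs_full <- function(t, state, m_S_delayed, kin, params) {
  params <- validate_parameters(params)
  validate_kinetics(kin, params)
  state <- .check_state(state, c("X_S", "X_A", "m_S", "m_A", "p_S"))
  if (state[[1L]] < 0 || state[[1L]] > 1 || state[[2L]] < 0 || state[[2L]] > 1)
    abort_domain("transcriptional activities X_S, X_A must lie in [0, 1]")
  if (any(state[3:5] < 0))
    abort_domain("concentrations m_S, m_A, p_S must be >= 0")
  if (!is.numeric(m_S_delayed) || length(m_S_delayed) != 1L ||
      !is.finite(m_S_delayed) || m_S_delayed < 0)
    abort_domain("m_S_delayed must be a nonnegative number")
  d <- .rhs_full_raw(state, m_S_delayed, kin, params)
  names(d) <- c("X_S", "X_A", "m_S", "m_A", "p_S")
  d
}

.check_state <- function(state, fields) {
  if (!is.numeric(state) || length(state) != length(fields) ||
      any(!is.finite(state)))
    abort_domain(sprintf("state must be a finite numeric vector (%s)",
                         paste(fields, collapse = ", ")))
  if (!is.null(names(state))) {
    if (!setequal(names(state), fields))
      abort_domain(sprintf("state names must be exactly: %s",
                           paste(fields, collapse = ", ")))
    state <- state[fields]
  }
  unname(state)
}
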