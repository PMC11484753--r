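# Explicit RNAP recruitment/detachment kinetics for the unreduced system,
# and the dimensional <-> dimensionless parameter map.

#' Explicit RNAP kinetics for the full five-variable system
#'
#' The quasi-steady-state reduction only constrains the detachment /
#' recruitment *ratios* (`k_off_S / k_on_S = K_S^n`, `k_off_A / k_on_A =
#' K_A`); the absolute rates set how fast the promoter on/off switching
#' relaxes. RNAP recruitment and detachment are much faster than the
#' circadian timescale, so the default recruitment rate is 100 per hour on
#' both strands, with detachment derived from the ratios. Scaling
#' `rate_scale` up at fixed ratios drives the full system toward its
#' reduced quasi-steady-state limit (see [simulate_model()]).
#'
#' @param params A `per2_params` object supplying `K_S`, `n`, `K_A`.
#' @param rate_scale RNAP recruitment rate `k_on` (per hour) used for both
#'   strands.
#' @return An object of class `per2_kinetics`: list with `k_on_S`,
#'   `k_off_S`, `k_on_A`, `k_off_A` (all per hour).
#' @export
full_kinetics <- function(params, rate_scale = 100) {
  params <- validate_parameters(params)
  if (!is.numeric(rate_scale) || length(rate_scale) != 1L ||
      !is.finite(rate_scale) || rate_scale <= 0)
    abort_validation("rate_scale must be a positive number")
  kin <- list(
    k_on_S = rate_scale,
    k_off_S = rate_scale * params$K_S^params$n,
    k_on_A = rate_scale,
    k_off_A = rate_scale * params$K_A
  )
  class(kin) <- "per2_kinetics"
  kin
}

#' Check kinetics/parameter consistency
#'
#' Verifies that explicit RNAP rates are strictly positive and reproduce
#' the quasi-steady-state ratios of a parameter set:
#' `k_off_S/k_on_S = K_S^n` and `k_off_A/k_on_A = K_A`.
#'
#' @param kin A `per2_kinetics` object.
#' @param params A `per2_params` object.
#' @param tol Relative tolerance on the two ratio identities.
#' @return `kin`, invisibly; raises a validation error on mismatch.
#' @export
validate_kinetics <- function(kin, params, tol = 1e-8) {
  params <- validate_parameters(params)
  fields <- c("k_on_S", "k_off_S", "k_on_A", "k_off_A")
  for (f in fields) {
    v <- kin[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      abort_validation(sprintf("kinetic rate '%s' must be a positive number", f))
  }
  rs <- kin$k_off_S / kin$k_on_S
  ra <- kin$k_off_A / kin$k_on_A
  if (abs(rs - params$K_S^params$n) > tol * max(1, params$K_S^params$n))
    abort_validation("k_off_S/k_on_S does not equal K_S^n")
  if (abs(ra - params$K_A) > tol * max(1, params$K_A))
    abort_validation("k_off_A/k_on_A does not equal K_A")
  invisible(kin)
}

.dim_fields <- c("v_SD", "mu_SD", "v_AD", "mu_AD", "g_SD", "eta_SD",
                 "f_S", "f_A", "n", "K_S", "K_A", "tau")

#' Dimensional parameter set
#'
#' The model is usually run in dimensionless concentrations (scaled by
#' `v_SD / mu_SD`, the Per2 transcription rate over its degradation rate),
#' but rate constants measured per hour can be supplied here and converted
#' with [nondimensionalize()].
#'
#' @param v_SD,mu_SD Per2 mRNA transcription and degradation rates (per hour).
#' @param v_AD,mu_AD Per2AS transcription and degradation rates (per hour).
#' @param g_SD,eta_SD PER2 translation and degradation rates (per hour).
#' @param f_S,f_A,n,K_S,K_A,tau Dimensionless fields as in
#'   [default_parameters()] (`tau` in hours).
#' @return An object of class `per2_dimensional`.
#' @export
dimensional_params <- function(v_SD, mu_SD, v_AD, mu_AD, g_SD, eta_SD,
                               f_S = 0, f_A = 0, n = 3, K_S = 0.3684,
                               K_A = 4.0, tau = 6.2) {
  dp <- list(v_SD = v_SD, mu_SD = mu_SD, v_AD = v_AD, mu_AD = mu_AD,
             g_SD = g_SD, eta_SD = eta_SD, f_S = f_S, f_A = f_A, n = n,
             K_S = K_S, K_A = K_A, tau = tau)
  for (f in .dim_fields) dp[[f]] <- .check_scalar(dp[[f]], f)
  for (f in c("v_SD", "mu_SD", "v_AD", "mu_AD", "g_SD", "eta_SD"))
    if (dp[[f]] <= 0)
      abort_validation(sprintf("dimensional rate '%s' must be > 0", f))
  class(dp) <- "per2_dimensional"
  dp
}

#' Nondimensionalize a dimensional parameter set
#'
#' Concentrations are rescaled by `v_SD / mu_SD`, which turns the rate
#' constants into the ratios `v_A = v_AD/v_SD`, `mu_A = mu_AD/mu_SD`,
#' `g_S = g_SD/mu_SD`, `eta_S = eta_SD/mu_SD`, while `mu_S = mu_SD` keeps
#' the per-hour timescale and `f_S`, `f_A`, `n`, `K_S`, `K_A`, `tau` carry
#' over unchanged. The concentration scale is recorded as an attribute so
#' trajectories can be converted back to dimensional units.
#'
#' @param dp A `per2_dimensional` object.
#' @return A `per2_params` object with attribute `concentration_scale`
#'   equal to `v_SD / mu_SD`.
#' @export
nondimensionalize <- function(dp) {
  if (!inherits(dp, "per2_dimensional"))
    dp <- do.call(dimensional_params, as.list(dp))
  params <- default_parameters(
    n = dp$n, f_S = dp$f_S, f_A = dp$f_A,
    mu_S = dp$mu_SD, K_S = dp$K_S,
    v_A = dp$v_AD / dp$v_SD, mu_A = dp$mu_AD / dp$mu_SD,
    K_A = dp$K_A, g_S = dp$g_SD / dp$mu_SD,
    eta_S = dp$eta_SD / dp$mu_SD, tau = dp$tau
  )
  attr(params, "concentration_scale") <- dp$v_SD / dp$mu_SD
  params
}
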