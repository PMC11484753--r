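# Parameter handling for the Per2/Per2AS transcriptional-interference model.
#
# All concentrations are dimensionless (scaled by the Per2 transcription/
# degradation ratio v_SD/mu_SD); time stays in hours, so mu_S carries the
# only remaining unit (per hour) and sets the system timescale.

.param_fields <- c("n", "f_S", "f_A", "mu_S", "K_S", "v_A", "mu_A",
                   "K_A", "g_S", "eta_S", "tau", "alpha")

abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("per2as_validation_error", "error")))
}

abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("per2as_config_error", "error")))
}

abort_domain <- function(msg) {
  stop(errorCondition(msg, class = c("per2as_domain_error", "error")))
}

.check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(sprintf("parameter '%s' must be a finite numeric scalar", name))
  as.numeric(x)
}

#' Validate a model parameter set
#'
#' Checks the domain constraints of every field of a [default_parameters()]
#' object: collision probabilities in \[0, 1\], strictly positive rates where
#' the model requires them, nonnegative delay and knock-down strength.
#' Validation is strict-fail: sweeps never silently leave the model's domain.
#'
#' @param params A list with the twelve model parameter fields.
#' @return The validated parameter set, invisibly classed `"per2_params"`.
#' @export
validate_parameters <- function(params) {
  missing <- setdiff(.param_fields, names(params))
  if (length(missing) > 0)
    abort_validation(paste0("missing parameter field(s): ",
                            paste(missing, collapse = ", ")))
  for (f in .param_fields) params[[f]] <- .check_scalar(params[[f]], f)
  chk <- function(ok, field, rule) {
    if (!ok) abort_validation(sprintf("parameter '%s' violates %s", field, rule))
  }
  chk(params$f_S >= 0 && params$f_S <= 1, "f_S", "0 <= f_S <= 1")
  chk(params$f_A >= 0 && params$f_A <= 1, "f_A", "0 <= f_A <= 1")
  chk(params$mu_S > 0,  "mu_S",  "mu_S > 0")
  chk(params$mu_A > 0,  "mu_A",  "mu_A > 0")
  chk(params$K_S > 0,   "K_S",   "K_S > 0")
  chk(params$K_A >= 0,  "K_A",   "K_A >= 0")
  chk(params$v_A >= 0,  "v_A",   "v_A >= 0")
  chk(params$g_S >= 0,  "g_S",   "g_S >= 0")
  chk(params$eta_S > 0, "eta_S", "eta_S > 0")
  chk(params$tau >= 0,  "tau",   "tau >= 0")
  chk(params$alpha >= 0, "alpha", "alpha >= 0")
  chk(params$n >= 1,    "n",     "n >= 1")
  params <- params[.param_fields]
  class(params) <- "per2_params"
  invisible(params)
}

#' Default model parameters with optional overrides
#'
#' Returns the reference parameter set of the dimensionless
#' Per2/Per2AS interference model: Hill exponent `n = 3`, Per2 mRNA
#' degradation `mu_S = log(2)/2` per hour (2 h half-life), `K_S = 0.3684`,
#' relative Per2AS transcription and degradation `v_A = mu_A = 1`,
#' RNAP detachment/recruitment ratio `K_A = 4`, PER2 translation
#' `g_S = 14/mu_S` (14 proteins per mRNA per hour, see
#' [translation_rate_per_hour()]), relative PER2 degradation `eta_S = 1`,
#' and delay `tau = 6.2` h from Per2 mRNA to repression-competent PER2.
#' The collision probabilities default to `f_S = f_A = 0` (no interference)
#' and the knock-down strength to `alpha = 0`.
#'
#' The translation-rate default is coupled to `mu_S`: overriding `mu_S`
#' without touching `g_S` recomputes `g_S = 14/mu_S` with the effective
#' `mu_S`, so the dimensional translation rate stays at 14 per hour.
#'
#' @param ... Named scalar overrides of any parameter field. Unknown names
#'   raise a configuration error; values violating the domain constraints
#'   raise a validation error naming the field.
#' @return An object of class `per2_params` (a named list of 12 numerics).
#' @examples
#' default_parameters()
#' default_parameters(f_S = 1, f_A = 1, K_A = 0.67)
#' @export
default_parameters <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]]))
    overrides <- overrides[[1L]]
  if (length(overrides) > 0 &&
      (is.null(names(overrides)) || any(names(overrides) == "")))
    abort_config("parameter overrides must be named")
  unknown <- setdiff(names(overrides), .param_fields)
  if (length(unknown) > 0)
    abort_config(paste0("unknown parameter name(s): ",
                        paste(unknown, collapse = ", "),
                        "; valid fields are: ",
                        paste(.param_fields, collapse = ", ")))
  mu_S <- if ("mu_S" %in% names(overrides))
    .check_scalar(overrides$mu_S, "mu_S") else log(2) / 2
  params <- list(
    n = 3, f_S = 0, f_A = 0,
    mu_S = mu_S, K_S = 0.3684,
    v_A = 1, mu_A = 1, K_A = 4.0,
    g_S = 14 / mu_S, eta_S = 1,
    tau = 6.2, alpha = 0
  )
  params[names(overrides)] <- overrides
  out <- validate_parameters(params)
  attr(out, "concentration_scale") <- attr(overrides, "concentration_scale")
  out
}

#' @export
print.per2_params <- function(x, ...) {
  cat("Per2/Per2AS interference model parameters\n")
  vals <- unlist(x[.param_fields])
  for (f in .param_fields)
    cat(sprintf("  %-6s %s\n", f, format(vals[[f]], digits = 6)))
  cs <- attr(x, "concentration_scale")
  if (!is.null(cs))
    cat(sprintf("  concentration scale v_SD/mu_SD = %s\n", format(cs)))
  invisible(x)
}

#' Per2 mRNA half-life under knock-down
#'
#' The shRNA knock-down adds first-order degradation `alpha * mu_S` to
#' Per2 mRNA, shortening its half-life to `log(2) / (mu_S * (1 + alpha))`.
#' At the defaults (`mu_S = log(2)/2`) this gives 2 h for `alpha = 0`
#' (control) and 0.4 h for `alpha = 4` (knock-down).
#'
#' @param params A `per2_params` object.
#' @return Half-life in hours.
#' @export
knockdown_half_life <- function(params) {
  params <- validate_parameters(params)
  log(2) / (params$mu_S * (1 + params$alpha))
}

#' Per-mRNA translation rate from elongation speed and protein length
#'
#' Number of complete proteins produced per hour from a single mRNA:
#' `floor(speed_aa_per_s * 3600 / protein_length_aa)`. For PER2
#' (1257 amino acids) at the average mammalian elongation speed of
#' 5 aa/s this gives 14 per hour, the basis of the `g_S = 14/mu_S` default.
#'
#' @param speed_aa_per_s Ribosome elongation speed, amino acids per second.
#' @param protein_length_aa Protein length in amino acids.
#' @return Integer proteins per hour (truncated).
#' @export
translation_rate_per_hour <- function(speed_aa_per_s, protein_length_aa) {
  if (!is.numeric(speed_aa_per_s) || length(speed_aa_per_s) != 1L ||
      !is.finite(speed_aa_per_s) || speed_aa_per_s <= 0)
    abort_domain("speed_aa_per_s must be a positive number")
  if (!is.numeric(protein_length_aa) || length(protein_length_aa) != 1L ||
      !is.finite(protein_length_aa) || protein_length_aa <= 0)
    abort_domain("protein_length_aa must be a positive number")
  as.integer(floor(speed_aa_per_s * 3600 / protein_length_aa))
}

#' Read / write parameter sets as flat YAML mappings
#'
#' Parameters serialize to a flat key-value mapping whose keys are exactly
#' the twelve field names of [default_parameters()]. Unknown keys in a file
#' are rejected; omitted keys fall back to the defaults (with the `g_S`
#' coupling to `mu_S` preserved).
#'
#' @param path File path of the YAML mapping.
#' @param params A `per2_params` object.
#' @return `read_parameters()` returns a `per2_params` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals))
    abort_config(sprintf("'%s' does not contain a key-value mapping", path))
  do.call(default_parameters, vals)
}

#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  params <- validate_parameters(params)
  yaml::write_yaml(unclass(params)[.param_fields], path, precision = 15L)
  invisible(path)
}
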