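# Closed-form load-relaxation predictors for the four constitutive models,
# valid under a constant hold angle theta0.  Angle units are degrees
# throughout (stiffness Nm/deg); no radian conversion is performed.

#' Standard linear solid (SLS) parameters
#'
#' A Kelvin solid with one Maxwell branch: a torsional spring `k_maxwell`
#' (Nm/deg) in series with a damper `c_damper` (Nm s/deg), the pair in
#' parallel with a spring `k_parallel` (Nm/deg).  The relaxation time
#' constant `tau = c_damper / k_maxwell` is stored derived; the damper
#' coefficient is the primary parameter because sensitivity tables report
#' the damping coefficient as its own row.
#'
#' @param k_maxwell Maxwell-branch spring stiffness, Nm/deg (> 0).
#' @param k_parallel Parallel (steady-state) spring stiffness, Nm/deg (> 0).
#' @param c_damper Damper coefficient, Nm s/deg (> 0).  Exactly one of
#'   `c_damper` and `tau` must be given.
#' @param tau Relaxation time constant, s; alternative to `c_damper`.
#' @return An object of class `c("sls_params", "model_params")`.
#' @export
sls_params <- function(k_maxwell, k_parallel, c_damper = NULL, tau = NULL) {
  if (is.null(c_damper) == is.null(tau))
    stop("give exactly one of `c_damper` and `tau`")
  if (is.null(c_damper)) c_damper <- tau * k_maxwell
  p <- structure(list(k_maxwell = k_maxwell, k_parallel = k_parallel,
                      c_damper = c_damper, tau = c_damper / k_maxwell),
                 class = c("sls_params", "model_params"))
  validate_params(p)
}

#' Prony-series (Wiechert) parameters
#'
#' Generalized Maxwell model: steady-state spring `k_inf` in parallel with
#' `n` Maxwell branches of stiffness `k[i]` and relaxation time `tau[i]`.
#' Branches are stored sorted by ascending time constant so that branch
#' labels are identifiable.
#'
#' @param k_inf Steady-state stiffness, Nm/deg (> 0).
#' @param k Branch stiffnesses, Nm/deg (> 0), one per branch.
#' @param tau Branch relaxation time constants, s (> 0), distinct.
#' @param n_max Maximum number of branches accepted (default 4).
#' @return An object of class `c("prony_params", "model_params")`.
#' @export
prony_params <- function(k_inf, k, tau, n_max = 4L) {
  if (length(k) != length(tau)) stop("`k` and `tau` must have equal length")
  if (length(k) < 1L || length(k) > n_max)
    stop("number of Maxwell branches must be in 1..", n_max)
  ord <- order(tau)
  p <- structure(list(k_inf = k_inf, k = k[ord], tau = tau[ord]),
                 class = c("prony_params", "model_params"))
  validate_params(p)
}

#' Schapery power-law parameters
#'
#' Relaxation form `M(t) = theta0 * (k_eq + c1 * t^(-c2))` with `k_eq` the
#' torsional stiffness at equilibrium (fixed from the final data point when
#' fitting) and `c1`, `c2` curve-fit constants.
#'
#' @param k_eq Equilibrium stiffness, Nm/deg (>= 0).
#' @param c1 Power-law amplitude, Nm/(deg s^-c2) (>= 0).
#' @param c2 Dimensionless power-law exponent (>= 0).
#' @return An object of class `c("schapery_params", "model_params")`.
#' @export
schapery_params <- function(k_eq, c1, c2) {
  p <- structure(list(k_eq = k_eq, c1 = c1, c2 = c2),
                 class = c("schapery_params", "model_params"))
  validate_params(p)
}

#' Modified superposition method (MSM) parameters
#'
#' Relaxation form `M(t) = theta0 * k0 * t^(-beta)`: `k0` is the torsional
#' stiffness at the start of load-relaxation (t = 1 s anchor) and `beta`
#' the initial relaxation rate.
#'
#' @param k0 Stiffness at the start of relaxation, Nm/deg (> 0).
#' @param beta Dimensionless initial relaxation rate (>= 0).
#' @return An object of class `c("msm_params", "model_params")`.
#' @export
msm_params <- function(k0, beta) {
  p <- structure(list(k0 = k0, beta = beta),
                 class = c("msm_params", "model_params"))
  validate_params(p)
}

validate_params <- function(p) UseMethod("validate_params")

#' @export
validate_params.sls_params <- function(p) {
  stopifnot(is.numeric(p$k_maxwell), length(p$k_maxwell) == 1L)
  if (!(p$k_maxwell > 0 && p$k_parallel > 0 && p$c_damper > 0))
    stop("SLS parameters must all be strictly positive")
  p
}

#' @export
validate_params.prony_params <- function(p) {
  if (!(p$k_inf > 0 && all(p$k > 0) && all(p$tau > 0)))
    stop("Prony parameters must all be strictly positive")
  if (any(diff(p$tau) <= 0))
    stop("Prony time constants must be distinct")
  p
}

#' @export
validate_params.schapery_params <- function(p) {
  if (p$k_eq < 0 || p$c1 < 0 || p$c2 < 0)
    stop("Schapery parameters must be non-negative")
  p
}

#' @export
validate_params.msm_params <- function(p) {
  if (!(p$k0 > 0) || p$beta < 0)
    stop("MSM requires k0 > 0 and beta >= 0")
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1L]))
  for (nm in names(x))
    cat(sprintf("  %-10s %s\n", nm,
                paste(signif(unlist(x[[nm]]), 6), collapse = ", ")))
  invisible(x)
}

check_time <- function(t, t_min = 0) {
  if (any(!is.finite(t))) stop("non-finite times")
  if (any(t < t_min))
    stop(sprintf("times must be >= %g s for this model", t_min))
}

#' Predicted SLS relaxation moment
#'
#' `M(t) = theta0 * (k_parallel + k_maxwell * exp(-t/tau))`, the moment of a
#' standard linear solid held at a constant flexion angle `theta0` from
#' t = 0.
#'
#' @param t Time since hold onset, s (>= 0), vectorized.
#' @param theta0 Hold angle, deg (> 0).
#' @param p An [sls_params()] object.
#' @return Moment, Nm, same length as `t`.
#' @export
predict_sls <- function(t, theta0, p) {
  stopifnot(inherits(p, "sls_params"), theta0 > 0)
  check_time(t)
  theta0 * (p$k_parallel + p$k_maxwell * exp(-t / p$tau))
}

#' Predicted Prony-series relaxation moment
#'
#' `M(t) = theta0 * (k_inf + sum_i k_i * exp(-t/tau_i))`.
#'
#' @inheritParams predict_sls
#' @param p A [prony_params()] object.
#' @return Moment, Nm.
#' @export
predict_prony <- function(t, theta0, p) {
  stopifnot(inherits(p, "prony_params"), theta0 > 0)
  check_time(t)
  decay <- vapply(seq_along(p$k),
                  function(i) p$k[i] * exp(-t / p$tau[i]),
                  numeric(length(t)))
  theta0 * (p$k_inf + if (length(t) == 1L) sum(decay) else rowSums(decay))
}

#' Predicted Schapery power-law relaxation moment
#'
#' `M(t) = theta0 * (k_eq + c1 * t^(-c2))`, evaluated for t >= `t_min`
#' (default 1 s) since the power law diverges at t = 0.
#'
#' @inheritParams predict_sls
#' @param p A [schapery_params()] object.
#' @param t_min Smallest admissible time, s.
#' @return Moment, Nm.
#' @export
predict_schapery <- function(t, theta0, p, t_min = 1) {
  stopifnot(inherits(p, "schapery_params"), theta0 > 0)
  check_time(t, t_min)
  theta0 * (p$k_eq + p$c1 * t^(-p$c2))
}

#' Predicted modified-superposition relaxation moment
#'
#' `M(t) = theta0 * k0 * t^(-beta)`, evaluated for t >= `t_min` (default
#' 1 s).
#'
#' @inheritParams predict_schapery
#' @param p An [msm_params()] object.
#' @return Moment, Nm.
#' @export
predict_msm <- function(t, theta0, p, t_min = 1) {
  stopifnot(inherits(p, "msm_params"), theta0 > 0)
  check_time(t, t_min)
  theta0 * p$k0 * t^(-p$beta)
}

#' Dispatching relaxation predictor
#'
#' Evaluates the closed-form relaxation moment of any supported parameter
#' object at times `t` and hold angle `theta0`.
#'
#' @inheritParams predict_sls
#' @param p A `model_params` object of any family.
#' @param ... Passed to the family predictor (e.g. `t_min`).
#' @return Moment, Nm.
#' @export
predict_moment <- function(t, theta0, p, ...) {
  switch(class(p)[1L],
         sls_params      = predict_sls(t, theta0, p),
         prony_params    = predict_prony(t, theta0, p),
         schapery_params = predict_schapery(t, theta0, p, ...),
         msm_params      = predict_msm(t, theta0, p, ...),
         stop("unknown model parameter class: ", class(p)[1L]))
}

model_kind <- function(p) {
  switch(class(p)[1L],
         sls_params = "sls", prony_params = "prony",
         schapery_params = "schapery", msm_params = "msm",
         stop("unknown model parameter class"))
}

# power-law families are only defined for t >= 1 s (time zeroed at hold onset)
model_t_min <- function(kind) if (kind %in% c("schapery", "msm")) 1 else 0

#' Serialize model parameters to JSON
#'
#' Writes the parameter values together with explicit unit strings so that
#' files are self-describing.
#'
#' @param p A `model_params` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when `path` given).
#' @export
params_to_json <- function(p, path = NULL) {
  units <- switch(class(p)[1L],
    sls_params = list(k_maxwell = "Nm/deg", k_parallel = "Nm/deg",
                      c_damper = "Nm*s/deg", tau = "s"),
    prony_params = list(k_inf = "Nm/deg", k = "Nm/deg", tau = "s"),
    schapery_params = list(k_eq = "Nm/deg", c1 = "Nm/deg*s^c2",
                           c2 = "dimensionless"),
    msm_params = list(k0 = "Nm/deg", beta = "dimensionless"))
  obj <- list(model = model_kind(p), params = unclass(p), units = units)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read model parameters from JSON
#'
#' @param x JSON string or file path produced by [params_to_json()].
#' @return A `model_params` object.
#' @export
params_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  pp <- obj$params
  switch(obj$model,
         sls = sls_params(pp$k_maxwell, pp$k_parallel, pp$c_damper),
         prony = prony_params(pp$k_inf, pp$k, pp$tau),
         schapery = schapery_params(pp$k_eq, pp$c1, pp$c2),
         msm = msm_params(pp$k0, pp$beta),
         stop("unknown model kind in JSON: ", obj$model))
}
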