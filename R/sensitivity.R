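# Dimensionless parameter-sensitivity coefficients of the model-predicted
# initial moment and moment drop, and angle-dependence trend fits
# (linear / exponential / exponential-through-origin) for cohort outcomes.

param_ids <- function(p) {
  switch(class(p)[1L],
         sls_params = c("k_maxwell", "k_parallel", "c_damper"),
         prony_params = c("k_inf", paste0("k", seq_along(p$k)),
                          paste0("tau", seq_along(p$tau))),
         schapery_params = c("k_eq", "c1", "c2"),
         msm_params = c("k0", "beta"))
}

get_param <- function(p, id) {
  if (inherits(p, "prony_params") && grepl("^(k|tau)[0-9]+$", id)) {
    i <- as.integer(sub("^[a-z]+", "", id))
    slot <- sub("[0-9]+$", "", id)
    return(p[[slot]][i])
  }
  p[[id]]
}

set_param <- function(p, id, value) {
  if (inherits(p, "prony_params") && grepl("^(k|tau)[0-9]+$", id)) {
    i <- as.integer(sub("^[a-z]+", "", id))
    slot <- sub("[0-9]+$", "", id)
    p[[slot]][i] <- value
    # bypass the ascending-tau reorder so branch identity is preserved
    return(structure(unclass(p), class = class(p)))
  }
  if (inherits(p, "sls_params") && id == "c_damper") {
    return(sls_params(p$k_maxwell, p$k_parallel, c_damper = value))
  }
  if (inherits(p, "sls_params") && id == "k_maxwell") {
    # damper coefficient held fixed; tau = c/k1 changes accordingly
    return(sls_params(value, p$k_parallel, c_damper = p$c_damper))
  }
  p[[id]] <- value
  p
}

# model-predicted outcome: initial moment is the moment at the start of the
# relaxation phase (t = 0 for the exponential models, t = 1 s for the
# power-law models, where their forms are first defined); moment drop is
# initial minus the moment at the horizon.  window_s > 0 switches to
# means over [t_start, t_start + window_s) and [horizon - window_s,
# horizon), matching the measurement-side 3-s windows.
predicted_outcome <- function(p, outcome, theta0, horizon, window_s = 0) {
  t_start <- model_t_min(model_kind(p))
  mom <- function(tt) predict_moment(tt, theta0, p)
  if (window_s > 0) {
    grid <- function(a, b) seq(a, b, length.out = 301L)
    m0 <- mean(mom(grid(t_start, t_start + window_s)))
    m1 <- mean(mom(grid(horizon - window_s, horizon)))
  } else {
    m0 <- mom(t_start)
    m1 <- mom(horizon)
  }
  switch(outcome,
         initial_moment = m0,
         moment_drop = m0 - m1,
         stop("outcome must be 'initial_moment' or 'moment_drop'"))
}

#' Sensitivity specification
#'
#' Describes one dimensionless sensitivity computation: which parameter of
#' which model is varied over which range, and which predicted outcome is
#' observed.
#'
#' @param nominal_params A `model_params` object holding the nominal
#'   (cohort-mean) parameter values.
#' @param param_id Parameter to vary; one of the ids listed by the model
#'   family (`"k_maxwell"`, `"k_parallel"`, `"c_damper"` for SLS;
#'   `"k_inf"`, `"k1"`, `"tau1"`, ... for Prony; `"k_eq"`, `"c1"`, `"c2"`
#'   for Schapery; `"k0"`, `"beta"` for MSM).
#' @param outcome `"initial_moment"` or `"moment_drop"`.
#' @param low,high Parameter range (cohort range), in the parameter's
#'   units; `low < high`.
#' @param theta0 Hold angle, deg.
#' @param horizon Hold duration used for the moment drop, s (default 960).
#' @param window_s Outcome evaluation window, s.  0 (default) evaluates
#'   the closed form at the window start, which preserves the exact
#'   analytic zeros of time-constant parameters; > 0 averages over the
#'   window as in [summarize_relaxation()].
#' @return A `sensitivity_spec`.
#' @export
sensitivity_spec <- function(nominal_params, param_id,
                             outcome = c("initial_moment", "moment_drop"),
                             low, high, theta0, horizon = 960,
                             window_s = 0) {
  stopifnot(inherits(nominal_params, "model_params"),
            low < high, theta0 > 0, horizon > 0, window_s >= 0)
  outcome <- match.arg(outcome)
  if (!param_id %in% param_ids(nominal_params))
    stop("unknown parameter '", param_id, "' for ",
         class(nominal_params)[1L])
  structure(list(nominal_params = nominal_params, param_id = param_id,
                 outcome = outcome, low = low, high = high,
                 theta0 = theta0, horizon = horizon, window_s = window_s),
            class = "sensitivity_spec")
}

#' Dimensionless sensitivity coefficient
#'
#' Evaluates the predicted outcome at both endpoints of the parameter
#' range (all other parameters at nominal) and forms
#' `SC = (|dR| / R_nominal) / ((high - low) / p_nominal)`,
#' the normalized outcome range over the normalized parameter range.  The
#' absolute value is reported.  The two textbook normalizations
#' `(dR/R)/(dp/p)` and `(dR/dp)(p/R)` are algebraically identical.
#'
#' @param spec A [sensitivity_spec()].
#' @return An object of class `sensitivity_result`: `sc` (dimensionless),
#'   `delta_R` (outcome units), `R_nominal`, `defined` (`FALSE` when the
#'   nominal outcome is zero).
#' @export
sensitivity_coefficient <- function(spec) {
  stopifnot(inherits(spec, "sensitivity_spec"))
  p_nom <- get_param(spec$nominal_params, spec$param_id)
  R_nom <- predicted_outcome(spec$nominal_params, spec$outcome,
                             spec$theta0, spec$horizon, spec$window_s)
  R_lo <- predicted_outcome(set_param(spec$nominal_params, spec$param_id,
                                      spec$low),
                            spec$outcome, spec$theta0, spec$horizon,
                            spec$window_s)
  R_hi <- predicted_outcome(set_param(spec$nominal_params, spec$param_id,
                                      spec$high),
                            spec$outcome, spec$theta0, spec$horizon,
                            spec$window_s)
  delta_R <- abs(R_hi - R_lo)
  defined <- R_nom != 0
  sc <- if (defined)
    (delta_R / abs(R_nom)) / ((spec$high - spec$low) / abs(p_nom))
  else NA_real_
  structure(list(sc = sc, delta_R = delta_R, R_nominal = R_nom,
                 defined = defined),
            class = "sensitivity_result")
}

#' Sensitivity table for a model family
#'
#' Computes the sensitivity coefficient of every parameter of a model with
#' respect to both the initial moment and the moment drop, mirroring a
#' model-by-parameter sensitivity table.
#'
#' @param nominal_params A `model_params` object (nominal values).
#' @param ranges Named list of `c(low, high)` ranges, one per parameter id;
#'   parameters without an entry default to nominal +/- 50%.
#' @inheritParams sensitivity_spec
#' @return data.frame with columns `model`, `parameter`, `sc_initial`,
#'   `sc_drop`.
#' @export
sensitivity_table <- function(nominal_params, ranges = list(), theta0,
                              horizon = 960, window_s = 0) {
  ids <- param_ids(nominal_params)
  rows <- lapply(ids, function(id) {
    rg <- ranges[[id]]
    if (is.null(rg)) {
      nom <- get_param(nominal_params, id)
      rg <- c(0.5 * nom, 1.5 * nom)
      if (rg[1] == rg[2]) rg <- c(nom, nom + 1)
    }
    sc_of <- function(outc)
      sensitivity_coefficient(sensitivity_spec(nominal_params, id, outc,
                                               rg[1], rg[2], theta0,
                                               horizon, window_s))$sc
    data.frame(model = model_kind(nominal_params), parameter = id,
               sc_initial = sc_of("initial_moment"),
               sc_drop = sc_of("moment_drop"))
  })
  do.call(rbind, rows)
}

#' Fit an angle-dependence trend to cohort outcomes
#'
#' Least-squares fit of cohort-mean outcomes against lumbar flexion level
#' (%FR).  Families: `"linear"` (`y = a + b x`), `"exponential"`
#' (`y = a exp(b x)`), and `"exponential_through_origin"`
#' (`y = a (exp(b x) - 1)`, which passes through (0, 0) so the origin can
#' be included as a data point).  Zero flexion produces zero moment, which
#' a plain exponential cannot represent.
#'
#' @param x Flexion levels (%FR or deg).
#' @param y Cohort-mean outcome at each level.
#' @param family Trend family.
#' @param include_origin Prepend the point (0, 0) before fitting.
#' @return An object of class `trend_fit`: `family`, `coefficients`
#'   (named), `r2`, `fitted`, `degenerate` (`TRUE` when the trend is flat
#'   and the exponential rate is pinned at ~0).
#' @export
fit_angle_trend <- function(x, y,
                            family = c("linear", "exponential",
                                       "exponential_through_origin"),
                            include_origin = FALSE) {
  family <- match.arg(family)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite inputs to trend fit")
  if (include_origin) { x <- c(0, x); y <- c(0, y) }
  if (length(x) < 3L) stop("need at least 3 points (after origin augmentation)")
  degenerate <- FALSE
  if (family != "linear" && stats::sd(y) == 0) {
    # flat trend: the exponential rate degenerates to the b -> 0 limit
    a <- if (family == "exponential") mean(y) else 0
    return(structure(list(family = family,
                          coefficients = c(a = a, b = 0),
                          r2 = NA_real_, fitted = rep(mean(y), length(y)),
                          degenerate = TRUE),
                     class = "trend_fit"))
  }
  if (family == "linear") {
    fit <- stats::lm(y ~ x)
    co <- stats::coef(fit)
    coefficients <- c(intercept = unname(co[1]), slope = unname(co[2]))
    fitted <- unname(stats::fitted(fit))
  } else if (family == "exponential") {
    pos <- y > 0
    seed <- if (sum(pos) >= 2L) stats::coef(stats::lm(log(y[pos]) ~ x[pos]))
            else c(log(max(mean(y), 1e-6)), 0.01)
    fit <- minpack.lm::nlsLM(y ~ a * exp(b * x),
                             start = list(a = exp(seed[[1]]), b = seed[[2]]),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- stats::coef(fit)
    coefficients <- c(a = unname(co["a"]), b = unname(co["b"]))
    fitted <- unname(stats::fitted(fit))
    degenerate <- abs(co["b"]) < 1e-8
  } else {
    a0 <- max(mean(y) / max(mean(x), 1), 1e-6)
    fit <- minpack.lm::nlsLM(y ~ a * (exp(b * x) - 1),
                             start = list(a = a0, b = 0.02),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    co <- stats::coef(fit)
    coefficients <- c(a = unname(co["a"]), b = unname(co["b"]))
    fitted <- unname(stats::fitted(fit))
    degenerate <- abs(co["b"]) < 1e-8
  }
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - fitted)^2)
  structure(list(family = family, coefficients = coefficients,
                 r2 = if (sst > 0) 1 - sse / sst else NA_real_,
                 fitted = fitted, degenerate = degenerate),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s: %s; R^2 = %s%s\n", x$family,
              paste(sprintf("%s = %.5g", names(x$coefficients),
                            x$coefficients), collapse = ", "),
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2)),
              if (x$degenerate) " (degenerate: flat trend)" else ""))
  invisible(x)
}
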