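# Dimensionless sensitivity coefficients and angle-trend fits.

test_that("time-constant sensitivities w.r.t. initial moment are exactly 0", {
  # any Kelvin-solid time-constant parameter leaves the instantaneous
  # stiffness unchanged, so the coefficient is 0 with no tolerance
  pr <- prony_fixture()
  for (id in c("tau1", "tau2")) {
    sc <- sensitivity_coefficient(
      sensitivity_spec(pr, id, "initial_moment", low = 1, high = 2000,
                       theta0 = 58, horizon = 960))
    expect_identical(sc$sc, 0)
  }
  sc_sls <- sensitivity_coefficient(
    sensitivity_spec(sls_fixture(), "c_damper", "initial_moment",
                     low = 10, high = 200, theta0 = 30))
  expect_identical(sc_sls$sc, 0)
  # power-law exponents do not move the t = 1 s anchor either
  sc_sch <- sensitivity_coefficient(
    sensitivity_spec(schapery_params(1, 0.5, 0.3), "c2", "initial_moment",
                     low = 0.1, high = 0.5, theta0 = 30))
  expect_identical(sc_sch$sc, 0)
  sc_msm <- sensitivity_coefficient(
    sensitivity_spec(msm_params(1.5, 0.05), "beta", "initial_moment",
                     low = 0.01, high = 0.2, theta0 = 30))
  expect_identical(sc_msm$sc, 0)
})

test_that("SLS parallel stiffness has zero moment-drop sensitivity", {
  sc <- sensitivity_coefficient(
    sensitivity_spec(sls_fixture(), "k_parallel", "moment_drop",
                     low = 0.5, high = 1.5, theta0 = 10, horizon = 960))
  expect_identical(sc$sc, 0)
})

test_that("SLS Maxwell-stiffness drop sensitivity matches direct evaluation", {
  # independent arithmetic: drop(k1) = theta0 k1 (1 - e^(-960 k1 / C)),
  # damper C = 50 Nm s/deg held fixed while k1 varies
  p <- sls_fixture()
  drop_of <- function(k1) {
    tau <- p$c_damper / k1
    10 * k1 * (1 - exp(-960 / tau))
  }
  delta_R <- abs(drop_of(0.75) - drop_of(0.25))
  R_nom <- drop_of(0.5)
  sc_expected <- (delta_R / R_nom) / ((0.75 - 0.25) / 0.5)
  sc <- sensitivity_coefficient(
    sensitivity_spec(p, "k_maxwell", "moment_drop",
                     low = 0.25, high = 0.75, theta0 = 10, horizon = 960))
  expect_equal(sc$sc, sc_expected, tolerance = 1e-12)
  expect_equal(sc$delta_R, delta_R, tolerance = 1e-12)
})

test_that("sensitivity coefficients are dimensionless under unit rescaling", {
  deg2rad <- pi / 180
  pr <- prony_fixture()
  pr_rad <- prony_params(pr$k_inf / deg2rad, pr$k / deg2rad, pr$tau)
  for (outc in c("initial_moment", "moment_drop")) {
    sc_deg <- sensitivity_coefficient(
      sensitivity_spec(pr, "k1", outc, low = 0.1, high = 0.5,
                       theta0 = 30, horizon = 960))$sc
    sc_rad <- sensitivity_coefficient(
      sensitivity_spec(pr_rad, "k1", outc, low = 0.1 / deg2rad,
                       high = 0.5 / deg2rad, theta0 = 30 * deg2rad,
                       horizon = 960))$sc
    expect_equal(sc_deg, sc_rad, tolerance = 1e-12)
  }
})

test_that("zero nominal outcome flags the coefficient undefined", {
  flat <- msm_params(1.5, 0)   # no relaxation: moment drop is 0
  sc <- sensitivity_coefficient(
    sensitivity_spec(flat, "k0", "moment_drop", low = 1, high = 2,
                     theta0 = 10))
  expect_false(sc$defined)
  expect_true(is.na(sc$sc))
})

test_that("sensitivity_table covers every parameter of each family", {
  tab <- sensitivity_table(prony_fixture(), theta0 = 58, horizon = 960)
  expect_setequal(tab$parameter, c("k_inf", "k1", "k2", "tau1", "tau2"))
  expect_equal(tab$sc_initial[tab$parameter %in% c("tau1", "tau2")],
               c(0, 0))
  # stiffnesses partition the initial moment: sc = k_i / k_total
  k_tot <- 1.0 + 0.3 + 0.2
  expect_equal(tab$sc_initial[tab$parameter == "k_inf"], 1.0 / k_tot,
               tolerance = 1e-9)
  # the slow branch dominates the drop over a 960-s horizon
  sc_tau <- tab$sc_drop[match(c("tau1", "tau2"), tab$parameter)]
  expect_lt(sc_tau[1], sc_tau[2])
})

test_that("window-averaged outcomes approximate the point evaluation", {
  sc_pt <- sensitivity_coefficient(
    sensitivity_spec(prony_fixture(), "k1", "moment_drop",
                     low = 0.1, high = 0.5, theta0 = 30, horizon = 960))$sc
  sc_win <- sensitivity_coefficient(
    sensitivity_spec(prony_fixture(), "k1", "moment_drop",
                     low = 0.1, high = 0.5, theta0 = 30, horizon = 960,
                     window_s = 3))$sc
  expect_equal(sc_win, sc_pt, tolerance = 0.05)
})

test_that("exact exponential-through-origin data are recovered", {
  x <- c(30, 40, 60, 80, 100)
  y <- 2 * (exp(0.03 * x) - 1)
  f <- fit_angle_trend(x, y, "exponential_through_origin",
                       include_origin = TRUE)
  expect_equal(unname(f$coefficients["a"]), 2, tolerance = 1e-6)
  expect_equal(unname(f$coefficients["b"]), 0.03, tolerance = 1e-6)
  expect_equal(f$r2, 1.0, tolerance = 1e-9)
})

test_that("linear and plain-exponential fits behave on simple data", {
  x <- c(30, 40, 60, 80, 100)
  f_lin <- fit_angle_trend(x, 2 + 0.5 * x, "linear")
  expect_equal(unname(f_lin$coefficients["slope"]), 0.5, tolerance = 1e-9)
  f_exp <- fit_angle_trend(x, 3 * exp(0.02 * x), "exponential")
  expect_equal(unname(f_exp$coefficients["b"]), 0.02, tolerance = 1e-6)
  # constant outcomes: flat linear fit, degenerate exponential rate
  f_const <- fit_angle_trend(x, rep(4, 5), "linear")
  expect_equal(unname(f_const$coefficients["slope"]), 0, tolerance = 1e-9)
  f_deg <- fit_angle_trend(x, rep(4, 5), "exponential")
  expect_true(f_deg$degenerate)
  expect_error(fit_angle_trend(c(x, NA), c(2 + 0.5 * x, 1), "linear"),
               "non-finite")
})

test_that("synthetic cohort means trend exponentially with flexion angle", {
  truth <- ground_truth_spec(force_noise_sd = 0, angle_noise_sd = 0)
  fr <- c(0.30, 0.40, 0.60, 0.80, 1.00)
  m0 <- vapply(fr, function(f) {
    tr <- generate_trial(protocol_spec(58.2, f, hold_duration = 30),
                         truth, seed = 1)
    al <- resample_align(tr)
    summarize_relaxation(al, segment_phases(al))$initial_moment
  }, numeric(1))
  f_exp <- fit_angle_trend(100 * fr, m0, "exponential_through_origin",
                           include_origin = TRUE)
  f_lin <- fit_angle_trend(100 * fr, m0, "linear", include_origin = TRUE)
  expect_gt(f_exp$r2, f_lin$r2)
  expect_gt(f_exp$r2, 0.93)
})
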