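# Hereditary-integral oracle and the seeded trial/cohort generators.

test_that("oracle matches the closed forms under a step-angle history", {
  t <- seq(0, 960, by = 0.1)
  for (p in list(sls_fixture(), prony_fixture())) {
    m_or <- truth_moment(clean_truth(p), t, rep(10, length(t)))
    m_cf <- predict_moment(t, 10, p)
    expect_lt(max(abs(m_or - m_cf) / m_cf), 1e-6)
  }
})

test_that("oracle limit cases: zero history and the elastic limit", {
  t <- seq(0, 100, by = 0.01)
  expect_equal(truth_moment(clean_truth(prony_fixture()), t,
                            rep(0, length(t))),
               rep(0, length(t)))
  # pure parallel spring: loading and unloading branches coincide
  spring <- clean_truth(sls_params(k_maxwell = 1e-12, k_parallel = 1,
                                   tau = 10))
  tri <- c(seq(0, 10, by = 0.01), seq(10 - 0.01, 0, by = -0.01))
  tt <- seq_along(tri) * 0.01
  m <- truth_moment(spring, tt, tri)
  up <- m[seq_len(1001)]
  down <- rev(m)[seq_len(1001)]
  expect_equal(up, down, tolerance = 1e-9)
})

test_that("halving the grid step changes the oracle by < 1e-4 relative", {
  truth <- clean_truth(prony_fixture())
  for (dt in c(0.1, 0.05)) {
    t1 <- seq(0, 120, by = dt)
    t2 <- seq(0, 120, by = dt / 2)
    ang1 <- trunkrelax:::trapezoid_angle(t1, 30, 3, 60)
    ang2 <- trunkrelax:::trapezoid_angle(t2, 30, 3, 60)
    m1 <- truth_moment(truth, t1, ang1)
    m2 <- truth_moment(truth, t2, ang2)[seq(1, length(t2), by = 2)]
    scale <- max(m1)
    expect_lt(max(abs(m1 - m2)) / scale, 1e-4)
  }
})

test_that("oracle agrees with independent ODE integration of the branches", {
  # independent route: deSolve integration of h' = -h/tau + k dtheta/dt
  p <- prony_fixture()
  truth <- clean_truth(p)
  hold <- 60; theta0 <- 30; rate <- 3
  t <- seq(0, 2 * theta0 / rate + hold, by = 0.05)
  ang <- trunkrelax:::trapezoid_angle(t, theta0, rate, hold)
  dtheta_dt <- function(tt) {
    t_ramp <- theta0 / rate
    ifelse(tt < t_ramp, rate,
           ifelse(tt < t_ramp + hold, 0, -rate))
  }
  deriv <- function(tt, y, parms)
    list(-y / p$tau + p$k * dtheta_dt(tt))
  sol <- deSolve::lsoda(c(0, 0), t, deriv, NULL, rtol = 1e-10,
                        atol = 1e-12)
  m_ode <- p$k_inf * ang + sol[, 2] + sol[, 3]
  m_or <- truth_moment(truth, t, ang)
  expect_lt(max(abs(m_or - pmax(m_ode, 0))) / max(m_or), 1e-5)
})

test_that("oracle rejects bad input", {
  truth <- clean_truth(sls_fixture())
  expect_error(truth_moment(truth, c(0, 1, 3), c(0, 1, 2)), "uniform")
  expect_error(ground_truth_spec(schapery_params(1, 0.5, 0.3)),
               "Kelvin-solid")
})

test_that("trial generation is seed-deterministic with the right duration", {
  prot <- quick_protocol()
  truth <- ground_truth_spec()
  t1 <- generate_trial(prot, truth, seed = 1)
  t2 <- generate_trial(prot, truth, seed = 1)
  expect_identical(t1[c("angle", "force", "angle_time", "force_time")],
                   t2[c("angle", "force", "angle_time", "force_time")])
  t3 <- generate_trial(prot, truth, seed = 2)
  expect_false(identical(t1$force, t3$force))
  # duration = 2 x ramp + hold, to within one sample
  theta0 <- prot$target_fraction_FR * prot$FR_angle
  expected <- 2 * theta0 / prot$ramp_rate + prot$hold_duration
  expect_equal(max(t1$force_time), expected, tolerance = 1e-3)
  expect_equal(max(t1$angle_time), expected, tolerance = 1e-2)
})

test_that("noise-free trial hold matches the closed form", {
  prot <- quick_protocol(fraction = 0.6, hold = 120, FR = 50)
  p <- sls_fixture()
  tr <- generate_trial(prot, clean_truth(p), seed = 1)
  theta0 <- 30
  t_ramp <- theta0 / 3
  hold_idx <- tr$force_time >= t_ramp & tr$force_time <= t_ramp + 120
  m <- tr$force[hold_idx] * tr$moment_arm
  t_hold <- tr$force_time[hold_idx] - t_ramp
  # ramp-aware closed form: the Maxwell branch reaches
  # k rate tau (1 - exp(-t_ramp/tau)) at hold onset and then decays
  h0 <- p$k_maxwell * 3 * p$tau * (1 - exp(-t_ramp / p$tau))
  m_cf <- theta0 * p$k_parallel + h0 * exp(-t_hold / p$tau)
  expect_lt(max(abs(m - m_cf)) / max(m_cf), 1e-6)
  # the step closed form is an upper bound during the hold
  expect_true(all(m <= predict_sls(t_hold, theta0, p) + 1e-9))
})

test_that("hold angles inside the neutral zone are rejected", {
  prot <- protocol_spec(FR_angle = 30, target_fraction_FR = 0.3,
                        hold_duration = 60)
  expect_error(generate_trial(prot, ground_truth_spec(nz_width = 10),
                              seed = 1),
               "neutral zone")
})

test_that("cohorts have one trial per subject x fraction, reproducibly", {
  co <- generate_cohort(4, c(0.6, 1.0), seed = 11, hold_duration = 30)
  expect_length(co$trials, 8)
  co2 <- generate_cohort(4, c(0.6, 1.0), seed = 11, hold_duration = 30)
  expect_identical(co$trials[[3]]$force, co2$trials[[3]]$force)
  expect_error(generate_cohort(4, numeric(0)), "non-empty")
  # degenerate FR distribution
  co3 <- generate_cohort(3, 1.0, seed = 5, FR_sd = 0, hold_duration = 30)
  expect_equal(co3$FR_angles, rep(58.2, 3))
})

test_that("cohort-mean initial moment increases across the five fractions", {
  # noise-free generator means at the default mechanical template
  truth <- ground_truth_spec(force_noise_sd = 0, angle_noise_sd = 0)
  fr <- c(0.30, 0.40, 0.60, 0.80, 1.00)
  m0 <- vapply(fr, function(f) {
    tr <- generate_trial(protocol_spec(58.2, f, hold_duration = 30),
                         truth, seed = 1)
    al <- resample_align(tr)
    seg <- segment_phases(al)
    summarize_relaxation(al, seg, window_s = 3)$initial_moment
  }, numeric(1))
  expect_true(all(diff(m0) > 0))
})

test_that("default trials show two-phase relaxation (fast share >= 30%)", {
  prot <- protocol_spec(FR_angle = 58.2, target_fraction_FR = 1.0)
  tr <- generate_trial(prot, ground_truth_spec(), seed = 4)
  al <- resample_align(tr)
  seg <- segment_phases(al)
  idx <- trunkrelax:::phase_idx(seg, "relaxation")
  t <- al$time[idx] - al$time[idx[1]]
  m <- al$moment[idx]
  w <- function(sel) mean(m[sel])
  m0 <- w(t < 3)
  m_60 <- w(t >= 57 & t < 60)
  m_end <- w(t >= max(t) - 3)
  total_drop <- m0 - m_end
  fast_drop <- m0 - m_60
  expect_gt(fast_drop / total_drop, 0.30)
})

test_that("trials round-trip through CSV + JSON sidecar", {
  dir <- withr::local_tempdir()
  tr <- generate_trial(quick_protocol(), ground_truth_spec(), seed = 3,
                       subject_id = 1L, trial_id = "S01_F060")
  write_trial_csv(tr, dir)
  back <- read_trial_csv(dir, "S01_F060")
  expect_equal(back$force, tr$force, tolerance = 1e-12)
  expect_equal(back$angle, tr$angle, tolerance = 1e-12)
  expect_equal(back$metadata$theta0, tr$metadata$theta0)
  expect_equal(unclass(back$metadata$truth$params),
               unclass(tr$metadata$truth$params), tolerance = 1e-12)
})
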