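# Seeded synthetic ramp-hold-ramp flexion trials with a generalized-Maxwell
# ground truth, plus the discrete hereditary-integral oracle used to compute
# that truth under arbitrary (non-constant) angle histories.

#' Exposure protocol specification
#'
#' Describes one ramp-hold-ramp flexion exposure: the trunk is flexed at
#' `ramp_rate` to a hold angle `target_fraction_FR * FR_angle`, held for
#' `hold_duration`, and returned at the same rate.  Angle is sampled at
#' `angle_rate_hz` (IMU) and harness force at `force_rate_hz` (load cell);
#' moment = force x `moment_arm`.
#'
#' @param FR_angle Flexion-relaxation angle of the subject, deg (> 0).
#' @param target_fraction_FR Hold angle as a fraction of `FR_angle`, in
#'   (0, 1]; the study levels are 0.30, 0.40, 0.60, 0.80, 1.00.
#' @param ramp_rate Loading/unloading angular velocity, deg/s (default 3).
#' @param hold_duration Hold (load-relaxation) duration, s (default 960,
#'   i.e. 16 min; reduce for quick simulations).
#' @param angle_rate_hz Angle sampling rate, Hz (default 100).
#' @param force_rate_hz Force sampling rate, Hz (default 1000).
#' @param moment_arm Vertical distance between harness rod and L5/S1, m.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(FR_angle, target_fraction_FR,
                          ramp_rate = 3, hold_duration = 960,
                          angle_rate_hz = 100, force_rate_hz = 1000,
                          moment_arm = 0.40) {
  stopifnot(FR_angle > 0, target_fraction_FR > 0, target_fraction_FR <= 1,
            ramp_rate > 0, hold_duration > 0,
            angle_rate_hz > 0, force_rate_hz > 0, moment_arm > 0)
  structure(list(FR_angle = FR_angle,
                 target_fraction_FR = target_fraction_FR,
                 ramp_rate = ramp_rate, hold_duration = hold_duration,
                 angle_rate_hz = angle_rate_hz,
                 force_rate_hz = force_rate_hz,
                 moment_arm = moment_arm),
            class = "protocol_spec")
}

#' Ground-truth specification for synthetic trials
#'
#' The mechanical truth behind a synthetic trial: a Kelvin-solid model
#' (`sls_params` or `prony_params`) acting on the angle in excess of a
#' low-stiffness neutral zone of width `nz_width`, with all stiffnesses
#' scaled by `exp(stiffness_angle_gain * theta0)` at the trial's hold angle
#' so that initial moment grows exponentially with flexion angle.  Additive
#' Gaussian noise emulates independent IMU and load-cell error.
#'
#' @param params A Kelvin-solid `model_params` object ([sls_params()] or
#'   [prony_params()]).  The default is a two-branch Prony series with time
#'   constants near 10 s and 1000 s, reproducing the fast and slow
#'   relaxation phases seen in vivo.
#' @param nz_width Width of the neutral zone, deg (>= 0).  Within it the
#'   truth stiffness is `nz_slope`, well below the 0.1 Nm/deg NZ criterion.
#' @param nz_slope Residual stiffness inside the neutral zone, Nm/deg.
#' @param stiffness_angle_gain Exponential stiffness-vs-hold-angle gain,
#'   1/deg.
#' @param force_noise_sd Load-cell noise SD, N (default 0.5, the RMS noise
#'   scale of an amplified strain-gauge load cell).
#' @param angle_noise_sd IMU angle noise SD, deg.
#' @return An object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(params = prony_params(k_inf = 0.10,
                                                    k = c(0.07, 0.11),
                                                    tau = c(10, 1000)),
                              nz_width = 10, nz_slope = 0.02,
                              stiffness_angle_gain = 0.02,
                              force_noise_sd = 0.5, angle_noise_sd = 0.1) {
  if (!inherits(params, c("sls_params", "prony_params")))
    stop("ground truth must be a Kelvin-solid model (sls or prony)")
  stopifnot(nz_width >= 0, nz_slope >= 0, nz_slope < 0.1,
            force_noise_sd >= 0, angle_noise_sd >= 0)
  structure(list(params = params, nz_width = nz_width, nz_slope = nz_slope,
                 stiffness_angle_gain = stiffness_angle_gain,
                 force_noise_sd = force_noise_sd,
                 angle_noise_sd = angle_noise_sd),
            class = "ground_truth_spec")
}

# view any Kelvin-solid params as (k_inf, branch k's, branch taus)
as_branches <- function(params) {
  if (inherits(params, "sls_params"))
    list(k_inf = params$k_parallel, k = params$k_maxwell, tau = params$tau)
  else
    list(k_inf = params$k_inf, k = params$k, tau = params$tau)
}

scale_stiffness <- function(params, factor) {
  if (inherits(params, "sls_params"))
    sls_params(params$k_maxwell * factor, params$k_parallel * factor,
               tau = params$tau)
  else
    prony_params(params$k_inf * factor, params$k * factor, params$tau)
}

#' Ground-truth moment under an arbitrary angle history
#'
#' Discrete hereditary (convolution) integral of the generalized-Maxwell
#' relaxation kernel against the angle-rate history, plus the parallel
#' elastic term and the neutral-zone residual stiffness.  Each Maxwell
#' branch is advanced by the recursion
#' `h[n+1] = h[n] e^(-dt/tau) + k tau (dtheta/dt) (1 - e^(-dt/tau))`,
#' which is exact for piecewise-linear angle histories.  An initial angle
#' `angle[1] > 0` is treated as an instantaneous step from zero, so a
#' constant history reproduces the closed-form relaxation equations to
#' machine precision.  Negative predicted moments are clamped to zero: the
#' harness measures pushing force only.
#'
#' @param truth A [ground_truth_spec()].
#' @param time Uniform, strictly increasing time grid, s.
#' @param angle Flexion angle at `time`, deg.
#' @return Moment, Nm, same length as `time`.
#' @export
truth_moment <- function(truth, time, angle) {
  stopifnot(inherits(truth, "ground_truth_spec"),
            length(time) == length(angle), length(time) >= 2L)
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("time grid must be uniform and strictly increasing")
  dt <- dt[1]
  br <- as_branches(truth$params)
  # deformation seen by the viscoelastic element: angle beyond the NZ
  theta_eff <- pmax(angle - truth$nz_width, 0)
  n <- length(time)
  m <- br$k_inf * theta_eff +
    truth$nz_slope * pmin(pmax(angle, 0), truth$nz_width)
  dtheta <- diff(theta_eff)
  for (i in seq_along(br$k)) {
    a <- exp(-dt / br$tau[i])
    b <- br$k[i] * br$tau[i] / dt * (1 - a)
    # recursive update h[j] = a h[j-1] + b dtheta[j]; h[1] is the
    # instantaneous elastic response to the initial step from rest
    x <- c(br$k[i] * theta_eff[1], b * dtheta)
    h <- as.numeric(stats::filter(x, a, method = "recursive"))
    m <- m + h
  }
  pmax(m, 0)
}

# ideal (noise-free) trapezoidal angle profile, deg, at times t
trapezoid_angle <- function(t, theta0, ramp_rate, hold_duration) {
  t_ramp <- theta0 / ramp_rate
  ang <- pmin(t * ramp_rate, theta0)
  t_down <- t_ramp + hold_duration
  down <- t > t_down
  ang[down] <- pmax(theta0 - (t[down] - t_down) * ramp_rate, 0)
  ang
}

#' Generate one synthetic flexion trial
#'
#' Builds the trapezoidal angle profile for the protocol, evaluates the
#' ground-truth moment on the force-sampling grid via [truth_moment()],
#' converts to harness force through the moment arm, and adds independent
#' Gaussian noise to the angle stream (IMU) and force stream (load cell).
#' Identical seeds give identical recordings.
#'
#' @param protocol A [protocol_spec()].
#' @param truth A [ground_truth_spec()].
#' @param seed Integer seed.
#' @param subject_id,trial_id Optional labels stored in metadata.
#' @return An object of class `trial_recording` with fields `angle_time`,
#'   `angle` (deg, at `angle_rate_hz`), `force_time`, `force` (N, at
#'   `force_rate_hz`), `moment_arm` and `metadata`.
#' @export
generate_trial <- function(protocol, truth, seed,
                           subject_id = NA_integer_, trial_id = NA_character_) {
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(truth, "ground_truth_spec"))
  theta0 <- protocol$target_fraction_FR * protocol$FR_angle
  if (theta0 <= truth$nz_width)
    stop("hold angle (", signif(theta0, 4), " deg) does not exceed the ",
         "neutral zone width (", truth$nz_width, " deg): ",
         "no measurable viscoelastic response")
  t_ramp <- theta0 / protocol$ramp_rate
  total <- 2 * t_ramp + protocol$hold_duration

  force_time <- seq(0, total, by = 1 / protocol$force_rate_hz)
  angle_time <- seq(0, total, by = 1 / protocol$angle_rate_hz)

  scaled <- truth
  scaled$params <- scale_stiffness(truth$params,
                                   exp(truth$stiffness_angle_gain * theta0))
  ang_ideal_f <- trapezoid_angle(force_time, theta0, protocol$ramp_rate,
                                 protocol$hold_duration)
  moment <- truth_moment(scaled, force_time, ang_ideal_f)

  set.seed(as.integer(seed %% .Machine$integer.max))
  force <- moment / protocol$moment_arm +
    stats::rnorm(length(force_time), 0, truth$force_noise_sd)
  ang_ideal_a <- trapezoid_angle(angle_time, theta0, protocol$ramp_rate,
                                 protocol$hold_duration)
  angle <- ang_ideal_a +
    stats::rnorm(length(angle_time), 0, truth$angle_noise_sd)

  structure(list(angle_time = angle_time, angle = angle,
                 force_time = force_time, force = force,
                 moment_arm = protocol$moment_arm,
                 metadata = list(protocol = protocol, truth = scaled,
                                 theta0 = theta0, t_ramp = t_ramp,
                                 seed = seed, subject_id = subject_id,
                                 trial_id = trial_id)),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(paste0("<trial_recording> %s: hold %.1f deg (%.0f%% FR),",
                     " %.0f s, %d angle / %d force samples\n"),
              ifelse(is.na(md$trial_id), "trial", md$trial_id), md$theta0,
              100 * md$protocol$target_fraction_FR,
              md$protocol$hold_duration,
              length(x$angle), length(x$force)))
  invisible(x)
}

#' Generate a synthetic cohort of flexion trials
#'
#' Draws per-subject flexion-relaxation angles from a truncated-positive
#' normal distribution (cohort default mean 58.2 deg, SD 12.0 deg) and
#' generates one trial per subject x target fraction.  Trials whose hold
#' angle would not exceed the neutral zone are skipped with a recorded
#' reason, mirroring unusable small-angle exposures.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param fractions Target fractions of the FR angle (non-empty).
#' @param truth_template A [ground_truth_spec()] shared by all trials.
#' @param seed Integer seed; the cohort is reproducible under it.
#' @param FR_mean,FR_sd Cohort FR-angle distribution, deg.
#' @param ... Further arguments to [protocol_spec()] (e.g. `hold_duration`).
#' @return A list with `trials` (list of `trial_recording`) and `skipped`
#'   (data.frame of skipped subject/fraction combinations with reasons).
#' @export
generate_cohort <- function(n_subjects, fractions,
                            truth_template = ground_truth_spec(), seed = 1L,
                            FR_mean = 58.2, FR_sd = 12.0, ...) {
  stopifnot(n_subjects >= 1)
  if (length(fractions) == 0L) stop("`fractions` must be non-empty")
  set.seed(as.integer(seed %% .Machine$integer.max))
  FR <- stats::rnorm(n_subjects, FR_mean, FR_sd)
  while (any(FR <= 0)) FR[FR <= 0] <- stats::rnorm(sum(FR <= 0), FR_mean, FR_sd)
  trial_seeds <- sample.int(.Machine$integer.max - 1L,
                            n_subjects * length(fractions))
  trials <- list()
  skipped <- data.frame(subject = integer(), fraction = numeric(),
                        reason = character())
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    for (f in fractions) {
      idx <- idx + 1L
      prot <- protocol_spec(FR_angle = FR[s], target_fraction_FR = f, ...)
      tr <- tryCatch(
        generate_trial(prot, truth_template, seed = trial_seeds[idx],
                       subject_id = s,
                       trial_id = sprintf("S%02d_F%03.0f", s, 100 * f)),
        error = function(e) e)
      if (inherits(tr, "error"))
        skipped <- rbind(skipped, data.frame(subject = s, fraction = f,
                                             reason = conditionMessage(tr)))
      else trials[[length(trials) + 1L]] <- tr
    }
  }
  list(trials = trials, skipped = skipped, FR_angles = FR)
}

#' Write / read a trial as plain-text CSV with a JSON sidecar
#'
#' The angle and force streams are written as separate CSV files
#' (`<id>_angle.csv` with `time_s, angle_deg`; `<id>_force.csv` with
#' `time_s, force_N`) plus `<id>_meta.json` holding protocol and truth
#' fields.
#'
#' @param trial A `trial_recording`.
#' @param dir Output directory (created if missing).
#' @param id File stem; defaults to the trial's `trial_id`.
#' @return Invisibly, the three file paths.
#' @export
write_trial_csv <- function(trial, dir, id = trial$metadata$trial_id) {
  stopifnot(inherits(trial, "trial_recording"))
  if (is.na(id)) id <- "trial"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(id, "_angle.csv"))
  ff <- file.path(dir, paste0(id, "_force.csv"))
  fm <- file.path(dir, paste0(id, "_meta.json"))
  utils::write.csv(data.frame(time_s = trial$angle_time,
                              angle_deg = trial$angle),
                   fa, row.names = FALSE)
  utils::write.csv(data.frame(time_s = trial$force_time,
                              force_N = trial$force),
                   ff, row.names = FALSE)
  md <- trial$metadata
  meta <- list(moment_arm = trial$moment_arm, theta0 = md$theta0,
               seed = md$seed, subject_id = md$subject_id, trial_id = id,
               protocol = unclass(md$protocol),
               truth = list(model = model_kind(md$truth$params),
                            params = unclass(md$truth$params),
                            nz_width = md$truth$nz_width,
                            nz_slope = md$truth$nz_slope,
                            stiffness_angle_gain = md$truth$stiffness_angle_gain,
                            force_noise_sd = md$truth$force_noise_sd,
                            angle_noise_sd = md$truth$angle_noise_sd))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), fm)
  invisible(c(angle = fa, force = ff, meta = fm))
}

#' @rdname write_trial_csv
#' @param dir Directory holding the three files.
#' @export
read_trial_csv <- function(dir, id) {
  ang <- utils::read.csv(file.path(dir, paste0(id, "_angle.csv")))
  frc <- utils::read.csv(file.path(dir, paste0(id, "_force.csv")))
  meta <- jsonlite::fromJSON(file.path(dir, paste0(id, "_meta.json")))
  pr <- meta$protocol
  protocol <- protocol_spec(pr$FR_angle, pr$target_fraction_FR, pr$ramp_rate,
                            pr$hold_duration, pr$angle_rate_hz,
                            pr$force_rate_hz, pr$moment_arm)
  tp <- meta$truth
  params <- switch(tp$model,
                   sls = sls_params(tp$params$k_maxwell, tp$params$k_parallel,
                                    tp$params$c_damper),
                   prony = prony_params(tp$params$k_inf, tp$params$k,
                                        tp$params$tau))
  truth <- ground_truth_spec(params, tp$nz_width, tp$nz_slope,
                             tp$stiffness_angle_gain, tp$force_noise_sd,
                             tp$angle_noise_sd)
  structure(list(angle_time = ang$time_s, angle = ang$angle_deg,
                 force_time = frc$time_s, force = frc$force_N,
                 moment_arm = meta$moment_arm,
                 metadata = list(protocol = protocol, truth = truth,
                                 theta0 = meta$theta0,
                                 t_ramp = meta$theta0 / protocol$ramp_rate,
                                 seed = meta$seed,
                                 subject_id = meta$subject_id,
                                 trial_id = meta$trial_id)),
            class = "trial_recording")
}
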