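# Raw stream -> aligned moment-angle record -> protocol phases -> windowed
# relaxation statistics.

#' Trunk moment from harness force
#'
#' Elementwise `moment = force * moment_arm`, with negative values clamped
#' to zero (the harness transmits pushing force only).
#'
#' @param force Force series, N.
#' @param moment_arm Moment arm, m (> 0).
#' @return Moment series, Nm.
#' @export
compute_moment <- function(force, moment_arm) {
  if (!is.numeric(moment_arm) || length(moment_arm) != 1L || moment_arm <= 0)
    stop("`moment_arm` must be a single positive number")
  pmax(force * moment_arm, 0)
}

#' Align force and angle streams onto a common grid
#'
#' Block-averages the force stream onto the (slower) angle grid — for the
#' default rates, 1000 -> 100 Hz by 10-sample means — converts to moment
#' via [compute_moment()], and restricts to the overlapping time span.
#' Equal-rate streams pass through unchanged apart from span intersection.
#'
#' @param trial A `trial_recording`.
#' @return An object of class `aligned_trial` with uniform `time` (s),
#'   `angle` (deg), `moment` (Nm) and `FR_angle` (deg).
#' @export
resample_align <- function(trial) {
  stopifnot(inherits(trial, "trial_recording"))
  prot <- trial$metadata$protocol
  ratio <- prot$force_rate_hz / prot$angle_rate_hz
  if (abs(ratio - round(ratio)) > 1e-8 || ratio < 1)
    stop("force rate must be an integer multiple of the angle rate")
  ratio <- as.integer(round(ratio))
  t0 <- max(trial$angle_time[1], trial$force_time[1])
  t1 <- min(trial$angle_time[length(trial$angle_time)],
            trial$force_time[length(trial$force_time)])
  if (t1 <= t0) stop("angle and force streams do not overlap in time")
  keep_a <- trial$angle_time >= t0 - 1e-9 & trial$angle_time <= t1 + 1e-9
  time <- trial$angle_time[keep_a]
  angle <- trial$angle[keep_a]
  if (ratio == 1L) {
    keep_f <- trial$force_time >= t0 - 1e-9 & trial$force_time <= t1 + 1e-9
    force <- trial$force[keep_f][seq_along(time)]
  } else {
    # `ratio`-sample mean centred on each angle timestamp; half-weighted
    # endpoints keep the window exactly symmetric (no half-sample lag)
    w <- c(0.5, rep(1, ratio - 1L), 0.5) / ratio
    sm <- as.numeric(stats::filter(trial$force, w, sides = 2))
    dt_f <- 1 / prot$force_rate_hz
    j <- round((time - trial$force_time[1]) / dt_f) + 1L
    half <- ratio %/% 2L
    nf <- length(trial$force)
    edge <- which(is.na(sm))
    for (i in edge)
      sm[i] <- mean(trial$force[max(1L, i - half):min(nf, i + half)])
    force <- sm[pmin(pmax(j, 1L), nf)]
  }
  structure(list(time = time, angle = angle,
                 moment = compute_moment(force, trial$moment_arm),
                 FR_angle = prot$FR_angle),
            class = "aligned_trial")
}

#' Construct an aligned trial directly
#'
#' Escape hatch for already-aligned data (e.g. constructed test records).
#'
#' @param time Uniform time grid, s.
#' @param angle Angle, deg.
#' @param moment Moment, Nm (clamped at zero).
#' @param FR_angle FR angle, deg.
#' @return An `aligned_trial`.
#' @export
aligned_trial <- function(time, angle, moment, FR_angle) {
  stopifnot(length(time) == length(angle), length(time) == length(moment))
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("time grid must be uniform and strictly increasing")
  structure(list(time = time, angle = angle, moment = pmax(moment, 0),
                 FR_angle = FR_angle),
            class = "aligned_trial")
}

moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  k <- rep(1 / width, width)
  y <- stats::filter(x, k, sides = 2)
  y <- as.numeric(y)
  # shrink the window near the edges rather than dropping samples
  na <- which(is.na(y))
  for (i in na) {
    lo <- max(1L, i - width %/% 2L); hi <- min(length(x), i + width %/% 2L)
    y[i] <- mean(x[lo:hi])
  }
  y
}

#' Segment the three protocol phases
#'
#' Estimates the angle rate by central differences after a 1-s moving
#' average smooth, then finds the loading phase (rate > `rate_threshold`),
#' the unloading phase (rate < -`rate_threshold`) and the load-relaxation
#' phase between them.  Intervals are half-open `[start, end)` sample
#' indices.
#'
#' @param aligned An `aligned_trial`.
#' @param rate_threshold Rate threshold, deg/s (default 0.5, one sixth of
#'   the 3 deg/s ramp).
#' @param smooth_s Smoothing window, s.
#' @return An object of class `phase_segmentation` with integer fields
#'   `loading`, `relaxation`, `unloading` (each `c(start, end)`).
#' @export
segment_phases <- function(aligned, rate_threshold = 0.5, smooth_s = 1) {
  stopifnot(inherits(aligned, "aligned_trial"))
  dt <- aligned$time[2] - aligned$time[1]
  n <- length(aligned$time)
  w <- max(1L, round(smooth_s / dt))
  if (w %% 2L == 0L) w <- w + 1L
  ang <- moving_average(aligned$angle, w)
  rate <- c(NA, (ang[-(1:2)] - ang[1:(n - 2)]) / (2 * dt), NA)
  rate[1] <- rate[2]; rate[n] <- rate[n - 1]

  up <- rate > rate_threshold
  down <- rate < -rate_threshold
  if (!any(up)) stop("no loading phase detected: unusable trial")
  if (!any(down)) stop("no unloading phase detected: unusable trial")
  up_idx <- which(up)
  runs_up <- cumsum(c(1L, diff(up_idx) != 1L))
  first_run <- up_idx[runs_up == 1L]
  loading <- c(first_run[1], first_run[length(first_run)] + 1L)
  unload_idx <- which(down)
  # last contiguous run of "down"
  runs <- cumsum(c(1L, diff(unload_idx) != 1L))
  last_run <- unload_idx[runs == runs[length(runs)]]
  unloading <- c(last_run[1], last_run[length(last_run)] + 1L)
  if (unloading[1] <= loading[2])
    stop("no plateau detected between loading and unloading: unusable trial")
  relaxation <- c(loading[2], unloading[1])
  seg <- structure(list(loading = loading, relaxation = relaxation,
                        unloading = c(unloading[1], min(unloading[2], n + 1L))),
                   class = "phase_segmentation")
  seg
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("<phase_segmentation> sample intervals [start, end):\n")
  for (nm in c("loading", "relaxation", "unloading"))
    cat(sprintf("  %-10s [%d, %d)\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

phase_idx <- function(seg, phase) seq(seg[[phase]][1], seg[[phase]][2] - 1L)

#' Windowed relaxation summary statistics
#'
#' Means over 3-s windows (half-open `[t0, t0 + window_s)`) at the start
#' and end of the load-relaxation phase give the initial and final moment;
#' their difference is the moment drop.  `t90` is the first time from hold
#' onset at which the moment falls to `initial - 0.9 * drop`; it is `NA`
#' (with `t90_resolved = FALSE`) when the drop is zero or the level is
#' never reached.
#'
#' @param aligned An `aligned_trial`.
#' @param seg A `phase_segmentation` from [segment_phases()].
#' @param window_s Window length, s (default 3).
#' @return An object of class `relaxation_summary`: `initial_moment`,
#'   `final_moment`, `moment_drop`, `moment_drop_pct`, `t90`,
#'   `t90_resolved`.
#' @export
summarize_relaxation <- function(aligned, seg, window_s = 3) {
  stopifnot(inherits(aligned, "aligned_trial"),
            inherits(seg, "phase_segmentation"))
  idx <- phase_idx(seg, "relaxation")
  t <- aligned$time[idx]
  m <- aligned$moment[idx]
  dur <- t[length(t)] - t[1]
  if (dur < 2 * window_s)
    stop("relaxation phase shorter than two analysis windows")
  t_rel <- t - t[1]
  first <- t_rel < window_s
  last <- t_rel >= (t_rel[length(t_rel)] + (t[2] - t[1])) - window_s
  initial <- mean(m[first])
  final <- mean(m[last])
  drop <- initial - final
  target <- initial - 0.9 * drop
  t90 <- NA_real_
  resolved <- FALSE
  if (drop > 0) {
    hit <- which(m <= target)
    if (length(hit) > 0L) { t90 <- t_rel[hit[1]]; resolved <- TRUE }
  }
  structure(list(initial_moment = initial, final_moment = final,
                 moment_drop = drop,
                 moment_drop_pct = if (initial > 0) 100 * drop / initial
                                   else NA_real_,
                 t90 = t90, t90_resolved = resolved),
            class = "relaxation_summary")
}

#' @export
print.relaxation_summary <- function(x, ...) {
  cat(sprintf(paste0("<relaxation_summary> initial %.2f Nm, final %.2f Nm,",
                     " drop %.2f Nm (%.1f%%), t90 %s\n"),
              x$initial_moment, x$final_moment, x$moment_drop,
              x$moment_drop_pct,
              if (x$t90_resolved) sprintf("%.1f s", x$t90) else "unresolved"))
  invisible(x)
}

#' Extract the relaxation segment for model fitting
#'
#' Returns the hold-phase time (zeroed at hold onset) and moment, together
#' with the hold angle `theta0` (mean angle over the hold).
#'
#' @param aligned An `aligned_trial`.
#' @param seg A `phase_segmentation`.
#' @return An object of class `relaxation_segment` with `time`, `moment`,
#'   `theta0`.
#' @export
extract_relaxation <- function(aligned, seg) {
  idx <- phase_idx(seg, "relaxation")
  t <- aligned$time[idx]
  structure(list(time = t - t[1], moment = aligned$moment[idx],
                 theta0 = mean(aligned$angle[idx])),
            class = "relaxation_segment")
}
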