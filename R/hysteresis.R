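# Loading/unloading angle-moment hysteresis loop, neutral-zone detection,
# and the E1/E2/dE energies with the RE viscoelastic-state ratio.

#' Build the angle-moment hysteresis loop
#'
#' Re-bins the loading-phase and unloading-phase samples onto a uniform
#' angle grid (default 0.25 deg) by within-bin averaging of the moment.
#'
#' @param aligned An `aligned_trial`.
#' @param seg A `phase_segmentation`.
#' @param bin_deg Angle bin width, deg.
#' @return An object of class `hysteresis_loop` with data.frames `loading`
#'   and `unloading`, each with columns `angle` (bin centres, ascending)
#'   and `moment`.
#' @export
build_loop <- function(aligned, seg, bin_deg = 0.25) {
  stopifnot(inherits(aligned, "aligned_trial"),
            inherits(seg, "phase_segmentation"), bin_deg > 0)
  bin_curve <- function(idx) {
    a <- aligned$angle[idx]
    m <- aligned$moment[idx]
    bins <- round(a / bin_deg)
    centre <- sort(unique(bins)) * bin_deg
    mom <- vapply(sort(unique(bins)),
                  function(b) mean(m[bins == b]), numeric(1))
    data.frame(angle = centre, moment = pmax(mom, 0))
  }
  loading <- bin_curve(phase_idx(seg, "loading"))
  unloading <- bin_curve(phase_idx(seg, "unloading"))
  if (nrow(loading) < 5L || nrow(unloading) < 5L)
    stop("fewer than 5 angle bins: angle excursion too small for a loop")
  structure(list(loading = loading, unloading = unloading,
                 bin_deg = bin_deg),
            class = "hysteresis_loop")
}

#' Construct a hysteresis loop from explicit curves
#'
#' For constructed test loops and closed-form limit cases.
#'
#' @param loading,unloading data.frames with `angle` (deg, ascending) and
#'   `moment` (Nm) columns.
#' @param bin_deg Nominal bin width, deg.
#' @return A `hysteresis_loop`.
#' @export
hysteresis_loop <- function(loading, unloading, bin_deg = 0.25) {
  for (cu in list(loading, unloading))
    stopifnot(is.data.frame(cu), all(c("angle", "moment") %in% names(cu)),
              !is.unsorted(cu$angle))
  structure(list(loading = loading, unloading = unloading,
                 bin_deg = bin_deg),
            class = "hysteresis_loop")
}

#' Neutral-zone width of an angle-moment curve
#'
#' The neutral zone (NZ) is the contiguous angle extent, starting at the
#' neutral (0 deg) posture, over which the local slope of the angle-moment
#' curve stays below `slope_thresh` and the moment stays below
#' `moment_thresh`.  The local slope at angle `a` is a linear-regression
#' slope over the trailing 1-deg window `[a - slope_window, a]`, so a bin
#' is judged by the curve on its neutral side.
#'
#' @param curve data.frame with `angle` (deg, ascending from ~0) and
#'   `moment` (Nm).
#' @param slope_thresh Slope criterion, Nm/deg (default 0.1).
#' @param moment_thresh Moment criterion, Nm (default 7).
#' @param slope_window Regression window, deg (default 1).
#' @return NZ width, deg (0 when the curve is immediately stiff).
#' @export
neutral_zone <- function(curve, slope_thresh = 0.1, moment_thresh = 7,
                         slope_window = 1) {
  stopifnot(is.data.frame(curve), all(c("angle", "moment") %in% names(curve)))
  a <- curve$angle; m <- curve$moment
  if (a[1] > slope_window / 2)
    stop("curve is not anchored at the neutral (0 deg) posture")
  nz_end <- 0
  for (i in seq_along(a)[-1]) {
    # trailing window, extended forward to a full span for the first bins
    lo <- max(a[i] - slope_window, a[1])
    hi <- max(a[i], lo + slope_window)
    in_win <- a >= lo - 1e-9 & a <= hi + 1e-9
    if (sum(in_win) >= 2L) {
      slope <- stats::coef(stats::lm(m[in_win] ~ a[in_win]))[2]
    } else slope <- (m[i] - m[i - 1L]) / (a[i] - a[i - 1L])
    if (!is.finite(slope)) slope <- 0
    if (slope >= slope_thresh || m[i] >= moment_thresh) break
    nz_end <- a[i]
  }
  unname(nz_end)
}

#' Normalized neutral zone and pre/post change
#'
#' Normalizes NZ widths by the FR angle (percent) and reports the
#' percentage change of the post-exposure NZ relative to the pre-exposure
#' value.
#'
#' @param pre_nz,post_nz NZ widths, deg.
#' @param FR_angle FR angle, deg (> 0).
#' @return An object of class `nz_result`: `nz_pre_deg`, `nz_post_deg`,
#'   `nz_pre_normalized`, `nz_post_normalized` (% of FR), `pct_change`
#'   (`NA` with `change_defined = FALSE` when `pre_nz` is 0).
#' @export
nz_change <- function(pre_nz, post_nz, FR_angle) {
  stopifnot(FR_angle > 0, pre_nz >= 0, post_nz >= 0)
  defined <- pre_nz > 0
  structure(list(nz_pre_deg = pre_nz, nz_post_deg = post_nz,
                 nz_pre_normalized = 100 * pre_nz / FR_angle,
                 nz_post_normalized = 100 * post_nz / FR_angle,
                 pct_change = if (defined) 100 * (post_nz - pre_nz) / pre_nz
                              else NA_real_,
                 change_defined = defined),
            class = "nz_result")
}

#' Hysteresis energies and the viscoelastic-state ratio RE
#'
#' E1 and E2 are the areas under the loading and unloading angle-moment
#' curves (trapezoidal integration over the angle grid, moments floored at
#' zero); the dissipated energy is dE = E1 - E2 and the viscoelastic state
#' RE = dE / E1.  RE = 0 for a purely elastic loop (identical curves) and
#' RE = 1 for a purely viscous loop (no energy recovered on unloading).
#'
#' @param loop A `hysteresis_loop`.
#' @return An object of class `energy_result`: `E1`, `E2` (Nm deg), `dE`,
#'   `RE` (`NA` with `RE_defined = FALSE` when E1 = 0).
#' @export
energies <- function(loop) {
  stopifnot(inherits(loop, "hysteresis_loop"))
  area <- function(cu) {
    if (nrow(cu) < 2L) return(0)
    pracma::trapz(cu$angle, pmax(cu$moment, 0))
  }
  E1 <- area(loop$loading)
  E2 <- area(loop$unloading)
  defined <- E1 > 0
  structure(list(E1 = E1, E2 = E2, dE = E1 - E2,
                 RE = if (defined) (E1 - E2) / E1 else NA_real_,
                 RE_defined = defined),
            class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("<energy_result> E1 %.2f, E2 %.2f Nm*deg; dE %.2f; RE %s\n",
              x$E1, x$E2, x$dE,
              if (x$RE_defined) sprintf("%.3f", x$RE) else "undefined"))
  invisible(x)
}
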