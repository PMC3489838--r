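# End-to-end orchestration: simulate -> preprocess -> hysteresis/NZ ->
# fit -> sensitivity/trends, with deterministic CSV/JSON artifacts.

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()].  Unknown fields are
#' rejected.  All angles are degrees, times seconds, moments Nm in every
#' file the pipeline writes.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param fractions Target %FR fractions.
#' @param hold_duration Hold duration, s.
#' @param FR_mean,FR_sd Cohort FR-angle distribution, deg.
#' @param truth A [ground_truth_spec()].
#' @param models Model families to fit.
#' @param n_starts Multi-start count for fitting.
#' @param seed Integer seed governing every random draw.
#' @param out_dir Output directory for artifacts (`NULL` for none).
#' @param ramp_rate,angle_rate_hz,force_rate_hz,moment_arm Protocol fields,
#'   see [protocol_spec()].
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 10L,
                            fractions = c(0.30, 0.40, 0.60, 0.80, 1.00),
                            hold_duration = 960,
                            FR_mean = 58.2, FR_sd = 12.0,
                            truth = ground_truth_spec(),
                            models = c("sls", "prony", "schapery", "msm"),
                            n_starts = 8L, seed = 1L, out_dir = NULL,
                            ramp_rate = 3, angle_rate_hz = 100,
                            force_rate_hz = 1000, moment_arm = 0.40) {
  stopifnot(n_subjects >= 1, length(fractions) >= 1,
            inherits(truth, "ground_truth_spec"),
            all(models %in% c("sls", "prony", "schapery", "msm")))
  structure(list(n_subjects = as.integer(n_subjects), fractions = fractions,
                 hold_duration = hold_duration, FR_mean = FR_mean,
                 FR_sd = FR_sd, truth = truth, models = models,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 out_dir = out_dir, ramp_rate = ramp_rate,
                 angle_rate_hz = angle_rate_hz,
                 force_rate_hz = force_rate_hz, moment_arm = moment_arm),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Accepts the [pipeline_config()] fields at the top level plus an optional
#' nested `truth` object (`model`, `params`, `nz_width`, `nz_slope`,
#' `stiffness_angle_gain`, `force_noise_sd`, `angle_noise_sd`).  Unknown
#' keys are rejected.
#'
#' @param path JSON file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0L)
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  if (!is.null(raw$truth)) {
    tp <- raw$truth
    params <- switch(tp$model,
                     sls = sls_params(tp$params$k_maxwell,
                                      tp$params$k_parallel,
                                      tp$params$c_damper),
                     prony = prony_params(tp$params$k_inf, tp$params$k,
                                          tp$params$tau),
                     stop("truth model must be 'sls' or 'prony'"))
    defaults <- ground_truth_spec()
    pick <- function(nm) if (!is.null(tp[[nm]])) tp[[nm]] else defaults[[nm]]
    raw$truth <- ground_truth_spec(params, pick("nz_width"),
                                   pick("nz_slope"),
                                   pick("stiffness_angle_gain"),
                                   pick("force_noise_sd"),
                                   pick("angle_noise_sd"))
  }
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL   # output location does not define the analysis
  js <- jsonlite::toJSON(lapply(cfg, function(x)
    if (is.list(x)) lapply(unclass(x), unclass) else x),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  # order-sensitive 31-bit polynomial rolling hash of the serialized config
  bytes <- utf8ToInt(as.character(js))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

analyze_one_trial <- function(trial, models, n_starts) {
  aligned <- resample_align(trial)
  seg <- segment_phases(aligned)
  summ <- summarize_relaxation(aligned, seg)
  loop <- build_loop(aligned, seg)
  nz_pre <- neutral_zone(loop$loading)
  nz_post <- neutral_zone(loop$unloading)
  nzr <- nz_change(nz_pre, nz_post, aligned$FR_angle)
  en <- energies(loop)
  rseg <- extract_relaxation(aligned, seg)
  fits <- lapply(stats::setNames(models, models), function(mo)
    fit_relaxation(rseg, model = mo, n_starts = n_starts))
  list(aligned = aligned, seg = seg, summary = summ, loop = loop,
       nz = nzr, energy = en, segment = rseg, fits = fits)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, analyzes every trial (alignment, segmentation,
#' windowed relaxation summary, hysteresis loop, neutral zone, energies),
#' fits the requested relaxation models, derives cohort-level sensitivity
#' tables (nominal = mean fitted parameters, range = min/max across
#' trials) and angle-dependence trend fits, and (optionally) writes all
#' artifacts to `config$out_dir`.  Trials that cannot be analyzed (no
#' plateau, hold inside the neutral zone, too-short relaxation) are
#' skipped with recorded reasons.  Identical config + seed gives
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `outcomes` (per-trial data.frame),
#'   `comparison` (model x %FR fit-quality table), `sensitivity`
#'   (data.frame), `trends` (list of `trend_fit`), `skipped` (data.frame),
#'   `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- generate_cohort(config$n_subjects, config$fractions,
                            truth_template = config$truth,
                            seed = config$seed,
                            FR_mean = config$FR_mean, FR_sd = config$FR_sd,
                            hold_duration = config$hold_duration,
                            ramp_rate = config$ramp_rate,
                            angle_rate_hz = config$angle_rate_hz,
                            force_rate_hz = config$force_rate_hz,
                            moment_arm = config$moment_arm)
  skipped <- cohort$skipped
  if (nrow(skipped) > 0L) skipped$stage <- "simulate"

  rows <- list()
  all_fits <- list()
  segments <- list()
  seg_groups <- character()
  for (tr in cohort$trials) {
    res <- tryCatch(analyze_one_trial(tr, config$models, config$n_starts),
                    error = function(e) e)
    md <- tr$metadata
    if (inherits(res, "error")) {
      skipped <- rbind(skipped,
                       data.frame(subject = md$subject_id,
                                  fraction = md$protocol$target_fraction_FR,
                                  reason = conditionMessage(res),
                                  stage = "analyze"))
      next
    }
    row <- data.frame(
      trial_id = md$trial_id, subject = md$subject_id,
      fraction = md$protocol$target_fraction_FR,
      FR_angle = md$protocol$FR_angle, theta0 = md$theta0,
      initial_moment = res$summary$initial_moment,
      final_moment = res$summary$final_moment,
      moment_drop = res$summary$moment_drop,
      moment_drop_pct = res$summary$moment_drop_pct,
      t90 = res$summary$t90,
      nz_pre_deg = res$nz$nz_pre_deg, nz_post_deg = res$nz$nz_post_deg,
      nz_pre_normalized = res$nz$nz_pre_normalized,
      nz_pct_change = res$nz$pct_change,
      E1 = res$energy$E1, E2 = res$energy$E2, dE = res$energy$dE,
      RE = res$energy$RE)
    for (mo in config$models) {
      row[[paste0("r2_", mo)]] <- res$fits[[mo]]$r2
      row[[paste0("rmse_", mo)]] <- res$fits[[mo]]$rmse
    }
    rows[[length(rows) + 1L]] <- row
    all_fits[[length(all_fits) + 1L]] <- res$fits
    segments[[length(segments) + 1L]] <- res$segment
    seg_groups <- c(seg_groups,
                    sprintf("%.0f%%", 100 * md$protocol$target_fraction_FR))
  }
  if (length(rows) == 0L) stop("no analyzable trials in the cohort")
  outcomes <- do.call(rbind, rows)

  # model x %FR fit-quality table from the per-trial fits
  qrows <- do.call(rbind, lapply(seq_along(all_fits), function(i)
    do.call(rbind, lapply(config$models, function(mo)
      data.frame(group = seg_groups[i], model = mo,
                 r2 = all_fits[[i]][[mo]]$r2,
                 rmse = all_fits[[i]][[mo]]$rmse)))))
  comparison <- stats::aggregate(cbind(r2, rmse) ~ model + group, qrows, mean)

  # cohort sensitivity: nominal = mean fitted parameter, range = min..max
  sens <- list()
  for (mo in config$models) {
    mats <- lapply(all_fits, function(f) unlist_params(f[[mo]]$params))
    pm <- do.call(rbind, mats)
    nominal <- rebuild_params(mo, colMeans(pm))
    if (is.null(nominal)) next
    ranges <- lapply(stats::setNames(colnames(pm), colnames(pm)),
                     function(id) range(pm[, id]))
    ranges <- ranges[vapply(ranges, function(r) r[1] < r[2], logical(1))]
    sens[[mo]] <- sensitivity_table(nominal, ranges,
                                    theta0 = mean(outcomes$theta0),
                                    horizon = config$hold_duration)
  }
  sensitivity <- if (length(sens) > 0L) do.call(rbind, sens) else NULL

  # angle trends on cohort means per fraction (x in %FR)
  means <- stats::aggregate(cbind(initial_moment, moment_drop,
                                  nz_pct_change) ~ fraction,
                            outcomes, mean)
  x <- 100 * means$fraction
  trends <- list()
  if (length(x) >= 2L) {  # >= 3 points once the origin is added
    for (oc in c("initial_moment", "moment_drop")) {
      trends[[paste0(oc, "_exponential")]] <-
        fit_angle_trend(x, means[[oc]], "exponential_through_origin",
                        include_origin = TRUE)
      trends[[paste0(oc, "_linear")]] <-
        fit_angle_trend(x, means[[oc]], "linear", include_origin = TRUE)
    }
  }

  result <- list(outcomes = outcomes, comparison = comparison,
                 sensitivity = sensitivity, trends = trends,
                 skipped = skipped, FR_angles = cohort$FR_angles,
                 config_hash = config_hash(config))
  if (!is.null(config$out_dir)) write_artifacts(result, config)
  invisible(result)
}

# flatten a params object to a named vector (Prony branches get k1..kn,
# tau1..taun automatically from unlist)
unlist_params <- function(p) unlist(unclass(p))

rebuild_params <- function(model, v) {
  tryCatch(switch(model,
    sls = sls_params(v[["k_maxwell"]], v[["k_parallel"]],
                     c_damper = v[["c_damper"]]),
    prony = {
      nb <- sum(grepl("^k[0-9]+$", names(v)))
      prony_params(v[["k_inf"]], v[paste0("k", seq_len(nb))],
                   v[paste0("tau", seq_len(nb))])
    },
    schapery = schapery_params(v[["k_eq"]], v[["c1"]], v[["c2"]]),
    msm = msm_params(v[["k0"]], v[["beta"]])),
    error = function(e) NULL)
}

write_artifacts <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  header <- c("# trunkrelax results schema v1",
              sprintf("# config_hash %s seed %d", result$config_hash,
                      config$seed))
  write_csv_versioned <- function(df, path) {
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE,
                            justify = "none"),
                     con, row.names = FALSE, quote = FALSE)
    close(con)
  }
  write_csv_versioned(result$outcomes, out("outcomes.csv"))
  write_csv_versioned(result$comparison, out("model_comparison.csv"))
  if (!is.null(result$sensitivity))
    write_csv_versioned(result$sensitivity, out("sensitivity.csv"))
  if (nrow(result$skipped) > 0L)
    write_csv_versioned(result$skipped, out("skipped_trials.csv"))
  trends <- lapply(result$trends, function(tf)
    list(family = tf$family, coefficients = as.list(tf$coefficients),
         r2 = tf$r2))
  writeLines(jsonlite::toJSON(trends, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             out("trends.json"))
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("config_hash: %s", result$config_hash),
                 sprintf("trials_analyzed: %d", nrow(result$outcomes)),
                 sprintf("trials_skipped: %d", nrow(result$skipped)),
                 if (nrow(result$skipped) > 0L)
                   sprintf("  skipped subject %s fraction %s [%s]: %s",
                           result$skipped$subject, result$skipped$fraction,
                           result$skipped$stage, result$skipped$reason))
  writeLines(log_lines, out("run_log.txt"))
  invisible(NULL)
}
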