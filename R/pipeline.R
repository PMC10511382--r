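#' Configuration for the end-to-end pipeline
#'
#' @param cohort a \code{\link{cohort_config}} (group sizes, marginals,
#'   correlation targets).
#' @param n_trials_whole whole-report trials per condition (default 20; the
#'   7-condition design then has 140 trials).
#' @param n_trials_partial partial-report trials per condition (default 18;
#'   288 trials over the 16 conditions).
#' @param partial_exposure_ms calibrated partial-report exposure.
#' @param fit_starts optimization restarts per subject fit (default 4 keeps
#'   the full pipeline fast; raise for final analyses).
#' @param n_boot bootstrap replications in the statistical battery.
#' @param trace_noise_sd_mm,trace_blink_rate_per_min pupil trace generator
#'   settings.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            n_trials_whole = 20,
                            n_trials_partial = 18,
                            partial_exposure_ms = 80,
                            fit_starts = 4,
                            n_boot = 1000,
                            trace_noise_sd_mm = 0.02,
                            trace_blink_rate_per_min = 2) {
  structure(
    list(cohort = cohort, n_trials_whole = n_trials_whole,
         n_trials_partial = n_trials_partial,
         partial_exposure_ms = partial_exposure_ms,
         fit_starts = fit_starts, n_boot = n_boot,
         trace_noise_sd_mm = trace_noise_sd_mm,
         trace_blink_rate_per_min = trace_blink_rate_per_min),
    class = "pipeline_config"
  )
}

## invert the rough PUI calibration of the trace generator: a slow oscillation
## of amplitude A around mean frequency f contributes ~ 240*A*f mm/min of
## cumulative change, plus a small white-noise floor after block averaging
amplitude_for_pui <- function(pui_target, mean_freq_hz = 0.125, noise_floor = 0.5) {
  max(0.01, (pui_target - noise_floor) / (240 * mean_freq_hz))
}

#' Run the full simulate - fit - PUI - analyze pipeline
#'
#' Simulates a cohort, then per subject: whole-report trials from their true
#' attention parameters (refit by maximum likelihood), partial-report trials
#' (alpha refit with the whole-report parameters shared), and a pupil trace
#' whose oscillation amplitude is calibrated to their target PUI (recomputed
#' with \code{\link{compute_pui}}). The measured cohort (fitted parameters and
#' computed pupillary measures alongside the questionnaire scores) then runs
#' through \code{\link{analyze_cohort}}. All stage seeds derive from
#' \code{seed}, and a run manifest records them together with the
#' configuration hash so a rerun reproduces the outputs byte-identically.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param seed integer master seed.
#' @param out_dir optional directory; when given, the true and measured cohort
#'   tables (CSV), per-subject fits (JSON), the analysis report (JSON) and the
#'   manifest (JSON) are written there.
#' @return List of class \code{pipeline_result}: \code{cohort} (simulated
#'   truth), \code{measured} (refit cohort), \code{fits}, \code{report},
#'   \code{manifest}.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  started <- Sys.time()
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  stage_seeds <- list(cohort = sample.int(2^30, 1),
                      subjects = sample.int(2^30, 1),
                      analysis = sample.int(2^30, 1))

  cohort <- simulate_cohort(config$cohort, seed = stage_seeds$cohort)
  measured <- cohort
  fits <- vector("list", nrow(cohort))
  names(fits) <- cohort$subject_id

  for (i in seq_len(nrow(cohort))) {
    sub_seed <- stage_seeds$subjects + i
    truth <- tva_params(cohort$vps[i], cohort$t0[i], cohort$k[i], cohort$mu[i])
    wr <- simulate_whole_report(truth,
                                n_trials_per_condition = config$n_trials_whole,
                                seed = sub_seed,
                                subject_id = cohort$subject_id[i])
    wfit <- fit_whole_report(wr, starts = config$fit_starts, seed = sub_seed + 1)
    pr <- simulate_partial_report(truth, attentional_weights(cohort$alpha[i]),
                                  exposure_ms = config$partial_exposure_ms,
                                  n_trials_per_condition = config$n_trials_partial,
                                  seed = sub_seed + 2,
                                  subject_id = cohort$subject_id[i])
    pfit <- fit_partial_report(pr, shared = wfit$params,
                               starts = config$fit_starts, seed = sub_seed + 3)
    tr <- simulate_pupil_trace(
      base_pd_mm = cohort$pd[i],
      oscillation_amplitude_mm = amplitude_for_pui(cohort$pui[i]),
      noise_sd_mm = config$trace_noise_sd_mm,
      blink_rate_per_min = config$trace_blink_rate_per_min,
      seed = sub_seed + 4
    )
    pui_res <- compute_pui(preprocess_trace(tr))

    measured$vps[i] <- wfit$params$C
    measured$t0[i] <- wfit$params$t0
    measured$k[i] <- wfit$params$K
    measured$mu[i] <- wfit$params$mu
    measured$alpha[i] <- pfit$weights$alpha
    measured$pui[i] <- pui_res$total_pui
    measured$pd[i] <- pui_res$mean_pd
    fits[[i]] <- list(whole = wfit, partial = pfit, pui = pui_res)
  }

  report <- analyze_cohort(measured, n_boot = config$n_boot,
                           seed = stage_seeds$analysis)

  manifest <- list(
    package = "tvarousal",
    version = as.character(packageVersion("tvarousal")),
    seed = seed, stage_seeds = stage_seeds,
    config_hash = config_hash(config),
    n_subjects = nrow(cohort),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = character()
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(cohort = file.path(out_dir, "cohort_true.csv"),
               measured = file.path(out_dir, "cohort_measured.csv"),
               fits = file.path(out_dir, "fits.json"),
               report = file.path(out_dir, "report.json"),
               manifest = file.path(out_dir, "manifest.json"))
    write.csv(cohort, paths["cohort"], row.names = FALSE)
    write.csv(measured, paths["measured"], row.names = FALSE)
    fit_list <- lapply(fits, function(f) {
      w <- write_fit_json(f$whole)
      w$alpha <- f$partial$weights$alpha
      w$pui <- f$pui$total_pui
      w$mean_pd <- f$pui$mean_pd
      w
    })
    jsonlite::write_json(fit_list, paths["fits"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    write_report_json(report, paths["report"])
    manifest$outputs <- as.list(paths)
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  structure(list(cohort = cohort, measured = measured, fits = fits,
                 report = report, manifest = manifest),
            class = "pipeline_result")
}

## md5 of the canonical JSON form of the configuration
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(as_plain(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run over %d subjects (seed %s)\n",
              x$manifest$n_subjects, x$manifest$seed))
  print(x$report)
  invisible(x)
}
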