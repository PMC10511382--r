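#' Default whole-report design
#'
#' Seven effective exposure duration conditions: five masked exposures
#' spanning near-threshold to near-maximum performance plus two unmasked
#' conditions at the second-shortest and the longest exposure.
#'
#' @param masked_exposures_ms the five masked exposure durations.
#' @return Data frame with columns \code{condition_id}, \code{exposure_ms},
#'   \code{masked}.
#' @export
whole_report_design <- function(masked_exposures_ms = c(10, 30, 60, 110, 200)) {
  stopifnot(length(masked_exposures_ms) >= 2)
  sorted <- sort(masked_exposures_ms)
  unmasked <- c(sorted[2], sorted[length(sorted)])
  data.frame(
    condition_id = seq_len(length(masked_exposures_ms) + 2),
    exposure_ms = c(sorted, unmasked),
    masked = c(rep(TRUE, length(sorted)), FALSE, FALSE)
  )
}

#' Simulate whole-report trials from the TVA race model
#'
#' Per trial, a capacity is drawn from the two-point K mixture, each of the
#' six letters is independently encoded with the condition's per-letter
#' probability, and the reported set is a random subset of the encoded letters
#' capped at the drawn capacity.
#'
#' @param params a \code{\link{tva_params}} object.
#' @param design condition table from \code{\link{whole_report_design}}.
#' @param n_trials_per_condition trials per condition (default 20, giving the
#'   140-trial standard design).
#' @param n_letters display size.
#' @param seed optional integer seed.
#' @param subject_id subject label.
#' @return A data frame of class \code{whole_report_data} with one row per
#'   trial: \code{subject_id}, \code{paradigm}, \code{condition_id},
#'   \code{exposure_ms}, \code{masked}, \code{displayed}, \code{reported},
#'   \code{score}.
#' @export
simulate_whole_report <- function(params, design = whole_report_design(),
                                  n_trials_per_condition = 20, n_letters = 6,
                                  seed = NULL, subject_id = "S1") {
  stopifnot(inherits(params, "tva_params"))
  if (is.null(design$exposure_ms) || is.null(design$masked)) {
    stop("simulate_whole_report: design needs exposure_ms and masked columns",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  caps <- capacity_pmf(params)
  cap_vals <- as.integer(names(caps))
  n_trials <- n_trials_per_condition
  per_cond <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    p <- condition_prediction(params, design$exposure_ms[i], design$masked[i],
                              n_letters)$p_encode
    k <- if (length(cap_vals) == 1) rep(cap_vals, n_trials)
         else sample(cap_vals, n_trials, replace = TRUE, prob = caps)
    displayed <- reported <- character(n_trials)
    score <- integer(n_trials)
    for (t in seq_len(n_trials)) {
      shown <- sample(REPORT_ALPHABET, n_letters)
      encoded <- shown[runif(n_letters) < p]
      stored <- if (length(encoded) > k[t]) sample(encoded, k[t]) else encoded
      displayed[t] <- paste(shown, collapse = "")
      reported[t] <- paste(stored, collapse = "")
      score[t] <- length(stored)
    }
    per_cond[[i]] <- data.frame(
      subject_id = subject_id, paradigm = "whole",
      condition_id = design$condition_id[i],
      exposure_ms = design$exposure_ms[i], masked = design$masked[i],
      displayed = displayed, reported = reported, score = score,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, per_cond)
  rownames(out) <- NULL
  class(out) <- c("whole_report_data", "data.frame")
  out
}

#' Simulate partial-report trials from the exponential race
#'
#' Finishing times of displayed items are sampled from exponential
#' distributions with rates \code{C * w / sum(w)}; items finishing within the
#' effective exposure are encoded, the fastest enter visual short-term memory
#' up to the drawn capacity, and stored targets are reported.
#'
#' @param shared a \code{\link{tva_params}} object (C, t0, K).
#' @param weights an \code{\link{attentional_weights}} object or a numeric
#'   alpha.
#' @param design condition table from \code{\link{partial_report_conditions}}.
#' @param exposure_ms the single calibrated exposure duration (displays are
#'   always masked).
#' @param n_trials_per_condition trials per condition (default 18, giving the
#'   288-trial standard design).
#' @param seed optional integer seed.
#' @param subject_id subject label.
#' @return A data frame of class \code{partial_report_data} with one row per
#'   trial: \code{subject_id}, \code{paradigm}, \code{condition_id},
#'   \code{type}, \code{exposure_ms}, \code{masked}, \code{displayed}
#'   (\code{"A:T;B:D"} form), \code{reported}, \code{score} (targets
#'   reported).
#' @export
simulate_partial_report <- function(shared, weights,
                                    design = partial_report_conditions(),
                                    exposure_ms = 80,
                                    n_trials_per_condition = 18,
                                    seed = NULL, subject_id = "S1") {
  stopifnot(inherits(shared, "tva_params"))
  if (!inherits(weights, "attentional_weights")) weights <- attentional_weights(weights)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  a <- max(0, exposure_ms - shared$t0) / 1000
  caps <- capacity_pmf(shared)
  cap_vals <- as.integer(names(caps))
  n_trials <- n_trials_per_condition
  per_cond <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    roles <- c(design$role1[i], design$role2[i])
    roles <- roles[!is.na(roles)]
    w <- ifelse(roles == "T", 1, weights$alpha)
    rates <- shared$C * w / sum(w)
    k_draw <- if (length(cap_vals) == 1) rep(cap_vals, n_trials)
              else sample(cap_vals, n_trials, replace = TRUE, prob = caps)
    displayed <- reported <- character(n_trials)
    score <- integer(n_trials)
    for (t in seq_len(n_trials)) {
      letters_shown <- sample(REPORT_ALPHABET, length(roles))
      times <- ifelse(rates > 0, rexp(length(rates), pmax(rates, 1e-12)), Inf)
      encoded <- which(times <= a)
      stored <- encoded[order(times[encoded])][seq_len(min(k_draw[t], length(encoded)))]
      rep_letters <- letters_shown[stored[roles[stored] == "T"]]
      displayed[t] <- paste(paste(letters_shown, roles, sep = ":"), collapse = ";")
      reported[t] <- paste(rep_letters, collapse = "")
      score[t] <- length(rep_letters)
    }
    per_cond[[i]] <- data.frame(
      subject_id = subject_id, paradigm = "partial",
      condition_id = design$condition_id[i], type = design$type[i],
      exposure_ms = exposure_ms, masked = TRUE,
      displayed = displayed, reported = reported, score = score,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, per_cond)
  rownames(out) <- NULL
  class(out) <- c("partial_report_data", "data.frame")
  out
}

#' Simulate a pupillographic sleepiness test trace
#'
#' A 25-Hz diameter series built as baseline + linear drift + slow
#' random-phase oscillation (the "fatigue waves" whose amplitude grows as
#' arousal drops) + white measurement noise, with blink artifacts (invalid
#' gaps of 0.1-0.4 s) and occasional dropouts longer than 3 s.
#'
#' @param duration_s recording length (default 660 s = 11 min).
#' @param sampling_rate Hz (default 25).
#' @param base_pd_mm baseline pupil diameter.
#' @param drift_mm_per_min linear drift (negative = slow constriction).
#' @param oscillation_amplitude_mm total amplitude of the slow oscillation.
#' @param oscillation_freq_hz frequency band of the slow oscillation
#'   (default 0.05-0.2 Hz; three random components are drawn from it).
#' @param noise_sd_mm white noise SD.
#' @param blink_rate_per_min expected blinks per minute.
#' @param long_dropout_rate_per_min expected >3-s dropouts per minute.
#' @param seed optional integer seed.
#' @return A raw \code{\link{pupil_trace}} with blink samples marked invalid.
#' @export
simulate_pupil_trace <- function(duration_s = 660, sampling_rate = 25,
                                 base_pd_mm = 6.9, drift_mm_per_min = -0.05,
                                 oscillation_amplitude_mm = 0.3,
                                 oscillation_freq_hz = c(0.05, 0.2),
                                 noise_sd_mm = 0.02,
                                 blink_rate_per_min = 2,
                                 long_dropout_rate_per_min = 0.05,
                                 seed = NULL) {
  if (duration_s <= 82.5) {
    stop("simulate_pupil_trace: duration_s must exceed one 82.5-s segment",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n <- round(duration_s * sampling_rate)
  t <- seq_len(n) / sampling_rate
  d <- base_pd_mm + drift_mm_per_min * t / 60
  n_comp <- 3
  freqs <- runif(n_comp, oscillation_freq_hz[1], oscillation_freq_hz[2])
  phases <- runif(n_comp, 0, 2 * pi)
  amp_weights <- c(0.5, 0.3, 0.2)
  for (j in seq_len(n_comp)) {
    d <- d + oscillation_amplitude_mm * amp_weights[j] *
      sin(2 * pi * freqs[j] * t + phases[j])
  }
  if (noise_sd_mm > 0) d <- d + rnorm(n, 0, noise_sd_mm)

  valid <- rep(TRUE, n)
  n_blinks <- rpois(1, blink_rate_per_min * duration_s / 60)
  if (n_blinks > 0) {
    starts <- sample.int(n, n_blinks)
    durs <- round(runif(n_blinks, 0.1, 0.4) * sampling_rate)
    for (b in seq_len(n_blinks)) {
      idx <- starts[b]:min(n, starts[b] + durs[b])
      d[idx] <- 0   # device reports collapsed diameter during blinks
      valid[idx] <- FALSE
    }
  }
  n_drop <- rpois(1, long_dropout_rate_per_min * duration_s / 60)
  if (n_drop > 0) {
    starts <- sample.int(n, n_drop)
    durs <- round(runif(n_drop, 3.5, 6) * sampling_rate)
    for (b in seq_len(n_drop)) {
      idx <- starts[b]:min(n, starts[b] + durs[b])
      d[idx] <- 0
      valid[idx] <- FALSE
    }
  }
  pupil_trace(d, sampling_rate, valid = valid)
}
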