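## variable order used throughout the cohort machinery
COHORT_VARS <- c("vps", "k", "t0", "alpha", "mu", "pui", "pd",
                 "fatigue_mental", "depression", "sleepiness",
                 "age", "education", "days_since_infection")

#' Default target rank-correlation matrix for the synthetic cohort
#'
#' Built from a single-factor path model in which a latent arousal level
#' drives processing speed (positively), pupillary unrest and mental fatigue
#' (negatively): loadings are chosen so the implied pairwise correlations hit
#' the study-level anchors rho(VPS, PUI) ~ -0.51, rho(VPS, fatigue) ~ -0.54
#' and rho(PUI, PD) ~ -0.45 (through a pupil-specific factor shared by PUI and
#' PD only). Capacity K is driven by VPS alone (rho = 0.574), which encodes
#' the full-mediation structure PUI -> VPS -> K: K is conditionally
#' independent of PUI given VPS. Depression correlates with fatigue through a
#' fatigue-specific factor (rho ~ 0.50) and sleepiness loads weakly on
#' fatigue (rho ~ 0.30); age, education, persistence mu and time since
#' infection are independent.
#'
#' @return A symmetric positive-definite correlation matrix over the cohort
#'   variables.
#' @export
default_cohort_correlation <- function() {
  v <- COHORT_VARS
  p <- length(v)
  ## loading matrix over independent factors: A (arousal), uP (pupil-specific),
  ## uF (fatigue-specific), eV (speed-specific, shared with K) + uniquenesses
  L <- matrix(0, p, 4, dimnames = list(v, c("A", "uP", "uF", "eV")))
  L["vps", c("A", "eV")] <- c(0.75, sqrt(1 - 0.75^2))
  L["pui", c("A", "uP")] <- c(-0.68, sqrt(1 - 0.68^2))
  L["fatigue_mental", c("A", "uF")] <- c(-0.72, sqrt(1 - 0.72^2))
  L["pd", "uP"] <- -0.447 / sqrt(1 - 0.68^2)     # rho(pd, pui) = -0.447
  L["depression", "uF"] <- 0.498 / sqrt(1 - 0.72^2)  # rho(dep, fatigue) = 0.498
  L["t0", "A"] <- -0.45
  L["alpha", "A"] <- 0.33
  ## chained variables expressed through their parents' loadings
  L["k", ] <- 0.574 * L["vps", ]                  # K <- VPS only
  L["sleepiness", ] <- 0.30 * L["fatigue_mental", ]
  R <- L %*% t(L)
  diag(R) <- 1
  dimnames(R) <- list(v, v)
  R
}

#' Configuration for the synthetic cohort generator
#'
#' Group-level marginal means/SDs are parameterized from the study's
#' descriptive tables: TVA parameters and questionnaire totals for both
#' groups, pupillary measures for the patient group (controls were not
#' measured in the study; plausible healthy daytime values are supplied so
#' both groups carry complete records). Scale bounds clamp the
#' back-transformed values; questionnaire scores are rounded to integers.
#'
#' @param n_per_group subjects per group (default 40).
#' @param means,sds named lists (\code{control}, \code{patient}) of named
#'   numeric vectors over the cohort variables.
#' @param target_spearman target rank-correlation matrix (default
#'   \code{\link{default_cohort_correlation}}).
#' @param prop_female per-group probability of female sex (study ratios
#'   26/40 and 32/40).
#' @param hads_max upper bound for the depression score. The instrument's
#'   standard range is 0-21; the source description says 0-24 -- the
#'   configured bound is used and the discrepancy is documented here.
#' @param bounds named list of c(lower, upper) clamps per variable.
#' @param integer_vars variables rounded to integers after transform.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_per_group = 40,
                          means = NULL, sds = NULL,
                          target_spearman = default_cohort_correlation(),
                          prop_female = c(control = 0.65, patient = 0.80),
                          hads_max = 21,
                          bounds = NULL,
                          integer_vars = c("fatigue_mental", "depression",
                                           "sleepiness", "age", "education",
                                           "days_since_infection")) {
  default_means <- list(
    control = c(vps = 33.72, k = 3.89, t0 = 9.92, alpha = 0.50, mu = 150,
                pui = 3.20, pd = 7.40, fatigue_mental = 8.97,
                depression = 2.72, sleepiness = 7.30, age = 44.05,
                education = 11.25, days_since_infection = NA),
    patient = c(vps = 26.23, k = 3.16, t0 = 15.16, alpha = 0.44, mu = 150,
                pui = 4.39, pd = 6.88, fatigue_mental = 18.65,
                depression = 6.85, sleepiness = 11.24, age = 47.95,
                education = 10.75, days_since_infection = 428)
  )
  default_sds <- list(
    control = c(vps = 11.92, k = 0.71, t0 = 12.19, alpha = 0.33, mu = 40,
                pui = 1.40, pd = 0.90, fatigue_mental = 2.90,
                depression = 4.55, sleepiness = 4.20, age = 12.25,
                education = 1.34, days_since_infection = NA),
    patient = c(vps = 12.26, k = 0.95, t0 = 13.65, alpha = 0.25, mu = 40,
                pui = 1.76, pd = 0.97, fatigue_mental = 4.17,
                depression = 3.98, sleepiness = 4.31, age = 8.44,
                education = 1.53, days_since_infection = 94.85)
  )
  if (is.null(means)) means <- default_means
  if (is.null(sds)) sds <- default_sds
  if (is.null(bounds)) {
    bounds <- list(vps = c(2, 200), k = c(0.5, 6), t0 = c(0, 100),
                   alpha = c(0, 4), mu = c(0, 500), pui = c(0.3, 15),
                   pd = c(1.5, 9), fatigue_mental = c(5, 25),
                   depression = c(0, hads_max), sleepiness = c(0, 24),
                   age = c(18, 90), education = c(8, 14),
                   days_since_infection = c(90, 1500))
  }
  for (g in c("control", "patient")) {
    sd_g <- sds[[g]]
    if (any(!is.na(sd_g) & sd_g <= 0)) {
      stop("cohort_config: SDs must be > 0", call. = FALSE)
    }
  }
  if (any(abs(target_spearman) > 1)) {
    bad <- which(abs(target_spearman) > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("cohort_config: target correlation (%s, %s) outside [-1, 1]",
                 rownames(target_spearman)[bad[1]],
                 colnames(target_spearman)[bad[2]]), call. = FALSE)
  }
  structure(
    list(n_per_group = n_per_group, means = means, sds = sds,
         target_spearman = target_spearman, prop_female = prop_female,
         hads_max = hads_max, bounds = bounds, integer_vars = integer_vars),
    class = "cohort_config"
  )
}

#' Simulate a subject-level cohort table
#'
#' Draws a Gaussian copula over the cohort variables whose correlation matrix
#' is derived from the configured target Spearman matrix (Pearson =
#' \code{2*sin(pi*rho_s/6)}), maps each variable to its group-specific normal
#' marginal, then clamps to scale bounds and rounds integer-valued measures.
#' Controls receive \code{NA} for days since infection, matching the study
#' design.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param seed optional integer seed.
#' @return A data frame of class \code{cohort_table}: \code{subject_id},
#'   \code{group} (\code{"control"}/\code{"patient"}), \code{sex}, and one
#'   column per cohort variable.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_per_group = 10), seed = 1)
#' table(coh$group)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  Rs <- config$target_spearman
  vars <- rownames(Rs)
  Rp <- 2 * sin(pi * Rs / 6)
  diag(Rp) <- 1
  ch <- tryCatch(chol(Rp), error = function(e) {
    off <- abs(Rs); diag(off) <- 0
    bad <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop(sprintf(paste("simulate_cohort: target correlation matrix is not",
                       "positive semi-definite (strongest constraint: %s vs %s)"),
                 vars[bad[1]], vars[bad[2]]), call. = FALSE)
  })
  groups <- c("control", "patient")
  out <- list()
  for (g in groups) {
    n <- config$n_per_group
    Z <- matrix(rnorm(n * length(vars)), n) %*% ch
    colnames(Z) <- vars
    df <- data.frame(
      subject_id = sprintf("%s%02d", if (g == "control") "HC" else "PC", seq_len(n)),
      group = g,
      sex = ifelse(runif(n) < config$prop_female[[g]], "F", "M"),
      stringsAsFactors = FALSE
    )
    for (v in vars) {
      m <- config$means[[g]][[v]]
      s <- config$sds[[g]][[v]]
      if (is.na(m) || is.na(s)) {
        df[[v]] <- NA_real_
        next
      }
      x <- m + s * Z[, v]
      b <- config$bounds[[v]]
      x <- pmin(pmax(x, b[1]), b[2])
      if (v %in% config$integer_vars) x <- round(x)
      df[[v]] <- x
    }
    out[[g]] <- df
  }
  res <- rbind(out$control, out$patient)
  res$group <- factor(res$group, levels = groups)
  class(res) <- c("cohort_table", "data.frame")
  res
}
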