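## one-tailed directions for the group battery: x = controls, y = patients;
## patients are hypothesized lower on C, K, alpha and higher on t0 and the
## fatigue/depression/sleepiness questionnaires
GROUP_TEST_DIRECTIONS <- c(
  vps = "greater", k = "greater", alpha = "greater",
  t0 = "less", fatigue_mental = "less", depression = "less",
  sleepiness = "less"
)

#' Full statistical battery over a cohort table
#'
#' Reproduces the analysis chain over a subject-level cohort: two-tailed
#' rank-sum tests for the matching variables (age, education) plus a Pearson
#' chi-squared test of the sex ratio; one-tailed rank-sum tests with effect
#' size r for the attention parameters and questionnaires (BH-FDR within the
#' family); bootstrapped kernel-density non-overlap for the attention
#' parameters; the Spearman correlation matrix within the patient group with
#' BH-FDR; the two regression models for processing speed (PUI + mental
#' fatigue, then + covariates) with bootstrap CIs, Cohen's f2 and the nested
#' model F test; and the PUI -> VPS -> K mediation.
#'
#' @param cohort a \code{\link{simulate_cohort}}-style data frame with
#'   \code{group} and the cohort measure columns.
#' @param n_boot bootstrap replications for non-overlap, regression and
#'   mediation (default 1000).
#' @param seed optional integer seed covering every resampling stage.
#' @param q FDR level (default 0.05).
#' @param nonoverlap_vars variables receiving a distribution non-overlap
#'   estimate.
#' @return An object of class \code{arousal_report}: \code{demographics},
#'   \code{group_tests} (data frame with W, z, p, r, FDR-adjusted p and
#'   significance), \code{nonoverlap}, \code{correlations}
#'   (\code{\link{spearman_matrix}} result), \code{regression} (model1,
#'   model2, nested F, f2, FDR over model p-values), \code{mediation}, and
#'   \code{flags} (headline qualitative findings).
#' @export
analyze_cohort <- function(cohort, n_boot = 1000, seed = NULL, q = 0.05,
                           nonoverlap_vars = c("vps", "k", "t0", "alpha")) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  ctrl <- cohort[cohort$group == "control", ]
  pat <- cohort[cohort$group == "patient", ]
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  seeds <- sample.int(.Machine$integer.max %/% 2, 8)

  ## -- demographics (two-tailed; matching checks) --
  demographics <- list()
  for (v in intersect(c("age", "education"), names(cohort))) {
    demographics[[v]] <- wilcoxon_rank_sum(ctrl[[v]], pat[[v]], "two.sided")
  }
  if ("sex" %in% names(cohort)) {
    tab <- table(cohort$group, cohort$sex)
    demographics$sex <- group_contingency_test(as.matrix(tab))
  }

  ## -- one-tailed group battery with effect size r and BH-FDR --
  vars <- intersect(names(GROUP_TEST_DIRECTIONS), names(cohort))
  tests <- lapply(vars, function(v) {
    wilcoxon_rank_sum(ctrl[[v]], pat[[v]],
                      alternative = GROUP_TEST_DIRECTIONS[[v]])
  })
  group_tests <- data.frame(
    variable = vars,
    W = vapply(tests, `[[`, numeric(1), "W"),
    z = vapply(tests, `[[`, numeric(1), "z"),
    p = vapply(tests, `[[`, numeric(1), "p"),
    r = vapply(tests, `[[`, numeric(1), "r"),
    stringsAsFactors = FALSE
  )
  fdr <- bh_fdr(group_tests$p, q)
  group_tests$p_adjusted <- fdr$p_adjusted
  group_tests$significant <- fdr$rejected

  ## -- distribution non-overlap for the attention parameters --
  nonoverlap <- list()
  for (i in seq_along(nonoverlap_vars)) {
    v <- nonoverlap_vars[i]
    if (!v %in% names(cohort)) next
    if (nrow(ctrl) < 5 || nrow(pat) < 5) next  # KDE needs a minimal sample
    nonoverlap[[v]] <- distribution_nonoverlap(ctrl[[v]], pat[[v]],
                                               n_boot = n_boot,
                                               seed = seeds[1] + i)
  }

  ## -- Spearman matrix within the patient group --
  cor_vars <- intersect(c("vps", "pui", "fatigue_mental", "pd", "depression",
                          "sleepiness", "days_since_infection", "age",
                          "k", "t0", "alpha"), names(cohort))
  correlations <- spearman_matrix(pat, cor_vars, q = q)

  ## -- regression models for VPS within patients --
  m1_pred <- c("pui", "fatigue_mental")
  m2_pred <- c(m1_pred, intersect(c("depression", "sleepiness",
                                    "days_since_infection", "age"),
                                  names(pat)))
  pat_cc <- pat[complete.cases(pat[c("vps", m2_pred)]), ]
  model1 <- ols_regression(pat_cc, "vps", m1_pred, n_boot = n_boot, seed = seeds[6])
  model2 <- ols_regression(pat_cc, "vps", m2_pred, n_boot = n_boot, seed = seeds[7])
  nested <- nested_model_f_test(model1, model2)
  model_fdr <- bh_fdr(c(model1 = model1$model_p, model2 = model2$model_p), q)
  regression <- list(model1 = model1, model2 = model2, nested = nested,
                     f2 = model1$f2,
                     model_p_adjusted = setNames(model_fdr$p_adjusted,
                                                 c("model1", "model2")))

  ## -- mediation: PUI -> VPS -> K --
  mediation <- mediate(pat, x = "pui", mediator = "vps", y = "k",
                       n_boot = n_boot, seed = seeds[8])

  flags <- list(
    vps_lower_in_patients =
      group_tests$significant[group_tests$variable == "vps"],
    vps_lower_in_patients_raw =
      group_tests$p[group_tests$variable == "vps"] < 0.05,
    regression_significant = regression$model_p_adjusted[["model1"]] <= 0.05,
    full_mediation = mediation$full_mediation
  )

  structure(
    list(demographics = demographics, group_tests = group_tests,
         nonoverlap = nonoverlap, correlations = correlations,
         regression = regression, mediation = mediation, flags = flags,
         n_boot = n_boot, seed = seed, q = q),
    class = "arousal_report"
  )
}

#' @export
print.arousal_report <- function(x, ...) {
  cat("Group comparisons (one-tailed rank-sum, BH-FDR):\n")
  tab <- x$group_tests
  tab[c("W", "z", "r")] <- lapply(tab[c("W", "z", "r")], round, 2)
  tab[c("p", "p_adjusted")] <- lapply(tab[c("p", "p_adjusted")], signif, 3)
  print(tab, row.names = FALSE)
  if (length(x$nonoverlap)) {
    cat("\nDistribution non-overlap:\n")
    for (v in names(x$nonoverlap)) {
      cat(sprintf("  %s: %.2f\n", v, x$nonoverlap[[v]]$estimate))
    }
  }
  cat(sprintf("\nModel 1 (VPS ~ PUI + mental fatigue): R2 = %.3f (adj. %.3f), f2 = %.2f, p = %.4g\n",
              x$regression$model1$R2, x$regression$model1$R2_adj,
              x$regression$f2, x$regression$model1$model_p))
  cat(sprintf("Nested model F(%d, %d) = %.2f, p = %.3f\n",
              x$regression$nested$df1, x$regression$nested$df2,
              x$regression$nested$F, x$regression$nested$p))
  print(x$mediation)
  invisible(x)
}
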