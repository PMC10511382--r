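test_that("generators are reproducible under a fixed seed", {
  p <- tva_params(30, 10, 3.5, 150)
  expect_identical(simulate_whole_report(p, seed = 3),
                   simulate_whole_report(p, seed = 3))
  expect_identical(simulate_partial_report(p, 0.5, seed = 3),
                   simulate_partial_report(p, 0.5, seed = 3))
  t1 <- simulate_pupil_trace(seed = 3)
  t2 <- simulate_pupil_trace(seed = 3)
  expect_identical(t1$diameter, t2$diameter)
  expect_identical(simulate_cohort(cohort_config(n_per_group = 30), seed = 3),
                   simulate_cohort(cohort_config(n_per_group = 30), seed = 3))
})

test_that("the standard designs have 140 and 288 trials", {
  p <- tva_params(33.77, 5.96, 3.85, 150)
  wr <- simulate_whole_report(p, seed = 1)
  expect_equal(nrow(wr), 140)
  expect_equal(length(unique(paste(wr$exposure_ms, wr$masked))), 7)
  pr <- simulate_partial_report(p, 0.45, seed = 1)
  expect_equal(nrow(pr), 288)
  expect_equal(as.vector(table(pr$condition_id)), rep(18, 16))
})

test_that("below-threshold simulation produces only zero scores", {
  p <- tva_params(30, 500, 4)
  design <- data.frame(condition_id = 1, exposure_ms = 50, masked = TRUE)
  d <- simulate_whole_report(p, design, n_trials_per_condition = 50, seed = 2)
  expect_true(all(d$score == 0))
  expect_true(all(d$reported == ""))
})

test_that("empirical whole-report means converge to the closed form", {
  p <- tva_params(30, 15, 3.5, 150)
  design <- data.frame(condition_id = 1:2, exposure_ms = c(110, 110),
                       masked = c(TRUE, FALSE))
  d <- simulate_whole_report(p, design, n_trials_per_condition = 5e4, seed = 4)
  for (i in 1:2) {
    pred <- condition_prediction(p, design$exposure_ms[i], design$masked[i])
    sub <- d$score[d$condition_id == design$condition_id[i]]
    se <- sd(sub) / sqrt(length(sub))
    expect_lt(abs(mean(sub) - pred$expected_score), 3 * se)
  }
})

test_that("empirical partial-report accuracy converges to the closed form", {
  p <- tva_params(30, 10, 3.85)
  w <- attentional_weights(0.6)
  design <- partial_report_conditions()[c(1, 5, 13), ]  # one of each type
  d <- simulate_partial_report(p, w, design, n_trials_per_condition = 3e4,
                               seed = 6)
  for (cid in design$condition_id) {
    sub <- d[d$condition_id == cid, ]
    pr <- partial_report_prediction(p, w, sub$type[1], sub$exposure_ms[1])
    mean_pred <- sum(as.numeric(names(pr$report_pmf)) * pr$report_pmf)
    se <- sd(sub$score) / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$score) - mean_pred), 3.5 * se)
  }
})

test_that("perfect selection never stores a distractor", {
  p <- tva_params(30, 10, 1)  # capacity 1: an encoded distractor would displace
  d <- simulate_partial_report(p, attentional_weights(0), seed = 7)
  td <- d[d$type == "TD", ]
  single <- d[d$type == "T", ]
  # with alpha = 0 the distractor never races, so T-D accuracy ~ single-T
  p_td <- mean(td$score); p_t <- mean(single$score)
  se <- sqrt(p_td * (1 - p_td) / nrow(td) + p_t * (1 - p_t) / nrow(single))
  expect_lt(abs(p_td - p_t), 3.5 * se + 1e-9)
})

test_that("a flat noiseless pupil generator yields zero unrest", {
  tr <- simulate_pupil_trace(oscillation_amplitude_mm = 0, noise_sd_mm = 0,
                             drift_mm_per_min = 0, blink_rate_per_min = 0,
                             long_dropout_rate_per_min = 0, seed = 8)
  expect_equal(compute_pui(tr)$total_pui, 0)
})

test_that("pupillary unrest rises with oscillation amplitude", {
  puis <- vapply(c(0.05, 0.1, 0.2), function(A) {
    tr <- simulate_pupil_trace(oscillation_amplitude_mm = A, noise_sd_mm = 0,
                               blink_rate_per_min = 0,
                               long_dropout_rate_per_min = 0, seed = 9)
    compute_pui(tr)$total_pui
  }, numeric(1))
  expect_true(all(diff(puis) > 0))
})

test_that("cohort rank correlations hit their copula targets", {
  coh <- simulate_cohort(cohort_config(n_per_group = 2000), seed = 10)
  pat <- coh[coh$group == "patient", ]
  sp <- function(a, b) cor(pat[[a]], pat[[b]], method = "spearman")
  expect_lt(abs(sp("vps", "pui") - (-0.51)), 0.05)
  expect_lt(abs(sp("vps", "fatigue_mental") - (-0.54)), 0.05)
  expect_lt(abs(sp("pui", "pd") - (-0.447)), 0.05)
  expect_lt(abs(sp("vps", "k") - 0.574), 0.05)
})

test_that("zero loadings give an uncorrelated cohort", {
  cfg <- cohort_config(n_per_group = 2000,
                       target_spearman = diag(length(rownames(default_cohort_correlation()))))
  dimnames(cfg$target_spearman) <- dimnames(default_cohort_correlation())
  coh <- simulate_cohort(cfg, seed = 11)
  pat <- coh[coh$group == "patient", ]
  for (pair in list(c("vps", "pui"), c("vps", "fatigue_mental"), c("pui", "pd"))) {
    expect_lt(abs(cor(pat[[pair[1]]], pat[[pair[2]]], method = "spearman")), 0.05)
  }
})

test_that("group separations and scale bounds match the configuration", {
  coh <- simulate_cohort(cohort_config(n_per_group = 2000), seed = 12)
  m <- tapply(coh$fatigue_mental, coh$group, mean)
  expect_lt(abs(m[["patient"]] - 18.65), 0.5)
  expect_lt(abs(m[["control"]] - 8.97), 0.5)
  expect_true(all(coh$fatigue_mental >= 5 & coh$fatigue_mental <= 25))
  expect_true(all(coh$depression >= 0 & coh$depression <= 21))
  expect_true(all(coh$sleepiness >= 0 & coh$sleepiness <= 24))
  expect_true(all(coh$alpha >= 0))
  expect_true(all(coh$k <= 6))
  expect_true(all(is.na(coh$days_since_infection[coh$group == "control"])))
  mv <- tapply(coh$vps, coh$group, mean)
  expect_gt(mv[["control"]], mv[["patient"]])
})

test_that("an infeasible correlation target is rejected with the pair named", {
  cfg <- cohort_config()
  cfg$target_spearman["vps", "pui"] <- cfg$target_spearman["pui", "vps"] <- -0.999
  cfg$target_spearman["vps", "k"] <- cfg$target_spearman["k", "vps"] <- 0.999
  cfg$target_spearman["pui", "k"] <- cfg$target_spearman["k", "pui"] <- 0.9
  expect_error(simulate_cohort(cfg, seed = 1), "positive semi-definite")
})
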