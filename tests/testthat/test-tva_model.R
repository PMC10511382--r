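test_that("condition predictions match brute-force subset enumeration", {
  # grid of parameter settings, each checked against the 2^6-subset oracle
  cases <- expand.grid(C = c(8, 24, 60), t0 = c(0, 10), K = c(2, 3.85, 6),
                       exposure = c(20, 110, 300), masked = c(TRUE, FALSE))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    params <- tva_params(cs$C, cs$t0, cs$K, mu = 150)
    pr <- condition_prediction(params, cs$exposure, cs$masked)
    a <- max(0, cs$exposure + 150 * (!cs$masked) - cs$t0)
    p <- 1 - exp(-cs$C / 6 * a / 1000)
    expect_equal(unname(pr$score_pmf), oracle_score_pmf(p, cs$K), tolerance = 1e-10)
    expect_equal(pr$expected_score, oracle_expected_score(p, cs$K), tolerance = 1e-10)
  }
})

test_that("below-threshold exposures encode nothing", {
  params <- tva_params(30, 50, 4)
  pr <- condition_prediction(params, 40, masked = TRUE)
  expect_equal(pr$p_encode, 0)
  expect_equal(unname(pr$score_pmf[1]), 1)
  expect_equal(pr$expected_score, 0)
})

test_that("expected score saturates at K for very fast processing", {
  params <- tva_params(1e6, 0, 4)
  pr <- condition_prediction(params, 200, masked = TRUE)
  expect_equal(pr$expected_score, 4, tolerance = 1e-6)
})

test_that("score pmf sums to one across a random parameter grid", {
  set.seed(42)
  for (i in 1:50) {
    params <- tva_params(runif(1, 1, 100), runif(1, 0, 50), runif(1, 0, 6),
                         runif(1, 0, 300))
    pr <- condition_prediction(params, runif(1, 5, 400), masked = runif(1) < 0.5)
    expect_equal(sum(pr$score_pmf), 1, tolerance = 1e-12)
    expect_true(all(pr$score_pmf >= 0))
  }
})

test_that("expected score is monotone in exposure, C and K", {
  es <- function(C, K, exp_ms) {
    condition_prediction(tva_params(C, 10, K), exp_ms, TRUE)$expected_score
  }
  exposures <- seq(20, 400, by = 20)
  expect_true(all(diff(vapply(exposures, function(e) es(30, 4, e), 0)) >= 0))
  expect_true(all(diff(vapply(seq(5, 100, 5), function(C) es(C, 4, 100), 0)) >= 0))
  expect_true(all(diff(vapply(seq(1, 6, 0.5), function(K) es(30, K, 100), 0)) >= 0))
})

test_that("an uncapped store reduces to the pure binomial mean", {
  params <- tva_params(40, 5, 6)
  pr <- condition_prediction(params, 120, masked = TRUE)
  expect_equal(pr$expected_score, 6 * pr$p_encode, tolerance = 1e-12)
})

test_that("unmasked displays gain exactly mu of effective exposure", {
  params <- tva_params(35, 12, 3.5, mu = 140)
  pm <- condition_prediction(params, 100 + 140, masked = TRUE)
  pu <- condition_prediction(params, 100, masked = FALSE)
  expect_equal(pm$score_pmf, pu$score_pmf, tolerance = 1e-12)
})

test_that("whole-report log-likelihood matches a per-trial product oracle", {
  params <- tva_params(24, 10, 4)
  empty <- data.frame(exposure_ms = numeric(0), masked = logical(0),
                      score = integer(0))
  expect_equal(whole_report_loglik(params, empty), 0)

  # below threshold, observed score 0: P = 1, logL = 0
  one <- data.frame(exposure_ms = 5, masked = TRUE, score = 0L)
  expect_equal(whole_report_loglik(params, one), 0)

  toy <- data.frame(exposure_ms = c(110, 110, 200), masked = c(TRUE, TRUE, FALSE),
                    score = c(2L, 4L, 3L))
  ll_oracle <- 0
  for (i in 1:3) {
    a <- max(0, toy$exposure_ms[i] + 0 * (!toy$masked[i]) - 10)
    p <- 1 - exp(-4 * a / 1000)
    ll_oracle <- ll_oracle + log(oracle_score_pmf(p, 4)[toy$score[i] + 1])
  }
  expect_equal(whole_report_loglik(params, toy), ll_oracle, tolerance = 1e-10)
})

test_that("impossible scores hit the likelihood floor instead of -Inf", {
  params <- tva_params(30, 10, 2)  # capacity 2 cannot produce a score of 5
  d <- data.frame(exposure_ms = 100, masked = TRUE, score = 5L)
  expect_equal(whole_report_loglik(params, d), log(1e-12))
})

test_that("fit_r2 behaves as a squared Pearson correlation", {
  expect_equal(fit_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(fit_r2(c(1, 2, 3), c(2, 3, 4)), 1)  # shift invariance
  obs <- c(1.0, 2.0, 3.0); pred <- c(1.1, 1.9, 3.2)
  expect_equal(fit_r2(obs, pred), cor(obs, pred)^2)
  expect_warning(r2 <- fit_r2(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r2))
})

test_that("maximum likelihood recovers generating parameters", {
  truth <- tva_params(30, 15, 3.5, 150)
  d <- simulate_whole_report(truth, n_trials_per_condition = 2000, seed = 11)
  fit <- fit_whole_report(d, starts = 8, seed = 12)
  expect_lt(abs(fit$params$C / 30 - 1), 0.10)
  expect_lt(abs(fit$params$t0 - 15), 10)
  expect_lt(abs(fit$params$K - 3.5), 0.3)
  expect_true(is.finite(fit$loglik))
  expect_identical(fit$convergence$status, "converged")
})

test_that("a single-condition dataset is rejected as unidentifiable", {
  d <- data.frame(exposure_ms = rep(100, 20), masked = TRUE,
                  score = rep(3L, 20))
  expect_error(fit_whole_report(d), "unidentifiable")
})

test_that("fitting idealized condition means gives near-perfect R2", {
  truth <- tva_params(33, 8, 4, 150)
  design <- whole_report_design()
  rows <- lapply(seq_len(nrow(design)), function(i) {
    es <- condition_prediction(truth, design$exposure_ms[i],
                               design$masked[i])$expected_score
    # 20 integer scores whose mean reproduces the expected value to 1/40
    n_hi <- round(20 * (es - floor(es)))
    data.frame(exposure_ms = design$exposure_ms[i], masked = design$masked[i],
               score = c(rep(floor(es), 20 - n_hi), rep(ceiling(es), n_hi)))
  })
  fit <- fit_whole_report(do.call(rbind, rows), starts = 6, seed = 5)
  expect_gte(fit$R2_fit, 0.99)
})

test_that("the likelihood prefers the generating parameters on average", {
  truth <- tva_params(30, 10, 3.5, 150)
  worse <- tva_params(45, 25, 2.5, 80)
  diffs <- vapply(1:5, function(s) {
    d <- simulate_whole_report(truth, n_trials_per_condition = 50, seed = 100 + s)
    whole_report_loglik(truth, d) - whole_report_loglik(worse, d)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("parameter validation rejects impossible values", {
  expect_error(tva_params(-1, 0, 4), "C must be")
  expect_error(tva_params(30, -5, 4), "t0")
  expect_error(tva_params(30, 0, 7), "K")
  expect_error(tva_params(NA, 0, 4), "finite")
  expect_error(condition_prediction(tva_params(30, 0, 4), -10, TRUE), "exposure_ms")
})
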