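test_that("rank-sum p-values agree with exhaustive permutation enumeration", {
  set.seed(31)
  pool <- c(0.4, 1.1, 2.3, 2.9, 3.6, 4.8, 5.5, 7.2, 8.0, 9.4)
  for (nx in c(2, 4, 5)) {
    for (rep in 1:5) {
      idx <- sample(length(pool), nx)
      x <- pool[idx]; y <- pool[-idx]
      for (alt in c("two.sided", "less", "greater")) {
        got <- wilcoxon_rank_sum(x, y, alternative = alt)
        expect_equal(got$p, oracle_wilcoxon_p(x, y, alt), tolerance = 1e-10,
                     info = paste(alt, nx, rep))
      }
    }
  }
  # the classic small-sample case: most extreme split one-tailed
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), "less")$p, 1 / 6)
})

test_that("rank-sum handles ties, degeneracy and reports r = |z|/sqrt(N)", {
  set.seed(32)
  x <- c(1, 2, 2, 3, 5, 5, 6, 8)
  y <- c(2, 3, 3, 4, 5, 7, 9, 9)
  got <- wilcoxon_rank_sum(x, y)
  expect_equal(got$r, abs(got$z) / sqrt(16))
  expect_true(got$p > 0 && got$p <= 1)
  deg <- wilcoxon_rank_sum(rep(3, 6), rep(3, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  expect_equal(deg$r, 0)
  same <- wilcoxon_rank_sum(rnorm(200), rnorm(200))
  expect_lt(same$r, 0.15)
  expect_gt(same$p, 0.05)
})

test_that("effect sizes reproduce the printed study statistics", {
  expect_equal(effect_size_r(0, 80), 0)
  expect_equal(round(effect_size_r(-3.03, 80), 2), 0.34)
  expect_equal(round(effect_size_r(-6.90, 80), 2), 0.77)
  expect_equal(round(effect_size_r(-4.72, 80), 2), 0.53)
})

test_that("the sex-ratio chi-squared uses uncorrected Pearson arithmetic", {
  counts <- matrix(c(26, 32, 14, 8), nrow = 2)  # female/male by group
  got <- group_contingency_test(counts)
  expect_equal(got$statistic, 2.257, tolerance = 1e-3)
  expect_equal(got$df, 1)
})

test_that("kernel-density non-overlap behaves at its analytic anchors", {
  set.seed(41)
  x <- rnorm(400); y <- rnorm(400)
  same <- distribution_nonoverlap(x, y, n_boot = 100, seed = 1)
  expect_lt(same$estimate, 0.1)
  far <- distribution_nonoverlap(rnorm(100), rnorm(100, 20), n_boot = 50, seed = 2)
  expect_gt(far$estimate, 0.97)
  expect_error(distribution_nonoverlap(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("the Spearman matrix matches a rank-then-Pearson oracle", {
  toy <- data.frame(a = c(3, 1, 4, 1.5, 9), b = c(2, 7, 1, 8, 2.8),
                    c = c(0.1, 0.5, 0.4, 0.9, 1.2))
  rep <- spearman_matrix(toy)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    oracle <- cor(rank(toy[[pair[1]]]), rank(toy[[pair[2]]]))
    expect_equal(rep$rho[pair[1], pair[2]], oracle, tolerance = 1e-10)
  }
  expect_equal(diag(rep$rho), setNames(rep(1, 3), names(toy)))
  expect_equal(rep$rho, t(rep$rho))
  mono <- data.frame(u = 1:6, v = c(10, 8, 7, 5, 3, 1))
  expect_equal(spearman_matrix(mono)$rho["u", "v"], -1)
  expect_true(all(rep$p_adjusted >= rep$p, na.rm = TRUE))
})

test_that("BH adjustment follows the step-up rule and is well-behaved", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04))$p_adjusted, c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(0.013)$p_adjusted, 0.013)
  expect_equal(bh_fdr(rep(0.02, 5))$p_adjusted, rep(0.02, 5))
  set.seed(51)
  p <- runif(20)
  adj <- bh_fdr(p)$p_adjusted
  expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
  perm <- sample(20)
  expect_equal(bh_fdr(p[perm])$p_adjusted, adj[perm])   # order invariance
  expect_equal(bh_fdr(adj)$p_adjusted, bh_fdr(bh_fdr(adj)$p_adjusted)$p_adjusted)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cohen's f2 reproduces the printed regression effect size", {
  expect_equal(cohens_f2(0), 0)
  expect_equal(cohens_f2(0.5), 1)
  expect_equal(round(cohens_f2(0.338), 2), 0.51)
  expect_error(cohens_f2(1), "r2_adj")
})

test_that("regression recovers exact and univariate identities", {
  set.seed(61)
  d <- data.frame(x1 = rnorm(50), x2 = rnorm(50))
  d$y_exact <- 2 * d$x1 - d$x2
  fit <- ols_regression(d, "y_exact", c("x1", "x2"), n_boot = 200, seed = 1)
  expect_equal(unname(fit$b[-1]), c(2, -1), tolerance = 1e-10)
  expect_equal(fit$R2, 1, tolerance = 1e-10)
  d$y <- d$x1 + rnorm(50)
  uni <- ols_regression(d, "y", "x1", n_boot = 200, seed = 2)
  expect_equal(unname(uni$beta), cor(d$y, d$x1), tolerance = 1e-10)
  expect_true(uni$b_ci["x1", 1] <= uni$b["x1"] &&
              uni$b["x1"] <= uni$b_ci["x1", 2])
  d$x1_copy <- d$x1
  expect_error(ols_regression(d, "y", c("x1", "x1_copy")), "collinear.*x1_copy")
})

test_that("bootstrap confidence intervals are seed-reproducible", {
  set.seed(71)
  d <- data.frame(x = rnorm(40)); d$y <- 0.5 * d$x + rnorm(40)
  f1 <- ols_regression(d, "y", "x", n_boot = 300, seed = 9)
  f2 <- ols_regression(d, "y", "x", n_boot = 300, seed = 9)
  expect_identical(f1$b_ci, f2$b_ci)
  dm <- data.frame(x = d$x, m = d$x + rnorm(40), y = d$y)
  m1 <- mediate(dm, "x", "m", "y", n_boot = 300, seed = 9)
  m2 <- mediate(dm, "x", "m", "y", n_boot = 300, seed = 9)
  expect_identical(m1$indirect_ci, m2$indirect_ci)
  expect_identical(m1$direct_ci, m2$direct_ci)
})

test_that("the nested-model F test matches a residual-sum-of-squares oracle", {
  set.seed(81)
  d <- data.frame(x1 = rnorm(12), x2 = rnorm(12), x3 = rnorm(12))
  d$y <- 1.5 * d$x1 + 0.3 * d$x3 + rnorm(12)
  red <- ols_regression(d, "y", "x1", n_boot = 50, seed = 1)
  full <- ols_regression(d, "y", c("x1", "x2", "x3"), n_boot = 50, seed = 1)
  got <- nested_model_f_test(red, full)
  rss_r <- sum(residuals(lm(y ~ x1, d))^2)
  rss_f <- sum(residuals(lm(y ~ x1 + x2 + x3, d))^2)
  F_oracle <- ((rss_r - rss_f) / 2) / (rss_f / (12 - 3 - 1))
  expect_equal(got$F, F_oracle, tolerance = 1e-10)
  expect_equal(got$df1, 2); expect_equal(got$df2, 8)
  expect_equal(got$p, pf(F_oracle, 2, 8, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(nested_model_f_test(full, red), "not nested")
  # an outcome already explained by the reduced model adds nothing
  d$y0 <- 2 * d$x1
  r0 <- ols_regression(d, "y0", "x1", n_boot = 50, seed = 1)
  f0 <- ols_regression(d, "y0", c("x1", "x2"), n_boot = 50, seed = 1)
  expect_lt(nested_model_f_test(r0, f0)$F, 1e-6)
})

test_that("mediation satisfies the exact linear decomposition", {
  # noiseless chain: M = 2X, Y = 3M
  d <- data.frame(x = seq(-2, 2, length.out = 20))
  d$m <- 2 * d$x + rnorm(20, 0, 1e-8)
  d$y <- 3 * d$m + rnorm(20, 0, 1e-8)
  md <- mediate(d, "x", "m", "y", n_boot = 100, seed = 3)
  expect_equal(md$indirect, 6, tolerance = 1e-4)
  expect_equal(md$direct, 0, tolerance = 1e-4)
  # total = direct + indirect holds exactly on arbitrary data
  set.seed(91)
  arb <- data.frame(x = rnorm(30), m = rnorm(30), y = rnorm(30))
  md2 <- mediate(arb, "x", "m", "y", n_boot = 100, seed = 4)
  expect_equal(md2$total, md2$direct + md2$indirect, tolerance = 1e-8)
  expect_error(mediate(data.frame(x = rep(1, 20), m = rnorm(20), y = rnorm(20)),
                       "x", "m", "y"), "zero variance")
})

test_that("the indirect-effect interval is calibrated under independence", {
  set.seed(101)
  covered <- vapply(1:50, function(s) {
    d <- data.frame(x = rnorm(200), m = rnorm(200), y = rnorm(200))
    md <- mediate(d, "x", "m", "y", n_boot = 400, seed = 1000 + s)
    md$indirect_ci[1] <= 0 && md$indirect_ci[2] >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("group tests on a separated cohort find the large fatigue effect", {
  hits <- vapply(1:10, function(s) {
    coh <- simulate_cohort(cohort_config(), seed = 2000 + s)
    gt <- wilcoxon_rank_sum(coh$fatigue_mental[coh$group == "control"],
                            coh$fatigue_mental[coh$group == "patient"],
                            alternative = "less")
    gt$r > 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
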