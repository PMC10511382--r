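#' Wilcoxon rank-sum test with effect size r
#'
#' Rank-sum (Mann-Whitney) test with midrank ties. The statistic \code{W}
#' follows the usual R convention (rank sum of \code{x} minus its minimum);
#' \code{z} is the normal approximation with tie and continuity correction and
#' \code{r = |z| / sqrt(n_x + n_y)} is the rank-biserial-style effect size
#' (medium for 0.3 < r < 0.5, large above 0.5). The p-value uses the exact
#' distribution for small untied samples and the normal approximation
#' otherwise (as \code{stats::wilcox.test}).
#'
#' @param x,y numeric samples.
#' @param alternative \code{"two.sided"}, \code{"less"} or \code{"greater"}
#'   (of \code{x} relative to \code{y}).
#' @param exact force exact/approximate p-value; default lets small untied
#'   samples use the exact distribution.
#' @param correct continuity correction for the normal approximation.
#' @return An object of class \code{rank_test_result} with \code{W}, \code{z},
#'   \code{p}, \code{r}, \code{n}, \code{alternative} and \code{degenerate}
#'   (TRUE when all values are tied).
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "less", "greater"),
                              exact = NULL, correct = TRUE) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("wilcoxon_rank_sum: both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y); N <- nx + ny
  rk <- rank(c(x, y))
  W <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  tie_tab <- table(rk)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    return(structure(list(W = W, z = 0, p = 1, r = 0, n = N,
                          alternative = alternative, degenerate = TRUE),
                     class = "rank_test_result"))
  }
  cc <- if (correct) sign(W - mu) * 0.5 else 0
  z <- (W - mu - cc) / sqrt(sigma2)
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = correct)$p.value
  )
  structure(list(W = W, z = z, p = p, r = abs(z) / sqrt(N), n = N,
                 alternative = alternative, degenerate = FALSE),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s): W = %.1f, z = %.2f, p = %.4g, r = %.2f (N = %d)\n",
              x$alternative, x$W, x$z, x$p, x$r, x$n))
  invisible(x)
}

#' Effect size r for a rank test
#'
#' \code{r = |z| / sqrt(N)}; medium for 0.3 < r < 0.5, large above 0.5.
#'
#' @param z normal-approximation statistic.
#' @param n_total total sample size across both groups, >= 2.
#' @export
effect_size_r <- function(z, n_total) {
  stopifnot(n_total >= 2)
  abs(z) / sqrt(n_total)
}

#' Pearson chi-squared test on a 2 x k contingency table
#'
#' Without continuity correction (the convention behind reported group-ratio
#' chi-squared values such as sex distributions).
#'
#' @param counts a matrix of counts (groups x categories).
#' @return List with \code{statistic}, \code{df}, \code{p}.
#' @examples
#' group_contingency_test(matrix(c(26, 32, 14, 8), 2)) # sex by group
#' @export
group_contingency_test <- function(counts) {
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Bootstrapped kernel-density non-overlap of two samples
#'
#' For each bootstrap replicate both groups are resampled with replacement,
#' Gaussian kernel densities (Silverman's rule bandwidth) are fit on a common
#' grid, and the non-overlap is \code{1 - integral(min(f, g))}. The reported
#' estimate is the mean over replicates, with a percentile interval.
#'
#' @param x,y numeric samples (>= 5 each, non-degenerate).
#' @param n_boot bootstrap replications (default 1000).
#' @param seed optional integer seed.
#' @param n_grid density grid size.
#' @param conf confidence level for the percentile interval.
#' @return List with \code{estimate}, \code{ci_lower}, \code{ci_upper},
#'   \code{n_boot}.
#' @export
distribution_nonoverlap <- function(x, y, n_boot = 1000, seed = NULL,
                                    n_grid = 512, conf = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 5, length(y) >= 5)
  if (var(x) == 0 || var(y) == 0) {
    stop("distribution_nonoverlap: zero-variance sample", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  bw <- max(stats::bw.nrd0(x), stats::bw.nrd0(y))
  lo <- min(x, y) - 3 * bw
  hi <- max(x, y) + 3 * bw
  step <- (hi - lo) / (n_grid - 1)
  vals <- vapply(seq_len(n_boot), function(b) {
    xs <- sample(x, replace = TRUE)
    ys <- sample(y, replace = TRUE)
    fx <- density(xs, bw = "nrd0", from = lo, to = hi, n = n_grid)$y
    fy <- density(ys, bw = "nrd0", from = lo, to = hi, n = n_grid)$y
    ovl <- sum(pmin(fx, fy)) * step
    1 - min(ovl, 1)
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(estimate = mean(vals),
       ci_lower = unname(quantile(vals, alpha)),
       ci_upper = unname(quantile(vals, 1 - alpha)),
       n_boot = n_boot)
}

#' Spearman correlation matrix with FDR control
#'
#' Midrank Spearman correlations for every variable pair, p-values from the
#' t approximation, and Benjamini-Hochberg adjustment over the set of pairwise
#' tests.
#'
#' @param data a data frame.
#' @param variables columns to correlate.
#' @param q FDR level for the significance flags (default 0.05).
#' @param min_n minimum complete cases per pair (default 4).
#' @return An object of class \code{correlation_report} with matrices
#'   \code{rho}, \code{p}, \code{p_adjusted} and logical \code{significant}.
#' @export
spearman_matrix <- function(data, variables = names(data), q = 0.05, min_n = 4) {
  X <- data[variables]
  p_n <- length(variables)
  rho <- p <- matrix(NA_real_, p_n, p_n, dimnames = list(variables, variables))
  diag(rho) <- 1
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    xi <- X[[i]]; xj <- X[[j]]
    ok <- complete.cases(xi, xj)
    if (sum(ok) < min_n) next
    if (var(xi[ok]) == 0 || var(xj[ok]) == 0) next  # constant: flagged missing
    ct <- suppressWarnings(cor.test(xi[ok], xj[ok], method = "spearman",
                                    exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  pv <- p[upper.tri(p)]
  adj <- rep(NA_real_, length(pv))
  adj[!is.na(pv)] <- p.adjust(pv[!is.na(pv)], method = "BH")
  p_adj <- matrix(NA_real_, p_n, p_n, dimnames = dimnames(p))
  p_adj[upper.tri(p_adj)] <- adj
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  structure(
    list(rho = rho, p = p, p_adjusted = p_adj,
         significant = !is.na(p_adj) & p_adj <= q, q = q),
    class = "correlation_report"
  )
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues p-values in [0, 1].
#' @param q FDR level for the rejection flags (default 0.05).
#' @return List with \code{p_adjusted} and logical \code{rejected}.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("bh_fdr: p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- p.adjust(pvalues, method = "BH")
  list(p_adjusted = adj, rejected = adj <= q)
}

#' Cohen's f-squared from adjusted R-squared
#'
#' \code{f2 = R2_adj / (1 - R2_adj)}; negative adjusted R-squared is clamped
#' to 0.
#'
#' @param r2_adj adjusted R-squared, < 1.
#' @export
cohens_f2 <- function(r2_adj) {
  if (r2_adj >= 1) stop("cohens_f2: r2_adj must be < 1", call. = FALSE)
  r2 <- max(r2_adj, 0)
  r2 / (1 - r2)
}

## fast least squares on a fixed design, returns coefficients
fast_ols <- function(X, y) {
  fit <- .lm.fit(X, y)
  fit$coefficients
}

#' Multiple linear regression with bootstrap confidence intervals
#'
#' Ordinary least squares with unstandardized (\code{b}) and standardized
#' (\code{beta}) coefficients, case-resampling percentile bootstrap intervals
#' for both and for the model R-squared, adjusted R-squared, Cohen's
#' \code{f2} (from adjusted R-squared), and the model F-test p-value.
#'
#' @param data a data frame.
#' @param outcome outcome column name.
#' @param predictors predictor column names.
#' @param n_boot bootstrap replications (default 1000).
#' @param seed optional integer seed.
#' @param conf confidence level (default 0.95).
#' @return An object of class \code{regression_result}.
#' @export
ols_regression <- function(data, outcome, predictors, n_boot = 1000,
                           seed = NULL, conf = 0.95) {
  cols <- c(outcome, predictors)
  cc <- complete.cases(data[cols])
  d <- data[cc, cols]
  n <- nrow(d)
  k <- length(predictors)
  if (n < k + 2) stop("ols_regression: need >= predictors + 2 complete cases",
                      call. = FALSE)
  y <- d[[outcome]]
  X <- cbind(`(Intercept)` = 1, as.matrix(d[predictors]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("ols_regression: rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  b <- qr.coef(qrX, y)
  fitted <- drop(X %*% b)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  f_stat <- (r2 / k) / ((1 - r2) / (n - k - 1))
  model_p <- pf(f_stat, k, n - k - 1, lower.tail = FALSE)
  sds <- vapply(d[predictors], sd, numeric(1))
  beta <- b[-1] * sds / sd(y)

  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  boot_b <- matrix(NA_real_, n_boot, length(b))
  boot_beta <- matrix(NA_real_, n_boot, k)
  boot_r2 <- numeric(n_boot)
  for (bb in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    Xb <- X[idx, , drop = FALSE]
    yb <- y[idx]
    cf <- tryCatch(fast_ols(Xb, yb), error = function(e) rep(NA_real_, length(b)))
    boot_b[bb, ] <- cf
    sds_b <- apply(Xb[, -1, drop = FALSE], 2, sd)
    boot_beta[bb, ] <- cf[-1] * sds_b / sd(yb)
    fit_b <- drop(Xb %*% cf)
    boot_r2[bb] <- 1 - sum((yb - fit_b)^2) / sum((yb - mean(yb))^2)
  }
  alpha <- (1 - conf) / 2
  ci <- function(m) t(apply(m, 2, quantile, probs = c(alpha, 1 - alpha),
                            na.rm = TRUE))
  b_ci <- ci(boot_b); rownames(b_ci) <- names(b)
  beta_ci <- ci(boot_beta); rownames(beta_ci) <- predictors
  r2_ci <- quantile(boot_r2, c(alpha, 1 - alpha), na.rm = TRUE)

  structure(
    list(outcome = outcome, predictors = predictors, n = n,
         b = b, b_ci = b_ci,
         beta = setNames(beta, predictors), beta_ci = beta_ci,
         R2 = r2, R2_adj = r2_adj, R2_ci = unname(r2_ci),
         f2 = if (r2_adj >= 1) Inf else cohens_f2(r2_adj),  # exact fit
         model_p = model_p, f_statistic = f_stat,
         rss = rss, df_residual = n - k - 1,
         n_boot = n_boot, cases = which(cc)),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: %s ~ %s (n = %d)\n", x$outcome,
              paste(x$predictors, collapse = " + "), x$n))
  tab <- data.frame(b = round(x$b, 3),
                    LL = round(x$b_ci[, 1], 3), UL = round(x$b_ci[, 2], 3))
  print(tab)
  cat(sprintf("R2 = %.3f (adj. %.3f), f2 = %.2f, model p = %.4g\n",
              x$R2, x$R2_adj, x$f2, x$model_p))
  invisible(x)
}

#' Extra-sum-of-squares F test for nested regression models
#'
#' @param fit_reduced,fit_full \code{regression_result} objects fit on the
#'   same cases with nested predictor sets.
#' @return List with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
nested_model_f_test <- function(fit_reduced, fit_full) {
  stopifnot(inherits(fit_reduced, "regression_result"),
            inherits(fit_full, "regression_result"))
  if (!all(fit_reduced$predictors %in% fit_full$predictors) ||
      length(fit_full$predictors) <= length(fit_reduced$predictors)) {
    stop("nested_model_f_test: models are not nested", call. = FALSE)
  }
  if (fit_reduced$outcome != fit_full$outcome ||
      !identical(fit_reduced$cases, fit_full$cases)) {
    stop("nested_model_f_test: models must share outcome and cases", call. = FALSE)
  }
  df1 <- length(fit_full$predictors) - length(fit_reduced$predictors)
  df2 <- fit_full$df_residual
  F_stat <- ((fit_reduced$rss - fit_full$rss) / df1) / (fit_full$rss / df2)
  list(F = F_stat, df1 = df1, df2 = df2,
       p = pf(F_stat, df1, df2, lower.tail = FALSE))
}

#' Simple mediation with percentile bootstrap
#'
#' OLS paths: \code{a} (mediator ~ x), \code{b} and direct \code{c'}
#' (outcome ~ mediator + x). The indirect effect is \code{a * b}; for linear
#' models total = direct + indirect exactly. Confidence intervals are
#' case-resampling percentile bootstrap. Full mediation is flagged when the
#' direct-effect interval covers 0 while the indirect interval excludes it.
#'
#' @param data a data frame.
#' @param x,mediator,y column names.
#' @param n_boot bootstrap replications (default 1000).
#' @param seed optional integer seed.
#' @param conf confidence level.
#' @return An object of class \code{mediation_result}.
#' @export
mediate <- function(data, x, mediator, y, n_boot = 1000, seed = NULL,
                    conf = 0.95) {
  cols <- c(x, mediator, y)
  d <- data[complete.cases(data[cols]), cols]
  n <- nrow(d)
  if (n < 10) stop("mediate: need >= 10 complete cases", call. = FALSE)
  if (any(vapply(d, var, numeric(1)) == 0)) {
    stop("mediate: zero variance in a variable", call. = FALSE)
  }
  xv <- d[[x]]; mv <- d[[mediator]]; yv <- d[[y]]
  paths <- function(xv, mv, yv) {
    a <- fast_ols(cbind(1, xv), mv)[2]
    cf <- fast_ols(cbind(1, mv, xv), yv)
    c(a = a, b = cf[2], direct = cf[3])
  }
  est <- paths(xv, mv, yv)
  total <- fast_ols(cbind(1, xv), yv)[2]
  indirect <- est[["a"]] * est[["b"]]

  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  boot <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("indirect", "direct")))
  for (bb in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    pb <- tryCatch(paths(xv[idx], mv[idx], yv[idx]),
                   error = function(e) c(a = NA_real_, b = NA_real_, direct = NA_real_))
    boot[bb, ] <- c(pb[["a"]] * pb[["b"]], pb[["direct"]])
  }
  alpha <- (1 - conf) / 2
  ind_ci <- unname(quantile(boot[, "indirect"], c(alpha, 1 - alpha), na.rm = TRUE))
  dir_ci <- unname(quantile(boot[, "direct"], c(alpha, 1 - alpha), na.rm = TRUE))

  structure(
    list(x = x, mediator = mediator, y = y, n = n,
         a_path = est[["a"]], b_path = est[["b"]],
         direct = est[["direct"]], indirect = unname(indirect),
         total = unname(total),
         indirect_se = sd(boot[, "indirect"], na.rm = TRUE),
         indirect_ci = ind_ci, direct_ci = dir_ci,
         full_mediation = (dir_ci[1] <= 0 && dir_ci[2] >= 0) &&
                          (ind_ci[1] > 0 || ind_ci[2] < 0),
         n_boot = n_boot),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation %s -> %s -> %s (n = %d)\n", x$x, x$mediator, x$y, x$n))
  cat(sprintf("  indirect = %.4f, SE %.4f, CI [%.4f, %.4f]\n",
              x$indirect, x$indirect_se, x$indirect_ci[1], x$indirect_ci[2]))
  cat(sprintf("  direct   = %.4f, CI [%.4f, %.4f]\n",
              x$direct, x$direct_ci[1], x$direct_ci[2]))
  cat(sprintf("  full mediation: %s\n", x$full_mediation))
  invisible(x)
}
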