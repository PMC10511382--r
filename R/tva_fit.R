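## ---- bounded multi-start maximum likelihood machinery ----

## Latin hypercube starting points over [lower, upper], one row per start
lhs_starts <- function(n, lower, upper) {
  d <- length(lower)
  u <- vapply(seq_len(d), function(j) (sample(n) - runif(n)) / n, numeric(n))
  u <- matrix(u, nrow = n)
  sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
}

## logistic reparameterization keeps Nelder-Mead inside the box
theta_from_u <- function(u, lower, upper) lower + (upper - lower) * plogis(u)
u_from_theta <- function(theta, lower, upper) {
  f <- pmin(pmax((theta - lower) / (upper - lower), 1e-6), 1 - 1e-6)
  qlogis(f)
}

## multi-start simplex minimization of nll over a box; returns best point
ml_optimize <- function(nll, lower, upper, starts = 8, maxit = 2000,
                        reltol = 1e-10) {
  inits <- lhs_starts(starts, lower, upper)
  best <- NULL
  total_iter <- 0
  for (s in seq_len(starts)) {
    u0 <- u_from_theta(inits[s, ], lower, upper)
    fn <- function(u) {
      val <- nll(theta_from_u(u, lower, upper))
      if (!is.finite(val)) 1e10 else val
    }
    opt <- if (length(u0) == 1) {
      o <- optim(u0, fn, method = "Brent", lower = -30, upper = 30,
                 control = list(maxit = maxit))
      o$counts <- c(`function` = maxit, gradient = NA)
      o
    } else {
      optim(u0, fn, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = reltol))
    }
    total_iter <- total_iter + opt$counts[["function"]]
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  list(theta = theta_from_u(best$par, lower, upper),
       nll = best$value,
       iterations = total_iter,
       restarts = starts,
       status = if (best$convergence == 0) "converged" else "max_iterations")
}

#' Fit the TVA whole-report model by maximum likelihood
#'
#' Multi-start bounded derivative-free optimization of (log C, t0, K, mu) over
#' the per-condition score likelihood. Starting points are a seeded Latin
#' hypercube over the bounds; the best of \code{starts} simplex runs is
#' returned. When the dataset contains no unmasked trials \code{mu} is fixed
#' at 0 (it is unidentifiable there).
#'
#' @param data whole-report trial data frame with columns \code{exposure_ms},
#'   \code{masked}, and \code{score} (or \code{displayed}/\code{reported}).
#' @param starts number of optimization restarts (>= 1, default 8).
#' @param seed optional integer seed for start generation.
#' @param bounds named list of c(lower, upper) for \code{C}, \code{t0},
#'   \code{K}, \code{mu}.
#' @param n_letters display size.
#' @return An object of class \code{tva_fit}: \code{params}
#'   (\code{\link{tva_params}}), \code{loglik}, \code{R2_fit} (squared Pearson
#'   correlation of observed vs predicted condition mean scores),
#'   \code{convergence} (iterations, restarts, status), and the observed and
#'   predicted condition means.
#' @examples
#' d <- simulate_whole_report(tva_params(30, 15, 3.5, 150),
#'                            n_trials_per_condition = 20, seed = 1)
#' fit <- fit_whole_report(d, starts = 4, seed = 1)
#' fit$params
#' @export
fit_whole_report <- function(data, starts = 8, seed = NULL,
                             bounds = list(C = c(1, 200), t0 = c(0, 100),
                                           K = c(0.5, 6), mu = c(0, 500)),
                             n_letters = 6) {
  data <- ensure_scores(data, paradigm = "whole")
  conds <- unique(paste(data$exposure_ms, data$masked))
  if (length(conds) < 2) {
    stop("fit_whole_report: unidentifiable - need >= 2 distinct effective exposure conditions",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  counts <- score_counts_by_condition(data, n_letters)
  has_unmasked <- any(!data$masked)
  floor <- 1e-12
  exposure <- counts$conditions$exposure_ms
  unmasked <- !counts$conditions$masked
  cmat <- counts$counts

  ## lean likelihood: same arithmetic as condition_prediction without the
  ## per-call object construction (hot path of the optimizer)
  nll_from <- function(C, t0, K, mu) {
    k0 <- floor(K + 1e-12)
    kf <- K - k0
    ll <- 0
    for (i in seq_along(exposure)) {
      a <- max(0, exposure[i] + mu * unmasked[i] - t0)
      p <- 1 - exp(-C / n_letters * a / 1000)
      pmf <- (1 - kf) * score_pmf_given_capacity(p, k0, n_letters)
      if (kf > 0) pmf <- pmf + kf * score_pmf_given_capacity(p, k0 + 1, n_letters)
      ll <- ll + sum(cmat[i, ] * log(pmax(pmf, floor)))
    }
    -ll
  }

  if (has_unmasked) {
    lower <- c(log(bounds$C[1]), bounds$t0[1], bounds$K[1], bounds$mu[1])
    upper <- c(log(bounds$C[2]), bounds$t0[2], bounds$K[2], bounds$mu[2])
    nll <- function(th) nll_from(exp(th[1]), th[2], th[3], th[4])
  } else {
    lower <- c(log(bounds$C[1]), bounds$t0[1], bounds$K[1])
    upper <- c(log(bounds$C[2]), bounds$t0[2], bounds$K[2])
    nll <- function(th) nll_from(exp(th[1]), th[2], th[3], 0)
  }

  res <- ml_optimize(nll, lower, upper, starts = starts)
  th <- res$theta
  params <- if (has_unmasked) tva_params(exp(th[1]), th[2], th[3], th[4])
            else tva_params(exp(th[1]), th[2], th[3], 0)

  obs <- predicted <- numeric(nrow(counts$conditions))
  for (i in seq_len(nrow(counts$conditions))) {
    n_i <- sum(counts$counts[i, ])
    obs[i] <- sum((0:n_letters) * counts$counts[i, ]) / n_i
    predicted[i] <- condition_prediction(params, counts$conditions$exposure_ms[i],
                                         counts$conditions$masked[i],
                                         n_letters)$expected_score
  }

  structure(
    list(params = params,
         loglik = -res$nll,
         R2_fit = fit_r2(obs, predicted),
         convergence = list(iterations = res$iterations,
                            restarts = res$restarts, status = res$status),
         conditions = counts$conditions,
         observed_means = obs,
         predicted_means = predicted),
    class = "tva_fit"
  )
}

#' @export
print.tva_fit <- function(x, ...) {
  print(x$params)
  if (!is.null(x$weights)) print(x$weights)
  cat(sprintf("logLik = %.2f, R2 = %.3f, status = %s\n",
              x$loglik, x$R2_fit, x$convergence$status))
  invisible(x)
}

#' Fit the partial-report model (top-down control alpha)
#'
#' Maximum-likelihood estimation of the distractor/target weight ratio
#' \code{alpha} from the per-condition target report counts, optionally also
#' estimating \code{C} and \code{t0} for the partial-report display when no
#' shared whole-report parameters are supplied (capacity \code{K} is then held
#' at \code{default_K}; with at most two display items capacities >= 2 are
#' equivalent).
#'
#' @param data partial-report trial data frame with columns \code{type} (or
#'   \code{displayed}), \code{exposure_ms}, and \code{score} (or
#'   \code{reported}).
#' @param shared optional \code{\link{tva_params}} fixing C, t0 and K.
#' @param starts,seed optimization restarts and seed, as in
#'   \code{\link{fit_whole_report}}.
#' @param bounds named list of c(lower, upper) for \code{alpha}, \code{C},
#'   \code{t0}.
#' @param default_K capacity used when \code{shared} is not given.
#' @return A \code{tva_fit} object whose \code{weights} field holds the
#'   estimated \code{\link{attentional_weights}}; \code{R2_fit} compares
#'   observed and predicted per-condition-type target accuracies.
#' @export
fit_partial_report <- function(data, shared = NULL, starts = 8, seed = NULL,
                               bounds = list(alpha = c(0, 5), C = c(1, 200),
                                             t0 = c(0, 100)),
                               default_K = 4) {
  data <- ensure_partial_types(data)
  data <- ensure_scores(data, paradigm = "partial")
  if (!any(data$type == "TD")) {
    stop("fit_partial_report: alpha unidentifiable - no target+distractor (T-D) trials",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }

  if (!is.null(shared)) {
    stopifnot(inherits(shared, "tva_params"))
    lower <- bounds$alpha[1]; upper <- bounds$alpha[2]
    nll <- function(th) -partial_report_loglik(shared, attentional_weights(th[1]), data)
  } else {
    lower <- c(bounds$alpha[1], log(bounds$C[1]), bounds$t0[1])
    upper <- c(bounds$alpha[2], log(bounds$C[2]), bounds$t0[2])
    nll <- function(th) {
      p <- tva_params(exp(th[2]), th[3], default_K, 0)
      -partial_report_loglik(p, attentional_weights(th[1]), data)
    }
  }
  res <- ml_optimize(nll, lower, upper, starts = starts)
  th <- res$theta
  weights <- attentional_weights(th[1])
  params <- if (!is.null(shared)) shared else tva_params(exp(th[2]), th[3], default_K, 0)

  ## per condition-type observed vs predicted mean target accuracy
  key <- paste(data$type, data$exposure_ms)
  uk <- unique(key)
  obs <- pred <- numeric(length(uk))
  for (i in seq_along(uk)) {
    rows <- data[key == uk[i], ]
    obs[i] <- mean(rows$score)
    pr <- partial_report_prediction(params, weights, rows$type[1], rows$exposure_ms[1])
    pred[i] <- sum(as.numeric(names(pr$report_pmf)) * pr$report_pmf)
  }
  r2 <- if (length(uk) >= 2) fit_r2(obs, pred) else NA_real_

  structure(
    list(params = params, weights = weights,
         loglik = -res$nll,
         R2_fit = r2,
         convergence = list(iterations = res$iterations,
                            restarts = res$restarts, status = res$status),
         observed_means = obs, predicted_means = pred),
    class = "tva_fit"
  )
}

## save/restore .Random.seed so seeded fits do not disturb the caller's stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
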