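#' TVA parameter vector
#'
#' Bundles the whole-report parameters of the exponential race model: visual
#' processing speed \code{C} (letters/second, the total encoding rate shared
#' across display items), perceptual threshold \code{t0} (ms, minimal
#' effective exposure), visual short-term memory capacity \code{K} (letters;
#' non-integer values are represented as a two-point mixture on the adjacent
#' integers \code{K_base} and \code{K_base + 1} with mass \code{K_frac} on the
#' larger) and visual persistence \code{mu} (ms, prolongation of effective
#' exposure on unmasked displays).
#'
#' @param C processing speed in letters/second, > 0.
#' @param t0 perceptual threshold in ms, >= 0.
#' @param K capacity in letters, in [0, 6]; \code{floor(K)} becomes
#'   \code{K_base} and the fractional part \code{K_frac}.
#' @param mu visual persistence in ms, >= 0.
#' @return An object of class \code{tva_params}.
#' @examples
#' tva_params(C = 33.77, t0 = 5.96, K = 3.85, mu = 150)
#' @export
tva_params <- function(C, t0, K, mu = 0) {
  vals <- c(C = C, t0 = t0, K = K, mu = mu)
  if (!all(is.finite(vals))) {
    stop("tva_params: all parameters must be finite, got ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  if (C <= 0) stop("tva_params: C must be > 0", call. = FALSE)
  if (t0 < 0) stop("tva_params: t0 must be >= 0", call. = FALSE)
  if (mu < 0) stop("tva_params: mu must be >= 0", call. = FALSE)
  if (K < 0 || K > 6) stop("tva_params: K must lie in [0, 6]", call. = FALSE)
  K_base <- floor(K + 1e-12)
  K_frac <- K - K_base
  if (K_frac < 1e-12) K_frac <- 0
  structure(
    list(C = C, t0 = t0, K = K_base + K_frac, K_base = as.integer(K_base),
         K_frac = K_frac, mu = mu),
    class = "tva_params"
  )
}

#' @export
print.tva_params <- function(x, ...) {
  cat(sprintf("TVA parameters: C = %.2f letters/s, t0 = %.2f ms, K = %.2f letters, mu = %.1f ms\n",
              x$C, x$t0, x$K, x$mu))
  invisible(x)
}

#' Attentional weights from partial report
#'
#' Target weight is fixed to 1 as the reference; \code{alpha = wD / wT} is the
#' top-down control parameter (lower = better selection).
#'
#' @param alpha ratio of distractor to target weight, >= 0.
#' @return An object of class \code{attentional_weights} with fields
#'   \code{wT}, \code{wD}, \code{alpha}.
#' @export
attentional_weights <- function(alpha) {
  if (!is.finite(alpha) || alpha < 0) {
    stop("attentional_weights: alpha must be finite and >= 0", call. = FALSE)
  }
  structure(list(wT = 1, wD = alpha, alpha = alpha),
            class = "attentional_weights")
}

#' @export
print.attentional_weights <- function(x, ...) {
  cat(sprintf("Attentional weights: wT = 1, wD = %.3f (alpha = %.3f)\n",
              x$wD, x$alpha))
  invisible(x)
}

## probability mass over capacities implied by the two-point K mixture
capacity_pmf <- function(params) {
  k0 <- params$K_base
  if (params$K_frac == 0) {
    setNames(1, as.character(k0))
  } else {
    setNames(c(1 - params$K_frac, params$K_frac), as.character(c(k0, k0 + 1L)))
  }
}

## score = min(#encoded, capacity k): binomial below k, upper tail lumped at k
score_pmf_given_capacity <- function(p_encode, k, n_letters) {
  pmf <- numeric(n_letters + 1)
  if (k <= 0) {
    pmf[1] <- 1
  } else if (k >= n_letters) {
    pmf <- dbinom(0:n_letters, n_letters, p_encode)
  } else {
    pmf[seq_len(k)] <- dbinom(0:(k - 1), n_letters, p_encode)
    pmf[k + 1] <- pbinom(k - 1, n_letters, p_encode, lower.tail = FALSE)
  }
  pmf
}

#' Predicted score distribution for one whole-report condition
#'
#' Computes the effective exposure \code{a = max(0, tau + mu*[unmasked] - t0)},
#' the per-letter encoding probability \code{p = 1 - exp(-(C/n) * a / 1000)}
#' (equal attentional weights across the display), and the probability mass
#' function of the report score 0..\code{n_letters} under the capacity
#' mixture: for capacity \code{k}, scores below \code{k} are binomial and all
#' mass of \code{k} or more encoded letters is lumped at \code{k}.
#'
#' @param params a \code{\link{tva_params}} object.
#' @param exposure_ms nominal exposure duration in ms, > 0.
#' @param masked logical; unmasked displays gain \code{mu} ms of effective
#'   exposure through visual persistence.
#' @param n_letters display size (default 6).
#' @return A list of class \code{tva_condition_prediction} with
#'   \code{effective_exposure_s}, \code{p_encode}, \code{score_pmf}
#'   (names "0".."n") and \code{expected_score}.
#' @examples
#' pr <- condition_prediction(tva_params(24, 10, 4), exposure_ms = 110, masked = TRUE)
#' pr$expected_score
#' @export
condition_prediction <- function(params, exposure_ms, masked, n_letters = 6) {
  stopifnot(inherits(params, "tva_params"))
  if (!is.finite(exposure_ms) || exposure_ms <= 0) {
    stop("condition_prediction: exposure_ms must be > 0", call. = FALSE)
  }
  a_ms <- max(0, exposure_ms + params$mu * (!masked) - params$t0)
  v <- params$C / n_letters
  p_encode <- 1 - exp(-v * a_ms / 1000)
  caps <- capacity_pmf(params)
  pmf <- numeric(n_letters + 1)
  for (i in seq_along(caps)) {
    k <- as.integer(names(caps)[i])
    pmf <- pmf + caps[[i]] * score_pmf_given_capacity(p_encode, k, n_letters)
  }
  structure(
    list(effective_exposure_s = a_ms / 1000,
         p_encode = p_encode,
         score_pmf = setNames(pmf, 0:n_letters),
         expected_score = sum((0:n_letters) * pmf)),
    class = "tva_condition_prediction"
  )
}

#' Log-likelihood of a whole-report dataset
#'
#' Sums \code{log P(score | condition)} over trials. Scores with zero
#' predicted probability contribute \code{log(floor)} instead of \code{-Inf}
#' so that optimization stays finite under misfit.
#'
#' @param params a \code{\link{tva_params}} object.
#' @param data a whole-report trial data frame (see
#'   \code{\link{simulate_whole_report}}) with columns \code{exposure_ms},
#'   \code{masked} and \code{score} (or \code{displayed}/\code{reported} from
#'   which scores are derived).
#' @param n_letters display size (default 6).
#' @param floor minimum per-trial likelihood (default 1e-12).
#' @return The log-likelihood (0 for an empty dataset).
#' @export
whole_report_loglik <- function(params, data, n_letters = 6, floor = 1e-12) {
  data <- ensure_scores(data, paradigm = "whole")
  if (nrow(data) == 0) return(0)
  if (any(data$score < 0 | data$score > n_letters)) {
    stop("whole_report_loglik: scores must lie in 0..", n_letters, call. = FALSE)
  }
  counts <- score_counts_by_condition(data, n_letters)
  ll <- 0
  for (i in seq_len(nrow(counts$conditions))) {
    pr <- condition_prediction(params, counts$conditions$exposure_ms[i],
                               counts$conditions$masked[i], n_letters)
    ll <- ll + sum(counts$counts[i, ] * log(pmax(pr$score_pmf, floor)))
  }
  ll
}

## aggregate trials into per-condition score count matrix (conditions x scores)
score_counts_by_condition <- function(data, n_letters = 6) {
  key <- paste(data$exposure_ms, data$masked)
  conditions <- unique(data.frame(exposure_ms = data$exposure_ms,
                                  masked = data$masked,
                                  stringsAsFactors = FALSE))
  ckey <- paste(conditions$exposure_ms, conditions$masked)
  counts <- matrix(0, nrow(conditions), n_letters + 1,
                   dimnames = list(NULL, 0:n_letters))
  for (i in seq_len(nrow(conditions))) {
    sc <- data$score[key == ckey[i]]
    tab <- tabulate(sc + 1L, nbins = n_letters + 1)
    counts[i, ] <- tab
  }
  list(conditions = conditions, counts = counts)
}

## compute trial scores from displayed/reported strings when absent
ensure_scores <- function(data, paradigm = c("whole", "partial")) {
  paradigm <- match.arg(paradigm)
  if (!is.null(data$score)) return(data)
  if (is.null(data$displayed) || is.null(data$reported)) {
    stop("trial data needs either a 'score' column or 'displayed'/'reported'",
         call. = FALSE)
  }
  data$score <- vapply(seq_len(nrow(data)), function(i) {
    shown <- parse_display(data$displayed[i])
    rep_letters <- strsplit(data$reported[i], "")[[1]]
    if (paradigm == "partial") {
      shown <- shown[shown$role == "T", , drop = FALSE]
    }
    length(intersect(rep_letters, shown$letter))
  }, integer(1))
  data
}

## "ABCDEF" (whole report) or "A:T;B:D" (partial report) -> letter/role table
parse_display <- function(displayed) {
  if (grepl(":", displayed, fixed = TRUE)) {
    items <- strsplit(displayed, ";", fixed = TRUE)[[1]]
    parts <- strsplit(items, ":", fixed = TRUE)
    data.frame(letter = vapply(parts, `[`, "", 1),
               role = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(letter = strsplit(displayed, "")[[1]], role = "T",
               stringsAsFactors = FALSE)
  }
}

#' Goodness of fit between observed and predicted condition means
#'
#' Squared Pearson correlation between the observed and model-predicted mean
#' scores across exposure conditions (the convention in the TVA literature for
#' reporting whole-report fit quality).
#'
#' @param observed,predicted equal-length numeric vectors of condition means,
#'   length >= 2.
#' @return R-squared in [0, 1], or \code{NA_real_} (with a warning) when the
#'   observed means have zero variance.
#' @export
fit_r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  if (sd(observed) == 0 || sd(predicted) == 0) {
    warning("fit_r2: zero variance in condition means; R2 undefined")
    return(NA_real_)
  }
  cor(observed, predicted)^2
}
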