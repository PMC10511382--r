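#' The 16 partial-report display conditions
#'
#' Letters appear at the corners of an imaginary square; two-letter displays
#' are always vertical or horizontal, never diagonal. The design comprises 4
#' single-target (T), 8 target-plus-distractor (T-D) and 4 dual-target (T-T)
#' conditions.
#'
#' @return A data frame with columns \code{condition_id}, \code{type} (one of
#'   \code{"T"}, \code{"TD"}, \code{"TT"}), \code{pos1}, \code{role1},
#'   \code{pos2}, \code{role2} (positions are \code{"TL"}, \code{"TR"},
#'   \code{"BL"}, \code{"BR"}).
#' @export
partial_report_conditions <- function() {
  corners <- c("TL", "TR", "BL", "BR")
  pairs <- rbind(c("TL", "TR"), c("BL", "BR"), c("TL", "BL"), c("TR", "BR"))
  rows <- list()
  for (p in corners) {
    rows[[length(rows) + 1]] <- data.frame(type = "T", pos1 = p, role1 = "T",
                                           pos2 = NA_character_, role2 = NA_character_)
  }
  for (i in seq_len(nrow(pairs))) {
    rows[[length(rows) + 1]] <- data.frame(type = "TD", pos1 = pairs[i, 1], role1 = "T",
                                           pos2 = pairs[i, 2], role2 = "D")
    rows[[length(rows) + 1]] <- data.frame(type = "TD", pos1 = pairs[i, 2], role1 = "T",
                                           pos2 = pairs[i, 1], role2 = "D")
  }
  for (i in seq_len(nrow(pairs))) {
    rows[[length(rows) + 1]] <- data.frame(type = "TT", pos1 = pairs[i, 1], role1 = "T",
                                           pos2 = pairs[i, 2], role2 = "T")
  }
  out <- do.call(rbind, rows)
  out <- cbind(condition_id = seq_len(nrow(out)), out)
  out
}

#' Predicted target-report distribution for a partial-report condition
#'
#' Items race with exponential rates \code{v_x = C * w_x / sum(w)} where the
#' sum runs over displayed items only (target weight 1, distractor weight
#' \code{alpha}). Encoded items (finishing before the effective exposure
#' \code{a}) enter visual short-term memory up to the capacity drawn from the
#' K mixture, fastest first; only encoded-and-stored targets are reported.
#' With at most two display items the order statistics of the race give the
#' report probabilities in closed form.
#'
#' @param shared a \code{\link{tva_params}} object supplying C, t0 and K
#'   (partial-report displays are always masked, so \code{mu} is unused).
#' @param weights an \code{\link{attentional_weights}} object.
#' @param type condition type: \code{"T"}, \code{"TD"} or \code{"TT"}.
#' @param exposure_ms exposure duration in ms.
#' @return A list with \code{report_pmf} (distribution of the number of
#'   correctly reported targets) and \code{rates} (per-item encoding rates,
#'   letters/s).
#' @export
partial_report_prediction <- function(shared, weights, type = c("T", "TD", "TT"),
                                      exposure_ms) {
  stopifnot(inherits(shared, "tva_params"))
  if (!inherits(weights, "attentional_weights")) weights <- attentional_weights(weights)
  type <- match.arg(type)
  a <- max(0, exposure_ms - shared$t0) / 1000
  C <- shared$C
  alpha <- weights$alpha
  caps <- capacity_pmf(shared)
  p_cap <- function(pred) sum(caps[vapply(names(caps), function(k) pred(as.integer(k)), TRUE)])
  p0 <- p_cap(function(k) k == 0)
  p1 <- p_cap(function(k) k == 1)
  p2 <- 1 - p0 - p1
  if (type == "T") {
    v <- C
    pT <- 1 - exp(-v * a)
    prob1 <- (p1 + p2) * pT
    pmf <- c(`0` = 1 - prob1, `1` = prob1)
    rates <- c(target = v)
  } else if (type == "TD") {
    vT <- C / (1 + alpha)
    vD <- C * alpha / (1 + alpha)
    ## capacity >= 2: target reported iff encoded; capacity 1: target must
    ## finish first among finishers, i.e. T < a and T < D
    p_enc <- 1 - exp(-vT * a)
    p_first <- if (vT + vD > 0) vT / (vT + vD) * (1 - exp(-(vT + vD) * a)) else 0
    prob1 <- p2 * p_enc + p1 * p_first
    pmf <- c(`0` = 1 - prob1, `1` = prob1)
    rates <- c(target = vT, distractor = vD)
  } else {
    v <- C / 2
    p <- 1 - exp(-v * a)
    pmf2 <- p2 * dbinom(0:2, 2, p)
    ## capacity 1: exactly one reported iff any encoded
    pmf1 <- c(exp(-2 * v * a), 1 - exp(-2 * v * a), 0) * p1
    pmf <- pmf2 + pmf1
    pmf[1] <- pmf[1] + p0
    names(pmf) <- 0:2
    rates <- c(target = v, target = v)
  }
  list(report_pmf = pmf, rates = rates)
}

#' Log-likelihood of a partial-report dataset
#'
#' The observation per trial is the number of correctly reported targets in
#' its condition type; positional differences are not modelled.
#'
#' @inheritParams partial_report_prediction
#' @param data partial-report trial data frame with columns \code{type},
#'   \code{exposure_ms} and \code{score} (number of targets reported).
#' @param floor minimum per-trial likelihood.
#' @return The log-likelihood.
#' @export
partial_report_loglik <- function(shared, weights, data, floor = 1e-12) {
  data <- ensure_partial_types(data)
  data <- ensure_scores(data, paradigm = "partial")
  if (nrow(data) == 0) return(0)
  key <- paste(data$type, data$exposure_ms)
  ll <- 0
  for (k in unique(key)) {
    rows <- data[key == k, ]
    pr <- partial_report_prediction(shared, weights, rows$type[1], rows$exposure_ms[1])
    pmf <- pmax(pr$report_pmf, floor)
    tab <- tabulate(rows$score + 1L, nbins = length(pmf))
    ll <- ll + sum(tab * log(pmf))
  }
  ll
}

## derive condition type (T / TD / TT) from the displayed role string
ensure_partial_types <- function(data) {
  if (!is.null(data$type)) return(data)
  if (is.null(data$displayed)) {
    stop("partial-report data needs a 'type' or 'displayed' column", call. = FALSE)
  }
  data$type <- vapply(data$displayed, function(d) {
    roles <- parse_display(d)$role
    if (length(roles) == 1) "T" else if (any(roles == "D")) "TD" else "TT"
  }, "", USE.NAMES = FALSE)
  data
}
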