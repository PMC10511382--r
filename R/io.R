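#' Write trial-level report data to CSV
#'
#' One row per trial with columns \code{subject_id}, \code{paradigm},
#' \code{condition_id}, \code{exposure_ms}, \code{masked} (0/1),
#' \code{displayed} (concatenated letters; \code{"A:T;B:D"} letter:role form
#' for partial report) and \code{reported}.
#'
#' @param data a whole- or partial-report trial data frame.
#' @param path output file path.
#' @export
write_trials <- function(data, path) {
  cols <- c("subject_id", "paradigm", "condition_id", "exposure_ms",
            "masked", "displayed", "reported")
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("write_trials: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- data[cols]
  out$masked <- as.integer(out$masked)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read trial-level report data from CSV
#'
#' Validates the schema and reports malformed rows with their line numbers:
#' unknown paradigm, duplicate letters within a display, letters outside the
#' 23-letter report alphabet, whole-report displays that are not 6 letters,
#' or more reported than displayed letters.
#'
#' @param path CSV file path.
#' @return A \code{whole_report_data} or \code{partial_report_data} data frame
#'   (with derived \code{score} and, for partial report, \code{type}); a named
#'   list of both when the file mixes paradigms.
#' @export
read_trials <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(displayed = "character", reported = "character"))
  required <- c("subject_id", "paradigm", "condition_id", "exposure_ms",
                "masked", "displayed", "reported")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("read_trials: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw$masked <- as.logical(as.integer(raw$masked))
  bad <- list()
  for (i in seq_len(nrow(raw))) {
    row_errs <- character()
    if (!raw$paradigm[i] %in% c("whole", "partial")) {
      row_errs <- c(row_errs, paste0("unknown paradigm '", raw$paradigm[i], "'"))
    }
    shown <- parse_display(raw$displayed[i])
    if (anyDuplicated(shown$letter)) {
      row_errs <- c(row_errs, "duplicate letters in display")
    }
    if (!all(shown$letter %in% REPORT_ALPHABET)) {
      row_errs <- c(row_errs, "letters outside the report alphabet")
    }
    if (raw$paradigm[i] == "whole" && nrow(shown) != 6) {
      row_errs <- c(row_errs, paste0(nrow(shown), "-letter whole-report display"))
    }
    rep_l <- strsplit(raw$reported[i], "")[[1]]
    if (length(rep_l) > nrow(shown)) {
      row_errs <- c(row_errs, "more reported than displayed letters")
    }
    if (length(row_errs)) bad[[as.character(i)]] <- row_errs
  }
  if (length(bad)) {
    msgs <- vapply(names(bad), function(i) {
      paste0("row ", i, ": ", paste(bad[[i]], collapse = "; "))
    }, "")
    stop("read_trials: invalid rows\n  ", paste(msgs, collapse = "\n  "),
         call. = FALSE)
  }
  finish <- function(d) {
    paradigm <- d$paradigm[1]
    if (paradigm == "partial") {
      d <- ensure_partial_types(d)
      d <- ensure_scores(d, "partial")
      class(d) <- c("partial_report_data", "data.frame")
    } else {
      d <- ensure_scores(d, "whole")
      class(d) <- c("whole_report_data", "data.frame")
    }
    rownames(d) <- NULL
    d
  }
  paradigms <- unique(raw$paradigm)
  if (length(paradigms) == 1) return(finish(raw))
  lapply(split(raw, raw$paradigm), finish)
}

#' Write a pupil trace to CSV
#'
#' Columns \code{time_s}, \code{diameter_mm}, \code{valid} (0/1).
#'
#' @param trace a \code{\link{pupil_trace}}.
#' @param path output file path.
#' @export
write_pupil_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pupil_trace"))
  n <- length(trace$diameter)
  write.csv(data.frame(time_s = (seq_len(n) - 1) / trace$sampling_rate,
                       diameter_mm = trace$diameter,
                       valid = as.integer(trace$valid)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a pupil trace from CSV
#'
#' @param path CSV with columns \code{time_s}, \code{diameter_mm},
#'   \code{valid}.
#' @return A \code{\link{pupil_trace}}; the sampling rate is inferred from the
#'   median time step.
#' @export
read_pupil_trace <- function(path) {
  d <- read.csv(path)
  required <- c("time_s", "diameter_mm", "valid")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("read_pupil_trace: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dt <- median(diff(d$time_s))
  pupil_trace(d$diameter_mm, sampling_rate = 1 / dt,
              valid = as.logical(d$valid))
}

## strip S3 classes so jsonlite serializes plainly
as_plain <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, as_plain)
  } else if (is.matrix(x)) {
    x
  } else {
    unclass(x)
  }
}

#' Serialize a TVA fit to the per-subject JSON interchange form
#'
#' @param fit a \code{tva_fit}.
#' @param path optional file path; when omitted the list is returned.
#' @return The list written (invisibly when \code{path} is given).
#' @export
write_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "tva_fit"))
  out <- list(C = fit$params$C, t0 = fit$params$t0, K = fit$params$K,
              mu = fit$params$mu,
              alpha = if (!is.null(fit$weights)) fit$weights$alpha else NULL,
              loglik = fit$loglik, R2_fit = fit$R2_fit,
              convergence = fit$convergence)
  out <- out[!vapply(out, is.null, TRUE)]
  if (is.null(path)) return(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Serialize an analysis report to JSON
#'
#' @param report an \code{arousal_report}.
#' @param path output file path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "arousal_report"))
  jsonlite::write_json(as_plain(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
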