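#' Construct a pupil diameter trace
#'
#' @param diameter numeric vector of pupil diameters in mm (25-Hz series by
#'   default).
#' @param sampling_rate sampling rate in Hz, > 0.
#' @param valid optional logical vector marking artifact-free samples
#'   (\code{FALSE} = blink/movement/missing); defaults to all valid.
#' @return An object of class \code{pupil_trace}.
#' @export
pupil_trace <- function(diameter, sampling_rate = 25, valid = NULL) {
  stopifnot(is.numeric(diameter), length(diameter) > 0, sampling_rate > 0)
  if (is.null(valid)) valid <- rep(TRUE, length(diameter))
  stopifnot(length(valid) == length(diameter))
  structure(
    list(diameter = as.numeric(diameter), sampling_rate = sampling_rate,
         valid = as.logical(valid),
         duration_s = length(diameter) / sampling_rate),
    class = "pupil_trace"
  )
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("Pupil trace: %.1f s at %g Hz (%d samples, %d flagged)\n",
              x$duration_s, x$sampling_rate, length(x$diameter), sum(!x$valid)))
  invisible(x)
}

#' Preprocess a pupil trace (artifact removal and interpolation)
#'
#' Samples that are flagged, implausible (outside
#' [\code{min_plausible_mm}, \code{max_plausible_mm}]) or follow a
#' physiologically impossible jump (> \code{max_jump_mm} between consecutive
#' samples) are treated as gaps and filled by linear interpolation between the
#' nearest valid neighbours (nearest-value extension at the edges). Gaps
#' longer than \code{max_gap_s} are still filled but recorded so that
#' overlapping PUI segments can be excluded downstream.
#'
#' @param raw a \code{\link{pupil_trace}}.
#' @param max_gap_s longest gap (s) that may be bridged by interpolation
#'   without invalidating its segment (default 3, the blink-duration rule).
#' @param min_plausible_mm,max_plausible_mm plausibility bounds (default
#'   1.5 and 9 mm).
#' @param max_jump_mm largest credible sample-to-sample change (default 1 mm
#'   per sample).
#' @return The trace with interpolated \code{diameter}, all-\code{TRUE}
#'   \code{valid}, and added fields \code{interpolated} (logical),
#'   \code{long_gaps} (two-column matrix of sample index ranges exceeding
#'   \code{max_gap_s}) and \code{n_samples_interpolated}.
#' @export
preprocess_trace <- function(raw, max_gap_s = 3.0, min_plausible_mm = 1.5,
                             max_plausible_mm = 9.0, max_jump_mm = 1.0) {
  stopifnot(inherits(raw, "pupil_trace"))
  d <- raw$diameter
  n <- length(d)
  bad <- !raw$valid | !is.finite(d) | d < min_plausible_mm | d > max_plausible_mm
  jump <- c(FALSE, abs(diff(d)) > max_jump_mm)
  ## jumps into/out of already-bad regions are artifacts of the gap itself
  jump[bad | c(FALSE, head(bad, -1))] <- FALSE
  bad <- bad | jump
  if (all(bad)) stop("preprocess_trace: unusable trace - no valid samples", call. = FALSE)

  long_gaps <- matrix(integer(0), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
  if (any(bad)) {
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gap_runs <- which(r$values)
    len_s <- r$lengths[gap_runs] / raw$sampling_rate
    long <- gap_runs[len_s > max_gap_s]
    if (length(long)) {
      long_gaps <- cbind(start = starts[long], end = ends[long])
    }
    good_idx <- which(!bad)
    d <- approx(good_idx, d[good_idx], xout = seq_len(n), rule = 2)$y
  }

  out <- pupil_trace(d, raw$sampling_rate, valid = rep(TRUE, n))
  out$interpolated <- bad
  out$long_gaps <- long_gaps
  out$n_samples_interpolated <- sum(bad)
  out
}

#' Block-average decimation (simple low-pass filter)
#'
#' Non-overlapping means of \code{block} consecutive samples; a trailing
#' partial block is discarded. At 25 Hz with the default block of 16 the
#' output rate is 1.5625 Hz.
#'
#' @param x a \code{\link{pupil_trace}} or numeric vector.
#' @param block block length (default 16).
#' @return Numeric vector of block means with attribute \code{rate} (Hz) when
#'   the input carries a sampling rate.
#' @export
block_average <- function(x, block = 16) {
  rate <- NULL
  if (inherits(x, "pupil_trace")) {
    rate <- x$sampling_rate
    x <- x$diameter
  }
  stopifnot(length(x) >= block)
  n_blocks <- length(x) %/% block
  means <- colMeans(matrix(x[seq_len(n_blocks * block)], nrow = block))
  if (!is.null(rate)) attr(means, "rate") <- rate / block
  means
}

#' Pupillary unrest for one decimated segment
#'
#' Sum of absolute successive differences of the block means within one
#' 82.5-s segment, normalized to a 1-minute period: \code{PUI = sum(|diff|) *
#' 60 / segment_s}, in mm/min. A constant segment yields exactly 0.
#'
#' @param decimated block means of one segment (128 values at 25 Hz / block
#'   16, giving 127 differences).
#' @param segment_s segment duration in seconds (default 82.5).
#' @return Segment PUI in mm/min, or \code{NA_real_} if the segment contains
#'   missing values.
#' @export
pui_segment <- function(decimated, segment_s = 82.5) {
  stopifnot(length(decimated) >= 2)
  if (anyNA(decimated)) return(NA_real_)
  sum(abs(diff(decimated))) * 60 / segment_s
}

#' Pupillary unrest index and mean pupil diameter for a recording
#'
#' Partitions the (preprocessed) trace into consecutive 82.5-s segments from
#' the recording start, computes the per-segment PUI from 16-sample block
#' means, and averages over valid segments. An 11-minute (660 s) recording
#' yields exactly 8 segments. A segment is excluded when it overlaps a gap
#' longer than the blink rule (3 s) or contains more than
#' \code{max_interp_frac} interpolated samples. Because 82.5 s at 25 Hz is
#' 2062.5 samples, each segment uses the first 128 complete blocks (2048
#' samples) and segment origins advance by 82.5 s of real time.
#'
#' @param trace a \code{\link{pupil_trace}}; raw traces are preprocessed with
#'   default settings first.
#' @param segment_s segment duration (default 82.5 s).
#' @param block block length for decimation (default 16).
#' @param max_interp_frac maximum tolerated fraction of interpolated samples
#'   per segment (default 0.25).
#' @return An object of class \code{pui_result}: \code{segment_puis} (mm/min,
#'   \code{NA} for excluded segments), \code{total_pui} (mean over valid
#'   segments, mm/min), \code{mean_pd} (mean diameter in mm over samples
#'   outside long gaps), \code{n_segments_used}, \code{n_samples_interpolated},
#'   \code{n_diffs_per_segment}, \code{decimated_rate_hz} and \code{flagged}
#'   (TRUE when fewer segments than expected were usable).
#' @examples
#' tr <- pupil_trace(rep(6, 660 * 25))
#' compute_pui(tr)$total_pui  # 0 for a perfectly stable pupil
#' @export
compute_pui <- function(trace, segment_s = 82.5, block = 16,
                        max_interp_frac = 0.25) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (is.null(trace$interpolated)) trace <- preprocess_trace(trace)
  rate <- trace$sampling_rate
  n <- length(trace$diameter)
  n_seg <- floor(n / (segment_s * rate))
  if (n_seg < 1) stop("compute_pui: trace shorter than one segment", call. = FALSE)
  blocks_per_seg <- floor(segment_s * rate / block)
  samples_per_seg <- blocks_per_seg * block

  in_long_gap <- rep(FALSE, n)
  if (nrow(trace$long_gaps) > 0) {
    for (i in seq_len(nrow(trace$long_gaps))) {
      in_long_gap[trace$long_gaps[i, 1]:trace$long_gaps[i, 2]] <- TRUE
    }
  }

  seg_puis <- rep(NA_real_, n_seg)
  for (s in seq_len(n_seg)) {
    start <- round((s - 1) * segment_s * rate) + 1L
    idx <- start:(start + samples_per_seg - 1L)
    if (max(idx) > n) break
    if (any(in_long_gap[idx])) next
    if (mean(trace$interpolated[idx]) > max_interp_frac) next
    seg_puis[s] <- pui_segment(block_average(trace$diameter[idx], block), segment_s)
  }
  used <- sum(!is.na(seg_puis))
  if (used < 1) stop("compute_pui: no valid segments", call. = FALSE)

  structure(
    list(segment_puis = seg_puis,
         total_pui = mean(seg_puis, na.rm = TRUE),
         mean_pd = mean(trace$diameter[!in_long_gap]),
         n_segments_used = used,
         n_samples_interpolated = trace$n_samples_interpolated,
         n_diffs_per_segment = blocks_per_seg - 1L,
         decimated_rate_hz = rate / block,
         flagged = used < n_seg),
    class = "pui_result"
  )
}

#' @export
print.pui_result <- function(x, ...) {
  cat(sprintf("PUI: %.3f mm/min over %d segment(s)%s; mean PD %.2f mm\n",
              x$total_pui, x$n_segments_used,
              if (x$flagged) " [flagged: segments excluded]" else "",
              x$mean_pd))
  invisible(x)
}
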