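#' Bandpass filter specification
#'
#' A Butterworth bandpass that keeps the 0.5-10 Hz pulse band, suppressing
#' respiratory drift below 0.5 Hz and electromagnetic interference above
#' 10 Hz. Applied forward-backward (zero phase) by default so fiducial
#' timing is not shifted.
#'
#' @param low_cut_hz Lower cutoff in Hz (default 0.5).
#' @param high_cut_hz Upper cutoff in Hz (default 10).
#' @param order Filter order (default 4); the zero-phase pass doubles the
#'   effective magnitude order.
#' @param zero_phase Apply forward-backward filtering (default `TRUE`).
#'
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_cut_hz = 0.5, high_cut_hz = 10, order = 4,
                        zero_phase = TRUE) {
  stopifnot(is_scalar_number(low_cut_hz), is_scalar_number(high_cut_hz),
            low_cut_hz > 0, low_cut_hz < high_cut_hz)
  stopifnot(is_scalar_number(order), order >= 1)
  structure(
    list(low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
         order = as.integer(order), zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

#' Repair short missing-value runs, reject long ones
#'
#' Gaps of at most `max_gap_samples` (30 samples at 125 Hz, under a quarter
#' of the shortest physiological beat) are filled by linear interpolation
#' from the flanking valid samples. Any longer gap, or a gap touching a
#' segment boundary, rejects the whole segment. Saturation flat lines
#' (consecutive identical extreme values) carry no missing mask and are
#' preserved untouched.
#'
#' @param segment A [ppg_segment()].
#' @param max_gap_samples Longest repairable run (default 30).
#'
#' @return The repaired [ppg_segment()] with an all-`FALSE` mask. Rejection
#'   raises a classed condition (`ppg_rejection`); table-level wrappers such
#'   as [preprocess_segments()] catch it and drop the segment.
#' @export
repair_missing <- function(segment, max_gap_samples = 30) {
  stopifnot(inherits(segment, "ppg_segment"))
  mask <- segment$missing_mask | is.na(segment$samples)
  if (!any(mask)) return(segment)
  x <- segment$samples
  n <- length(x)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    if (r$lengths[j] > max_gap_samples) {
      reject_segment("missing run of %d samples exceeds threshold %d",
                     r$lengths[j], max_gap_samples)
    }
    if (starts[j] == 1 || ends[j] == n) {
      reject_segment("missing run touches the segment boundary")
    }
  }
  valid <- which(!mask)
  x[mask] <- approx(valid, x[valid], xout = which(mask))$y
  out <- segment
  out$samples <- x
  out$missing_mask <- rep(FALSE, n)
  out
}

#' Bandpass-filter a segment
#'
#' Zero-phase Butterworth bandpass per the supplied [filter_spec()]. A
#' constant (DC) input maps to numerically zero output; passband tones are
#' preserved.
#'
#' @param segment A [ppg_segment()] with no missing values.
#' @param spec A [filter_spec()].
#'
#' @return The filtered [ppg_segment()].
#' @export
bandpass <- function(segment, spec = filter_spec()) {
  stopifnot(inherits(segment, "ppg_segment"), inherits(spec, "filter_spec"))
  if (any(segment$missing_mask) || anyNA(segment$samples)) {
    stop("bandpass requires a segment with no missing values; run repair_missing() first")
  }
  nyq <- segment$sample_rate_hz / 2
  if (spec$high_cut_hz >= nyq) {
    stop("high_cut_hz (", spec$high_cut_hz, ") must be below Nyquist (", nyq, ")")
  }
  bf <- signal::butter(spec$order, c(spec$low_cut_hz, spec$high_cut_hz) / nyq,
                       type = "pass")
  out <- segment
  if (spec$zero_phase) {
    # pad by several low-cut time constants so reflection transients decay
    # before they reach the data
    padlen <- round(3 * segment$sample_rate_hz / spec$low_cut_hz)
    out$samples <- zero_phase_filter(bf$b, bf$a, segment$samples, padlen)
  } else {
    zi <- filter_initial_state(bf$b, bf$a)
    out$samples <- iir_filter(bf$b, bf$a, segment$samples, zi * segment$samples[1])
  }
  out
}

#' Z-score normalize a segment
#'
#' Standardizes to zero mean and unit standard deviation, computed per
#' segment. Constant segments cannot be normalized and are rejected.
#'
#' @param segment A [ppg_segment()] with no missing values.
#' @return The standardized [ppg_segment()].
#' @export
zscore <- function(segment) {
  stopifnot(inherits(segment, "ppg_segment"))
  if (anyNA(segment$samples)) {
    stop("zscore requires a segment with no missing values")
  }
  s <- stats::sd(segment$samples)
  if (!is.finite(s) || s == 0) {
    reject_segment("zero-variance segment cannot be z-score normalized")
  }
  out <- segment
  out$samples <- (segment$samples - mean(segment$samples)) / s
  out
}

#' Run the fixed preprocessing chain on one segment
#'
#' Order is fixed: missing-value repair, bandpass filtering, z-score
#' normalization.
#'
#' @inheritParams repair_missing
#' @inheritParams bandpass
#' @return The preprocessed [ppg_segment()] (z-units), or a `ppg_rejection`
#'   condition.
#' @export
preprocess_segment <- function(segment, spec = filter_spec(),
                               max_gap_samples = 30) {
  zscore(bandpass(repair_missing(segment, max_gap_samples), spec))
}

#' Preprocess a table of segments, dropping rejected ones
#'
#' Applies [preprocess_segment()] to every row of a segment table (as
#' produced by [extract_windows()]), replacing the `segment` list-column
#' with preprocessed segments and dropping rows rejected by the
#' missing-value or normalization rules.
#'
#' @param segments Tibble with a `segment` list-column.
#' @inheritParams preprocess_segment
#' @return The filtered tibble; the number of rejected rows is recorded in
#'   attribute `n_rejected`.
#' @export
preprocess_segments <- function(segments, spec = filter_spec(),
                                max_gap_samples = 30) {
  out <- purrr::map(segments$segment, function(seg) {
    tryCatch(preprocess_segment(seg, spec, max_gap_samples),
             ppg_rejection = function(cond) NULL)
  })
  keep <- !purrr::map_lgl(out, is.null)
  res <- segments[keep, , drop = FALSE]
  res$segment <- out[keep]
  attr(res, "n_rejected") <- sum(!keep)
  res
}
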