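#' Construct a PPG segment record
#'
#' A `ppg_segment` is the unit object passed between pipeline stages: a
#' fixed-rate one-dimensional waveform with patient/time metadata and an
#' authoritative missing-value mask. At the default 125 Hz a 10-second
#' segment holds 1250 samples.
#'
#' @param samples Numeric vector of waveform samples (arbitrary units before
#'   normalization, z-units after). Missing samples are `NA` and must be
#'   flagged in `missing_mask`.
#' @param sample_rate_hz Positive sampling rate in Hz.
#' @param start_time Segment start time in seconds (timezone-naive offset).
#' @param patient_id Patient identifier string.
#' @param missing_mask Logical vector, same length as `samples`; `TRUE` marks
#'   a missing sample. The mask is authoritative: entries masked `TRUE` are
#'   treated as gaps even if a numeric value is present.
#'
#' @return An object of class `ppg_segment`.
#' @export
#' @examples
#' seg <- ppg_segment(sin(2 * pi * 1.2 * (0:1249) / 125), 125)
#' seg
ppg_segment <- function(samples, sample_rate_hz = 125, start_time = 0,
                        patient_id = "unknown", missing_mask = NULL) {
  stopifnot(is.numeric(samples), length(samples) >= 1)
  stopifnot(is_scalar_number(sample_rate_hz), sample_rate_hz > 0)
  if (is.null(missing_mask)) missing_mask <- is.na(samples)
  stopifnot(is.logical(missing_mask), length(missing_mask) == length(samples))
  missing_mask <- missing_mask | is.na(samples)
  structure(
    list(
      samples = as.numeric(samples),
      sample_rate_hz = sample_rate_hz,
      start_time = start_time,
      patient_id = as.character(patient_id),
      missing_mask = missing_mask
    ),
    class = "ppg_segment"
  )
}

#' @export
print.ppg_segment <- function(x, ...) {
  cat(sprintf(
    "<ppg_segment> %s: %d samples @ %g Hz (%.1f s), start %.1f s, %d missing\n",
    x$patient_id, length(x$samples), x$sample_rate_hz,
    length(x$samples) / x$sample_rate_hz, x$start_time, sum(x$missing_mask)
  ))
  invisible(x)
}

#' @export
length.ppg_segment <- function(x) length(x$samples)

seg_duration <- function(segment) length(segment$samples) / segment$sample_rate_hz

seg_end_time <- function(segment) segment$start_time + seg_duration(segment)
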