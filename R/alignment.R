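#' Pair glucose measurements with fixed-length PPG segments
#'
#' For each glucose measurement, a +/-`half_window_minutes` interval around
#' the measurement time is treated as a physiological state window and cut
#' into consecutive, non-overlapping 10-second segments. When the full window
#' is not covered by the record, the longest continuous available run is
#' used; trailing partial segments are dropped. When the windows of two
#' nearby measurements overlap, each segment is kept only for the measurement
#' nearest its centre (ties go to the earlier measurement).
#'
#' @param record A [ppg_segment()] holding the full waveform record.
#' @param measurements Tibble with columns `patient_id`, `time` (seconds) and
#'   `glucose_mgdl`, as produced by [generate_glucose_timeline()] or
#'   [read_glucose_csv()].
#' @param half_window_minutes Half-width of the state window (default 9).
#' @param segment_seconds Segment length in seconds (default 10).
#'
#' @return A tibble with one row per extracted segment: `patient_id`,
#'   `measurement_time`, `glucose_mgdl`, `segment_start` (seconds) and a
#'   `segment` list-column of [ppg_segment()] objects. Zero rows (with a
#'   warning) when no window overlaps the record.
#' @export
extract_windows <- function(record, measurements, half_window_minutes = 9,
                            segment_seconds = 10) {
  stopifnot(inherits(record, "ppg_segment"))
  stopifnot(all(c("patient_id", "time", "glucose_mgdl") %in% names(measurements)))
  measurements <- dplyr::arrange(measurements, .data$time)
  if (nrow(measurements) == 0) return(empty_window_tbl())
  if (!all(measurements$patient_id == record$patient_id)) {
    stop("record and measurements must share patient_id (record: '",
         record$patient_id, "')")
  }
  fs <- record$sample_rate_hz
  seg_n <- as.integer(round(segment_seconds * fs))
  half_s <- half_window_minutes * 60
  rec_start <- record$start_time
  rec_end <- seg_end_time(record)

  rows <- list()
  for (i in seq_len(nrow(measurements))) {
    t_meas <- measurements$time[i]
    a <- max(t_meas - half_s, rec_start)
    b <- min(t_meas + half_s, rec_end)
    if (b - a < segment_seconds) next
    n_seg <- floor((b - a) / segment_seconds)
    for (k in seq_len(n_seg) - 1) {
      seg_start <- a + k * segment_seconds
      centre <- seg_start + segment_seconds / 2
      dist <- abs(measurements$time - centre)
      nearest <- which(dist == min(dist))[1]  # tie -> earlier measurement
      if (nearest != i) next
      i0 <- as.integer(round((seg_start - rec_start) * fs)) + 1L
      span <- i0:(i0 + seg_n - 1L)
      if (span[1] < 1 || span[length(span)] > length(record$samples)) next
      seg <- ppg_segment(
        record$samples[span], fs, start_time = seg_start,
        patient_id = record$patient_id,
        missing_mask = record$missing_mask[span]
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = record$patient_id,
        measurement_time = t_meas,
        glucose_mgdl = measurements$glucose_mgdl[i],
        segment_start = seg_start,
        segment = list(seg)
      )
    }
  }
  if (length(rows) == 0) {
    warning("no overlap between record span and any measurement window")
    return(empty_window_tbl())
  }
  dplyr::bind_rows(rows)
}

empty_window_tbl <- function() {
  tibble::tibble(
    patient_id = character(), measurement_time = numeric(),
    glucose_mgdl = numeric(), segment_start = numeric(), segment = list()
  )
}

#' Read a glucose measurement table from CSV
#'
#' Expects columns `patient_id`, `time` (seconds) and `glucose_mgdl`.
#'
#' @param path CSV path.
#' @return A tibble sorted by patient and time.
#' @export
read_glucose_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "glucose_mgdl")
  if (!all(need %in% names(df))) {
    stop("glucose CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$glucose_mgdl <= 0)) stop("glucose values must be positive")
  dplyr::arrange(tibble::as_tibble(df), .data$patient_id, .data$time)
}
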