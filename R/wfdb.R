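# Minimal WFDB record I/O: format 16 (16-bit two's-complement little-endian)
# .dat files with plain-text .hea headers, the layout used by the ICU
# waveform records this toolkit targets. Only what the pipeline needs is
# implemented: single- or multi-signal format-16 records, gain/baseline
# scaling, and the -32768 invalid-sample code for missing values.

WFDB_INVALID <- -32768L

#' Write a segment as a WFDB-compatible record pair
#'
#' Writes `<record>.hea` and `<record>.dat` (format 16, little-endian).
#' Missing samples are stored as the WFDB invalid-sample code -32768.
#'
#' @param segment A [ppg_segment()].
#' @param dir Output directory (created if needed).
#' @param record_name Record name (file stem).
#' @param gain ADC units per physical unit (default 200).
#' @param description Signal description written to the header; the reader
#'   selects PPG channels by matching this field.
#'
#' @return The header path, invisibly.
#' @export
write_waveform <- function(segment, dir, record_name, gain = 200,
                           description = "PLETH") {
  stopifnot(inherits(segment, "ppg_segment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(segment$samples)
  adc <- ifelse(
    segment$missing_mask | is.na(segment$samples),
    WFDB_INVALID,
    pmax(-32767, pmin(32767, round(segment$samples * gain)))
  )
  adc <- as.integer(adc)

  dat_name <- paste0(record_name, ".dat")
  writeBin(adc, file.path(dir, dat_name), size = 2, endian = "little")

  checksum <- sum(adc) %% 65536
  if (checksum >= 32768) checksum <- checksum - 65536
  init <- adc[1]
  base <- seconds_to_base_time(segment$start_time)
  hea <- c(
    sprintf("%s 1 %g %d %s", record_name, segment$sample_rate_hz, n, base),
    sprintf("%s 16 %g(0)/NU 16 0 %d %d 0 %s",
            dat_name, gain, init, checksum, description),
    sprintf("# patient_id: %s", segment$patient_id)
  )
  hea_path <- file.path(dir, paste0(record_name, ".hea"))
  writeLines(hea, hea_path)
  invisible(hea_path)
}

seconds_to_base_time <- function(seconds) {
  seconds <- max(0, seconds)
  h <- floor(seconds / 3600)
  m <- floor((seconds - 3600 * h) / 60)
  s <- seconds - 3600 * h - 60 * m
  sprintf("%02d:%02d:%06.3f", h, m, s)
}

base_time_to_seconds <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) return(0)
  vals <- suppressWarnings(as.numeric(parts))
  if (any(is.na(vals))) return(0)
  vals[1] * 3600 + vals[2] * 60 + vals[3]
}

#' Read a WFDB record and extract its PPG channel
#'
#' Parses the `.hea` header, reads the interleaved format-16 `.dat` samples,
#' applies gain/baseline scaling, decodes -32768 entries as missing values,
#' and returns the photoplethysmography channel as a [ppg_segment()].
#'
#' @param path Path to the record: the `.hea` file, the `.dat` file, or the
#'   bare record stem.
#' @param channel Optional channel index or description pattern. By default
#'   the first channel whose description matches `"PLETH"` or `"PPG"`
#'   (case-insensitively) is used; if no channel matches, the error names the
#'   available channels.
#'
#' @return A [ppg_segment()].
#' @export
read_waveform <- function(path, channel = NULL) {
  stem <- sub("\\.(hea|dat)$", "", path)
  hea_path <- paste0(stem, ".hea")
  if (!file.exists(hea_path)) stop("header not found: ", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  comments <- lines[startsWith(trimws(lines), "#")]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) < 2) stop("corrupt WFDB header: ", hea_path)

  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head_tok) < 4) stop("corrupt WFDB header line: ", lines[1])
  n_sig <- suppressWarnings(as.integer(head_tok[2]))
  fs <- suppressWarnings(as.numeric(head_tok[3]))
  n_samp <- suppressWarnings(as.integer(head_tok[4]))
  if (any(is.na(c(n_sig, fs, n_samp))) || n_sig < 1 || fs <= 0 || n_samp < 1) {
    stop("corrupt WFDB header line: ", lines[1])
  }
  start_time <- if (length(head_tok) >= 5) base_time_to_seconds(head_tok[5]) else 0

  if (length(lines) < 1 + n_sig) stop("corrupt WFDB header: missing signal lines")
  sig <- lapply(lines[1 + seq_len(n_sig)], function(line) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) < 2) stop("corrupt WFDB signal line: ", line)
    fmt <- tok[2]
    if (fmt != "16") stop("unsupported WFDB format '", fmt, "' (only 16)")
    gain_spec <- if (length(tok) >= 3) tok[3] else "200"
    m <- regmatches(gain_spec,
                    regexec("^([-0-9.eE+]+)(\\(([-0-9.]+)\\))?(/(.*))?$", gain_spec))[[1]]
    gain <- suppressWarnings(as.numeric(m[2]))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- suppressWarnings(as.numeric(m[4]))
    if (is.na(baseline)) baseline <- 0
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ") else ""
    list(file = tok[1], gain = gain, baseline = baseline, description = desc)
  })
  descs <- vapply(sig, `[[`, "", "description")

  if (is.null(channel)) {
    hit <- grep("PLETH|PPG", descs, ignore.case = TRUE)
    if (length(hit) == 0) {
      stop("no PPG/PLETH channel in record '", stem, "'; available channels: ",
           paste(sprintf("[%d] %s", seq_along(descs), descs), collapse = ", "))
    }
    channel <- hit[1]
  } else if (is.character(channel)) {
    hit <- grep(channel, descs, ignore.case = TRUE)
    if (length(hit) == 0) {
      stop("no channel matching '", channel, "'; available channels: ",
           paste(descs, collapse = ", "))
    }
    channel <- hit[1]
  }
  stopifnot(channel >= 1, channel <= n_sig)

  dat_path <- file.path(dirname(hea_path), sig[[channel]]$file)
  if (!file.exists(dat_path)) stop("data file not found: ", dat_path)
  raw <- readBin(dat_path, what = "integer", n = n_samp * n_sig,
                 size = 2, signed = TRUE, endian = "little")
  if (length(raw) < n_samp * n_sig) {
    stop("data file shorter than header declares: ", dat_path)
  }
  adc <- raw[seq(channel, by = n_sig, length.out = n_samp)]
  missing <- adc == WFDB_INVALID
  values <- (adc - sig[[channel]]$baseline) / sig[[channel]]$gain
  values[missing] <- NA_real_

  pid <- "unknown"
  pid_line <- grep("patient_id:", comments, value = TRUE)
  if (length(pid_line) > 0) pid <- trimws(sub(".*patient_id:", "", pid_line[1]))

  ppg_segment(values, fs, start_time = start_time, patient_id = pid,
              missing_mask = missing)
}
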