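#' Configuration for the synthetic PPG generator
#'
#' Defines the study conditions emulated by [generate_segment()]: a
#' quasi-periodic pulse with a dicrotic wave, plus controllable degradations
#' (baseline wander, Gaussian noise, motion-artifact bursts, saturation flat
#' lines and missing-value runs).
#'
#' @param sample_rate_hz Sampling rate in Hz (default 125, the rate of the
#'   ICU waveform records the toolkit targets).
#' @param duration_s Segment duration in seconds; `duration_s *
#'   sample_rate_hz` must be a whole number of samples.
#' @param heart_rate_bpm Heart rate in beats per minute, within the
#'   physiological 40-140 range.
#' @param dicrotic_amplitude Dicrotic lobe amplitude as a fraction of the
#'   systolic amplitude, in `[0, 1)`.
#' @param noise_sd Standard deviation of additive Gaussian noise, in units of
#'   the (unit-amplitude) clean pulse.
#' @param artifact_burst_rate Expected motion-artifact bursts per minute.
#'   Each burst injects isolated large-amplitude spikes that, after
#'   per-segment z-scoring, exceed `|z| = 4` and produce within-wave
#'   amplitude differences above 8 by construction.
#' @param dropout_run_lengths Integer vector of missing-run lengths
#'   (samples); each run is placed at a random position and encoded as `NA`
#'   with the missing mask set.
#' @param flatline_fraction Fraction of the segment replaced by a single
#'   saturation flat line (consecutive identical extreme values), in `[0, 1)`.
#' @param baseline_amplitude Amplitude of a slow (0.25 Hz) baseline wander
#'   component, in clean-pulse units.
#' @param seed Integer seed; generation is bit-reproducible for a fixed seed.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(sample_rate_hz = 125, duration_s = 10,
                         heart_rate_bpm = 75, dicrotic_amplitude = 0.35,
                         noise_sd = 0, artifact_burst_rate = 0,
                         dropout_run_lengths = integer(),
                         flatline_fraction = 0, baseline_amplitude = 0,
                         seed = 1L) {
  stopifnot(is_scalar_number(sample_rate_hz), sample_rate_hz > 0)
  stopifnot(is_scalar_number(duration_s), duration_s > 0)
  n <- duration_s * sample_rate_hz
  if (abs(n - round(n)) > 1e-9) {
    stop("duration_s * sample_rate_hz must be an integer number of samples")
  }
  stopifnot(is_scalar_number(heart_rate_bpm))
  if (heart_rate_bpm < 40 || heart_rate_bpm > 140) {
    stop("heart_rate_bpm must lie in [40, 140]")
  }
  stopifnot(is_scalar_number(dicrotic_amplitude),
            dicrotic_amplitude >= 0, dicrotic_amplitude < 1)
  stopifnot(is_scalar_number(noise_sd), noise_sd >= 0)
  stopifnot(is_scalar_number(artifact_burst_rate), artifact_burst_rate >= 0)
  stopifnot(is.numeric(dropout_run_lengths), all(dropout_run_lengths >= 0))
  stopifnot(is_scalar_number(flatline_fraction),
            flatline_fraction >= 0, flatline_fraction < 1)
  stopifnot(is_scalar_number(baseline_amplitude), baseline_amplitude >= 0)
  structure(
    list(
      sample_rate_hz = sample_rate_hz,
      duration_s = duration_s,
      heart_rate_bpm = heart_rate_bpm,
      dicrotic_amplitude = dicrotic_amplitude,
      noise_sd = noise_sd,
      artifact_burst_rate = artifact_burst_rate,
      dropout_run_lengths = as.integer(dropout_run_lengths),
      flatline_fraction = flatline_fraction,
      baseline_amplitude = baseline_amplitude,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# Pulse morphology: a primary systolic lobe plus a delayed, smaller dicrotic
# lobe, both Gaussian in the beat phase, and a sharp end-diastolic dip at the
# wave foot. The dicrotic constants put the secondary wave on the descending
# limb, where mis-detection as an extra valley/peak occurs in real PPG; the
# dip makes the foot a unique minimum so valley locations are deterministic.
pulse_template <- function(phase, dicrotic_amplitude) {
  exp(-0.5 * ((phase - 0.30) / 0.085)^2) +
    dicrotic_amplitude * exp(-0.5 * ((phase - 0.62) / 0.10)^2) -
    0.15 * (exp(-0.5 * (phase / 0.05)^2) +
              exp(-0.5 * ((phase - 1) / 0.05)^2))
}

#' Generate one synthetic PPG segment with ground-truth fiducials
#'
#' Produces a quasi-periodic PPG-like waveform at the configured heart rate,
#' with optional baseline wander, Gaussian noise, motion-artifact bursts,
#' saturation flat lines and missing-value runs, together with the
#' construction-time systolic peak and valley locations and per-wave
#' clean/corrupted counts.
#'
#' @param config A [synth_config()].
#'
#' @return A list with elements `segment` (a [ppg_segment()]) and `truth`, a
#'   list holding `peak_indices`, `valley_indices` (1-based sample indices,
#'   strictly alternating), `clean_wave_count`, `corrupted_wave_count`, and
#'   `artifact_samples` (indices touched by artifact bursts).
#' @export
#' @examples
#' out <- generate_segment(synth_config(heart_rate_bpm = 60, seed = 7))
#' diff(out$truth$peak_indices)
generate_segment <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sample_rate_hz
  n <- as.integer(round(config$duration_s * fs))
  period <- fs * 60 / config$heart_rate_bpm

  idx0 <- 0:(n - 1)
  phase <- (idx0 %% period) / period
  clean <- pulse_template(phase, config$dicrotic_amplitude)

  # Ground-truth extrema from the noise-free construction: one systolic peak
  # per complete beat, one valley (wave foot) between consecutive peaks.
  n_beats <- floor(n / period)
  extra <- n - n_beats * period
  # a trailing partial beat still contains its systolic peak if the peak
  # phase (0.30) fits in the remainder
  if (extra >= 0.45 * period) n_beats <- n_beats + 1
  peaks <- integer(0)
  for (k in seq_len(n_beats) - 1) {
    lo <- max(1L, as.integer(floor(k * period)) + 1L)
    hi <- min(n, as.integer(ceiling((k + 1) * period)))
    if (hi <= lo) next
    span <- lo:hi
    peaks <- c(peaks, span[which.max(clean[span])])
  }
  peaks <- unique(peaks)
  valleys <- integer(0)
  if (length(peaks) >= 2) {
    for (k in seq_len(length(peaks) - 1)) {
      span <- peaks[k]:peaks[k + 1]
      valleys <- c(valleys, span[which.min(clean[span])])
    }
  }

  with_seed(config$seed, {
    x <- clean
    if (config$baseline_amplitude > 0) {
      x <- x + config$baseline_amplitude *
        sin(2 * pi * 0.25 * idx0 / fs + runif(1, 0, 2 * pi))
    }
    if (config$noise_sd > 0) {
      x <- x + rnorm(n, 0, config$noise_sd)
    }

    artifact_samples <- integer(0)
    n_bursts <- rpois(1, config$artifact_burst_rate * config$duration_s / 60)
    if (n_bursts > 0) {
      for (b in seq_len(n_bursts)) {
        centre <- sample.int(n, 1)
        # a burst: 2-4 isolated spikes of alternating sign within ~0.25 s;
        # amplitudes are far outside the clean-pulse range so the z-score and
        # amplitude-difference outlier criteria trip by construction
        n_spikes <- sample(2:4, 1)
        pos <- unique(pmin(n, pmax(1, centre + sample(-15:15, n_spikes))))
        amp <- runif(length(pos), 12, 18) * rep_len(c(1, -1), length(pos))
        x[pos] <- x[pos] + amp
        artifact_samples <- c(artifact_samples, pos)
      }
      artifact_samples <- sort(unique(artifact_samples))
    }

    if (config$flatline_fraction > 0) {
      run <- as.integer(round(config$flatline_fraction * n))
      if (run >= 1) {
        start <- sample.int(n - run + 1, 1)
        x[start:(start + run - 1)] <- max(clean)  # saturation at range limit
      }
    }

    mask <- rep(FALSE, n)
    runs <- config$dropout_run_lengths[config$dropout_run_lengths > 0]
    for (len in runs) {
      if (len > n) stop("dropout run longer than the segment")
      for (try in 1:100) {
        start <- sample.int(n - len + 1, 1)
        span <- start:(start + len - 1)
        if (!any(mask[span])) {
          # keep runs separated so each stays one maximal gap
          guard <- max(1, start - 1):min(n, start + len)
          if (!any(mask[guard])) {
            mask[span] <- TRUE
            break
          }
        }
      }
    }
    x[mask] <- NA_real_

    segment <- ppg_segment(x, fs, start_time = 0,
                           patient_id = sprintf("synth-%d", config$seed),
                           missing_mask = mask)

    corrupted <- 0L
    clean_ct <- 0L
    if (length(valleys) >= 2) {
      for (k in seq_len(length(valleys) - 1)) {
        span <- valleys[k]:valleys[k + 1]
        bad <- any(span %in% artifact_samples) || any(mask[span])
        if (bad) corrupted <- corrupted + 1L else clean_ct <- clean_ct + 1L
      }
    }

    list(
      segment = segment,
      truth = list(
        peak_indices = peaks,
        valley_indices = valleys,
        clean_wave_count = clean_ct,
        corrupted_wave_count = corrupted,
        artifact_samples = artifact_samples
      )
    )
  })
}

#' Generate a sparse synthetic glucose timeline
#'
#' Emulates the sparse glucose supervision of ICU records, where patients
#' typically have only a few measurements per day, as a tidy table.
#'
#' @param n_measurements Number of measurements (>= 1).
#' @param value_range Length-2 numeric `(low, high)` in mg/dL. For
#'   label-compatible output keep `low >= 70` and `high <= 250`.
#' @param spacing_minutes Mean spacing between consecutive measurements;
#'   actual spacings jitter uniformly within +/-20% so timestamps are
#'   strictly increasing but irregular.
#' @param seed Integer seed.
#' @param patient_id Patient identifier.
#' @param start_time First measurement time in seconds.
#'
#' @return A tibble with columns `patient_id`, `time` (seconds) and
#'   `glucose_mgdl`, timestamps strictly increasing.
#' @export
#' @examples
#' generate_glucose_timeline(3, spacing_minutes = 480, seed = 1)
generate_glucose_timeline <- function(n_measurements,
                                      value_range = c(90, 220),
                                      spacing_minutes = 480, seed = 1L,
                                      patient_id = "synth-patient",
                                      start_time = 0) {
  stopifnot(is_scalar_number(n_measurements), n_measurements >= 1)
  stopifnot(is.numeric(value_range), length(value_range) == 2,
            value_range[1] <= value_range[2])
  stopifnot(is_scalar_number(spacing_minutes), spacing_minutes > 0)
  if (value_range[1] < 70 || value_range[2] > 250) {
    warning("value_range outside [70, 250] mg/dL; labels will be clipped")
  }
  n <- as.integer(n_measurements)
  with_seed(seed, {
    gaps <- spacing_minutes * 60 * runif(n - 1, 0.8, 1.2)
    times <- start_time + c(0, cumsum(gaps))
    mid <- mean(value_range)
    spread <- diff(value_range) / 4
    # bounded random walk: consecutive measurements correlate, as they do in
    # clinical records, so the history features carry real signal
    walk_sd <- diff(value_range) / 6
    values <- numeric(n)
    values[1] <- min(value_range[2], max(value_range[1], rnorm(1, mid, spread)))
    for (j in seq_len(n - 1)) {
      values[j + 1] <- min(value_range[2],
                           max(value_range[1],
                               values[j] + rnorm(1, 0, walk_sd)))
    }
    tibble::tibble(
      patient_id = patient_id,
      time = times,
      glucose_mgdl = values
    )
  })
}
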