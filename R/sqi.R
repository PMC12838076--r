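#' Signal-quality threshold configuration
#'
#' Adaptive per-segment thresholds on per-wave skewness, kurtosis and
#' standard deviation, plus fixed outlier criteria on z-scored samples. The
#' improved constants (default) are `a1 = 1.5`, skewness offsets
#' `0.6 / -0.4`, and a multiplicative standard-deviation threshold
#' `Tsigma = mean(std) * a3` with `a3 = 1`; outliers are samples with
#' `z > 4` or `z < -4` and waves with an amplitude difference above 8.
#' `legacy = TRUE` selects the original constants (`a1 = 3.1`,
#' `a2 = 0.8 / -0.3`, additive `a3 = 3.2`) without the outlier criteria,
#' for comparison.
#'
#' @param a1 Kurtosis offset added to the mean kurtosis.
#' @param a2_upper,a2_lower Skewness offsets around the mean skewness.
#' @param a3 Standard-deviation multiplier (improved, default) or additive
#'   offset (legacy).
#' @param z_hi,z_lo Sample-level z-score outlier bounds.
#' @param amp_diff Within-wave amplitude-difference bound (z-units).
#' @param sigma_multiplicative Use `Tsigma = mean(std) * a3` (`TRUE`,
#'   improved) or `mean(std) + a3` (`FALSE`, legacy).
#' @param std_margin Relative guard band applied when comparing a wave's
#'   std to `Tsigma` (default 0.05). With `a3 = 1` the threshold sits
#'   exactly at the segment mean, so statistically homogeneous segments
#'   would always fail their largest-std wave on numerical or filter-edge
#'   variation alone; the margin is far below the smallest artifact effect
#'   (spikes inflate a wave's std by 50% or more).
#' @param beat_range Admissible wave span in samples at 125 Hz (default
#'   `c(53, 187)`, the physiological beat range); scaled by `fs/125`.
#' @param criteria Character vector of enabled criteria, any of
#'   `"kurtosis"`, `"skew_high"`, `"skew_low"`, `"std"`, `"z_high"`,
#'   `"z_low"`, `"amp_diff"`, `"degenerate"`, `"span"`. Disable individual
#'   criteria for sensitivity analysis.
#' @param legacy If `TRUE`, return the original four-threshold scheme.
#'
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(a1 = 1.5, a2_upper = 0.6, a2_lower = -0.4,
                             a3 = 1, z_hi = 4, z_lo = -4, amp_diff = 8,
                             sigma_multiplicative = TRUE,
                             std_margin = 0.05,
                             beat_range = c(53, 187),
                             criteria = sqi_criteria(), legacy = FALSE) {
  if (legacy) {
    a1 <- 3.1
    a2_upper <- 0.8
    a2_lower <- -0.3
    a3 <- 3.2
    sigma_multiplicative <- FALSE
    criteria <- c("kurtosis", "skew_high", "skew_low", "std")
  }
  stopifnot(a2_lower < a2_upper, z_lo < z_hi)
  stopifnot(all(criteria %in% sqi_criteria()))
  structure(
    list(a1 = a1, a2_upper = a2_upper, a2_lower = a2_lower, a3 = a3,
         z_hi = z_hi, z_lo = z_lo, amp_diff = amp_diff,
         sigma_multiplicative = sigma_multiplicative,
         std_margin = std_margin,
         beat_range = beat_range, criteria = criteria, legacy = legacy),
    class = "threshold_config"
  )
}

#' The nine signal-quality criteria
#'
#' @return Character vector naming all criteria checked by [wave_passes()].
#' @export
sqi_criteria <- function() {
  c("kurtosis", "skew_high", "skew_low", "std", "z_high", "z_low",
    "amp_diff", "degenerate", "span")
}

#' Per-wave statistics
#'
#' Population (1/n) moments of one wave: `skewness = (1/n) sum((x -
#' mean)^3) / std^3`, `kurtosis = (1/n) sum((x - mean)^4) / std^4`, `std =
#' sqrt((1/n) sum((x - mean)^2))`, plus the extreme z values and the
#' within-wave amplitude difference used by the outlier criteria.
#'
#' @param wave Numeric vector of one wave's samples (z-units), length >= 4.
#' @return A one-row tibble: `n`, `skewness`, `kurtosis`, `std`, `max_z`,
#'   `min_z`, `max_amplitude_diff`, `degenerate`. Zero-spread waves are
#'   flagged degenerate with `NA` moment ratios.
#' @export
wave_stats <- function(wave) {
  stopifnot(is.numeric(wave), length(wave) >= 4, !anyNA(wave))
  n <- length(wave)
  m <- mean(wave)
  d <- wave - m
  s <- sqrt(sum(d^2) / n)
  degenerate <- !is.finite(s) || s == 0
  tibble::tibble(
    n = n,
    skewness = if (degenerate) NA_real_ else sum(d^3) / n / s^3,
    kurtosis = if (degenerate) NA_real_ else sum(d^4) / n / s^4,
    std = s,
    max_z = max(wave),
    min_z = min(wave),
    max_amplitude_diff = max(wave) - min(wave),
    degenerate = degenerate
  )
}

#' Statistics for every wave of a segment
#'
#' @param segment A preprocessed (z-scored) [ppg_segment()].
#' @param waves Wave table from [segment_waves()].
#' @return Tibble of [wave_stats()] rows keyed by `wave_id`.
#' @export
segment_wave_stats <- function(segment, waves) {
  stopifnot(inherits(segment, "ppg_segment"))
  if (nrow(waves) == 0) {
    return(dplyr::bind_cols(tibble::tibble(wave_id = integer()),
                            wave_stats(c(0, 1, 0, 1))[0, ]))
  }
  purrr::map_dfr(seq_len(nrow(waves)), function(k) {
    w <- segment$samples[waves$start[k]:waves$end[k]]
    dplyr::bind_cols(tibble::tibble(wave_id = waves$wave_id[k]), wave_stats(w))
  })
}

#' Adaptive thresholds from a segment's wave statistics
#'
#' `Tk = mean(kurtosis) + a1`, `Ts_upper = mean(skewness) + a2_upper`,
#' `Ts_lower = mean(skewness) + a2_lower`, and `Tsigma = mean(std) * a3`
#' (multiplicative, improved scheme) or `mean(std) + a3` (legacy).
#' Degenerate waves are excluded from the means.
#'
#' @param stats Tibble of wave statistics ([segment_wave_stats()]).
#' @param cfg A [threshold_config()].
#' @return A named list: `Tk`, `Ts_upper`, `Ts_lower`, `Tsigma`.
#' @export
sqi_thresholds <- function(stats, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "threshold_config"))
  if (nrow(stats) == 0) stop("cannot compute thresholds from zero waves")
  k_bar <- mean(stats$kurtosis, na.rm = TRUE)
  s_bar <- mean(stats$skewness, na.rm = TRUE)
  sig_bar <- mean(stats$std, na.rm = TRUE)
  list(
    Tk = k_bar + cfg$a1,
    Ts_upper = s_bar + cfg$a2_upper,
    Ts_lower = s_bar + cfg$a2_lower,
    Tsigma = if (cfg$sigma_multiplicative) sig_bar * cfg$a3 else sig_bar + cfg$a3
  )
}

#' Evaluate the quality criteria for one wave
#'
#' A wave fails if any enabled criterion trips: kurtosis above `Tk`,
#' skewness outside `(Ts_lower, Ts_upper]` bounds, standard deviation above
#' `Tsigma`, any sample z-score beyond `+/-4`, a within-wave amplitude
#' difference above 8, a degenerate (zero-spread) wave, or a wave span
#' outside the physiological beat range.
#'
#' @param stats A one-row wave-statistics tibble ([wave_stats()], with `n`).
#' @param thresholds Output of [sqi_thresholds()].
#' @param cfg A [threshold_config()].
#' @param sample_rate_hz Sampling rate used to scale the beat-span range.
#' @return A list: `pass` (logical) and `flags`, a named logical vector over
#'   [sqi_criteria()].
#' @export
wave_passes <- function(stats, thresholds, cfg = threshold_config(),
                        sample_rate_hz = 125) {
  scale <- sample_rate_hz / 125
  span_lo <- cfg$beat_range[1] * scale
  span_hi <- cfg$beat_range[2] * scale
  degenerate <- isTRUE(stats$degenerate)
  flags <- c(
    kurtosis = !degenerate && stats$kurtosis > thresholds$Tk,
    skew_high = !degenerate && stats$skewness > thresholds$Ts_upper,
    skew_low = !degenerate && stats$skewness < thresholds$Ts_lower,
    std = stats$std > thresholds$Tsigma * (1 + cfg$std_margin),
    z_high = stats$max_z > cfg$z_hi,
    z_low = stats$min_z < cfg$z_lo,
    amp_diff = stats$max_amplitude_diff > cfg$amp_diff,
    degenerate = degenerate,
    span = stats$n < span_lo || stats$n > span_hi
  )
  flags[setdiff(sqi_criteria(), cfg$criteria)] <- FALSE
  list(pass = !any(flags), flags = flags)
}

grade_bands <- function(fail_fraction) {
  if (fail_fraction == 0) return("A")
  cut_points <- c(0.2, 0.4, 0.6, 0.8, 1)
  LETTERS[2:6][findInterval(fail_fraction, cut_points, left.open = TRUE) + 1]
}

#' Grade a 10-second segment A-F
#'
#' Detects waves from the corrected fiducials, computes per-wave statistics
#' and adaptive thresholds, evaluates every criterion per wave, and grades
#' the segment by the failing fraction `f`: A when `f = 0`, B when
#' `0 < f <= 0.2`, then C/D/E/F by successive 20% bands.
#'
#' @param segment A preprocessed [ppg_segment()].
#' @param fids A corrected `fiducial_set` for the segment.
#' @param cfg A [threshold_config()].
#' @return A one-row tibble: `grade` (ordered factor A-F), `fail_fraction`,
#'   `n_waves`, and one `fail_<criterion>` count column per criterion.
#' @export
grade_segment <- function(segment, fids, cfg = threshold_config()) {
  waves <- segment_waves(fids, segment)
  if (nrow(waves) == 0) {
    reject_segment("segment has no complete wave and cannot be graded")
  }
  stats <- segment_wave_stats(segment, waves)
  th <- sqi_thresholds(stats, cfg)
  checks <- purrr::map(seq_len(nrow(stats)), function(k) {
    wave_passes(stats[k, ], th, cfg, segment$sample_rate_hz)
  })
  fails <- !purrr::map_lgl(checks, "pass")
  flag_mat <- do.call(rbind, purrr::map(checks, "flags"))
  counts <- colSums(flag_mat)
  f <- mean(fails)
  out <- tibble::tibble(
    grade = factor(grade_bands(f), levels = LETTERS[1:6], ordered = TRUE),
    fail_fraction = f,
    n_waves = nrow(stats)
  )
  for (nm in names(counts)) out[[paste0("fail_", nm)]] <- counts[[nm]]
  out
}

#' Detect fiducials and grade a table of segments
#'
#' Convenience wrapper: for each row of a preprocessed segment table, runs
#' [detect_fiducials()], [correct_fiducials()] and [grade_segment()],
#' dropping ungradable segments.
#'
#' @param segments Tibble with a `segment` list-column of preprocessed
#'   segments.
#' @param cfg A [threshold_config()].
#' @param clamp A [step_clamp()].
#' @return The input tibble with grading columns appended and a `fiducials`
#'   list-column; ungradable rows dropped (count in attribute `n_rejected`).
#' @export
grade_segments <- function(segments, cfg = threshold_config(),
                           clamp = step_clamp()) {
  res <- purrr::map(segments$segment, function(seg) {
    tryCatch({
      fids <- correct_fiducials(detect_fiducials(seg, clamp), seg)
      list(grade = grade_segment(seg, fids, cfg), fids = fids)
    }, ppg_rejection = function(cond) NULL)
  })
  keep <- !purrr::map_lgl(res, is.null)
  out <- segments[keep, , drop = FALSE]
  grades <- dplyr::bind_rows(purrr::map(res[keep], "grade"))
  out <- dplyr::bind_cols(out, grades)
  out$fiducials <- purrr::map(res[keep], "fids")
  attr(out, "n_rejected") <- sum(!keep)
  out
}
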