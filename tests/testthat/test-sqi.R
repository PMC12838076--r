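test_that("wave statistics match closed-form symmetric cases", {
  s <- wave_stats(c(-1, 1, -1, 1))
  expect_equal(s$skewness, 0)
  expect_equal(s$kurtosis, 1)
  expect_equal(s$std, 1)
  expect_equal(wave_stats(c(-1, 0, 1, -1, 0, 1))$skewness, 0)
})

test_that("wave statistics agree with a direct-summation oracle", {
  set.seed(99)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(10:200, 1)
    x <- rnorm(n) * runif(1, 0.5, 3) + runif(1, -2, 2)
    got <- wave_stats(x)
    want <- moment_oracle(x)
    worst <- max(
      worst,
      abs(got$skewness - want$skewness) / max(1e-300, abs(want$skewness)),
      abs(got$kurtosis - want$kurtosis) / abs(want$kurtosis),
      abs(got$std - want$std) / abs(want$std)
    )
  }
  expect_lt(worst, 1e-12)
})

test_that("degenerate waves are flagged", {
  s <- wave_stats(rep(2, 10))
  expect_true(s$degenerate)
  expect_true(is.na(s$skewness))
})

test_that("adaptive thresholds implement the printed arithmetic", {
  stats <- dplyr::bind_rows(
    wave_stats(c(-1, 1, -1, 1)), wave_stats(c(-1, 1, -1, 1)),
    wave_stats(c(-1, 1, -1, 1))
  )
  stats$skewness <- c(0.0, 0.1, 0.2)
  stats$kurtosis <- c(2, 2, 2)
  stats$std <- c(1, 1, 1)
  th <- sqi_thresholds(stats, threshold_config())
  expect_equal(th$Ts_upper, 0.1 + 0.6)
  expect_equal(th$Ts_lower, 0.1 - 0.4)
  expect_equal(th$Tk, 2 + 1.5)
  expect_equal(th$Tsigma, 1 * 1)

  legacy <- sqi_thresholds(stats, threshold_config(legacy = TRUE))
  expect_equal(legacy$Tk, 2 + 3.1)
  expect_equal(legacy$Ts_upper, 0.1 + 0.8)
  expect_equal(legacy$Ts_lower, 0.1 - 0.3)
  expect_equal(legacy$Tsigma, 1 + 3.2)

  expect_error(sqi_thresholds(stats[0, ], threshold_config()), "zero waves")
})

test_that("outlier criteria trip on z-score and amplitude bounds", {
  th <- list(Tk = 10, Ts_upper = 10, Ts_lower = -10, Tsigma = 10)
  cfg <- threshold_config()
  base <- wave_stats(sin(seq(0, 2 * pi, length.out = 100)))

  spiky <- base
  spiky$max_z <- 4.5
  res <- wave_passes(spiky, th, cfg)
  expect_false(res$pass)
  expect_true(res$flags[["z_high"]])

  wide <- base
  wide$max_amplitude_diff <- 8.2
  res <- wave_passes(wide, th, cfg)
  expect_false(res$pass)
  expect_true(res$flags[["amp_diff"]])

  ok <- wave_passes(base, th, cfg)
  expect_true(ok$pass)
  expect_false(any(ok$flags))
})

test_that("waves at the segment means pass all adaptive criteria", {
  stats <- dplyr::bind_rows(lapply(1:5, function(i) {
    wave_stats(sin(seq(0, 2 * pi, length.out = 100)) + i * 1e-15)
  }))
  th <- sqi_thresholds(stats, threshold_config())
  for (k in 1:5) {
    expect_true(wave_passes(stats[k, ], th, threshold_config())$pass)
  }
})

test_that("individual criteria can be disabled by configuration", {
  th <- list(Tk = 10, Ts_upper = 10, Ts_lower = -10, Tsigma = 10)
  spiky <- wave_stats(sin(seq(0, 2 * pi, length.out = 100)))
  spiky$max_z <- 6
  cfg_off <- threshold_config(criteria = setdiff(sqi_criteria(), "z_high"))
  expect_true(wave_passes(spiky, th, cfg_off)$pass)
})

test_that("beat-span criterion flags non-physiological wave lengths", {
  th <- list(Tk = 10, Ts_upper = 10, Ts_lower = -10, Tsigma = 10)
  short <- wave_stats(sin(seq(0, 2 * pi, length.out = 40)))
  expect_true(wave_passes(short, th, threshold_config())$flags[["span"]])
  long <- wave_stats(sin(seq(0, 2 * pi, length.out = 200)))
  expect_true(wave_passes(long, th, threshold_config())$flags[["span"]])
})

test_that("grades follow the 20% failing-fraction bands", {
  expect_equal(ppglucose:::grade_bands(0), "A")
  expect_equal(ppglucose:::grade_bands(0.10), "B")
  expect_equal(ppglucose:::grade_bands(0.20), "B")
  expect_equal(ppglucose:::grade_bands(0.30), "C")
  expect_equal(ppglucose:::grade_bands(0.50), "D")
  expect_equal(ppglucose:::grade_bands(0.70), "E")
  expect_equal(ppglucose:::grade_bands(0.95), "F")
})

test_that("artifact-free synthetic segments grade A end to end", {
  for (hr in c(60, 75, 100)) {
    for (seed in 1:3) {
      cg <- clean_graded(heart_rate_bpm = hr, seed = seed)
      expect_equal(as.character(cg$grade$grade), "A")
      expect_equal(cg$grade$fail_fraction, 0)
    }
  }
})

test_that("spikes in one of ~11 waves produce grade B with flagged criteria", {
  for (seed in 1:3) {
    res <- generate_segment(synth_config(heart_rate_bpm = 75, seed = seed))
    raw <- inject_spike_pair(res$segment, res$truth, wave = 4)
    seg <- preprocess_segment(raw)
    fids <- correct_fiducials(detect_fiducials(seg), seg)
    g <- grade_segment(seg, fids)
    expect_equal(as.character(g$grade), "B")
    expect_gt(g$fail_z_high, 0)
    expect_gt(g$fail_amp_diff, 0)
  }
})

test_that("failing fraction degrades monotonically with artifact rate", {
  rates <- c(0, 8, 25, 60)
  mean_fail <- vapply(rates, function(rate) {
    mean(vapply(1:6, function(seed) {
      res <- generate_segment(synth_config(heart_rate_bpm = 75, seed = seed,
                                           artifact_burst_rate = rate))
      seg <- preprocess_segment(res$segment)
      fids <- correct_fiducials(detect_fiducials(seg), seg)
      grade_segment(seg, fids)$fail_fraction
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_fail) >= 0))
  expect_equal(mean_fail[1], 0)
  expect_gt(mean_fail[4], mean_fail[1])
})

test_that("adding a failing wave never improves the grade", {
  res <- generate_segment(synth_config(heart_rate_bpm = 75, seed = 11))
  raw <- res$segment
  grades_seen <- character(0)
  fracs <- numeric(0)
  for (n_spiked in 0:3) {
    seg_raw <- raw
    waves <- c(2, 5, 8)
    for (k in seq_len(n_spiked)) {
      seg_raw <- inject_spike_pair(seg_raw, res$truth, wave = waves[k])
    }
    seg <- preprocess_segment(seg_raw)
    fids <- correct_fiducials(detect_fiducials(seg), seg)
    g <- grade_segment(seg, fids)
    grades_seen <- c(grades_seen, as.character(g$grade))
    fracs <- c(fracs, g$fail_fraction)
  }
  expect_true(all(diff(fracs) >= 0))
  expect_true(all(grades_seen == sort(grades_seen)))
})

test_that("zero complete waves makes a segment ungradable", {
  seg <- ppg_segment(sin((0:1249) / 300), 125)
  fids <- fiducial_set(peaks = 600, valleys = 100)
  expect_error(grade_segment(seg, fids), class = "ppg_rejection")
})
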