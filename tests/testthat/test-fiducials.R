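test_that("moving steps are clamped to the printed physiological bounds", {
  expect_equal(clamp_step(50, "peak"), 90)
  expect_equal(clamp_step(120, "peak"), 120)
  expect_equal(clamp_step(200, "peak"), 150)
  expect_equal(clamp_step(30, "valley"), 60)
  expect_equal(clamp_step(200, "valley"), 150)
  # clamps scale with the sampling rate
  expect_equal(clamp_step(50, "peak", sample_rate_hz = 250), 180)
})

test_that("clean 75 bpm segments give inter-peak intervals of 100 +/- 2", {
  cg <- clean_graded(heart_rate_bpm = 75, seed = 7)
  gaps <- diff(cg$fiducials$peaks)
  expect_true(all(abs(gaps - 100) <= 2))
  # oracle: per-period argmax on the known-truth synthetic signal
  m <- match_metrics(cg$fiducials$peaks, cg$truth$peak_indices)
  expect_gte(m["recall"], 0.95)
  expect_gte(m["precision"], 0.95)
})

test_that("peak recall and precision reach 0.95 across the heart-rate range", {
  for (hr in c(40, 60, 100, 140)) {
    rec <- numeric(0)
    prec <- numeric(0)
    for (seed in 1:5) {
      cg <- clean_graded(heart_rate_bpm = hr, seed = seed)
      m <- match_metrics(cg$fiducials$peaks, cg$truth$peak_indices)
      rec <- c(rec, m["recall"])
      prec <- c(prec, m["precision"])
    }
    expect_gte(mean(rec), 0.95)
    expect_gte(mean(prec), 0.95)
  }
})

test_that("correction enforces the higher-peak rule", {
  # two peaks with no valley between and none findable: monotone bridge
  x <- c(seq(0, 1, length.out = 100), seq(1, 1.2, length.out = 41),
         seq(1.2, 0, length.out = 100))
  seg <- ppg_segment(x, 125)
  fids <- fiducial_set(peaks = c(100, 140), valleys = integer())
  out <- correct_fiducials(fids, seg)
  expect_equal(out$peaks, 140)  # amplitude(140) > amplitude(100)
})

test_that("correction deletes the left (dicrotic) valley", {
  # two valleys flanking a dicrotic notch with no missed peak between
  x <- rep(0, 300)
  x[100] <- -0.5             # true wave foot
  x[115] <- 0.2              # small dicrotic bump (not a missed systole)
  x[130] <- -0.3             # dicrotic-wave valley
  x[c(60, 200)] <- 1.5       # surrounding systolic peaks
  xs <- stats::spline(seq_along(x)[x != 0], x[x != 0], xout = 1:300)$y
  seg <- ppg_segment(xs, 125)
  fids <- fiducial_set(peaks = c(60, 200), valleys = c(100, 130))
  out <- correct_fiducials(fids, seg)
  expect_false(100 %in% out$valleys)
  expect_true(130 %in% out$valleys)
  expect_alternating(out)
})

test_that("correction is idempotent and a fixed point on alternating input", {
  for (seed in 1:4) {
    cg <- clean_graded(heart_rate_bpm = 66, seed = seed)
    once <- cg$fiducials
    twice <- correct_fiducials(once, cg$segment)
    expect_identical(once, twice)
    expect_alternating(once)
  }
})

test_that("every corrected wave contains exactly one peak", {
  for (hr in c(60, 100, 140)) {
    cg <- clean_graded(heart_rate_bpm = hr, seed = 3)
    waves <- segment_waves(cg$fiducials, cg$segment)
    expect_true(all(!is.na(waves$peak)))
    for (k in seq_len(nrow(waves))) {
      inside <- cg$fiducials$peaks[cg$fiducials$peaks > waves$start[k] &
                                     cg$fiducials$peaks < waves$end[k]]
      expect_length(inside, 1)
    }
  }
})

test_that("wave segmentation counts valley-to-valley spans", {
  fids <- fiducial_set(peaks = seq(55, by = 100, length.out = 11),
                       valleys = seq(5, by = 100, length.out = 11))
  seg <- ppg_segment(rep(0, 1250), 125)
  expect_equal(nrow(segment_waves(fids, seg)), 10)
  one <- fiducial_set(peaks = 50, valleys = 5)
  expect_equal(nrow(segment_waves(one, seg)), 0)

  cg <- clean_graded(heart_rate_bpm = 60, seed = 5)
  n_waves <- nrow(segment_waves(cg$fiducials, cg$segment))
  expect_true(n_waves %in% c(8, 9, 10))
})

test_that("a segment shorter than one clamped step yields an empty set", {
  seg <- ppg_segment(sin((0:49) / 5), 125)
  fids <- detect_fiducials(seg)
  expect_length(fids$peaks, 0)
  expect_length(fids$valleys, 0)
})
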