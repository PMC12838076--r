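make_seg <- function(x, fs = 125) ppg_segment(x, fs)

test_that("gaps up to the 30-sample threshold are interpolated, longer gaps reject", {
  base <- sin(2 * pi * 1.2 * (0:1249) / 125)

  x30 <- base
  x30[500:529] <- NA
  rep30 <- repair_missing(make_seg(x30))
  expect_false(anyNA(rep30$samples))
  expect_false(any(rep30$missing_mask))
  # linear interpolation between the flanking valid samples
  expect_equal(rep30$samples[500:529],
               approx(c(499, 530), base[c(499, 530)], xout = 500:529)$y)

  x31 <- base
  x31[500:530] <- NA
  expect_error(repair_missing(make_seg(x31)), class = "ppg_rejection")
})

test_that("repair never alters valid samples and is identity without gaps", {
  base <- cos(2 * pi * (0:1249) / 100)
  seg <- make_seg(base)
  expect_identical(repair_missing(seg)$samples, base)
  gap <- base
  gap[200:210] <- NA
  rep <- repair_missing(make_seg(gap))
  expect_identical(rep$samples[-(200:210)], base[-(200:210)])
})

test_that("boundary gaps cannot be interpolated and reject the segment", {
  x <- sin((0:1249) / 20)
  x[1:5] <- NA
  expect_error(repair_missing(make_seg(x)), class = "ppg_rejection")
  y <- sin((0:1249) / 20)
  y[1246:1250] <- NA
  expect_error(repair_missing(make_seg(y)), class = "ppg_rejection")
})

test_that("saturation flat lines are preserved, not treated as gaps", {
  out <- generate_segment(synth_config(seed = 3, flatline_fraction = 0.05))
  seg <- repair_missing(out$segment)
  r <- rle(seg$samples)
  expect_gte(max(r$lengths), 0.05 * 1250 - 1)
})

test_that("bandpass preserves the pulse band and rejects drift and DC", {
  t <- (0:1249) / 125
  rms <- function(x) sqrt(mean(x^2))

  in5 <- sin(2 * pi * 5 * t)
  out5 <- bandpass(make_seg(in5))$samples
  expect_lt(abs(rms(out5) / rms(in5) - 1), 0.05)

  in01 <- sin(2 * pi * 0.1 * t)
  out01 <- bandpass(make_seg(in01))$samples
  expect_lt(rms(out01) / rms(in01), 0.10)

  outdc <- bandpass(make_seg(rep(3, 1250)))$samples
  expect_lt(max(abs(outdc)), 1e-6 * 3)
})

test_that("bandpass is linear", {
  set.seed(42)
  a <- rnorm(1250)
  b <- rnorm(1250)
  fa <- bandpass(make_seg(a))$samples
  fb <- bandpass(make_seg(b))$samples
  fab <- bandpass(make_seg(2 * a + 3 * b))$samples
  expect_lt(max(abs(fab - (2 * fa + 3 * fb))), 1e-6 * max(abs(fab)))
})

test_that("bandpass validates configuration and inputs", {
  expect_error(filter_spec(low_cut_hz = 11, high_cut_hz = 10))
  seg <- make_seg(sin((0:1249) / 10))
  expect_error(bandpass(seg, filter_spec(high_cut_hz = 70)), "Nyquist")
  gap <- sin((0:1249) / 10)
  gap[5] <- NA
  expect_error(bandpass(make_seg(gap)), "missing")
})

test_that("zscore standardizes, is idempotent, and rejects constants", {
  set.seed(1)
  seg <- make_seg(rnorm(1250, 5, 3))
  z <- zscore(seg)
  expect_equal(mean(z$samples), 0, tolerance = 1e-12)
  expect_equal(sd(z$samples), 1, tolerance = 1e-12)
  z2 <- zscore(z)
  expect_equal(z2$samples, z$samples, tolerance = 1e-12)
  expect_error(zscore(make_seg(rep(2, 1250))), class = "ppg_rejection")
})

test_that("table-level preprocessing drops rejected segments with a count", {
  good <- generate_segment(synth_config(seed = 1))$segment
  bad <- generate_segment(synth_config(seed = 2,
                                       dropout_run_lengths = 80L))$segment
  tbl <- tibble::tibble(segment = list(good, bad))
  out <- preprocess_segments(tbl)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_rejected"), 1)
  expect_false(anyNA(out$segment[[1]]$samples))
})
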