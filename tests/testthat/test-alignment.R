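test_that("WFDB records round-trip through write and read", {
  dir <- withr::local_tempdir()
  out <- generate_segment(synth_config(seed = 4, dropout_run_lengths = 25L))
  write_waveform(out$segment, dir, "rec1")
  back <- read_waveform(file.path(dir, "rec1"))

  expect_equal(back$sample_rate_hz, 125)
  expect_identical(back$missing_mask, out$segment$missing_mask)
  # format-16 storage quantizes at 1/gain; a second round trip is exact
  expect_lt(max(abs(back$samples - out$segment$samples), na.rm = TRUE),
            1 / (2 * 200) + 1e-12)
  write_waveform(back, dir, "rec2")
  again <- read_waveform(file.path(dir, "rec2"))
  expect_identical(again$samples, back$samples)
})

test_that("header metadata is parsed and errors are explicit", {
  dir <- withr::local_tempdir()
  seg <- generate_segment(synth_config(seed = 1))$segment
  seg$start_time <- 3725.5
  write_waveform(seg, dir, "recA", description = "PLETH")
  back <- read_waveform(file.path(dir, "recA.hea"))
  expect_equal(back$sample_rate_hz, 125)
  expect_equal(back$start_time, 3725.5)
  expect_equal(back$patient_id, seg$patient_id)

  # non-PPG channel only -> error naming the channels
  write_waveform(seg, dir, "recB", description = "ECG II")
  expect_error(read_waveform(file.path(dir, "recB")), "ECG II")

  writeLines("garbage", file.path(dir, "recC.hea"))
  expect_error(read_waveform(file.path(dir, "recC")), "corrupt")
  expect_error(read_waveform(file.path(dir, "missing")), "not found")
})

make_record <- function(duration_s, start_time = 0, patient_id = "p1",
                        seed = 1) {
  rec <- generate_segment(synth_config(duration_s = duration_s,
                                       heart_rate_bpm = 70,
                                       seed = seed))$segment
  rec$start_time <- start_time
  rec$patient_id <- patient_id
  rec
}

glu <- function(time, patient_id = "p1", value = 120) {
  tibble::tibble(patient_id = patient_id, time = time, glucose_mgdl = value)
}

test_that("a fully covered window yields 108 ten-second segments", {
  rec <- make_record(1200)
  w <- extract_windows(rec, glu(600))
  expect_equal(nrow(w), 108)
  expect_true(all(vapply(w$segment, length, 1L) == 1250))
  # every segment inside [t - 9 min, t + 9 min]
  expect_true(all(w$segment_start >= 600 - 540))
  expect_true(all(w$segment_start + 10 <= 600 + 540 + 1e-9))
})

test_that("truncated coverage uses the longest continuous run", {
  # record ends 95 s after the measurement; starts long before
  rec <- make_record(1300)
  w <- extract_windows(rec, glu(1205))
  expect_equal(nrow(w), floor((540 + 95) / 10))

  # record entirely outside the window -> empty with a warning
  rec2 <- make_record(60)
  expect_warning(w2 <- extract_windows(rec2, glu(5000)), "no overlap")
  expect_equal(nrow(w2), 0)
})

test_that("segments go to the nearest measurement when windows overlap", {
  rec <- make_record(1800)
  meas <- glu(c(700, 1000))
  w <- extract_windows(rec, meas)
  centre <- w$segment_start + 5
  nearest <- ifelse(abs(centre - 700) <= abs(centre - 1000), 700, 1000)
  expect_equal(w$measurement_time, nearest)
  # window overlap must not duplicate grid positions per measurement
  expect_false(any(duplicated(w[, c("measurement_time", "segment_start")])))
})

test_that("segment counts never exceed the window capacity", {
  rec <- make_record(4000, seed = 2)
  for (t_meas in c(300, 2000, 3900)) {
    w <- extract_windows(rec, glu(t_meas))
    expect_lte(nrow(w), 2 * 9 * 60 / 10)
  }
})

test_that("windowing is idempotent on re-extraction", {
  rec <- make_record(1200)
  w1 <- extract_windows(rec, glu(600))
  w2 <- extract_windows(rec, glu(600))
  expect_identical(
    purrr::map(w1$segment, "samples"),
    purrr::map(w2$segment, "samples")
  )
})

test_that("patient mismatch and malformed glucose tables error", {
  rec <- make_record(1200)
  expect_error(extract_windows(rec, glu(600, patient_id = "other")),
               "patient_id")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(patient_id = "p1", time = 0, glucose_mgdl = 100),
            path, row.names = FALSE)
  tbl <- read_glucose_csv(path)
  expect_equal(tbl$glucose_mgdl, 100)
  write.csv(data.frame(patient = "p1"), path, row.names = FALSE)
  expect_error(read_glucose_csv(path), "columns")
})
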