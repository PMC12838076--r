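# Shared fixtures: everything is generated in code at test time.

# Generate a clean segment, preprocess it, detect + correct fiducials and
# grade it in one go.
clean_graded <- function(heart_rate_bpm = 75, seed = 1, ...) {
  res <- generate_segment(synth_config(heart_rate_bpm = heart_rate_bpm,
                                       seed = seed, ...))
  seg <- preprocess_segment(res$segment)
  fids <- correct_fiducials(detect_fiducials(seg), seg)
  list(segment = seg, fiducials = fids, truth = res$truth,
       grade = grade_segment(seg, fids))
}

# Inject a paired +/- spike (motion-artifact model) inside one wave of a
# raw (pre-preprocessing) segment, on the descending limb away from the
# fiducials, so exactly that wave is corrupted.
inject_spike_pair <- function(segment, truth, wave = 4, amplitude = 15) {
  p <- truth$peak_indices
  period <- round(median(diff(p)))
  at <- p[wave] + round(0.3 * period)
  at2 <- at + max(4, round(0.1 * period))
  segment$samples[at] <- segment$samples[at] + amplitude
  segment$samples[at2] <- segment$samples[at2] - amplitude
  segment
}

# Recall/precision of detected indices vs truth with a sample tolerance.
match_metrics <- function(detected, truth, tol = 3) {
  if (length(truth) == 0 || length(detected) == 0) {
    return(c(recall = 0, precision = 0))
  }
  hits <- vapply(truth, function(t) any(abs(detected - t) <= tol), TRUE)
  fp <- vapply(detected, function(d) !any(abs(truth - d) <= tol), TRUE)
  c(recall = mean(hits), precision = 1 - mean(fp))
}

# Direct-summation oracle for the per-wave moment statistics, written
# independently of wave_stats(): explicit compensated (Kahan) loops over
# the printed formulas.
kahan_sum <- function(values) {
  s <- 0
  c <- 0
  for (v in values) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}
moment_oracle <- function(x) {
  n <- length(x)
  xbar <- kahan_sum(x) / n
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- x[i] - xbar
  s2 <- kahan_sum(d^2)
  std <- sqrt(s2 / n)
  s3 <- kahan_sum(d^3)
  s4 <- kahan_sum(d^4)
  list(skewness = s3 / n / std^3, kurtosis = s4 / n / std^4, std = std)
}

expect_alternating <- function(fids) {
  merged <- rbind(
    data.frame(i = fids$peaks, t = "P"),
    data.frame(i = fids$valleys, t = "V")
  )
  merged <- merged[order(merged$i), ]
  expect_true(all(merged$t[-1] != merged$t[-nrow(merged)]),
              label = "peaks and valleys strictly alternate")
}
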