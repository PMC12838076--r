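#' Step-size clamps for the fiducial march
#'
#' Physiological limits on the peak-to-peak and valley-to-valley moving step,
#' in samples at 125 Hz: a proposed peak step below 90 is forced to 90 and
#' above 150 to 150; a proposed valley step below 60 is forced to 60 and
#' above 150 to 150. Clamps scale with `sample_rate / 125` for other rates.
#'
#' @param peak_min,peak_max Peak-step bounds (samples at 125 Hz).
#' @param valley_min,valley_max Valley-step bounds (samples at 125 Hz).
#' @param search_half_width Half-width of the extremum search window around
#'   the stepped landing point (default 30 samples, about the span of a
#'   quarter wave).
#'
#' @return A `step_clamp` list.
#' @export
step_clamp <- function(peak_min = 90, peak_max = 150, valley_min = 60,
                       valley_max = 150, search_half_width = 30) {
  stopifnot(peak_min <= peak_max, valley_min <= valley_max,
            search_half_width >= 1)
  structure(
    list(peak_min = peak_min, peak_max = peak_max, valley_min = valley_min,
         valley_max = valley_max, search_half_width = search_half_width),
    class = "step_clamp"
  )
}

#' Clamp a proposed moving step
#'
#' @param step Proposed step in samples.
#' @param type `"peak"` or `"valley"`.
#' @param clamp A [step_clamp()].
#' @param sample_rate_hz Sampling rate; bounds scale by `sample_rate/125`.
#' @return The clamped step.
#' @export
clamp_step <- function(step, type = c("peak", "valley"), clamp = step_clamp(),
                       sample_rate_hz = 125) {
  type <- match.arg(type)
  scale <- sample_rate_hz / 125
  bounds <- if (type == "peak") {
    c(clamp$peak_min, clamp$peak_max)
  } else {
    c(clamp$valley_min, clamp$valley_max)
  }
  pmin(pmax(step, round(bounds[1] * scale)), round(bounds[2] * scale))
}

# Hill-climb from index j to the nearest local extremum of sgn * x.
climb_to_extremum <- function(x, j, sgn, max_moves = length(x)) {
  n <- length(x)
  g <- sgn * x
  for (k in seq_len(max_moves)) {
    left <- if (j > 1) g[j - 1] else -Inf
    right <- if (j < n) g[j + 1] else -Inf
    if (left <= g[j] && right <= g[j]) break
    j <- if (right > left) j + 1L else j - 1L
  }
  j
}

is_local_extremum <- function(x, j, sgn) {
  n <- length(x)
  if (j <= 1 || j >= n) return(FALSE)
  g <- sgn * x
  # plateau-tolerant: compare against nearest differing neighbours
  l <- j - 1
  while (l > 1 && g[l] == g[j]) l <- l - 1
  r <- j + 1
  while (r < n && g[r] == g[j]) r <- r + 1
  g[l] < g[j] && g[r] < g[j]
}

# March one extremum type through the segment: advance from the last
# accepted extremum by the clamped step, take the window extremum, verify
# that neighbouring values are smaller (peaks) or larger (valleys), and
# hill-climb to a true local extremum when the window lands on a slope.
march_extrema <- function(x, type, clamp, fs) {
  n <- length(x)
  sgn <- if (type == "peak") 1 else -1
  scale <- fs / 125
  w <- max(1L, as.integer(round(clamp$search_half_width * scale)))
  cmin <- clamp_step(0, type, clamp, fs)
  cmax <- clamp_step(.Machine$integer.max, type, clamp, fs)
  if (n < cmin) return(integer(0))

  # initialization: global extremum in the first clamped-step span
  first_span <- 1:min(cmax, n)
  j <- first_span[which.max(sgn * x[first_span])]
  j <- climb_to_extremum(x, j, sgn)
  accepted <- j
  cursor <- j
  default_step <- round(125 * scale)

  repeat {
    k <- length(accepted)
    proposed <- if (k >= 2) accepted[k] - accepted[k - 1] else default_step
    step <- clamp_step(proposed, type, clamp, fs)
    centre <- cursor + step
    if (centre - w > n) break
    lo <- max(accepted[k] + 1L, centre - w)
    hi <- min(n, centre + w)
    if (lo > hi) break
    span <- lo:hi
    j <- span[which.max(sgn * x[span])]
    if (!is_local_extremum(x, j, sgn)) {
      j <- climb_to_extremum(x, j, sgn)
    }
    if (j > accepted[k] && is_local_extremum(x, j, sgn)) {
      accepted <- c(accepted, j)
      cursor <- j
    } else {
      cursor <- centre  # nothing acceptable here; keep marching
    }
    if (cursor > n) break
  }
  accepted
}

#' Detect systolic peaks and valleys (uncorrected)
#'
#' Iterative march with clamped moving steps and window search: from the
#' last accepted peak (valley) the detector advances by the clamped step,
#' takes the local extremum in a search window, and verifies that the values
#' before and after a peak are smaller (and vice versa for valleys),
#' nudging to a neighbouring extremum when the check fails. The returned set
#' is uncorrected; run [correct_fiducials()] to enforce alternation.
#'
#' @param segment A preprocessed [ppg_segment()].
#' @param clamp A [step_clamp()].
#'
#' @return A `fiducial_set`: list with sorted integer `peaks` and `valleys`.
#' @export
detect_fiducials <- function(segment, clamp = step_clamp()) {
  stopifnot(inherits(segment, "ppg_segment"))
  x <- segment$samples
  if (anyNA(x)) stop("detect_fiducials requires a repaired segment")
  fs <- segment$sample_rate_hz
  fiducial_set(
    peaks = march_extrema(x, "peak", clamp, fs),
    valleys = march_extrema(x, "valley", clamp, fs)
  )
}

#' Create a fiducial set
#'
#' @param peaks,valleys Sorted integer sample indices.
#' @return A `fiducial_set` list.
#' @export
fiducial_set <- function(peaks = integer(), valleys = integer()) {
  structure(
    list(peaks = as.integer(sort(peaks)), valleys = as.integer(sort(valleys))),
    class = "fiducial_set"
  )
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> %d peaks, %d valleys\n",
              length(x$peaks), length(x$valleys)))
  invisible(x)
}

merge_fiducials <- function(fids) {
  idx <- c(fids$peaks, fids$valleys)
  type <- c(rep("P", length(fids$peaks)), rep("V", length(fids$valleys)))
  o <- order(idx, type)  # deterministic on ties
  list(idx = idx[o], type = type[o])
}

# Interior candidate extrema between two indices, closest-to-midpoint first.
interior_candidates <- function(x, a, b, sgn) {
  if (b - a < 2) return(integer(0))
  span <- (a + 1):(b - 1)
  cand <- span[vapply(span, function(j) is_local_extremum(x, j, sgn), TRUE)]
  if (length(cand) == 0) return(integer(0))
  cand[order(abs(cand - (a + b) / 2))]
}

# One alternation pass: resolve same-type neighbours in the merged sequence.
# A "missed" extremum must have near-systolic height (peaks) or near-foot
# depth (valleys) when enough context exists to estimate them, so dicrotic
# bumps and notches are not resurrected as missed detections.
alternation_pass <- function(idx, type, x) {
  changed <- FALSE
  peaks <- idx[type == "P"]
  valleys <- idx[type == "V"]
  have_ctx <- length(peaks) >= 2 && length(valleys) >= 2
  if (have_ctx) {
    med_p <- median(x[peaks])
    med_v <- median(x[valleys])
    amp <- med_p - med_v
    peak_floor <- med_p - 0.3 * amp
    valley_ceil <- med_v + 0.3 * amp
  }
  i <- 1
  while (i < length(idx)) {
    if (type[i] != type[i + 1]) {
      i <- i + 1
      next
    }
    a <- idx[i]
    b <- idx[i + 1]
    if (type[i] == "P") {
      # two consecutive peaks: search for a missed valley between them
      cand <- interior_candidates(x, a, b, -1)
      cand <- cand[x[cand] < pmin(x[a], x[b])]
      if (have_ctx) cand <- cand[x[cand] <= valley_ceil]
      if (length(cand) > 0) {
        idx <- append(idx, cand[1], after = i)
        type <- append(type, "V", after = i)
      } else {
        # no missed valley: the higher peak is retained (tie -> earlier)
        drop <- if (x[b] > x[a]) i else i + 1
        idx <- idx[-drop]
        type <- type[-drop]
      }
    } else {
      # two consecutive valleys: search for a missed peak between them
      cand <- interior_candidates(x, a, b, 1)
      cand <- cand[x[cand] > pmax(x[a], x[b])]
      if (have_ctx) cand <- cand[x[cand] >= peak_floor]
      if (length(cand) > 0) {
        idx <- append(idx, cand[1], after = i)
        type <- append(type, "P", after = i)
      } else {
        # the left valley may be a dicrotic-wave valley: delete the left one
        idx <- idx[-i]
        type <- type[-i]
      }
    }
    changed <- TRUE
  }
  list(idx = idx, type = type, changed = changed)
}

# Missed-beat recovery: between consecutive accepted peaks, a skipped
# systolic peak shows up as an interior local maximum of near-systolic
# height; dicrotic bumps sit much lower and are not recovered. This
# implements the "was an extremum missed due to detection error" inspection
# for spans the clamped march stepped over.
recover_missed_peaks <- function(idx, type, x, fs = 125) {
  changed <- FALSE
  min_sep <- round(40 * fs / 125)  # below the shortest physiological beat
  repeat {
    peaks <- idx[type == "P"]
    valleys <- idx[type == "V"]
    if (length(peaks) < 3 || length(valleys) < 2) break
    amp <- median(x[peaks]) - median(x[valleys])
    floor_height <- median(x[peaks]) - 0.3 * amp
    # interior spans between consecutive peaks, plus the leading and
    # trailing spans where the march's initialization or termination can
    # have skipped a beat; for edge spans only the separation from the
    # real neighbouring peak is constrained
    n_peak <- length(peaks)
    spans <- data.frame(
      a = c(peaks[-n_peak], max(1L, peaks[1] - 3L * min_sep), peaks[n_peak]),
      b = c(peaks[-1], peaks[1], min(length(x), peaks[n_peak] + 3L * min_sep)),
      kind = c(rep("interior", n_peak - 1), "lead", "trail")
    )
    inserted <- FALSE
    for (k in seq_len(nrow(spans))) {
      a <- spans$a[k]
      b <- spans$b[k]
      kind <- spans$kind[k]
      cand <- interior_candidates(x, a, b, 1)
      cand <- setdiff(cand, idx)
      cand <- cand[x[cand] >= floor_height]
      cand <- switch(kind,
        interior = cand[cand - a >= min_sep & b - cand >= min_sep],
        lead = cand[b - cand >= min_sep],
        trail = cand[cand - a >= min_sep]
      )
      if (length(cand) == 0) next
      new_peak <- cand[1]
      add_idx <- new_peak
      add_type <- "P"
      # restore a flanking valley towards each real neighbouring peak that
      # lacks one, so alternation survives the insertion
      if (kind != "lead" &&
            !any(type == "V" & idx > a & idx < new_peak) &&
            new_peak - a >= 2) {
        sp <- (a + 1):(new_peak - 1)
        vb <- sp[which.min(x[sp])]
        if (!(vb %in% idx)) {
          add_idx <- c(vb, add_idx)
          add_type <- c("V", add_type)
        }
      }
      if (kind != "trail" &&
            !any(type == "V" & idx > new_peak & idx < b) &&
            b - new_peak >= 2) {
        sp <- (new_peak + 1):(b - 1)
        vb <- sp[which.min(x[sp])]
        if (!(vb %in% idx)) {
          add_idx <- c(add_idx, vb)
          add_type <- c(add_type, "V")
        }
      }
      idx <- c(idx, add_idx)
      type <- c(type, add_type)
      o <- order(idx)
      idx <- idx[o]
      type <- type[o]
      inserted <- TRUE
      changed <- TRUE
      break
    }
    if (!inserted) break
  }
  list(idx = idx, type = type, changed = changed)
}

#' Correct a fiducial set to strict peak/valley alternation
#'
#' Normal continuous waveforms exhibit alternating peaks and valleys. Two
#' consecutive peaks with no intervening valley trigger a re-search for a
#' missed valley; if none exists, the higher peak is retained. Two
#' consecutive valleys with no missed peak between them indicate that the
#' left valley is a dicrotic-wave valley, so the left valley is deleted and
#' the right one retained. Spans where the clamped march skipped a full beat
#' are re-inspected and near-systolic-height missed peaks (with their
#' flanking valleys) are restored. The output strictly alternates and the
#' operation is idempotent.
#'
#' @param fids A `fiducial_set`.
#' @param segment The [ppg_segment()] the indices refer to.
#' @return A corrected `fiducial_set`.
#' @export
correct_fiducials <- function(fids, segment) {
  stopifnot(inherits(fids, "fiducial_set"), inherits(segment, "ppg_segment"))
  x <- segment$samples
  m <- merge_fiducials(fids)
  idx <- m$idx
  type <- m$type
  if (length(idx) == 0) return(fiducial_set())

  for (iter in 1:20) {
    res <- alternation_pass(idx, type, x)
    idx <- res$idx
    type <- res$type
    rec <- recover_missed_peaks(idx, type, x, segment$sample_rate_hz)
    idx <- rec$idx
    type <- rec$type
    if (!res$changed && !rec$changed) break
  }
  # final safety: enforce alternation strictly
  res <- alternation_pass(idx, type, x)
  fiducial_set(peaks = res$idx[res$type == "P"],
               valleys = res$idx[res$type == "V"])
}

#' Segment a waveform into single waves
#'
#' One wave per consecutive valley-to-valley span of the corrected fiducial
#' set; partial leading and trailing spans are excluded.
#'
#' @param fids A corrected `fiducial_set`.
#' @param segment The [ppg_segment()] the indices refer to.
#' @return A tibble with one row per wave: `wave_id`, `start`, `end`
#'   (inclusive sample indices) and `peak` (the systolic peak inside the
#'   wave, `NA` if none).
#' @export
segment_waves <- function(fids, segment) {
  stopifnot(inherits(fids, "fiducial_set"))
  v <- fids$valleys
  if (length(v) < 2) {
    return(tibble::tibble(wave_id = integer(), start = integer(),
                          end = integer(), peak = integer()))
  }
  starts <- v[-length(v)]
  ends <- v[-1]
  peak <- vapply(seq_along(starts), function(k) {
    p <- fids$peaks[fids$peaks > starts[k] & fids$peaks < ends[k]]
    if (length(p) == 0) NA_integer_ else p[1]
  }, integer(1))
  tibble::tibble(
    wave_id = seq_along(starts),
    start = as.integer(starts),
    end = as.integer(ends),
    peak = peak
  )
}
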