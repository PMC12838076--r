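N_GLUCOSE_CLASSES <- 180L
GLUCOSE_MIN <- 70
GLUCOSE_MAX <- 250

#' Discretize glucose values into 1 mg/dL classes
#'
#' The 70-250 mg/dL prediction range is split into 180 one-mg/dL bins;
#' `class = floor(value - 70)` (0-based). Out-of-range values are clipped to
#' the boundary class with a warning.
#'
#' @param value_mgdl Numeric vector of glucose values in mg/dL.
#' @return Integer vector of class indices in `0..179`.
#' @export
#' @examples
#' discretize_glucose(c(70, 149.5, 249.9))
discretize_glucose <- function(value_mgdl) {
  if (any(!is.finite(value_mgdl))) stop("glucose values must be finite")
  out_of_range <- value_mgdl < GLUCOSE_MIN | value_mgdl >= GLUCOSE_MAX
  if (any(out_of_range)) {
    warning(sum(out_of_range), " glucose value(s) outside [70, 250) mg/dL ",
            "clipped to the boundary class")
  }
  cls <- floor(value_mgdl - GLUCOSE_MIN)
  as.integer(pmin(pmax(cls, 0), N_GLUCOSE_CLASSES - 1))
}

#' Map class indices back to glucose values
#'
#' Inverse of [discretize_glucose()] via bin centres: `70.5 + class`.
#'
#' @param class_index Integer vector of class indices in `0..179`.
#' @return Numeric vector of bin-centre glucose values in mg/dL.
#' @export
class_to_glucose <- function(class_index) {
  stopifnot(all(class_index >= 0), all(class_index < N_GLUCOSE_CLASSES))
  GLUCOSE_MIN + 0.5 + as.numeric(class_index)
}

#' Build a soft label distribution for a glucose class
#'
#' The centre category receives weight exactly 0.5 and neighbour weights
#' decrease linearly with distance, vanishing at `radius + 1`; each side
#' carries mass 0.25 so the full vector sums to 1. Near the range
#' boundaries the truncated side's mass is redistributed over the surviving
#' neighbours (proportionally to their linear-decay weights) with the
#' centre kept at 0.5.
#'
#' @param class_index Class index in `0..n_classes-1`.
#' @param radius Neighbour support radius (default 2, a 5-class support).
#' @param n_classes Number of classes (default 180).
#' @return Probability vector of length `n_classes` summing to 1.
#' @export
#' @examples
#' soft_label(90)[89:93]  # 1/12, 1/6, 1/2, 1/6, 1/12
soft_label <- function(class_index, radius = 2, n_classes = N_GLUCOSE_CLASSES) {
  stopifnot(is_scalar_number(class_index),
            class_index >= 0, class_index < n_classes)
  if (radius < 0) stop("radius must be non-negative")
  class_index <- as.integer(class_index)
  out <- numeric(n_classes)
  centre <- class_index + 1L
  if (radius == 0) {
    out[centre] <- 1
    return(out)
  }
  # linear decay weights, each full side carrying mass 0.25
  d <- seq_len(radius)
  w <- 0.25 * (radius + 1 - d) / sum(radius + 1 - d)
  offsets <- c(-rev(d), d)
  weights <- c(rev(w), w)
  ok <- class_index + offsets >= 0 & class_index + offsets < n_classes
  if (!any(ok)) {
    out[centre] <- 1
    return(out)
  }
  weights <- weights[ok] * 0.5 / sum(weights[ok])
  out[centre] <- 0.5
  out[centre + offsets[ok]] <- weights
  out
}

#' Kullback-Leibler divergence loss between label distributions
#'
#' `sum(target * log(target / predicted))`, with zero-mass target entries
#' contributing zero and the prediction floored at `eps` for numerical
#' stability.
#'
#' @param target,predicted Probability vectors of equal length, each
#'   summing to 1.
#' @param eps Floor applied to `predicted` (default 1e-12).
#' @return Non-negative divergence (nats).
#' @export
#' @examples
#' kl_loss(c(1, 0), c(0.5, 0.5))  # log(2)
kl_loss <- function(target, predicted, eps = 1e-12) {
  if (length(target) != length(predicted)) {
    stop("target and predicted must have equal length")
  }
  stopifnot(abs(sum(target) - 1) < 1e-6, abs(sum(predicted) - 1) < 1e-6)
  p <- pmax(predicted, eps)
  pos <- target > 0
  sum(target[pos] * log(target[pos] / p[pos]))
}

#' Balance class counts by random down-sampling
#'
#' Classes whose sample count exceeds the mean count (computed over the
#' occupied classes and floored to an integer) are randomly down-sampled to
#' exactly that mean; classes at or below the mean are untouched. The
#' subset is deterministic for a fixed seed.
#'
#' @param labels Tibble with a `class` column of 0-based class indices.
#' @param seed Integer seed.
#' @return The retained subset of `labels` (row order preserved).
#' @export
balance_classes <- function(labels, seed = 1L) {
  stopifnot("class" %in% names(labels), nrow(labels) >= 1)
  counts <- table(labels$class)
  target <- floor(mean(counts))
  with_seed(seed, {
    keep <- logical(nrow(labels))
    for (cl in names(counts)) {
      rows <- which(labels$class == as.integer(cl))
      if (length(rows) > target) rows <- sort(sample(rows, target))
      keep[rows] <- TRUE
    }
    labels[keep, , drop = FALSE]
  })
}

#' Six-dimensional auxiliary feature vector from glucose history
#'
#' Contextual features fused with the waveform embedding: the previous and
#' second-previous glucose values, the time interval to the previous
#' measurement and between the two previous measurements, the rate of
#' change `(prev - prev2) / interval2`, and the glucose level class of the
#' previous value (0 hypo < 70, 1 normal 70-180, 2 hyper > 180). With
#' fewer than two prior measurements the earliest value is repeated, the
#' rate set to zero, and the row flagged as padded.
#'
#' @param history Tibble of prior measurements (`time` seconds,
#'   `glucose_mgdl`); only rows with `time < current_time` are used.
#' @param current_time Prediction time in seconds.
#' @return One-row tibble: `prev_glucose_mgdl`, `prev2_glucose_mgdl`,
#'   `interval_minutes`, `interval2_minutes`, `rate_mgdl_per_min`,
#'   `level_class`, `padded`.
#' @export
aux_features <- function(history, current_time) {
  stopifnot(all(c("time", "glucose_mgdl") %in% names(history)))
  history <- dplyr::arrange(
    dplyr::filter(history, .data$time < current_time), .data$time
  )
  if (nrow(history) == 0) stop("aux_features requires at least one prior measurement")
  n <- nrow(history)
  prev <- history$glucose_mgdl[n]
  t_prev <- history$time[n]
  padded <- n < 2
  if (padded) {
    prev2 <- prev
    t_prev2 <- t_prev
  } else {
    prev2 <- history$glucose_mgdl[n - 1]
    t_prev2 <- history$time[n - 1]
  }
  interval2 <- (t_prev - t_prev2) / 60
  rate <- if (interval2 > 0) (prev - prev2) / interval2 else 0
  tibble::tibble(
    prev_glucose_mgdl = prev,
    prev2_glucose_mgdl = prev2,
    interval_minutes = (current_time - t_prev) / 60,
    interval2_minutes = interval2,
    rate_mgdl_per_min = rate,
    level_class = glucose_level_class(prev),
    padded = padded
  )
}

#' Glucose level classification
#'
#' @param value_mgdl Numeric vector of glucose values.
#' @return Integer vector: 0 (hypoglycemic, < 70), 1 (normal, 70-180),
#'   2 (hyperglycemic, > 180).
#' @export
glucose_level_class <- function(value_mgdl) {
  ifelse(value_mgdl < 70, 0L, ifelse(value_mgdl > 180, 2L, 1L))
}

# Fixed standardization bringing the six auxiliary features to zero-centred
# unit-order magnitudes before they enter the network: glucose values are
# centred on the middle of the 70-250 mg/dL range, intervals on a typical
# few-hour spacing, and the level class on "normal".
scale_aux <- function(aux) {
  cbind(
    (aux$prev_glucose_mgdl - 160) / 50,
    (aux$prev2_glucose_mgdl - 160) / 50,
    (aux$interval_minutes - 120) / 240,
    (aux$interval2_minutes - 120) / 240,
    aux$rate_mgdl_per_min,
    aux$level_class - 1
  )
}
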