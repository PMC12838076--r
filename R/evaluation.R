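#' Mean absolute relative difference (MARD)
#'
#' The standard continuous-glucose-monitoring accuracy metric:
#' `mean(|measured - reference| / reference) * 100`, in percent.
#'
#' @param measured Numeric vector of estimated glucose values (mg/dL).
#' @param reference Numeric vector of reference glucose values (mg/dL),
#'   all positive, same length.
#' @return MARD in percent.
#' @export
#' @examples
#' mard(c(90, 220), c(100, 200))  # 10
mard <- function(measured, reference) {
  if (length(measured) != length(reference) || length(measured) < 1) {
    stop("measured and reference must be equal-length, non-empty vectors")
  }
  if (any(reference <= 0)) stop("reference values must be positive")
  mean(abs(measured - reference) / reference) * 100
}

#' Clarke error grid zone of a (reference, measured) pair
#'
#' Two zone definitions are provided. `"banded"` (default) assigns zones by
#' pure relative error: Zone A for errors within 0-20%, B 20-40%, C 40-60%,
#' D 60-80%, E 80% and beyond. `"canonical"` implements the classical 1987
#' polygonal Clarke grid with its special handling of the hypoglycemic
#' range, for comparison with the standard presentation.
#'
#' @param reference Reference glucose (mg/dL), positive; vectorized.
#' @param measured Measured/estimated glucose (mg/dL), positive; vectorized.
#' @param mode `"banded"` or `"canonical"`.
#' @return Character vector of zones `"A"`-`"E"`.
#' @export
#' @examples
#' clarke_zone(100, 119)          # "A" (19% error)
#' clarke_zone(100, 130)          # "B" (30% error)
clarke_zone <- function(reference, measured, mode = c("banded", "canonical")) {
  mode <- match.arg(mode)
  if (any(reference <= 0) || any(measured <= 0)) {
    stop("glucose values must be positive")
  }
  n <- max(length(reference), length(measured))
  reference <- rep_len(reference, n)
  measured <- rep_len(measured, n)
  if (mode == "banded") {
    rel <- abs(measured - reference) / reference
    zones <- cut(rel, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
                 labels = c("A", "B", "C", "D", "E"))
    return(as.character(zones))
  }
  vapply(seq_len(n), function(i) {
    canonical_clarke(reference[i], measured[i])
  }, character(1))
}

# Classical 1987 Clarke error grid polygon rules (x = reference,
# y = measured), in the widely used conditional-cascade form.
canonical_clarke <- function(x, y) {
  if ((x <= 70 && y <= 70) || (y <= 1.2 * x && y >= 0.8 * x)) {
    "A"
  } else if ((x >= 180 && y <= 70) || (x <= 70 && y >= 180)) {
    "E"
  } else if ((x >= 70 && x <= 290 && y >= x + 110) ||
             (x >= 130 && x <= 180 && y <= (7 / 5) * x - 182)) {
    "C"
  } else if ((x >= 240 && y >= 70 && y <= 180) ||
             (x <= 175 / 3 && y <= 180 && y >= 70) ||
             (x >= 175 / 3 && x <= 70 && y >= (6 / 5) * x)) {
    "D"
  } else {
    "B"
  }
}

#' Zone-occupancy table for a set of predictions
#'
#' @inheritParams clarke_zone
#' @param measured Numeric vector of estimates (mg/dL).
#' @param reference Numeric vector of references (mg/dL), same length.
#' @return A tibble with one row per zone A-E: `zone`, `n`, `fraction`
#'   (fractions sum to 1).
#' @export
zone_table <- function(measured, reference, mode = c("banded", "canonical")) {
  mode <- match.arg(mode)
  if (length(measured) != length(reference) || length(measured) < 1) {
    stop("measured and reference must be equal-length, non-empty vectors")
  }
  z <- factor(clarke_zone(reference, measured, mode), levels = LETTERS[1:5])
  counts <- table(z)
  tibble::tibble(
    zone = LETTERS[1:5],
    n = as.integer(counts),
    fraction = as.numeric(counts) / length(measured)
  )
}

#' Full evaluation report: MARD plus zone occupancy
#'
#' @inheritParams zone_table
#' @return A `ppg_eval` object: list with `mard_percent`, `zones` (tibble),
#'   `mode`, `n`.
#' @export
eval_report <- function(measured, reference, mode = c("banded", "canonical")) {
  mode <- match.arg(mode)
  structure(
    list(
      mard_percent = mard(measured, reference),
      zones = zone_table(measured, reference, mode),
      mode = mode,
      n = length(measured),
      measured = measured,
      reference = reference
    ),
    class = "ppg_eval"
  )
}

#' @export
print.ppg_eval <- function(x, ...) {
  cat(sprintf("<ppg_eval> n = %d, MARD = %.2f%% (%s zoning)\n",
              x$n, x$mard_percent, x$mode))
  zf <- sprintf("%s: %.1f%%", x$zones$zone, 100 * x$zones$fraction)
  cat(" zones:", paste(zf, collapse = "  "), "\n")
  invisible(x)
}

#' @rdname eval_report
#' @param x A `ppg_eval` object.
#' @param ... Unused.
#' @export
glance.ppg_eval <- function(x, ...) {
  out <- tibble::tibble(n = x$n, mard_percent = x$mard_percent, mode = x$mode)
  for (k in seq_len(nrow(x$zones))) {
    out[[paste0("zone_", x$zones$zone[k])]] <- x$zones$fraction[k]
  }
  out
}
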