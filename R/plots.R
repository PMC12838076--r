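#' Plot a PPG segment, optionally with fiducials
#'
#' @param object A [ppg_segment()].
#' @param fiducials Optional `fiducial_set` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppg_segment
#' @export
autoplot.ppg_segment <- function(object, fiducials = NULL, ...) {
  df <- tibble::tibble(
    time = object$start_time +
      (seq_along(object$samples) - 1) / object$sample_rate_hz,
    value = object$samples
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8", linewidth = 0.4, na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = sprintf("PPG segment (%s)", object$patient_id)) +
    ggplot2::theme_minimal()
  if (!is.null(fiducials)) {
    fd <- tibble::tibble(
      index = c(fiducials$peaks, fiducials$valleys),
      type = c(rep("peak", length(fiducials$peaks)),
               rep("valley", length(fiducials$valleys)))
    )
    fd$time <- object$start_time + (fd$index - 1) / object$sample_rate_hz
    fd$value <- object$samples[fd$index]
    p <- p + ggplot2::geom_point(
      data = fd,
      ggplot2::aes(x = .data$time, y = .data$value, colour = .data$type),
      size = 1.6
    ) +
      ggplot2::scale_colour_manual(values = c(peak = "#d7301f",
                                              valley = "#238443"))
  }
  p
}

#' Clarke error grid plot of an evaluation report
#'
#' Scatter of (reference, measured) pairs over the classical Clarke grid
#' boundaries, annotated with the report's MARD.
#'
#' @param object A `ppg_eval` from [eval_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppg_eval
#' @export
autoplot.ppg_eval <- function(object, ...) {
  df <- tibble::tibble(
    reference = object$reference, measured = object$measured,
    zone = clarke_zone(object$reference, object$measured, object$mode)
  )
  lim <- max(400, df$reference, df$measured)
  seg <- tibble::tibble(
    x = c(0, 0, 70, 70, 70, 180, 240, 0, 175 / 3, 130, 70, 290),
    y = c(0, 70, 84, 180, 180, 70, 180, 180, 70, 0, 56, 400),
    xend = c(lim, 175 / 3, 70, 70, lim, 180, lim, 70, 70, 180, 290, lim),
    yend = c(lim, 70, 180, lim, 180, 0, 180, 180, 84, 70, 400, 400)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$reference,
                                        y = .data$measured)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$zone), alpha = 0.7,
                        size = 1.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::coord_cartesian(xlim = c(0, lim), ylim = c(0, lim)) +
    ggplot2::labs(
      x = "reference glucose (mg/dL)", y = "estimated glucose (mg/dL)",
      title = sprintf("Clarke error grid (%s zoning), MARD %.2f%%",
                      object$mode, object$mard_percent)
    ) +
    ggplot2::theme_minimal()
  if (object$mode == "canonical") {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      inherit.aes = FALSE, colour = "grey40", linewidth = 0.3
    )
  }
  p
}

#' Training-curve plot for a model fit
#'
#' @param object A `glucose_fit` from [train_model()].
#' @param ... Unused.
#' @return A ggplot object showing train/validation KL loss per epoch and
#'   learning-rate reductions.
#' @method autoplot glucose_fit
#' @export
autoplot.glucose_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                        colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "KL loss", colour = NULL,
                  title = "Training curves") +
    ggplot2::theme_minimal()
  cuts <- object$log$epoch[object$log$reduced]
  if (length(cuts) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = cuts, linetype = 3,
                                 colour = "grey40")
  }
  p
}

#' Bar chart of quality-grade occupancy
#'
#' @param grades Tibble with a `grade` column, e.g. from
#'   [grade_segments()].
#' @return A ggplot object.
#' @export
plot_quality_grades <- function(grades) {
  stopifnot("grade" %in% names(grades))
  ggplot2::ggplot(grades, ggplot2::aes(x = .data$grade)) +
    ggplot2::geom_bar(fill = "#2c7fb8") +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "SQI grade", y = "segments",
                  title = "Signal quality grades") +
    ggplot2::theme_minimal()
}
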