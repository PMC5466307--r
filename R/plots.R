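#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a 1D+t velocity map
#'
#' Space-time raster of the projected velocity (cm/s); the ascending aorta
#' appears as a band of periodic bright systolic stripes.
#'
#' @param object A `velocity_map`.
#' @param t_max Optional right edge of the time window (s).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.velocity_map <- function(object, t_max = NULL, ...) {
  times <- frame_times(object)
  keep <- if (is.null(t_max)) seq_along(times) else which(times <= t_max)
  df <- expand.grid(pixel = seq_len(nrow(object$velocity)) + object$pixel_offset,
                    t = times[keep])
  df$velocity <- as.vector(object$velocity[, keep])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$pixel,
                                   fill = .data$velocity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "pixel", fill = "v (cm/s)",
                  title = "1D+t projected velocity") +
    ggplot2::theme_minimal()
}

#' Plot segmentation candidate courses
#'
#' One velocity time course per ROI, the selected aorta highlighted.
#'
#' @param object A `segmentation`.
#' @param t_max Optional right edge of the time window (s).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.segmentation <- function(object, t_max = NULL, ...) {
  times <- object$t0 + (seq_along(object$course) - 1L) * object$dt
  df <- tidyr::unnest(
    dplyr::mutate(object$rois,
                  t = purrr::map(.data$course, ~times),
                  chosen = .data$roi == object$chosen$roi),
    cols = c("course", "t")
  )
  if (!is.null(t_max)) df <- df[df$t <= t_max, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$course,
                                   group = .data$roi,
                                   colour = .data$chosen,
                                   linewidth = .data$chosen)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::scale_linewidth_manual(values = c(`TRUE` = 0.8, `FALSE` = 0.3)) +
    ggplot2::labs(x = "time (s)", y = "mean ROI velocity (cm/s)",
                  title = "ROI velocity courses (aorta in red)") +
    ggplot2::guides(colour = "none", linewidth = "none") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' @param object A `bland_altman`.
#' @param ... Unused.
#' @return A ggplot with bias and 95% limits of agreement.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = 1000 * .data$diff)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 1000 * object$bias, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 1000 * c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of methods (s)", y = "difference (ms)",
                  title = sprintf("Bland-Altman: bias %.1f ms, LoA [%.1f, %.1f] ms",
                                  1000 * object$bias, 1000 * object$loa_low,
                                  1000 * object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted cardiac model over its training cycles
#'
#' @param object A `cardiac_model` with an underlying fit.
#' @param data Optional tibble with `hr` and `systole_s` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cardiac_model <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data, ggplot2::aes(x = .data$hr, y = .data$systole_s), alpha = 0.3
    )
  }
  p + ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                           colour = "firebrick") +
    ggplot2::labs(x = "heart rate (bpm)", y = "systole duration (s)",
                  title = sprintf("%s: S = %.3f %+.4f*HR", object$kind,
                                  object$intercept, object$slope)) +
    ggplot2::theme_minimal()
}

#' Plot an aortic course with its baseline and detected end-systole times
#'
#' @param course Velocity course (cm/s).
#' @param times Frame times (s).
#' @param baseline A `systole_baseline`.
#' @param samples Optional `systole_samples` tibble; valid end-systole
#'   crossings are marked.
#' @param t_max Optional right edge of the time window (s).
#' @return A ggplot.
#' @export
plot_baseline <- function(course, times, baseline, samples = NULL,
                          t_max = NULL) {
  df <- tibble::tibble(t = times, course = course, baseline = baseline$values)
  if (!is.null(t_max)) df <- df[df$t <= t_max, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$course), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$baseline), colour = "black",
                       linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "velocity (cm/s)",
                  title = "Aortic course and iterative baseline") +
    ggplot2::theme_minimal()
  if (!is.null(samples)) {
    cr <- samples[samples$valid, ]
    cr$t_cross <- cr$r_time + cr$systole_s
    if (!is.null(t_max)) cr <- cr[cr$t_cross <= t_max, ]
    p <- p + ggplot2::geom_vline(xintercept = cr$t_cross,
                                 colour = "firebrick", alpha = 0.5)
  }
  p
}
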