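#' Plot a channel-tuning function reconstruction
#'
#' Channel response against channel offset, one line per condition. With a
#' time-resolved reconstruction the profiles are averaged over `window`
#' (default: all time points).
#'
#' @param object A `ctf_reconstruction`.
#' @param window Optional `c(from, to)` time window (ms) to average over.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ctf_reconstruction <- function(object, window = NULL, ...) {
  df <- tidy(object)
  if (!is.null(window)) {
    df <- dplyr::filter(df, .data$time >= window[1], .data$time <= window[2])
  }
  df <- df |>
    dplyr::group_by(.data$condition, .data$offset) |>
    dplyr::summarise(response = mean(.data$response), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$offset, .data$response,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$offsets) +
    ggplot2::labs(x = "Channel offset (deg)", y = "Channel response",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot CTF slope time courses
#'
#' @param slopes A tibble from [ctf_slopes()] (optionally with a `subject`
#'   column, in which case the mean and +/-1 SEM across subjects are
#'   drawn).
#' @return A ggplot.
#' @export
plot_ctf_slopes <- function(slopes) {
  if ("subject" %in% names(slopes)) {
    df <- slopes |>
      dplyr::group_by(.data$condition, .data$time) |>
      dplyr::summarise(
        sem = sd(.data$slope) / sqrt(dplyr::n()),
        slope = mean(.data$slope), .groups = "drop"
      )
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$slope,
                                          colour = .data$condition,
                                          fill = .data$condition)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$slope - .data$sem,
                                        ymax = .data$slope + .data$sem),
                           alpha = 0.2, colour = NA)
  } else {
    p <- ggplot2::ggplot(slopes, ggplot2::aes(.data$time, .data$slope,
                                              colour = .data$condition))
  }
  p + ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "Time (ms)", y = "CTF slope", colour = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fitted response-error mixture over the data
#'
#' @param object A `mixture_fit`.
#' @param errors The response errors (degrees) the model was fitted to.
#' @param nontarget_offsets Optional non-target offsets for the swap
#'   component's expected density.
#' @param ... Unused.
#' @return A ggplot of the error histogram with the fitted mixture
#'   density overlaid.
#' @export
autoplot.mixture_fit <- function(object, errors, nontarget_offsets = NULL, ...) {
  grid <- seq(-180, 180, by = 1)
  dens_target <- (1 - object$p_guess -
                    ifelse(is.na(object$p_swap), 0, object$p_swap)) *
    exp(vm_log_density(grid, object$kappa))
  dens <- dens_target + object$p_guess / (2 * pi)
  if (!is.na(object$p_swap) && !is.null(nontarget_offsets)) {
    swap <- rowMeans(vapply(
      nontarget_offsets,
      function(o) exp(vm_log_density(circ_diff(grid, o), object$kappa)),
      numeric(length(grid))
    ))
    dens <- dens + object$p_swap * swap
  }
  df_fit <- tibble(error = grid, density = dens * pi / 180)  # per degree
  ggplot2::ggplot(tibble(error = errors), ggplot2::aes(.data$error)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = 10, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = df_fit,
                       ggplot2::aes(.data$error, .data$density),
                       colour = "firebrick") +
    ggplot2::labs(x = "Response error (deg)", y = "Density") +
    ggplot2::theme_minimal()
}

#' Plot a cluster-based permutation test result
#'
#' @param object A `cluster_result` over a 1-D (time) series.
#' @param times Optional time axis for the x coordinates.
#' @param ... Unused.
#' @return A ggplot of the pointwise t series with significant clusters
#'   shaded and the cluster-forming threshold drawn.
#' @export
autoplot.cluster_result <- function(object, times = NULL, ...) {
  if (is.matrix(object$t_values)) {
    abort("Plotting is implemented for 1-D (time) cluster results.")
  }
  times <- times %||% seq_along(object$t_values)
  df <- tibble(time = times, t = object$t_values)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$t)) +
    ggplot2::geom_hline(yintercept = object$t_threshold, linetype = 2,
                        colour = "grey40")
  sig <- object$clusters[object$clusters$significant, ]
  for (m in sig$members) {
    p <- p + ggplot2::annotate(
      "rect", xmin = times[min(m)], xmax = times[max(m)],
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick"
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "Time", y = "t statistic") +
    ggplot2::theme_minimal()
}
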