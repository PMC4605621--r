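#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrogram
#'
#' @param object A `koala_spectrogram` from [spectrogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.koala_spectrogram <- function(object, ...) {
  df <- tidyr::expand_grid(
    time = object$time, freq = object$freq
  )
  df$db <- as.vector(t(object$db))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq, fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::labs(
      x = "Time (s)", y = "Frequency (Hz)", fill = "dB"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an F0 contour
#'
#' @param object An `f0_contour` from [track_f0()].
#' @param ... Unused.
#' @return A ggplot of the voiced F0 track over time.
#' @export
autoplot.f0_contour <- function(object, ...) {
  df <- object[object$voiced, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$f0)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "Time (s)", y = "F0 (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot cluster model selection
#'
#' Silhouette score against candidate number of clusters, marking the
#' chosen solution.
#'
#' @param object A `two_step_cluster` from [two_step_cluster()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.two_step_cluster <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "red", `FALSE` = "black"), guide = "none"
    ) +
    ggplot2::labs(x = "Number of clusters", y = "Mean silhouette") +
    ggplot2::theme_minimal()
}

#' Plot canonical discriminant scores
#'
#' Scatter of the first two canonical functions, coloured by group.
#'
#' @param object A `koala_dfa` from [discriminant_analysis()].
#' @param data The feature table the analysis was fitted to.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.koala_dfa <- function(object, data, ...) {
  X <- scale(as.matrix(data[object$vars])) # matches the fit's scaling
  sc <- X %*% object$coefficients
  df <- tibble::tibble(
    df1 = sc[, 1],
    df2 = if (ncol(sc) > 1) sc[, 2] else 0,
    group = object$observed
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$df1, .data$df2, colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Function 1", y = "Function 2", colour = object$group) +
    ggplot2::theme_minimal()
}
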