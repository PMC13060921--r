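#' Plot a fitted copy-number mixture
#'
#' Draws the weighted component densities of a fitted mixture; pass a
#' cohort to overlay its normalized histogram.
#'
#' @param object a `dj_gmm`.
#' @param data optional cohort data frame with a `cn` column to overlay.
#' @param binwidth histogram bin width for the overlay.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot dj_gmm
#' @export
autoplot.dj_gmm <- function(object, data = NULL, binwidth = 0.1, ...) {
  grid <- seq(min(object$means) - 1, max(object$means) + 1, by = 0.01)
  dens <- purrr::map_dfr(seq_along(object$means), function(k) {
    tibble(cn = grid, component = object$labels[k],
           density = object$weights[k] *
             stats::dnorm(grid, object$means[k], object$sigmas[k]))
  })
  p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$cn, y = .data$density))
  if (!is.null(data)) {
    p <- p + ggplot2::geom_histogram(
      data = as_tibble(data),
      ggplot2::aes(x = .data$cn, y = ggplot2::after_stat(.data$density)),
      binwidth = binwidth, inherit.aes = FALSE,
      fill = "grey85", colour = "grey70")
  }
  p +
    ggplot2::geom_line(ggplot2::aes(colour = .data$component)) +
    ggplot2::labs(x = "diploid copy number", y = "density",
                  colour = "component")
}

#' Plot a k-mer spectrum calibration
#'
#' Histogram of the k-mer spectrum with the detected 1-/2-copy peaks and
#' the 2-copy peak boundaries marked.
#'
#' @param object a `dj_peak_calibration`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot dj_peak_calibration
#' @export
autoplot.dj_peak_calibration <- function(object, ...) {
  h <- object$histogram
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$multiplicity,
                                       y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$two_copy, colour = "red") +
    ggplot2::geom_vline(xintercept = object$boundaries,
                        linetype = "dashed", colour = "red")
  if (is.finite(object$one_copy)) {
    p <- p + ggplot2::geom_vline(xintercept = object$one_copy,
                                 colour = "blue")
  }
  p + ggplot2::labs(x = "k-mer multiplicity", y = "distinct k-mers")
}

#' Histogram of a copy-number cohort
#'
#' @param data cohort data frame with a `cn` column.
#' @param binwidth histogram bin width (default 0.1).
#' @return A ggplot object.
#' @export
plot_cohort <- function(data, binwidth = 0.1) {
  ggplot2::ggplot(as_tibble(data), ggplot2::aes(x = .data$cn)) +
    ggplot2::geom_histogram(binwidth = binwidth,
                            fill = "grey60", colour = "grey40") +
    ggplot2::labs(x = "diploid copy number", y = "samples")
}
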