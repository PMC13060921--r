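#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted mixture model
#'
#' One row per component: label, fixed mean, fitted weight and standard
#' deviation, plus bootstrap standard errors when the model was fitted with
#' [bootstrap_fit()].
#'
#' @param x a `dj_gmm`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy dj_gmm
#' @export
tidy.dj_gmm <- function(x, ...) {
  out <- tibble(component = seq_along(x$means), label = x$labels,
                mean = x$means, weight = x$weights, sigma = x$sigmas)
  reps <- x$bootstrap$replicates
  if (!is.null(reps)) {
    se <- reps |>
      group_by(.data$component) |>
      summarise(weight_se = stats::sd(.data$weight),
                sigma_se = stats::sd(.data$sigma), .groups = "drop")
    out <- left_join(out, se, by = "component")
  }
  out
}

#' @rdname tidy.dj_gmm
#' @method glance dj_gmm
#' @export
glance.dj_gmm <- function(x, ...) {
  tibble(n = x$n, k = length(x$means), loglik = x$loglik,
         n_iter = x$n_iter, converged = x$converged,
         bootstrap_B = x$bootstrap$B %||% NA_integer_)
}

#' Tidy a linear calibration fit
#'
#' @param x a `dj_transform`.
#' @param ... unused.
#' @return A tibble of coefficient estimates (`tidy`) or fit summaries
#'   (`glance`).
#' @method tidy dj_transform
#' @export
tidy.dj_transform <- function(x, ...) {
  tibble(term = c("(Intercept)", "slope"),
         estimate = c(x$beta0, x$beta1))
}

#' @rdname tidy.dj_transform
#' @method glance dj_transform
#' @export
glance.dj_transform <- function(x, ...) {
  tibble(n = x$n, rss = x$rss, sigma2 = x$sigma2,
         r_squared = x$r_squared,
         source_mode = x$source_mode, target_scale = x$target_scale)
}
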