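#' Fit a linear cross-reference calibration
#'
#' Ordinary least squares fit of `target = beta0 + beta1 * source + eps`,
#' used to transform copy-number estimates obtained on one reference build
#' (e.g. an alternate-build fast mode) onto the scale of another (the
#' complete-reference estimates). The residual sum of squares of competing
#' source modes drives mode selection ([select_mode_by_rss()]).
#'
#' @param data data frame of paired estimates, one row per sample.
#' @param source,target bare column names of the source-scale and
#'   target-scale estimates.
#' @param source_mode,target_scale optional labels stored on the fit.
#' @return An object of class `dj_transform` with elements `beta0`, `beta1`,
#'   `rss`, `sigma2` (residual variance, RSS/(n-2)), `r_squared`, `n`.
#' @examples
#' d <- data.frame(x = c(0, 1, 2), y = c(1, 1, 4))
#' fit <- fit_linear_transform(d, x, y)
#' c(fit$beta0, fit$beta1, fit$rss) # 0.5 1.5 1.5
#' @export
fit_linear_transform <- function(data, source, target,
                                 source_mode = NULL, target_scale = NULL) {
  x <- pull(data, {{ source }})
  y <- pull(data, {{ target }})
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired estimates", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate design: source estimates are constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  res <- stats::resid(fit)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    beta0 = unname(stats::coef(fit)[1L]),
    beta1 = unname(stats::coef(fit)[2L]),
    rss = rss,
    sigma2 = rss / (n - 2L),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    n = n,
    source_mode = source_mode %||% as_name(enquo(source)),
    target_scale = target_scale %||% as_name(enquo(target))
  ), class = "dj_transform")
}

#' @export
print.dj_transform <- function(x, ...) {
  cat(sprintf("<dj_transform> %s -> %s: y = %.4f + %.4f x (n=%d, RSS=%.4g)\n",
              x$source_mode, x$target_scale, x$beta0, x$beta1, x$n, x$rss))
  invisible(x)
}

#' @export
predict.dj_transform <- function(object, newdata, ...) {
  object$beta0 + object$beta1 * as.numeric(newdata)
}

#' Apply a fitted calibration to a cohort
#'
#' @param data data frame of estimates.
#' @param transform a `dj_transform` from [fit_linear_transform()].
#' @param source bare column name holding source-scale values.
#' @param new_col name of the added column (default `"cn_transformed"`).
#' @return `data` with the transformed column appended; the source mode is
#'   recorded in the `"source_mode"` attribute.
#' @export
apply_transform <- function(data, transform, source,
                            new_col = "cn_transformed") {
  stopifnot(inherits(transform, "dj_transform"))
  x <- pull(data, {{ source }})
  out <- as_tibble(data)
  out[[new_col]] <- predict(transform, x)
  attr(out, "source_mode") <- transform$source_mode
  out
}

#' Select the estimation mode with the lowest residual sum of squares
#'
#' @param candidates named list of `dj_transform` fits (names are mode
#'   labels), or a named numeric vector of RSS values.
#' @return The winning mode label. Ties are broken by mode-name order and
#'   reported with a warning.
#' @export
select_mode_by_rss <- function(candidates) {
  if (length(candidates) == 0L) {
    stop("no candidate modes supplied", call. = FALSE)
  }
  rss <- if (is.numeric(candidates)) candidates
         else vapply(candidates, `[[`, numeric(1L), "rss")
  if (is.null(names(rss)) || any(!nzchar(names(rss)))) {
    stop("candidates must be named by mode", call. = FALSE)
  }
  rss <- rss[order(names(rss))]
  best <- which(rss == min(rss))
  if (length(best) > 1L) {
    warning("RSS tie between modes: ",
            paste(names(rss)[best], collapse = ", "),
            "; returning the first by name", call. = FALSE)
  }
  names(rss)[best[1L]]
}

#' Compare two copy-number distributions
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test with the rank-biserial
#' correlation `RBC = 1 - 2U/(n_a * n_b)` as effect size, where `U` is the
#' rank-sum statistic of `a` versus `b`. The report flags the distributions
#' as indistinguishable when `p > alpha`.
#'
#' @param a,b numeric vectors of copy-number estimates (each length >= 2),
#'   or data frames with a `cn` column.
#' @param alpha significance level for the indistinguishability flag.
#' @return One-row tibble: `n_a`, `n_b`, `u`, `p_value`, `rbc`,
#'   `indistinguishable`.
#' @export
compare_distributions <- function(a, b, alpha = 0.05) {
  if (is.data.frame(a)) a <- a$cn
  if (is.data.frame(b)) b <- b$cn
  if (length(a) < 2L || length(b) < 2L) {
    stop("both samples must have at least 2 observations", call. = FALSE)
  }
  # ties make exact p-values unavailable; the normal approximation is used
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  u <- unname(wt$statistic)
  rbc <- 1 - 2 * u / (length(a) * length(b))
  tibble(n_a = length(a), n_b = length(b), u = u,
         p_value = wt$p.value, rbc = rbc,
         indistinguishable = wt$p.value > alpha)
}

#' Split a cohort into training and test sets
#'
#' @param data cohort data frame.
#' @param ratio training fraction (default 0.75).
#' @param seed optional RNG seed, recorded on the result.
#' @return List with elements `train` and `test`.
#' @export
train_test_split <- function(data, ratio = 0.75, seed = NULL) {
  stopifnot(ratio > 0, ratio < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  idx <- sample.int(n, size = round(n * ratio))
  out <- list(train = data[idx, , drop = FALSE],
              test = data[-idx, , drop = FALSE])
  attr(out, "seed") <- seed
  out
}

#' Serialize / restore a linear calibration as JSON
#' @param transform a `dj_transform`.
#' @param path JSON file path.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "dj_transform"))
  jsonlite::write_json(unclass(transform), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "dj_transform")
}
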