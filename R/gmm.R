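#' Default mixture layout for DJ copy-number classification
#'
#' Seven fixed component means covering the empirically observed DJ dosage
#' peaks: integer copies 8-13 plus an intermediate component at 10.7
#' capturing partially duplicated DJ haplotypes. Component standard
#' deviations are constrained to `[0.1, 0.2]`.
#'
#' @return `dj_default_means()`: numeric vector of 7 means.
#' @export
dj_default_means <- function() c(8, 9.1, 10.1, 10.7, 11.1, 11.9, 13)

#' @rdname dj_default_means
#' @return `dj_default_labels()`: bin labels per component; the 10.7
#'   component is the `"10-11"` intermediate (partial duplication) class.
#' @export
dj_default_labels <- function() c("8", "9", "10", "10-11", "11", "12", "13")

#' @rdname dj_default_means
#' @return `dj_default_sigma_bounds()`: `c(0.1, 0.2)`.
#' @export
dj_default_sigma_bounds <- function() c(0.1, 0.2)

#' Construct a fixed-mean Gaussian mixture model
#'
#' @param means strictly increasing component means (never re-estimated).
#' @param weights mixture weights, summing to 1.
#' @param sigmas component standard deviations within `sigma_bounds`.
#' @param sigma_bounds `c(sigma_min, sigma_max)`.
#' @param labels bin label per component.
#' @return An object of class `dj_gmm`.
#' @export
gmm_model <- function(means = dj_default_means(),
                      weights = rep(1 / length(means), length(means)),
                      sigmas = rep(mean(sigma_bounds), length(means)),
                      sigma_bounds = dj_default_sigma_bounds(),
                      labels = NULL) {
  K <- length(means)
  if (is.null(labels)) {
    labels <- if (K == 7L && all(means == dj_default_means())) {
      dj_default_labels()
    } else {
      as.character(round(means))
    }
  }
  stopifnot(K >= 1L, length(weights) == K, length(sigmas) == K,
            length(labels) == K, length(sigma_bounds) == 2L)
  if (is.unsorted(means, strictly = TRUE)) {
    stop("component means must be strictly increasing", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (any(sigmas < sigma_bounds[1] - 1e-12) ||
      any(sigmas > sigma_bounds[2] + 1e-12)) {
    stop("sigmas must lie inside sigma_bounds", call. = FALSE)
  }
  structure(list(means = means, weights = weights, sigmas = sigmas,
                 sigma_bounds = sigma_bounds, labels = labels,
                 loglik = NA_real_, n_iter = 0L, converged = NA,
                 trajectory = numeric(), clamped = logical(),
                 n = NA_integer_, bootstrap = NULL),
            class = "dj_gmm")
}

#' @export
print.dj_gmm <- function(x, ...) {
  cat("<dj_gmm>", length(x$means), "components, sigma in [",
      x$sigma_bounds[1], ",", x$sigma_bounds[2], "]\n")
  print(tibble(label = x$labels, mean = x$means,
               weight = round(x$weights, 4), sigma = round(x$sigmas, 4)))
  if (!is.na(x$loglik)) {
    cat(sprintf("  logLik %.4f after %d iteration(s); converged: %s\n",
                x$loglik, x$n_iter, x$converged))
  }
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  bootstrap: B=%d (%d usable)\n",
                x$bootstrap$B, x$bootstrap$B_ok))
  }
  invisible(x)
}

extract_cn <- function(data, col) {
  if (is.numeric(data)) return(as.numeric(data))
  pull(data, {{ col }})
}

# log density matrix n x K and per-row logsumexp
gmm_logdens <- function(x, model) {
  K <- length(model$means)
  ld <- vapply(seq_len(K), function(k) {
    stats::dnorm(x, model$means[k], model$sigmas[k], log = TRUE) +
      log(model$weights[k])
  }, numeric(length(x)))
  ld <- matrix(ld, nrow = length(x), ncol = K)
  m <- ld[, 1L]
  for (k in seq_len(K)[-1L]) m <- pmax(m, ld[, k])
  lse <- m + log(rowSums(exp(ld - m)))
  list(ld = ld, lse = lse)
}

#' EM fit of a fixed-mean, variance-constrained Gaussian mixture
#'
#' Expectation-maximization over weights and standard deviations only:
#' component means stay fixed throughout. After every M-step the standard
#' deviations are clamped into `sigma_bounds` (projected EM); the
#' log-likelihood is therefore guaranteed non-decreasing only across
#' iterations without clamping. Convergence is declared when the relative
#' change in log-likelihood between successive iterations falls below `tol`
#' (set `tol_type = "absolute"` for an absolute-change criterion). All
#' density evaluation is in log space.
#'
#' @param data cohort data frame (or numeric vector) of continuous
#'   copy-number estimates.
#' @param col bare column name holding the estimates (default `cn`).
#' @param means fixed component means.
#' @param sigma_bounds standard-deviation bounds (default `c(0.1, 0.2)`).
#' @param max_iter maximum EM iterations (default 500).
#' @param tol convergence tolerance on the log-likelihood change
#'   (default 1e-10, relative).
#' @param tol_type `"relative"` or `"absolute"`.
#' @param weights_init,sigma_init optional initial values; defaults are
#'   uniform weights and the bounds midpoint.
#' @param labels optional bin labels per component.
#' @return A fitted `dj_gmm` carrying the log-likelihood trajectory, the
#'   iteration count, a convergence flag and per-iteration clamping marks.
#' @export
em_fit_fixed_means <- function(data, col = cn,
                               means = dj_default_means(),
                               sigma_bounds = dj_default_sigma_bounds(),
                               max_iter = 500L, tol = 1e-10,
                               tol_type = c("relative", "absolute"),
                               weights_init = NULL, sigma_init = NULL,
                               labels = NULL) {
  tol_type <- match.arg(tol_type)
  x <- extract_cn(data, {{ col }})
  K <- length(means)
  n <- length(x)
  if (n < K) stop("need at least as many observations as components",
                  call. = FALSE)
  if (any(!is.finite(x))) stop("data must be finite", call. = FALSE)
  model <- gmm_model(
    means = means,
    weights = weights_init %||% rep(1 / K, K),
    sigmas = sigma_init %||% rep(mean(sigma_bounds), K),
    sigma_bounds = sigma_bounds, labels = labels)

  traj <- numeric(0)
  clamped <- logical(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e <- gmm_logdens(x, model)
    ll <- sum(e$lse)
    if (!is.finite(ll)) {
      stop("non-finite log-likelihood at iteration ", it, call. = FALSE)
    }
    r <- exp(e$ld - e$lse)
    nk <- colSums(r)
    w <- nk / n
    sig <- model$sigmas
    upd <- nk > n * 1e-12
    sig2 <- colSums(r * (outer(x, model$means, "-"))^2)[upd] / nk[upd]
    sig[upd] <- sqrt(pmax(sig2, 1e-12))
    clamp <- sig < sigma_bounds[1] | sig > sigma_bounds[2]
    sig <- pmin(pmax(sig, sigma_bounds[1]), sigma_bounds[2])
    model$weights <- w
    model$sigmas <- sig
    traj <- c(traj, ll)
    clamped <- c(clamped, any(clamp))
    if (it > 1L) {
      delta <- abs(ll - traj[it - 1L])
      if (tol_type == "relative") delta <- delta / abs(traj[it - 1L])
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
  }
  model$loglik <- traj[length(traj)]
  model$n_iter <- length(traj)
  model$converged <- converged
  model$trajectory <- traj
  model$clamped <- clamped
  model$n <- n
  model
}

#' Bootstrap-aggregated mixture fit
#'
#' Fits [em_fit_fixed_means()] on `B` bootstrap resamples (with replacement,
#' same size as the data) and averages the per-replicate weights and
#' standard deviations; averaged weights are renormalized to sum to exactly
#' 1 (the average preserves the sum to float precision; the
#' renormalization is recorded in the model metadata). Replicates that fail
#' to fit are dropped with a warning; more than 10% failures is an error.
#'
#' @inheritParams em_fit_fixed_means
#' @param B number of bootstrap replicates.
#' @param seed optional RNG seed, recorded on the model.
#' @param ... further arguments passed to [em_fit_fixed_means()].
#' @return A `dj_gmm` whose `weights`/`sigmas` are the bootstrap averages;
#'   `$bootstrap` holds `B`, the usable replicate count, the seed, and a
#'   tibble of per-replicate estimates for uncertainty reporting.
#' @export
bootstrap_fit <- function(data, col = cn, B = 1000L, seed = NULL,
                          means = dj_default_means(),
                          sigma_bounds = dj_default_sigma_bounds(),
                          labels = NULL, ...) {
  x <- extract_cn(data, {{ col }})
  n <- length(x)
  K <- length(means)
  if (n < K) stop("need at least as many observations as components",
                  call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    xb <- x[sample.int(n, n, replace = TRUE)]
    fit <- tryCatch(
      em_fit_fixed_means(xb, means = means, sigma_bounds = sigma_bounds,
                         labels = labels, ...),
      error = function(e) NULL)
    if (!is.null(fit)) {
      reps[[b]] <- tibble(replicate = b, component = seq_len(K),
                          weight = fit$weights, sigma = fit$sigmas)
    }
  }
  ok <- !vapply(reps, is.null, logical(1L))
  if (any(!ok)) {
    warning(sum(!ok), " bootstrap replicate(s) failed to fit and were ",
            "dropped", call. = FALSE)
  }
  if (mean(!ok) > 0.10) {
    stop("more than 10% of bootstrap replicates failed to fit",
         call. = FALSE)
  }
  rep_tbl <- bind_rows(reps[ok])
  agg <- rep_tbl |>
    group_by(.data$component) |>
    summarise(weight = mean(.data$weight), sigma = mean(.data$sigma),
              .groups = "drop")
  w <- agg$weight / sum(agg$weight)
  model <- gmm_model(means = means, weights = w, sigmas = agg$sigma,
                     sigma_bounds = sigma_bounds, labels = labels)
  model$n <- n
  model$bootstrap <- list(B = B, B_ok = sum(ok), seed = seed,
                          renormalized = TRUE, replicates = rep_tbl)
  model
}

#' Classify samples into discrete copy-number bins
#'
#' Posterior membership of each value under the mixture:
#' `post_k(x) = psi_k N(x; u_k, sigma_k) / sum_j psi_j N(x; u_j, sigma_j)`,
#' evaluated in log space so extreme values never underflow to an error.
#' Each sample is assigned the maximum-a-posteriori component; posterior
#' ties (within 1e-9) break toward the lower mean.
#'
#' @param data cohort data frame (or numeric vector) of estimates.
#' @param model a fitted `dj_gmm`.
#' @param col bare column name holding the estimates (default `cn`).
#' @return The input as a tibble with appended columns `component`, `bin`
#'   (component label), `map_prob` and one `post_<label>` column per
#'   component (posteriors sum to 1 per row).
#' @export
classify_samples <- function(data, model, col = cn) {
  stopifnot(inherits(model, "dj_gmm"))
  x <- extract_cn(data, {{ col }})
  e <- gmm_logdens(x, model)
  lp <- e$ld - e$lse
  post <- exp(lp)
  comp <- apply(lp, 1L, function(row) {
    cand <- which(row >= max(row) - 1e-9)
    cand[1L] # means ascending: ties go to the lower mean
  })
  out <- if (is.data.frame(data)) as_tibble(data) else tibble(cn = x)
  out$component <- as.integer(comp)
  out$bin <- model$labels[comp]
  out$map_prob <- post[cbind(seq_along(x), comp)]
  pn <- paste0("post_", gsub("[^0-9A-Za-z]+", "_", model$labels))
  for (k in seq_along(pn)) out[[pn[k]]] <- post[, k]
  out
}

#' @rdname classify_samples
#' @param x numeric vector of copy-number values.
#' @export
classify_sample <- function(x, model) classify_samples(x, model)

#' Candidate component means from peaks consistent across cohorts
#'
#' Bins each cohort's copy-number values (bin width 0.1 by default), finds
#' local maxima with at least `min_prominence` counts of prominence, and
#' keeps the peak locations found (within `tolerance`) in *every* cohort.
#' A single cohort trivially satisfies consistency with itself.
#'
#' @param cohorts list of numeric vectors (or data frames with a `cn`
#'   column), one per cohort; each ideally from at least 100 samples.
#' @param tolerance maximum distance between matched peaks (default 0.1).
#' @param binwidth histogram bin width (default 0.1).
#' @param min_prominence minimum peak prominence in counts; default
#'   `max(3, 0.005 * n)` per cohort.
#' @return Sorted numeric vector of consistent peak positions (mean of the
#'   matched positions across cohorts).
#' @export
find_consistent_peaks <- function(cohorts, tolerance = 0.1, binwidth = 0.1,
                                  min_prominence = NULL) {
  vals <- lapply(cohorts, function(d) if (is.data.frame(d)) d$cn else d)
  if (length(vals) == 0L) stop("no cohorts supplied", call. = FALSE)
  if (any(lengths(vals) < 100L)) {
    warning("peak finding on cohorts with fewer than 100 samples is ",
            "unreliable", call. = FALSE)
  }
  peak_set <- lapply(vals, function(v) {
    brk <- seq(floor(min(v) / binwidth) * binwidth - binwidth,
               ceiling(max(v) / binwidth) * binwidth + binwidth,
               by = binwidth)
    h <- graphics::hist(v, breaks = brk, plot = FALSE)
    y <- h$counts
    prom <- min_prominence %||% max(3, 0.005 * length(v))
    n <- length(y)
    if (n < 3L) return(numeric())
    idx <- 2:(n - 1L)
    cand <- idx[y[idx] > y[idx - 1L] & y[idx] >= y[idx + 1L]]
    keep <- vapply(cand, function(i) {
      left <- min(y[1:i])
      right <- min(y[i:n])
      y[i] - max(left, right) >= prom
    }, logical(1L))
    h$mids[cand[keep]]
  })
  ref <- peak_set[[1L]]
  consistent <- vapply(ref, function(p) {
    all(vapply(peak_set, function(ps) {
      length(ps) > 0 && min(abs(ps - p)) <= tolerance
    }, logical(1L)))
  }, logical(1L))
  if (!any(consistent)) {
    stop("no peaks are consistent across cohorts; consider the fixed ",
         "default means dj_default_means()", call. = FALSE)
  }
  pos <- vapply(ref[consistent], function(p) {
    mean(vapply(peak_set, function(ps) ps[which.min(abs(ps - p))],
                numeric(1L)))
  }, numeric(1L))
  sort(unname(pos))
}

#' Serialize / restore a mixture model as JSON
#' @param model a `dj_gmm`.
#' @param path JSON file path.
#' @export
write_gmm <- function(model, path) {
  stopifnot(inherits(model, "dj_gmm"))
  obj <- list(means = model$means, weights = model$weights,
              sigmas = model$sigmas, sigma_bounds = model$sigma_bounds,
              labels = model$labels, n = model$n,
              B = model$bootstrap$B, seed = model$bootstrap$seed,
              renormalized = model$bootstrap$renormalized)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- gmm_model(means = obj$means, weights = obj$weights,
                     sigmas = obj$sigmas, sigma_bounds = obj$sigma_bounds,
                     labels = obj$labels)
  model$n <- obj$n
  if (!is.null(obj$B)) {
    model$bootstrap <- list(B = obj$B, B_ok = NA_integer_, seed = obj$seed,
                            renormalized = isTRUE(obj$renormalized),
                            replicates = NULL)
  }
  model
}
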