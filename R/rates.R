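#' Per-haplotype event rate from a cohort frequency
#'
#' Under the assumption that the 10 acrocentric haplotypes of a diploid
#' genome gain or lose a DJ independently, a cohort frequency `f` of
#' single-event genomes (one DJ lost, i.e. 9 copies; or one or more gained)
#' implies a per-haplotype event probability `p = 1 - (1 - f)^(1/n)`.
#' Computed via `log1p`/`expm1` to keep precision at small `f`.
#'
#' @param f cohort frequency in `[0, 1)`.
#' @param n independent haplotypes per genome (default 10).
#' @return Per-haplotype probability.
#' @examples
#' per_haplotype_rate(0.031) # ~0.0031
#' per_haplotype_rate(0.089) # ~0.0093
#' @export
per_haplotype_rate <- function(f, n = 10) {
  if (any(f < 0 | f >= 1)) {
    stop("cohort frequency must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(n >= 1)
  -expm1(log1p(-f) / n)
}

#' False-positive rate of 8-DJ screening
#'
#' Probability that exactly `k` of `n` independent acrocentric haplotypes
#' each lack a DJ with probability `p` — a genome mimicking the 8-DJ
#' carrier signature through two coincident single-haplotype deletions
#' rather than a fusion: `C(n, k) p^k (1 - p)^(n - k)`.
#'
#' @param p per-haplotype DJ-deletion probability.
#' @param n haplotypes per genome (default 10).
#' @param k coincident deletions mimicking a carrier (default 2).
#' @return Probability.
#' @examples
#' fp_rate(per_haplotype_rate(0.031)) # ~4e-4, i.e. ~0.04% of samples
#' @export
fp_rate <- function(p, n = 10, k = 2) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (k > n) stop("k cannot exceed n", call. = FALSE)
  choose(n, k) * p^k * (1 - p)^(n - k)
}

#' False-negative rate of 8-DJ screening
#'
#' Probability that a true carrier harbors at least one duplicated DJ among
#' its `m` unaffected acrocentric haplotypes — pushing the total above 8 and
#' masking the fusion: `1 - (1 - p_dup)^m`.
#'
#' @param p_dup per-haplotype DJ-duplication probability.
#' @param m unaffected acrocentric haplotypes in a carrier (default 8).
#' @return Probability.
#' @examples
#' fn_rate(per_haplotype_rate(0.089)) # ~0.072
#' @export
fn_rate <- function(p_dup, m = 8) {
  if (any(p_dup < 0 | p_dup > 1)) stop("p_dup must lie in [0, 1]",
                                       call. = FALSE)
  stopifnot(m >= 0)
  -expm1(m * log1p(-p_dup))
}

#' End-to-end screening-rate report
#'
#' Converts cohort frequencies of DJ loss (9-copy genomes) and gain
#' (>10-copy genomes) into per-haplotype rates, the screening
#' false-positive rate (two coincident deletions mimicking a carrier) and
#' false-negative rate (a duplication masking a carrier). When the observed
#' 8-DJ cohort frequency is supplied, the report also gives the fraction of
#' observed 8-DJ calls attributable to coincident deletions (capped at 1
#' with a warning).
#'
#' @param f_loss cohort frequency of 9-DJ genomes.
#' @param f_gain cohort frequency of genomes with one or more gained DJs.
#' @param f_obs_8dj optional observed cohort frequency of 8-DJ genomes.
#' @param n_haplotypes acrocentric haplotypes per genome (default 10).
#' @param k_fp coincident deletions mimicking a carrier (default 2).
#' @param m_unaffected unaffected haplotypes in a carrier (default 8).
#' @return One-row tibble: `f_loss`, `f_gain`, `p_del`, `p_dup`, `fp_rate`,
#'   `fn_rate`, and `fp_fraction_of_8dj` when `f_obs_8dj` is given.
#' @examples
#' rob_rates(0.031, 0.089, f_obs_8dj = 0.0012)
#' @export
rob_rates <- function(f_loss, f_gain, f_obs_8dj = NULL,
                      n_haplotypes = 10, k_fp = 2, m_unaffected = 8) {
  p_del <- per_haplotype_rate(f_loss, n_haplotypes)
  p_dup <- per_haplotype_rate(f_gain, n_haplotypes)
  fp <- fp_rate(p_del, n_haplotypes, k_fp)
  fn <- fn_rate(p_dup, m_unaffected)
  out <- tibble(f_loss = f_loss, f_gain = f_gain,
                p_del = p_del, p_dup = p_dup,
                fp_rate = fp, fn_rate = fn)
  if (!is.null(f_obs_8dj)) {
    frac <- fp / f_obs_8dj
    if (frac > 1) {
      warning("estimated false positives exceed the observed 8-DJ ",
              "frequency; fraction capped at 1", call. = FALSE)
      frac <- 1
    }
    out$fp_fraction_of_8dj <- frac
  }
  out
}
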