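# numerically safe log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Weighted median under the strict cumulative-count rule
#'
#' Returns the smallest value whose cumulative multiplicity strictly exceeds
#' half of the total multiplicity. This is the histogram-median convention
#' used for k-mer multiplicity spectra throughout the package; it differs
#' from the conventional average-of-two-central-values median (used here for
#' per-base depth tracks, see [depth_median()]) whenever the cumulative count
#' lands exactly on the half-total.
#'
#' @param values numeric vector of distinct values (need not be sorted).
#' @param counts non-negative multiplicities, same length as `values`.
#' @return A single numeric value.
#' @examples
#' weighted_median(c(5, 10, 20), c(3, 4, 3)) # 10
#' weighted_median(c(1, 9), c(5, 5))         # 9, not 5
#' @export
weighted_median <- function(values, counts) {
  if (length(values) != length(counts)) {
    stop("`values` and `counts` must have the same length", call. = FALSE)
  }
  keep <- counts > 0
  values <- values[keep]
  counts <- counts[keep]
  if (length(values) == 0L) {
    stop("weighted_median() needs at least one value with positive count",
         call. = FALSE)
  }
  ord <- order(values)
  v <- values[ord]
  cum <- cumsum(counts[ord])
  v[which(cum > cum[length(cum)] / 2)[1L]]
}

#' Median of a per-base depth track
#'
#' Depth tracks are stored as the depths of *covered* positions only,
#' mirroring the default output of `samtools depth` (zero-depth positions are
#' omitted). Set `include_zero = TRUE` to pad the track with zeros up to the
#' full region length before taking the median.
#'
#' @param depths numeric vector of per-base depths at covered positions.
#' @param region_length total number of bases in the region.
#' @param include_zero include zero-depth positions in the median?
#' @return Median depth (conventional median: mean of the two central values
#'   on even counts).
#' @export
depth_median <- function(depths, region_length = length(depths),
                         include_zero = FALSE) {
  if (include_zero) {
    if (region_length < length(depths)) {
      stop("`region_length` is smaller than the number of covered positions",
           call. = FALSE)
    }
    pad <- region_length - length(depths)
    if (pad > 0) depths <- c(depths, rep(0, pad))
  }
  if (length(depths) == 0L) {
    stop("empty depth track: no covered positions", call. = FALSE)
  }
  stats::median(depths)
}
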