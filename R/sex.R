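#' Infer sex-chromosome complement from X/Y coverage
#'
#' Computes per-chromosome coverage as mapped reads divided by chromosome
#' length and classifies a sample as XX when `covX/covY` exceeds the
#' threshold (default 4) or Y coverage is exactly zero, and XY otherwise.
#' The call determines which sex-chromosome-complement (SCC) masked
#' reference variant downstream alignment should use: Y-masked for XX,
#' PAR-masked-Y for XY.
#'
#' @param data per-chromosome statistics: a data frame with columns
#'   `seqname`, `length`, `mapped` (e.g. `chrom_stats(summary)`), or a
#'   `dj_alignment_summary`.
#' @param x_name,y_name sequence names of the X and Y chromosomes.
#' @param threshold `covX/covY` ratio above which the call is XX.
#' @param sample optional sample label carried into the output.
#' @return One-row tibble with `sample`, `cov_x`, `cov_y`, `ratio`, `call`.
#' @examples
#' stats <- data.frame(seqname = c("chrX", "chrY"),
#'                     length = c(1e6, 5e5),
#'                     mapped = c(50000, 2500))
#' infer_sex(stats) # ratio 10 -> XX
#' @export
infer_sex <- function(data, x_name = "chrX", y_name = "chrY", threshold = 4,
                      sample = NA_character_) {
  if (inherits(data, "dj_alignment_summary")) {
    if (is.na(sample)) sample <- data$sample
    data <- data$chrom_stats
  }
  tbl <- as_tibble(data)
  stopifnot(all(c("seqname", "length", "mapped") %in% names(tbl)))
  get_cov <- function(nm) {
    row <- tbl[tbl$seqname == nm, ]
    if (nrow(row) != 1L) {
      stop("missing (or duplicated) entry for sequence '", nm,
           "' in the per-chromosome statistics", call. = FALSE)
    }
    row$mapped / row$length
  }
  cov_x <- get_cov(x_name)
  cov_y <- get_cov(y_name)
  ratio <- if (cov_y == 0) Inf else cov_x / cov_y
  call <- if (cov_y == 0 || ratio > threshold) "XX" else "XY"
  tibble(sample = sample, cov_x = cov_x, cov_y = cov_y,
         ratio = ratio, call = call)
}
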