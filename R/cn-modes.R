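#' Mapping-based copy-number estimation modes
#'
#' All modes estimate the diploid copy number of a target region as twice
#' the ratio of target coverage to autosomal background coverage; they
#' differ in how each coverage is measured:
#'
#' * `chm13_highres` — per-base depth medians: `2 * median(Depth_T) /
#'   median(Depth_B)` over target and background depth tracks.
#' * `pilot_fast` — raw index counts: `2 * (RC_T/Len_T) /
#'   ((sum RC_A - RU_A)/Len_A)`.
#' * `fast` — raw counts, median per-autosome coverage background:
#'   `2 * (RC_T/Len_T) / median(RC_C/Len_C)`.
#' * `fast_precise` — filtered counts (duplicates, secondary and
#'   supplementary records excluded), total-autosome background:
#'   `2 * (FRC_T/Len_T) / (FRC_A/Len_A)`.
#' * `fast_refine` — filtered counts, median per-autosome background:
#'   `2 * (FRC_T/Len_T) / median(FRC_C/Len_C)`.
#' * `grch38_highres` — per-base target depth, median per-autosome mean
#'   coverage background: `2 * (sum Depth_T/Len_T) / median(Cov_C)`.
#'
#' Depth medians are taken over covered positions only by default
#' (`include_zero = FALSE`), matching a depth track piped from
#' `samtools depth` without the all-positions flag; set
#' `include_zero = TRUE` to count zero-depth positions. A zero background
#' anywhere is a hard error, never a silent `NaN`.
#'
#' @param summary a `dj_alignment_summary`.
#' @param include_zero include zero-depth positions in depth medians?
#' @return The continuous diploid copy-number estimate (numeric scalar).
#' @seealso [estimate_copy_number()] for the tibble-returning front end.
#' @name cn_modes
NULL

autosome_stats <- function(summary) {
  cs <- summary$chrom_stats
  auto <- cs[cs$seqname %in% summary$autosomes, , drop = FALSE]
  if (nrow(auto) == 0L || all(auto$length <= 0)) {
    stop("no autosomes with positive length in the alignment summary",
         call. = FALSE)
  }
  auto
}

check_len_t <- function(summary) {
  lt <- summary$target_length
  if (is.null(lt) || !is.finite(lt) || lt <= 0) {
    stop("target length Len_T must be a positive number", call. = FALSE)
  }
  lt
}

check_pos <- function(x, what) {
  if (!is.finite(x) || x <= 0) {
    stop("undefined estimate: ", what, " is zero or missing", call. = FALSE)
  }
  x
}

#' @rdname cn_modes
#' @export
cn_highres_chm13 <- function(summary, include_zero = FALSE) {
  if (is.null(summary$target_depth) || is.null(summary$background_depth)) {
    stop("chm13_highres mode needs target and background depth tracks",
         call. = FALSE)
  }
  med_t <- depth_median(summary$target_depth,
                        region_length = check_len_t(summary),
                        include_zero = include_zero)
  med_b <- depth_median(summary$background_depth,
                        region_length = summary$background_length %||%
                          length(summary$background_depth),
                        include_zero = include_zero)
  2 * med_t / check_pos(med_b, "background median depth")
}

#' @rdname cn_modes
#' @export
cn_pilot_fast <- function(summary) {
  auto <- autosome_stats(summary)
  lt <- check_len_t(summary)
  len_a <- sum(auto$length)
  bg <- (sum(auto$mapped) - sum(auto$unmapped)) / len_a
  2 * (summary$target_rc / lt) / check_pos(bg, "autosomal background")
}

#' @rdname cn_modes
#' @export
cn_fast <- function(summary) {
  auto <- autosome_stats(summary)
  lt <- check_len_t(summary)
  bg <- stats::median(auto$mapped / auto$length)
  2 * (summary$target_rc / lt) / check_pos(bg, "median autosome coverage")
}

#' @rdname cn_modes
#' @export
cn_fast_precise <- function(summary) {
  auto <- autosome_stats(summary)
  if (anyNA(auto$filtered_mapped)) {
    stop("fast_precise mode needs filtered per-autosome read counts",
         call. = FALSE)
  }
  lt <- check_len_t(summary)
  bg <- sum(auto$filtered_mapped) / sum(auto$length)
  2 * (summary$target_frc / lt) /
    check_pos(bg, "filtered autosomal background")
}

#' @rdname cn_modes
#' @export
cn_fast_refine <- function(summary) {
  auto <- autosome_stats(summary)
  if (anyNA(auto$filtered_mapped)) {
    stop("fast_refine mode needs filtered per-autosome read counts",
         call. = FALSE)
  }
  lt <- check_len_t(summary)
  bg <- stats::median(auto$filtered_mapped / auto$length)
  2 * (summary$target_frc / lt) /
    check_pos(bg, "median filtered autosome coverage")
}

#' @rdname cn_modes
#' @export
cn_highres_grch38 <- function(summary) {
  if (is.null(summary$target_depth) || is.null(summary$autosome_coverage)) {
    stop("grch38_highres mode needs a target depth track and per-autosome ",
         "coverage summaries", call. = FALSE)
  }
  lt <- check_len_t(summary)
  bg <- stats::median(summary$autosome_coverage$mean_depth)
  2 * (sum(summary$target_depth) / lt) /
    check_pos(bg, "median autosome mean coverage")
}

#' Bin a continuous copy-number estimate
#'
#' The default rule assigns the nearest integer, with ties at `.5` rounding
#' up (8.16 -> 8, 8.88 -> 9, 9.5 -> 10). The `"dj_threshold"` rule is
#' identical except that the boundary between bins 10 and 11 sits at 10.4
#' (estimates below 10.4 bin to at most 10), reflecting the empirical gap
#' between the 10-copy bulk and the partial-duplication shoulder of the DJ
#' distribution. Both rules agree everywhere outside (10.4, 10.5).
#'
#' @param value numeric vector of non-negative copy-number estimates.
#' @param rule `"nearest"` (default) or `"dj_threshold"`.
#' @return Integer vector of bins.
#' @examples
#' bin_copy_number(c(8.16, 8.88, 10.09, 9.5)) # 8 9 10 10
#' bin_copy_number(10.45)                     # 10
#' bin_copy_number(10.45, rule = "dj_threshold") # 11
#' @export
bin_copy_number <- function(value, rule = c("nearest", "dj_threshold")) {
  rule <- match.arg(rule)
  stopifnot(all(is.finite(value)))
  bin <- as.integer(floor(value + 0.5)) # ties at .5 round up
  if (rule == "dj_threshold") {
    lo <- value > 10 & value <= 10.4
    hi <- value > 10.4 & value < 10.5
    bin[lo] <- 10L
    bin[hi] <- 11L
  }
  bin
}

cn_mode_funs <- list(
  chm13_highres = cn_highres_chm13,
  pilot_fast = cn_pilot_fast,
  fast = cn_fast,
  fast_precise = cn_fast_precise,
  fast_refine = cn_fast_refine,
  grch38_highres = cn_highres_grch38
)

#' Estimate target copy number under one or more modes
#'
#' Tibble-returning front end over the individual [cn_modes] estimators.
#'
#' @param summary a `dj_alignment_summary`.
#' @param mode character vector of modes among `chm13_highres`,
#'   `pilot_fast`, `fast`, `fast_precise`, `fast_refine`, `grch38_highres`.
#' @param rule binning rule passed to [bin_copy_number()].
#' @param include_zero passed to `chm13_highres` (depth medians).
#' @return Tibble with columns `sample`, `target`, `mode`, `cn`, `bin`.
#' @export
estimate_copy_number <- function(summary,
                                 mode = names(cn_mode_funs),
                                 rule = c("nearest", "dj_threshold"),
                                 include_zero = FALSE) {
  rule <- match.arg(rule)
  mode <- match.arg(mode, names(cn_mode_funs), several.ok = TRUE)
  cn <- vapply(mode, function(m) {
    if (m == "chm13_highres") cn_highres_chm13(summary, include_zero)
    else cn_mode_funs[[m]](summary)
  }, numeric(1L))
  tibble(sample = summary$sample,
         target = summary$target_name,
         mode = mode,
         cn = unname(cn),
         bin = bin_copy_number(unname(cn), rule = rule))
}
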