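# summaries built directly from tables so every formula is checked by
# hand-computable arithmetic
mk_summary <- function(lengths, mapped, unmapped = rep(0, length(mapped)),
                       filtered = NULL, ...) {
  cs <- tibble::tibble(seqname = paste0("chr", seq_along(lengths)),
                       length = lengths, mapped = mapped,
                       unmapped = unmapped)
  if (!is.null(filtered)) cs$filtered_mapped <- filtered
  alignment_summary(cs, ...)
}

test_that("cn_pilot_fast matches the index-count formula", {
  s <- mk_summary(lengths = 1e8, mapped = 1.01e6, unmapped = 1e4,
                  target_length = 10000, target_rc = 500)
  # 2 * (500/10000) / ((1010000 - 10000)/1e8) = 2 * 0.05 / 0.01 = 10
  expect_equal(cn_pilot_fast(s), 10)
})

test_that("cn_fast uses the median per-autosome coverage", {
  s <- mk_summary(lengths = rep(1e6, 3), mapped = c(9000, 10000, 11000),
                  target_length = 10000, target_rc = 500)
  # background = median(0.009, 0.010, 0.011) = 0.01 -> CN 10
  expect_equal(cn_fast(s), 10)
  # median is robust: one outlier autosome leaves the estimate unchanged
  s2 <- mk_summary(lengths = rep(1e6, 3), mapped = c(9000, 10000, 90000),
                   target_length = 10000, target_rc = 500)
  expect_equal(cn_fast(s2), 10)
})

test_that("cn_fast_precise and cn_fast_refine use filtered counts", {
  s <- mk_summary(lengths = rep(1e6, 4),
                  mapped = c(12000, 13000, 12500, 12500),
                  filtered = c(9000, 10000, 11000, 10000),
                  target_length = 10000, target_rc = 999, target_frc = 500)
  # precise: background = 40000/4e6 = 0.01 -> 10
  expect_equal(cn_fast_precise(s), 10)
  # refine: background = median(0.009, 0.010, 0.011, 0.010) = 0.01 -> 10
  expect_equal(cn_fast_refine(s), 10)
  s$chrom_stats$filtered_mapped <- NA_real_
  expect_error(cn_fast_precise(s), "filtered")
  expect_error(cn_fast_refine(s), "filtered")
})

test_that("depth-based modes match their median/mean formulas", {
  s <- mk_summary(lengths = 1e6, mapped = 1e4,
                  target_length = 5, target_rc = 100,
                  target_depth = c(10, 12, 14, 16, 100),
                  background_depth = c(2, 3, 4),
                  background_length = 3,
                  autosome_coverage = tibble::tibble(
                    seqname = paste0("chr", 1:3),
                    mean_depth = c(2.8, 3.0, 3.2)))
  # chm13: 2 * median(10,12,14,16,100) / median(2,3,4) = 2*14/3
  expect_equal(cn_highres_chm13(s), 28 / 3)
  # grch38: 2 * (sum depth / Len_T) / median mean coverage
  expect_equal(cn_highres_grch38(s), 2 * (152 / 5) / 3)
})

test_that("include_zero pads depth tracks before the median", {
  s <- mk_summary(lengths = 1e6, mapped = 1e4,
                  target_length = 6, target_rc = 1,
                  target_depth = c(10, 10, 10, 10),
                  background_depth = c(2, 2, 2),
                  background_length = 3)
  expect_equal(cn_highres_chm13(s), 10)
  # 6-long target track pads to (10,10,10,10,0,0) -> median 10 still,
  # 4-long with region 8 pads to half zeros -> median 5
  s$target_length <- 8
  expect_equal(cn_highres_chm13(s, include_zero = TRUE), 5)
})

test_that("a uniform genome yields CN exactly 2", {
  # target behaves exactly like the diploid baseline; each mode's own
  # target/background pair is made exactly consistent
  s <- mk_summary(lengths = rep(1e6, 3), mapped = rep(10000, 3),
                  filtered = rep(10000, 3),
                  target_length = 50000, target_rc = 500, target_frc = 500,
                  target_depth = rep(3, 10),
                  background_depth = rep(3, 10), background_length = 10,
                  autosome_coverage = tibble::tibble(
                    seqname = paste0("chr", 1:3),
                    mean_depth = rep(30 / 50000, 3)))
  est <- estimate_copy_number(s)
  expect_equal(est$cn, rep(2, 6), tolerance = 1e-12)
  expect_equal(est$bin, rep(2L, 6))
  expect_equal(est$mode, c("chm13_highres", "pilot_fast", "fast",
                           "fast_precise", "fast_refine", "grch38_highres"))
})

test_that("all modes are invariant to a global coverage rescaling", {
  base <- function(f) mk_summary(
    lengths = rep(1e6, 3), mapped = f * c(9000, 10000, 11000),
    filtered = f * c(8000, 9500, 10500),
    target_length = 10000, target_rc = f * 480, target_frc = f * 450,
    target_depth = f * c(28, 30, 32),
    background_depth = f * c(5, 6, 7), background_length = 3,
    autosome_coverage = tibble::tibble(seqname = paste0("chr", 1:3),
                                       mean_depth = f * c(5.5, 6, 6.5)))
  e1 <- estimate_copy_number(base(1))
  e3 <- estimate_copy_number(base(3))
  expect_equal(e1$cn, e3$cn, tolerance = 1e-12)
})

test_that("fast and fast_refine coincide when nothing is flag-filtered", {
  s <- mk_summary(lengths = rep(1e6, 3), mapped = c(9000, 10000, 11000),
                  filtered = c(9000, 10000, 11000),
                  target_length = 10000, target_rc = 480, target_frc = 480)
  expect_equal(cn_fast(s), cn_fast_refine(s))
})

test_that("zero background is a hard error, never NaN", {
  s <- mk_summary(lengths = rep(1e6, 3), mapped = rep(0, 3),
                  filtered = rep(0, 3),
                  target_length = 1000, target_rc = 10, target_frc = 10)
  expect_error(cn_pilot_fast(s), "zero or missing")
  expect_error(cn_fast(s), "zero or missing")
  expect_error(cn_fast_precise(s), "zero or missing")
  expect_error(cn_fast_refine(s), "zero or missing")
})

test_that("missing Len_T or autosomes raise informative errors", {
  s <- mk_summary(lengths = 1e6, mapped = 1e4, target_rc = 10)
  expect_error(cn_fast(s), "Len_T")
  s2 <- alignment_summary(
    tibble::tibble(seqname = "weird_contig", length = 1e6,
                   mapped = 1e4, unmapped = 0),
    target_length = 100, target_rc = 10)
  expect_error(cn_fast(s2), "no autosomes")
})

test_that("bin_copy_number reproduces the printed binning conventions", {
  expect_equal(bin_copy_number(c(8.16, 8.88, 10.09, 9.5)), c(8L, 9L, 10L, 10L))
  expect_equal(bin_copy_number(10.45), 10L)
  expect_equal(bin_copy_number(10.45, rule = "dj_threshold"), 11L)
  # the two rules agree everywhere outside (10.4, 10.5)
  x <- seq(0, 15, by = 0.01)
  x <- x[x <= 10.4 | x >= 10.5]
  expect_equal(bin_copy_number(x), bin_copy_number(x, rule = "dj_threshold"))
  expect_equal(bin_copy_number(c(10.41, 10.2), rule = "dj_threshold"),
               c(11L, 10L))
  expect_error(bin_copy_number(NaN), "is.finite")
})

test_that("alignment_summary rejects inconsistent counts", {
  cs <- tibble::tibble(seqname = "chr1", length = 1e6,
                       mapped = 100, unmapped = 0, filtered_mapped = 200)
  expect_error(alignment_summary(cs), "filtered_mapped exceeds mapped")
  cs2 <- tibble::tibble(seqname = "chr1", length = 1e6,
                        mapped = -1, unmapped = 0)
  expect_error(alignment_summary(cs2), "non-negative")
})

test_that("read_filter validates the flag mask", {
  f <- read_filter()
  expect_equal(f$flag_mask, 3332L)
  expect_setequal(f$bits, c(4L, 256L, 1024L, 2048L))
  expect_error(read_filter(3), "supported SAM flag bits")
  expect_equal(read_filter(4L + 512L)$bits, c(4L, 512L))
})
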