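test_that("mask_reference hard-masks exactly the given intervals", {
  seqs <- Biostrings::DNAStringSet(c(s1 = "ACGTACGT", s2 = "TTTTTTTT"))
  mask <- data.frame(seqname = "s1", start = 2, end = 6)
  out <- mask_reference(seqs, mask)
  expect_equal(as.character(out[["s1"]]), "ACNNNNGT")
  expect_equal(as.character(out[["s2"]]), "TTTTTTTT")
  expect_equal(Biostrings::width(out), Biostrings::width(seqs))
})

test_that("masking is idempotent and handles multiple/overlapping intervals", {
  seqs <- Biostrings::DNAStringSet(c(s1 = "ACGTACGTACGT"))
  mask <- data.frame(seqname = "s1", start = c(0, 2, 8), end = c(3, 5, 12))
  once <- mask_reference(seqs, mask)
  twice <- mask_reference(once, mask)
  expect_equal(as.character(once[["s1"]]), "NNNNNCGTNNNN")
  expect_identical(as.character(twice), as.character(once))
})

test_that("mask_reference rejects bad coordinates with clear errors", {
  seqs <- Biostrings::DNAStringSet(c(s1 = "ACGT"))
  expect_error(mask_reference(seqs, data.frame(seqname = "nope",
                                               start = 0, end = 2)),
               "unknown sequence: nope")
  expect_error(mask_reference(seqs, data.frame(seqname = "s1",
                                               start = 1, end = 9)),
               "s1:1-9")
})

test_that("target_regions validates, merges and carries Len_T", {
  tr <- target_regions(
    data.frame(seqname = "chr13", start = c(0, 50, 200), end = c(60, 100, 300)),
    name = "DJ", reference = "chm13")
  expect_s3_class(tr, "dj_regions")
  expect_equal(nrow(tr), 2L)         # 0-60 and 50-100 merge
  expect_equal(tr$start, c(0, 200))
  expect_equal(tr$end, c(100, 300))
  expect_equal(region_target_length(tr), 200)
  expect_equal(region_name(tr), "DJ")
  # external Len_T override survives
  tr2 <- target_regions(data.frame(seqname = "c", start = 0, end = 10),
                        target_length = 340000)
  expect_equal(region_target_length(tr2), 340000)
  expect_error(target_regions(data.frame(seqname = "c", start = 5, end = 5)),
               "start < end")
  expect_error(
    target_regions(data.frame(seqname = "c", start = 0, end = 100),
                   seq_lengths = c(c = 50)),
    "beyond sequence end")
})

test_that("merge_intervals conserves covered bases and honours gap", {
  iv <- data.frame(seqname = c("a", "a", "a", "b"),
                   start = c(0, 10, 30, 0), end = c(10, 20, 40, 5))
  m0 <- merge_intervals(iv, gap = 0)
  expect_equal(m0$start, c(0, 30, 0))
  expect_equal(m0$end, c(20, 40, 5))
  expect_equal(sum(m0$end - m0$start), sum(iv$end - iv$start))
  m10 <- merge_intervals(iv, gap = 10)
  expect_equal(m10[m10$seqname == "a", ]$start, 0)
  expect_equal(m10[m10$seqname == "a", ]$end, 40)
})

test_that("BED round trip preserves 0-based half-open intervals", {
  tr <- target_regions(data.frame(seqname = c("chr13", "chr21"),
                                  start = c(100, 0), end = c(250, 75)),
                       name = "DJ")
  path <- tempfile(fileext = ".bed")
  write_bed(tr, path)
  lines <- readLines(path)
  expect_equal(length(lines), 2L)
  expect_match(lines[1], "^chr13\t100\t250")
  back <- read_bed(path, name = "DJ")
  expect_equal(back$seqname, tr$seqname)
  expect_equal(back$start, tr$start)
  expect_equal(back$end, tr$end)
  expect_equal(region_target_length(back), region_target_length(tr))
})

test_that("regions_as_granges converts BED to 1-based closed", {
  gr <- regions_as_granges(data.frame(seqname = "c", start = 0, end = 10))
  expect_equal(GenomicRanges::start(gr), 1L)
  expect_equal(GenomicRanges::end(gr), 10L)
  expect_equal(GenomicRanges::width(gr), 10L)
})

test_that("read_paf parses mandatory columns and validates records", {
  path <- tempfile(fileext = ".paf")
  writeLines(c(
    paste(c("q1", 1000, 0, 900, "+", "t1", 5000, 100, 1000, 850, 920, 60),
          collapse = "\t"),
    paste(c("q2", 2000, 100, 1500, "-", "t1", 5000, 0, 1400, 1200, 1450, 60,
            "tp:A:P"), collapse = "\t")
  ), path)
  rec <- read_paf(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$query_name, c("q1", "q2"))
  expect_equal(rec$matching_bases, c(850, 1200))
  expect_equal(rec$strand, c("+", "-"))
  # invalid record: matching > block
  writeLines(paste(c("q", 100, 0, 50, "+", "t", 100, 0, 50, 60, 50, 0),
                   collapse = "\t"), path)
  expect_error(read_paf(path), "invalid PAF record")
  writeLines("q\t100\t0", path)
  expect_error(read_paf(path), "fewer than 12 fields")
  writeLines(character(), path)
  expect_equal(nrow(read_paf(path)), 0L)
})

test_that("filter_target_alignments applies length/identity/coverage rules", {
  rec <- tibble::tibble(
    query_name = c("q1", "q1", "q2", "q3"),
    query_length = c(5e4, 5e4, 3e4, 2e4),
    query_start = c(0, 15000, 0, 0),
    query_end = c(12000, 27000, 9999, 15000),
    strand = "+",
    target_name = "DJ", target_length = 20000,
    target_start = c(0, 0, 0, 0),
    target_end = c(12000, 12000, 9999, 15000),
    matching_bases = c(11900, 9000, 9900, 14000),
    block_length = c(12000, 12000, 9999, 15000),
    mapq = 60)
  out <- filter_target_alignments(rec, min_length_bp = 10000,
                                  min_identity_pct = 90,
                                  min_coverage_pct = 50)
  # q1/15000-27000 fails identity (75%); q2 fails length (9999 < 10000)
  # AND coverage (49.995% < 50%); q3 passes (identity 93.3, coverage 75)
  expect_equal(out$seqname, c("q1", "q3"))
  excl <- attr(out, "excluded")
  expect_equal(nrow(excl), 2L)
  expect_equal(excl$reason[excl$query_name == "q2"], "length,coverage")
  expect_equal(excl$reason[excl$query_start == 15000], "identity")
})

test_that("a 10 kbp block is kept at the default length threshold", {
  rec <- tibble::tibble(
    query_name = "q", query_length = 2e4, query_start = 0, query_end = 10000,
    strand = "+", target_name = "DJ", target_length = 10000,
    target_start = 0, target_end = 10000,
    matching_bases = 10000, block_length = 10000, mapq = 60)
  out <- filter_target_alignments(rec)
  expect_equal(nrow(out), 1L)
  short <- rec
  short$block_length <- 9999
  short$matching_bases <- 9999
  short$query_end <- 9999
  short$target_end <- 9999
  expect_warning(out2 <- filter_target_alignments(short), "no alignment")
  expect_equal(nrow(out2), 0L)
})

test_that("zero thresholds give the merged union of all records", {
  rec <- tibble::tibble(
    query_name = "q", query_length = 1e4,
    query_start = c(0, 400), query_end = c(500, 900),
    strand = "+", target_name = "DJ", target_length = 1000,
    target_start = 0, target_end = 1000,
    matching_bases = 400, block_length = 500, mapq = 60)
  out <- filter_target_alignments(rec, min_length_bp = 0)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(0, 900))
})

test_that("infer_sex classifies from X/Y coverage with the ratio rule", {
  stats <- data.frame(seqname = c("chrX", "chrY"),
                      length = c(1e6, 5e5), mapped = c(50000, 2500))
  out <- infer_sex(stats)
  expect_equal(out$call, "XX")     # ratio 10 > 4
  expect_equal(out$ratio, 10)
  xy <- data.frame(seqname = c("chrX", "chrY"),
                   length = c(1e6, 1e6), mapped = c(25000, 25000))
  expect_equal(infer_sex(xy)$call, "XY")  # ratio 1
  zero_y <- data.frame(seqname = c("chrX", "chrY"),
                       length = c(1e6, 1e6), mapped = c(25000, 0))
  out0 <- infer_sex(zero_y)
  expect_equal(out0$call, "XX")
  expect_equal(out0$ratio, Inf)
  # ratio exactly at threshold is not strictly greater -> XY
  at <- data.frame(seqname = c("chrX", "chrY"),
                   length = c(1e6, 1e6), mapped = c(40000, 10000))
  expect_equal(infer_sex(at)$call, "XY")
  expect_error(infer_sex(data.frame(seqname = "chrX", length = 1e6,
                                    mapped = 1)), "chrY")
})
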