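#' Read filter specification
#'
#' SAM-flag bitmask of records excluded from "filtered" read counts. The
#' default, 3332 = unmapped (4) + secondary (256) + duplicate (1024) +
#' supplementary (2048), matches `samtools view -c -F 3332` and is the
#' filter behind the Fast-precise and Fast-refine estimation modes.
#' Supported bits: 4, 256, 512 (QC fail), 1024, 2048.
#'
#' @param flag_mask integer sum of distinct SAM flag bits to exclude.
#' @param count_policy how a read overlapping several target intervals is
#'   counted: `"per-interval"` (once per overlapped interval, mirroring
#'   per-region `samtools view -c` calls) or `"unique"` (once per read).
#' @return A list of class `dj_read_filter`.
#' @export
read_filter <- function(flag_mask = 3332L,
                        count_policy = c("per-interval", "unique")) {
  count_policy <- match.arg(count_policy)
  known <- c(4L, 256L, 512L, 1024L, 2048L)
  bits <- known[bitwAnd(flag_mask, known) > 0L]
  if (sum(bits) != flag_mask) {
    stop("flag_mask must be a sum of the supported SAM flag bits ",
         "(4, 256, 512, 1024, 2048); got ", flag_mask, call. = FALSE)
  }
  structure(list(flag_mask = as.integer(flag_mask), bits = bits,
                 count_policy = count_policy),
            class = "dj_read_filter")
}

# translate excluded-bit mask into an Rsamtools scanBamFlag
mask_to_scanflag <- function(flag_mask) {
  args <- list()
  if (bitwAnd(flag_mask, 4L)) args$isUnmappedQuery <- FALSE
  if (bitwAnd(flag_mask, 256L)) args$isSecondaryAlignment <- FALSE
  if (bitwAnd(flag_mask, 512L)) args$isNotPassingQualityControls <- FALSE
  if (bitwAnd(flag_mask, 1024L)) args$isDuplicate <- FALSE
  if (bitwAnd(flag_mask, 2048L)) args$isSupplementaryAlignment <- FALSE
  do.call(Rsamtools::scanBamFlag, args)
}

# flag exclusion used for depth/coverage tracks, mirroring the default
# `-ff UNMAP,SECONDARY,QCFAIL,DUP` of samtools depth / coverage
depth_flag <- function() mask_to_scanflag(4L + 256L + 512L + 1024L)

default_autosomes <- function(seqnames) {
  seqnames[grepl("^(chr)?[0-9]+$", seqnames)]
}

#' Construct an alignment summary from per-chromosome statistics
#'
#' The alignment summary is the tabular container all mapping-based
#' copy-number modes operate on: per-sequence raw and filtered mapped read
#' counts, unmapped counts, target-restricted counts, per-base depth tracks
#' and per-autosome mean coverage. [summarize_alignments()] builds one from
#' a BAM file; this constructor builds one directly from tables (synthetic
#' data, precomputed index statistics, unit tests).
#'
#' @param chrom_stats tibble with columns `seqname`, `length`, `mapped`,
#'   `unmapped`, and optionally `filtered_mapped`.
#' @param autosomes character vector of autosome sequence names; defaults to
#'   names matching `^(chr)?[0-9]+$`.
#' @param target_name label of the target region set.
#' @param target_length canonical target length Len_T (bp).
#' @param target_rc,target_frc raw and filtered read counts over the target.
#' @param target_depth numeric vector of per-base depths at covered target
#'   positions.
#' @param background_depth per-base depths at covered background positions.
#' @param background_length total background length (bp), for zero-inclusive
#'   medians.
#' @param autosome_coverage tibble `seqname`, `mean_depth` (per-autosome mean
#'   coverage, the `samtools coverage` meandepth analogue).
#' @param sample sample label.
#' @return A list of class `dj_alignment_summary`.
#' @export
alignment_summary <- function(chrom_stats, autosomes = NULL,
                              target_name = "target",
                              target_length = NULL,
                              target_rc = NA_real_, target_frc = NA_real_,
                              target_depth = NULL,
                              background_depth = NULL,
                              background_length = NULL,
                              autosome_coverage = NULL,
                              sample = NA_character_) {
  cs <- as_tibble(chrom_stats)
  stopifnot(all(c("seqname", "length", "mapped", "unmapped") %in% names(cs)))
  if (!"filtered_mapped" %in% names(cs)) cs$filtered_mapped <- NA_real_
  bad <- !is.na(cs$filtered_mapped) & cs$filtered_mapped > cs$mapped
  if (any(bad)) {
    stop("filtered_mapped exceeds mapped for: ",
         paste(cs$seqname[bad], collapse = ", "), call. = FALSE)
  }
  if (any(cs$mapped < 0 | cs$unmapped < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  autosomes <- autosomes %||% default_autosomes(cs$seqname)
  structure(list(
    chrom_stats = cs,
    autosomes = autosomes,
    target_name = target_name,
    target_length = target_length,
    target_rc = target_rc,
    target_frc = target_frc,
    target_depth = target_depth,
    background_depth = background_depth,
    background_length = background_length,
    autosome_coverage = autosome_coverage,
    sample = sample
  ), class = "dj_alignment_summary")
}

#' @export
print.dj_alignment_summary <- function(x, ...) {
  cat("<dj_alignment_summary>", if (!is.na(x$sample)) x$sample else "", "\n")
  cat("  sequences:", nrow(x$chrom_stats),
      " autosomes:", length(x$autosomes), "\n")
  cat(sprintf("  target '%s': Len_T=%s RC_T=%s FRC_T=%s\n",
              x$target_name, format(x$target_length),
              format(x$target_rc), format(x$target_frc)))
  invisible(x)
}

#' @rdname alignment_summary
#' @param x a `dj_alignment_summary`.
#' @export
chrom_stats <- function(x) x$chrom_stats

#' Summarize a BAM file for copy-number estimation
#'
#' Collects everything the mapping-based estimators need from a
#' coordinate-sorted, indexed BAM: index statistics per sequence (mapped /
#' unmapped counts, mirroring `samtools idxstats`), filtered per-sequence
#' counts under the read filter, raw and filtered target read counts,
#' per-base depth over the target (and optional background) intervals, and
#' per-autosome mean coverage. Depth tracks exclude unmapped, secondary,
#' QC-fail and duplicate records, mirroring the defaults of
#' `samtools depth` / `samtools coverage`.
#'
#' @param bam path to an indexed BAM file.
#' @param targets target region set ([target_regions()]).
#' @param background optional background region set for per-base depth
#'   (high-resolution mode).
#' @param autosomes autosome names; defaults to `^(chr)?[0-9]+$` matches.
#' @param filter a [read_filter()].
#' @param compute_depth collect per-base depth and per-autosome coverage
#'   (needed by the two high-resolution modes)?
#' @param target_length canonical Len_T override; defaults to the region
#'   set's target length.
#' @param sample sample label (defaults to the BAM basename).
#' @return A `dj_alignment_summary`.
#' @export
summarize_alignments <- function(bam, targets, background = NULL,
                                 autosomes = NULL, filter = read_filter(),
                                 compute_depth = TRUE,
                                 target_length = NULL,
                                 sample = NULL) {
  bf <- Rsamtools::BamFile(bam)
  idx <- Rsamtools::idxstatsBam(bf)
  idx <- idx[idx$seqnames != "*", , drop = FALSE]
  cs <- tibble(seqname = as.character(idx$seqnames),
               length = as.numeric(idx$seqlength),
               mapped = as.numeric(idx$mapped),
               unmapped = as.numeric(idx$unmapped))
  autosomes <- autosomes %||% default_autosomes(cs$seqname)

  chrom_gr <- GenomicRanges::GRanges(
    cs$seqname, IRanges::IRanges(1L, as.integer(cs$length)))
  flt <- mask_to_scanflag(filter$flag_mask)
  fc <- Rsamtools::countBam(
    bf, param = Rsamtools::ScanBamParam(which = chrom_gr, flag = flt))
  cs$filtered_mapped <- as.numeric(fc$records)
  if (sum(cs$mapped) > 0 && sum(cs$mapped) == sum(cs$filtered_mapped) &&
      bitwAnd(filter$flag_mask, 1024L) > 0L) {
    # unmarked duplicates cannot be detected downstream
    warning("no duplicate-flagged reads found genome-wide; if duplicates ",
            "were never marked, filtered modes cannot exclude them",
            call. = FALSE)
  }

  tgr <- regions_as_granges(targets)
  count_target <- function(flag = NULL) {
    param <- if (is.null(flag)) Rsamtools::ScanBamParam(which = tgr)
             else Rsamtools::ScanBamParam(which = tgr, flag = flag)
    if (filter$count_policy == "unique" && length(tgr) > 1L) {
      p2 <- Rsamtools::ScanBamParam(
        which = tgr, what = "qname",
        flag = flag %||% Rsamtools::scanBamFlag())
      nm <- unlist(lapply(Rsamtools::scanBam(bf, param = p2),
                          `[[`, "qname"))
      length(unique(nm))
    } else {
      sum(Rsamtools::countBam(bf, param = param)$records)
    }
  }
  rc_t <- count_target()
  frc_t <- count_target(flt)

  target_depth <- background_depth <- NULL
  autosome_cov <- NULL
  background_length <- NULL
  if (compute_depth) {
    target_depth <- pileup_depth(bf, tgr)$count
    if (!is.null(background)) {
      bgr <- regions_as_granges(background)
      background_depth <- pileup_depth(bf, bgr)$count
      background_length <- sum(GenomicRanges::width(bgr))
    }
    auto_tbl <- cs[cs$seqname %in% autosomes, ]
    agr <- GenomicRanges::GRanges(
      auto_tbl$seqname, IRanges::IRanges(1L, as.integer(auto_tbl$length)))
    pd <- pileup_depth(bf, agr)
    sums <- vapply(split(pd$count, pd$seqnames), sum, numeric(1L))
    autosome_cov <- tibble(
      seqname = auto_tbl$seqname,
      mean_depth = unname(sums[auto_tbl$seqname]) / auto_tbl$length)
    autosome_cov$mean_depth[is.na(autosome_cov$mean_depth)] <- 0
  }

  alignment_summary(
    cs, autosomes = autosomes,
    target_name = region_name(targets) %||% "target",
    target_length = target_length %||% region_target_length(targets),
    target_rc = rc_t, target_frc = frc_t,
    target_depth = target_depth,
    background_depth = background_depth,
    background_length = background_length,
    autosome_coverage = autosome_cov,
    sample = sample %||% sub("\\.bam$", "", basename(bam))
  )
}

pileup_depth <- function(bf, gr) {
  pp <- Rsamtools::PileupParam(max_depth = 100000L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = FALSE)
  res <- Rsamtools::pileup(
    bf,
    scanBamParam = Rsamtools::ScanBamParam(which = gr, flag = depth_flag()),
    pileupParam = pp)
  tibble(seqnames = as.character(res$seqnames), pos = res$pos,
         count = as.numeric(res$count))
}
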