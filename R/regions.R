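#' Target region sets
#'
#' A target region set is a tibble of genomic intervals in BED semantics
#' (0-based, half-open) with a set name, an optional reference-build label, a
#' canonical target length `Len_T` and optional per-sequence lengths. It
#' represents the DJ / PHR / rDNA targets, background regions and mask sets
#' used for copy-number estimation.
#'
#' The canonical target length defaults to the summed width of the merged
#' intervals but may be supplied externally — the read-count normalization
#' modes divide target read counts by the target length *on the original
#' build*, which can differ from the (possibly fragmented) lifted intervals.
#'
#' @param intervals data frame with columns `seqname`, `start`, `end` and
#'   optionally `strand` (0-based half-open coordinates).
#' @param name label for the set (e.g. `"DJ"`, `"PHR"`, `"rDNA"`).
#' @param reference reference-build label.
#' @param target_length canonical target length in bp; defaults to the summed
#'   merged interval width.
#' @param seq_lengths optional named vector of sequence lengths used to
#'   validate interval bounds.
#' @param merge merge overlapping/adjacent intervals (default `TRUE`).
#' @return A tibble of class `dj_regions` with attributes `name`,
#'   `reference`, `target_length` and `seq_lengths`.
#' @examples
#' target_regions(data.frame(seqname = "chr13", start = 0L, end = 100L),
#'                name = "DJ")
#' @export
target_regions <- function(intervals, name = "target",
                           reference = NA_character_,
                           target_length = NULL, seq_lengths = NULL,
                           merge = TRUE) {
  tbl <- as_tibble(intervals)
  stopifnot(all(c("seqname", "start", "end") %in% names(tbl)))
  if (!"strand" %in% names(tbl)) tbl$strand <- "*"
  tbl <- tbl[, c("seqname", "start", "end", "strand")]
  tbl$seqname <- as.character(tbl$seqname)
  if (nrow(tbl) > 0) {
    if (any(tbl$start < 0) || any(tbl$start >= tbl$end)) {
      stop("intervals must satisfy 0 <= start < end", call. = FALSE)
    }
    if (!is.null(seq_lengths)) {
      len <- seq_lengths[tbl$seqname]
      if (anyNA(len)) {
        stop("intervals on sequences absent from `seq_lengths`: ",
             paste(unique(tbl$seqname[is.na(len)]), collapse = ", "),
             call. = FALSE)
      }
      bad <- which(tbl$end > len)
      if (length(bad)) {
        b <- bad[1L]
        stop(sprintf("interval %s:%d-%d extends beyond sequence end (%d bp)",
                     tbl$seqname[b], tbl$start[b], tbl$end[b], len[b]),
             call. = FALSE)
      }
    }
    if (merge) tbl <- merge_intervals(tbl, gap = 0L)
  }
  structure(
    tbl,
    class = c("dj_regions", class(tbl)),
    name = name,
    reference = reference,
    target_length = target_length %||% sum(tbl$end - tbl$start),
    seq_lengths = seq_lengths
  )
}

#' @rdname target_regions
#' @param x a `dj_regions` object.
#' @export
region_target_length <- function(x) attr(x, "target_length")

#' @rdname target_regions
#' @export
region_name <- function(x) attr(x, "name")

#' Merge intervals in BED coordinates
#'
#' @param intervals data frame with `seqname`, `start`, `end` (0-based,
#'   half-open).
#' @param gap maximum gap (bp) bridged when merging; 0 merges only
#'   overlapping or book-ended intervals.
#' @return Tibble of merged intervals, sorted by sequence and start.
#' @export
merge_intervals <- function(intervals, gap = 0L) {
  tbl <- as_tibble(intervals)
  if (nrow(tbl) == 0L) {
    return(tibble(seqname = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  out <- lapply(split(tbl, tbl$seqname), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end),
                          min.gapwidth = gap + 1L)
    tibble(seqname = d$seqname[1L],
           start = IRanges::start(ir) - 1L,
           end = IRanges::end(ir),
           strand = "*")
  })
  out <- bind_rows(out)
  arrange(out, .data$seqname, .data$start)
}

#' Convert a region set to a GRanges
#' @param x `dj_regions` object or interval data frame (BED semantics).
#' @return `GenomicRanges::GRanges` (1-based closed coordinates).
#' @export
regions_as_granges <- function(x) {
  tbl <- as_tibble(x)
  strand <- if ("strand" %in% names(tbl)) tbl$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(tbl$seqname,
                         IRanges::IRanges(tbl$start + 1L, tbl$end),
                         strand = strand)
}

#' Read/write BED region sets
#'
#' Thin wrappers over rtracklayer that keep the package-internal 0-based,
#' half-open convention at the tibble surface.
#'
#' @param path BED file path.
#' @param ... passed on to [target_regions()].
#' @return `read_bed()`: a `dj_regions` tibble. `write_bed()`: `path`,
#'   invisibly.
#' @export
read_bed <- function(path, ...) {
  gr <- rtracklayer::import(path, format = "BED")
  target_regions(
    tibble(seqname = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr) - 1L,
           end = GenomicRanges::end(gr),
           strand = as.character(GenomicRanges::strand(gr))),
    ...
  )
}

#' @rdname read_bed
#' @param x region set to write.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(regions_as_granges(x), path, format = "BED")
  invisible(path)
}

#' Mask reference sequence inside a region set
#'
#' Replaces every base inside the mask intervals with `N`, leaving all other
#' bases and all sequence lengths unchanged. Used to restrict mapping-based
#' copy-number estimation to a single copy of a multi-copy target (the other
#' copies are hard-masked so all target reads pile onto one locus).
#'
#' Masking is idempotent: masking a masked set again is a no-op.
#'
#' @param sequences a `Biostrings::DNAStringSet` (named).
#' @param regions mask intervals (`dj_regions` or interval data frame, BED
#'   semantics).
#' @return The masked `DNAStringSet`.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(s1 = "ACGTACGT"))
#' mask <- data.frame(seqname = "s1", start = 2, end = 6)
#' as.character(mask_reference(seqs, mask)) # "ACNNNNGT"
#' @export
mask_reference <- function(sequences, regions) {
  stopifnot(methods::is(sequences, "DNAStringSet"))
  tbl <- as_tibble(regions)
  if (nrow(tbl) == 0L) return(sequences)
  out <- sequences
  for (sq in unique(tbl$seqname)) {
    if (!sq %in% names(out)) {
      stop("mask interval on unknown sequence: ", sq, call. = FALSE)
    }
    iv <- tbl[tbl$seqname == sq, ]
    len <- Biostrings::width(out)[match(sq, names(out))]
    bad <- which(iv$end > len | iv$start < 0)
    if (length(bad)) {
      b <- bad[1L]
      stop(sprintf(
        "mask interval %s:%d-%d outside sequence bounds (length %d)",
        sq, iv$start[b], iv$end[b], len), call. = FALSE)
    }
    ir <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
    out[[sq]] <- Biostrings::replaceAt(
      out[[sq]], ir, strrep("N", IRanges::width(ir)))
  }
  out
}
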