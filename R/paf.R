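#' Read PAF alignment records
#'
#' Parses the 12 mandatory PAF columns (trailing SAM-style tags are ignored).
#' PAF coordinates are already 0-based, half-open on both query and target.
#'
#' @param path PAF file path.
#' @return Tibble with columns `query_name`, `query_length`, `query_start`,
#'   `query_end`, `strand`, `target_name`, `target_length`, `target_start`,
#'   `target_end`, `matching_bases`, `block_length`, `mapq`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_paf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 12L
  if (any(short)) {
    stop("PAF line ", which(short)[1L], " has fewer than 12 fields",
         call. = FALSE)
  }
  col <- function(i) vapply(fields, `[[`, character(1L), i)
  num <- function(i) as.numeric(col(i))
  tbl <- tibble(
    query_name = col(1), query_length = num(2),
    query_start = num(3), query_end = num(4),
    strand = col(5),
    target_name = col(6), target_length = num(7),
    target_start = num(8), target_end = num(9),
    matching_bases = num(10), block_length = num(11),
    mapq = num(12)
  )
  validate_paf(tbl)
  tbl
}

empty_paf <- function() {
  tibble(query_name = character(), query_length = numeric(),
         query_start = numeric(), query_end = numeric(),
         strand = character(),
         target_name = character(), target_length = numeric(),
         target_start = numeric(), target_end = numeric(),
         matching_bases = numeric(), block_length = numeric(),
         mapq = numeric())
}

validate_paf <- function(tbl) {
  ok <- tbl$query_start >= 0 & tbl$query_start < tbl$query_end &
    tbl$query_end <= tbl$query_length &
    tbl$target_start >= 0 & tbl$target_start < tbl$target_end &
    tbl$target_end <= tbl$target_length &
    tbl$matching_bases <= tbl$block_length
  if (any(!ok)) {
    stop("invalid PAF record(s) at row(s): ",
         paste(head(which(!ok), 5L), collapse = ", "), call. = FALSE)
  }
  invisible(tbl)
}

#' Filter lifted target alignments into a region set
#'
#' Builds target regions on a new reference from alignments of the original
#' target sequence. Records are kept when the alignment block is at least
#' `min_length_bp` long (records strictly shorter are excluded), the gap-
#' compressed identity `100 * matching_bases / block_length` reaches
#' `min_identity_pct`, and the alignment covers at least `min_coverage_pct`
#' percent of the aligned target sequence. Surviving query intervals are
#' merged (0 bp gap tolerance) into a [target_regions()] set on the new
#' reference; excluded records are attached as the `"excluded"` attribute
#' with the failing criteria.
#'
#' With all thresholds at zero the result is simply the merged union of all
#' record intervals.
#'
#' @param records PAF records as returned by [read_paf()].
#' @param min_length_bp minimum alignment block length (default 10000; a
#'   block of exactly 10 kbp is kept).
#' @param min_identity_pct minimum percent identity (default 0).
#' @param min_coverage_pct minimum percent of the target sequence covered by
#'   the alignment block (default 0).
#' @param name,reference passed to [target_regions()].
#' @return A `dj_regions` set on the query (new reference) coordinates.
#' @export
filter_target_alignments <- function(records, min_length_bp = 10000,
                                     min_identity_pct = 0,
                                     min_coverage_pct = 0,
                                     name = "target",
                                     reference = NA_character_) {
  tbl <- as_tibble(records)
  tbl$identity_pct <- 100 * tbl$matching_bases / tbl$block_length
  tbl$coverage_pct <-
    100 * (tbl$target_end - tbl$target_start) / tbl$target_length
  fail_len <- tbl$block_length < min_length_bp
  fail_idy <- tbl$identity_pct < min_identity_pct
  fail_cov <- tbl$coverage_pct < min_coverage_pct
  keep <- !(fail_len | fail_idy | fail_cov)

  reason <- vapply(seq_len(nrow(tbl)), function(i) {
    paste(c(if (fail_len[i]) "length" , if (fail_idy[i]) "identity",
            if (fail_cov[i]) "coverage"), collapse = ",")
  }, character(1L))
  excluded <- tbl[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]

  kept <- tbl[keep, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("no alignment records pass the filters; returning an empty ",
            "region set", call. = FALSE)
  }
  seq_lengths <- NULL
  if (nrow(kept) > 0L) {
    seq_lengths <- vapply(split(kept$query_length, kept$query_name),
                          `[[`, numeric(1L), 1L)
  }
  out <- target_regions(
    tibble(seqname = kept$query_name,
           start = kept$query_start,
           end = kept$query_end,
           strand = kept$strand),
    name = name, reference = reference, seq_lengths = seq_lengths,
    merge = TRUE
  )
  attr(out, "excluded") <- excluded
  out
}
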