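#' K-mer utilities for reference-free dosage estimation
#'
#' Marker k-mers are canonical k-mers present exactly once in each copy of a
#' multi-copy target unit; their multiplicity in a read set scales with the
#' diploid copy number of the unit. All k-mer handling in the package is
#' canonical: a k-mer and its reverse complement are the same key, stored as
#' the lexicographically smaller of the pair. K-mers containing characters
#' other than A/C/G/T are discarded.
#'
#' @name kmer_tools
NULL

# all k-length substrings of one sequence (character scalar)
seq_kmers <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character())
  substring(toupper(seq), seq_len(n), seq_len(n) + k - 1L)
}

revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @rdname kmer_tools
#' @param kmers character vector of k-mers over A/C/G/T.
#' @return `canonicalize_kmers()`: the canonical form of each k-mer.
#' @export
canonicalize_kmers <- function(kmers) {
  rc <- revcomp_chr(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Count canonical k-mers in a set of sequences
#'
#' @param seqs character vector or `Biostrings::DNAStringSet`.
#' @param k k-mer length (default 31).
#' @param canonical collapse strand pairs to canonical k-mers?
#' @return Tibble with columns `kmer`, `count`, sorted by `kmer`.
#' @export
count_kmers <- function(seqs, k = 31L, canonical = TRUE) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  km <- unlist(lapply(seqs, seq_kmers, k = k), use.names = FALSE)
  km <- km[!grepl("[^ACGT]", km)]
  if (canonical && length(km)) km <- canonicalize_kmers(km)
  if (length(km) == 0L) {
    return(tibble(kmer = character(), count = integer()))
  }
  tab <- table(km)
  tibble(kmer = names(tab), count = as.integer(tab))
}

#' Select marker k-mers shared single-copy across target units
#'
#' Returns the canonical k-mers that occur exactly once in *every* supplied
#' unit sequence — the candidate markers whose read multiplicity tracks the
#' total number of unit copies in a genome. Reverse-complementing any unit
#' leaves the result unchanged.
#'
#' @param units list/vector of unit sequences (character or `DNAStringSet`),
#'   at least 2.
#' @param k k-mer length (default 31).
#' @return Sorted character vector of canonical marker k-mers; empty (with a
#'   warning) when no k-mer qualifies.
#' @export
select_shared_single_copy_kmers <- function(units, k = 31L) {
  if (methods::is(units, "XStringSet")) units <- as.character(units)
  if (length(units) < 2L) {
    stop("need at least 2 unit sequences", call. = FALSE)
  }
  per_unit <- lapply(units, function(u) {
    cnt <- count_kmers(u, k = k)
    cnt$kmer[cnt$count == 1L]
  })
  out <- sort(Reduce(intersect, per_unit))
  if (length(out) == 0L) {
    warning("no k-mer occurs exactly once in every unit", call. = FALSE)
  }
  out
}

#' K-mer multiplicity histograms
#'
#' A k-mer histogram maps multiplicity (how many times a distinct k-mer was
#' seen in the reads) to the number of distinct k-mers with that
#' multiplicity — the k-mer spectrum. Serialized as two-column TSV
#' (`multiplicity<TAB>count`, no header), the format emitted by standard
#' k-mer counters.
#'
#' @param multiplicity positive integer multiplicities.
#' @param count non-negative counts of distinct k-mers.
#' @return Tibble with columns `multiplicity`, `count`.
#' @export
kmer_histogram <- function(multiplicity, count) {
  stopifnot(length(multiplicity) == length(count))
  if (any(multiplicity < 1) || any(count < 0)) {
    stop("multiplicities must be >= 1 and counts >= 0", call. = FALSE)
  }
  arrange(tibble(multiplicity = as.numeric(multiplicity),
                 count = as.numeric(count)), .data$multiplicity)
}

#' @rdname kmer_histogram
#' @param values raw multiplicity observations (e.g. one per marker k-mer)
#'   to tabulate into a histogram.
#' @export
tabulate_multiplicities <- function(values) {
  values <- values[values >= 1]
  if (length(values) == 0L) {
    return(kmer_histogram(numeric(), numeric()))
  }
  tab <- table(values)
  kmer_histogram(as.numeric(names(tab)), as.numeric(tab))
}

#' @rdname kmer_histogram
#' @param path two-column TSV path.
#' @export
read_kmer_histogram <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("multiplicity", "count"),
                         col_types = "dd", progress = FALSE)
  kmer_histogram(tbl$multiplicity, tbl$count)
}

#' @rdname kmer_histogram
#' @param hist histogram tibble to write.
#' @export
write_kmer_histogram <- function(hist, path) {
  readr::write_tsv(hist[, c("multiplicity", "count")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Multiplicity band for expected marker dosage
#'
#' Markers of a `copies`-copy target in reads with haploid k-mer coverage
#' `kcov` are expected near `copies * kcov`; the band
#' `[kcov*(copies - halfwidth), kcov*(copies + halfwidth)]` (half a copy by
#' default) tolerates small coverage variation and sequencing bias.
#' `rounding = "floor_ceil"` takes the integer hull of the real-valued band;
#' `"multiple25"` rounds each bound to the nearest multiple of 25, the
#' hand-rounded convention of the bundled calibration preset (kcov 49.9
#' gives 475–525).
#'
#' @param kcov haploid k-mer coverage (externally fitted, or estimated as
#'   half the 2-copy peak).
#' @param copies expected diploid copy number of the target (default 10).
#' @param halfwidth band half-width in copies (default 0.5).
#' @param rounding `"floor_ceil"` (default) or `"multiple25"`.
#' @return Numeric `c(lo, hi)`.
#' @examples
#' kmer_band(50)                          # 475 525
#' kmer_band(49.9, rounding = "multiple25") # 475 525
#' @export
kmer_band <- function(kcov, copies = 10, halfwidth = 0.5,
                      rounding = c("floor_ceil", "multiple25")) {
  rounding <- match.arg(rounding)
  stopifnot(kcov > 0, copies > halfwidth)
  lo <- kcov * (copies - halfwidth)
  hi <- kcov * (copies + halfwidth)
  band <- switch(rounding,
    floor_ceil = c(floor(lo), ceiling(hi)),
    multiple25 = c(round(lo / 25) * 25, round(hi / 25) * 25)
  )
  if (band[1] >= band[2]) stop("degenerate multiplicity band", call. = FALSE)
  band
}

#' Restrict marker k-mers to the expected multiplicity band
#'
#' Drops markers whose multiplicity in the calibration reads falls outside
#' the [kmer_band()] — k-mers that are not actually single-copy-per-unit in
#' the sequenced genome (collapsed repeats, private variation).
#'
#' @param marker_hist histogram of marker multiplicities in the calibration
#'   reads ([kmer_histogram()]).
#' @inheritParams kmer_band
#' @return The filtered histogram; errors if the band retains nothing
#'   (usually a mis-estimated `kcov`).
#' @export
band_filter_markers <- function(marker_hist, kcov, copies = 10,
                                halfwidth = 0.5,
                                rounding = c("floor_ceil", "multiple25")) {
  band <- kmer_band(kcov, copies, halfwidth, match.arg(rounding))
  out <- marker_hist[marker_hist$multiplicity >= band[1] &
                       marker_hist$multiplicity <= band[2], , drop = FALSE]
  if (nrow(out) == 0L || sum(out$count) == 0) {
    stop("no marker k-mers inside the multiplicity band [", band[1], ", ",
         band[2], "]; kcov may be mis-estimated", call. = FALSE)
  }
  attr(out, "band") <- band
  out
}

#' Locate copy-number peaks in a k-mer spectrum
#'
#' Excludes the low-multiplicity error region (everything up to the first
#' local minimum of the lightly smoothed counts, and never below
#' `error_floor`), then collects local maxima. With a single peak the
#' spectrum is treated as homozygous-like and that peak is the 2-copy peak;
#' with several, the highest-count peak at or above the second-lowest peak
#' position is the 2-copy peak and the lowest-position peak (when it lies
#' below the 2-copy peak) is reported as the 1-copy (heterozygous) peak.
#' Peak boundaries are the surrounding local minima of the smoothed counts.
#'
#' @param hist k-mer histogram ([kmer_histogram()]) with at least 10
#'   multiplicity bins.
#' @param smooth_window centered moving-average window (odd; default 3; 1
#'   disables smoothing).
#' @param error_floor smallest multiplicity a peak may occupy (default 5).
#' @return A list of class `dj_peak_calibration`: `one_copy`, `two_copy`,
#'   `boundaries` (2-copy peak flanking minima), `trough` (end of the error
#'   region), `peaks` (tibble of all candidate peaks), `histogram`.
#' @export
detect_copy_peaks <- function(hist, smooth_window = 3L, error_floor = 5L) {
  if (nrow(hist) < 10L) {
    stop("k-mer histogram needs at least 10 multiplicity bins", call. = FALSE)
  }
  grid <- seq(min(hist$multiplicity), max(hist$multiplicity))
  y <- rep(0, length(grid))
  y[match(hist$multiplicity, grid)] <- hist$count
  ys <- y
  if (smooth_window > 1L) {
    w <- as.integer(smooth_window)
    if (w %% 2L == 0L) stop("smooth_window must be odd", call. = FALSE)
    sm <- stats::filter(y, rep(1 / w, w), sides = 2)
    ys[!is.na(sm)] <- sm[!is.na(sm)]
  }
  n <- length(ys)
  # end of the error region: first rise of the smoothed counts
  rises <- which(diff(ys) > 0)
  if (length(rises) == 0L) {
    stop("monotone spectrum: no peak beyond the error region; cannot ",
         "calibrate the 2-copy peak", call. = FALSE)
  }
  trough_idx <- rises[1L]
  floor_idx <- which(grid >= error_floor)
  floor_idx <- if (length(floor_idx)) floor_idx[1L] else n
  start_idx <- max(trough_idx, floor_idx, 2L)
  if (start_idx > n - 1L) {
    stop("no local maximum beyond the error region; cannot calibrate the ",
         "2-copy peak", call. = FALSE)
  }
  idx <- seq(start_idx, n - 1L)
  is_peak <- ys[idx] > ys[idx - 1L] & ys[idx] >= ys[idx + 1L]
  pk <- idx[is_peak]
  if (length(pk) == 0L) {
    stop("no local maximum beyond the error region; cannot calibrate the ",
         "2-copy peak", call. = FALSE)
  }
  peaks <- tibble(multiplicity = grid[pk], height = ys[pk])
  if (nrow(peaks) == 1L) {
    two_idx <- 1L
  } else {
    cand <- which(peaks$multiplicity >= sort(peaks$multiplicity)[2L])
    two_idx <- cand[which.max(peaks$height[cand])]
  }
  two_copy <- peaks$multiplicity[two_idx]
  one_copy <- NA_real_
  lower <- peaks$multiplicity < two_copy
  if (any(lower)) one_copy <- min(peaks$multiplicity[lower])

  # flanking minima of the 2-copy peak
  p <- match(two_copy, grid)
  left <- p
  while (left > 1L && ys[left - 1L] <= ys[left]) left <- left - 1L
  right <- p
  while (right < n && ys[right + 1L] <= ys[right]) right <- right + 1L

  structure(list(one_copy = one_copy, two_copy = two_copy,
                 boundaries = c(grid[left], grid[right]),
                 trough = grid[trough_idx],
                 peaks = peaks, histogram = hist),
            class = "dj_peak_calibration")
}

#' @export
print.dj_peak_calibration <- function(x, ...) {
  cat("<dj_peak_calibration> 2-copy peak:", x$two_copy,
      " 1-copy peak:", x$one_copy, "\n")
  cat("  boundaries: [", x$boundaries[1], ",", x$boundaries[2],
      "]  error trough:", x$trough, "\n")
  invisible(x)
}

#' Reference-free copy number from marker k-mer multiplicities
#'
#' `CN = 2 * median(marker multiplicities) / two-copy peak`, the median
#' taken under the strict cumulative rule of [weighted_median()].
#'
#' @param marker_hist histogram of marker k-mer multiplicities in the sample
#'   reads.
#' @param calibration a `dj_peak_calibration` (or the 2-copy peak value
#'   directly).
#' @param rule binning rule, see [bin_copy_number()].
#' @param sample,target labels carried into the output.
#' @return One-row tibble `sample`, `target`, `mode = "kmer"`, `cn`, `bin`.
#' @export
cn_from_kmers <- function(marker_hist, calibration,
                          rule = c("nearest", "dj_threshold"),
                          sample = NA_character_, target = "DJ") {
  rule <- match.arg(rule)
  peak <- if (inherits(calibration, "dj_peak_calibration")) {
    calibration$two_copy
  } else {
    as.numeric(calibration)
  }
  if (!is.finite(peak) || peak <= 0) {
    stop("2-copy peak must be a positive number", call. = FALSE)
  }
  if (nrow(marker_hist) == 0L || sum(marker_hist$count) == 0) {
    stop("empty marker histogram: no marker k-mers found in the reads",
         call. = FALSE)
  }
  med <- weighted_median(marker_hist$multiplicity, marker_hist$count)
  cn <- 2 * med / peak
  tibble(sample = sample, target = target, mode = "kmer",
         cn = cn, bin = bin_copy_number(cn, rule = rule))
}

#' Fallback haploid coverage estimate from a calibration
#'
#' `kcov` is normally fitted externally from the full read spectrum; when
#' unavailable it can be approximated as half the detected 2-copy peak.
#'
#' @param calibration a `dj_peak_calibration`.
#' @return Numeric haploid k-mer coverage.
#' @export
estimate_kcov <- function(calibration) {
  stopifnot(inherits(calibration, "dj_peak_calibration"))
  calibration$two_copy / 2
}
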