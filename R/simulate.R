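#' Simulate an alignment fixture with known target dosage
#'
#' Generates a toy diploid genome — `n_autosomes` autosomal contigs plus a
#' dedicated target-bearing contig (`chrDJ`) whose central interval carries
#' `target_copy` copies relative to the diploid baseline of 2 — and writes a
#' coordinate-sorted, indexed BAM of fixed-length single-end reads. Read
#' starts follow a Poisson process at `lambda / read_length` per base,
#' multiplied by `target_copy / 2` inside the target interval. Configured
#' fractions of reads additionally carry duplicate (1024), secondary (256)
#' or supplementary (2048) flags as extra records, toggled independently so
#' each filter term is separately testable; by default the flagged records
#' are confined to the target region, emulating the duplicate-like pile-ups
#' seen at collapsed repeats. The target lives on its own contig so that the
#' autosomal background rate is exactly `lambda` — on a real genome the
#' target is a negligible fraction of the autosomes, which a <=5 Mb toy
#' genome cannot imitate from inside an autosome.
#'
#' All generators are deterministic under a fixed seed.
#'
#' @param dir output directory (created if missing).
#' @param seed RNG seed.
#' @param n_autosomes,autosome_length autosomal contig count and length.
#' @param target_length,target_flank target interval length and flank length
#'   on the target contig.
#' @param target_copy true diploid copy number of the target.
#' @param lambda mean per-base read depth of the diploid baseline.
#' @param read_length fixed read length (bp).
#' @param dup_frac,sec_frac,supp_frac fractions of reads duplicated with the
#'   corresponding extra flag bit.
#' @param unmapped_frac placed-unmapped records added per mapped read.
#' @param flag_scope `"target"` (default) restricts flagged extras to reads
#'   starting in the target interval; `"genome"` applies them everywhere.
#' @param sex `NULL`, `"XX"` or `"XY"`; when set, chrX/chrY contigs with the
#'   corresponding coverage are added.
#' @param sample sample label.
#' @param compute_summary also build the [summarize_alignments()] object?
#' @return List with `sam`, `bam`, `targets`, `background`, `truth` (tibble
#'   with the true copy number), `summary` (or `NULL`), `seed`.
#' @export
simulate_alignment_fixture <- function(dir = tempfile("djfix"),
                                       seed = NULL,
                                       n_autosomes = 22L,
                                       autosome_length = 40000L,
                                       target_length = 20000L,
                                       target_flank = 5000L,
                                       target_copy = 10,
                                       lambda = 30,
                                       read_length = 150L,
                                       dup_frac = 0, sec_frac = 0,
                                       supp_frac = 0, unmapped_frac = 0,
                                       flag_scope = c("target", "genome"),
                                       sex = NULL,
                                       sample = "sim",
                                       compute_summary = TRUE) {
  flag_scope <- match.arg(flag_scope)
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  autos <- paste0("chr", seq_len(n_autosomes))
  dj_len <- 2L * target_flank + target_length
  seqs <- tibble(seqname = c(autos, "chrDJ"),
                 length = c(rep(autosome_length, n_autosomes), dj_len))
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("XX", "XY"))
    seqs <- bind_rows(seqs, tibble(seqname = c("chrX", "chrY"),
                                   length = rep(autosome_length, 2L)))
  }
  rate <- lambda / read_length
  t_start <- target_flank
  t_end <- target_flank + target_length

  gen <- function(seqname, seg_start, seg_end, seg_rate, seqlen) {
    nr <- stats::rpois(1L, seg_rate * (seg_end - seg_start))
    if (nr == 0L) return(NULL)
    pos0 <- floor(stats::runif(nr, seg_start, seg_end))
    pos0 <- pmin(pos0, seqlen - read_length)
    pos0 <- pos0[pos0 >= 0]
    if (length(pos0) == 0L) return(NULL)
    tibble(rname = seqname, pos = as.integer(pos0) + 1L, flag = 0L)
  }

  reads <- list()
  for (i in seq_len(n_autosomes)) {
    reads[[length(reads) + 1L]] <-
      gen(autos[i], 0L, autosome_length, rate, autosome_length)
  }
  reads[[length(reads) + 1L]] <- gen("chrDJ", 0L, t_start, rate, dj_len)
  reads[[length(reads) + 1L]] <-
    gen("chrDJ", t_start, t_end, rate * target_copy / 2, dj_len)
  reads[[length(reads) + 1L]] <- gen("chrDJ", t_end, dj_len, rate, dj_len)
  if (!is.null(sex)) {
    x_rate <- if (sex == "XX") rate else rate / 2
    y_rate <- if (sex == "XX") 0 else rate / 2
    reads[[length(reads) + 1L]] <-
      gen("chrX", 0L, autosome_length, x_rate, autosome_length)
    if (y_rate > 0) {
      reads[[length(reads) + 1L]] <-
        gen("chrY", 0L, autosome_length, y_rate, autosome_length)
    }
  }
  reads <- bind_rows(reads)
  reads$qname <- sprintf("r%07d", seq_len(nrow(reads)))

  in_scope <- if (flag_scope == "target") {
    reads$rname == "chrDJ" & reads$pos > t_start & reads$pos <= t_end
  } else {
    rep(TRUE, nrow(reads))
  }
  extra <- list()
  for (spec in list(c(dup_frac, 1024L), c(sec_frac, 256L),
                    c(supp_frac, 2048L))) {
    frac <- spec[1L]
    bit <- as.integer(spec[2L])
    if (frac > 0) {
      pick <- which(in_scope & stats::runif(nrow(reads)) < frac)
      if (length(pick)) {
        ex <- reads[pick, ]
        ex$flag <- bitwOr(ex$flag, bit)
        ex$qname <- paste0(ex$qname, ".f", bit)
        extra[[length(extra) + 1L]] <- ex
      }
    }
  }
  n_mapped <- nrow(reads)
  if (unmapped_frac > 0) {
    nu <- round(unmapped_frac * n_mapped)
    if (nu > 0) {
      extra[[length(extra) + 1L]] <- tibble(
        rname = rep_len(autos, nu), pos = 1L, flag = 4L,
        qname = sprintf("u%07d", seq_len(nu)))
    }
  }
  reads <- bind_rows(c(list(reads), extra))
  reads <- reads[order(match(reads$rname, seqs$seqname), reads$pos), ]

  seq_str <- strrep("A", read_length)
  qual_str <- strrep("I", read_length)
  cigar <- ifelse(bitwAnd(reads$flag, 4L) > 0L, "*",
                  paste0(read_length, "M"))
  mapq <- ifelse(bitwAnd(reads$flag, 4L) > 0L, 0L, 60L)
  body <- paste(reads$qname, reads$flag, reads$rname, reads$pos, mapq,
                cigar, "*", 0L, 0L, seq_str, qual_str, sep = "\t")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", seqs$seqname, seqs$length))
  sam <- file.path(dir, paste0(sample, ".sam"))
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, sample), overwrite = TRUE,
                          indexDestination = TRUE)

  seq_lengths <- setNames(seqs$length, seqs$seqname)
  targets <- target_regions(
    tibble(seqname = "chrDJ", start = t_start, end = t_end),
    name = "DJ", reference = "toy", seq_lengths = seq_lengths)
  background <- target_regions(
    tibble(seqname = autos, start = 0L, end = autosome_length),
    name = "autosomes", reference = "toy", seq_lengths = seq_lengths)
  write_bed(targets, file.path(dir, "target.bed"))
  write_bed(background, file.path(dir, "background.bed"))
  truth <- tibble(target = "DJ", seqname = "chrDJ",
                  start = t_start, end = t_end, true_cn = target_copy)

  summary <- NULL
  if (compute_summary) {
    summary <- withCallingHandlers(
      summarize_alignments(bam, targets, background = background,
                           autosomes = autos, sample = sample),
      warning = function(w) {
        if (grepl("duplicate-flagged", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  list(sam = sam, bam = bam, targets = targets, background = background,
       truth = truth, summary = summary, seed = seed)
}

#' Simulate a k-mer multiplicity spectrum with known peaks
#'
#' Builds a read k-mer spectrum as Poisson draws around an expected profile:
#' a geometrically decaying error spike from multiplicity 1, Gaussian bumps
#' at the 1-copy (`kcov`) and 2-copy (`2 * kcov`) positions, and a marker
#' bump from `n_markers` marker k-mers at `marker_copies * kcov`. The
#' marker sub-histogram is drawn per marker (Poisson with mean
#' `marker_copies * kcov`) and also added into the full spectrum.
#'
#' @param seed RNG seed.
#' @param kcov haploid k-mer coverage (1-copy peak position).
#' @param marker_copies true diploid copy number of the marker target.
#' @param n_markers number of marker k-mers.
#' @param error_count expected distinct error k-mers at multiplicity 1.
#' @param error_decay geometric decay of the error spike per multiplicity.
#' @param one_copy_mass,two_copy_mass total distinct k-mers under the 1- and
#'   2-copy bumps (bump widths are `sqrt` of their positions).
#' @return List with `full` and `markers` histograms
#'   ([kmer_histogram()] tibbles) and `truth` (bump centers).
#' @export
simulate_kmer_spectrum <- function(seed = NULL, kcov = 25,
                                   marker_copies = 10, n_markers = 2000L,
                                   error_count = 2e5, error_decay = 0.5,
                                   one_copy_mass = 8e5,
                                   two_copy_mass = 2.4e6) {
  if (!is.null(seed)) set.seed(seed)
  marker_peak <- marker_copies * kcov
  top <- ceiling(max(3 * kcov, marker_peak + 6 * sqrt(marker_peak)))
  m <- seq_len(top)
  expected <- error_count * error_decay^(m - 1) +
    one_copy_mass * stats::dnorm(m, kcov, sqrt(kcov)) +
    two_copy_mass * stats::dnorm(m, 2 * kcov, sqrt(2 * kcov))
  counts <- stats::rpois(length(m), expected)

  marker_hist <- kmer_histogram(numeric(), numeric())
  if (n_markers > 0L) {
    mult <- stats::rpois(n_markers, marker_peak)
    marker_hist <- tabulate_multiplicities(mult)
    add <- marker_hist[marker_hist$multiplicity <= top, ]
    counts[add$multiplicity] <- counts[add$multiplicity] + add$count
  }
  keep <- counts > 0
  list(full = kmer_histogram(m[keep], counts[keep]),
       markers = marker_hist,
       truth = list(one_copy = kcov, two_copy = 2 * kcov,
                    marker_peak = marker_peak,
                    marker_copies = marker_copies))
}

#' Default cohort mixture weights
#'
#' Component weights of the simulated DJ copy-number cohort, matching the
#' frequencies observed in large screening cohorts: the 10-copy class
#' dominates (85%), single losses ~3%, the partial-duplication intermediate
#' 2%, single gains 8%, and the 8-copy carrier class ~0.1%.
#'
#' @return Numeric vector of 7 weights summing to 1.
#' @export
dj_cohort_weights <- function() c(0.001, 0.03, 0.85, 0.02, 0.08, 0.015, 0.004)

#' Simulate a copy-number cohort from a labeled mixture
#'
#' Draws `n` samples from the Gaussian mixture
#' `sum_k psi_k N(u_k, sigma_k^2)` with the true component label retained —
#' the input the mixture classifier is trained and validated on.
#'
#' @param n cohort size.
#' @param weights mixture weights (default [dj_cohort_weights()]).
#' @param means component means (default [dj_default_means()]).
#' @param sigmas component standard deviations (scalar or per component;
#'   default 0.15).
#' @param labels bin labels per component.
#' @param seed RNG seed.
#' @return Tibble with columns `sample`, `component`, `bin`, `cn`
#'   (empty for `n = 0`).
#' @export
simulate_cohort <- function(n = 2402L, weights = dj_cohort_weights(),
                            means = dj_default_means(), sigmas = 0.15,
                            labels = NULL, seed = NULL) {
  K <- length(means)
  stopifnot(length(weights) == K, abs(sum(weights) - 1) < 1e-8)
  sigmas <- rep_len(sigmas, K)
  if (is.null(labels)) {
    labels <- if (K == 7L && all(means == dj_default_means())) {
      dj_default_labels()
    } else {
      as.character(round(means))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) {
    return(tibble(sample = character(), component = integer(),
                  bin = character(), cn = numeric()))
  }
  comp <- sample.int(K, n, replace = TRUE, prob = weights)
  tibble(sample = sprintf("S%05d", seq_len(n)),
         component = comp,
         bin = labels[comp],
         cn = stats::rnorm(n, means[comp], sigmas[comp]))
}
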