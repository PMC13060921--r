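# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own code paths.

# reverse complement via chartr + string reversal (not Biostrings)
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# exhaustive shared single-copy canonical k-mer computation
oracle_marker_kmers <- function(units, k) {
  per_unit <- lapply(units, function(u) {
    n <- nchar(u) - k + 1L
    if (n < 1L) return(character())
    km <- vapply(seq_len(n), function(i) substr(u, i, i + k - 1L),
                 character(1L))
    km <- km[!grepl("[^ACGT]", km)]
    rc <- oracle_revcomp(km)
    canon <- ifelse(km <= rc, km, rc)
    tab <- table(canon)
    names(tab)[tab == 1L]
  })
  sort(Reduce(intersect, per_unit))
}

# exact binomial point mass by enumerating all 2^n haplotype states
oracle_exact_k_of_n <- function(p, n, k) {
  states <- expand.grid(rep(list(c(0L, 1L)), n))
  probs <- apply(states, 1L, function(s) prod(ifelse(s == 1L, p, 1 - p)))
  sum(probs[rowSums(states) == k])
}

# exact P(at least one of m) by enumeration
oracle_at_least_one <- function(p, m) {
  if (m == 0L) return(0)
  states <- expand.grid(rep(list(c(0L, 1L)), m))
  probs <- apply(states, 1L, function(s) prod(ifelse(s == 1L, p, 1 - p)))
  sum(probs[rowSums(states) >= 1L])
}

# near-identical unit copies: one random base sequence with a small
# fraction of substitutions per copy (uses the caller's RNG state)
mutated_units <- function(n_units, len, sub_rate = 0.01) {
  alph <- c("A", "C", "G", "T")
  base <- sample(alph, len, replace = TRUE)
  vapply(seq_len(n_units), function(i) {
    u <- base
    hit <- which(stats::runif(len) < sub_rate)
    u[hit] <- sample(alph, length(hit), replace = TRUE)
    paste(u, collapse = "")
  }, character(1L))
}

# closed-form simple linear regression (normal equations)
oracle_ols <- function(x, y) {
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  yhat <- b0 + b1 * x
  list(beta0 = b0, beta1 = b1, rss = sum((y - yhat)^2))
}

# exact two-sided rank-sum p-value by enumerating all rank assignments
# (assumes no ties across the pooled sample)
oracle_ranksum <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  ranks <- seq_len(n1 + n2)
  u_all <- apply(combs, 2L, function(idx) {
    sum(ranks[idx]) - n1 * (n1 + 1) / 2
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# brute-force mapping-mode recomputation from a per-read record table
# (columns: rname, pos (1-based), flag), mirroring the formulas from first
# principles rather than through the alignment summary container
oracle_mode_cn <- function(reads, seq_lengths, autosomes,
                           t_seq, t_start, t_end, len_t, read_length = 150L,
                           mode = c("pilot_fast", "fast", "fast_precise",
                                    "fast_refine")) {
  mode <- match.arg(mode)
  mapped <- reads[bitwAnd(reads$flag, 4L) == 0L, ]
  unmapped <- reads[bitwAnd(reads$flag, 4L) > 0L, ]
  filt <- mapped[bitwAnd(mapped$flag, 256L + 1024L + 2048L) == 0L, ]
  # a read counts toward the target when it OVERLAPS the (1-based)
  # interval (t_start+1, t_end], the `samtools view -c region` semantics
  in_target <- function(d) {
    d$rname == t_seq & d$pos <= t_end &
      d$pos + read_length - 1L >= t_start + 1L
  }
  cnt_by <- function(d) {
    vapply(autosomes, function(a) sum(d$rname == a), numeric(1L))
  }
  len_a <- sum(seq_lengths[autosomes])
  switch(mode,
    pilot_fast = {
      rc_t <- sum(in_target(mapped))
      bg <- (sum(cnt_by(mapped)) -
               sum(unmapped$rname %in% autosomes)) / len_a
      2 * (rc_t / len_t) / bg
    },
    fast = {
      rc_t <- sum(in_target(mapped))
      bg <- median(cnt_by(mapped) / seq_lengths[autosomes])
      2 * (rc_t / len_t) / bg
    },
    fast_precise = {
      frc_t <- sum(in_target(filt))
      bg <- sum(cnt_by(filt)) / len_a
      2 * (frc_t / len_t) / bg
    },
    fast_refine = {
      frc_t <- sum(in_target(filt))
      bg <- median(cnt_by(filt) / seq_lengths[autosomes])
      2 * (frc_t / len_t) / bg
    })
}
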