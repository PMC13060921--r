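---
title: "DJ dosage genotyping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DJ dosage genotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(djdose)
```

## The problem

Robertsonian translocations (ROBs) fuse two acrocentric chromosomes at
their short arms. Each fusion removes both distal short-arm segments,
including one copy of the *distal junction* (DJ) — a large, highly
conserved segmental duplication sitting immediately distal to every
ribosomal DNA array. A normal diploid genome carries 10 DJ copies (one
per acrocentric haplotype); a balanced ROB carrier carries 8. Estimating
the diploid DJ dosage from ordinary short-read whole-genome sequencing
therefore screens for carriers without karyotyping: a genome binned at 8
DJs is a carrier candidate, 9 indicates a single deletion, 11 or more a
duplication.

`djdose` implements the full dosage-genotyping stack: reference
preparation, mapping-based copy-number (CN) estimation in several
normalization modes, a reference-free k-mer estimator, cross-reference
harmonization, a constrained Gaussian-mixture classifier, and closed-form
screening error-rate models — plus seeded simulators so everything is
testable without sequencing data.

## Reference preparation

The DJ is multi-copy, so reads from every copy must pile onto a single
locus for a read-depth ratio to measure dosage. `mask_reference()`
hard-masks (with `N`) all but one copy; the interval bookkeeping uses
BED semantics (0-based, half-open) throughout via `target_regions()`.
Targets defined on one assembly are lifted to another by aligning the
target sequence and filtering the alignment records
(`filter_target_alignments()`): records shorter than `min_length_bp`
(default 10 kbp, inclusive), below a percent-identity floor
(`100 * matching / block_length`), or covering too little of the aligned
target are excluded, and the surviving query intervals are merged.
`infer_sex()` picks the sex-chromosome-complement reference variant
(Y-masked for XX, PAR-masked-Y for XY) from the X/Y coverage ratio with
a default threshold of 4.

## Mapping-based copy number

All modes share one idea: `CN = 2 * target coverage / autosomal
background coverage`. They differ in how each side is measured:

| mode | target numerator | background denominator |
|---|---|---|
| `chm13_highres` | median per-base depth | median per-base depth of a background set |
| `pilot_fast` | raw reads / `Len_T` | `(sum RC_A - RU_A) / Len_A` |
| `fast` | raw reads / `Len_T` | median per-autosome `RC_C / Len_C` |
| `fast_precise` | filtered reads / `Len_T` | `FRC_A / Len_A` |
| `fast_refine` | filtered reads / `Len_T` | median per-autosome `FRC_C / Len_C` |
| `grch38_highres` | summed depth / `Len_T` | median per-autosome mean coverage |

"Filtered" counts exclude reads whose SAM flag matches the mask 3332 =
unmapped (4) + secondary (256) + duplicate (1024) + supplementary
(2048), i.e. `samtools view -c -F 3332`. Depth tracks follow the
`samtools depth`/`coverage` default instead (4 + 256 + 512 + 1024) and
are stored for covered positions only; `include_zero = TRUE` pads with
zeros before the median. The canonical target length `Len_T` is a
property of the target definition, not of the (possibly fragmented)
lifted intervals, so it can be supplied externally. A zero background is
a hard error rather than a silent `NaN`.

Continuous estimates are binned with `bin_copy_number()`: nearest
integer, ties at `.5` rounding up. The `"dj_threshold"` rule moves only
the 10/11 boundary to 10.4, reflecting the empirical gap between the
10-copy bulk and the partial-duplication shoulder.

```{r}
fx <- simulate_alignment_fixture(seed = 7, n_autosomes = 6,
                                 autosome_length = 10000,
                                 target_length = 5000,
                                 target_flank = 1500, lambda = 15)
estimate_copy_number(fx$summary)
```

## Reference-free k-mer estimation

Marker k-mers are canonical 31-mers occurring exactly once in every DJ
unit (`select_shared_single_copy_kmers()`); their multiplicity in a read
set scales with total DJ dosage. The estimator is

```
CN = 2 * median(marker multiplicities) / two-copy peak
```

with the median taken under the strict cumulative rule
(`weighted_median()`: the smallest value whose cumulative count strictly
exceeds half the total). The 2-copy peak comes from the full read
spectrum (`detect_copy_peaks()`): counts are lightly smoothed (moving
average, window 3), everything up to the first rise — and never below
multiplicity 5 — is treated as sequencing-error k-mers, and among the
remaining local maxima the highest-count peak at or above the
second-lowest peak position is the 2-copy peak. Markers whose
multiplicity falls outside the band `kcov * (copies ± 0.5)`
(`kmer_band()`; optionally rounded to multiples of 25, so `kcov = 49.9`
gives 475–525) are discarded as not actually single-copy-per-unit.

```{r}
sp <- simulate_kmer_spectrum(seed = 1, kcov = 25, marker_copies = 10)
cal <- detect_copy_peaks(sp$full)
cal
cn_from_kmers(sp$markers, cal)
```

## Harmonization across references

Estimates from different references/modes sit on slightly different
scales. `fit_linear_transform()` fits `target = b0 + b1 * source` by
ordinary least squares on paired samples; `select_mode_by_rss()` picks
the source mode with the lowest residual sum of squares (ties break by
mode name, with a warning). `compare_distributions()` reports a
two-sided Mann–Whitney test plus the rank-biserial correlation
`1 - 2U/(n_a n_b)` to check that two cohorts' estimates are
statistically indistinguishable after transformation.

## Mixture classification

Cohort DJ estimates cluster at reproducible positions, so the classifier
is a Gaussian mixture with *fixed* means `(8, 9.1, 10.1, 10.7, 11.1,
11.9, 13)` — the 10.7 component captures partially duplicated
haplotypes and maps to the `"10-11"` bin. EM re-estimates only weights
and standard deviations, the latter projected into `[0.1, 0.2]` after
every M-step; convergence is a relative log-likelihood change below
`1e-10`. `bootstrap_fit()` averages the parameters over bootstrap
resamples (the default is `B = 1000`, sized for population cohorts; the
bundled acceptance checks use `B = 200` to stay desk-sized) and
renormalizes the averaged weights. `classify_samples()` assigns maximum-a-posteriori
bins in log space, so extreme outliers never underflow; posterior ties
break toward the lower mean. If the fixed means are in doubt,
`find_consistent_peaks()` recovers candidate means as histogram peaks
reproduced across independent cohorts.

```{r}
cohort <- simulate_cohort(n = 800, seed = 3)
fit <- em_fit_fixed_means(cohort)
tidy(fit)
head(classify_samples(cohort, fit)[, c("cn", "bin", "map_prob")])
```

## Screening error rates

Treating the 10 acrocentric haplotypes as independent, a cohort
frequency `f` of single-event genomes implies a per-haplotype rate
`p = 1 - (1 - f)^(1/10)` (computed via `log1p`/`expm1`). Two coincident
deletions mimic a carrier: `FP = C(10,2) p_del^2 (1-p_del)^8`. A
duplication on any of a carrier's 8 unaffected haplotypes masks it:
`FN = 1 - (1 - p_dup)^8`.

```{r}
rob_rates(0.031, 0.089, f_obs_8dj = 0.0012)
```

## What the simulators do and do not emulate

`simulate_alignment_fixture()` draws fixed-length single-end reads from
a Poisson process at `lambda / read_length` starts per base, multiplied
by `target_copy / 2` inside the target. Pairing, base errors, GC bias
and mapping ambiguity are deliberately out of scope — dosage math needs
none of them. Two design points matter:

* The target lives on its own contig (`chrDJ`) with flanks, rather than
  inside an autosome. On a real genome the target is a negligible
  fraction of the autosomal background; in a few-megabase toy genome an
  embedded high-copy target would visibly inflate its host autosome and
  bias the background, so separating it keeps the background rate
  exactly `lambda`.
* Duplicate/secondary/supplementary records are added as *extra* flagged
  copies of existing reads, by default only over the target
  (`flag_scope = "target"`), emulating duplicate-like pile-ups at
  collapsed repeats. This makes the raw-count `fast` mode inflate by
  roughly the duplicate fraction while `fast_precise` is untouched —
  each filter bit is separately testable.

`simulate_kmer_spectrum()` builds a spectrum from a geometric error
spike plus Gaussian bumps at `kcov`, `2 kcov` and the marker position,
with Poisson bin noise. `simulate_cohort()` draws labeled mixture
samples with weights matching large-cohort frequencies (85% at 10
copies, 0.1% at 8).

## Numerical choices

* Mixture densities and posteriors are computed in log space with a
  `logsumexp` reduction.
* Small-probability algebra uses `log1p`/`expm1`.
* The EM standard-deviation update floors the variance at `1e-12`
  before the bound projection, and components with vanishing
  responsibility mass keep their previous sigma.
* The strict weighted median is used for k-mer histograms; per-base
  depth medians use the conventional `stats::median`.

## Limitations

* The estimators assume an unbiased autosomal background; strong
  GC/mappability bias must be handled upstream.
* The fixed mixture means encode the DJ-specific peak layout; other
  targets need `find_consistent_peaks()` or externally chosen means.
* The per-component `±0.02` weight-recovery and the classification
  checks are evaluated at desk scale (`n = 2402`, `B = 200`);
  population-scale guarantees require the full bootstrap.
* The rate models assume independence across the 10 haplotypes.
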