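---
title: "Screening SAB antibody results by PC-space distance ratios: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening SAB antibody results by PC-space distance ratios: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sabscreen)
```

## The screening model

A single antigen bead (SAB) assay reports one normalized MFI per HLA
specificity per serum draw. The screening question is longitudinal: does the
newest draw's reactivity *pattern* deviate from the patient's own history by
more than the history's internal scatter?

For one patient and assay class, the package assembles the matrix of MFI
values over the beads common to all draws (rows = historic draws plus the
index draw, columns = beads), column-centers it, and projects the rows onto
the leading eigenvectors of the sample covariance matrix (divisor $n-1$).
In the resulting score space the Euclidean distance between draws measures
pattern dissimilarity, and the screening statistic is the distance ratio

$$DR = \frac{\text{mean } ED(\text{index},\ h_i)}
            {\text{mean } ED(h_i,\ h_j),\ i<j}$$

with the denominator taken over unordered *historic* pairs only. The index
sample is flagged when $DR \ge$ the threshold (inclusive). Three readings
of this statistic were genuinely open and are fixed as follows:

* **Joint PCA.** The PC basis is fitted on historic *and* index rows
  together, as one analysis per patient, rather than projecting the index
  onto a historic-only basis. A deviant index therefore attracts the
  leading components toward itself — which is precisely the behaviour that
  makes the statistic sensitive: the deviation is concentrated into the
  retained plane instead of being truncated away.
* **Denominator excludes the index.** The two natural verbal descriptions
  of the ratio ("distance of the sample of interest over the average
  distance of the other samples") are reconcilable only when the reference
  scatter is computed among the historic samples alone; including index
  pairs would dilute the numerator's own signal into the denominator.
  `fold_difference_profile()` applies the same exclusion rule to each
  sample in turn, in a single joint score space, for cohort-style analyses.
* **Covariance, not correlation, PCA.** MFI magnitude is the signal: a
  uniform 2-fold MFI rise with unchanged rank order is exactly the kind of
  event the method is expected to surface, and unit-variance scaling would
  suppress it. Variables are therefore centered but never standardized —
  in both the screening and the bead-scan orientation.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `ratio_threshold` | 1.4 | dimensionless | ROC-calibrated operating point separating stable from changed patterns; inclusive comparison ($\ge$) |
| `reactivity_cutoff` | 1000 | MFI | assay positivity cutoff; an index sample with every bead below it carries no pattern and is discarded (`nonreactive_discarded`) |
| `min_historic` | 2 | draws | below two historic draws no historic pair exists, so the denominator is undefined; reported as `insufficient_history`, not an error, so batch runs continue |
| `n_components` | 2 | — | the distance formula is defined on the PC1/PC2 plane; configurable upward, always capped at the matrix rank (rank-1 histories are measured in 1-D) |
| `epsilon` | 1e-9 | score units | degeneracy tolerance: both mean distances below it give $DR = 1$ (identical data), a zero denominator alone gives $DR = \infty$ (identical history, deviant index — flagged) |

Bead-scan inclusion uses the same cutoff with a configurable comparison
(`strict_less` for an archive-wide rule at 1000, `less_equal` for a pilot
rule at 1200), applied to each sample's maximum bead MFI: a sample
qualifies only when *all* beads are at background, because only then does
between-bead variance isolate nonspecific reactivity. Whether the original
inclusion rule meant per-sample maxima or another summary is not
documented; the per-sample maximum is the strictest reading and is the
default.

## Numerical determinism

PCA is computed by dense symmetric eigendecomposition of the covariance
matrix (or of the $n \times n$ Gram matrix when beads outnumber draws,
which shares the non-zero spectrum and is much cheaper at $p \approx 96$,
$n \approx 7$). Reruns are bit-identical: no randomized solver paths, and a
fixed sign convention — each loading vector is oriented so its entry of
largest absolute value is non-negative, ties broken by lowest variable
index. Components with numerically zero eigenvalue get all-zero scores;
a matrix with zero total variance is flagged degenerate (zero scores, zero
explained fractions). Bead rankings break distance-ratio ties by bead
identifier in C-locale order. The bead-scan ratio is normalized by the
self-inclusive grand mean, so ratios average to exactly 1.

For ROC calibration, candidate thresholds are midpoints between adjacent
distinct pooled scores plus $\pm\infty$; sensitivity uses $\ge$ (matching
the inclusive flag rule) and specificity $<$. The optimal threshold
maximizes Youden's $J$; ties resolve to the *larger* threshold, i.e. fewer
flags. The Mann-Whitney p-value is exact by enumeration when
$n_a n_b \le 400$ with no ties (configurable switchover), otherwise a
tie-corrected, continuity-corrected normal approximation.

## The synthetic cohort generator

No SAB patient data are deposited, so validation runs on a seeded
generator (`simulate_patient()`, `simulate_study()`,
`simulate_low_reactivity_archive()`) that emulates:

* a latent per-bead profile — a random subset of beads positive with means
  uniform on 2000–15000 MFI, the rest lognormal background (median 150,
  log-sd 0.5);
* multiplicative lognormal draw-to-draw noise with CV 0.15 (mean-1
  multiplier), chosen because MFI is non-negative and assay noise scales
  with signal; the CV is a realistic replicate-level figure for solid-phase
  assays;
* index events: de-novo specificities (1–2 background beads raised to
  3000–10000 MFI), global inflation of historically positive beads by a
  percent increase drawn from 119.67–243.33% (all at least 2-fold — the
  magnitude range documented for flagged pure-inflation samples), and a
  speculative prozone-like distortion (top positives suppressed to 20%,
  lower positives doubled);
* over-reactive beads in low-reactivity archives: per-bead deviations from
  the bead median scaled 5x plus sporadic near-cutoff spikes, clamped
  below the inclusion cutoff so the archive survives its own filter
  (background values at or above the cutoff are redrawn for the same
  reason).

The default study design — 25 event patients (alternating event types),
20 stable and 13 highly sensitized control patients, 5 historic draws plus
one index draw each — matches the cohort scale the method was
characterized on. What the generator does **not** model: inter-bead
correlation from shared epitopes (real beads co-vary in cross-reactive
groups), serum dilution series, lot-to-lot recalibration, and heavy-tailed
or sample-specific background shifts beyond the lognormal. Passing
recovery tests therefore demonstrate internal consistency of the method
under its stated assumptions, not clinical performance on real sera.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use: 100 random matrices (up to
10 x 20) against a brute-force covariance eigendecomposition and an SVD
(`prcomp`) oracle; exact hand geometries (equilateral triangle, unit
square) at 1e-12; 50 random ROC instances up to 50 x 50 against pairwise
concordance counts, with Mann-Whitney enumeration oracles at 8 + 8; 200
replicate studies for screening recovery and threshold transfer (train/test
batches of 12 event + 12 control patients, a realistic single-run batch
scale); and 100 replicate 96-bead x 300-sample archives for bead-scan
recovery. These sizes make the whole suite run in about a minute while
keeping the Monte-Carlo error of the recovery rates well below the margins
being asserted.

## Known limitations

* The method detects *that* a pattern changed, not *which* specificity
  drove it; bead-level attribution stays with manual review.
* Uniform 2-fold inflation is flagged by design even when clinically
  benign — the statistic is scale-invariant across the whole matrix but
  deliberately sensitive to inflation of the positive subset relative to a
  stable background.
* With few historic draws (2–3) the denominator is estimated from 1–3
  pairs and the ratio is noisy; `min_historic` is configurable upward for
  deployments that can afford it.
* Degenerate histories (identical draws) are handled by explicit rules
  rather than statistics; real data reach them only through duplicated
  uploads, which the duplicate-record checks in `read_samples_csv()` catch
  earlier.
* Threshold calibration on synthetic batches transfers within the asserted
  Youden-J gap, but a laboratory deploying the method should recalibrate
  on its own labelled cohorts (`roc_auc()` on `dr_batch()`-style data).
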