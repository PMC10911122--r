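---
title: "Echotexture banding and correlation-maximizing range search: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Echotexture banding and correlation-maximizing range search: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echorange)
```

## The problem

Quantitative muscle ultrasonography summarizes a B-mode image by first-order
statistics of its grayscale histogram inside a polygonal region of interest
(ROI): the mean numerical pixel value (NPV), its standard deviation
("heterogeneity"), and the pixel frequency distribution. Whole-ROI summaries
average over the entire 0–255 intensity scale, so a change confined to a
narrow slice of that scale — e.g., pixels near fibroadipose septa brightening
as inflammatory exudate accumulates — is diluted beyond detection.

Two refinements are implemented here:

1. **Echointensity (EI) banding** — compute NPV, SD and EI% (the percentage
   of ROI pixels in the band) separately within fixed intensity bands. Two
   conventional presets partition the 8-bit scale into 50-unit bands
   (0–50, 51–100, 101–150, 151–200, 201–255) and 25-unit bands
   (0–25, …, 226–250, 251–255).
2. **Range search** — instead of fixed bands, enumerate *every* contiguous
   intensity interval $[lo, hi] \subseteq [0, 255]$ (32,896 of them),
   compute each subject's mean intensity over the pixels falling in the
   interval, correlate those per-subject means with an external per-subject
   measurement (e.g., a protein-expression value), and report the interval
   with the strongest correlation.

## The search and its statistics

For a cohort of $n$ subjects with pixel samples $X_1,\dots,X_n$ and an
output variable $y$, the score of a range $R=[lo,hi]$ is the Pearson
product-moment correlation

$$ r(R) = \mathrm{cor}\big(\bar x(R),\, y\big), \qquad
   \bar x_s(R) = \mathrm{mean}\{v \in X_s : lo \le v \le hi\}. $$

Per-subject cumulative count/sum/sum-of-squares tables over the intensity
axis make each $\bar x_s(R)$ an $O(1)$ table difference, so the full scan is
$O(L^2 n)$ and the correlations for all ranges (and, in the permutation
test, all permutations at once) reduce to a handful of matrix products.

**Objective.** The search maximizes $|r|$, not $r$: a strong negative
correlation between a range's mean and a marker is as informative as a
positive one, and empirically selected ranges can carry either sign.

**Admissibility.** A subject enters a range's correlation only if it has at
least `min_pixels_per_subject` pixels there. By default, subjects below the
floor are excluded pairwise and a range is skipped when fewer than 3
subjects remain; `strict = TRUE` requires every subject to meet the floor.
For recovery-style analyses we recommend — and the test suite uses —
`range_constraints(min_pixels_per_subject = 25, strict = TRUE)`: with
pairwise exclusion at the default floor of one pixel, sparsely populated
ranges supported by as few as 3 subjects reach $|r| \approx 1$ by chance
alone and swamp any real signal. That pathology is inherent to comparing
correlation magnitudes across different effective sample sizes, not an
implementation artifact, so the default remains faithful to the permissive
convention while the strict configuration is what a practitioner should use
when the goal is locating a reproducible range.

**Ties.** Ranges whose $|r|$ is within $10^{-9}$ of the maximum are
reported together; the winner is the narrowest, then lowest-`lo`, tied
range. With an exact affine marker (coupling 1 in the generator), the
planted range attains $|r| = 1$ and appears in the tie set.

**Selection bias.** The naive two-tailed Pearson p of the winning range
treats it as if it had been chosen a priori, which after a scan over tens
of thousands of candidates is wildly anti-conservative — on null cohorts
the naive p falls below 0.05 in essentially every run. The package
therefore provides `max_r_permutation_test()`: the output variable is
permuted across subjects, the *entire* search is re-run per permutation,
and the family-wise p is $(1 + \#\{\max|r|_{perm} \ge \max|r|_{obs}\}) /
(n_{perm}+1)$. Because the output variable is exchangeable across subjects
under the null, this p is exact up to permutation-sampling noise; its
rejection rate at $\alpha = 0.05$ on null cohorts is nominal.

**Scattered sets.** Arbitrary (non-contiguous) intensity subsets cannot be
searched exhaustively ($2^{256}$ candidates). A greedy forward selection is
provided: the per-subject mean of a *singleton* intensity is the intensity
itself — constant across subjects, with undefined correlation — so the
greedy search starts from the best *pair* of intensities (found
exhaustively over all pairs) and then adds one intensity at a time while
$|r|$ improves by more than a tolerance. The greedy trace is returned so
the heuristic's path is auditable. It is a heuristic: it inherits no
optimality guarantee beyond its first exhaustive step.

## Statistical kernels and conventions

- **Pearson correlation**: p from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on
  $t(n-2)$, two-tailed; $|r|=1$ reports $p = 0$.
- **Group comparison**: classical pooled-variance Student t (two-sided),
  with Welch available behind a flag; groups are summarized as mean ± SEM.
- **SD convention**: within-ROI and within-band SDs are *population* SDs
  (denominator $n$), the convention of bitmap-analysis software; sample SD
  is available via `sd_type = "sample"`. SEM uses the sample SD.
- **Empty bands** report missing NPV/SD (never zero), and subjects missing
  a band are excluded pairwise from that band's correlations, with the
  correlation reported missing below 3 complete pairs.
- **Normalization**: $G_i = T\,(f_i - f_{\min})/(f_{\max} - f_{\min})$ with
  per-image extremes by default (cohort-wide extremes available via
  `f_min`/`f_max` or the pipeline's `global_minmax`), rounded to the
  nearest integer with ties away from zero, clamped to $[0, T]$. The map is
  idempotent and order-preserving. Constant images are rejected.
- **Rasterization**: a pixel belongs to a polygonal ROI iff its center
  (integer coordinates, x = column, y = row, 0-based) satisfies the
  even-odd rule; centers exactly on an edge are resolved by a half-open
  rule (left/top edges inclusive), implemented by testing the center
  nudged by $+10^{-7}$ in both coordinates.
- **Pipeline order**: convert to grayscale → normalize → mask, i.e., ROI
  statistics are computed on normalized images.

## The synthetic cohort generator

No in-vivo data ship with the package, so every stage is validated against
a seeded generator (`generate_cohort()`) that emulates a 12-subject,
two-group (6 "sham" / 6 "surgery") imaging study:

- **Speckle background**: intensities drawn from a gamma distribution
  (shape 4, scale 16; mean 64), rounded and clipped to 0–255 — a standard
  stand-in for the right-skewed first-order statistics of B-mode speckle.
- **Between-subject texture heterogeneity**: each subject replaces half of
  its pixels with draws from its own random mixture of 10 Gaussian
  intensity bumps (centers uniform on 0–255, SD 5–15). Real muscle
  ultrasonograms differ between animals in fiber composition, septa and
  gain response, so per-subject histograms differ in *localized* intensity
  neighborhoods; without this feature all subjects share one histogram and
  every range's mean is essentially the same function of the planted
  signal, which makes range recovery ill-posed at realistic sample sizes.
- **Planted signal**: within the planted range (default 86–101, a range of
  the width reported in comparable analyses), half of each subject's
  in-range pixels are brightened by `pixel_gain` (default 3) intensity
  units per unit of a latent lognormal(0, 0.4) value, clamped at the range
  ceiling so the signal stays confined to the range. The latent value is
  shifted additively by `group_effect` (default 1) in the surgery group,
  producing roughly a 2-fold group difference in coupled markers — the
  magnitude reported for inflammatory mediators in comparable studies.
- **Markers**: each coupled marker equals the subject's realized in-range
  mean plus independent Gaussian noise calibrated so the correlation with
  that mean matches the `coupling` target (0.9 by default; 1 gives an
  exact affine relation, 0 gives markers independent of the images). Null
  markers are independent lognormal draws. Default marker names mirror a
  five-mediator panel (three coupled: CaMKII, ERK1/2, substance P; two
  null: CGRP, PAR2).
- **Reproducibility**: all randomness flows from one seed through four
  named substreams (images/ROIs, latents, planting, marker noise), so the
  same seed reproduces the cohort byte for byte.

**What the generator does not emulate**: spatial speckle correlation
(pixels are i.i.d. given the histogram), point-spread-function blur,
attenuation/depth gain artifacts, anatomically structured septa, or
measurement error in ROI placement. Passing tests therefore demonstrate
the *statistical* machinery — enumeration, correlation, selection,
calibration — not robustness to spatially structured imaging artifacts.

## Problem sizes and numerical choices in the test suite

- Oracle equivalence runs 20 cohorts at $L = 31$ (10 subjects × 500
  pixels), where a brute-force re-computation of every range mean is fast;
  agreement is required to $10^{-12}$ in $r$.
- Planted-range recovery runs 50 seeds at the full study scale (12
  subjects, ≈13,500 ROI pixels from 128×128 images). At coupling 0.9 the
  selected range overlaps the truth with Jaccard ≥ 0.5 in well over half
  the seeds (the suite fixes the threshold at 60%); perfect recovery of a
  16-value range from 12 noisy observations is not statistically
  attainable, because ranges heavily overlapping the truth carry almost
  the same information. At coupling 1.0 the planted range attains
  $|r| = 1$ and appears in the tie set in every seed.
- Permutation calibration uses 200 null cohorts (64×64 images keep the
  run in minutes) with 199 permutations; the naive-p rejection rate
  demonstrates the selection bias, the permutation rejection count must
  fall in the central 95% binomial interval around 0.05.
- The study-design emulation runs 16 seeds and requires the
  coupled-vs-null contrast (all three coupled markers significant in
  selected-range NPV, neither null marker significant) in more than half
  of them, with banded NPVs showing no systematic group differences
  (mean significant fraction ≤ 0.15 across the 16 band tests — 16 t-tests
  at $\alpha = 0.05$ make occasional isolated rejections expected even
  under a true null).
- Band identities (EI% conservation, mean reconstruction, law of total
  variance) hold to $10^{-9}$ or better on all fixtures.

## Known limitations

- The scattered-set search is greedy; only its first step is exhaustive.
- The permutation test permutes the output variable, which also destroys
  any group structure; it tests the global null of no range/marker
  association, not a group-adjusted null.
- Band tables apply no multiple-testing correction (deliberately, to
  mirror conventional banded reporting); the permutation test is the
  provided remedy for the searched maximum only.
- Images are assumed pre-cropped 8-bit PNG/TIFF; DICOM, cine loops and
  speckle-reduction filtering are out of scope.
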