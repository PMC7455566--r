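---
title: "Feature diagnosticity mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature diagnosticity mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdimap)
```

## The problem and the method

Which parts of an image does a person actually use when they recognize it?
Classification-image ("reverse correlation") methods answer this by showing
many randomly perturbed stimuli and correlating the random variation with
the observer's responses. `fdimap` implements a sparse-feature variant of
this idea:

1. **Decomposition.** Each grayscale image is reduced to a bank of 1,000
   Gabor wavelets — localized, oriented gratings that jointly approximate
   the image. Wavelets are the natural vocabulary here because they
   factorize an image into position, orientation and spatial frequency, the
   dimensions along which hypotheses about detail-oriented vision are
   stated.
2. **Probing.** Each trial presents a *partial reconstruction*: the sum of
   a random 90-wavelet subset, rescaled to the full 0–255 display range.
   Observers report the image category (e.g. cat vs dog) or "unsure".
3. **Feature diagnosticity.** For every participant, image and feature, the
   *feature diagnosticity index* (FDi) is the mean recognition accuracy
   over the trials whose subset contained that feature, z-scored within
   each participant × image slice.
4. **Statistics.** FDi maps are validated by split-half replicability
   against a feature-label permutation null, then related to feature
   spatial frequency (or distance from the eyes / image center) via binned
   ANOVAs, and to questionnaire-measured autistic traits via
   reliance-on-detail slopes, per-trait effects and a robust regression on
   clinical trait diagnosticity.

A simulated-observer generator plants known feature weightings, so every
stage can be validated by parameter recovery without human data.

## The wavelet dictionary

Spatial frequencies follow a 29-level geometric ladder,
$sf(n) = \tfrac{10}{45} \times 1.08^{n}$, spanning 0.24 to 2.07 cycles per
degree of visual angle (cycles/dva) at the default geometry of a 250 px
image covering 22.5°. The number of wavelets sampled per frequency grows as
a power law, $nw(sf) = 272 \times sf^{1.8}$ (21 at the coarsest level,
1,008 at the finest), so that the dictionary allocates capacity roughly in
proportion to the number of distinguishable positions at each scale.
Orientations are quantized to 18 equidistant values (0°–170°).

```{r ladder}
round(ladder_sf(c(1, 15, 29)), 3)
features_per_sf(ladder_sf(c(1, 29)))
```

Two dictionary parameters are not dictated by the ladder and were fixed as
package defaults:

* **Envelope width.** The Gaussian envelope SD is half the carrier
  wavelength (`sigma_factor = 0.5`), the usual ~1-octave bandwidth choice
  in spatial-vision work; it keeps coarse wavelets spatially extended and
  fine wavelets local. It is configurable in `decomposition_config()`.
* **Phase.** Phase is treated as continuous in $[0, 2\pi)$ and estimated
  from the arctangent of the quadrature (even/odd) filter responses rather
  than quantized: the decomposition looks for the *optimally fitting*
  phase at each pixel, and the quadrature pair gives it in closed form.

## The decomposition algorithm

`decompose()` proceeds coarse-to-fine through the ladder. At each level:

1. Even/odd Gabor filter pairs at all 18 orientations are applied by FFT
   convolution with reflective boundary padding (avoiding edge ringing that
   would bias amplitudes at image borders). Even kernels are mean-corrected
   so responses ignore the image mean. Per pixel, the best orientation,
   phase and response amplitude are kept.
2. Only the top 25% of pixels by amplitude are retained; `nw(sf)` of them
   are sampled uniformly without replacement.
3. Each sampled wavelet's **sample covariance** with the level's input
   image is computed (both arrays mean-centered, $n-1$ denominator), and
   wavelets below one fifth of the maximum observed covariance are
   discarded. Covariance is measured on unit-amplitude renderings: final
   amplitudes are equal anyway, and this keeps the discard rule a pure
   shape-match criterion.
4. The next level's input is the residual of the current input after
   least-squares regression on the wavelets just selected (plus an
   intercept, which absorbs DC drift across levels; the residual is
   orthogonal to every regressor, so later levels cannot re-select already
   explained structure). The regression design is sparse — each wavelet is
   supported on a ±6σ window — and the normal equations are solved with a
   small ridge fallback if the design is rank-deficient.

Finally, candidates pooled over all levels are ranked by **signed**
covariance with the *original* image and the top `n_final` (default 1,000)
are kept with equal amplitudes. Signed — rather than absolute — covariance
is used for consistency with the mid-iteration discard rule, which compares
signed values against a signed maximum. The returned bank is ordered by
covariance, so the best-$k$ sub-bank is a prefix.

Two behaviors worth knowing: when `nw` exceeds the available post-screen
candidates, all of them are taken (logged); a level where no wavelet
survives the covariance floor simply contributes nothing (warning), which
happens routinely at fine scales on sparse synthetic images.

## The simulated observer

`simulate_cohort()` and `simulate_experiment()` define the study conditions
the package is tested under:

* **Cohort.** 52 participants by default; AQ questionnaire totals drawn
  from a normal distribution with mean 14.3 and SD 5.9, truncated to 5–30
  and rounded — the range and moments typical of neurotypical student
  samples. Each participant endorses exactly `aq_total` of the 50 items,
  uniformly at random; the five canonical 10-item subscales are scored from
  the endorsements. The high-AQ group is everyone strictly above the cohort
  median. Session counts are drawn from the empirical distribution 6, 5, 4,
  3, 2 sessions for 2, 14, 25, 10, 1 of 52 participants; each session has
  50 trials per image.
* **Ground-truth weights.** Feature $f$ of a bank has planted diagnosticity
  $w_f = b_f + c_p \, z(sf_f)$, where $b_f$ is the feature's normalized
  covariance rank (in $(0,1]$) and $c_p$ is the participant's
  spatial-frequency coupling: `sf_coupling[group]` (defaults 0 for low-AQ,
  0.05 for high-AQ) plus `item_coupling` (default 0.01) times the sum of
  centered clinical log-diagnosticities of the endorsed items. The second
  term makes reliance-on-detail scale with *which* traits a participant
  endorses, not just how many — the structure the trait-level statistics
  are designed to recover. `base_weight_scale = 0` flattens $b_f$ and, with
  zero couplings, yields the fully uninformative (pure-noise) observer used
  for null calibration.
* **Decision rule.** Trial evidence is the mean planted weight of the 90
  presented features plus Gaussian noise (SD 0.04); responses are the
  correct category above 0.5, the wrong category below 0.46, "unsure"
  in between. The mean (not the sum) makes difficulty invariant to subset
  size and keeps thresholds on the weight scale. These defaults put cohort
  marginals near 50% correct / 21% wrong / 29% unsure — a calibration
  anchor of the generator, not a reproduction claim.
* **Reaction times.** $\max(150, \mathcal N(\text{base}_p, 313))$ ms with
  per-participant baselines around 895 ms. By default RT carries *no*
  feature information, so RT-based FDi correctly fails to replicate;
  setting `rt_coupling_ms > 0` plants RT structure for positive testing of
  the RT pipeline.

The planted effect sizes were chosen once, when the generator was designed,
to be comfortably detectable at the simulation scales used by the test
suite (they correspond to top-bin group differences a few times larger than
what human data of this kind show); they are parameters of the testbed, not
estimates.

What the generator does **not** emulate: perceptual grouping and configural
cues (evidence is linear in feature weights), lapses and response biases,
learning across sessions, and any dependence of RT on difficulty by
default. Passing recovery tests therefore demonstrates that the estimator
chain is correct and calibrated — not that real recognition behaves like
the linear observer.

## FDi estimation choices

* **Correctness coding.** "Unsure" and wrong-category responses both count
  as non-recognition; accuracy is `response == true_category`.
* **Z-scoring.** Within each participant × image slice, the sample SD
  ($n-1$; configurable to population SD) is used. Z-scoring removes
  between-image recognizability and between-participant performance
  differences, which is what makes FDi values comparable and poolable.
* **Missing cells.** A feature never shown to a participant for an image
  (under 1% of cells at 200 trials/image with 90/1000 sampling) is imputed
  as 0 *after* standardization and counted in a message: 0 is the
  no-information value on the z scale and keeps the flattened 10,000-vector
  correlations well defined. A constant slice (e.g. an all-correct
  participant-image) is uninformative and set to all zeros with a warning.
* **Split-half replicability.** Participants are split 100 times into
  halves of ⌈n/2⌉ and ⌊n/2⌋; FDi is averaged within each half; the Pearson
  correlation between the two flattened image × feature maps is averaged
  over splits. The permutation null re-computes that statistic with the
  second half's feature labels freshly permuted per iteration while reusing
  the observed splits — permutation across splits at a cost of
  `n_perm × n_splits` correlations — and the p-value uses the add-one
  estimator, so $p \in (0, 1]$ and the floor is $1/(1+n_\text{perm})$.
* **RT variant.** `rt_fdi()` substitutes per-feature mean RT for accuracy,
  using all trials by default (`correct_only = TRUE` restricts), since
  restricting to correct trials would entangle the RT map with the accuracy
  map.

## Binning and the group ANOVAs

Features of all images are pooled (10 × 1,000 by default) and sorted by the
criterion — spatial frequency, distance to the nearest eye landmark, or
distance to the image center, distances in dva — with ties broken by image
then feature id, and cut into five equal bins (2,000 features each;
remainders go to the lowest bins). Bin boundaries are data-dependent and
reported, not fixed constants.

Each participant's mean FDi per bin feeds a 5 × 2 (bin × AQ group) ANOVA.
`two_way_anova()` deliberately offers two error terms:

* `error = "flat"` (default) tests all effects against the pooled residual
  of the fixed-effects model on cell means, giving the error-df pattern
  (4, 250) for 52 participants — the convention this machinery mirrors.
* `error = "within"` is the calibrated repeated-measures test. Because the
  five bin means of a z-scored participant sum to exactly zero, the subject
  main variance is exactly zero, and the flat residual then over-counts the
  subject-stratified error df by a factor $b/(b-1)$ — inflating F by 1.25
  and the nominal 5% test to a true size near 10.7%. The within-participant
  error term (df $(n-g)(b-1)$) restores the nominal size, as the package's
  null-calibration tests verify over 200 simulated cohorts. The pipeline
  uses `"within"` for inference and keeps `"flat"` for comparability of the
  df pattern.

Type II sums of squares are used for the unbalanced group factor (e.g.
25 vs 27 after a median split). The highest-bin group contrast is a
pooled-variance two-sample t-test (df $n_1+n_2-2$; Welch available behind a
flag). The recognition-rate ANOVA (category × group on 52 × 2 cell means,
flat error df 100) uses the same machinery.

## Trait statistics

*Reliance-on-detail* is the OLS slope of a participant's five bin means on
bin index 1–5. A trait's *effect* is the difference in mean
reliance-on-detail between endorsers and non-endorsers of that AQ item —
the simplest contrast consistent with asking how the *presence* of a trait
shifts reliance; items endorsed by everyone or no one have undefined
effects and are reported as missing. *Clinical diagnosticity* of a trait is
the natural log of its endorsement-prevalence ratio between diagnosed ASD
individuals and neurotypical controls (ln 7.7 ≈ 2.04); prevalence tables
are user-supplied CSVs, and a clearly labelled synthetic table
(`synthetic_trait_table()`, also shipped as
`inst/extdata/synthetic_trait_table.csv`) stands in for published values in
tests — its log-diagnosticities are planted highest for social-skill items
and lowest for attention-to-detail items, echoing the published pattern,
with a constant 0.10 control prevalence so the log-ratio is exact.

The effects-on-diagnosticity regression uses iteratively reweighted least
squares with Tukey bisquare weights (`MASS::rlm`), t = slope / robust SE,
df = n − 2. The estimator choice is a package decision — worth flagging,
since several robust estimators exist; bisquare IRLS is the common default
and coincides with OLS on clean linear data (degenerate zero-residual fits
are returned as exact OLS, where the bisquare scale is undefined). The
subscale analysis is a one-way ANOVA across the 50 item effects (df 4, 45)
with five pooled-variance t contrasts of each 10-item subscale against the
other 40 (df 48), Bonferroni-corrected (×5, capped at 1).

## Numerical conventions

* Pixel coordinates are 0-based column (x) / row (y) indices of pixel
  centers; the image center of a 250 px image is (124.5, 124.5).
* Display rescaling maps min→0, max→255 with round-half-to-even, making
  8-bit outputs bit-identical across platforms; constant images are a
  degenerate-input error.
* Wavelet support is truncated at ±6σ for sums, covariances and regression
  designs (envelope < 2e-8 of peak outside), and at ±3.5σ for the
  quadrature filter kernels.
* All randomized operations take explicit integer seeds and restore the
  caller's RNG state; per-stage streams are derived from the global seed by
  hashing, so pipeline outputs are byte-identical across runs with the same
  seed.

## Problem sizes used in the test suite

The suite validates the full method at reduced, fixed scales chosen to keep
it fast while leaving the statistics well-powered: parameter recovery on a
52-participant cohort with 10 synthetic 1,000-feature banks at 200 vs 50
trials/image; null calibration over 200 cohorts of 13 participants, 2
images × 500 features; planted-effect detection over 20 cohorts (26 or 52
participants, 4 images × 500 features); decomposition sanity on a 100 px
image with 20 planted wavelets. Split-half permutation tests in the suite
use 20–50 splits and 99–499 permutations; the package defaults (100 splits,
10,000 permutations) match the method's standard operating point.

## Known limitations

* The decomposition is a greedy screen-and-rank procedure, not matching
  pursuit or sparse coding; it is faithful to the method it implements but
  will not produce minimal-error dictionaries.
* Equal final amplitudes mean reconstruction error is not monotone in bank
  size once the bank saturates a sparse image; on natural images at the
  default 1,000 features the under-complete regime applies.
* The flat-df ANOVA variant is reported for comparability but is liberal
  for z-scored bin means (see above); use the within-participant error for
  inference.
* The observer model is linear and memoryless; it is a testbed for the
  estimators, not a model of human recognition.
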