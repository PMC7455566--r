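# fdimap — feature diagnosticity mapping for image recognition

`fdimap` asks which low-level visual features drive the recognition of a
natural image, and whether reliance on fine detail scales with autistic
traits. It is aimed at visual psychophysicists and cognitive
neuroscientists running reverse-correlation ("classification image")
experiments with sparse feature dictionaries.

The workflow:

1. **Sparse decomposition.** A grayscale image is reduced to a bank of
   1,000 equal-amplitude Gabor wavelets. Spatial frequencies follow a
   29-level geometric ladder, *sf*(n) = (10/45) · 1.08ⁿ (0.24–2.07
   cycles/degree of visual angle); the number of wavelets sampled per
   frequency grows as *nw* = 272 · *sf*^1.8 (21 at the coarsest level,
   1,008 at the finest). Selection is iterative and coarse-to-fine:
   quadrature Gabor filters find the best orientation/phase per pixel, the
   top 25% by amplitude are screened, *nw* are sampled, low-covariance
   candidates are dropped, the explained structure is regressed out, and
   the pooled survivors with the highest covariance against the original
   image form the bank.
2. **Probe trials.** Each trial shows the sum of a random 90-feature
   subset, rescaled to the full 0–255 range; observers answer "cat", "dog"
   or "unsure".
3. **Feature diagnosticity index (FDi).** Per participant × image ×
   feature: mean recognition accuracy over trials containing the feature,
   z-scored within each participant × image slice. Validated by split-half
   replicability across participants against a feature-label permutation
   null.
4. **Group and trait statistics.** Features are pooled into five
   equal-size ascending bins (by spatial frequency, eye distance or
   center distance); bin × AQ-group ANOVAs, a highest-bin group contrast,
   per-participant reliance-on-detail slopes (OLS on bin index 1–5),
   per-AQ-item effects, and a bisquare robust regression of item effects
   on clinical trait diagnosticity, ln(prevalence ratio).
5. **Simulated observers.** `simulate_experiment()` plants known feature
   weightings (a spatial-frequency coupling for high-AQ participants and
   per-item couplings proportional to trait diagnosticity) so the entire
   chain is testable by parameter recovery, null calibration and power
   checks.

## Worked example

Simulated cohort of 26 participants, four synthetic 500-feature banks,
100 trials per image:

```r
library(fdimap)

ids   <- c("cat01", "dog01", "cat02", "dog02")
banks <- lapply(setNames(nm = ids), function(id)
  synthetic_feature_bank(id, n_features = 500, seed = match(id, ids)))

sim <- simulate_experiment(cohort_config(n_participants = 26), banks,
                           seed = 1, n_sessions = 2)
sim
#> <fdi_simulation> 10400 trials, 26 participants, 4 images; 50.6% correct

fdi <- compute_fdi(sim$trials, n_features = 500)
permutation_p(fdi, n_splits = 50, n_perm = 999, seed = 1)
#> <replicability> accuracy FDi: mean split-half r = 0.3459, p = 0.001 (50 splits, 999 permutations)

fv   <- feature_values(banks, "sf")
bins <- assign_bins(fv$value, 5, fv$image_id, fv$feature_id)
bm   <- participant_bin_means(fdi, bins)
bin_group_anova(bm, sim$cohort$profiles$group, error = "within")
#> <anova_result>
#>   bin                F(4, 96) = 8.153, p = 1.055e-05
#>   bin:group          F(4, 96) = 11.003, p = 2.186e-07
```

Reading the output: FDi patterns replicate across cohort halves (r = 0.35
against a permutation null floor of 0.001), and the planted
spatial-frequency coupling of the high-AQ group surfaces as the bin × group
interaction. The highest-bin contrast makes the direction explicit
(`highest_bin_contrast(bm, groups)`: t(24) = 4.38, mean FDi 0.033 for
high-AQ vs −0.034 for low-AQ), and the trait route
(`reliance_on_detail()` → `trait_effects()` → `robust_regress()`) recovers
a positive slope of item effects on clinical diagnosticity.

Real data enter through `decompose()` (PNG images → feature banks),
`ingest_trials()` (behavioral CSV) and `read_trait_table()` /
`read_landmarks()`; `run_pipeline(run_config(...))` ties the stages
together and writes FDi tables, replicability/ANOVA/trait JSON reports and
a summary. A thin CLI lives at `inst/scripts/fdimap`
(`fdimap decompose`, `fdimap run`).

Note on ANOVA error terms: `two_way_anova(..., error = "flat")` reproduces
the conventional flat error-df pattern (interaction F(4, 250) for a 52 × 5
× 2 design) but is structurally liberal for z-scored bin means;
`error = "within"` is the calibrated repeated-measures test and is what the
pipeline reports. See the methods vignette
(`vignettes/feature-diagnosticity-mapping.Rmd`).

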