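# microstatr

Resting-state EEG **microstate** analysis in R: two-level
polarity-invariant modified k-means segmentation, template backfitting,
temporal metrics, and the group-comparison statistics used to ask
whether microstate dynamics differ between clinical groups — for
example, between patients who do and do not go on to develop chronic
postoperative pain. A seeded synthetic cohort generator with full
ground truth makes every stage verifiable on a desk machine.

## The method

EEG topographies are quasi-stable for ~80–120 ms at a time
(*microstates*, classically four classes A–D). The pipeline:

1. **GFP** — global field power, the spatial SD of the scalp map at
   each sample: `GFP(t) = sqrt(mean_c (v_c(t) − v̄(t))²)`. Topographies
   at GFP peaks (outliers above mean + 2 SD of peak GFP removed) enter
   clustering.
2. **Modified k-means, disregarding polarity** — maps are assigned by
   maximal `|corr|`, centers are sign-aligned means, re-normalized;
   100 random restarts keep the best solution by **GEV**
   (GFP-weighted explained topographic variance); a **CV criterion**
   penalizes template count against channel count. Clustering runs per
   subject (k = 4), then the pooled individual templates are
   re-clustered across subjects and labeled A–D against canonical
   reference maps.
3. **Backfitting** — every sample gets the class of the most similar
   template, yielding per subject: duration (ms), occurrence (runs/s),
   coverage (%), and 12 transition percentages that sum to 100.
4. **Statistics** — Shapiro–Wilk-routed t / Mann–Whitney comparisons
   with Cohen's d (HP − LP), 2 × 4 mixed ANOVA, covariate-adjusted GLM,
   Benjamini–Hochberg FDR per family, and Pearson/Spearman metric–NRS
   correlations.

## Worked example

```r
library(microstatr)

cfg <- sim_config(n_hp = 7, n_lp = 13, length_s = 60, snr = 5, seed = 101)
coh <- simulate_cohort(cfg)          # recordings + metadata + ground truth
fit <- fit_microstates(coh$recordings, restarts = 20, seed = 102)
fit
#> Two-level microstate segmentation (k = 4)
#>   subjects: 20
#>   mean backfit GEV: 0.9641
#>   group template GEV (peak maps): 1

abs(diag(cor(coef(fit), coh$ground_truth$templates)))
#>         A         B         C         D
#> 0.9999991 0.9999992 0.9999995 0.9999990
```

The fit recovers the four planted topographies essentially exactly at
SNR 5, and the mean backfit GEV of 0.96 says the four templates explain
96% of the GFP-weighted topographic variance — on real recordings
values around 0.8 are typical, the synthetic cohort being cleaner than
patient EEG. `fit$metrics` holds one row per subject
(duration/occurrence/coverage per class and the 12 transition
percentages); `microstate_stats(fit$metrics, coh$subjects)` runs the
full group battery:

```r
st <- microstate_stats(fit$metrics, coh$subjects)
st$anova$occurrence$posthoc[3, c("comparison", "test", "p", "p_fdr", "d")]
#>   comparison test          p      p_fdr        d
#> 3      occ_C    t 0.03312928 0.06625855 1.081717

st$nrs_correlation$spearman
#>        rho          p
#> 0.60945698 0.00433505
```

The planted MS-C occurrence effect surfaces with realized d = 1.08 and
raw p = .033 in this 20-subject cohort (after BH correction across the
four classes it just misses .05 — at this scale that is expected; the
generator calibrates the population effect, 0.88 by default, for the
full 21/45 cohort). The coverage–NRS Spearman correlation lands at its
design target of ~0.6. A full simulate → segment → test → write run is
one call: `run_pipeline(default_config(), out_dir = "out")`.

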