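---
title: "Microstate segmentation and group statistics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate segmentation and group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstatr)
```

## The model

Resting-state EEG does not wander continuously through topography space:
for stretches of roughly 80–120 ms the scalp potential field keeps one
quasi-stable spatial configuration, then switches abruptly to another.
These stretches are *microstates*, conventionally reduced to four classes
(A–D). `microstatr` implements the standard two-level segmentation:

1. **Global field power (GFP).** For a scalp voltage vector $v(t)$ over
   $C$ channels, $\mathrm{GFP}(t) = \sqrt{\tfrac1C \sum_c (v_c(t) -
   \bar v(t))^2}$ — the spatial SD of the momentary topography. GFP
   peaks are the moments of highest topographic signal-to-noise and the
   only samples used for clustering. Peaks whose GFP exceeds
   mean + 2 SD of all peak GFPs are discarded as residual artifacts.
2. **Polarity-invariant modified k-means** on the peak topographies. A
   topography and its sign-flipped copy represent the same generator
   configuration, so assignment uses the absolute spatial (Pearson)
   correlation, and the center update is the *sign-aligned* mean of
   cluster members, re-centered to zero mean and re-normalized. Each of
   `restarts` random initializations (k maps drawn without replacement)
   is iterated to convergence; the restart with the highest global
   explained variance wins. With $L(t)$ the assignment and $a_k$ the
   unit-norm templates,
   $$\mathrm{GEV} = \frac{\sum_t \big(\mathrm{GFP}(t)\,
   \mathrm{corr}(v(t), a_{L(t)})\big)^2}{\sum_t \mathrm{GFP}(t)^2},$$
   and the cross-validation criterion is the residual variance
   $\hat\sigma^2 = \sum_t \big(v_t^\top v_t - (a_{L(t)}^\top v_t)^2\big)
   / (T(C-1))$ scaled by $((C-1)/(C-K-1))^2$, penalizing template count
   against channel count.
3. **Two levels.** K-means runs per subject on that subject's peak maps
   (k = 4); the resulting 4-per-subject templates are pooled and
   re-clustered across subjects. Group maps are labeled A–D by the
   one-to-one matching to canonical reference topographies (A/B the two
   diagonal gradients, C the occipital-dominant symmetric map, D the
   fronto-central extremum) that maximizes total polarity-invariant
   similarity over all 4! permutations.
4. **Backfitting and metrics.** Every unmasked sample of every recording
   gets the label of the template with maximal $|\mathrm{corr}|$. From
   the label sequence: mean **duration** (ms) per class, **occurrence**
   (runs/s), **coverage** (% of unmasked samples), and the 12
   off-diagonal **transition percentages**, defined jointly as
   $100 \cdot \#(i \to j) / \#(\text{all transitions})$ so that the
   twelve values sum to 100.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `k` | 4 | number of microstate classes; fixed by design, no meta-criterion |
| `restarts` | 100 | random k-means restarts, best GEV kept |
| `peak_rule` | `"mean+2sd"` | GFP-peak outlier screen; `"2sd"` is the literal alternative reading |
| band-pass | 0.1–80 Hz | broadband resting EEG band |
| notch | 48–52 Hz | 50 Hz mains |
| `target_sfreq` | 500 Hz | analysis sampling rate |
| `alpha` | .05 | two-sided significance level |

Choices that were genuinely open, and how they were settled:

* **Peak exclusion.** "Two times the standard deviation of all GFP
  peaks" admits two readings; the mean + 2 SD outlier convention is the
  default, the bare 2 SD threshold is available as `peak_rule = "2sd"`.
  On synthetic data the two rarely differ (the peak-GFP distribution is
  unimodal with mean well above 2 SD).
* **"Iterated 100 times"** is read as 100 random restarts keeping the
  best-GEV solution, with up to 1000 update sweeps per restart
  (convergence in practice takes < 30). The alternative reading — a cap
  of 100 update iterations — is strictly weaker and is subsumed by the
  `max_iter` argument.
* **Center update.** The sign-aligned arithmetic mean reconciles "mean
  of all data within the set" with polarity invariance. The
  eigenvector update (principal axis of the weighted outer-product sum)
  is the GEV-optimal center and is used as the *oracle* in tests; on
  well-separated clusters both yield the same partition with GEV
  differences below 0.005.
* **Backfitting** labels every sample, not only GFP peaks, and applies
  no temporal smoothing or minimum-duration rejection. Ties in
  $|\mathrm{corr}|$ go to the lowest class index; zero-variance samples
  inherit the previous valid label (the next one at the start).
* **Reference.** Data are converted to common average reference before
  any topographic step, the standard in the microstate literature (the
  spatial correlation mean-centers maps regardless, so this is mostly a
  presentation choice). Averaged-mastoid re-referencing applies only at
  the preprocessing stage when M1/M2 are present.
* **Boundary runs** (touching the recording edge or a mask edge) count
  toward duration and occurrence; at 5-minute scale the truncation bias
  is negligible.
* **Filters.** Zero-phase (forward–backward) Butterworth. The 0.1 Hz
  high-pass corner is five decades below Nyquist at 500 Hz, where a
  single transfer-function band-pass is numerically fragile, so the
  band-pass is applied as a cascade: 2nd-order high-pass at 0.1 Hz,
  then 4th-order low-pass at 80 Hz. Bad segments are masked, never
  spliced out, so sample indices stay aligned with ground truth; no run
  or transition is counted across a mask boundary.
* **Bad channels** are repaired by inverse-distance-weighted
  interpolation over the 4 nearest good electrodes; spherical splines
  would be the heavier alternative. More than three damaged channels
  excludes the subject (a `subject_excluded` condition the pipeline
  logs and survives).

## The synthetic cohort generator

No public recordings accompany the study conditions this package
validates against, so `simulate_cohort()` generates a cohort with the
statistical structure the analysis assumes, plus full ground truth:

* **State dynamics.** A semi-Markov chain over K = 4 classes: run
  lengths are gamma (mean 100 ms, shape 4, i.e. bulk mass at 80–120 ms),
  successors drawn from an off-diagonal row-stochastic matrix (uniform
  1/3 by default), initial state from the embedded chain's stationary
  distribution.
* **Rendering.** `signal = envelope × template[label(t)] + noise` on a
  30-channel 10–20 montage. The envelope is `0.3 + |sin(2π·10t + φ)|`:
  a 10 Hz alpha carrier plausible for eyes-closed rest, with a strictly
  positive floor so every sample carries a well-defined topography.
  Polarity alternates randomly between runs, as oscillatory topographies
  do in real EEG — microstate analysis disregards it, and it keeps the
  rendered channels free of a standing DC topography that a high-pass
  filter would otherwise remove. Spatially white Gaussian noise is
  scaled so RMS(signal)/RMS(noise) equals the configured SNR exactly
  (default 5). Amplitudes are arbitrary units: only topography shape
  matters downstream.
* **Cohort structure.** 21 high-pain (HP) and 45 low-pain (LP) subjects
  by default. Between-subject heterogeneity enters as lognormal jitter
  on the mean duration (SD 0.12 on the log) and on a multiplicative
  bias of transition entries into class C (SD 0.3 on the log). The HP
  group's log-bias is shifted by a calibrated amount so that the
  standardized group difference (Cohen's d) in *true* MS-C occurrence
  equals the configured effect, 0.88 by default. The calibration solves
  for the shift with deterministic Gaussian-quantile quadrature over
  the subject-level parameters, including an analytic term for the
  finite-recording sampling variance of the run count (the long-run
  variance of the class indicator along the embedded chain plus the
  gamma renewal-count variance) — the planted effect refers to the
  realized label-sequence metric, not to an idealized infinite
  recording. Planting the effect on the transition matrix (rather than
  adding offsets to metrics) makes occurrence, coverage and
  transition effects co-occur, as they do in the clinical tables.
* **Pain scores.** NRS is drawn as integers 4–10 (HP, weights falling
  from 4 to 10) and 0–3 (LP), then rank-matched within group to each
  subject's true C coverage with rank noise of 0.5 × group size,
  targeting a cohort-level Spearman correlation of about 0.6 between C
  coverage and NRS; the realized value varies by cohort (SD ≈ 0.09).
* **Covariates** (age, BMI, education, BDI-II, ASA, surgery type, ALND,
  chemotherapy flags) are drawn from distributions matching the
  clinical cohort's group margins, so the covariate-adjustment GLM has
  realistic material to work with.

What the generator does **not** emulate: ocular/muscle/electrode
artifacts, volume-conduction forward modeling, 1/f background spectra,
eyes-open data, or inter-channel noise correlation. Passing
recovery tests therefore demonstrates correctness of the algorithms
under the stated generative model, not robustness to real-world
artifacts — which is exactly what a desk-scale validation can show.

## Statistics

Group comparisons are routed by per-group Shapiro–Wilk tests at α =
.05 (the stricter per-group convention): both normal → pooled-variance
Student t (Welch available), otherwise Mann–Whitney U with normal
approximation and tie correction. Cohen's d (pooled SD, sign HP − LP)
is always reported. Each temporal parameter is additionally tested with
a 2 (group) × 4 (class) mixed ANOVA (`aov` with an `Error(subject)`
stratum); significant group or interaction effects gate per-class
post-hoc tests. Benjamini–Hochberg correction is applied per family —
the 4 classes of one parameter, or the 12 transition comparisons —
matching the number of corrected values reported per table in studies
of this design. The 2×2 clinical contingency tables use Pearson
chi-square *without* continuity correction, which is what reproduces
the printed significance values from the published counts. The GLM
(Gaussian, identity link) adjusts the primary group effects for age,
surgery type, BDI-II and ALND as a sensitivity analysis; metric–NRS
association is reported as both Pearson and Spearman coefficients, the
published headline value being a Spearman correlation.

## Numerical and scale choices

Problem sizes in the test suite are scaled to desk hardware as the
package's own validation design: recovery runs use 20 subjects × 60 s
(noisy) and 4 × 20 s (noiseless); transition-law recovery uses one
600 s sequence; error calibration uses 200 replicate null cohorts of
10 + 10 subjects × 30 s with 5 k-means restarts (restarts only affect
the quality of the template optimum, not the null distribution of the
group test), and the planted-effect power check uses the analytic
noncentral-t value at n = 21/45 against 2000 Monte-Carlo replicates.
The calibrated type-I quantity is the family-level false-discovery
event rate of the BH-corrected occurrence family — the probability,
under the global null, that any class is falsely rejected — which
Benjamini–Hochberg pins at α; the rejection rate of one specific
pre-named class is α/K-scale by construction and is not a meaningful
calibration target for a corrected family.
Empty k-means clusters are re-seeded from the worst-fitted map;
convergence is declared when assignments stabilize or the GEV gain
drops below 1e-6. All randomness flows from explicit integer seeds;
identical seed and configuration reproduce every output byte for byte.

## Known limitations

* EDF input/output is not provided; recordings interchange as
  delimited channel × sample matrices with a JSON sidecar.
* ICA-based artifact removal is out of scope (synthetic inputs carry no
  artifacts; contaminated stretches enter as bad-segment annotations).
* No microstate syntax/entropy analyses, no source localization, no
  meta-criterion for choosing k.
* The canonical reference maps are idealized geometric topographies on
  the 2-D projected montage; they serve to fix the A–D labeling, not as
  a normative template database.
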