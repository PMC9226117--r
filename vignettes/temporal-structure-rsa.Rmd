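---
title: "Methods: pattern-similarity change and learned temporal structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pattern-similarity change and learned temporal structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clockrsa)
```

## The problem and the model

Participants learn four sequences ("virtual days") of five events each.
Each event has a time on a hidden virtual clock (virtual hours on a
6 a.m.–midnight timeline), and because the clock runs at different speeds
for different sequences, three time metrics are partially dissociated:
**virtual time** (hours on the hidden clock), **order** (sequence
position), and **real time** (seconds of elapsed stimulus time). Before
and after learning, all 20 event images are viewed in identical random
streams of 10 mini-blocks while multi-voxel activity patterns are
recorded.

The core dependent measure is **pattern-similarity change**. For each
scan phase, the similarity of two events $i \ne j$ is the mean Fisher-z
Pearson correlation between the pattern of $i$ in mini-block $a$ and the
pattern of $j$ in mini-block $b$ over all $a \ne b$ (90 ordered block
pairs at 10 blocks; same-block comparisons are excluded so that shared
within-block noise cannot masquerade as similarity). Change is the
post-learning minus pre-learning matrix. Because stimulus order and
timing are identical in the two phases, temporal autocorrelation of the
signal cancels from the contrast; the generator therefore does not model
it.

Analyses relate the 190 pairwise change values to the pairwise
distances of the three time metrics, z-scored within participant *and
within the pair subset that enters the model* (same-sequence pairs,
different-sequence pairs, or all pairs). Two inference engines are
implemented:

* **Summary statistics.** Per subject, an OLS fit of change on the
  predictors; each focal t-value is referred to a null built by
  shuffling the outcome (`permutation_z()`), and the right-tail p is
  mapped to a Z-score, $Z = \Phi^{-1}(1 - p_r)$ with
  $p_r = (1 + \#\{t_{null} \ge t_{obs}\})/(1 + n_{perm})$. Group-level
  inference is a two-sided sign-flip test on the per-subject Z-values
  (`group_signflip_test()`), with Hedges-corrected Cohen's d and a
  noncentral-t confidence interval. 2×2 within-subject contrasts use a
  permutation repeated-measures ANOVA with generalized $\eta^2$.
* **Mixed models.** Pair-level change is modeled with lme4 under
  maximum likelihood; a focal fixed effect is tested by a likelihood
  ratio test against the nested model without it
  (`fit_mixed_and_lrt()`), $\chi^2$ with one degree of freedom.
  Factorial predictors are deviation-coded (±0.5).

The searchlight engine repeats the same-sequence, different-sequence,
and interaction models inside radius-3 spheres around every brain voxel
(only gray-matter voxels analyzed; spheres with ≤ 25 gray voxels are
discarded), stores the focal t at the center, smooths (FWHM 3 mm), and
performs group inference by sign-flips with threshold-free cluster
enhancement and a max-statistic small-volume correction.

## Numerical choices

* **Fisher-z clip.** Correlations are clipped to $\pm(1 - 10^{-7})$
  before `atanh`, so identical patterns give a large finite value
  instead of infinity. The bound is recorded on the result.
* **Permutation-Z caps.** The add-one rule bounds the positive Z at
  $\Phi^{-1}(n_{perm}/(n_{perm}+1))$; the negative tail is clipped to
  the same attainable bound, keeping every Z finite as the pipeline
  requires. With very strong effects every subject can sit exactly at
  the cap; the group sign-flip test then degrades (with a warning) to
  the exact sign test, which is the correct limit: only the
  all-same-sign flip patterns are as extreme as an infinite t. An
  all-zero input returns p = 1.
* **Tie rule.** Null statistics at least as extreme as the observed one
  count against it (conservative), with a $10^{-12}$ slack so
  sign-patterns that reproduce the observed statistic are not lost to
  round-off.
* **Random-effects ladder.** Mixed fits start maximal (all slopes,
  correlated), then drop correlations, then non-focal slopes. The focal
  random slope is never dropped; a singular last-rung fit is accepted
  but flagged.
* **TFCE.** $H = 2$, $E = 0.5$, 100 integration steps, 26-connectivity.
  The cited neuroimaging tooling does not print its parameters; these
  mirror its documented defaults and are a reimplementation choice, not
  a bit-level claim. Positive and negative directions are enhanced
  separately and combined for a two-sided test; the voxelwise
  uncorrected p uses the same TFCE statistic, which makes corrected ≥
  uncorrected a theorem rather than a tendency.
* **NMDS.** Majorization (SMACOF) with isotonic disparity regression
  (`stats::isoreg`), stopping when stress-1 decreases by less than
  $10^{-6}$ or after 300 iterations; stress-1
  $\sqrt{\sum(\hat d - d)^2 / \sum d^2}$. The embedding is restarted
  many times (1000 by default) and the lowest-stress solution returned;
  the first start is the classical-scaling (Torgerson) solution — the
  common default of majorization implementations — which protects
  exactly embeddable inputs from tie-degenerate solutions in which
  distinct input distances collapse onto one disparity plateau; the
  remaining starts are random. Null re-embeddings in the stress
  permutation test use 10 starts for tractability. A constant distance
  matrix is flagged degenerate: permuting it is the identity.
* **Median splits** put ties in the "low" half (at-or-below rule);
  splits are descriptive only.
* **Sorting.** Group-to-sequence assignment maximizes overlap by
  exhaustive search over the 24 mappings (exact). A swap error requires
  a mutual same-position interchange; one-sided misplacements are plain
  errors. Surrogate sorts move each selected event to a uniformly
  chosen wrong group and are scored through the same assignment path.

## The synthetic world

`sim_config()` states the simulated world once; tests never move these
values toward a desired outcome.

* Structure: 28 subjects, 4 × 5 events with virtual times drawn in
  [6, 24] hours (minimum gap 1.5 h), clock speeds 0.12/0.24 virtual
  hours per real second alternating across sequences (two distinct
  speeds, as the paradigm requires), 10 mini-blocks, 100 voxels per
  region.
* Patterns: the post-phase 20×20 mean-pattern correlation matrix is the
  planted target — baseline plus `a_within` (+0.04) times z-scored
  virtual distance for same-sequence pairs and `b_across` (−0.04) for
  different-sequence pairs — projected to the nearest
  positive-semidefinite correlation matrix (eigenvalue clipping, unit
  diagonal); the pre phase is unstructured. Mini-block patterns are the
  event mean plus independent voxel noise (sd 1). Because noise
  attenuates the observable correlation by
  $\sigma_m^2/(\sigma_m^2 + \sigma_n^2)$, the generator scales the
  planted matrix by the reciprocal, so downstream regressions recover
  the stated slopes unbiasedly — a property the recovery tests check.
  No quantitative effect-size anchor in raw correlation units is
  published for this paradigm; ±0.04 gives desk-scale power at these
  dimensions and is used by the power checks.
* Behavior: remembered time = virtual time + γ·d(e) + noise, where d(e)
  is the deviation of the event's time from the mean time of
  same-position events in the other sequences (γ defaults to 0.5); each
  subject's noise sd is log-normal around the nominal 0.5 virtual hours
  (σ_log 0.4), matching the across-subject spread of timeline errors
  this paradigm shows — without it, strong effects push every subject
  to the identical capped Z. Sorting starts correct; with probability
  0.3 one same-position pair is swapped between sequences and with
  probability 0.3 one event moves to a random wrong group.
* Volumes: a 12³ grid holding a spherical "brain" (radius 5 voxels,
  1.5 mm voxels) with 50% of brain voxels marked gray matter; the
  planted cluster is a radius-3 sphere, matching the searchlight
  radius. A radius-2 cluster fills only ~25% of a radius-3 search
  sphere at this gray fraction, diluting the planted slope ~4× — hence
  the searchlight checks plant 0.12 (dilution-compensated) in the
  cluster, while null volumes plant nothing. An "entorhinal" generator
  mode plants one negative slope for all pairs regardless of sequence
  membership, used by the region-contrast checks.

What a green test does *not* establish: the generator draws independent
Gaussian noise across voxels, blocks, and phases — no hemodynamics, no
motion, no anatomical geometry, no spatial noise correlations — so
passing checks validate the statistical machinery, not robustness to
scanner physics.

## Scaled protocol sizes

The calibration check runs the full two-level pipeline on 1,000 null
experiments at reduced resampling counts (subject shuffles 500, group
flips 1,000), as that protocol itself specifies. The searchlight checks
are scaled to 10 planted-cluster runs (28 subjects) and 20 null runs
(12 subjects — family-wise error control by the max-statistic is valid
at any n, and 2¹² sign patterns keep the null fine-grained) so the
suite fits a desk-scale compute budget; the 90% / 5% thresholds are
kept. With 20 null runs, one false positive equals the 5% bound
exactly; note the binomial discreteness: even a perfectly calibrated 5%
procedure produces more than 5 hits in 100 runs about 40% of the time,
so the permutation correction's practical conservativeness is what
makes this check stable.

## Known limitations

* The mixed-model confidence interval construction for paired Hedges d
  inverts the noncentral-t distribution of the difference statistic and
  rescales; it is documented and tested for containment of the point
  estimate, not for digit-level agreement with any particular package.
* The across-sequence variant of the first/last control predictor is
  not implemented; only same-sequence (position 1, position 5) pairs
  are flagged.
* No automatic outlier exclusion exists; an explicit exclusion list in
  the run configuration is the only mechanism.
* NIfTI support covers uncompressed little-endian NIfTI-1 with the
  common datatypes — enough to interoperate with nibabel — not the full
  standard.

## A worked run

```{r example}
cfg <- sim_config()
exp <- simulate_experiment(cfg, seed = 1)
pairs <- build_pair_table(exp$design)
changes <- lapply(exp$patterns, function(p) {
  similarity_change(pairwise_similarity(p$pre, "pre"),
                    pairwise_similarity(p$post, "post"))
})
res <- sequence_interaction_test(changes, pairs, n_perm = 1000,
                                 n_flips = 1000, seed = 1)
glance(res$same$group)   # within-sequence effect (positive)
glance(res$different$group)  # across-sequence effect (negative)
glance(res$mixed)        # membership x virtual time interaction
autoplot(nonmetric_mds(model_predicted_distances(res$mixed, pairs),
                       n_starts = 100, seed = 1),
         design = exp$design)
```
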