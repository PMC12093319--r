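---
title: "Methods: metabolomic clocks, convergence and trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolomic clocks, convergence and trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical methods
it implements, the assumptions behind them, and the design choices made
where the design was genuinely open. The numbers quoted in the README
are produced by the code shown there; this document states no result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The experimental design being modeled

The unit of replication is the *replicate population*: an independently
maintained outbred lineage within a selection regime (A = accelerated,
10-day generation cycle; C = control, 28-day cycle) and selection
history (long-standing or recently derived). Five replicates per
regime-history cell give 10 replicates per regime. Each replicate is
sampled as a pool of ~50 female flies at each of its regime's sampling
ages — ages are always counted in days from egg. The default design
samples A-types at 9, 21, 28 and 35 d and C-types at 21, 28, 35 and
70 d, for 80 pooled samples over a 202-metabolite targeted LC-MS panel
processed in three batches.

Day-9 A-type samples are collected less than a day after eclosion, a
transient physiological state with no C-type counterpart. They are
therefore excluded from clock fitting and from the per-metabolite mixed
models, but retained in the group-mean matrix so the clustering display
covers the full design.

## Normalization

The chain is `filter_complete()` → `log_center()` →
`batch_residualize()`, in that fixed order:

1. metabolites with any missing value are dropped (no imputation);
2. abundances are natural-log transformed — the base is a free choice
   since every downstream inference is invariant to a global rescaling
   — and each sample (row) is mean-centered to absorb sample-to-sample
   loading differences;
3. per metabolite, the residuals of a least-squares fit on batch as a
   categorical main effect are kept. Batches are treated as
   exchangeable labels; batch-by-metabolite interactions are not
   modeled. Singleton batches are refused (their residuals would be
   identically zero); callers can merge batches instead.

The final stage is idempotent, and adding a constant multiplicative
offset to one batch leaves the output unchanged — both properties are
asserted in the test suite at 1e-9.

`technical_cv()` summarises assay reproducibility as the per-metabolite
coefficient of variation across technical replicate injections, using
the sample (n−1) standard deviation.

## Convergence testing

PCA is computed on the covariance matrix (metabolites centered, not
rescaled — abundances are already on a common log scale, and rescaling
would upweight low-variance metabolites), restricted to ages sampled in
both regimes so scores are comparable.

Each of the first 12 PC score vectors is fit with

    score ~ age * regime * history + (1 | replicate)

with age an unordered categorical factor (only term significance is
interpreted, not polynomial contrasts). Term p-values come from
likelihood-ratio chi-square tests of nested maximum-likelihood fits:
for each term, the reduced model removes the term and every
higher-order term containing it, and the comparison model adds the term
back. This choice fits a true mixed model throughout; per-coefficient
small-sample corrections (Kenward-Roger style) are deliberately not
used, which makes the between-replicate term tests somewhat liberal
with 20 replicate clusters.

Divergence between selection histories is declared when *any* tested
component shows a regime:history or regime:history:age effect at raw
p < 0.05. This is an intentionally liberal, unadjusted criterion —
divergence is the outcome the convergence hypothesis must survive, so
the test is biased toward finding it. The consequence, confirmed by the
package's own null simulations, is a high family-wise firing rate under
the null (roughly `1 − (1 − p₁)^24` across 12 components × 2 terms);
users wanting a calibrated decision should use the Bonferroni-adjusted
per-term p-values also returned. Main effects are reported with
Bonferroni adjustment across the tested components.

The regime discriminator is a two-component PLS regression of a 0/1
regime code on the metabolite matrix; class probability is the
continuous prediction clipped to [0, 1] with the decision at 0.5.
Cross-validated accuracy uses seeded, regime-stratified folds;
training accuracy and the ROC/AUC are resubstitution quantities, since
the original analysis's reporting basis is ambiguous and both are
exposed.

## Clocks and age acceleration

A clock is fit by elastic net with predictors standardized to zero mean
and unit variance *within the training set*; the standardization
parameters are stored so held-out samples are transformed with training
statistics only. The penalty pair is selected by seeded 5-fold CV RMSE
over mixing parameters {0.1, …, 1.0} crossed with a log-spaced path of
100 penalty strengths running four decades down from the smallest
penalty that zeroes all coefficients. Monte-Carlo studies in the tests
and acceptance script use a thinned grid ({0.2, 0.6, 1} × 40
strengths) to keep 20–50-seed experiments inside desk-scale runtimes;
the grid density changes which near-optimal penalty is chosen, not the
qualitative fit.

Within-regime accuracy uses leave-one-replicate-out prediction: for
each replicate, a clock is fit on the other replicates and predicts the
withheld replicate's samples. Leakage-freedom is structural — the
training index of every iteration is recorded on the returned object
and audited in the tests. CV folds inside each LORO iteration are
seeded as `seed + replicate index`. Between-regime predictions come
from a clock fit on *all* samples of one regime, predicting only the
other regime; self-prediction is refused.

The age-acceleration model is ordinary least squares of predicted age
on chronological age, a 0/1 prediction-mode indicator and their
interaction, with conventional t-tests (no robust errors). All
available non-excluded ages enter the fit even where one regime has no
counterpart age (C day 70): the between-regime clock is still making an
out-of-sample prediction there, and dropping it would discard the
design's only old-age anchor.

Feature comparison between two clocks reports the 2×2 membership table
(both / A-only / C-only / neither over the panel), the *sample* odds
ratio `(both × neither) / (A-only × C-only)` alongside Fisher's exact
p-value, the Pearson correlation of shared coefficients (defined only
for ≥ 3 shared features), and rank-sum tests of |β| for shared versus
clock-unique features.

## Trajectory analysis

Each metabolite is fit with
`abundance ~ Sel + Age + Sel:Age + (1 | Rep)` (age categorical,
matching the sampled-timepoint design), with likelihood-ratio tests:
interaction from full vs. additive, each main effect from additive vs.
the additive model without that term. Per-metabolite convergence
failures are flagged, not fatal. Benjamini-Hochberg control is applied
within each term across metabolites at q < 0.01.

Group means per (regime, age) cell are clustered hierarchically
(Euclidean distance, complete linkage) in both directions, with values
used unscaled — they are already normalized residuals, and per-row
z-scoring would erase the abundance-magnitude differences the aged
phenotype flag relies on. The cluster count K is chosen by K-means
(Lloyd, 25 seeded restarts per K, minimum WSS kept) and the largest
discrete second difference of the WSS curve, ties broken toward smaller
K; the row partition itself comes from cutting the dendrogram at that
K. Choosing K by one objective and partitioning by another mixes
criteria, but it is implemented exactly because it is the procedure the
analysis is defined by.

A cluster is flagged as showing the *aged phenotype* when, restricted
to its rows, (a) the C-70 column profile is strictly closer (Euclidean)
to the centroid of the A 21/28/35 columns than to the centroid of the
C 21/28/35 columns, and (b) on average the A columns are strictly
closer to C-70 than to the young-C centroid. This is a quantitative
rendering of a pattern originally identified by inspection; exact ties
fail both strict inequalities, so constant clusters are never flagged.

## Network enrichment

Pathway enrichment for a metabolite cluster uses random walk with
restart on a user-supplied (or simulated) metabolite-pathway graph:
scores are the stationary distribution of a walk restarting with
probability 0.5 (exposed as a parameter; the value is a free choice) to
the uniform seed-set distribution, solved exactly as a dense linear
system on the largest connected component. The empirical p-value of a
pathway compares its observed score with `n_perm` equal-size random
draws from the annotated background, with the add-one correction
`p = (1 + #[perm ≥ obs]) / (1 + n_perm)` so p is never zero, and BH
FDR across pathways. The default `n_perm = 10^4` (configurable
upward) keeps desk-scale runtimes; clusters with fewer than four
mapped metabolites are skipped, not errored. This diffusion scheme is
a generic stand-in with the same structure as KEGG-graph diffusion
methods, not a reimplementation of any specific tool's normalization.

## Mortality

Cohort death logs are pooled by day-wise summation and summarised as
age-specific mortality `M_d = (n_{d−1} − n_d) / n_{d−1}`, the
proportion of flies entering day d that die on day d, which lies in
[0, 1]; days after extinction are omitted. The simulator draws
binomial deaths under a discrete Gompertz hazard
`min(1, a·exp(b·d))` and runs each cohort to extinction, two cohorts
per replicate, mirroring the caged assay design.

## The synthetic-data generator

`simulate_metabolome()` emits, per metabolite, a latent Gaussian
log-abundance: baseline ~ N(10, 1), plus `slope_regime × age` for
age-responsive metabolites, a regime offset for regime-responsive
ones, an optional extra A-slope for interaction metabolites, a history
offset (default 0 — the convergence null), replicate intercepts,
batch offsets, and residual noise; the emitted value is the
exponential, so the pipeline's log transform is exercised. Day-9
A-type samples get an extra offset on a random 30% of metabolites to
emulate the post-eclosion state. Batch labels are assigned by
randomization so batch is unconfounded with the design. Pooling ~50
flies is modeled only as a small residual SD (0.1 log-units), not as
explicit individuals, because the analysis operates on pooled samples.

Default effect sizes are free parameters chosen once for testability —
the source study reports no generative effect sizes: latent aging
slopes 0.04 (A) and 0.02 (C) log-units/day so the fast regime ages at
twice the control rate over the sampled range; regime offset 0.5;
replicate SD 0.05; batch SD 0.2; half the panel age-responsive and a
fifth regime-responsive. Under these conditions the within-regime
clocks are highly accurate and the acceleration fit recovers the
planted slope ratio's sign and rough magnitude, which is what the
acceptance checks assert.

What the generator does *not* emulate: metabolite-metabolite
correlation structure (metabolites are conditionally independent given
the design), non-Gaussian heavy tails, missingness mechanisms beyond
random incompleteness, age-varying variance, and any real biochemical
pathway structure (the network fixture plants memberships by
construction). Passing tests therefore demonstrate that the *methods*
recover planted structure of the assumed form, not that real data has
that structure.

## Problem sizes and numerical choices

Monte-Carlo problem sizes are the package's own balance of power
against desk-scale runtime, and are stated where used: 50 seeds for
the β₃ sign-recovery check (full 202-metabolite panel, thinned penalty
grid), 100 simulations for the divergence null rate, 20 runs on a
60-metabolite panel for the mixed-model null calibration (the flag
rate is a per-metabolite proportion, so panel size affects only its
variance), 20 seeds for planted-K recovery. Mixed models are fitted
once as templates and refitted per response (`lme4::refit`), which is
exact and an order of magnitude faster than refitting from formulas.
Likelihood-ratio p-values use the chi-square reference; at the
boundary (replicate variance estimated at 0) they coincide with
fixed-effects LRTs, asserted in the tests at 1e-3. The RWR linear
system is solved directly (dense); tests cross-check it against
personalized PageRank with damping `1 − restart`. K-means restarts
that fail (more centers than distinct rows) are retried and only an
all-restart failure errors.

## Known limitations

- The divergence criterion is uncalibrated by construction (see
  above); its Bonferroni companion p-values are the calibrated option.
- Elastic-net clocks shrink toward the mean age, so β₁ < 1 is
  expected; β₃ is interpreted relative to the fitted β₁, not to 1.
- The per-metabolite LMM treats age categorically; smooth age trends
  spread power across level contrasts.
- The enrichment permutation draws uniformly from annotated
  metabolites, ignoring degree bias in the network; planted-signal
  recovery is unaffected but real-network p-values inherit the usual
  degree caveats.
- With fewer than 3 shared clock features the coefficient correlation
  is reported as undefined rather than estimated.
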