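# metaboclock

Metabolomic aging clocks and trajectory analysis for experimentally
evolved *Drosophila* populations.

## The scientific problem

Selection for early reproduction reliably produces fly populations that
develop fast and die young. If that accelerated-aging phenotype has a
metabolic basis, it should be visible in the metabolome three ways:

1. **Convergence** — replicate populations under the same selection
   regime (accelerated **A**, 10-day generation cycle, vs. control
   **C**, 28-day cycle) should end up with the same metabolomic state
   whether they are long-standing or recently derived lineages.
2. **Biological age** — a "metabolomic clock" trained to predict
   chronological age (days from egg) from metabolite abundances in one
   regime should, when applied to the other regime, reveal differences
   in the apparent *rate* of aging.
3. **Trajectories** — individual metabolites should show age-by-regime
   abundance patterns in which old controls resemble younger
   accelerated-regime flies (an "aged phenotype").

`metaboclock` implements that entire analysis for pooled-sample
LC-MS relative-abundance tables, and ships a synthetic-data generator
that emulates the study design (2 regimes x 2 selection histories x 5
replicate populations x multiple ages = 80 pooled samples over a
202-metabolite panel, in 3 LC-MS batches), so every stage is testable
without any external download.

## The models at the core

**Normalization.** Metabolites with missing values are dropped,
abundances are natural-log transformed, each sample (row) is
mean-centered, and LC-MS batch effects are removed per metabolite as
the residuals of `metabolite ~ batch`.

**Clocks.** A clock is an elastic-net regression of age on standardized
metabolite abundances, with the penalty pair (mixing parameter and
strength) chosen by seeded 5-fold cross-validated RMSE over a dense
grid. Within-regime accuracy is assessed by leave-one-replicate-out
(LORO) prediction — every prediction comes from a model whose training
set excluded the predicted sample's entire replicate population — and
summarised as

R² = 1 − Σᵢ(yᵢ − ŷᵢ)² / Σᵢ(yᵢ − ȳ)².

**Age acceleration.** Within-regime LORO predictions and between-regime
predictions (a clock trained on all of one regime, predicting only the
other) are compared with

predicted age ~ α + β₁·age + β₂·regime + β₃·age×regime + ε,

where "regime" indicates the prediction mode (0 = within, 1 = between):
β₂ is an age-independent shift in apparent age and β₃ the difference in
apparent aging *rate*. A faster-aging regime seen through the control
clock gives β₃ > 0; the converse gives β₃ < 0.

**Convergence.** PCA on the covariance matrix of the normalized data at
the common ages; each of the first 12 PC score vectors is fit with
`score ~ age × regime × history + (1|replicate)` and likelihood-ratio
term tests; divergence between histories is declared if any PC shows a
regime:history or regime:history:age effect at raw p < 0.05 (a
deliberately liberal criterion). A two-component PLS discriminator
trained on the long-standing populations tests whether regime is
predictable in the recently derived ones.

**Trajectories.** Per-metabolite mixed models
`abundance ~ Sel + Age + Sel:Age + (1|Rep)` with likelihood-ratio
p-values, Benjamini-Hochberg control per term at q < 0.01; group-mean
matrices clustered hierarchically (Euclidean, complete linkage) with
the cluster count chosen by the largest second difference of the
K-means within-cluster sum of squares; clusters whose C-70 profile sits
closer to the A columns than to the young-C columns are flagged as the
aged phenotype. Cluster enrichment uses random-walk-with-restart
diffusion on a metabolite-pathway network with a permutation empirical
p-value (add-one corrected) and BH FDR.

## Worked example

Simulate a scenario in which A-type flies age at twice the latent rate
of C-type flies, then ask the C-clock what it thinks of A samples:

```r
library(metaboclock)

cfg <- sim_config(
  ages_by_regime     = list(A = c(21, 28, 35), C = c(21, 28, 35, 70)),
  latent_aging_slope = c(A = 0.04, C = 0.02))
sim  <- simulate_metabolome(cfg, seed = 1)
norm <- normalize_abundance(sim$table)
norm
#> <abundance_table> 70 samples x 202 metabolites [stage: normalized]
#>   regime: A, C
#>   history: long, recent
#>   age_days: 21, 28, 35, 70
#>   batch: 1, 2, 3

a  <- subset_samples(norm, norm$meta$regime == "A")
c_ <- subset_samples(norm, norm$meta$regime == "C")

within_c <- loro_predictions(c_, seed = 1,
                             alpha_grid = c(0.2, 0.6, 1), nlambda = 40)
within_c
#> <age_prediction_set> 40 predictions (mode: within); R^2 = 0.968

between <- between_regime_predictions(c_, a, seed = 2,
                                      alpha_grid = c(0.2, 0.6, 1),
                                      nlambda = 40)
between$clock
#> <metabolomic_clock> [C-clock]
#>   112 of 202 metabolites with nonzero coefficients
#>   alpha = 0.2, lambda = 1.268, CV RMSE = 4.353 days

fit_age_acceleration(within_c, between$predictions)
#> <age_acceleration> within (n=40) vs between (n=30) predictions
#>       Estimate Std. Error t value Pr(>|t|)
#> alpha   2.1151     1.1123  1.9016   0.0616
#> beta1   0.9431     0.0259 36.3470   0.0000
#> beta2  -5.7377     3.0348 -1.8906   0.0631
#> beta3   1.1584     0.1022 11.3391   0.0000
```

Reading the output: the C-clock tracks chronological age almost 1:1 in
its own regime (β₁ = 0.94, LORO R² = 0.97), and sees the A-type
metabolome aging at roughly twice that rate (β₃ = +1.16, p < 1e-10) —
it recovers the planted 2x slope ratio. Running the mirror analysis
(A-clock predicting C samples) yields a negative β₃ of about half the
within-regime slope.

`run_all(cfg, out_dir = "out", seed = 1)` executes the whole pipeline
(normalization, convergence tests, both clock directions, mixed
models, clustering, enrichment, mortality) and writes stage TSVs plus
a JSON report.

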