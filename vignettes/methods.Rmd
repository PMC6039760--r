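---
title: "Low-density SNP panels by tree-ensemble importance, validated with GBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-density SNP panels by tree-ensemble importance, validated with GBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gblupsel)
```

## The problem

Commercial genomic selection in livestock is constrained by genotyping
cost. If a few hundred to a few thousand SNPs chosen for their relevance to
a trait can deliver prediction accuracy close to a full medium-density chip,
low-density panels become economical. `gblupsel` implements one complete
workflow for building and auditing such panels:

1. rank every SNP by a tree-ensemble variable importance measure (VIM)
   computed on a *discovery* cohort;
2. assemble candidate panels (top-k, all positive-importance SNPs) plus
   phenotype-blind baselines (evenly spaced, all SNPs);
3. on an independent *validation* cohort, quantify each panel with a
   VanRaden genomic relationship matrix (GRM), REML variance components,
   and cross-validated accuracy of genomic breeding values (GEBVs).

## Models

### The three importance measures

All three rankers use the same primitive: a CART regression tree on 0/1/2
allele dosages, where each SNP admits exactly two split thresholds (0.5 and
1.5) and a split's quality is its sum-of-squared-error reduction.

* **Random forest permutation importance (%IncMSE).** Each tree is grown on
  a 2/3 subsample of animals (without replacement by default; a bootstrap
  flag exists) with `mtry` candidate SNPs per split. The out-of-bag (OOB)
  third serves as the tree's validation set: permuting a SNP's OOB column
  and recording the relative MSE increase measures how much the tree's
  predictions rely on that SNP. The score is the percentage increase
  averaged over the trees *containing* the SNP; SNPs never used score 0.
  Negative scores are preserved — they mark SNPs whose presence was
  actively harmful, worth excluding from prediction models.
* **Gradient boosting relative influence.** Least-squares boosting starts
  from the phenotype mean and repeatedly adds `learning_rate` times a
  depth-limited tree fitted to the residuals. A SNP's influence is the sum
  of squared-error improvements over all its splits in all stages
  (non-negative by construction).
* **Second-order gain.** The same boosting loop driven by the second-order
  expansion of the squared loss: with per-record gradient `g = f - y` and
  unit hessian, a split's gain is
  `0.5 (G_L^2/(H_L+λ) + G_R^2/(H_R+λ) - (G_L+G_R)^2/(H_L+H_R+λ)) - γ`
  and a leaf's weight is `-G/(H+λ)`. A SNP's score is its total gain,
  normalized to sum to one. With `λ = γ = 0` and depth 1 this reduces
  exactly to the first-order split — a reduction the test suite checks.

Because the machine-learning stage cannot hold fixed effects in the model,
phenotypes are pre-adjusted by OLS on contemporary group (treatment
contrasts) and linear age before ranking; `y_adjusted` is the residual
re-centered at the grand mean and `y_corrected` the mean-zero residual.
They are the same quantity up to centering, and the corrected form is what
prediction accuracy is scored against.

### GBLUP validation

The validation model is `y = Xb + Za + e` with `a ~ N(0, σ²_a G)` and
`e ~ N(0, σ²_e I)`, where `G = WW' / (2Σ p_k(1-p_k))` is the VanRaden GRM
built from the panel's centered dosages (`W_jk = x_jk - 2p_k`); allele
frequencies come from the analyzed cohort unless overridden. REML
estimation exploits the eigendecomposition `ZGZ' = UDU'`: after rotating
`y` and `X` by `U'`, the covariance is diagonal and the restricted
likelihood can be profiled over the variance ratio `λ = σ²_a/σ²_e` by 1-D
bounded search on the log scale (bounds `[1e-6, 1e6]`, tolerance `1e-8`),
with the scale recovered in closed form. The profile is unimodal for a
single random effect in practice; an exhaustive 2-D grid oracle in the
tests guards the optimum. Standard errors come from the inverse
average-information matrix, `se(h²)` by the delta method. GEBVs for all
animals — phenotyped or not — are `σ²_a G[, obs] V⁻¹ (y - Xb̂)` on observed
records.

Per the validation design, the cohort model keeps the *raw* phenotype with
contemporary group and age in `X` (a `use_adjusted` flag enables the
pre-adjusted alternative). Five-fold cross-validation masks each fold in
turn, refits REML on the remainder, and scores
`cor(GEBV, y_corrected) / sqrt(h²)`. The `h²` in the denominator is, by
default, the panel's own REML estimate on the full validation cohort (one
value per panel); a per-fold-training mode and a fixed numeric value are
available, since which of these a given study used is often ambiguous.

## The synthetic cohort generator

Real cattle cohorts of this kind are access-restricted, so the package
ships a generator whose defaults state the world the analysis assumes:
biallelic SNPs with allele frequencies from a truncated Beta on
`[0.01, 0.5]` (uniform by default) across 29 autosomes; 0/1/2 genotypes
drawn either under Hardy–Weinberg (`unrelated`) or as paternal half-sib
families (`half_sib`: one sampled sire gamete plus one population gamete);
a phenotype `y = μ + group + slope·(age - mean age) + u + e` with 20
contemporary groups (SD 15 kg), age slope 0.7 kg/day over 323–400 days,
grand mean 210 kg and phenotypic variance 600 kg² — the scale of yearling
live weight in tropical beef cows. QTLs are drawn among SNPs with design
frequency ≥ 0.05 (so causal loci survive the MAF-0.01 QC at desk scale);
their `N(0,1)` effects are rescaled so the *expected* additive variance
`Σ α² 2pq` hits `h²_true · σ²_p` exactly, and the realized ratio is
recorded in the truth object — tests can therefore separate estimator error
from simulation noise. The default genomic heritability is 0.125, matching
the all-SNP estimate scale for such cohorts.

What the generator does **not** emulate: linkage disequilibrium beyond an
optional crude adjacent-locus copying mode (`ld_copy`), selection,
assortative mating, genotyping error, dominance or epistasis. A green test
therefore establishes correctness of the *procedure* under an additive,
(near-)independent-locus world — not that the procedure's real-data numbers
would reproduce.

Two consequences of the stated world matter for interpretation:

* With independent loci, a phenotype-blind panel (e.g. evenly spaced)
  carries literally no trait signal and its REML heritability is boundary
  zero — unlike real data, where relatedness and LD give any panel a
  baseline. Properties that compare panels in CV therefore use the
  half-sib mode, which restores the relatedness mechanism.
* With `N(0,1)` effect sizes, a minority of QTLs carries most of the
  variance; the small-effect tail is statistically invisible at desk-scale
  `n`. Top-k panels reliably capture most of the QTL *variance* (tested),
  but not a fixed fraction of QTL *count* — even an exhaustive
  marginal-correlation ranking cannot. The acceptance suite keeps the
  count-based criterion asserted as stated, and it is expected to fail for
  this reason, with the variance-based analogue tested green.

## Numerical and design choices

* **%IncMSE scaling.** The permutation score is the raw percentage MSE
  increase, *not* divided by its between-tree standard error (the scaled
  variant common in software is a different statistic). One OOB permutation
  is drawn per tree and applied to each used SNP's column in turn; scores
  are means, so this is statistically equivalent to per-SNP permutations
  and makes the forest exactly reproducible by the pure-R oracle in the
  tests.
* **mtry per split.** Candidate SNPs are re-drawn at every split (standard
  forest behavior) rather than per tree; with `mtry = m` the two coincide,
  which is what the oracle tests exploit.
* **Tuning statistic.** Tuning curves use the *forest-aggregated* OOB MSE
  (average the OOB predictions per animal first), not the mean of per-tree
  OOB MSEs: individual deep trees overfit, and only the aggregated
  statistic reproduces the expected ordering (single-marker `mtry = 1`
  worst, `0.1·m` best). Boosters use a seeded 20% held-out fold. The
  plateau detector returns the smallest grid point within 2% of the grid
  minimum.
* **Ties.** Equal importance scores rank in genome order (chromosome,
  position); equal split improvements resolve to the first candidate
  scanned. Both rules are deterministic.
* **Rank-deficient GRMs.** REML never inverts `G` (the eigen-path needs
  only `ZGZ'`), so no ridge is needed there. Diagnostics invert `G + 0.01 I`
  only when the plain Cholesky fails, and record the ridge actually used.
  The diagonal is screened for multimodality with Sarle's bimodality
  coefficient (> 0.555), the classic check for hidden subpopulations or
  mislabelled animals.
* **Degenerate REML inputs.** A spectrally flat `ZGZ'` (e.g. `G = I`)
  leaves only `σ²_a + σ²_e` identified; the solver flags
  `not_identifiable` instead of returning an arbitrary split. Optima at
  the ratio bounds are flagged `boundary`.
* **Null-safety floor.** Fold accuracies divide by
  `sqrt(max(h², 0.05))`. Under a permutation null the estimated `h²` piles
  up near zero and an unfloored denominator would explode; the floor
  rescales but cannot move the null center away from zero. Folds whose
  training `h²` is below `min_h2_train` (default 0.01) are skipped per the
  evaluation contract; permutation-null checks set it to 0 because skipping
  folds there would condition on noise.
* **Stage seeds.** The pipeline derives per-stage seeds from the global
  seed by FNV-1a hashing of the stage name, so any stage can be re-run in
  isolation with identical results; every output is stamped with the
  config hash. The data stage's TSV files are its interface — even a first
  run reloads from them, making fresh and resumed runs bit-identical.
* **Age.** Enters the adjustment model linearly (class-coded age is not
  implemented; at 77-day cohort age ranges the linear term is adequate).

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_animals = 2000, m_snps = 2000, n_qtl = 20,
                  h2_true = 0.3, family_structure = "half_sib",
                  n_sires = 100, seed = 1)
co <- split_cohort(simulate_cohort(cfg), n_discovery = 1000)

pdis <- adjust_phenotypes(co$discovery$phenotypes)
v <- gbm_importance(co$discovery$genotypes, pdis$y_adjusted,
                    boost_params(ntree = 200))

val <- co$validation
cvc <- cv_config(5, seed = 7)
folds <- make_folds(val$phenotypes$animal_id, cvc)
r_vim <- cv_accuracy(val$genotypes, val$phenotypes,
                     top_k(v, 200, "GBM200"), cvc, folds = folds)
r_even <- cv_accuracy(val$genotypes, val$phenotypes,
                      evenly_spaced(val$genotypes$map, 200), cvc,
                      folds = folds)
panel_comparison(list(r_vim, r_even))
```

## Known limitations

Single trait, single random effect, additive model only; no imputation
(missing calls are a QC removal, matching the full-genotype requirement of
the rankers); no multi-allelic sites or phased data; no LD-aware de-biasing
of importance scores; the generator's LD mode is a crude copying process,
not a population-genetic model. Variance components estimated from panels
much smaller than `n` are noisy and systematically attenuated or inflated —
that behavior is real (it is the low-density caution this workflow exists
to quantify) and is surfaced, not corrected.
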