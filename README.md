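# fusemap

Charting individual brain development from multimodal regional brain
features is hard precisely because those features change together: dozens
of regional volumes and surface areas shift during adolescence, and
modelling each one separately multiplies comparisons while missing the
shared structure. fusemap takes the subject-similarity route instead: it
integrates the modalities into a single subject-by-subject similarity
network, embeds subjects on its dominant axes, and treats a subject's
coordinate on the first axis — the *brain embedding score* — as a compact,
unitless summary of where they sit in the population. Longitudinal change
in that score (Δ embedding) becomes a one-number marker of developmental
brain dynamics that can be related to pubertal maturation and
psychopathology.

The package is aimed at researchers working with pre-extracted regional
tables (e.g. FreeSurfer Desikan-Killiany volume and area, bilaterally
averaged to 34 regions per modality) from developmental cohorts, including
multi-site studies and settings where a model trained on one cohort must
be applied to another.

## What it implements

1. **Similarity network fusion (SNF).** Per modality, squared Euclidean
   distances between subjects become affinities through a scaled
   exponential kernel with an adaptive local bandwidth,
   `W_ij = exp(-D_ij / (mu * eps_ij^2))`, governed by the number of
   neighbours `K = 30` and edge weighting `mu = 0.8`. Iterative
   cross-diffusion fuses the per-modality affinity networks into one
   symmetric similarity matrix (`T = 20` iterations).
2. **Diffusion map embedding.** The fused network is embedded via the
   eigenvectors of its (density-corrected, `alpha = 0.5`) Markov
   transition matrix; at diffusion time `t = 0` component *k* is weighted
   by `lambda_k / (1 - lambda_k)`, emphasising global structure. The first
   component is the brain embedding score.
3. **Harmonization.** Parametric empirical-Bayes batch correction
   (ComBat) removes site/scanner location and scale effects per modality,
   per timepoint, separately for train and test partitions.
4. **Transfer learning.** An instance-weighted reverse-boosting regressor
   (TrAdaBoostR2, `N = 10` rounds) with elastic-net base learners
   (`l1_ratio = 0.5`, `penalty_strength = 1.0`) learns the mapping from
   raw concatenated features to the first embedding on a source cohort
   plus a held-out target adaptation set, down-weighting source subjects
   the target cannot explain; prediction is the weighted median of the
   last `N/2` estimators.
5. **Phenotypes and associations.** Pubertal Development Scale scoring
   (`PDS_mean`, change scores, ABCD-style pubertal categories), diagnosis
   counts as a psychopathology proxy, and sex-stratified OLS association
   models with partial eta-squared and Bonferroni control.
6. **Synthetic cohorts.** A seeded generator plants a latent maturation
   score in multimodal features, PDS items and diagnosis counts, so the
   entire pipeline is testable without access-restricted data.

See `vignettes/fusemap-methods.Rmd` for the full model account and design
rationale.

## Worked example

Generate a cohort with a planted maturation signal, fuse and embed it,
and relate the embedding to the scored puberty phenotype:

```r
library(fusemap)

cohort <- generate_cohort(generator_config(n_subjects = 200, seed = 42))
fe  <- fuse_and_embed(cohort$modalities$single)
emb <- fe$embedding

round(emb$eigenvalues[1:3], 3)
#> [1] 0.891 0.747 0.651
round(cor(emb$scores[, 1], cohort$latent$z), 3)
#> [1] -0.961

ph  <- score_phenotypes(cohort$phenotypes)
dat <- data.frame(embedding = emb$scores[, 1], ph)
res <- fit_linear_model(dat, dv = "embedding", iv = "pds_mean",
                        covariates = "age", stratum = "female",
                        alpha_family = 0.05, m = 2)
sprintf("b = %.2f, p = %.2g, eta2p = %.3f, n = %d",
        res$b, res$p, res$eta_sq_partial, res$n)
#> [1] "b = -6.67, p = 7.4e-19, eta2p = 0.585, n = 93"
```

The leading eigenvalue (0.89) shows one dominant similarity axis; the
first embedding correlates at |r| = 0.96 with the planted maturation
score (the sign of an eigenvector is arbitrary; a deterministic skewness
convention fixes it). The female-stratum linear model recovers the
planted coupling between pubertal stage and the embedding, controlling
for age: about −6.7 embedding units per PDS point, a large effect
(eta2p = 0.59) in this deliberately clean synthetic cohort — real-cohort
effects are far smaller.

Per-region interpretability comes from the loadings:

```r
ld <- feature_loadings(cohort$modalities$single$modality_1, emb$scores[, 1])
#  strongest: region_19, loading -0.95
```

A thin command-line front end with `simulate`, `fuse`, `embed`, `fit`,
`predict`, `delta`, `associate` and `run` subcommands is installed at
`system.file("cli/fusemap.R", package = "fusemap")`; `run` executes the
configured end-to-end pipeline (`run_pipeline()`).

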