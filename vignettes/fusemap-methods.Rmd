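---
title: "Subject-similarity reference spaces: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-similarity reference spaces: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fusemap charts individual brain development by locating subjects in a
low-dimensional space built from their mutual similarity in multimodal
regional brain features, rather than by modelling each regional measure
separately. This vignette is the package's own account of the methods: the
models and their assumptions, the parameters that matter, the synthetic
cohorts used for validation, and the places where a design decision was
genuinely open.

## The similarity model

Each modality (e.g. bilaterally averaged cortical volume and surface area
over 34 Desikan-Killiany regions) is a subjects-by-features table. Features
are z-scored per column by default (`snf.standardize`), because raw
volume/area magnitudes differ by orders of magnitude across regions and
would otherwise dominate the distance; statistics from a training partition
can be reused on held-out data.

Pairwise squared Euclidean distances $D_{ij}$ are converted to affinities
with a scaled exponential kernel,

$$W_{ij} = \exp\!\left(-\frac{D_{ij}}{\mu\,\varepsilon_{ij}^2}\right),
\qquad
\varepsilon_{ij} = \tfrac{1}{3}\left(\bar d_{K}(i) + \bar d_{K}(j) + d_{ij}\right),$$

where $d = \sqrt{D}$ and $\bar d_K(i)$ is the mean distance from subject
$i$ to its $K$ nearest neighbours. The bandwidth adapts to local density,
and squaring it makes the exponent dimensionless, so affinities are
invariant to a global rescaling of the features — a property the rest of
the pipeline relies on. When duplicate-heavy data drive
$\varepsilon_{ij}$ to zero, the bandwidth is floored at machine epsilon
with a warning.

Similarity network fusion (SNF) then integrates the modalities. Each
affinity matrix is normalized two ways: a *full* kernel
$P_{ij} = W_{ij} / (2\sum_{k \neq i} W_{ik})$ for $j \neq i$ with
$P_{ii} = 1/2$, and a *sparse* kernel supported on each subject's $K$
nearest neighbours (self excluded, ties at the $K$-th neighbour broken by
ascending subject index for determinism). For $T$ iterations each
modality's full kernel is diffused through its own sparse kernel against
the average of the other modalities' kernels,
$P_v \leftarrow S_v \,\bar P_{u \neq v}\, S_v^\top$, re-symmetrized to
guard against float drift, and renormalized. The final fused network is
the symmetrized average of the per-modality kernels, renormalized the same
way. A single modality simply diffuses against itself.

Defaults are $K = 30$, $\mu = 0.8$ and $T = 20$ with no convergence
stopping, the configuration of the reference implementation family; for
cohorts smaller than $K + 1$ the neighbourhood is clamped to $n - 1$ with
a warning, which the synthetic tests at $n < 31$ exercise deliberately.
Prior grid searches in this literature report embeddings that are robust
across wide ranges of $K$ and $\mu$, which is why the package exposes but
does not tune them.

## Diffusion map embedding

The fused network $S$ is embedded with anisotropic diffusion maps. With
degrees $d_i = \sum_j S_{ij}$, the kernel
$L_{ij} = S_{ij}/(d_i^\alpha d_j^\alpha)$ is row-normalized into a Markov
matrix $M$; its leading non-trivial right eigenvectors $\psi_k$ (the
trivial $\lambda = 1$, constant pair is dropped) are the embedding axes.
The eigenproblem is solved on the symmetric conjugate
$D^{1/2} M D^{-1/2}$ for numerical stability; the two routes agree to
$10^{-8}$ in the test suite's dense oracle comparison.

Three conventions matter and are fixed deliberately:

* **Eigenvector normalization.** $\psi_k$ is scaled to unit norm in
  $L^2(\pi)$, $\pi$ the stationary distribution. This is the convention of
  the diffusion-map implementations this package follows and it gives
  per-subject entries of order 1 *regardless of cohort size*, which keeps
  the downstream elastic net's fixed penalty meaningful.
* **Diffusion time.** At the default $t = 0$, component $k$ is weighted by
  $\lambda_k/(1-\lambda_k)$, emphasising the most global structure;
  $t > 0$ uses $\lambda_k^t$; `scale_eigenvectors = FALSE` returns plain
  eigenvectors.
* **Sign.** An eigenvector's sign is arbitrary, so each component is
  flipped to nonnegative skewness (falling back to a nonnegative first
  entry), making runs on different cohorts comparable before any
  alignment step.

A disconnected similarity graph (eigenvalue 1 with multiplicity above one)
is an error suggesting a larger $K$; complex eigenvalue residue above
$10^{-8}$ is likewise an error rather than silently truncated.

The first component — the *brain embedding score* — is the quantity
carried forward: it captures the dominant axis of inter-subject
similarity. One intrinsic limitation documented by the tests: for data on
an effectively one-dimensional manifold the leading diffusion coordinate
is monotone but cosine-like in the latent position, so its *rank*
agreement with a planted latent is near-perfect while the *linear*
correlation plateaus slightly below 1 even without noise.

## Alignment and evaluation

Where predicted and reference scores cover the *same* subjects, orthogonal
Procrustes alignment (columns centered, rotation/reflection from the SVD
of the cross-product) is applied before computing RMSE, MAE, $R^2$ and
Pearson's $r$; for a single component this reduces to a sign flip. An
isotropic scale factor is available (`scale = TRUE`) and the pipeline's
evaluation step uses it: two cohorts' fused networks have different
leading eigenvalues, hence different $\lambda/(1-\lambda)$ score scales,
and a pure rotation cannot reconcile magnitudes; $r$ is unaffected either
way.

Across *disjoint* cohorts subject-matched Procrustes does not exist. The
adaptation targets are therefore aligned to the source convention by the
deterministic sign rule plus a spread match
(`align_embedding_scale()`: rescale to the reference SD). This assumes
comparable heterogeneity between cohorts, an assumption worth a
sensitivity check when the target population is unusually homogeneous.

Per-feature interpretability is provided by `feature_loadings()`, the
Pearson correlation of each raw feature with the first embedding;
constant features are reported as `NA`, not zero.

## The transfer model

The mapping from the concatenated raw modality features (34 + 34 columns)
to the first embedding score is learned by TrAdaBoostR2: reverse boosting
over the pooled source + target-adaptation sample with elastic-net base
learners. The elastic net uses the fixed defaults `l1_ratio = 0.5`,
`penalty_strength = 1.0` — deliberately untuned, favouring
out-of-sample generalization — solved by glmnet at that single penalty
with observation weights rescaled to sum to $n$ (the convention shared by
the standard solvers); a zero penalty is solved exactly by weighted least
squares. One model is trained jointly for both sexes; sex-stratified
analysis happens downstream.

Each boosting round fits with the current instance weights, computes
adjusted errors $e_i = |\hat y_i - y_i| / \max_j |\hat y_j - y_j|$
(linear loss by default; square and exponential are exposed), the target
error rate $\varepsilon_t$ and confidence
$\beta_t = \varepsilon_t/(1-\varepsilon_t)$, then *decays* poorly
predicted source weights by $\beta_S^{e_i}$ with
$\beta_S = 1/(1+\sqrt{2\ln n_S/N})$ and *grows* poorly predicted target
weights by $\beta_t^{-e_i}$, renormalizing to the simplex. Rounds with
$\varepsilon_t \ge 0.5$ keep boosting but contribute zero confidence; a
perfect round terminates early with a large confidence. Estimators from
the last $\lceil N/2 \rceil$ of the $N = 10$ default rounds are kept with
weights $\ln(1/\beta_t)$, and prediction is their weighted median (first
prediction, ascending, whose cumulative weight reaches half the total).
If no kept round earned positive confidence, prediction falls back to
uniform weights over the kept estimators. Weighted fitting uses analytic
weights rather than resampling, so a fitted model and its predictions are
bit-reproducible.

The adaptation targets $y$ for the held-out target subset are computed by
running fusion + embedding on that subset and aligning to the source
convention as above — the held-out design implies such targets exist for
adaptation subjects, and this is the one place the package takes a stance
on an ambiguity in the workflow; it is isolated in the pipeline stage and
easy to substitute.

## Harmonization

Multi-site feature tables are corrected with parametric empirical-Bayes
batch harmonization (ComBat): features are standardized to pooled
mean/variance, per-batch locations and variances are estimated and shrunk
toward their batch-level means under a normal/inverse-gamma prior with
moment-matched hyperpriors, iterating the conditional updates to a
relative tolerance of $10^{-6}$. The shrunk variance $\delta^*$ is a
variance, so the adjustment divides by $\sqrt{\delta^*}$. The fit/apply
split lets a model estimated on one partition be applied to another with
the same batches; unseen batch labels, single batches, batches with fewer
than two subjects and zero-variance features are errors. Following the
source workflow, harmonization is applied independently per modality, per
timepoint, and separately for train and test partitions; no biological
covariates are preserved in the standardization by default. The
implementation agrees with the `sva` reference to ~$10^{-6}$ in the test
suite.

## Phenotype scoring and association models

`PDS_mean` is the arithmetic mean of the sex-specific Pubertal
Development Scale items (ordinal 1–4); the binary menarche item is recoded
no = 1 / yes = 4 onto the item scale before averaging (configurable).
Change scores subtract baseline from follow-up and require the same
reporter at both visits. Pubertal categories use the standard
ABCD/Crockett conversion — males: sum of three items (3–12) with the
complement rules for sums 4–5 containing a 3 (mid) and 6–8 containing a 4
(late); females: two-item sum (2–8) crossed with menarche — and the
boundaries are isolated in one function so a different scheme can be
substituted. Missing items invalidate a score listwise. Psychopathology
severity is proxied by the count of consensus diagnoses.

Association models are ordinary least squares per sex stratum with one
predictor of interest, covariates of no interest (age or Δage, site as
dummy indicators with alphabetically first reference level), listwise
deletion, two-sided tests, and partial eta-squared
$t^2/(t^2 + \mathrm{df}_{res})$ — identical to the sum-of-squares form for
a single added-last column, which the tests verify to $10^{-10}$.
Interaction models keep both main effects. Bonferroni control is
family-size driven (`alpha / m`), with `m` declared per analysis set
because multiplicity families are analysis-level choices.

## The synthetic cohorts

The generator exists so that every stage is testable without
access-restricted cohort data; it emulates the *statistical assumptions*
of the framework, not the marginal distributions of real regional
morphometry.

Each subject carries a latent maturation score
$z = a\,(\mathrm{age} - \mathrm{age}_{\min}) + 0.5\,[\mathrm{female}] +
\mathcal N(0,1)$ with $a = 3/(\mathrm{age}_{\max}-\mathrm{age}_{\min})$ —
the simplest monotone age–maturation link, with girls maturing earlier.
Modality 1 loads linearly on $z$; modality 2 through the mildly
saturating $4\tanh(z/4)$, chosen so its curvature stays gentle over the
realized latent range (link–latent correlation 0.99 noise-free) while the
modalities still carry shared plus complementary signal. Features add a
sex-gradient pattern (strength 0.5), per-site additive offsets and
multiplicative scale effects, and Gaussian noise (`noise_sd = 0.5` per
feature against unit-scale loadings — a moderately favourable
signal-to-noise ratio appropriate for a method-validation cohort).

PDS items are ordinalized by fixed thresholds (−0.8, 0.2, 1.2) on the
standardized latent plus logistic reporter noise (scale 0.55), giving a
latent–`PDS_mean` correlation of roughly 0.85 at defaults; menarche is a
single higher threshold (0.9). In longitudinal cohorts the item scale is
anchored to the pooled two-visit latent so that growth moves the items;
loadings, site assignment and sex patterns are held fixed across visits,
the latent advances by a sex-specific increment (default female 1.0,
male 0.5 over a two-year interval — females faster, matching the known
direction of pubertal change scores), and feature/reporter noise is drawn
fresh per visit. Diagnosis counts are Poisson with rate
$2 + c\,|z - \hat z(\mathrm{age}, \mathrm{sex})|$, coupled in females
only by default (mirroring the female-specific clinical association),
zero-truncated and capped at 10 in the clinical flavour.

All randomness derives from one seed split into named substreams per
generation block, so toggling one block never perturbs another and an
identical configuration is bit-reproducible.

What passing tests on these cohorts do **not** show: robustness to real
scanner artefacts, non-Gaussian regional distributions, missing-data
patterns, family structure, or population stratification. The generator's
planted truth makes recovery quantifiable; it does not make the cohorts
realistic.

## Problem sizes and numerical tolerances

The validation suite runs at desk scale, chosen to exercise each claim
with comfortable statistical margins: latent recovery on a 600-subject
cohort; the transfer pipeline at 800 source + 200 adaptation + 400 test
subjects under a planted covariate shift (narrow target age band,
three sites); adaptation benefit over 20 seeded replicates; harmonization
at 500 subjects per site; association calibration over 500 null
replicates at $n = 1000$ and sex-specific detection over 20 replicates at
$n = 3000$ per stratum. Oracle agreements (loop-based SNF, dense
eigendecomposition) are asserted at $10^{-8}$, simplex and effect-size
identities at $10^{-10}$–$10^{-12}$.

## Known limitations

* The first diffusion coordinate is a *curved* monotone function of a
  one-dimensional latent; analyses assuming strict linearity in the
  latent will see mild attenuation.
* Cross-cohort score alignment by SD matching assumes comparable
  population heterogeneity.
* Only the first embedding component is validated; later components mix
  sex structure and modality-specific variance and are exposed but not
  interpreted.
* Longitudinal ComBat variants and reference-batch ComBat are out of
  scope, as are mixed-effects models for family relatedness and any
  image-level processing: inputs are pre-extracted regional tables.
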