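---
title: "Phenomic selection with NIR spectra: models, simulation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenomic selection with NIR spectra: models, simulation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Phenomic selection predicts the performance of plant genotypes from
near-infrared reflectance spectra (NIRS) of harvested material, using the
whole-spectrum shrinkage models of genomic selection.  In a wheat breeding
program the spectra are cheap (every plot's grain is scanned anyway), while
multi-environment yield trials are expensive, so a breeder wants to know:
given spectra of new material, how well can grain yield or protein content
be predicted, and under which operational scenario?

`phenosel` implements the full analysis pipeline at desk scale: simulation
of multi-environment trials with spectra, mixed-model adjustment, spectral
preprocessing with tunable Savitzky-Golay filtering, two predictors
(rrBLUP, PLSR), repeated cross-validated prediction ability under three
breeding scenarios, and DAPC diagnostics of spectral structure.  Because
real breeding data of this kind are private, a first-class synthetic-data
module emulates their statistical structure; every downstream claim is
testable against known truth.

## The trial mixed model

Every plot observation (an agronomic trait or a single NIR wavelength) is
modelled as

$$y_{ijsh} = \mu + g_i + l_j + r_{js} + b_{jsh} + gl_{ij} + \epsilon_{ijsh},$$

with genotype $g$, environment (location-year) $l$, replicate nested in
environment $r$, incomplete block nested in replicate $b$, the
genotype-by-environment interaction $gl$ and residual $\epsilon$.  All
random effects are independent mean-zero normals with their own variance.
`fit_reml()` estimates the variance components by REML (delegated to
lme4's `lmer`, the same model family the original ASReml analyses used);
terms that a layout cannot identify (a replicate term in an unreplicated
environment, G$\times$E with a single environment) are dropped and reported
as zero.

Genotype adjusted means (BLUEs) come from the same model with genotype
fixed (`estimate_blues()`, cell-means parameterization), along with the
mean standard error of a difference (SED) over all genotype pairs.  For
spectra, `spectra_blues()` applies the model per wavelength, refitting the
shared model structure for speed; wavelengths with singular or
non-convergent fits are removed for all environments, mirroring standard
practice.  In a single-environment table where no genotype is replicated
the model degenerates and raw plot spectra stand in for BLUEs (the
unreplicated yield-trial fallback).

Broad-sense heritability uses the Cullis form suited to unbalanced trials,

$$H^2 = 1 - \frac{\bar\vartheta_{BLUP}}{2\sigma^2_g},$$

where $\bar\vartheta_{BLUP}$ is the mean prediction-error variance (PEV) of
a difference of two genotype BLUPs.  The PEV matrix is computed exactly
from the mixed-model equations at the REML estimates (`cullis_h2()`); a
seeded 10,000-pair sample replaces the exact pairwise mean above 2000
genotypes.  $H^2$ outside $[0,1]$ (possible with this estimator) is clamped
with a warning because downstream reports treat it as a proportion.

## Preprocessing and the eight feature-engineering scenarios

The Savitzky-Golay filter fits a degree-$p$ polynomial by least squares in
a moving window of $w$ points and returns the $d$-th derivative of the
local fit at the window centre.  `savitzky_golay()` computes the exact
convolution weights $(A'A)^{-1}A'$ per window; derivatives are per nm (on
the 1 nm instrument grid this equals the per-index derivative, so no step
rescaling is needed; other uniform grids are rescaled by the step).  Edge
handling: the $(w-1)/2$ points per side, where no full window exists, are
trimmed rather than extrapolated, and the trimmed grid propagates through
the pipeline.

`apply_fes()` composes the eight feature-engineering scenarios (FES): the
cross of Savitzky-Golay filtering (ids 5-8), aggregation to genotype level
by arithmetic mean (odd ids) or mixed-model BLUEs (even ids) for spectra
and trait alike, and centering/scaling of the genotype spectra (ids 3, 4,
7, 8).  The stage order is fixed — filter at plot level, then aggregate,
then scale — because scaling before aggregation gives different answers on
unbalanced data (asserted in the tests).  The trait itself is never
scaled: the source overview marks scaling for the spectra only, and
Pearson prediction ability is scale-invariant in the response anyway.
During cross-validation the scaling statistics are recomputed on the
training folds of every split and reused on held-out rows, so no
information leaks; the same rule applies across environments (training
environment statistics applied to the prediction environment).

## Predictors

**rrBLUP.**  $y = 1\mu + Zu + \epsilon$ with $u \sim N(0, I\sigma^2_u)$,
giving $\hat u = (Z'Z + \lambda I)^{-1}Z'(y - 1\hat\mu)$ with
$\lambda = \hat\sigma^2_\epsilon/\hat\sigma^2_u$.  The two variances are
estimated by REML: one spectral decomposition of the centered feature
kernel reduces the likelihood to one dimension, maximized by Brent search
on $\log\lambda$ (tolerance 1e-8, bounds $e^{\pm 25}$; hitting a bound
means the ratio is unidentifiable, e.g. for a noise-free response).  The
kernel (dual) solution is used when features outnumber samples and is
algebraically identical to the primal ridge solution — an identity the
acceptance tests verify to 1e-10.

**PLSR.**  Deterministic univariate NIPALS on centered data, default 12
components (the conventional choice for grain NIRS), capped at the
effective rank with a warning.  `select_plsr_components()` approximates
permutation-based component selection by repeated-CV RMSEP with the
one-standard-error parsimony rule; this is an approximation of the
original procedure and is flagged as such.

## Evaluation, tuning and scenarios

Prediction ability is the Pearson correlation between predicted and
observed genotype values, estimated by 5-fold cross-validation with random
assignment of genotypes to folds, replicated (default 1000 times; the
package tests scale this down and say so).  The default per-replicate
ability is the mean of the five per-fold correlations (`per_fold_mean`);
pooling all held-out predictions first is available as `pooled` — the two
agree closely in the mean and differ mainly in spread, and the source does
not state which was used.

`grid_search_sg()` tunes $(p, d, w)$ over the default grid $p \in \{2,3,4\}
\times d \in \{1,2\} \times w \in \{29,\dots,89\}$ (42 combinations),
rebuilding the full preprocessing pipeline per combination (filtering
precedes BLUE aggregation, so BLUEs must be recomputed each time — this is
exactly why the original tuning cost three quarters of a million BLUE
fits).  Ties in mean ability are broken by the parsimony rule; "less
complex" is declared as lexicographic smallest-first on (derivative order,
polynomial order, window size), so an all-tied grid returns $(2, 1, 29)$.

The three breeding scenarios:

1. **New genotypes, same environment** — within-environment repeated CV,
   one result per environment (`scenario1_within_env()`).
2. **Known genotypes, new environment** — train in environment A, predict
   the shared genotypes from their spectra in B, one ability per ordered
   pair (`scenario2_cross_env()`).  Abilities may be negative; only
   $[-1, 1]$ is enforced.
3. **New genotypes, series performance** — train on series-level genotype
   BLUEs, predict from central-environment spectra (the phenomic estimated
   performance, PEP), correlate with the new genotypes' series trait BLUEs
   (`scenario3_series()`).  Overlap between training and prediction
   genotypes triggers a warning, not an error.

Wavelengths dropped for singularities are intersected across training and
test data before any cross-set prediction.

## DAPC

`dapc_fit()` follows the standard procedure: PCA reduction, k-means group
inference on all PCs when no labels are given (k chosen by the BIC
criterion $n\log(W_k/n) + k\log n$ over 20 seeded restarts), then linear
discriminant analysis (MASS) on the retained PCs.  The retained-PC count
is selected by repeated stratified 90/10 cross-validation of assignment
accuracy (100 repeats by default; the split sizes are a package choice, the
source gives none), ties toward fewer PCs.

## The synthetic world

`simulate_dataset()` draws from a stated world chosen once:

* **Designs**: partially replicated (a seeded-shuffle-selected 20% of
  genotypes duplicated, the same set in every environment, as checks would
  be) or resolvable alpha-lattice with two replicates and blocks of about
  10 plots.
* **Trait variances** (grain-yield-like, t$^2$ ha$^{-2}$): genotype 0.19,
  environment 0.50, replicate 0.02, block 0.05, G$\times$E 0.36, residual
  0.24 — the genotype / G$\times$E / residual triple reproduces the
  reported multi-environment panel summaries, the environment and
  design-effect values are plausible fill-ins (the source tabulates only
  the first three), and the trait mean 6.6 t ha$^{-1}$ sits mid-range of
  the reported dataset means.
* **Spectra**: a fixed smooth base reflectance curve plus smooth
  environment offset curves plus genotype and G$\times$E components built
  as rank-8 sums of Gaussian bumps over wavelength (smoothness mimics real
  NIRS; the source gives no generative model) times i.i.d. scores, plus
  white measurement noise.  Per wavelength the genotype / G$\times$E /
  residual variances are normalized exactly to the proportions
  `p_g`/`p_gl`/`p_e`, default 0.40/0.50/0.10 — the reported per-wavelength
  decomposition (about 40% genotype, 50% G$\times$E).  Total component
  standard deviation is 0.05 reflectance units per wavelength.
* **Trait-spectrum link**: a fraction `link_strength` (default 0.5) of the
  trait genotype variance is the image of the genotype spectral scores
  under a fixed linear map — so prediction ability is controllable, with
  `link_strength = 0` a true null and `link_strength = 1` noise-free
  predictability.  The same construction applies at the G$\times$E level
  (`link_strength_ge`), but through *per-environment, mutually orthogonal*
  decoding directions: which spectral features matter for the trait
  differs between environments.  This is the package's resolution of an
  open design question — with a single global direction, a model trained
  in one environment could decode the trait's G$\times$E part in another
  environment and cross-environment ability would not vanish even for
  spectra carrying no genotype main effect, contradicting the observed
  mechanism (NIRS capture G$\times$E, which does not transfer across
  environments).  Orthogonality is exact while the number of environments
  does not exceed the loading rank.
* **Origins** are round-robin genotype labels with zero spectral effect by
  default (`spectra_origin_sd = 0`), matching the observation that spectra
  cluster by environment, not by genotype origin.

What the generator does **not** emulate: reflectance physics, moisture and
instrument drift, spatial field trends, heterogeneous environmental error
variances, and nonlinear trait-spectrum relationships (the predictors
under study are linear).  A green test therefore establishes that the
*statistical machinery* behaves as specified under the stated variance
structure — not that any particular real dataset would reach a given
ability.

## Numerical choices and degenerate inputs

* REML components within $10^{-12}\,\mathrm{sd}(y)^2$ of zero are reported
  as 0 with a boundary flag; non-convergence is flagged, and treated as a
  singularity (column dropped) in per-wavelength fits.
* A response with no within-genotype variation short-circuits the mixed
  model: BLUEs are plain genotype means with SED 0 (the noise-free limit,
  where REML itself is degenerate).
* A constant response to `fit_rrblup()` returns a flagged degenerate model
  ($\hat u = 0$, intercept $= \bar y$) with a warning rather than an
  error, so that mass screening over traits does not abort.
* Zero-variance feature columns are dropped at scaling time with a
  warning; an all-constant matrix is an error.
* Held-out CV folds with zero response variance yield `NA` fold
  correlations, excluded from the replicate mean with a warning.
* Environment connectivity (shared genotypes) is checked before series
  BLUEs; disconnected environments are a hard error since genotype
  contrasts across them are inestimable.

## Known limitations

* Variance-component estimation is exact REML but through `lmer`; models
  with crossed heterogeneous residuals, spatial correlation or pedigree
  kinship are out of scope.
* The SED is computed from the genotype-fixed (BLUE) fit; whether the
  original tables used the fixed- or random-genotype fit is not stated.
* Permutation-based PLSR component selection is approximated by
  CV-RMSEP with the one-SE rule.
* Grid-search tuning recomputes per-wavelength BLUEs for every
  combination; at full scale (1001 wavelengths, 42 combinations, many
  datasets) this is cluster work, and the package makes no attempt to
  parallelize it.
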