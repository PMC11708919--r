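---
title: "Factor-analytic MET models with environmental-covariate priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factor-analytic MET models with environmental-covariate priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metfa)
```

## The model and its assumptions

`metfa` treats each experiment of a multi-environment trial (MET) — in
hybrid maize, one tester family within one location-year — as a separate
"trait" of the same set of genotypes, and models the genotype ×
experiment matrix $Y$ ($n \times t$) hierarchically:

$$Y = XB + F\Lambda + E, \qquad
  f_k = u_{Fk} + e_{Fk}, \qquad
  E_{\cdot j} = u_{Rj} + e_{Rj},$$

with $u \sim N(0,\sigma^2_g K)$ for the genomic relationship matrix $K$
and $e \sim N(0, \sigma^2_e I)$.  The $k$ columns of $F$ are latent
traits shared across environments; the loading rows of $\Lambda$ say how
much each latent trait matters in each environment.  Prediction into
*new* environments is possible because each loading row is itself a
regression on environmental covariates (ECs):

$$\lambda_{k\cdot} = \sum_{l=1}^{L} W_l a_{lk} + \epsilon_k,\quad
  a_{lk} \sim N(0, \sigma^2_l \tau_k^{-1}),\quad
  \epsilon_{kj} \sim N(0, (\psi_{jk}\tau_k)^{-1}),$$

with $\psi_{jk} \sim \mathrm{Ga}(\nu/2,\nu/2)$ local (heavy-tailed)
shrinkage and $\tau_k = \prod_{h \le k}\delta_h$ the multiplicative-gamma
factor shrinkage, $\delta_1 \sim \mathrm{Ga}(\alpha_1,\beta_1)$,
$\delta_{h>1} \sim \mathrm{Ga}(\alpha_2,\beta_2)$.  The model assumes
one trait-matrix row per genotype (replicated plots are reduced to BLUEs
upstream), Gaussian phenotypes after that reduction, and missingness
that is ignorable given the model (cells are imputed by full data
augmentation each sweep).

Two identifiability choices are baked in rather than left to the
sampler.  First, factor traits have total prior variance fixed at 1 —
$h^2_{Fk}$ partitions it — so $\Lambda$ absorbs all scale; without this
the scale of $F$ versus $\Lambda$ is arbitrary.  Second, the factor-level
fixed effects are fixed at zero: with an intercept-only $X$ they are
linearly redundant with the level-1 fixed effects $B$ (any factor mean
can be moved into $B$ through $\Lambda$), so sampling them would only
add a random walk along a flat direction.

The sign of each factor is *not* identified (flipping a column of $F$,
the matching row of $\Lambda$, column of $U_F$ and coefficients $a$
leaves the likelihood untouched).  None of the package's outputs depend
on signs: predictions and the $\Lambda^2$ diagnostics are invariant, and
the test suite asserts the invariance explicitly.

## Sampler design

All conditionals are conjugate; one Gibbs sweep cycles five blocks in
fixed order: genetic effects → factor scores → loadings → loading
regression → imputation.  Notable mechanics:

* **Heritabilities on a grid.**  Variance partitions of factor and
  residual traits are sampled on the discrete grid
  $h^2 \in \{0, 1/m, \dots, (m-1)/m\}$ ($m$ = `h2_grid_size`, default
  20) using the exact marginal likelihood in the eigenbasis of $K$,
  which is decomposed once per run.  This avoids Metropolis tuning
  entirely at the cost of $1/m$ resolution, ample for prediction.
* **One Cholesky per sweep for $F$.**  Because augmentation completes
  the data, every row of $F$ shares the same $k \times k$ posterior
  precision; the row updates are a single triangular solve against an
  $n \times k$ right-hand side.
* **Residual-trait variances** get inverse-Gamma updates with the
  genetic component marginalised (sampling $\sigma^2_{Rj}$ against the
  grid-likelihood quadratic form), which mixes better than conditioning
  on $u_{Rj}$.
* **Fixed effects** use a flat prior by default; `prior_B_var` switches
  to a proper $N(0, v)$ prior.  The proper prior exists because the
  package's prior-recovery diagnostic runs the sampler with every cell
  missing — a chain whose stationary distribution is the joint prior —
  and that argument requires all priors proper.

## Defaults and the parameters that matter

| parameter | default | why |
|---|---|---|
| `k_max` | 50 | generous ceiling; the multiplicative-gamma prior turns surplus factors off |
| `n_iter`, `burn_in`, `thin` | 5000 / 2500 / 5 | conservative for production runs; small fixtures converge in a few hundred sweeps |
| `h2_grid_size` | 20 | 0.05 resolution on heritability |
| `nu` | 3 | heavy-tailed local shrinkage on loading-regression residuals |
| `alpha1, beta1` | 2.1, 1 | proper, $E(\delta_1) > 1$ |
| `alpha2, beta2` | 3.1, 1 | $E(\delta_{h>1}) > 1$, so shrinkage strengthens with factor index |
| `sigma_a, sigma_b` | 3, 1 | proper inverse-Gamma on per-EC-term coefficient variances |

EC terms are built once from metadata: categorical terms are coded as
*full* one-hot indicators — deliberately over-parameterised, with the
shared per-term variance $\sigma^2_l$ absorbing the redundancy exactly
as a random-effect coding would — so that all levels are shrunk
symmetrically and an unseen level naturally contributes zero.
Quantitative terms are centred and scaled to unit variance at
design-build time and the transform is stored, because the shared
$\sigma^2_l$ prior is scale-sensitive; new environments are transformed
with the *training* scaling.

A model label such as `"S+T::T"` separates the prior side (terms that
shape loadings during training) from the predictor side (terms used to
build loadings for new environments).  Terms in the prior but not the
predictor contribute zero at prediction time; a predictor side of `"O"`
means no EC-based loading prediction at all, and new environments get
the constant (experiment-average or cluster-average) prediction instead.

## What the simulation generator emulates

`simulate_met()` draws data from the model's own generative process, at
defaults chosen to mirror a demanding MET: 500 lines × 500 environments
(400 training), 10 latent factors, heritability 0.8 for every factor
and residual trait, and factors carrying 80% of phenotypic variance on
average.  Kinship is $K = ZZ^\top/100 + 0.5I$ with $Z$ a 500 × 50
standard-normal matrix — 50 informative eigenvalues over a 0.5 baseline,
enough for moderate genomic prediction but far from a real pedigree.
The loading structure has three interpretable parts: a constant first
row (positive covariance everywhere), a second row tracking an
environmental gradient that is fully, partially, or only categorically
observable depending on `ec_mode`, and iid "unpredictable" rows.  Their
shares of the average per-column loading sum of squares are
`main_effect_prop` (default 0.25), the gradient remainder, and
`unpredictable_prop` (default 0.4); the defaults sit mid-grid so that
neither the predictable nor the unpredictable part dominates.  In the
multivariate mode the gradient is drawn with covariance
$WW^\top/20 + 0.5I$, making about half its variance explainable from the
exposed $W$ — a deliberate ceiling on how good EC-based prediction can
be.

Calibration is exact where it can be: the residual matrix is rescaled by
a single global scalar, solved with `uniroot` so that the realized
across-environment mean of $\mathrm{var}(F\Lambda_{\cdot j}) /
\mathrm{var}(Y_{\cdot j})$ equals `factor_share`, and the missing-cell
count is exactly `round(missing_prop * n * t)`.

What the generator does **not** emulate: genotype-by-trial connectivity
patterns of real breeding programs (missingness is uniform at random),
linkage disequilibrium or marker structure behind $K$, non-Gaussian
traits, spatial field trends, and ECs measured with error.  Passing
tests on simulated data therefore demonstrate correctness of the
machinery and behaviour *under the model's own assumptions*, not
real-data performance.

## Evaluation machinery

Cross-validation follows MET practice: CV1 masks whole genotypes, CV2
masks genotype-experiment cells with fold order permuted independently
per experiment, and the four new-environment scenarios (held-out trials,
states with enough experiments, testers, two-year blocks with shared
genotypes removed) are layered on top of each CV2 training set.  A test
experiment is scored only on its CV2-holdout genotypes, so ability
estimates in new-environment scenarios are never inflated by cells the
model saw.  When the number of genotypes is not divisible by the fold
count, fold sizes differ by at most one.

Per-experiment abilities $r_i$ (Pearson correlations on $n_i$ test
pairs) are pooled by a random-effects meta-analysis with Hunter–Schmidt
sampling variances $(1-\bar r^2)^2/(n_i-1)$, $\bar r$ the
sample-size-weighted mean, via `metafor::rma(method = "HS")`.  Paired
model comparisons difference the two abilities per experiment with a
normal-theory standard error for dependent correlations; the covariance
term needs the correlation between the two prediction vectors, which
callers may supply (`r_ab`) — the default assumes independence, which is
conservative (larger SE) whenever the two models' predictions are
positively correlated, as they practically always are.

## Numerical choices

* Kinship eigenvalues are floored at $10^{-10}$ wherever an inverse is
  needed (cross-kinship prediction, GBLUP); near-singular training
  kinships warn rather than fail.
* The loading-regression coefficient update retries once with a
  $10^{-10}$ ridge jitter if its Cholesky fails, then propagates the
  error with the factor index.
* SVD initialisation orders components by descending singular value
  (ties resolved by column index, as returned); variance partitions
  start at 0.5; $\delta$ starts from its prior so no chain starts from
  a measure-zero configuration.
* GBLUP REML optimises the profiled likelihood over
  $\log(\sigma^2_g/\sigma^2_e) \in [-10, 10]$ (tolerance $10^{-8}$),
  a range generous enough that the boundary is effectively
  $h^2 \in [0.00005, 0.99995]$.
* An ability is undefined (and excluded from pooling, with the row
  retained as `NA`) when fewer than two test pairs exist or either
  vector is constant.
* Degenerate inputs follow report-then-proceed semantics: all-missing
  trait columns are warnings (the sampler mean-imputes and proceeds),
  while id mismatches and rank-deficient designs are hard errors.

## Problem sizes used by the test suite

The suite favours many small, sharply targeted fixtures over few large
ones: conjugate-algebra oracles run on 1×1 and 2×2 instances with
$10^4$ Monte-Carlo draws; prior recovery uses a 4-genotype, 3-experiment
data-free chain of 12,000 sweeps; parameter recovery uses 100 lines ×
10 experiments with 2 true factors; and the connectivity comparison uses
120 lines × 6 trials with 25% CV2-style holdout, fit with 500 sweeps.
These sizes were chosen so each statistical claim is testable with
comfortable Monte-Carlo margins while the whole suite stays quick enough
to run habitually.

## Known limitations

* **No connectivity, no benefit.**  When trials share no genotypes, the
  factor loadings of different trials cannot be linked by data, and the
  factor model can fall *behind* per-trial GBLUP (the acceptance suite
  demonstrates this deliberately).  The model is a tool for connected
  METs.
* Loading-EC regressions learn from experiments as replicates: with few
  experiments per EC level the coefficients are mostly prior, and
  `Gon`/`Ann` predictions revert toward the intercept factor.
* `Gon` contains no residual-trait component by construction — a new
  environment has no residual trait — so its abilities are bounded by
  how much of the genetic signal the factors carry.
* Memory: retained draws store dense $F$, $U_R$ arrays
  (`n_draws × n × t`); for very large METs persist thinned chains with
  `write_metfa_samples()` rather than raising `n_iter`.
* Each trait is modelled separately; multi-trait joint analysis is out
  of scope, as is marker-effect (SNP-BLUP) parameterisation.
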