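---
title: "Genomic selection with gselect: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection with gselect: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gselect)
```

## The model

Genomic selection replaces phenotyping every selection cycle with
predictions of genetic merit from genome-wide markers. `gselect` fits the
univariate GBLUP mixed model

$$ y = \mu + g + \varepsilon,\qquad
   g \sim N(0, K\sigma_g^2),\qquad
   \varepsilon \sim N(0, I\sigma_\varepsilon^2), $$

where $y$ holds one preprocessed phenotype value per genotype, $\mu$ is the
population mean, $g$ the vector of additive genetic values, and $K$ the
realized additive relationship matrix computed from marker dosages. The
GBLUPs $\hat g$ are the genomic estimated breeding values (GEBVs) used to
rank individuals, and narrow-sense heritability is reported as
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_\varepsilon^2)$. Because $y$ is a
vector of adjusted genotype means rather than plot-level records, this
$h^2$ is on the entry-mean scale; it is reported as-is.

### The relationship matrix

The model itself does not dictate a construction for $K$; `gselect` pins
the VanRaden convention used throughout the RR-BLUP ecosystem. Dosages are
taken on the $\{0,1,2\}$ scale, each polymorphic marker $j$ is centered at
twice its allele frequency, $w_{ij} = m_{ij} - 2p_j$, and

$$ K = \frac{WW^\top}{c}, \qquad c = 2\sum_j p_j(1 - p_j). $$

Monomorphic markers carry no relationship information and are excluded from
both $W$ and $c$. Centering with frequencies from the same matrix makes
every column of $W$ sum to zero, which has two convenient exact
consequences: the GLS estimate of $\mu$ reduces to the arithmetic mean of
$y$, and the fitted GEBVs sum to zero.

### REML by spectral decomposition

Variance components are estimated by restricted maximum likelihood,
parameterised by the ratio $\lambda = \sigma_\varepsilon^2/\sigma_g^2$.
The intercept is projected out with an orthonormal basis of
$\mathbf{1}^\perp$ and the projected kinship is eigendecomposed once
($O(n^3)$); each likelihood evaluation is then $O(n)$:

$$ \ell_R(\lambda) = -\tfrac12\Big[(n-1)\log\big(2\pi\hat\sigma_g^2\big)
   + \sum_{i=1}^{n-1}\log(\xi_i + \lambda) + (n-1)\Big],
   \qquad
   \hat\sigma_g^2 = \frac{1}{n-1}\sum_i \frac{\eta_i^2}{\xi_i + \lambda}. $$

$\log\lambda$ is optimised over $[-20, 20]$ (covering $h^2$ from about
$2\times10^{-9}$ to $1 - 2\times10^{-9}$) by bounded one-dimensional search
with tolerance $10^{-8}$. A solution at either bound is flagged
(`fit$boundary`) rather than treated as an error: it is the expected
outcome for pure-noise phenotypes. Eigenvalues that come out marginally
negative from floating-point noise are clipped to zero before the
likelihood is evaluated. The test suite pins this fit against an
independent dense implementation that forms $(K + \lambda I)^{-1}$ and its
determinants explicitly on a 2001-point grid.

### Marker effects and candidate prediction

Ridge-regression marker effects are back-solved from the kinship fit,

$$ \hat u = \tfrac1c W^\top (K + \hat\lambda I)^{-1}(y - \hat\mu\mathbf 1), $$

and satisfy $W\hat u = \hat g$ exactly — the GBLUP/RR-BLUP identity, which
the tests verify to $10^{-8}$. Selection candidates (genotyped, not
phenotyped) are predicted on this route: their dosages are centered with
the *training* allele frequencies and multiplied by $\hat u$ over the
shared markers. Training frequencies define the model's coordinate system;
using candidate frequencies would silently shift every prediction. Markers
absent from the candidate set are dropped without rescaling, with a
warning reporting the overlap; below an overlap fraction of 0.5 (the
`min_overlap` default) prediction is refused outright, since a model
applied to a mostly foreign marker panel no longer measures what it was
trained on.

## Phenotype preprocessing

Field trials produce several plots per genotype. Before model fitting each
trait is reduced to one value per genotype:

* **Designed trials** (RCBD, alpha lattice, augmented): a linear mixed
  model with genotype as a fixed effect and replication and/or block as
  random intercepts (block nested in replication when both are recorded),
  fit by REML with `nlme::lme`. Adjusted values are estimated genotype
  *means* (intercept plus effect), not contrasts against a reference
  genotype, so they stay on the phenotype scale. The augmented design is
  modelled like the lattice — genotype fixed, block random — with
  unreplicated entries simply contributing single observations.
* **No usable design information** (design `UNKNOWN`, or the
  replication/block columns missing or constant): the arithmetic mean of
  the genotype's non-missing plots.
* **Multiple trials**: values are computed within each trial first, then
  averaged, unweighted, over the trials in which each genotype appears.
  Genotypes observed in only a subset of trials are averaged over that
  subset without penalty.

Plots with a missing trait value are dropped before fitting, and genotypes
left with no observation are omitted. One degenerate case is handled
outside `lme`: data that saturate the genotype + design structure exactly
(zero residual variance, e.g. a simulated noiseless trial) make REML
ill-posed, so the adjustment uses the limiting fixed-effects adjusted
means, which is what the mixed model converges to as
$\sigma^2 \to 0$ (random effects unshrunken). For balanced designs both
routes equal the raw genotype means, a property the tests exploit.

## KNN imputation of missing dosages

Missing marker dosages are imputed by K nearest neighbours over
individuals (rows): the distance between two individuals is the Euclidean
distance over the markers observed in both, scaled by
$\sqrt{m/m_\text{shared}}$ so that individuals with little overlap are not
artificially close. For a missing cell the $k$ nearest individuals *with
data at that marker* donate their mean dosage; if none exists the column
mean is used. Defaults: $k = 5$, a small-$k$ choice that is stable on
populations of tens to hundreds of individuals. Ties in distance break by
ascending row index so results are deterministic. Imputed dosages are left
continuous — rounding to integers would discard information and nothing
downstream requires integrality — so the output encoding is `CONTINUOUS`.
Distances use only the originally observed cells, making the operation
idempotent. The exact distance scaling is this package's own choice and is
pinned by an exhaustive brute-force oracle in the tests, not by any
external convention. Imputation quality is not otherwise validated here;
when a dataset has been imputed upstream with a dedicated tool, that
should be preferred (`run_train(..., impute = FALSE)` enforces complete
input).

## Cross-validation

Accuracy is estimated by k-fold cross-validation (default $k = 10$): a
seeded uniform partition into folds whose sizes differ by at most one, the
extra individuals landing where the shuffle puts them. For each fold the
*entire* pipeline is refit on the remaining folds — kinship, centering
frequencies, REML, marker effects — and the held-out individuals are
predicted through the marker-effects route. Recomputing the centering
frequencies inside each fold matters: frequencies estimated on all
individuals leak information from the held-out set. The fold's score is
the Pearson correlation between predicted GEBVs and the held-out adjusted
phenotypes (after preprocessing no raw-plot response exists), and the
model accuracy is the mean over folds. A fold with zero variance in either
vector has no defined correlation; it is excluded from the mean with a
warning rather than recorded as zero, which would bias accuracy toward
zero. One seeded pass is one call; callers wanting replicated
cross-validation loop over seeds.

## The simulator

`simulate_genotypes` draws unlinked biallelic loci in Hardy–Weinberg
proportions: per marker $p \sim U(\text{maf}_\text{lo},
\text{maf}_\text{hi})$ (default 0.1–0.5), dosages
$\sim\text{Binomial}(2, p)$. `simulate_phenotypes` picks QTL uniformly
among the markers, draws standard-normal effects, and adds Gaussian noise
calibrated against the *realized* breeding-value variance so that
$\mathrm{var}(g)/(\mathrm{var}(g)+\sigma_\varepsilon^2)$ equals the target
$h^2$ exactly for the dataset in hand — sharper recovery tests at small
$n$ than calibrating against the expected variance. `simulate_trial` lays
the values out as RCBD (random intercept per replication) or alpha
lattice/augmented (random intercept per incomplete block nested in
replication) with i.i.d. plot noise. Everything is reproducible
bit-for-bit from the seed.

What the simulator does *not* emulate — and what passing tests therefore
do not demonstrate about real data — includes linkage disequilibrium and
marker redundancy, population structure and family stratification
(kinship here concentrates near the identity), genotype-by-environment
interaction, dominance and epistasis, non-Gaussian trait distributions,
and informative missingness in either genotypes or phenotypes. Accuracy
on real breeding populations, where LD lowers the effective number of
independent loci and relatives share long haplotypes, is typically higher
at matched $n$ than on these worst-case unlinked simulations.

## Worked example

```{r example, eval = FALSE}
g   <- simulate_genotypes(n = 300, m = 1000, seed = 1)
sim <- simulate_phenotypes(g, n_qtl = 50, h2 = 0.5, seed = 2)
K   <- kinship_matrix(g)
fit <- fit_gblup(sim$phenotypes, K)
fit$h2                      # ~0.50
eff <- marker_effects(fit, g, K)
cv  <- k_fold_cross_validate(sim$phenotypes, g, k = 10, seed = 3)
cv$accuracy                 # ~0.23 at these sizes (see below)
```

At $n = 300$, $m = 1000$ unlinked loci and $h^2 = 0.5$, theory puts the
achievable accuracy near $\sqrt{n_\text{train} h^2 / (n_\text{train} h^2 +
M_e)}\cdot\sqrt{h^2} \approx 0.24$ with $M_e \approx m$; the
cross-validation estimates concentrate there, and an oracle ridge
regression using the true simulation variances does no better. Simulated
accuracies in the 0.2–0.3 range at these sizes are thus the statistical
ceiling, not an implementation loss.

## Numerical choices, sizes and limitations

* Test and validation problem sizes ($n$ up to 300, $m$ up to 1000–2000,
  20 replicates for recovery studies) were chosen to make sampling error
  small relative to the tested tolerances while keeping a full suite run
  in well under a minute of compute for the unit tests.
* Genotype encodings `[-1,0,1]` and `[0,1,2]` are interconverted by the
  affine shift; a file containing only $\{0,1\}$ is ambiguous between the
  two and defaults to `[0,1,2]` with a warning.
* The selection index is a raw weighted sum of per-trait GEBVs by
  default; per-trait z-score standardisation is available
  (`standardize = TRUE`) for traits on incommensurate scales. Rankings
  are invariant to positive rescaling of the weight vector.
* Output tables are sorted by descending value with ties broken by
  genotype name, so repeated runs are diffable; all randomness flows from
  explicit seed arguments.
* Out of scope: Bayesian marker-effect models (BayesA/B, Bayesian LASSO),
  multivariate GBLUP, dominance or epistasis kernels, spatial field
  models, pedigree-aware imputation, and genetic correlations between
  traits.
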