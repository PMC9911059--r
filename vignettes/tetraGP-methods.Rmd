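---
title: "Genomic prediction models for tetraploid multi-environment trials"
author: "tetraGP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction models for tetraploid multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetraGP)
```

## The problem

Potato and other autotetraploid crops are tested in multi-location,
multi-year trials, and breeders want to predict the performance of
untested cultivar-by-environment(-by-trait) combinations from genome-wide
SNP markers.  Two features make this harder than the diploid
single-trait case: tetrasomic inheritance means a biallelic SNP has five
genotype classes (AAAA ... BBBB) whose effects need not be additive in the
allele count, and genotype x environment interaction (G x E) means a
cultivar's genetic merit changes across location-years.  tetraGP
implements a full modelling chain for this setting: a tetrasomic
relationship matrix, four Bayesian prediction models of increasing
structure, the sparse-testing cross-validation schemes used to compare
them, and a synthetic trial generator with known truth.

## The tetrasomic relationship matrix

Each SNP is expanded into five 0/1 indicator columns, one per genotype
class, so both additive and nonadditive genotype effects are captured.
With $x_{ji}$ the indicator of cultivar $j$ at column $i$, $p_i$ the
column frequency, and $M$ the number of polymorphic columns,

$$K_{jk} = \frac{1}{M}\sum_{i=1}^{M}
  \frac{(x_{ji}-p_i)(x_{ki}-p_i)}{p_i(1-p_i)}, \qquad
K_{jj} = 1 + \frac{1}{M}\sum_{i=1}^{M}
  \frac{x_{ji}^2 - 2p_ix_{ji} + p_i^2}{p_i(1-p_i)}.$$

Because $x^2-2px+p^2 = (x-p)^2$, the matrix equals a normalized Gram
matrix of centred, scaled indicators plus the identity; it is therefore
symmetric positive definite with diagonal at least one, which every
downstream factorization relies on.  Columns with $p_i \in \{0, 1\}$
would divide by zero and carry no information, so they are excluded
from both the sum and $M$.  Cultivars missing more than 10% of their
SNP calls are dropped; remaining missing calls are imputed to the SNP's
modal genotype class, and frequencies are computed after imputation on
the analysis set, keeping the matrix self-contained.  A relative jitter
of $10^{-8}$ times the mean diagonal is added before any factorization,
guarding the Cholesky/eigen steps when near-duplicate clones are
present.

## The four prediction models

All models operate on the complete cultivar x environment (x trait)
grid in canonical order (environment, then cultivar, then trait);
absent or held-out cells are treated as masked and imputed by data
augmentation, which is what allows arbitrary missingness patterns.

**M1 (single-trait reaction norm).**
$y = Z_E\mu_E + g + ge + \varepsilon$ with
$g \sim N(0, \sigma^2_g Z_g K Z_g')$ and
$ge \sim N(0, \sigma^2_{ge}\, Z_g K Z_g' \# Z_E E Z_E')$, where $\#$ is
the Hadamard product and $E$ is an environment relationship matrix
(identity by default, making interaction effects independent between
environments); errors are homoscedastic.  M1 can predict entirely
untested environments because nothing in it requires environment-specific
covariances.

**M2 (environmental covariances).**
$y = Z_E\mu_E + u + \varepsilon$ with $u \sim N(0, U_E \otimes K)$: the
genomic main effect and G x E are modelled jointly through an
unstructured $m \times m$ covariance $U_E$ between environments,
estimated from the data, with heteroscedastic per-environment error
variances.  M2 (and M3) refuse to predict a fully unobserved
environment: the corresponding rows of $U_E$ have no data.

**M3 (M2 plus an identity-kernel effect).**
Adds $f \sim N(0, F_E \otimes I)$, independent of $u$ and
$\varepsilon$.  Its cultivar kernel is the identity, so it captures
environment-covariant variation *not* explained by the marker-based
kernel — nonadditive or epistatic effects missing from $K$.

**M4 (multitrait multi-environment).**
$Y = 1\mu' + Z_E\mu_E + g + ge + \varepsilon$ on the $n_T \times t$
response matrix, with matrix-normal effects
$g \sim MN(0, Z_g K Z_g', U_g)$,
$ge \sim MN(0, Z_g K Z_g' \# Z_E Z_E', U_{ge})$ and
$\varepsilon \sim MN(0, I, \Sigma_t)$; the three $t \times t$ trait
covariances are sampled unstructured.  A cultivar observed for some
traits borrows information for its masked traits through $U_g$,
$U_{ge}$ and $\Sigma_t$ — the mechanism behind the trait-wise
sparse-testing scheme.

A useful identity connects M1 and M2: with
$U_E = \sigma^2_g J + \sigma^2_{ge} I$ and homoscedastic errors, the
Kronecker covariance of M2 equals the Hadamard covariance of M1
exactly.  The test suite asserts this to $10^{-12}$, and uses it as a
cross-check between the two engine layouts.

## Gibbs sampler

All four models are fitted by conjugate Gibbs sampling.  Computational
choices that matter:

* The kernel is eigendecomposed once ($K = V\Lambda V'$); every
  kernel-structured update is diagonal in that basis.
* Trait (or environment) covariances are jointly diagonalized against
  the residual covariance each sweep (solve
  $L^{-1} U L^{-T} = QDQ'$ with $\Sigma = LL'$), making every
  multivariate row update elementwise.  With the environment relation
  $E$ eigendecomposed as well, the M4 interaction update is a fully
  separable three-way rotation.
* Masked cells are drawn from their conditional normal each sweep
  (data augmentation); rows are grouped by missingness pattern so the
  per-pattern Schur complements are computed once per sweep.
* Reported predictive means are Rao-Blackwellized: the tracker
  averages the *conditional means* of the random effects rather than
  their draws, which substantially reduces Monte-Carlo error at masked
  cells; predictive SDs are taken from the raw draws so they reflect
  the full posterior spread of the linear predictor.
* For a cultivar observed for some traits and masked for others in the
  same environment, the predictive mean additionally includes the
  residual's cross-trait conditional mean
  \(E[\varepsilon_{mis} \mid \varepsilon_{obs}]\); omitting it would
  discard the within-row information carried by \(\Sigma_t\) and
  biases multitrait predictions measurably.
* Fixed effects (environment/trait means) have flat priors.  The M4
  intercept is absorbed into the environment means during sampling and
  reported as their average, since the model is over-parameterized as
  written.
* Environments with no observed cells are dropped from the sampling
  grid (M1/M4) and predicted as the grand mean of the estimated
  environment means plus the genomic main effect.  The interaction
  term contributes nothing for such environments, and predictive SDs
  are correspondingly wider.  Pearson correlations are invariant to
  this additive convention; squared errors are not, which is flagged
  here once and documented in `?fitGEModel`.

Priors are weakly informative and data-scaled: scalar variances are
scaled-inverse-$\chi^2$ with 5 degrees of freedom and scale chosen so
the prior mode is half the sample variance of the observed responses;
covariance matrices are inverse-Wishart with $d + 4$ degrees of freedom
and scale $0.5\,S_{\mathrm{pheno}}(df - d - 1)$.  Default MCMC settings
are 30,000 iterations, 5,000 burn-in, thinning 5; all tests and the
examples here use much shorter chains, which is adequate because the
fully conjugate, jointly diagonalized updates mix quickly for variance
components.  Convergence is monitored by a split-chain potential scale
reduction factor on every variance parameter, with a warning (never an
error) above 1.1.  One master seed drives everything; per-fold and
per-trait sub-seeds are derived by a deterministic integer recurrence
so folds are independent and replayable.

## Cross-validation schemes

Seven schemes describe which cells of the target environments are
masked:

| scheme | model | masking |
|---|---|---|
| M1Sa, M4Ma | M1, M4 | every cell of the target environments (one fold) |
| M1Sp, M2Sp, M3Sp | M1-M3 | 70% of cultivars, same set for all traits |
| M4Mp | M4 | 70% of cultivars, masked for *all* traits |
| M4Mp* | M4 | an independent 70% sample *per trait* |

The number masked is `round(0.7 n)` with ties rounded up.  Folds are
generated from the master seed only, so the identical partitions can
be reused across the models being compared.  Accuracy is scored per
(target environment, trait) as the Pearson correlation (COR) and mean
squared error (PMSE) between observed and predicted values of that
fold's masked cells, aggregated as mean and SD over folds; folds
leaving fewer than three scoreable cells for some environment-trait
combination are skipped with a warning rather than silently patched.
Phenotypes are fitted on their raw scale, so PMSE is in squared trait
units.

## The synthetic trial generator

`simulateDosages()` draws per-SNP B-allele frequencies from a Beta(2,2)
truncated to [0.05, 0.95] (echoing a MAF > 0.05 marker filter) and
dosages as Binomial(4, q) — tetrasomic random mating.  Setting
`nFamilies` instead creates full-sib families (two random-mating
parents, bivalent gametes drawn hypergeometrically), giving the panel
the relatedness structure of a breeding program; this matters for
parameter-recovery experiments because separating $U_E \otimes K$ from
$\Sigma \otimes I$ (or $F_E \otimes I$) relies on off-diagonal kinship,
which a fully unrelated panel barely has.

`simulateTrial()` draws phenotypes from the exact generative equations
of whichever model is requested, so recovery tests compare posteriors
against recorded truth.  The `"study"` scenario emulates the structure
of a Nordic potato trial series — 253 cultivars, 2,000 SNPs, 3
locations x 2 years, 7 traits — with per-trait between-environment
genetic correlations spanning high (0.85), moderate (0.5) and
near-zero/negative (-0.1) regimes, cross-trait genetic correlation
0.5, heritability about one half, and heteroscedastic environment
error scales.  What it does **not** emulate: linkage disequilibrium,
selection, field spatial trends, or replicate-level plot errors —
passing tests demonstrate that the estimators recover the assumed
covariance structures, not that real potato data satisfy them.

## Worked example

```{r example, eval = FALSE}
cfg <- defaultStudyScenario(nCultivars = 80, nSnps = 300)
panel <- simulateDosages(cfg, seed = 1)
kin <- tetraKinship(panel)
sim <- simulateTrial(panel, cfg, seed = 2, kinship = kin)

plan <- makeCVPlan("M4Mp*", sim$table,
                   targetEnvironments = c("HEL2021", "MOS2021", "UM2021"),
                   nRepeats = 3, seed = 3)
res <- runScheme(sim$table, kin, plan,
                 settings = mcmcSettings(2000, 500, 2, seed = 4))
head(res$metrics)
```

## Numerical choices and limitations

* Problem sizes in the test-suite experiments (200 cultivars and 400
  SNPs for recovery, 120 cultivars for the scheme-ordering studies,
  3,000-iteration chains) were chosen as the smallest at which the
  estimators are comfortably inside their tolerance bands in pilot
  runs; they are the package's own reduced-scale study conditions.
* Monomorphic indicator columns are excluded from the divisor $M$
  rather than retained at a fixed marker count; retaining them would
  divide by zero and uniformly deflate the matrix.
* Whether the "+1" on the diagonal is a modelling intention or an
  artifact of the formula pair is not decidable from the formulas
  alone; it is implemented exactly as written, and its consequence
  ($K = \mathrm{Gram}/M + I$, eigenvalues $\ge 1$) is asserted in the
  tests.
* The per-environment error variances of M2/M3 are only weakly
  identified against the diagonal of $U_E$ (or $F_E$) when cultivars
  are unrelated; posteriors are proper but wide, and point estimates
  lean on the prior.  This is a property of the model class, not of
  the sampler.
* M1's error variance is homoscedastic across environments, as the
  model is defined; no per-environment relaxation is provided.
* Significance testing of accuracy differences between models is out
  of scope; the schemes report fold means and SDs only.
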