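---
title: "Genotype imputation and genome-enabled prediction: models and design"
author: "gpimpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype imputation and genome-enabled prediction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`gpimpute` studies a practical question in genomic prediction: when
individuals to be predicted are genotyped on a cheap low-density SNP panel,
is it better to impute their genotypes up to the full panel before
prediction, or to work with the reduced panel directly?  The package
provides every stage needed to answer this on simulated data: a population
simulator emulating a heterogeneous-stock (HS) mouse population, locus QC,
pedigree-based phenotype pre-correction, haplotype-HMM imputation, three
whole-genome prediction models of increasing flexibility, and
family-structured cross-validation.

# The synthetic population

`simulatePopulation()` gene-drops phased haplotypes through a pedigree:

* Founders are fully inbred strains (both gametes identical), 8 by
  default, with strain haplotypes drawn so every locus segregates.
* Random mating proceeds for `nGenerations` (default 12) through a pool of
  `nBreeders` (default 64) per generation, producing the fine-grained
  haplotype mosaic characteristic of an HS population.
* Recombination follows the Haldane model (crossovers as a Poisson
  process, no interference): between adjacent loci at distance $d$ cM the
  transmitted strand switches with probability
  $r = \tfrac12(1 - e^{-2d/100})$.  This closed form doubles as the test
  oracle.
* The final generation consists of `nFamilies` full-sib litters of
  `litterSize`; cage equals family except for a configurable fraction
  (default 10%) of families split over two cages.  Cage-family
  confounding is thus built in, as in the real HS data where most cage
  mates are full sibs.

Defaults are desk-scale (hundreds of individuals, hundreds of SNPs); the
real study's 1,904 individuals with 13,459 SNPs are a configuration, not a
default.  The acceptance study uses 600 individuals (60 families of 10)
and 300 SNPs on 5 chromosomes of 100 cM; with 60 loci per chromosome the
1.7 cM spacing yields strong local LD after 12 generations of mixing.
Because the generation depth and family-size distribution of the real HS
colony are not published in a form this package could mirror, these
defaults were chosen once as field-plausible values and documented here
rather than tuned.

`simulatePhenotypes()` builds, per trait,
$$y = \text{fixed covariates} + a + d + w + c + e,$$
with additive values $a$ from `nQtl` (default 30) loci with normal or
gamma effects, dominance $d$ from heterozygosity indicators, epistasis $w$
as additive-by-additive products over random QTL pairs (the simplest
non-additive architecture the semi/non-parametric models could exploit),
cage effects $c$ and Gaussian residuals $e$.  Every random component is
rescaled so its realized variance equals its target exactly; this makes
realized heritability match the architecture closely without per-seed
luck.  Covariates (age 8-12 weeks, gender, month batched by family, cage
density) get configurable linear effects; the real study names these
covariates but not their distributions, so simple categorical/uniform
choices are used.  Two stock architectures mirror the study's traits: a
body-weight-like trait ($h^2 = 0.40$) and a body-mass-index-like trait
($h^2 = 0.15$), both with modest dominance and epistasis.

What the generator does *not* emulate: the real allele-frequency spectrum,
mutation, selection, sex linkage, genotyping error in the "true" data, and
missing phenotypes.  Passing tests therefore demonstrate internal
correctness and qualitative pattern reproduction, not quantitative
agreement with any real dataset.

# Quality control and panels

`filterLoci()` applies the three standard locus filters: minor allele
frequency $\ge$ 0.05 (computed ignoring missing entries), call rate $\ge$
95%, and Hardy-Weinberg equilibrium at $p \ge 0.01$.  The HWE test is a
plain one-df chi-square without continuity correction (an exact
enumeration test is available via `method = "exact"`); the filter order in
the report is call rate, then MAF, then HWE.  `selectEquallySpaced()`
builds low-density panels as the floor points of a uniform index grid over
the QC-retained, map-ordered loci, first locus always included —
deterministic, and reproducing the 1,809 / 905 / 453 / 201 panel family
(50/75/90% masking) exactly.  Index-based (rather than bp-based) spacing
was chosen because the source protocol does not specify the basis; a
position basis is available.

# Phenotype pre-correction

`fitMixedModel()` fits $y = X\theta + Wc + Zu + e$ with
$u \sim N(0, A\sigma_u^2)$, $c \sim N(0, I\sigma_c^2)$,
$e \sim N(0, I\sigma_e^2)$, where $A$ is the pedigree numerator
relationship matrix from the tabular recursion.  Variance components are
estimated by REML.  Rather than an EM/AI iteration, the restricted
log-likelihood is maximized directly over the two variance ratios with
the residual variance profiled out; the likelihood is evaluated in the
eigenbasis of $A$ with a Woodbury identity for the cage block, making each
evaluation $O(nq^2)$ for $q$ cages.  At the scales this package targets
(n at most a few thousand) this is simpler and at least as robust as a
hand-rolled AI-REML, and the estimates are the same optimum.  Fixed and
random solutions then come from Henderson's mixed-model equations, whose
residual is checked in the tests.  The corrected response is
$y^* = y - X\hat\theta - W\hat c$: the additive BLUP $\hat u$ is reported
but *not* subtracted, so $y^*$ retains all genetic signal (additive and
non-additive) for the downstream models.  Treatment coding with
first-level reference is used for fixed factors; $y^*$ is invariant to
this choice, which the tests assert.  Pre-correction uses all phenotyped
individuals (it happens once, before any cross-validation split), which
mirrors the source protocol; the no-leakage guarantees concern model
fitting and imputation, not this step.

# Imputation

`imputeGenotypes()` implements a diploid Li-Stephens haplotype-copying
HMM.  The hidden state is an ordered pair of reference haplotypes; each
haplotype independently switches template between adjacent loci with
probability $1 - e^{-\lambda d}$ ($d$ in cM), choosing the new template
uniformly; chromosomes are independent.  Emission allows a per-allele
error rate $\varepsilon$ (default 0.01), so an observed genotype code is
the sum of two independently mis-read alleles.  Forward-backward over the
factorized transition costs $O(H^2)$ per locus per target, implemented in
C++.  Posterior genotype probabilities are reported per masked entry; the
imputed code is the posterior argmax.

Numerical and design choices:

* The switch intensity default is $\lambda = 0.05$/cM.  A mosaic after
  $G$ generations suggests roughly $G/100$ switches per cM (0.12 for the
  default population), but with a finite, subsampled reference the
  smoother prior imputed more accurately across all masking rates and
  both reference layouts in the package's own calibration runs, so the
  smoother value is the default and the parameter is exposed.
* Reference haplotypes are capped (default 200) by seeded subsampling for
  runtime; the acceptance study uses 120.
* The imputer sees only population haplotypes — pedigree information is
  deliberately unused, matching the protocol it emulates.
* For simulated data the reference haplotypes are the simulator's truth;
  phased real input would need external phasing, which is out of scope.
* This is not a reimplementation of Beagle's localized haplotype-cluster
  model; it is the same model family (haplotype-clustering HMMs) in a
  form that is fully specifiable and testable by exhaustive path
  enumeration.

Scoring (`scoreImputation()`) reports overall accuracy at masked entries
and the distribution of errors over the three categories 0↔1, 1↔2, 0↔2,
normalized over erroneous entries so the three shares sum to 1.

# Prediction models

All three models consume the pre-corrected response and the training-set
genotype codes; the same cross-validation split (same seed) is shared by
all models within a scenario.

**Bayesian LASSO** (`fitBL()`): $y = \mu + X\beta + e$ with independent
double-exponential priors on marker effects in their scale-mixture
representation: $\beta_j \sim N(0, \tau_j^2\sigma_\varepsilon^2)$,
$\tau_j^2 \sim \text{Exp}(\lambda^2/2)$,
$\sigma_\varepsilon^2 \sim \chi^{-2}(df, S)$,
$\lambda^2 \sim \text{Gamma}(\alpha_1, \alpha_2)$ with defaults
$S = df = 1$, $\alpha_1 = 1.2$, $\alpha_2 = 10^{-5}$ (shape/rate; the
convention follows the BLR lineage of samplers this hierarchy comes
from).  Gibbs conditionals: Gaussian for each $\beta_j$, inverse-Gaussian
for $1/\tau_j^2$, scaled-inverse-chi-square for $\sigma_\varepsilon^2$,
$\text{Gamma}(p + \alpha_1, \sum_j \tau_j^2/2 + \alpha_2)$ for
$\lambda^2$.  The sweep is compiled (Rcpp) and driven by R's RNG, so a
seed fixes the chain.  Markers are centered, not standardized, and an
intercept is always included — the original runs do not state either
choice, so both are documented here.  Chains default to 6,000 iterations
with 1,000 burn-in at test scale (the full-scale protocol of 70,000/5,000
is a setting, not a default).  An optional pedigree random effect is
*not* included: the prior hierarchy lists scale parameters for a $u$ term
that never appears in the model equation, and the package follows the
model equation.

**RKHS with kernel averaging** (`buildKernels()`, `fitRKHS()`): Gaussian
kernels $K_m = \exp(-h_m d_{ii'})$ on squared Euclidean genotype
distances, with genotypic values $g = f_1 + f_2 + f_3$,
$f_m \sim N(0, K_m \sigma_{\alpha,m}^2)$, and scaled-inverse-chi-square
priors ($df = 5$, $S = \mathrm{var}(y)/2 \times (df-2)$) on all
variances.  The stated bandwidth rule $h = a/q_{0.5}$ with
$a \in \{-5, -1, -1/5\}$ would make kernels explode if applied with the
negative sign inside $\exp(-h d)$; the package therefore uses the
magnitudes, $h_m = |a_m|/q_{0.5}$, which reproduces the intended
local/intermediate/global kernel family.  $q_{0.5}$ is the median of
off-diagonal distances (the diagonal zeros are excluded as they carry no
scale information), and distances are computed on centered codes.
Sampling runs in each kernel's eigenbasis (eigenvalues below $10^{-8}$
dropped, which enforces PSD); conditionals are Gaussian for each $f_m$
and scaled-inverse-chi-square for the variances.  Prediction uses
cross-kernels at the training bandwidths; predicting the training set
reproduces the in-sample posterior means exactly, which the tests check.

**Bayesian-regularized network** (`trainBRANN()`): a single hidden layer
of 5 tangent-sigmoid neurons and a linear output, trained by
Levenberg-Marquardt on $f = \gamma E_D + \alpha E_w$ ($E_D$ = sum of
squared residuals on the standardized target, $E_w$ = sum of squared
weights, biases included).  After each accepted LM step the regularizers
are re-estimated by the evidence framework: with $H = 2\gamma J^TJ +
2\alpha I$ the Gauss-Newton Hessian, the effective parameter count is
$\gamma_{\mathrm{eff}} = P - 2\alpha\,\mathrm{tr}(H^{-1})$, then
$\alpha \leftarrow \gamma_{\mathrm{eff}}/(2E_w)$ and
$\gamma \leftarrow (n - \gamma_{\mathrm{eff}})/(2E_D)$.  Because the
parameter count exceeds $n$ at genomic widths, the updates are started
from an *over*-regularized state ($\alpha = P/(2E_w)$, $\gamma = 1$) and
relaxed — starting under-regularized makes
$\gamma_{\mathrm{eff}} \to \min(n, P)$ immediately and collapses the data
weight, a known failure mode.  The damped system is solved through a thin
SVD of the Jacobian (Woodbury form), which also yields
$\mathrm{tr}(H^{-1})$ from the singular values; this is algebraically the
dense solve at a fraction of the cost since $n \ll P$.  Inputs are scaled
per column to $[-1,1]$ with training min/max; the target is standardized
and back-transformed.  The ensemble averages *predictions* over random
restarts (default 20; the alternative of averaging correlations is a
different estimand and was not adopted), and a restart that diverges is
excluded with a warning rather than aborting.  With heavy shrinkage an
ensemble can legitimately collapse to a constant prediction, in which
case the predictive correlation is undefined and reported as missing.

# Cross-validation and the experiment

`makeSplit()` implements the two family layouts: *across* assigns whole
families to training or testing (target fraction 2/3, achieved within
5%); *within* randomizes individuals of each family to both sides, with
every family of at least 2 contributing to both.  Families are full-sib
groups from the simulator's final generation.  *Across* splits have lower
train-test relatedness (verified against the mean cross-block of $A$).

`runExperiment()` runs the factorial: trait × layout × masking rate ×
genotype condition × model.  Per scenario the test set's genotypes are
masked to the panel and imputed back using *training individuals only* as
reference; models are trained on the full-panel training set and applied
to (i) the true full-panel test genotypes, (ii) the imputed test
genotypes, and (iii) — with a re-trained model — the reduced panel, the
only leakage-free reading of the reduced condition since train and test
features must align.  Metrics are the Pearson correlation between
predicted and observed corrected phenotypes and the prediction mean
squared error.  Every random step derives its seed deterministically from
the master seed, so identical configurations produce byte-identical
tables; a panel that covers every locus short-circuits the imputed and
reduced conditions to the full one.

# Problem sizes and limitations

The shipped tests and the acceptance study run at 600 individuals × 300
SNPs with 5 replicates for the pattern checks, chains of 1,500-20,000
iterations, 4 network restarts and a 120-haplotype reference — sizes
chosen so the whole suite runs on a laptop in minutes while leaving the
Monte-Carlo margins comfortable.  Known limitations: imputation accuracy
at 90% masking sits below the real-data figures because the desk-scale
panel is far sparser per centimorgan; the HMM stores the forward lattice
densely ($O(H^2 L)$ memory), which caps practical reference sizes around
a few hundred haplotypes; the exact test for HWE is enumerative and
intended for per-locus use; and the network's evidence updates assume the
Gauss-Newton approximation, so its reported effective parameter count is
an estimate, not an exact posterior quantity.
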