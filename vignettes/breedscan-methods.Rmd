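---
title: "Methods: mixture-model GWAS and cross-population EHH scans in breedscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture-model GWAS and cross-population EHH scans in breedscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedscan)
```

breedscan maps binary traits in closed, within-breed case/control cohorts
with two complementary engines: a Bayesian normal-mixture GWAS that models
all variant effects jointly, and a cross-population extended haplotype
homozygosity (XP-EHH) scan that contrasts haplotype lengths between cases
and controls. This vignette documents the models, their assumptions, the
parameters that matter, the synthetic-cohort generator used throughout the
test suite, and the numerical and design decisions that were genuinely
open.

## The mixture-model GWAS

The linear model is

$$ y = W\alpha + \sum_{j=1}^m x_j \beta_j + e, \qquad e \sim N(0,
\sigma^2_e I), $$

with $y$ the 0/1 case status analysed directly on the observed scale (no
liability transformation -- the standard practice for this model family on
case/control data), $W$ fixed-effect covariates (intercept plus, usually,
principal components of the genotype matrix), and $x_j$ the
column-centred allele2 dosage of variant $j$. Each effect comes from a
four-component mixture

$$ \beta_j \sim \pi_1 \, \delta_0 + \pi_2 \, N(0, 10^{-4}\sigma^2_g) +
\pi_3 \, N(0, 10^{-3}\sigma^2_g) + \pi_4 \, N(0, 10^{-2}\sigma^2_g), $$

so the non-null components hold up to 0.01%, 0.1% and 1% of the genetic
variance $\sigma^2_g$. The Gibbs cycle samples (1) fixed effects from
their conditional normals under flat priors, (2) per variant -- in an
order re-randomized every iteration -- the class indicator with
probability proportional to $\pi_k$ times the marginal likelihood of the
residual with $\beta_j$ integrated out, then $\beta_j$ from its
conditional normal, (3) $\pi$ from a Dirichlet(1 + class counts), and (4)
$\sigma^2_g, \sigma^2_e$ from scaled inverse-$\chi^2$ conditionals.
Residuals are maintained with the subtract/add trick, so one iteration is
$O(nm)$. The per-variant statistic reported is the absolute value of the
posterior-mean effect, averaged over chains first and taken absolute
second, so chains that disagree in sign cancel rather than inflate.

Key configuration (`bayesRConfig()`):

* `variance_coefficients` -- the mixture variance multipliers, fixed at
  `(0, 1e-4, 1e-3, 1e-2)`.
* `n_iterations` / `burn_in` / `n_chains` -- desk-scale defaults
  20,000 / 5,000 / 3, which converge on cohorts of a few hundred samples
  and a few thousand variants (the between-chain spread of
  $\sigma^2_g$ stays below 20% of its mean in the test suite); the
  full-replication setting for dense genome-wide panels is
  300,000 / 100,000 / 5.
* `dirichlet_prior` -- symmetric `(1, 1, 1, 1)`.
* Variance priors -- $\nu = 4$ with scales set to half of `var(y)` for
  both components; weakly informative and configurable.

Design choices that were open:

* **Centred, not standardized, genotypes.** Reported effects stay on the
  per-allele-copy scale of the phenotype, which is the scale on which
  per-locus tables are conventionally printed. Standardizing would
  re-weight rare variants and change the meaning of the effect-size
  threshold.
* **Covariates sampled jointly** with the variant effects rather than
  regressed out beforehand. Pre-regression would freeze the covariate fit
  before the genetic terms exist; joint sampling lets them compete, at
  the cost of a mild divergence risk from tools that pre-adjust.
* **Effect-variant threshold.** Variants with mean absolute effect
  $\ge 10^{-4}$ are called effect variants and merged into loci when
  consecutive effect variants sit closer than 1 Mb (strict inequality,
  single linkage). A `top_n` mode is provided for the alternative
  top-50-variants reporting style.

### The null noise floor of the reported effect

One behaviour of this model deserves an honest warning. At desk scale
(hundreds of samples), the two smallest non-null components are nearly
unidentified: for component variance $v$, the class-odds penalty
$\sqrt{\sigma^2_e/(v\,x'x + \sigma^2_e)}$ and reward
$\exp\{(x'r)^2 v / (2\sigma^2_e(v\,x'x+\sigma^2_e))\}$ cancel in
expectation when the trait is independent of the genotype, so class
occupancy follows $\pi$, whose posterior under a symmetric unit Dirichlet
stays spread over the simplex. Every null variant then retains a small
persistent shrunken effect proportional to its chance correlation with
$y$, on the order of $\sigma^2_g (\sum_k \pi_k\gamma_k)\, x'y /
\sigma^2_e$. On permuted-label cohorts of 400 samples and 2,000 variants
this floor sits near $5\times10^{-4}$ -- *above* the $10^{-4}$
effect-variant threshold -- and neither longer chains nor smaller variance
priors remove it, because it is a persistent bias, not Monte-Carlo noise
(the $\sigma^2_g$ trace is stationary under the null). The acceptance
suite measures this fraction and reports it as-is. Consequence for
practice: the absolute effect threshold is only meaningful relative to a
cohort's own null distribution (e.g. a label-permutation run), and
rankings (top-$n$) are more transferable than threshold counts at small
$n$. Planted-effect recovery is unaffected: truly associated variants
rank far above the floor.

## EHH, iHH and XP-EHH

Allele-specific EHH at marker distance $d$ from a core site, among the
$n_c$ haplotypes carrying the core allele, is

$$ \mathrm{EHH}(d) = \frac{\sum_h n_h (n_h - 1)}{n_c (n_c - 1)}, $$

summing over the distinct extended haplotypes spanning core to $d$. The
site-level mode used for the two-population comparison pools *all*
haplotypes and normalizes the homozygosity sum by its value at the core
site; published site-level variants differ, so this choice is fixed and
documented here, and the allele-specific mode is retained for decay plots
around a focal allele. Both modes start at 1 and are non-increasing;
extension stops below an EHH cutoff (default 0.05), at the chromosome
border, or at an inter-marker gap larger than `max_gap_bp`.

iHH is the trapezoidal integral of the decay curve over physical distance
in bp, after setting values below the cutoff to zero -- no interpolation
of the crossing point; the rule is simpler and stated. Curves truncated
at a border integrate over their observed support and carry a flag; a
strict `discard_border` switch drops them instead, since the reference
implementation of this statistic defaults to discarding.

XP-EHH at a variant is `log(iHH_cases) - log(iHH_controls)` (the
difference-of-logs form makes panel-swap antisymmetry bit-exact),
standardized by the genome-wide mean and standard deviation of the raw
scores; positive scores mean longer case haplotypes. P-values are
two-sided normal tail probabilities (the sidedness is a documented
choice), reported as $-\log_{10} p$. Variants with zero iHH in either
population are dropped and listed.

Candidate regions: windows of 1 Mb are slid on a 0.1 Mb grid; a window
qualifies with at least `min_n_extreme = 2` variants at
$-\log_{10} p \ge 4$, and overlapping or touching qualifying windows merge
into one region reporting variant counts, the percentage of extreme
variants and the top variant by absolute score. The window parameters can
be read two ways ("0.1 Mb overlap" of 1 Mb windows implies a 0.9 Mb
step); the dense 0.1 Mb grid is the default because published region
bounds align to a 0.1 Mb grid, and the coarser step remains available
through `step_bp`.

## The synthetic-cohort generator

`simulationConfig()` fixes the study conditions the tests run under:

* **Haplotypes** come from a Li-Stephens-style copying model: founder
  haplotypes (30 per subpopulation) drawn site-wise from ancestral
  frequencies U(0.1, 0.9); each cohort haplotype copies a founder mosaic
  with per-site switch probability 0.01 and per-site mutation 0.002 on a
  1 kb marker grid. With 1 kb spacing the mean copy tract is ~100 kb,
  matching the long-range LD of closed breed populations. Optional
  substructure draws a second subpopulation from Balding-Nichols-diverged
  frequencies (drift parameter `subpop_divergence`), which reproduces the
  PC-separable breed-type split the analyses must absorb.
* **Phenotypes** follow a liability-threshold model: per-variant effect
  classes from `mixture_proportions` (default `(0.99, 0.007, 0.002,
  0.001)`), effects from the matching normal components, genetic values
  rescaled so the realized liability heritability equals
  `heritability_liability` (default 0.5, a plausible within-breed value
  for a strongly familial inflammatory disease), Gaussian noise, and an
  empirical threshold that makes case counts exact at any cohort size
  (default case fraction 0.5, reflecting case/control sampling rather
  than population prevalence). Cohort sizes default to 300, the scale of
  the within-breed cohorts this package targets (~200-400). For power
  studies, `n_planted_top` forces evenly spaced variants into the
  top-effect class with effects *at* the class scale
  ($|\beta| = \sqrt{10^{-2}\sigma^2_g}$, random sign) rather than drawn
  from the component normal -- a normal draw can land near zero, which
  would plant no recoverable signal and make recovery rates meaningless.
* **Sweeps** are injected by haplotype copying, not forward simulation:
  within the target phenotype group, recipients receive the donor
  haplotype around the core until the donor frequency reaches
  `carrier_target_frequency`. By default each recipient's copied extent
  per side is exponential with mean `flank/2`, truncated at `flank`
  (default 100 kb): haplotype sharing then decays with distance from the
  core the way recombination erodes a real sweep, and the homozygosity
  signal peaks at the selected site. The idealized `decay = "none"` mode
  copies the full span (at target frequency 1 the group becomes exactly
  monomorphic over the span, which the exact-value tests use). The flank
  default keeps the swept fraction of the simulated chromosome small
  (~7%), mirroring real genomes where sweeps occupy a vanishing fraction
  of the scan; a sweep spanning a large fraction of the scanned region
  inflates the standardization variance and masks itself.

What the generator does *not* emulate: coalescent-exact genealogies,
recombination-map heterogeneity in cM, genotyping error, imputation
artefacts, and kinship structure beyond the two-subpopulation split.
Passing tests therefore demonstrate correctness of the statistical
machinery under a faithful but idealized LD structure, not robustness to
every artefact of array data.

## Numerical choices and degenerate inputs

* Missing dosages are `NA` in memory, the PLINK missing code on disk;
  QC follows the fixed order variant-missingness, sample-missingness, then
  MAF recomputed on surviving samples (mirroring the conventional
  `--geno --mind --maf` semantics), and is idempotent.
* PCA covariates mean-impute, centre and scale columns, and fix each
  component's sign so the largest-magnitude score is positive --
  deterministic output up to floating point.
* Effect-variant ties in `top_n` mode break by genomic order; the top
  variant of a locus is the member with maximal absolute effect.
* `ehhCurve` rejects monomorphic cores in allele-specific mode and cores
  with fewer than two carriers; site-level scans flag degenerate cores
  (homozygosity zero at the core) and report them dropped.
* `xpehhScan` refuses to standardize when the raw scores have zero
  variance (e.g. identical panels) rather than emitting NaNs.
* The risk index ships both weighting schemes -- `count` (0/1/2, the
  default) and `half` (0/0.5/1) -- because published descriptions of this
  index state 0/0.5/1 weights while reporting means only consistent with
  risk-allele counts over ~11 loci; `count` is exactly twice `half`, so
  the choice rescales but never reorders individuals. Missing genotypes
  contribute the locus mean weight.
* Every simulation stage, chain and pipeline stage derives its RNG stream
  deterministically from one user seed (kept below $2^{31}$), so stages
  can be rerun in isolation and whole runs reproduce byte-identically.

## Problem sizes in the test suite

The suite exercises the engines at the cohort scale the package targets:
mixture-model recovery at $n = 600$, $m = 3{,}000$ with 5 planted
top-class effects over 10 seeds and 3 chains of 20,000 iterations; its
null calibration at $n = 400$, $m = 2{,}000$ with permuted labels;
XP-EHH null calibration on exchangeable half-cohorts of 250 samples at
5,000 variants over 10 seeds; sweep detection at 80% carrier frequency
over 20 seeds; and EHH equivalence against brute-force enumeration on
1,000 random panels of up to 12 haplotypes and 20 markers. These sizes
are the package's reference conditions; larger cohorts only relax the
identifiability caveats above.

## Known limitations

* The linear-on-observed-scale treatment of binary traits ignores the
  liability scale; effects are attenuated for very unbalanced cohorts.
* The site-level EHH definition is one of several in use; iHH magnitudes
  are not directly comparable across definitions, although standardized
  XP-EHH scores largely are.
* The null noise floor of the absolute-effect threshold at small $n$
  (discussed above) means threshold-based effect-variant *counts* are
  cohort-relative; rankings and planted-effect recovery are stable.
* The copying-model generator shares founders across cases and controls;
  it cannot create confounding between sweep status and phenotype beyond
  what `injectSweep` introduces deliberately.
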