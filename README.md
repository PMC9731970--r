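# breedscan

Genetic mapping for within-breed case/control cohorts — the setting of
pedigree dog breeds, where long-range LD, breed-type substructure and
ongoing artificial selection shape both disease association and haplotype
diversity. The package pairs two mapping engines over shared genotype and
haplotype containers:

1. **A four-component Bayesian mixture-model GWAS** (BayesR-type). All
   variant effects are modelled jointly,

   *y* = *Wα* + Σ*ⱼ xⱼβⱼ* + *e*,  *βⱼ* ~ *π*₁δ₀ + *π*₂N(0, 10⁻⁴σ²g) +
   *π*₃N(0, 10⁻³σ²g) + *π*₄N(0, 10⁻²σ²g),

   fitted by a compiled Gibbs sampler (collapsed class-indicator updates,
   Dirichlet-sampled mixture proportions, scaled inverse-χ² variance
   updates). Per-variant posterior mean absolute effects feed locus
   calling (effect variants at |effect| ≥ 10⁻⁴ merged within 1 Mb), a
   per-dog risk index over the top variants, Welch case/control
   comparison, and ANOVA variance-explained decompositions.

2. **A cross-population XP-EHH selection scan.** Site-level extended
   haplotype homozygosity is integrated over physical distance (iHH) in
   case and control haplotype panels; XP-EHH = log iHH_cases − log
   iHH_controls, standardized genome-wide, with two-sided normal
   −log₁₀ *p* and sliding-window candidate-region calling (1 Mb windows,
   0.1 Mb grid, ≥ 2 extreme variants at −log₁₀ *p* ≥ 4).

Around the engines: PLINK text/binary I/O, QC filters
(`--geno/--mind/--maf` semantics), PCA covariates, allelic χ² and
logistic scans, LD r², haplotype-carrier classification, and a
haplotype-copying cohort simulator with liability-threshold phenotypes,
optional substructure and injectable selective sweeps — with ground truth
returned for recovery studies.

## Worked example

```r
library(breedscan)

## a cohort of 300 dogs on a 15 Mb chromosome of 3,000 SNPs, with 5
## planted risk variants and a selective sweep (80% carrier frequency in
## cases) injected at a neutral site, 5.0 Mb
cfg <- simulationConfig(n_samples = 300, m_variants = 3000, spacing_bp = 5000,
                        n_planted_top = 5,
                        mixture_proportions = c(1, 0, 0, 0),
                        sweep = list(group = "cases", core_index = 1000,
                                     carrier_target_frequency = 0.8,
                                     flank_length_bp = 250000,
                                     decay = "exponential"),
                        seed = 42)
co  <- simulateCohort(cfg)
fit <- fitBayesR(co$phenotypes$status, co$genotypes,
                 config = bayesRConfig(n_iterations = 5000, burn_in = 1000,
                                       n_chains = 2, seed = 1))
ev   <- callEffectVariants(fit, top_n = 5)
loci <- mergeIntoLoci(ev, co$genotypes, co$phenotypes)
ri   <- computeRiskIndex(co$genotypes, loci, scheme = "count")
wt   <- welchTTest(ri$index[co$phenotypes$status == 1],
                   ri$index[co$phenotypes$status == 0])

sp  <- splitPanelByStatus(co$panel, co$phenotypes)
sc  <- xpehhScan(sp$case, sp$control)
reg <- callCandidateRegions(sc)

loci[, c("locus_id", "n_variants", "top_variant", "top_effect",
         "risk_allele", "ea_freq_cases", "ea_freq_controls")]
round(c(t = wt$t, df = wt$df, p = wt$p), 4)
reg[, c("start_bp", "end_bp", "n_variants", "n_extreme", "top_variant",
        "top_score")]
```

Output from this exact script:

```
                locus_id n_variants top_variant top_effect risk_allele
1   chr1:4985000-5000000          3      v01000  0.2097693           C
2   chr1:7500000-7500000          1      v01500 -0.1464219           A
3 chr1:15000000-15000000          1      v03000  0.1253736           C
  ea_freq_cases ea_freq_controls
1     0.9166667        0.5533333
2     0.5600000        0.7900000
3     0.2900000        0.1200000
       t       df        p
 14.7966 297.6850   0.0000
  start_bp  end_bp n_variants n_extreme top_variant top_score
1  3900000 6100000        440        67      v00996  8.955667
```

Three associated loci are called. Two are planted causal variants
(v01500, whose *negative* effect means its counted allele C is
protective, so the risk allele is A; and v03000). The first locus sits at
the injected sweep: driving a haplotype to ~80% frequency in cases
*creates* a case/control allele-frequency difference at the swept site
(0.92 vs 0.55) — hitchhiking risk, which the association engine picks up
even though no effect was planted there. The risk index over the loci
separates cases from controls at t ≈ 14.8, and the region caller flags a
single candidate region whose top variant, v00996, lies 20 kb from the
sweep core with a strongly positive score — positive meaning longer case
haplotypes, the signature of selection in cases. Triangulating the two
engines this way (which associated loci are also under selection?) is
precisely the analysis the package automates.

A thin command-line front end over the same functions ships in
`inst/scripts/breedscan.R`
(`simulate | qc | bayesr | loci | riskindex | xpehh | regions | run`),
driven by a flat `key = value` config (see `readFlatConfig()`).

## The methods vignette

`vignettes/breedscan-methods.Rmd` documents the model and its
assumptions, the EHH definitions, the generator's scope, numerical
choices, and known limitations — including an honest analysis of the
null noise floor of the absolute-effect threshold at desk scale.
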