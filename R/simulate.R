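## Synthetic cohort generator: haplotype-copying panels, liability-threshold
## case/control phenotypes with four-component mixture effects, and
## injectable selective sweeps.  Ground truth is returned for recovery tests.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator into a validated
#' list.  Defaults describe a single within-breed case/control cohort of
#' 300 dogs on a 3 Mb chromosome of 3,000 SNPs with block-wise LD from the
#' haplotype-copying process, a liability-scale heritability of 0.5 and a
#' 50% case fraction (cohort sampling, not population prevalence).
#'
#' @param n_samples Number of diploid individuals.
#' @param m_variants Number of biallelic SNPs.
#' @param n_founder_haplotypes Founder haplotypes per subpopulation for the
#'   copying process (>= 2).
#' @param mutation_rate_per_site Per-site allele-flip probability while
#'   copying.
#' @param switch_rate_per_site Per-site probability of switching founder
#'   template (recombination analogue; smaller = longer LD blocks).
#' @param spacing_bp Inter-marker spacing in bp (uniform grid).
#' @param subpop_fraction Fraction of samples in the second subpopulation
#'   (0 disables substructure).
#' @param subpop_divergence Drift parameter F in `[0, 1)` of the
#'   Balding-Nichols allele-frequency divergence between subpopulations.
#' @param mixture_proportions Probabilities of the four effect classes
#'   (zero, small, medium, large); must sum to 1.
#' @param variance_coefficients Variance of each class as a multiple of the
#'   genetic variance; fixed to `c(0, 1e-4, 1e-3, 1e-2)` in the analysis
#'   model and defaulted to the same here.
#' @param n_planted_top Number of variants forced into the largest-effect
#'   class (evenly spaced across the map), for power studies.  Planted
#'   effects are set at the class scale (magnitude `sqrt(gamma_4 *
#'   sigma2_g)`, random sign) rather than drawn from the component normal,
#'   so every planted variant carries recoverable signal.
#' @param heritability_liability Fraction of liability variance that is
#'   genetic.
#' @param prevalence Case fraction of the cohort (empirical threshold on
#'   realized liabilities, so case counts are exact).
#' @param covariate_effects Named numeric; currently `subpop` = liability
#'   shift of subpopulation 2, creating structure confounding.
#' @param sweep List with `group` (`"none"`, `"cases"`, `"controls"`),
#'   `core_index`, `carrier_target_frequency`, `flank_length_bp`, and
#'   `decay` (`"exponential"`, the default, draws each recipient's copied
#'   extent from a truncated exponential so haplotype sharing decays away
#'   from the core as recombination would erode a real sweep; `"none"`
#'   copies the full span into every recipient).
#' @param seed Integer seed; every simulation stage derives its stream from
#'   it.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_samples = 300,
                             m_variants = 3000,
                             n_founder_haplotypes = 30,
                             mutation_rate_per_site = 0.002,
                             switch_rate_per_site = 0.01,
                             spacing_bp = 1000,
                             subpop_fraction = 0,
                             subpop_divergence = 0,
                             mixture_proportions = c(0.99, 0.007, 0.002, 0.001),
                             variance_coefficients = c(0, 1e-4, 1e-3, 1e-2),
                             n_planted_top = 0,
                             heritability_liability = 0.5,
                             prevalence = 0.5,
                             covariate_effects = c(subpop = 0),
                             sweep = list(group = "none", core_index = NA,
                                          carrier_target_frequency = 0.8,
                                          flank_length_bp = 100000,
                                          decay = "exponential"),
                             seed = 1) {
    if (is.null(sweep$decay)) sweep$decay <- "exponential"
    cfg <- list(n_samples = as.integer(n_samples),
                m_variants = as.integer(m_variants),
                n_founder_haplotypes = as.integer(n_founder_haplotypes),
                mutation_rate_per_site = mutation_rate_per_site,
                switch_rate_per_site = switch_rate_per_site,
                spacing_bp = as.integer(spacing_bp),
                subpop_fraction = subpop_fraction,
                subpop_divergence = subpop_divergence,
                mixture_proportions = mixture_proportions,
                variance_coefficients = variance_coefficients,
                n_planted_top = as.integer(n_planted_top),
                heritability_liability = heritability_liability,
                prevalence = prevalence,
                covariate_effects = covariate_effects,
                sweep = sweep,
                seed = as.integer(seed))
    if (cfg$n_founder_haplotypes < 2L)
        stop("n_founder_haplotypes must be >= 2")
    if (abs(sum(cfg$mixture_proportions) - 1) > 1e-8 ||
        any(cfg$mixture_proportions < 0))
        stop("mixture_proportions must be a probability vector summing to 1")
    if (any(cfg$variance_coefficients < 0) ||
        cfg$variance_coefficients[1] != 0)
        stop("variance_coefficients must be non-negative with first entry 0")
    probs <- c(cfg$subpop_fraction, cfg$subpop_divergence,
               cfg$heritability_liability)
    if (any(probs < 0 | probs > 1))
        stop("fractions must lie in [0, 1]")
    if (!cfg$sweep$group %in% c("none", "cases", "controls"))
        stop("sweep$group must be none, cases or controls")
    if (!cfg$sweep$decay %in% c("exponential", "none"))
        stop("sweep$decay must be exponential or none")
    if (cfg$sweep$group != "none" &&
        (is.na(cfg$sweep$core_index) ||
         cfg$sweep$core_index < 1 || cfg$sweep$core_index > cfg$m_variants))
        stop("sweep core_index must lie within the variant map")
    class(cfg) <- "SimulationConfig"
    cfg
}

## deterministic per-stage seed stream (kept < 2^31)
.stageSeed <- function(seed, stage)
    as.integer((as.numeric(seed) * 97L + stage * 1009L) %% 2147483647)

.simVariantMap <- function(cfg) {
    m <- cfg$m_variants
    variantMap(sprintf("v%05d", seq_len(m)), rep("1", m),
               cfg$spacing_bp * seq_len(m),
               rep("A", m), rep("C", m))
}

.copyHaplotypes <- function(founders, n_hap, switch_rate, mutation_rate) {
    m <- ncol(founders); K <- nrow(founders)
    out <- matrix(0L, n_hap, m)
    for (i in seq_len(n_hap)) {
        switches <- c(TRUE, stats::runif(m - 1) < switch_rate)
        seg <- cumsum(switches)
        templ <- sample.int(K, max(seg), replace = TRUE)
        hap <- founders[cbind(templ[seg], seq_len(m))]
        flip <- stats::runif(m) < mutation_rate
        hap[flip] <- 1L - hap[flip]
        out[i, ] <- hap
    }
    out
}

#' Simulate a phased haplotype panel
#'
#' Li-Stephens-style copying model: founder haplotypes are drawn site-wise
#' from ancestral allele frequencies `U(0.1, 0.9)`; each cohort haplotype
#' copies a mosaic of founders with per-site template-switch probability
#' `switch_rate_per_site` and per-site mutation `mutation_rate_per_site`.
#' An optional second subpopulation uses founders drawn from
#' Balding-Nichols-diverged frequencies (drift `subpop_divergence`).
#'
#' @param cfg A [simulationConfig()].
#' @return List with `panel` ([HaplotypePanel-class]) and `truth` (list
#'   holding per-sample subpopulation labels etc., grown by the later
#'   simulation stages).
#' @export
simulateHaplotypePanel <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(.stageSeed(cfg$seed, 1L))
    n <- cfg$n_samples; m <- cfg$m_variants
    vm <- .simVariantMap(cfg)
    p <- stats::runif(m, 0.1, 0.9)
    n2 <- round(n * cfg$subpop_fraction); n1 <- n - n2
    FST <- cfg$subpop_divergence
    subFreq <- function() {
        if (n2 == 0L || FST <= 0) return(p)
        a <- p * (1 - FST) / FST; b <- (1 - p) * (1 - FST) / FST
        stats::rbeta(m, a, b)
    }
    drawPop <- function(n_s) {
        ps <- subFreq()
        founders <- matrix(stats::rbinom(cfg$n_founder_haplotypes * m, 1L,
                                         rep(ps, each = cfg$n_founder_haplotypes)),
                           nrow = cfg$n_founder_haplotypes)
        .copyHaplotypes(founders, 2L * n_s, cfg$switch_rate_per_site,
                        cfg$mutation_rate_per_site)
    }
    haps <- drawPop(n1)
    if (n2 > 0L) haps <- rbind(haps, drawPop(n2))
    panel <- HaplotypePanel(haps, vm)
    truth <- list(
        samples = data.frame(sample_id = sampleIDs(panel),
                             subpop = rep(c(1L, 2L), c(n1, n2)),
                             stringsAsFactors = FALSE),
        config = cfg)
    list(panel = panel, truth = truth)
}

#' Collapse a phased panel to genotype dosages
#'
#' Consecutive haplotype pairs (the two phases of each sample) are summed
#' into allele2 dosages.
#'
#' @param panel A [HaplotypePanel-class] with an even number of rows.
#' @return A [GenotypeMatrix-class].
#' @export
pairToGenotypes <- function(panel) {
    stopifnot(is(panel, "HaplotypePanel"))
    h <- panel@haplotypes
    if (nrow(h) %% 2L != 0L) stop("haplotype count must be even")
    ids <- panel@sampleOf$sample_id
    odd <- seq(1L, nrow(h), by = 2L)
    if (!all(ids[odd] == ids[odd + 1L]))
        stop("the two phases of each sample must be adjacent rows")
    d <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
    rownames(d) <- ids[odd]
    GenotypeMatrix(d, panel@variants)
}

#' Simulate a case/control phenotype on the liability scale
#'
#' Per-variant effect classes are drawn from `mixture_proportions`; effects
#' from `N(0, gamma_k * sigma2_g)`.  The genetic value (centred genotypes
#' times effects) is rescaled so its realized variance equals
#' `heritability_liability`, environmental noise `N(0, 1 - h2)` and any
#' covariate shift are added, and the top `prevalence` fraction of realized
#' liabilities becomes cases (empirical threshold, so case counts are
#' exact).
#'
#' @param g A complete (no missing) [GenotypeMatrix-class].
#' @param cfg A [simulationConfig()].
#' @param truth Optional truth list from [simulateHaplotypePanel()] (adds
#'   subpopulation covariate effects and is extended in place).
#' @return List with `phenotypes` (`data.frame(sample_id, status)`) and
#'   `truth` (adds per-variant `class`/`effect`, per-sample `liability` and
#'   `status`).
#' @export
simulatePhenotype <- function(g, cfg, truth = NULL) {
    stopifnot(is(g, "GenotypeMatrix"), inherits(cfg, "SimulationConfig"))
    if (cfg$prevalence <= 0 || cfg$prevalence >= 1)
        stop("prevalence must lie strictly inside (0, 1)")
    if (anyNA(g@dosages)) stop("genotypes must be complete")
    set.seed(.stageSeed(cfg$seed, 2L))
    n <- nSamples(g); m <- nVariants(g)
    h2 <- cfg$heritability_liability
    cls <- sample.int(4L, m, replace = TRUE, prob = cfg$mixture_proportions)
    planted <- integer(0)
    if (cfg$n_planted_top > 0L) {
        planted <- unique(round(seq(1L, m, length.out = cfg$n_planted_top)))
        cls[planted] <- 4L
    }
    gamma <- cfg$variance_coefficients
    beta <- stats::rnorm(m, 0, sqrt(gamma[cls]))
    ## planted variants carry effects AT the top-class scale (fixed
    ## magnitude, random sign): a draw near zero would plant nothing
    if (length(planted))
        beta[planted] <- sqrt(gamma[4]) *
            sign(stats::rnorm(length(planted)))
    X <- g@dosages
    storage.mode(X) <- "double"
    Xc <- scale(X, center = TRUE, scale = FALSE)
    gval <- drop(Xc %*% beta)
    vg <- stats::var(gval)
    if (h2 > 0 && vg > 0) {
        sc <- sqrt(h2 / vg)
        gval <- gval * sc; beta <- beta * sc
    } else {
        gval <- rep(0, n); beta <- rep(0, m)
    }
    covTerm <- rep(0, n)
    subEff <- unname(cfg$covariate_effects["subpop"])
    if (!is.null(truth) && !is.null(truth$samples$subpop) &&
        isTRUE(!is.na(subEff) && subEff != 0)) {
        z <- truth$samples$subpop == 2L
        covTerm <- subEff * (z - mean(z))
    }
    liab <- gval + covTerm + stats::rnorm(n, 0, sqrt(max(1 - h2, 1e-8)))
    ncase <- round(n * cfg$prevalence)
    status <- integer(n)
    status[order(liab, decreasing = TRUE)[seq_len(ncase)]] <- 1L
    ph <- data.frame(sample_id = sampleIDs(g), status = status,
                     stringsAsFactors = FALSE)
    if (is.null(truth)) truth <- list(config = cfg)
    if (is.null(truth$samples))
        truth$samples <- data.frame(sample_id = sampleIDs(g))
    truth$samples$liability <- liab
    truth$samples$status <- status
    truth$variants <- data.frame(
        index = seq_len(m), variant_id = g@variants$variant_id,
        class = cls, effect = beta, stringsAsFactors = FALSE)
    truth$causal <- which(beta != 0)
    list(phenotypes = ph, truth = truth)
}

#' Inject a localized selective sweep into one phenotype group
#'
#' Within the target group, haplotypes over the span
#' `[core - flank, core + flank]` are overwritten with copies of a donor
#' haplotype (the group's most frequent span sequence) until the donor
#' frequency in the group reaches `carrier_target_frequency`.  Haplotypes
#' outside the span, and all haplotypes of the other group, are untouched.
#' This creates the long-shared-haplotype signal a cross-population EHH
#' scan detects, without forward simulation.
#'
#' With `decay = "exponential"` (the default) each recipient's copied
#' extent on each side of the core is drawn from an exponential with mean
#' `flank/2`, truncated at `flank`: haplotype sharing then decays with
#' distance from the core, the way recombination erodes a real sweep, and
#' the homozygosity signal peaks at the selected site.  `decay = "none"`
#' copies the full span into every recipient, giving an idealized
#' flat-topped sweep (useful for exact-value tests: at target frequency 1
#' the group is monomorphic over the span).
#'
#' @param panel A [HaplotypePanel-class].
#' @param truth Truth list carrying per-sample `status` (from
#'   [simulatePhenotype()]); required when `sweep$group != "none"`.
#' @param cfg A [simulationConfig()] whose `sweep` block is applied.
#' @return List with modified `panel` and `truth` (adds `truth$sweep`).
#' @export
injectSweep <- function(panel, truth, cfg) {
    stopifnot(is(panel, "HaplotypePanel"), inherits(cfg, "SimulationConfig"))
    sw <- cfg$sweep
    if (sw$group == "none") return(list(panel = panel, truth = truth))
    if (is.null(truth$samples$status))
        stop("sweep targets a phenotype group; simulate phenotypes first")
    set.seed(.stageSeed(cfg$seed, 3L))
    v <- panel@variants
    core <- as.integer(sw$core_index)
    span <- which(v$chromosome == v$chromosome[core] &
                  abs(v$position_bp - v$position_bp[core]) <= sw$flank_length_bp)
    want <- if (sw$group == "cases") 1L else 0L
    st <- truth$samples$status[match(panel@sampleOf$sample_id,
                                     truth$samples$sample_id)]
    rows <- which(st == want)
    h <- panel@haplotypes
    key <- apply(h[rows, span, drop = FALSE], 1L, paste, collapse = "")
    tab <- sort(table(key), decreasing = TRUE)
    donorKey <- names(tab)[1]
    carriers <- key == donorKey
    f0 <- mean(carriers)
    if (sw$carrier_target_frequency < f0)
        stop(sprintf("target frequency %.3f below current donor frequency %.3f",
                     sw$carrier_target_frequency, f0))
    needed <- ceiling(sw$carrier_target_frequency * length(rows)) - sum(carriers)
    if (needed > 0L) {
        donorRow <- rows[which(carriers)[1]]
        recipients <- sample(rows[!carriers], needed)
        decay <- if (is.null(sw$decay)) "exponential" else sw$decay
        corePos <- v$position_bp[core]
        for (r in recipients) {
            if (decay == "none") {
                h[r, span] <- h[donorRow, span]
            } else {
                ext <- pmin(stats::rexp(2, rate = 2 / sw$flank_length_bp),
                            sw$flank_length_bp)
                sub <- span[v$position_bp[span] >= corePos - ext[1] &
                            v$position_bp[span] <= corePos + ext[2]]
                h[r, sub] <- h[donorRow, sub]
            }
        }
    }
    panel@haplotypes <- h
    truth$sweep <- list(core_index = core,
                        core_id = v$variant_id[core],
                        core_bp = v$position_bp[core],
                        span = range(span), group = sw$group,
                        target_frequency = sw$carrier_target_frequency)
    list(panel = panel, truth = truth)
}

#' Simulate a full cohort
#'
#' Convenience wrapper running [simulateHaplotypePanel()],
#' [pairToGenotypes()], [simulatePhenotype()] and (when configured)
#' [injectSweep()], re-deriving genotypes after the sweep.
#'
#' @param cfg A [simulationConfig()].
#' @return List with `panel`, `genotypes`, `phenotypes`, `truth`.
#' @export
simulateCohort <- function(cfg) {
    sim <- simulateHaplotypePanel(cfg)
    geno <- pairToGenotypes(sim$panel)
    ph <- simulatePhenotype(geno, cfg, sim$truth)
    out <- list(panel = sim$panel, genotypes = geno,
                phenotypes = ph$phenotypes, truth = ph$truth)
    if (cfg$sweep$group != "none") {
        swept <- injectSweep(sim$panel, ph$truth, cfg)
        out$panel <- swept$panel
        out$truth <- swept$truth
        out$genotypes <- pairToGenotypes(swept$panel)
    }
    out
}

#' Write a simulated cohort to disk
#'
#' Emits PLINK binary genotypes, the haplotype table, a phenotype TSV and a
#' ground-truth TSV under a common prefix.
#'
#' @param cohort Result of [simulateCohort()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
writeCohort <- function(cohort, prefix) {
    writeGenotypes(cohort$genotypes, prefix, "plink_binary")
    writeGenotypes(cohort$panel, prefix, "haplotype_table")
    utils::write.table(cohort$phenotypes, paste0(prefix, ".pheno.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cohort$truth$variants, paste0(prefix, ".truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(prefix)
}
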