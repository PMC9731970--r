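test_that("EHH hand cases: identical, 2/2 split, all distinct", {
    ## 4 carrier haplotypes of allele 1 at core (column 3)
    identicalP <- toyPanel(c("11111", "11111", "11111", "11111",
                             "00000", "00000"))
    cu <- ehhCurve(identicalP, 3, focal = 1)
    expect_true(all(cu$ehh == 1))
    expect_identical(length(cu$ehh), 5L)

    ## carriers split 2/2 at the first flanking marker:
    ## EHH = (2*1 + 2*1) / (4*3) = 1/3
    split22 <- toyPanel(c("00100", "00100", "00110", "00110",
                          "00000", "00000"))
    cu2 <- ehhCurve(split22, 3, focal = 1)
    right1 <- cu2$ehh[cu2$index == 4]
    expect_equal(right1, 1 / 3)

    ## all carriers distinct at the flanking marker -> EHH 0, extension stops
    distinctP <- toyPanel(c("010", "111", "000", "000"))
    cu3 <- ehhCurve(distinctP, 2, focal = 1)
    expect_equal(cu3$ehh[cu3$index == 3], 0)
    expect_identical(cu3$stop_right, "cutoff")
})

test_that("EHH matches brute-force enumeration on random small panels", {
    set.seed(77)
    for (rep in 1:120) {
        nh <- sample(4:12, 1)
        m <- sample(5:20, 1)
        h <- matrix(rbinom(nh * m, 1, runif(1, 0.25, 0.75)), nh, m)
        if (nrow(h) %% 2L) h <- rbind(h, h[1, ])
        panel <- HaplotypePanel(h, toyMap(ncol(h)))
        core <- sample(m, 1)
        ## site-level
        o <- ehhOracle(haplotypes(panel), NULL, core, allele = NULL)
        if (!is.null(o)) {
            cu <- ehhCurve(panel, core, focal = "site")
            expect_identical(cu$index, o$index)
            expect_equal(cu$ehh, o$ehh)
        }
        ## allele-specific, when >= 2 carriers and polymorphic
        carr <- sum(haplotypes(panel)[, core] == 1)
        if (carr >= 2 && carr < nrow(haplotypes(panel))) {
            oa <- ehhOracle(haplotypes(panel), NULL, core, allele = 1)
            cua <- ehhCurve(panel, core, focal = 1)
            expect_identical(cua$index, oa$index)
            expect_equal(cua$ehh, oa$ehh)
        }
    }
})

test_that("EHH is non-increasing away from the core in both modes", {
    set.seed(42)
    for (rep in 1:20) {
        panel <- randomPanel(20, 30, seed = 1000 + rep)
        core <- 15
        for (mode in list("site", 1)) {
            if (!identical(mode, "site")) {
                carr <- sum(haplotypes(panel)[, core] == 1)
                if (carr < 2 || carr == nrow(haplotypes(panel))) next
            }
            cu <- ehhCurve(panel, core, focal = mode, cutoff = 0)
            ci <- which(cu$index == core)
            left <- cu$ehh[seq_len(ci)]
            right <- cu$ehh[ci:length(cu$ehh)]
            expect_true(all(diff(left) >= -1e-12))
            expect_true(all(diff(right) <= 1e-12))
        }
    }
})

test_that("monomorphic cores are rejected in allele-specific mode", {
    p <- toyPanel(c("111", "111", "111", "111"))
    expect_error(ehhCurve(p, 2, focal = 1), "monomorphic")
})

test_that("iHH integrates the curve with the below-cutoff-to-zero rule", {
    mkCurve <- function(pos, ehh, cutoff = 0.05)
        structure(list(core_id = "c", core_bp = pos[1], focal = "site",
                       index = seq_along(pos), position_bp = pos, ehh = ehh,
                       n_hap = 10, cutoff = cutoff,
                       stop_left = "cutoff", stop_right = "cutoff"),
                  class = "EHHCurve")
    ## EHH = 1 over +/- 5 kb then 0 -> rectangle of 10,000 bp
    cu <- mkCurve(c(-5000, 0, 5000) + 10000, c(1, 1, 1))
    expect_equal(as.numeric(integrateIHH(cu)), 10000)
    ## one-sided (0,1), (1000,0.5), (2000,0.04): 750 + 250 = 1000
    cu2 <- mkCurve(c(0, 1000, 2000), c(1, 0.5, 0.04))
    expect_equal(as.numeric(integrateIHH(cu2)), 1000)
    ## doubling distances doubles iHH
    cu3 <- mkCurve(c(0, 2000, 4000), c(1, 0.5, 0.04))
    expect_equal(as.numeric(integrateIHH(cu3)), 2000)
    ## empty support -> 0 with flag
    cu4 <- mkCurve(numeric(0), numeric(0))
    v <- integrateIHH(cu4)
    expect_identical(as.numeric(v), 0)
    expect_true(attr(v, "degenerate"))
})

test_that("scan-level iHH equals integrating the site-level curve", {
    panel <- randomPanel(30, 40, seed = 5)
    ihh <- breedscan:::.site_ihh_all(haplotypes(panel),
                                     as.numeric(variantMapOf(panel)$position_bp),
                                     0.05, -1)
    for (j in c(1, 10, 20, 40)) {
        cu <- ehhCurve(panel, j, focal = "site")
        expect_equal(ihh$ihh[j], as.numeric(integrateIHH(cu)))
    }
})

test_that("identical panels make XP-EHH standardization fail loudly", {
    panel <- randomPanel(20, 50, seed = 6)
    expect_error(xpehhScan(panel, panel), "zero variance")
})

test_that("swapping the panels negates every raw score exactly", {
    cfg <- simulationConfig(n_samples = 60, m_variants = 400, seed = 51)
    co <- simulateCohort(cfg)
    sp <- splitPanelByStatus(co$panel, co$phenotypes)
    ab <- xpehhScan(sp$case, sp$control)
    ba <- xpehhScan(sp$control, sp$case)
    expect_identical(ab$raw, -ba$raw)
})

test_that("the logp column is the two-sided normal transform of the score", {
    cfg <- simulationConfig(n_samples = 60, m_variants = 300, seed = 52)
    co <- simulateCohort(cfg)
    sp <- splitPanelByStatus(co$panel, co$phenotypes)
    sc <- xpehhScan(sp$case, sp$control)
    ## invert 2*Phi(-z) = 1e-4 numerically: z* ~ 3.8906
    zstar <- uniroot(function(z) 2 * pnorm(-z) - 1e-4, c(3, 5),
                     tol = 1e-10)$root
    expect_equal(zstar, 3.8906, tolerance = 1e-4)
    expect_identical(sc$logp >= 4, abs(sc$score) >= zstar)
    expect_equal(mean(sc$score), 0, tolerance = 1e-12)
    expect_equal(var(sc$score), 1, tolerance = 1e-12)
})

test_that("exchangeable panels give calibrated, roughly normal scores", {
    stats <- vapply(1:10, function(s) {
        cfg <- simulationConfig(n_samples = 250, m_variants = 1500,
                                seed = 600 + s)
        co <- simulateCohort(cfg)
        ## random half-split of samples: exchangeable populations
        set.seed(s)
        ids <- sampleIDs(co$genotypes)
        grp <- sample(rep(0:1, length.out = length(ids)))
        ph <- data.frame(sample_id = ids, status = grp)
        sp <- splitPanelByStatus(co$panel, ph)
        sc <- xpehhScan(sp$case, sp$control)
        c(frac = mean(sc$logp >= 4), skew = mean(sc$score^3))
    }, numeric(2))
    expect_lt(mean(stats["frac", ]), 1e-3)
    expect_lt(abs(mean(stats["skew", ])), 0.3)
})

test_that("windowed region calling matches hand enumeration", {
    mkScores <- function(pos, logp) {
        data.frame(variant_id = sprintf("v%04d", seq_along(pos)),
                   chromosome = "1", position_bp = pos,
                   raw = 0, score = logp, logp = logp)
    }
    ## 3 extreme variants within 200 kb -> one region containing all 3
    pos <- c(seq(1e5, 3e6, by = 1e5))
    lp <- rep(0.5, length(pos))
    lp[pos %in% c(1e6, 1.1e6, 1.2e6)] <- 5
    r <- callCandidateRegions(mkScores(pos, lp))
    expect_identical(nrow(r), 1L)
    expect_identical(r$n_extreme, 3L)
    ## hand enumeration: qualifying starts 200000..1100000, merged
    expect_identical(r$start_bp, 2e5)
    expect_identical(r$end_bp, 2.1e6)

    ## a single isolated extreme variant -> no region
    lp2 <- rep(0.5, length(pos)); lp2[pos == 1e6] <- 5
    expect_identical(nrow(callCandidateRegions(mkScores(pos, lp2))), 0L)

    ## two clusters 5 Mb apart -> two disjoint grid-aligned regions
    pos3 <- seq(5e4, 8e6, by = 5e4)
    lp3 <- rep(0.5, length(pos3))
    lp3[pos3 %in% c(1e6, 1.05e6)] <- 5
    lp3[pos3 %in% c(6e6, 6.05e6)] <- 5
    r3 <- callCandidateRegions(mkScores(pos3, lp3))
    expect_identical(nrow(r3), 2L)
    expect_identical(r3$start_bp, c(1e5, 5.1e6))
    expect_identical(r3$end_bp, c(2e6, 7e6))
    expect_true(all(r3$start_bp %% 1e5 == 0))
})

test_that("an injected case sweep is detected at and around its core", {
    hits <- vapply(1:5, function(s) {
        cfg <- simulationConfig(n_samples = 300, m_variants = 3000,
                                seed = 700 + s,
                                sweep = list(group = "cases",
                                             core_index = 1500,
                                             carrier_target_frequency = 0.8,
                                             flank_length_bp = 100000,
                                             decay = "exponential"))
        co <- simulateCohort(cfg)
        sp <- splitPanelByStatus(co$panel, co$phenotypes)
        sc <- xpehhScan(sp$case, sp$control)
        top <- sc[which.max(abs(sc$score)), ]
        (abs(top$position_bp - co$truth$sweep$core_bp) <= 1e5) &&
            (top$score > 0)
    }, logical(1))
    expect_gte(sum(hits), 4)
})
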