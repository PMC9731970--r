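test_that("PLINK text round-trips dosages and alleles", {
    d <- matrix(c(0L, 1L, 2L,
                  2L, NA, 0L), nrow = 3)
    g <- toyGenotypes(d, samples = c("d1", "d2", "d3"))
    pre <- file.path(tempdir(), "pedrt")
    writeGenotypes(g, pre, "plink_text")
    g2 <- readGenotypes(pre, "plink_text")
    expect_identical(dosages(g2), dosages(g))
    expect_identical(variantMapOf(g2)$allele2, c("C", "C"))
    expect_identical(sampleIDs(g2), c("d1", "d2", "d3"))
})

test_that("PLINK binary encodes the v1 2-bit codes", {
    ## hand-encoded .bed: 4 samples, 1 variant with genotypes
    ## hom-ref(00), het(10), hom-alt(11), missing(01)
    ## byte (sample1 in lowest bits): 01 11 10 00 -> 0x78
    pre <- file.path(tempdir(), "handbed")
    writeLines("1\tsnp1\t0\t100\tA\tC", paste0(pre, ".bim"))
    writeLines(sprintf("s%d\ts%d\t0\t0\t0\t-9", 1:4, 1:4), paste0(pre, ".fam"))
    con <- file(paste0(pre, ".bed"), "wb")
    writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x78)), con)
    close(con)
    g <- readGenotypes(pre, "plink_binary")
    expect_identical(unname(dosages(g)[, 1]), c(0L, 1L, 2L, NA))

    ## and the writer emits the same byte back
    writeGenotypes(g, paste0(pre, "w"), "plink_binary")
    expect_identical(readBin(paste0(pre, "w.bed"), "raw", 10),
                     as.raw(c(0x6c, 0x1b, 0x01, 0x78)))
})

test_that("PLINK binary payload size follows ceil(n/4) x m and round-trips", {
    set.seed(42)
    d <- matrix(sample(c(0L, 1L, 2L, NA), 12, replace = TRUE), 4, 3)
    g <- toyGenotypes(d)
    pre <- file.path(tempdir(), "bedrt")
    writeGenotypes(g, pre, "plink_binary")
    expect_identical(file.size(paste0(pre, ".bed")),
                     3 + ceiling(4 / 4) * 3)
    g2 <- readGenotypes(pre, "plink_binary")
    expect_identical(dosages(g2), dosages(g))
    expect_identical(variantMapOf(g2), variantMapOf(g))
})

test_that("text and binary readers agree on the same cohort", {
    set.seed(7)
    d <- matrix(sample(c(0L, 1L, 2L, NA), 60, replace = TRUE,
                       prob = c(.4, .3, .2, .1)), 10, 6)
    g <- toyGenotypes(d)
    pre <- file.path(tempdir(), "agree")
    writeGenotypes(g, pre, "plink_text")
    writeGenotypes(g, pre, "plink_binary")
    expect_identical(dosages(readGenotypes(pre, "plink_text")),
                     dosages(readGenotypes(pre, "plink_binary")))
})

test_that("haplotype table: phased pairs collapse to dosages and round-trip", {
    p <- toyPanel(c("0101", "1100"))  # one sample
    expect_identical(unname(dosages(pairToGenotypes(p))[1, ]),
                     c(1L, 2L, 0L, 1L))
    pre <- file.path(tempdir(), "haprt")
    writeGenotypes(p, pre, "haplotype_table")
    p2 <- readGenotypes(pre, "haplotype_table")
    expect_identical(haplotypes(p2), haplotypes(p))
    expect_identical(variantMapOf(p2), variantMapOf(p))
})

test_that("empty cohort writes valid headers with zero records", {
    g <- GenotypeMatrix(matrix(integer(), 0, 3), toyMap(3))
    pre <- file.path(tempdir(), "empty")
    writeGenotypes(g, pre, "plink_binary")
    expect_identical(readBin(paste0(pre, ".bed"), "raw", 3),
                     as.raw(c(0x6c, 0x1b, 0x01)))
    g2 <- readGenotypes(pre, "plink_binary")
    expect_identical(dim(g2), c(0L, 3L))
})

test_that("malformed .bed magic and dimension mismatches are rejected", {
    pre <- file.path(tempdir(), "badbed")
    writeLines("1\tsnp1\t0\t100\tA\tC", paste0(pre, ".bim"))
    writeLines("s1\ts1\t0\t0\t0\t-9", paste0(pre, ".fam"))
    con <- file(paste0(pre, ".bed"), "wb")
    writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x00)), con)
    close(con)
    expect_error(readGenotypes(pre, "plink_binary"), "magic")
    con <- file(paste0(pre, ".bed"), "wb")
    writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00, 0x00)), con)  # 2 payload bytes
    close(con)
    expect_error(readGenotypes(pre, "plink_binary"), "payload")
})

test_that("non-biallelic .ped variants fail descriptively", {
    pre <- file.path(tempdir(), "tri")
    writeLines("1\tsnp1\t0\t100", paste0(pre, ".map"))
    writeLines(c("f1\ts1\t0\t0\t0\t-9\tA\tC",
                 "f2\ts2\t0\t0\t0\t-9\tA\tG"), paste0(pre, ".ped"))
    expect_error(readGenotypes(pre, "plink_text"), "biallelic")
})

test_that("qcFilter applies variant, sample, then recomputed MAF rules", {
    ## one variant missing in 10% of samples at threshold 0.05 -> removed
    d <- matrix(1L, 10, 2)
    d[1, 1] <- NA
    d[, 2] <- rep(c(0L, 1L), 5)
    g <- toyGenotypes(d)
    res <- qcFilter(g, max_variant_missing = 0.05, max_sample_missing = 1,
                    min_maf = 0)
    expect_identical(variantMapOf(res$genotypes)$variant_id, "v002")
    expect_identical(res$removed$reason, "missingness")

    ## monomorphic variant at min_maf 0.05 -> removed
    d2 <- cbind(rep(0L, 10), rep(c(0L, 1L, 2L, 1L, 0L), 2))
    res2 <- qcFilter(toyGenotypes(d2), 1, 1, min_maf = 0.05)
    expect_identical(variantMapOf(res2$genotypes)$variant_id, "v002")
    expect_true(any(res2$removed$reason == "maf"))
})

test_that("qcFilter matches an independent recount on a crafted 6x5 matrix", {
    d <- rbind(c(0L, 1L, NA, 2L, 0L),
               c(NA, NA, NA, 1L, 0L),   # sample 50% missing after v-filter
               c(1L, 1L, 0L, 1L, 0L),
               c(2L, 0L, NA, 0L, 0L),
               c(0L, 1L, 0L, 2L, 0L),
               c(1L, 2L, 0L, 1L, 0L))
    g <- toyGenotypes(d, samples = paste0("s", 1:6))
    res <- qcFilter(g, 0.4, 0.4, 0.05)
    ## independent recount: v3 missing in 3/6 > 0.4 -> drop; then s2 missing
    ## 2/4 > 0.4 -> drop; then MAF on remaining 5 samples: v5 monomorphic
    keepV <- colMeans(is.na(d)) <= 0.4
    d1 <- d[, keepV]
    keepS <- rowMeans(is.na(d1)) <= 0.4
    d2 <- d1[keepS, ]
    fr <- colMeans(d2, na.rm = TRUE) / 2
    keepM <- pmin(fr, 1 - fr) >= 0.05
    expect_identical(dosages(res$genotypes),
                     dosages(g)[keepS, keepV, drop = FALSE][, keepM,
                                                           drop = FALSE])
    expect_setequal(res$removed$id[res$removed$type == "sample"], "s2")
})

test_that("qcFilter is idempotent", {
    set.seed(5)
    d <- matrix(sample(c(0L, 1L, 2L, NA), 200, replace = TRUE,
                       prob = c(.45, .25, .2, .1)), 20, 10)
    g <- toyGenotypes(d)
    r1 <- qcFilter(g, 0.2, 0.2, 0.1)
    r2 <- qcFilter(r1$genotypes, 0.2, 0.2, 0.1)
    expect_identical(dosages(r2$genotypes), dosages(r1$genotypes))
    expect_identical(nrow(r2$removed), 0L)
})

test_that("alleleStats counts alleles over non-missing denominators", {
    g <- toyGenotypes(matrix(c(2L, 2L, 2L,
                               0L, 1L, 1L,
                               0L, 1L, NA), nrow = 3, byrow = FALSE))
    grp <- factor(rep("all", 3))
    f <- alleleStats(g, grp)
    expect_equal(unname(f[1, "all"]), 1.0)          # all hom allele2
    expect_equal(unname(f[3, "all"]), 1 / 4)        # (0,1,NA) -> 1 of 4
    g5 <- toyGenotypes(matrix(c(0L, 1L, 1L, 2L, 2L), ncol = 1))
    expect_equal(unname(alleleStats(g5, rep("g", 5))[1, 1]), 0.6)  # 6/10
})

test_that("group frequencies pooled with group weights give the overall frequency", {
    set.seed(9)
    d <- matrix(sample(c(0L, 1L, 2L, NA), 300, replace = TRUE), 30, 10)
    g <- toyGenotypes(d)
    grp <- factor(rep(c("a", "b"), 15))
    f <- alleleStats(g, grp)
    expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
    na <- colSums(!is.na(d[grp == "a", ]))
    nb <- colSums(!is.na(d[grp == "b", ]))
    pooled <- (f[, "a"] * na + f[, "b"] * nb) / (na + nb)
    overall <- alleleStats(g, rep("all", 30))[, 1]
    expect_equal(unname(pooled), unname(overall))
})

test_that("PC1 separates two diverged subpopulations", {
    cfg <- simulationConfig(n_samples = 80, m_variants = 400,
                            subpop_fraction = 0.5, subpop_divergence = 0.3,
                            seed = 21)
    sim <- simulateHaplotypePanel(cfg)
    g <- pairToGenotypes(sim$panel)
    pcs <- pcaCovariates(g, 2)
    p1 <- pcs[sim$truth$samples$subpop == 1L, 1]
    p2 <- pcs[sim$truth$samples$subpop == 2L, 1]
    expect_true(max(range(p1)[1], range(p2)[1]) >
                min(range(p1)[2], range(p2)[2]) ||
                min(p1) > max(p2) || min(p2) > max(p1))
    expect_true(min(p1) > max(p2) || min(p2) > max(p1))  # zero overlap
})

test_that("pcaCovariates is symmetric for duplicated samples and honours k", {
    set.seed(3)
    d <- matrix(sample(0:2, 60, replace = TRUE), 10, 6)
    g <- toyGenotypes(rbind(d, d),
                      samples = paste0("s", 1:20))
    pcs <- pcaCovariates(g, 3)
    expect_equal(pcs[1:10, ], pcs[11:20, ], ignore_attr = TRUE)
    expect_identical(ncol(pcaCovariates(g, 0)), 0L)
    expect_error(pcaCovariates(toyGenotypes(d), 11), "rank")
})

test_that("phenotype reader validates status and sample coverage", {
    f <- file.path(tempdir(), "ph.tsv")
    writeLines(c("sample_id\tstatus\tPC1", "s1\t1\t0.2", "s2\t0\t-0.1"), f)
    ph <- readPhenotypes(f)
    expect_identical(ph$status, c(1L, 0L))
    g <- toyGenotypes(matrix(0L, 1, 2), samples = "s1")
    expect_error(readPhenotypes(f, g), "absent")
    writeLines(c("sample_id\tstatus", "s1\t2"), f)
    expect_error(readPhenotypes(f), "status")
})
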