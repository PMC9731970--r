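fakeResult <- function(effects, positions = NULL, chr = NULL) {
    m <- length(effects)
    if (is.null(positions)) positions <- 1000L * seq_len(m)
    if (is.null(chr)) chr <- rep("1", m)
    g <- GenotypeMatrix(matrix(0L, 2, m,
                               dimnames = list(c("s1", "s2"), NULL)),
                        variantMap(sprintf("v%03d", seq_len(m)), chr,
                                   positions, rep("A", m), rep("C", m)))
    summarizeChains(list(list(beta_mean = effects,
                              class_prob = cbind(1, 0, 0, 0)[rep(1, m), ],
                              pi_mean = c(1, 0, 0, 0),
                              alpha_mean = c(intercept = 0),
                              varG_mean = 0, varE_mean = 1,
                              varG_trace = 1, n_kept = 1L)), g)
}

test_that("effect-variant calling applies a strict >= threshold", {
    r <- fakeResult(c(0.000104, 0.00009999, -0.000104, 2e-4, 0))
    ev <- callEffectVariants(r, threshold = 1e-4)
    expect_setequal(ev$variant_id, c("v001", "v003", "v004"))
    expect_false("v002" %in% ev$variant_id)  # 0.00009999 excluded
    expect_identical(ev$variant_id[1], "v004")  # sorted by |effect| desc
})

test_that("top_n mode returns exactly n with genomic-order tie break", {
    set.seed(1)
    eff <- rep(c(5e-4, 1e-4), each = 30)  # 60 variants, massive ties
    r <- fakeResult(eff)
    ev <- callEffectVariants(r, top_n = 50)
    expect_identical(nrow(ev), 50L)
    ## ties at 1e-4 resolved by position: the first 20 of the second block
    tied <- ev$variant_id[ev$mean_abs_effect == 1e-4]
    expect_identical(tied, sprintf("v%03d", 31:50))
})

test_that("locus merging uses a strict 1 Mb single-linkage rule", {
    g2 <- function(positions, chr = rep("1", length(positions))) {
        GenotypeMatrix(matrix(rep(c(0L, 1L, 2L, 1L), length(positions)), 4,
                              dimnames = list(paste0("s", 1:4), NULL)),
                       variantMap(sprintf("v%03d", seq_along(positions)),
                                  chr, positions,
                                  rep("A", length(positions)),
                                  rep("C", length(positions))))
    }
    ph <- data.frame(sample_id = paste0("s", 1:4), status = c(1, 1, 0, 0))
    ev <- data.frame(variant_id = c("v001", "v002"), chromosome = "1",
                     position_bp = c(1e6, 1.9e6),
                     mean_effect = c(2e-4, 1e-4),
                     mean_abs_effect = c(2e-4, 1e-4))
    one <- mergeIntoLoci(ev, g2(c(1e6, 1.9e6)), ph)    # 900 kb apart
    expect_identical(nrow(one), 1L)
    expect_identical(one$n_variants, 2L)
    ev$position_bp <- c(1e6, 2e6)                      # exactly 1 Mb apart
    two <- mergeIntoLoci(ev, g2(c(1e6, 2e6)), ph)
    expect_identical(nrow(two), 2L)
})

test_that("planted clusters are recovered with correct member counts", {
    ## 11 clusters of 3 variants (10 kb apart), clusters separated by 5 Mb
    positions <- as.integer(outer(c(0, 1e4, 2e4), (1:11) * 5e6, `+`))
    m <- length(positions)
    eff <- rep(1e-4 * (1:3), 11)
    r <- fakeResult(eff, positions = sort(positions))
    ev <- callEffectVariants(r, threshold = 1e-4)
    set.seed(2)
    g <- GenotypeMatrix(matrix(sample(0:2, 6 * m, TRUE), 6, m,
                               dimnames = list(paste0("s", 1:6), NULL)),
                        variantMap(sprintf("v%03d", seq_len(m)), rep("1", m),
                                   sort(positions), rep("A", m), rep("C", m)))
    ph <- data.frame(sample_id = paste0("s", 1:6), status = rep(c(1, 0), 3))
    loci <- mergeIntoLoci(ev, g, ph)
    expect_identical(nrow(loci), 11L)
    expect_true(all(loci$n_variants == 3L))
    ## invariance to input ordering
    loci2 <- mergeIntoLoci(ev[sample(nrow(ev)), ], g, ph)
    expect_identical(loci[, c("locus_id", "top_variant", "n_variants")],
                     loci2[, c("locus_id", "top_variant", "n_variants")])
})

test_that("risk index sums locus weights and count is exactly twice half", {
    m <- 11
    vm <- variantMap(sprintf("v%03d", 1:m), rep("1", m), (1:m) * 2e6,
                     rep("A", m), rep("C", m))
    loci <- data.frame(top_variant = sprintf("v%03d", 1:m),
                       risk_allele = rep("C", m))
    hom_risk <- GenotypeMatrix(matrix(2L, 1, m, dimnames = list("s1", NULL)), vm)
    hom_non <- GenotypeMatrix(matrix(0L, 1, m, dimnames = list("s1", NULL)), vm)
    expect_identical(computeRiskIndex(hom_non, loci, "half")$index, 0)
    expect_identical(computeRiskIndex(hom_risk, loci, "half")$index, 11)
    expect_identical(computeRiskIndex(hom_risk, loci, "count")$index, 22)

    ## het at 3 of 5 loci, hom-risk at 2: half scheme gives 3*0.5 + 2*1
    vm5 <- variantMap(sprintf("v%03d", 1:5), rep("1", 5), (1:5) * 2e6,
                      rep("A", 5), rep("C", 5))
    loci5 <- data.frame(top_variant = sprintf("v%03d", 1:5),
                        risk_allele = rep("C", 5))
    g5 <- GenotypeMatrix(matrix(c(1L, 1L, 1L, 2L, 2L), 1,
                                dimnames = list("s1", NULL)), vm5)
    expect_identical(computeRiskIndex(g5, loci5, "half")$index, 3.5)

    ## risk allele on the allele1 side flips the dosage
    lociA <- data.frame(top_variant = sprintf("v%03d", 1:m),
                        risk_allele = rep("A", m))
    expect_identical(computeRiskIndex(hom_non, lociA, "count")$index, 22)

    set.seed(3)
    grand <- GenotypeMatrix(matrix(sample(0:2, 8 * m, TRUE), 8, m,
                                   dimnames = list(paste0("s", 1:8), NULL)), vm)
    expect_equal(computeRiskIndex(grand, loci, "count")$index,
                 2 * computeRiskIndex(grand, loci, "half")$index)
})

test_that("variance explained is 100% for the response itself and ~0 for noise", {
    set.seed(4)
    y <- rnorm(50)
    ve <- varianceExplained(y, y)
    expect_equal(ve$pct_variance[ve$term == "predictor"], 100, tolerance = 1e-8)
    y2 <- rnorm(10000)
    x2 <- rnorm(10000)
    ve2 <- varianceExplained(y2, x2)
    expect_lt(ve2$pct_variance[ve2$term == "predictor"], 0.1)
})

test_that("known variance shares are recovered and type-I shares sum to 100", {
    set.seed(5)
    n <- 5000
    x1 <- rnorm(n, 0, sqrt(0.3))
    x2 <- rnorm(n, 0, sqrt(0.2))
    y <- x1 + x2 + rnorm(n, 0, sqrt(0.5))
    ve <- varianceExplained(y, data.frame(x1 = x1, x2 = x2))
    expect_equal(ve$pct_variance[ve$term == "x1"], 30, tolerance = 2)
    expect_equal(ve$pct_variance[ve$term == "x2"], 20, tolerance = 2)
    expect_equal(sum(ve$pct_variance), 100, tolerance = 1e-8)
})

test_that("collinear predictors are flagged with zero df", {
    set.seed(6)
    x <- rnorm(40)
    y <- x + rnorm(40, 0, 0.1)
    ve <- varianceExplained(y, data.frame(a = x, b = 2 * x))
    expect_true(ve$aliased[ve$term == "b"])
    expect_identical(ve$df[ve$term == "b"], 0)
    expect_equal(sum(ve$pct_variance), 100, tolerance = 1e-8)
})

test_that("covariates are entered before predictors in the decomposition", {
    set.seed(7)
    n <- 2000
    z <- rnorm(n)
    y <- z + rnorm(n)
    ## predictor correlated with covariate: entering z first absorbs the share
    ve <- varianceExplained(y, data.frame(p = z + rnorm(n, 0, 0.1)),
                            covariates = data.frame(z = z))
    expect_gt(ve$pct_variance[ve$term == "cov_z"], 40)
    expect_lt(ve$pct_variance[ve$term == "p"], 5)
})
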