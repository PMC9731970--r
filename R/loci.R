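## Locus calling from per-variant posterior effects, the per-individual risk
## index, and ANOVA variance-explained summaries.

#' Call effect variants from a mixture-model GWAS result
#'
#' Either every variant whose posterior mean absolute effect is `>=
#' threshold` (strict `>=` on the stated bound), or the `top_n` variants by
#' `mean_abs_effect`.  Results are sorted by `|effect|` descending, ties
#' broken by genomic order.
#'
#' @param result A [BayesRResult-class].
#' @param threshold Effect-size bound; the conventional reporting cutoff is
#'   `1e-4`.
#' @param top_n If given, overrides `threshold` and returns the strongest
#'   `top_n` variants.
#' @return `data.frame` of selected rows of [variantEffects()].
#' @export
callEffectVariants <- function(result, threshold = 1e-4, top_n = NULL) {
    eff <- variantEffects(result)
    ord <- order(-eff$mean_abs_effect,
                 eff$chromosome, eff$position_bp)
    eff <- eff[ord, , drop = FALSE]
    if (!is.null(top_n)) {
        top_n <- min(as.integer(top_n), nrow(eff))
        out <- eff[seq_len(top_n), , drop = FALSE]
    } else {
        if (threshold <= 0) stop("threshold must be > 0 (or give top_n)")
        out <- eff[eff$mean_abs_effect >= threshold, , drop = FALSE]
    }
    rownames(out) <- NULL
    out
}

#' Merge effect variants into associated loci
#'
#' Single-linkage merge: effect variants on the same chromosome whose
#' consecutive positions are `< max_gap_bp` apart (strict `<`, default
#' 1 Mb) form one locus.  Each locus reports its member variants, the top
#' variant (largest `|effect|`), the effect allele (allele2, the counted
#' allele) with its case/control frequencies, the risk allele (the allele
#' more frequent in cases), and optionally the phenotypic variance
#' explained by the top-variant genotype.
#'
#' @param effect_variants Output of [callEffectVariants()].
#' @param g The [GenotypeMatrix-class] (for allele frequencies).
#' @param pheno Phenotype `data.frame` with `sample_id` and `status`.
#' @param covariates Optional covariate matrix entered before the genotype
#'   term in the variance-explained ANOVA.
#' @param max_gap_bp Merge distance bound (strict `<`).
#' @return `data.frame` with one row per locus.
#' @export
mergeIntoLoci <- function(effect_variants, g, pheno, covariates = NULL,
                          max_gap_bp = 1e6) {
    if (nrow(effect_variants) == 0L)
        return(data.frame(locus_id = character(), chromosome = character(),
                          start_bp = integer(), end_bp = integer(),
                          n_variants = integer(), members = character(),
                          top_variant = character(), top_effect = numeric(),
                          effect_allele = character(),
                          other_allele = character(),
                          ea_freq_cases = numeric(),
                          ea_freq_controls = numeric(),
                          risk_allele = character(),
                          variance_explained_pct = numeric()))
    ev <- effect_variants[order(effect_variants$chromosome,
                                effect_variants$position_bp), , drop = FALSE]
    newLocus <- c(TRUE, ev$chromosome[-1] != ev$chromosome[-nrow(ev)] |
                  diff(ev$position_bp) >= max_gap_bp)
    lid <- cumsum(newLocus)
    vm <- variantMapOf(g)
    status <- pheno$status[match(sampleIDs(g), pheno$sample_id)]
    grp <- factor(ifelse(status == 1, "case", "control"),
                  levels = c("case", "control"))
    freqs <- alleleStats(g, grp)
    out <- do.call(rbind, lapply(split(seq_len(nrow(ev)), lid), function(ii) {
        sub <- ev[ii, , drop = FALSE]
        top <- sub[which.max(abs(sub$mean_effect)), ]
        j <- match(top$variant_id, vm$variant_id)
        fc <- freqs[j, "case"]; fk <- freqs[j, "control"]
        risk <- if (isTRUE(fc >= fk)) vm$allele2[j] else vm$allele1[j]
        ve <- NA_real_
        if (!is.null(status) && !anyNA(status)) {
            dos <- dosages(g)[, j]
            if (risk == vm$allele1[j]) dos <- 2L - dos
            vex <- varianceExplained(status, data.frame(genotype = dos),
                                     covariates = covariates)
            ve <- vex$pct_variance[vex$term == "genotype"]
        }
        data.frame(locus_id = sprintf("chr%s:%d-%d", sub$chromosome[1],
                                      min(sub$position_bp),
                                      max(sub$position_bp)),
                   chromosome = sub$chromosome[1],
                   start_bp = min(sub$position_bp),
                   end_bp = max(sub$position_bp),
                   n_variants = nrow(sub),
                   members = paste(sub$variant_id, collapse = ","),
                   top_variant = top$variant_id,
                   top_effect = top$mean_effect,
                   effect_allele = vm$allele2[j],
                   other_allele = vm$allele1[j],
                   ea_freq_cases = fc,
                   ea_freq_controls = fk,
                   risk_allele = risk,
                   variance_explained_pct = ve,
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Per-individual risk index over associated loci
#'
#' Sums risk-allele weights at each locus's top variant.  Scheme `"half"`
#' scores genotypes 0 / 0.5 / 1 risk units per locus; scheme `"count"`
#' (default) counts risk alleles 0 / 1 / 2, exactly twice the `"half"`
#' index.  A missing genotype contributes that locus's mean weight.
#'
#' @param g A [GenotypeMatrix-class].
#' @param loci Locus table from [mergeIntoLoci()] (uses `top_variant` and
#'   `risk_allele`).
#' @param scheme `"count"` or `"half"`.
#' @return `data.frame(sample_id, index)` with attribute `scheme`.
#' @export
computeRiskIndex <- function(g, loci, scheme = c("count", "half")) {
    scheme <- match.arg(scheme)
    vm <- variantMapOf(g)
    idx <- rep(0, nSamples(g))
    for (i in seq_len(nrow(loci))) {
        j <- match(loci$top_variant[i], vm$variant_id)
        if (is.na(j)) stop("locus top variant not in genotype data: ",
                           loci$top_variant[i])
        dos <- dosages(g)[, j]
        if (loci$risk_allele[i] == vm$allele1[j]) dos <- 2L - dos
        w <- as.numeric(dos)
        if (anyNA(w)) w[is.na(w)] <- mean(w, na.rm = TRUE)
        if (scheme == "half") w <- w / 2
        idx <- idx + w
    }
    out <- data.frame(sample_id = sampleIDs(g), index = idx,
                      stringsAsFactors = FALSE)
    attr(out, "scheme") <- scheme
    out
}

#' Sequential ANOVA variance-explained decomposition
#'
#' Fits a linear model with covariates entered first, then each predictor
#' column in order, and reports the type-I (sequential) sum of squares of
#' every term as a percentage of the total sum of squares.  Percentages
#' plus the residual row sum to 100 by construction.  Collinear terms are
#' reported with zero df and flagged.
#'
#' @param y Numeric response (e.g. 0/1 status).
#' @param predictors Numeric vector (e.g. a risk index) or
#'   matrix/data.frame of predictor columns.
#' @param covariates Optional numeric matrix/data.frame entered before the
#'   predictors.
#' @return `data.frame(term, df, sum_sq, pct_variance, aliased)` including
#'   a `residual` row.
#' @export
varianceExplained <- function(y, predictors, covariates = NULL) {
    if (is.null(dim(predictors)))
        predictors <- data.frame(predictor = predictors)
    predictors <- as.data.frame(predictors)
    dat <- data.frame(.y = as.numeric(y))
    if (!is.null(covariates)) {
        covariates <- as.data.frame(covariates)
        names(covariates) <- paste0("cov_", names(covariates))
        dat <- cbind(dat, covariates)
    }
    dat <- cbind(dat, predictors)
    if (nrow(dat) <= ncol(dat))
        stop("need more observations than model terms")
    terms <- setdiff(names(dat), ".y")
    fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    fit <- stats::lm(fml, data = dat)
    ## only the sums of squares are used, so the F-test warning on
    ## perfect fits is irrelevant here
    an <- suppressWarnings(stats::anova(fit))
    sst <- sum(an[, "Sum Sq"])
    res <- data.frame(term = rownames(an),
                      df = an[, "Df"],
                      sum_sq = an[, "Sum Sq"],
                      pct_variance = 100 * an[, "Sum Sq"] / sst,
                      stringsAsFactors = FALSE)
    res$term[res$term == "Residuals"] <- "residual"
    ## terms dropped for collinearity never reach the anova table; restore
    aliased <- setdiff(terms, res$term)
    if (length(aliased))
        res <- rbind(res, data.frame(term = aliased, df = 0, sum_sq = 0,
                                     pct_variance = 0))
    res$aliased <- res$df == 0
    rownames(res) <- NULL
    res
}
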