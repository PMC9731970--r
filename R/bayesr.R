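## Four-component normal-mixture GWAS ("BayesR"-type): R-side driver for the
## compiled Gibbs sampler, multi-chain summarization.

#' Configuration of the mixture-model GWAS sampler
#'
#' The per-variant effect prior is a four-component normal mixture with
#' variances `variance_coefficients * sigma2_g`: a point mass at zero and
#' components holding up to 0.01%, 0.1% and 1% of the genetic variance.
#' The desk-scale defaults (20,000 iterations, 5,000 burn-in, 3 chains)
#' converge on cohorts of a few hundred samples and a few thousand
#' variants; the full-replication setting used for dense genome-wide panels
#' is 300,000 iterations, 100,000 burn-in and 5 chains
#' (`bayesRConfig(n_iterations = 3e5, burn_in = 1e5, n_chains = 5)`).
#'
#' @param variance_coefficients Mixture variance multipliers; first entry
#'   must be 0.
#' @param n_iterations Gibbs iterations per chain.
#' @param burn_in Iterations discarded before averaging (`< n_iterations`).
#' @param n_chains Independent chains; posterior means are averaged across
#'   chains.
#' @param thinning Keep every `thinning`-th post-burn-in draw.
#' @param dirichlet_prior Dirichlet concentration over the four classes.
#' @param nu_g,nu_e Prior degrees of freedom of the scaled inverse
#'   chi-square priors on the genetic and residual variances.
#' @param scale_frac_g,scale_frac_e Prior scales as fractions of `var(y)`;
#'   weakly informative defaults of one half each.
#' @param seed Integer seed; chain `c` uses a stream derived from
#'   `seed + c`.
#' @return A list of class `BayesRConfig`.
#' @export
bayesRConfig <- function(variance_coefficients = c(0, 1e-4, 1e-3, 1e-2),
                         n_iterations = 20000, burn_in = 5000,
                         n_chains = 3, thinning = 1,
                         dirichlet_prior = c(1, 1, 1, 1),
                         nu_g = 4, nu_e = 4,
                         scale_frac_g = 0.5, scale_frac_e = 0.5,
                         seed = 1) {
    if (burn_in >= n_iterations) stop("burn_in must be < n_iterations")
    if (variance_coefficients[1] != 0 || any(variance_coefficients < 0))
        stop("variance_coefficients must be non-negative with first entry 0")
    cfg <- list(variance_coefficients = variance_coefficients,
                n_iterations = as.integer(n_iterations),
                burn_in = as.integer(burn_in),
                n_chains = as.integer(n_chains),
                thinning = as.integer(thinning),
                dirichlet_prior = dirichlet_prior,
                nu_g = nu_g, nu_e = nu_e,
                scale_frac_g = scale_frac_g, scale_frac_e = scale_frac_e,
                seed = as.integer(seed))
    class(cfg) <- "BayesRConfig"
    cfg
}

#' Fit the four-component mixture-model GWAS
#'
#' Gibbs cycle per iteration: fixed effects from their conditional normals
#' (flat priors); each variant, in freshly randomized order, gets its class
#' indicator sampled with probability proportional to `pi_k` times the
#' marginal likelihood of the residual under `beta_j ~ N(0, gamma_k
#' sigma2_g)`, then its effect from the conditional normal (zero for class
#' 1); `pi` from `Dirichlet(prior + class counts)`; the genetic and
#' residual variances from scaled inverse chi-square conditionals.
#' Genotypes are column-centred (not standardized), so reported effects are
#' per copy of allele2 on the scale of `y`.  A binary `status` outcome is
#' analysed as-is by the linear model, exactly as the reference
#' implementation of this model family does.
#'
#' @param y Numeric response (0/1 case status or quantitative); non-finite
#'   values are rejected.
#' @param g A [GenotypeMatrix-class]; missing dosages are mean-imputed.
#' @param covariates Optional numeric matrix/data.frame of fixed-effect
#'   covariates (e.g. principal components), one row per sample.  An
#'   intercept is always included.
#' @param config A [bayesRConfig()].
#' @return A [BayesRResult-class] with per-variant signed posterior mean
#'   effects, `mean_abs_effect` (absolute value of the cross-chain average
#'   -- average first, then absolute), class-membership probabilities,
#'   posterior mean mixture proportions and variance components.
#' @export
fitBayesR <- function(y, g, covariates = NULL, config = bayesRConfig()) {
    stopifnot(is(g, "GenotypeMatrix"), inherits(config, "BayesRConfig"))
    y <- as.numeric(y)
    if (any(!is.finite(y))) stop("y contains non-finite values")
    if (length(y) != nSamples(g)) stop("length(y) must equal nSamples(g)")
    X <- g@dosages
    storage.mode(X) <- "double"
    if (anyNA(X)) {
        cm <- colMeans(X, na.rm = TRUE)
        for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- cm[j]
    }
    X <- scale(X, center = TRUE, scale = FALSE)
    W <- cbind(intercept = 1, as.matrix(if (is.null(covariates))
        matrix(numeric(), length(y), 0) else covariates))
    storage.mode(W) <- "double"
    vy <- stats::var(y)
    if (vy == 0) {
        warning("y has zero variance; returning all-zero effects")
        chains <- list(.zeroChain(g, W, config))
        return(summarizeChains(chains, g))
    }
    chains <- vector("list", config$n_chains)
    for (cc in seq_len(config$n_chains)) {
        set.seed(.stageSeed(config$seed + cc, 11L))
        fit <- .bayesr_gibbs(X, y, W, config$variance_coefficients,
                             config$n_iterations, config$burn_in,
                             config$thinning, config$dirichlet_prior,
                             config$nu_g, config$scale_frac_g * vy,
                             config$nu_e, config$scale_frac_e * vy)
        names(fit$alpha_mean) <- colnames(W)
        chains[[cc]] <- fit
    }
    summarizeChains(chains, g)
}

.zeroChain <- function(g, W, config) {
    m <- nVariants(g)
    list(beta_mean = rep(0, m),
         class_prob = cbind(rep(1, m), 0, 0, 0),
         pi_mean = c(1, 0, 0, 0),
         alpha_mean = stats::setNames(rep(0, ncol(W)), colnames(W)),
         varG_mean = 0, varE_mean = 0,
         varG_trace = numeric(), n_kept = 0L)
}

#' Summarize Gibbs chains into a result object
#'
#' Cross-chain mean of the per-chain posterior means; the reported
#' `mean_abs_effect` is the absolute value of that average (average first,
#' then absolute, so chains with opposing signs cancel).  The between-chain
#' standard deviation of each variant's mean effect is kept as a
#' convergence diagnostic.
#'
#' @param chains List of per-chain summaries as produced internally by
#'   [fitBayesR()] (fields `beta_mean`, `class_prob`, `pi_mean`,
#'   `alpha_mean`, `varG_mean`, `varE_mean`).
#' @param g The [GenotypeMatrix-class] the chains were fitted on (supplies
#'   variant ids).
#' @return A [BayesRResult-class].
#' @export
summarizeChains <- function(chains, g) {
    stopifnot(length(chains) >= 1L)
    nc <- length(chains)
    bmat <- sapply(chains, `[[`, "beta_mean")
    bmat <- matrix(bmat, ncol = nc)
    bmean <- rowMeans(bmat)
    bsd <- if (nc > 1) apply(bmat, 1, stats::sd) else rep(0, nrow(bmat))
    clsP <- Reduce(`+`, lapply(chains, `[[`, "class_prob")) / nc
    eff <- data.frame(
        variant_id = variantMapOf(g)$variant_id,
        chromosome = variantMapOf(g)$chromosome,
        position_bp = variantMapOf(g)$position_bp,
        mean_effect = bmean,
        mean_abs_effect = abs(bmean),
        between_chain_sd = bsd,
        p_class1 = clsP[, 1], p_class2 = clsP[, 2],
        p_class3 = clsP[, 3], p_class4 = clsP[, 4],
        stringsAsFactors = FALSE)
    alpha <- rowMeans(matrix(sapply(chains, `[[`, "alpha_mean"),
                             ncol = nc))
    names(alpha) <- names(chains[[1]]$alpha_mean)
    new("BayesRResult",
        effects = eff,
        pi = rowMeans(matrix(sapply(chains, `[[`, "pi_mean"), ncol = nc)),
        varG = mean(sapply(chains, `[[`, "varG_mean")),
        varE = mean(sapply(chains, `[[`, "varE_mean")),
        mu = unname(alpha[1]),
        fixedEffects = alpha,
        nChains = as.integer(nc),
        chains = chains)
}

#' Write per-variant effects and a model summary to TSV
#'
#' @param result A [BayesRResult-class].
#' @param prefix Output path prefix; writes `<prefix>.effects.tsv` and
#'   `<prefix>.model.tsv`.
#' @return `prefix`, invisibly.
#' @export
writeBayesRResult <- function(result, prefix) {
    utils::write.table(variantEffects(result),
                       paste0(prefix, ".effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ms <- data.frame(
        parameter = c("pi1", "pi2", "pi3", "pi4", "varG", "varE", "mu",
                      names(result@fixedEffects)),
        value = c(result@pi, result@varG, result@varE, result@mu,
                  unname(result@fixedEffects)))
    utils::write.table(ms, paste0(prefix, ".model.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(prefix)
}
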