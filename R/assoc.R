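## Single-variant association tests, LD, haplotype-carrier classification
## and the small-sample statistics reported alongside the scans.

#' Allelic chi-square association scan
#'
#' Per variant, builds the 2x2 allele-count table (case/control x
#' allele1/allele2) from non-missing genotypes and computes the 1-df
#' Pearson chi-square without continuity correction -- the basic allelic
#' test of standard GWAS tooling.
#'
#' @param g A [GenotypeMatrix-class].
#' @param pheno `data.frame` with `sample_id` and binary `status`.
#' @return `data.frame(variant_id, chromosome, position_bp, chisq, p,
#'   logp)`; monomorphic variants get `chisq = 0`, `p = 1`.
#' @export
allelicChisqScan <- function(g, pheno) {
    status <- pheno$status[match(sampleIDs(g), pheno$sample_id)]
    if (anyNA(status) || !all(status %in% c(0, 1)))
        stop("every genotyped sample needs a binary status")
    d <- g@dosages
    case <- status == 1
    a2_case <- colSums(d[case, , drop = FALSE], na.rm = TRUE)
    a2_ctrl <- colSums(d[!case, , drop = FALSE], na.rm = TRUE)
    n_case <- 2 * colSums(!is.na(d[case, , drop = FALSE]))
    n_ctrl <- 2 * colSums(!is.na(d[!case, , drop = FALSE]))
    a1_case <- n_case - a2_case
    a1_ctrl <- n_ctrl - a2_ctrl
    N <- n_case + n_ctrl
    ## Pearson chi-square on the 2x2 table, no correction
    det <- a1_case * a2_ctrl - a2_case * a1_ctrl
    den <- as.numeric(n_case) * n_ctrl * (a1_case + a1_ctrl) *
        (a2_case + a2_ctrl)
    chisq <- ifelse(den > 0, N * det^2 / den, 0)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    data.frame(variant_id = variantMapOf(g)$variant_id,
               chromosome = variantMapOf(g)$chromosome,
               position_bp = variantMapOf(g)$position_bp,
               chisq = chisq, p = p, logp = -log10(p),
               stringsAsFactors = FALSE)
}

#' Logistic regression association scan with covariates
#'
#' Per variant, fits `status ~ dosage + covariates` by iteratively
#' reweighted least squares and reports the allele-dosage coefficient with
#' its two-sided Wald p-value.  Non-converged fits and (quasi-)separated
#' variants are flagged and get `p = NA`; a constant dosage is flagged as
#' degenerate.
#'
#' @param g A [GenotypeMatrix-class].
#' @param pheno `data.frame` with `sample_id` and binary `status`.
#' @param covariates Optional covariate matrix/data.frame, one row per
#'   sample.
#' @return `data.frame(variant_id, beta, se, z, p, logp, converged)`.
#' @export
logisticScan <- function(g, pheno, covariates = NULL) {
    status <- pheno$status[match(sampleIDs(g), pheno$sample_id)]
    if (anyNA(status) || !all(status %in% c(0, 1)))
        stop("every genotyped sample needs a binary status")
    d <- g@dosages
    W <- if (is.null(covariates)) NULL else as.matrix(covariates)
    m <- ncol(d)
    beta <- se <- z <- p <- rep(NA_real_, m)
    conv <- logical(m)
    for (j in seq_len(m)) {
        x <- d[, j]
        ok <- !is.na(x)
        if (stats::sd(x[ok]) == 0) next  # degenerate: constant dosage
        X <- cbind(dosage = as.numeric(x[ok]),
                   if (is.null(W)) NULL else W[ok, , drop = FALSE])
        fit <- suppressWarnings(stats::glm.fit(
            cbind(1, X), status[ok], family = stats::binomial()))
        cf <- fit$coefficients["dosage"]
        if (!fit$converged || is.na(cf) || abs(cf) > 15) next
        ## Wald s.e. from the IRLS weighted cross-product
        XX <- cbind(1, X)
        wt <- fit$weights
        V <- tryCatch(solve(crossprod(XX * sqrt(wt))), error = function(e) NULL)
        if (is.null(V)) next
        conv[j] <- TRUE
        beta[j] <- cf
        se[j] <- sqrt(V["dosage", "dosage"])
        z[j] <- beta[j] / se[j]
        p[j] <- 2 * stats::pnorm(-abs(z[j]))
    }
    data.frame(variant_id = variantMapOf(g)$variant_id,
               beta = beta, se = se, z = z, p = p, logp = -log10(p),
               converged = conv, stringsAsFactors = FALSE)
}

#' Pearson chi-square with Yates continuity correction
#'
#' For a 2x2 table `(a, b; c, d)`:
#' `chisq = N (|ad - bc| - N/2)^2 / (r1 r2 c1 c2)`, with the correction
#' truncated so it can never push the statistic below zero (when
#' `|ad - bc| < N/2`, `chisq = 0`).
#'
#' @param tab 2x2 numeric matrix (rows: case/control; columns: allele or
#'   carrier class).
#' @return List with `chisq`, `df` (1) and `p`.
#' @export
yatesChisq <- function(tab) {
    tab <- as.matrix(tab)
    if (!all(dim(tab) == c(2, 2)) || any(tab < 0))
        stop("tab must be a 2x2 table of non-negative counts")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("all table margins must be positive")
    N <- sum(tab)
    det <- abs(tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])
    corr <- max(det - N / 2, 0)
    chisq <- N * corr^2 / prod(rowSums(tab), colSums(tab))
    list(chisq = chisq, df = 1L,
         p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Welch two-sample t-test (two-sided)
#'
#' Welch statistic with Satterthwaite degrees of freedom; the comparison
#' conventionally reported for case-vs-control risk indices.
#'
#' @param x,y Numeric vectors (>= 2 values each).
#' @return List with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welchTTest <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
        stop("need at least two values per group")
    vx <- stats::var(x) / length(x)
    vy <- stats::var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
         mean_x = mean(x), mean_y = mean(y))
}

#' Pairwise LD as squared correlation
#'
#' Squared Pearson correlation of dosages (genotype mode) or of 0/1
#' haplotype alleles (phased mode, given a [HaplotypePanel-class]).
#'
#' @param x A [GenotypeMatrix-class] or [HaplotypePanel-class].
#' @param pairs Two-column matrix (or data.frame) of variant ids or
#'   indices.
#' @return Numeric vector of r-squared values, one per pair.
#' @export
ldR2 <- function(x, pairs) {
    mat <- if (is(x, "HaplotypePanel")) x@haplotypes else dosages(x)
    vm <- variantMapOf(x)
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stop("pairs must have two columns")
    resolve <- function(v) {
        if (is.character(v)) match(v, vm$variant_id) else as.integer(v)
    }
    i <- resolve(pairs[, 1]); j <- resolve(pairs[, 2])
    if (anyNA(i) || anyNA(j)) stop("unknown variant id in pairs")
    vapply(seq_along(i), function(k) {
        a <- mat[, i[k]]; b <- mat[, j[k]]
        if (stats::sd(a, na.rm = TRUE) == 0 || stats::sd(b, na.rm = TRUE) == 0)
            stop("both variants of a pair must be polymorphic")
        stats::cor(a, b, use = "pairwise.complete.obs")^2
    }, numeric(1))
}

#' Haplotype-carrier classification at a target allele sequence
#'
#' Counts, per sample, how many of its two phased haplotypes exactly match
#' the target allele sequence at the given sites (class 2 = homozygous
#' carrier, 1 = heterozygous, 0 = non-carrier), and summarizes class
#' counts and percentages by status group.
#'
#' @param panel A [HaplotypePanel-class].
#' @param sites Ordered variant ids (one chromosome).
#' @param target Allele sequence at the sites: allele labels from the
#'   variant map (e.g. `c("C", "C", "G")`) or 0/1 codes.
#' @param pheno Optional `data.frame(sample_id, status)` for the by-group
#'   summary.
#' @return List with `classes` (`data.frame(sample_id, copies)`),
#'   `frequency` (carried copies / 2n) and, when `pheno` is given,
#'   `summary` (`data.frame(group, class, n, pct)`).
#' @export
haplotypeCarrierClasses <- function(panel, sites, target, pheno = NULL) {
    stopifnot(is(panel, "HaplotypePanel"))
    vm <- panel@variants
    j <- match(sites, vm$variant_id)
    if (anyNA(j)) stop("unknown site id(s): ",
                       paste(sites[is.na(j)], collapse = ", "))
    if (length(unique(vm$chromosome[j])) != 1L)
        stop("sites must lie on one chromosome")
    if (length(target) != length(j))
        stop("target must give one allele per site")
    code <- integer(length(j))
    for (k in seq_along(j)) {
        code[k] <- if (target[k] %in% c(0, 1, "0", "1")) as.integer(target[k])
                   else if (identical(target[k], vm$allele1[j[k]])) 0L
                   else if (identical(target[k], vm$allele2[j[k]])) 1L
                   else stop("target allele ", target[k],
                             " not valid at site ", sites[k])
    }
    h <- panel@haplotypes[, j, drop = FALSE]
    hit <- rowSums(h == matrix(code, nrow(h), length(code), byrow = TRUE)) ==
        length(code)
    so <- panel@sampleOf
    copies <- tapply(hit, so$sample_id, sum)
    ids <- unique(so$sample_id)
    classes <- data.frame(sample_id = ids,
                          copies = as.integer(copies[ids]),
                          stringsAsFactors = FALSE)
    out <- list(classes = classes,
                frequency = sum(hit) / nrow(h))
    if (!is.null(pheno)) {
        st <- pheno$status[match(classes$sample_id, pheno$sample_id)]
        grp <- ifelse(st == 1, "case", "control")
        sm <- do.call(rbind, lapply(c("case", "control"), function(gv) {
            cc <- classes$copies[grp == gv]
            data.frame(group = gv, class = 0:2,
                       n = vapply(0:2, function(k) sum(cc == k), integer(1)),
                       pct = 100 * vapply(0:2, function(k) mean(cc == k),
                                          numeric(1)),
                       stringsAsFactors = FALSE)
        }))
        out$summary <- sm
    }
    out
}
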