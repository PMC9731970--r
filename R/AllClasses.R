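#' @import methods
NULL

.validVariantMap <- function(v) {
    msgs <- character()
    need <- c("variant_id", "chromosome", "position_bp", "allele1", "allele2")
    if (!is.data.frame(v) || !all(need %in% names(v)))
        return(sprintf("variant map must be a data.frame with columns %s",
                       paste(need, collapse = ", ")))
    if (anyDuplicated(v$variant_id))
        msgs <- c(msgs, "variant_id values must be unique")
    if (any(v$position_bp < 1))
        msgs <- c(msgs, "position_bp must be >= 1")
    for (chr in unique(v$chromosome)) {
        p <- v$position_bp[v$chromosome == chr]
        if (any(diff(p) <= 0)) {
            msgs <- c(msgs, sprintf(
                "positions must be strictly increasing within chromosome %s", chr))
            break
        }
    }
    if (length(msgs)) msgs else TRUE
}

#' Assemble a variant map
#'
#' A variant map is a plain `data.frame` describing the markers of a
#' [GenotypeMatrix] or [HaplotypePanel]: one row per variant with columns
#' `variant_id`, `chromosome`, `position_bp` (1-based), `allele1` and
#' `allele2`.  Dosages throughout the package count copies of `allele2`.
#'
#' @param variant_id Character vector of unique variant identifiers.
#' @param chromosome Chromosome label per variant.
#' @param position_bp 1-based physical position (bp), strictly increasing
#'   within each chromosome.
#' @param allele1,allele2 Allele labels; `allele2` is the counted allele.
#' @return A validated `data.frame` with the five columns above.
#' @export
variantMap <- function(variant_id, chromosome, position_bp, allele1, allele2) {
    v <- data.frame(variant_id = as.character(variant_id),
                    chromosome = as.character(chromosome),
                    position_bp = as.integer(position_bp),
                    allele1 = as.character(allele1),
                    allele2 = as.character(allele2),
                    stringsAsFactors = FALSE)
    ok <- .validVariantMap(v)
    if (!isTRUE(ok)) stop(paste(ok, collapse = "; "))
    v
}

#' GenotypeMatrix: samples-by-variants dosage matrix
#'
#' Holds unphased genotypes as an `n x m` integer matrix of allele2 dosages
#' in `{0, 1, 2}` with `NA` as the missing-genotype sentinel, together with
#' the variant map.  Row names are sample identifiers, column names variant
#' identifiers.
#'
#' @slot dosages Integer matrix, samples in rows, variants in columns.
#' @slot variants Variant map `data.frame` (see [variantMap()]).
#' @export
setClass("GenotypeMatrix",
         representation(dosages = "matrix", variants = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
    msgs <- character()
    ok <- .validVariantMap(object@variants)
    if (!isTRUE(ok)) msgs <- c(msgs, ok)
    d <- object@dosages
    if (ncol(d) != nrow(object@variants))
        msgs <- c(msgs, "ncol(dosages) must equal nrow(variants)")
    if (nrow(d) > 0L && is.null(rownames(d)))
        msgs <- c(msgs, "dosages must carry sample ids as rownames")
    else if (anyDuplicated(rownames(d)))
        msgs <- c(msgs, "sample ids must be unique")
    vals <- d[!is.na(d)]
    if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
        msgs <- c(msgs, "dosages must be 0, 1, 2 or NA")
    if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages Numeric/integer matrix of allele2 dosages (`0/1/2`, `NA`
#'   for missing), samples in rows.  Row names are used as sample ids; if
#'   absent, `S1..Sn` are assigned.
#' @param variants Variant map with one row per column of `dosages`.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosages, variants) {
    d <- as.matrix(dosages)
    storage.mode(d) <- "integer"
    if (is.null(rownames(d)))
        rownames(d) <- if (nrow(d)) paste0("S", seq_len(nrow(d))) else character()
    colnames(d) <- variants$variant_id
    new("GenotypeMatrix", dosages = d, variants = as.data.frame(variants))
}

#' HaplotypePanel: phased 0/1 allele matrix
#'
#' Holds phased haplotypes as a `2n x m` binary matrix (1 = carries
#' `allele2`) over a variant map, with a bookkeeping table mapping each
#' haplotype row to its sample and phase (1 or 2).  Collapsing the two
#' phases of each sample by addition reproduces the dosage matrix
#' ([pairToGenotypes()]).
#'
#' @slot haplotypes Integer 0/1 matrix, two rows per sample.
#' @slot variants Variant map `data.frame`.
#' @slot sampleOf `data.frame` with columns `sample_id`, `phase`, one row
#'   per haplotype row.
#' @export
setClass("HaplotypePanel",
         representation(haplotypes = "matrix", variants = "data.frame",
                        sampleOf = "data.frame"))

setValidity("HaplotypePanel", function(object) {
    msgs <- character()
    ok <- .validVariantMap(object@variants)
    if (!isTRUE(ok)) msgs <- c(msgs, ok)
    h <- object@haplotypes
    if (ncol(h) != nrow(object@variants))
        msgs <- c(msgs, "ncol(haplotypes) must equal nrow(variants)")
    if (length(h) && !all(h %in% c(0L, 1L)))
        msgs <- c(msgs, "haplotype alleles must be 0 or 1")
    so <- object@sampleOf
    if (!all(c("sample_id", "phase") %in% names(so)) || nrow(so) != nrow(h))
        msgs <- c(msgs, "sampleOf must map every haplotype row to (sample_id, phase)")
    else {
        tab <- table(so$sample_id)
        if (length(tab) && any(tab != 2L))
            msgs <- c(msgs, "each sample must contribute exactly two haplotypes")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param haplotypes 0/1 matrix with an even number of rows; consecutive row
#'   pairs belong to one sample unless `sampleOf` says otherwise.
#' @param variants Variant map with one row per column.
#' @param sampleOf Optional `data.frame(sample_id, phase)`; defaults to
#'   consecutive pairing with samples `S1..Sn`.
#' @return A [HaplotypePanel-class] object.
#' @export
HaplotypePanel <- function(haplotypes, variants, sampleOf = NULL) {
    h <- as.matrix(haplotypes)
    storage.mode(h) <- "integer"
    if (is.null(sampleOf)) {
        if (nrow(h) %% 2L != 0L)
            stop("haplotype count must be even (two per sample)")
        n <- nrow(h) %/% 2L
        sampleOf <- data.frame(
            sample_id = rep(if (n) paste0("S", seq_len(n)) else character(), each = 2L),
            phase = rep(c(1L, 2L), times = n),
            stringsAsFactors = FALSE)
    }
    rownames(h) <- paste0(sampleOf$sample_id, "_", sampleOf$phase)
    colnames(h) <- variants$variant_id
    new("HaplotypePanel", haplotypes = h, variants = as.data.frame(variants),
        sampleOf = as.data.frame(sampleOf))
}

#' BayesRResult: posterior summaries of the mixture-model GWAS
#'
#' @slot effects `data.frame` with one row per variant: `variant_id`,
#'   `mean_effect` (signed posterior mean of the sampled effect),
#'   `mean_abs_effect` (absolute value of the signed mean -- average first,
#'   then absolute), `between_chain_sd`, and class-membership probabilities
#'   `p_class1..p_class4`.
#' @slot pi Posterior mean mixture proportions (length 4, sums to 1).
#' @slot varG,varE Posterior mean genetic and residual variances.
#' @slot mu Posterior mean intercept.
#' @slot fixedEffects Named posterior means of fixed-effect coefficients.
#' @slot nChains Number of chains averaged.
#' @slot chains Optional list of per-chain summaries.
#' @export
setClass("BayesRResult",
         representation(effects = "data.frame", pi = "numeric",
                        varG = "numeric", varE = "numeric", mu = "numeric",
                        fixedEffects = "numeric", nChains = "integer",
                        chains = "list"))

setValidity("BayesRResult", function(object) {
    msgs <- character()
    if (length(object@pi) != 4L || abs(sum(object@pi) - 1) > 1e-8)
        msgs <- c(msgs, "pi must be a 4-component simplex point")
    need <- c("variant_id", "mean_effect", "mean_abs_effect")
    if (!all(need %in% names(object@effects)))
        msgs <- c(msgs, "effects must have variant_id, mean_effect, mean_abs_effect")
    if (length(msgs)) msgs else TRUE
})

## ---- accessors -------------------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("variantMapOf", function(x) standardGeneric("variantMapOf"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("variantEffects", function(x) standardGeneric("variantEffects"))
#' @rdname accessors
#' @export
setGeneric("mixtureProportions", function(x) standardGeneric("mixtureProportions"))

#' Accessors for breedscan containers
#'
#' `dosages()` returns the raw dosage matrix, `haplotypes()` the phased
#' allele matrix, `variantMapOf()` the variant map, `sampleIDs()` the sample
#' identifiers, `nSamples()`/`nVariants()` the dimensions,
#' `variantEffects()` the per-variant posterior summary table and
#' `mixtureProportions()` the posterior mean mixture proportions.
#'
#' @param x A [GenotypeMatrix-class], [HaplotypePanel-class] or
#'   [BayesRResult-class] object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)
#' @rdname accessors
setMethod("variantMapOf", "GenotypeMatrix", function(x) x@variants)
#' @rdname accessors
setMethod("variantMapOf", "HaplotypePanel", function(x) x@variants)
#' @rdname accessors
setMethod("sampleIDs", "GenotypeMatrix", function(x) rownames(x@dosages))
#' @rdname accessors
setMethod("sampleIDs", "HaplotypePanel",
          function(x) unique(x@sampleOf$sample_id))
#' @rdname accessors
setMethod("haplotypes", "HaplotypePanel", function(x) x@haplotypes)
#' @rdname accessors
setMethod("nVariants", "GenotypeMatrix", function(x) ncol(x@dosages))
#' @rdname accessors
setMethod("nVariants", "HaplotypePanel", function(x) ncol(x@haplotypes))
#' @rdname accessors
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@dosages))
#' @rdname accessors
setMethod("nSamples", "HaplotypePanel", function(x) nrow(x@haplotypes) %/% 2L)
#' @rdname accessors
setMethod("variantEffects", "BayesRResult", function(x) x@effects)
#' @rdname accessors
setMethod("mixtureProportions", "BayesRResult", function(x) x@pi)

#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@dosages))
#' @export
setMethod("dim", "HaplotypePanel", function(x) dim(x@haplotypes))

#' Subset a GenotypeMatrix by samples (i) and variants (j)
#' @param x A `GenotypeMatrix`.
#' @param i,j Sample and variant indices (any standard matrix index).
#' @param ... Ignored.
#' @param drop Ignored (always `FALSE`).
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@dosages))
    if (missing(j)) j <- seq_len(ncol(x@dosages))
    GenotypeMatrix(x@dosages[i, j, drop = FALSE],
                   x@variants[j, , drop = FALSE])
})

#' Subset a HaplotypePanel by haplotype rows (i) and variants (j)
#' @param x A `HaplotypePanel`.
#' @param i Haplotype row indices; must keep complete sample pairs.
#' @param j Variant indices.
#' @param ... Ignored.
#' @param drop Ignored (always `FALSE`).
#' @export
setMethod("[", "HaplotypePanel", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@haplotypes))
    if (missing(j)) j <- seq_len(ncol(x@haplotypes))
    HaplotypePanel(x@haplotypes[i, j, drop = FALSE],
                   x@variants[j, , drop = FALSE],
                   x@sampleOf[i, , drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
    d <- dim(object@dosages)
    cat(sprintf("GenotypeMatrix: %d samples x %d variants\n", d[1], d[2]))
    cat(sprintf("  chromosomes: %s\n",
                paste(unique(object@variants$chromosome), collapse = ", ")))
    nm <- sum(is.na(object@dosages))
    cat(sprintf("  missing dosages: %d (%.2f%%)\n", nm,
                if (prod(d)) 100 * nm / prod(d) else 0))
})

setMethod("show", "HaplotypePanel", function(object) {
    d <- dim(object@haplotypes)
    cat(sprintf("HaplotypePanel: %d haplotypes (%d samples) x %d variants\n",
                d[1], d[1] %/% 2L, d[2]))
    cat(sprintf("  chromosomes: %s\n",
                paste(unique(object@variants$chromosome), collapse = ", ")))
})

setMethod("show", "BayesRResult", function(object) {
    cat(sprintf("BayesRResult: %d variants, %d chain(s)\n",
                nrow(object@effects), object@nChains))
    cat(sprintf("  pi: %s\n", paste(signif(object@pi, 3), collapse = ", ")))
    cat(sprintf("  varG = %.4g, varE = %.4g, mu = %.4g\n",
                object@varG, object@varE, object@mu))
    top <- utils::head(object@effects[
        order(-object@effects$mean_abs_effect), c("variant_id", "mean_abs_effect")], 3)
    cat("  top variants by |effect|:\n")
    for (k in seq_len(nrow(top)))
        cat(sprintf("    %s  %.3g\n", top$variant_id[k], top$mean_abs_effect[k]))
})
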