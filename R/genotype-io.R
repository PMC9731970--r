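## Genotype / haplotype / phenotype I/O in standard PLINK-compatible formats.
##
## Conventions fixed across the package:
##   * dosage counts copies of allele2 (the second allele column of the map);
##   * missing dosage is NA in memory, "0 0" in .ped, code 01 in .bed;
##   * coordinates are 1-based inclusive (PLINK convention).

.PED_META_COLS <- 6L

#' Read genotypes or haplotypes from disk
#'
#' Supported formats: PLINK text (`.ped`/`.map`), PLINK 1 binary
#' (`.bed`/`.bim`/`.fam`, SNP-major), and the package's phased haplotype
#' table (`<prefix>.hap.tsv` + `<prefix>.hapvar.tsv`).
#'
#' For PLINK text, allele labels are not recorded in `.map`, so the reader
#' orients each variant alphabetically: `allele1` is the lexicographically
#' smaller observed allele and `allele2` (the counted allele) the larger.
#' A variant observed with a single allele gets `allele2 = "0"` and all-zero
#' dosages.  The binary `.bim` carries the allele order explicitly.
#'
#' @param path File prefix (without extension).
#' @param format One of `"plink_text"`, `"plink_binary"`,
#'   `"haplotype_table"`.
#' @return A [GenotypeMatrix-class] (PLINK formats) or
#'   [HaplotypePanel-class] (haplotype table).
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path,
                          format = c("plink_binary", "plink_text",
                                     "haplotype_table")) {
    format <- match.arg(format)
    switch(format,
           plink_text = .readPedMap(path),
           plink_binary = .readBedBimFam(path),
           haplotype_table = .readHaplotypeTable(path))
}

#' Write genotypes or haplotypes to disk
#'
#' Inverse of [readGenotypes()]; `readGenotypes(writeGenotypes(x, p, f), f)`
#' reproduces `x`'s dosages (for PLINK text this requires `allele1 <
#' allele2` alphabetically; see [readGenotypes()]).
#'
#' @param data A [GenotypeMatrix-class] or (for `haplotype_table`) a
#'   [HaplotypePanel-class].
#' @param path Output file prefix.
#' @param format Output format, as in [readGenotypes()].
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(data, path,
                           format = c("plink_binary", "plink_text",
                                      "haplotype_table")) {
    format <- match.arg(format)
    switch(format,
           plink_text = .writePedMap(data, path),
           plink_binary = .writeBedBimFam(data, path),
           haplotype_table = .writeHaplotypeTable(data, path))
    invisible(path)
}

.readTokens <- function(file) {
    lines <- readLines(file)
    lines <- lines[nzchar(trimws(lines))]
    lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
}

.readMap <- function(file) {
    tok <- .readTokens(file)
    if (!length(tok))
        return(data.frame(chromosome = character(), variant_id = character(),
                          position_bp = integer()))
    m <- do.call(rbind, tok)
    data.frame(chromosome = m[, 1], variant_id = m[, 2],
               position_bp = as.integer(m[, 4]), stringsAsFactors = FALSE)
}

.readPedMap <- function(path) {
    mapf <- paste0(path, ".map"); pedf <- paste0(path, ".ped")
    if (!file.exists(mapf) || !file.exists(pedf))
        stop("missing .ped/.map pair at prefix ", path)
    map <- .readMap(mapf)
    m <- nrow(map)
    tok <- .readTokens(pedf)
    n <- length(tok)
    samples <- character(n)
    a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
    for (i in seq_len(n)) {
        row <- tok[[i]]
        if (length(row) != .PED_META_COLS + 2L * m)
            stop(sprintf(".ped row %d has %d fields; expected %d",
                         i, length(row), .PED_META_COLS + 2L * m))
        samples[i] <- row[2]
        if (m) {
            al <- row[-seq_len(.PED_META_COLS)]
            a1[i, ] <- al[seq(1L, 2L * m, by = 2L)]
            a2[i, ] <- al[seq(2L, 2L * m, by = 2L)]
        }
    }
    dos <- matrix(NA_integer_, n, m)
    all1 <- character(m); all2 <- character(m)
    for (j in seq_len(m)) {
        obs <- c(a1[, j], a2[, j])
        alleles <- sort(setdiff(unique(obs), "0"))
        if (length(alleles) > 2L)
            stop(sprintf("variant %s is not biallelic: alleles %s",
                         map$variant_id[j], paste(alleles, collapse = "/")))
        all1[j] <- if (length(alleles) >= 1L) alleles[1] else "0"
        all2[j] <- if (length(alleles) == 2L) alleles[2] else "0"
        ok <- a1[, j] != "0" & a2[, j] != "0"
        dos[ok, j] <- (a1[ok, j] == all2[j]) + (a2[ok, j] == all2[j])
    }
    rownames(dos) <- samples
    GenotypeMatrix(dos, variantMap(map$variant_id, map$chromosome,
                                   map$position_bp, all1, all2))
}

.writePedMap <- function(data, path) {
    stopifnot(is(data, "GenotypeMatrix"))
    v <- data@variants
    mapl <- sprintf("%s\t%s\t0\t%d", v$chromosome, v$variant_id, v$position_bp)
    writeLines(mapl, paste0(path, ".map"))
    d <- data@dosages
    ped <- vapply(seq_len(nrow(d)), function(i) {
        g <- d[i, ]
        A <- ifelse(is.na(g), "0", ifelse(g >= 1L, v$allele2, v$allele1))
        B <- ifelse(is.na(g), "0", ifelse(g == 2L, v$allele2, v$allele1))
        paste(c(rownames(d)[i], rownames(d)[i], "0", "0", "0", "-9",
                as.vector(rbind(A, B))), collapse = "\t")
    }, character(1))
    writeLines(ped, paste0(path, ".ped"))
}

.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

.readBedBimFam <- function(path) {
    bedf <- paste0(path, ".bed"); bimf <- paste0(path, ".bim")
    famf <- paste0(path, ".fam")
    for (f in c(bedf, bimf, famf))
        if (!file.exists(f)) stop("missing PLINK binary file: ", f)
    bim <- .readTokens(bimf)
    fam <- .readTokens(famf)
    m <- length(bim); n <- length(fam)
    samples <- vapply(fam, `[`, character(1), 2L)
    bimM <- if (m) do.call(rbind, bim) else
        matrix(character(), 0, 6)
    raw <- readBin(bedf, "raw", n = file.size(bedf))
    if (length(raw) < 3L || !identical(raw[1:3], .BED_MAGIC))
        stop(".bed file has malformed magic bytes (expected 6c 1b 01): ", bedf)
    bpv <- ceiling(n / 4)
    payload <- raw[-(1:3)]
    if (length(payload) != bpv * m)
        stop(sprintf(".bed payload is %d bytes; %d variants x %d samples need %d",
                     length(payload), m, n, bpv * m))
    dos <- matrix(NA_integer_, n, m)
    if (m && n) {
        codes <- matrix(0L, 4L, length(payload))
        ints <- as.integer(payload)
        for (b in 0:3) codes[b + 1L, ] <- bitwAnd(bitwShiftR(ints, 2L * b), 3L)
        lut <- c(`0` = 0L, `1` = NA_integer_, `2` = 1L, `3` = 2L)
        for (j in seq_len(m)) {
            cj <- as.vector(codes[, ((j - 1L) * bpv + 1L):(j * bpv)])[seq_len(n)]
            dos[, j] <- lut[cj + 1L]
        }
    }
    rownames(dos) <- samples
    GenotypeMatrix(dos, variantMap(bimM[, 2], bimM[, 1],
                                   as.integer(bimM[, 4]),
                                   bimM[, 5], bimM[, 6]))
}

.writeBedBimFam <- function(data, path) {
    stopifnot(is(data, "GenotypeMatrix"))
    v <- data@variants
    writeLines(sprintf("%s\t%s\t0\t%d\t%s\t%s", v$chromosome, v$variant_id,
                       v$position_bp, v$allele1, v$allele2),
               paste0(path, ".bim"))
    d <- data@dosages
    ids <- rownames(d)
    writeLines(sprintf("%s\t%s\t0\t0\t0\t-9", ids, ids), paste0(path, ".fam"))
    n <- nrow(d); m <- ncol(d); bpv <- ceiling(n / 4)
    con <- file(paste0(path, ".bed"), "wb")
    on.exit(close(con))
    writeBin(.BED_MAGIC, con)
    code <- c(`0` = 0L, `1` = 2L, `2` = 3L)  # dosage -> 2-bit code; NA -> 01
    for (j in seq_len(m)) {
        cj <- rep(0L, bpv * 4L)
        g <- d[, j]
        cj[seq_len(n)] <- ifelse(is.na(g), 1L, code[as.character(g)])
        cm <- matrix(cj, nrow = 4L)
        bytes <- cm[1, ] + bitwShiftL(cm[2, ], 2L) +
            bitwShiftL(cm[3, ], 4L) + bitwShiftL(cm[4, ], 6L)
        writeBin(as.raw(bytes), con)
    }
}

.readHaplotypeTable <- function(path) {
    hapf <- paste0(path, ".hap.tsv"); varf <- paste0(path, ".hapvar.tsv")
    if (!file.exists(hapf) || !file.exists(varf))
        stop("missing haplotype table pair at prefix ", path)
    v <- utils::read.delim(varf, colClasses = "character")
    vm <- variantMap(v$variant_id, v$chromosome, as.integer(v$position_bp),
                     v$allele1, v$allele2)
    h <- utils::read.delim(hapf, check.names = FALSE, colClasses = "character")
    if (!all(c("sample_id", "phase") %in% names(h)))
        stop("haplotype table must have sample_id and phase columns")
    idx <- match(vm$variant_id, names(h))
    if (anyNA(idx))
        stop("haplotype table is missing columns for some variants")
    mat <- as.matrix(h[, idx, drop = FALSE])
    storage.mode(mat) <- "integer"
    HaplotypePanel(mat, vm,
                   data.frame(sample_id = h$sample_id,
                              phase = as.integer(h$phase)))
}

.writeHaplotypeTable <- function(data, path) {
    stopifnot(is(data, "HaplotypePanel"))
    utils::write.table(data@variants, paste0(path, ".hapvar.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    df <- cbind(data@sampleOf, as.data.frame(data@haplotypes))
    utils::write.table(df, paste0(path, ".hap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a phenotype/covariate table
#'
#' Tab-delimited with mandatory columns `sample_id` and `status`
#' (1 = case, 0 = control); any further numeric columns are covariates.
#'
#' @param file Path to the TSV.
#' @param genotypes Optional [GenotypeMatrix-class]; if given, every
#'   phenotyped sample must be present in it.
#' @return A `data.frame`.
#' @export
readPhenotypes <- function(file, genotypes = NULL) {
    ph <- utils::read.delim(file, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "status") %in% names(ph)))
        stop("phenotype table needs sample_id and status columns")
    if (anyNA(ph$status) || !all(ph$status %in% c(0, 1)))
        stop("status must be 0 (control) or 1 (case) with no missing values")
    if (!is.null(genotypes)) {
        miss <- setdiff(ph$sample_id, sampleIDs(genotypes))
        if (length(miss))
            stop("phenotyped samples absent from genotype data: ",
                 paste(utils::head(miss, 5), collapse = ", "))
    }
    ph
}

#' Apply standard cohort QC filters
#'
#' Filters in the fixed order used by standard GWAS tooling: (1) variants
#' with missingness above `max_variant_missing`, (2) samples with
#' missingness above `max_sample_missing` (computed on surviving variants),
#' (3) variants with minor allele frequency below `min_maf`, recomputed on
#' surviving samples.  Defaults correspond to the usual
#' `--geno 0.05 --mind 0.05 --maf 0.05`.
#'
#' @param g A [GenotypeMatrix-class].
#' @param max_variant_missing,max_sample_missing Maximum tolerated missing
#'   fraction per variant / per sample, in `[0, 1]`.
#' @param min_maf Minimum minor allele frequency, in `[0, 1]`.
#' @return A list with `genotypes` (filtered [GenotypeMatrix-class]) and
#'   `removed` (`data.frame` of removed ids with `type`, `reason`,
#'   `value`).
#' @export
qcFilter <- function(g, max_variant_missing = 0.05,
                     max_sample_missing = 0.05, min_maf = 0.05) {
    stopifnot(is(g, "GenotypeMatrix"),
              max_variant_missing >= 0, max_variant_missing <= 1,
              max_sample_missing >= 0, max_sample_missing <= 1,
              min_maf >= 0, min_maf <= 1)
    d <- g@dosages
    removed <- data.frame(id = character(), type = character(),
                          reason = character(), value = numeric(),
                          stringsAsFactors = FALSE)
    vmiss <- colMeans(is.na(d))
    dropv <- vmiss > max_variant_missing
    if (any(dropv))
        removed <- rbind(removed, data.frame(
            id = colnames(d)[dropv], type = "variant",
            reason = "missingness", value = vmiss[dropv]))
    d <- d[, !dropv, drop = FALSE]
    vm <- g@variants[!dropv, , drop = FALSE]

    smiss <- if (ncol(d)) rowMeans(is.na(d)) else rep(0, nrow(d))
    drops <- smiss > max_sample_missing
    if (any(drops))
        removed <- rbind(removed, data.frame(
            id = rownames(d)[drops], type = "sample",
            reason = "missingness", value = smiss[drops]))
    d <- d[!drops, , drop = FALSE]

    freq <- colMeans(d, na.rm = TRUE) / 2
    freq[is.nan(freq)] <- 0
    maf <- pmin(freq, 1 - freq)
    dropm <- maf < min_maf
    if (any(dropm))
        removed <- rbind(removed, data.frame(
            id = colnames(d)[dropm], type = "variant",
            reason = "maf", value = maf[dropm]))
    d <- d[, !dropm, drop = FALSE]
    vm <- vm[!dropm, , drop = FALSE]
    if (ncol(d) == 0L)
        warning("qcFilter removed all variants")
    list(genotypes = GenotypeMatrix(d, vm), removed = removed)
}

#' Per-group allele frequencies
#'
#' Frequency of a named allele per variant within each sample group:
#' allele count / (2 x non-missing samples in the group).
#'
#' @param g A [GenotypeMatrix-class].
#' @param groups Factor (or coercible) over samples partitioning them into
#'   groups, e.g. case/control status.
#' @param allele `"allele2"` (the counted allele, default) or `"allele1"`.
#' @return Numeric matrix, variants x groups.
#' @export
alleleStats <- function(g, groups, allele = c("allele2", "allele1")) {
    allele <- match.arg(allele)
    stopifnot(is(g, "GenotypeMatrix"))
    groups <- as.factor(groups)
    if (length(groups) != nSamples(g))
        stop("groups must have one entry per sample")
    d <- g@dosages
    out <- sapply(levels(groups), function(lv) {
        sub <- d[groups == lv, , drop = FALSE]
        cnt <- colSums(sub, na.rm = TRUE)
        nn <- colSums(!is.na(sub))
        f <- ifelse(nn > 0, cnt / (2 * nn), NA_real_)
        if (allele == "allele1") 1 - f else f
    })
    out <- matrix(out, nrow = ncol(d),
                  dimnames = list(colnames(d), levels(groups)))
    out
}

#' Principal components of the dosage matrix
#'
#' Plumbing covariates for population structure: missing dosages are
#' mean-imputed, columns centred and scaled to unit variance (monomorphic
#' columns dropped), and the first `k` right-singular-vector scores
#' returned.  Sign is fixed so the largest-magnitude loading of each
#' component is positive, making results deterministic.
#'
#' @param g A [GenotypeMatrix-class].
#' @param k Number of components (`k = 0` gives an `n x 0` matrix).
#' @return Numeric matrix `n x k` with columns `PC1..PCk` and sample ids as
#'   row names.
#' @export
pcaCovariates <- function(g, k = 2) {
    stopifnot(is(g, "GenotypeMatrix"), k >= 0)
    d <- g@dosages
    storage.mode(d) <- "double"
    if (k == 0)
        return(matrix(numeric(), nrow(d), 0,
                      dimnames = list(rownames(d), NULL)))
    cm <- colMeans(d, na.rm = TRUE)
    for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- cm[j]
    sds <- apply(d, 2, stats::sd)
    keep <- sds > 0
    x <- scale(d[, keep, drop = FALSE])
    sv <- svd(x, nu = min(k, min(dim(x))), nv = 0)
    if (k > length(sv$d) || k > sum(sv$d > 1e-8 * sv$d[1]))
        if (k > min(dim(x)))
            stop("k exceeds the rank of the dosage matrix")
    scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
    ## sign convention: largest-|u| entry of each component positive
    for (j in seq_len(k)) {
        i <- which.max(abs(scores[, j]))
        if (scores[i, j] < 0) scores[, j] <- -scores[, j]
    }
    dimnames(scores) <- list(rownames(d), paste0("PC", seq_len(k)))
    scores
}

#' Greedy r-squared window pruning
#'
#' A simple LD pruner: scans variants in map order and drops any variant
#' whose squared correlation with a retained variant inside the trailing
#' window exceeds `r2max`.
#'
#' @param g A [GenotypeMatrix-class].
#' @param window_size Number of preceding retained variants to compare
#'   against.
#' @param r2max Correlation-squared threshold above which a variant is
#'   dropped.
#' @return A [GenotypeMatrix-class] with the retained variants.
#' @export
ldPrune <- function(g, window_size = 25, r2max = 0.999) {
    stopifnot(is(g, "GenotypeMatrix"))
    d <- g@dosages
    storage.mode(d) <- "double"
    m <- ncol(d)
    keep <- logical(m)
    kept <- integer(0)
    for (j in seq_len(m)) {
        cand <- kept[kept > length(kept) - window_size]
        cand <- utils::tail(kept, window_size)
        ok <- TRUE
        for (i in cand) {
            r <- suppressWarnings(stats::cor(d[, i], d[, j],
                                             use = "pairwise.complete.obs"))
            if (!is.na(r) && r * r > r2max) { ok <- FALSE; break }
        }
        if (ok) { keep[j] <- TRUE; kept <- c(kept, j) }
    }
    g[, keep]
}
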