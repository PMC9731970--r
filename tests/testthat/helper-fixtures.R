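# Shared builders for small in-code fixtures.

toyMap <- function(m, chr = "1", spacing = 1000L, a1 = "A", a2 = "C") {
    variantMap(sprintf("v%03d", seq_len(m)), rep(chr, m),
               spacing * seq_len(m), rep(a1, m), rep(a2, m))
}

toyGenotypes <- function(dosage_matrix, map = NULL, samples = NULL) {
    d <- as.matrix(dosage_matrix)
    if (is.null(map)) map <- toyMap(ncol(d))
    if (!is.null(samples)) rownames(d) <- samples
    GenotypeMatrix(d, map)
}

# panel from a character vector of 0/1 strings, one per haplotype
toyPanel <- function(hapstrings, map = NULL) {
    h <- do.call(rbind, lapply(strsplit(hapstrings, ""), as.integer))
    if (is.null(map)) map <- toyMap(ncol(h))
    HaplotypePanel(h, map)
}

randomPanel <- function(n_hap, m, seed) {
    set.seed(seed)
    h <- matrix(rbinom(n_hap * m, 1, runif(1, 0.2, 0.8)), n_hap, m)
    if (n_hap %% 2L == 1L) h <- rbind(h, h[1, , drop = FALSE])
    HaplotypePanel(h[seq_len(n_hap + n_hap %% 2L), , drop = FALSE], toyMap(m))
}

# independent brute-force EHH oracle: enumerate extended haplotype strings
# from the core outward and apply the homozygosity formula directly
ehhOracle <- function(hap, pos, core, allele = NULL, cutoff = 0.05) {
    homSum <- function(strs) {
        cnt <- table(strs)
        sum(cnt * (cnt - 1))
    }
    if (is.null(allele)) {           # site-level
        rows <- seq_len(nrow(hap))
        S0 <- homSum(hap[, core])
        if (S0 == 0) return(NULL)
        denom <- S0
    } else {                         # allele-specific
        rows <- which(hap[, core] == allele)
        denom <- length(rows) * (length(rows) - 1)
    }
    walk <- function(dirIdx) {
        out_idx <- integer(0); out_ehh <- numeric(0)
        for (t in dirIdx) {
            span <- sort(c(core, t))
            strs <- apply(hap[rows, span[1]:span[2], drop = FALSE],
                          1, paste, collapse = "")
            e <- homSum(strs) / denom
            out_idx <- c(out_idx, t); out_ehh <- c(out_ehh, e)
            if (e < cutoff) break
        }
        list(idx = out_idx, ehh = out_ehh)
    }
    left <- walk(rev(seq_len(core - 1)))
    right <- walk(if (core < ncol(hap)) (core + 1):ncol(hap) else integer(0))
    idx <- c(rev(left$idx), core, right$idx)
    list(index = idx, ehh = c(rev(left$ehh), 1, right$ehh))
}
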