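## EHH / iHH computation, the case-vs-control XP-EHH statistic and windowed
## candidate-region calling.

#' Extended haplotype homozygosity decay curve
#'
#' Extends marker by marker in both directions from a core variant.  In
#' allele-specific mode the curve is computed over the haplotypes carrying
#' the core allele: at marker distance `d`,
#' `EHH = sum_h n_h (n_h - 1) / (n_c (n_c - 1))` over distinct extended
#' haplotypes among the `n_c` carriers.  Site-level mode pools all
#' haplotypes and normalizes the homozygosity sum by its value at the core
#' site.  Both start at 1 at the core and are non-increasing outward.
#' Extension stops when EHH falls below `cutoff` (the first below-cutoff
#' value is retained in the curve), at the chromosome border, or when an
#' inter-marker gap exceeds `max_gap_bp`.
#'
#' @param panel A [HaplotypePanel-class].
#' @param core Variant id (or index) of the core site.
#' @param focal `"site"` for site-level mode, or the core allele (`0`/`1`
#'   or an allele label from the variant map) for allele-specific mode.
#' @param cutoff EHH truncation limit (default 0.05).
#' @param max_gap_bp Optional maximum tolerated inter-marker gap.
#' @return An object of class `EHHCurve`: list with `core_id`, `core_bp`,
#'   `focal`, `position_bp`, `ehh`, `n_hap` and per-direction stop reasons
#'   (`"border"`, `"cutoff"`, `"gap"`).
#' @export
ehhCurve <- function(panel, core, focal = "site", cutoff = 0.05,
                     max_gap_bp = NULL) {
    stopifnot(is(panel, "HaplotypePanel"))
    vm <- panel@variants
    j <- if (is.character(core)) match(core, vm$variant_id) else as.integer(core)
    if (is.na(j) || j < 1L || j > nrow(vm))
        stop("core variant not found in the panel map")
    allele <- -1L
    if (!identical(focal, "site")) {
        allele <- if (focal %in% c(0, 1)) as.integer(focal)
                  else if (identical(focal, vm$allele1[j])) 0L
                  else if (identical(focal, vm$allele2[j])) 1L
                  else stop("focal allele does not match the core variant")
        carriers <- sum(panel@haplotypes[, j] == allele)
        if (carriers == sum(!is.na(panel@haplotypes[, j])) || carriers == 0L)
            stop("core variant is monomorphic for the focal allele")
        if (carriers < 2L)
            stop("allele-specific EHH needs >= 2 carrier haplotypes")
    }
    dec <- .ehh_decay(panel@haplotypes, j, allele, as.numeric(vm$position_bp),
                      cutoff, if (is.null(max_gap_bp)) -1 else max_gap_bp)
    structure(list(core_id = vm$variant_id[j],
                   core_bp = vm$position_bp[j],
                   focal = if (allele < 0) "site" else
                       c(vm$allele1[j], vm$allele2[j])[allele + 1L],
                   index = dec$index,
                   position_bp = vm$position_bp[dec$index],
                   ehh = dec$ehh,
                   n_hap = dec$n_hap,
                   cutoff = cutoff,
                   stop_left = dec$stop_left,
                   stop_right = dec$stop_right),
              class = "EHHCurve")
}

#' @export
print.EHHCurve <- function(x, ...) {
    cat(sprintf("EHHCurve at %s (%s mode, %d haplotypes)\n",
                x$core_id, if (identical(x$focal, "site")) "site-level"
                else paste0("allele ", x$focal), x$n_hap))
    cat(sprintf("  support: %d markers, %d..%d bp (stop: left %s, right %s)\n",
                length(x$ehh), min(x$position_bp), max(x$position_bp),
                x$stop_left, x$stop_right))
    invisible(x)
}

#' Integrate an EHH curve into iHH (bp)
#'
#' Trapezoidal integral of the decay curve over physical distance, in both
#' directions from the core, after setting EHH values below the curve's
#' cutoff to zero (no interpolation of the crossing point).  Curves
#' truncated at a chromosome border are integrated over their observed
#' support and flagged.
#'
#' @param curve An [ehhCurve()] result.
#' @return iHH in bp, with attributes `border` (logical) and `degenerate`.
#' @export
integrateIHH <- function(curve) {
    stopifnot(inherits(curve, "EHHCurve"))
    if (length(curve$ehh) == 0L)
        return(structure(0, border = FALSE, degenerate = TRUE))
    e <- ifelse(curve$ehh < curve$cutoff, 0, curve$ehh)
    p <- as.numeric(curve$position_bp)
    area <- if (length(e) > 1L)
        sum(diff(p) * (utils::head(e, -1) + utils::tail(e, -1)) / 2)
    else 0
    structure(area,
              border = curve$stop_left == "border" ||
                  curve$stop_right == "border",
              degenerate = FALSE)
}

#' Cross-population XP-EHH scan
#'
#' At every variant, computes the site-level iHH in each panel and the raw
#' statistic `ln(iHH_A / iHH_B)` (population A conventionally the cases, so
#' positive scores mean longer case haplotypes).  Raw scores are
#' standardized by their genome-wide mean and standard deviation, and
#' two-sided normal p-values reported as `-log10(p)`.  Variants with zero
#' iHH in either population are dropped and reported.
#'
#' @param panel_A Case [HaplotypePanel-class].
#' @param panel_B Control [HaplotypePanel-class]; must share `panel_A`'s
#'   variant map.
#' @param cutoff EHH truncation limit passed to the decay computation.
#' @param max_gap_bp Optional maximum tolerated inter-marker gap.
#' @param discard_border If `TRUE`, variants whose decay was truncated at a
#'   chromosome border in either population are dropped rather than
#'   integrated over observed support.
#' @return An object of class `XPEHHResult`: `data.frame` with columns
#'   `variant_id`, `chromosome`, `position_bp`, `ihh_A`, `ihh_B`, `raw`,
#'   `score` (standardized), `logp`, plus attributes `dropped` (variant
#'   ids) and `n_hap` (haplotype counts used).
#' @export
xpehhScan <- function(panel_A, panel_B, cutoff = 0.05, max_gap_bp = NULL,
                      discard_border = FALSE) {
    stopifnot(is(panel_A, "HaplotypePanel"), is(panel_B, "HaplotypePanel"))
    vmA <- panel_A@variants; vmB <- panel_B@variants
    if (!identical(vmA$variant_id, vmB$variant_id) ||
        !identical(vmA$position_bp, vmB$position_bp))
        stop("panels must share an identical variant map")
    gap <- if (is.null(max_gap_bp)) -1 else max_gap_bp
    iA <- .site_ihh_all(panel_A@haplotypes, as.numeric(vmA$position_bp),
                        cutoff, gap)
    iB <- .site_ihh_all(panel_B@haplotypes, as.numeric(vmB$position_bp),
                        cutoff, gap)
    drop <- iA$ihh <= 0 | iB$ihh <= 0 | iA$degenerate | iB$degenerate
    if (discard_border) drop <- drop | iA$border | iB$border
    raw <- rep(NA_real_, nrow(vmA))
    ## difference of logs (not log of ratio) so that swapping the panels
    ## negates every raw value bit-exactly
    raw[!drop] <- log(iA$ihh[!drop]) - log(iB$ihh[!drop])
    sdr <- stats::sd(raw[!drop])
    if (!is.finite(sdr) || sdr == 0)
        stop("raw XP-EHH scores have zero variance; standardization undefined")
    score <- (raw - mean(raw[!drop])) / sdr
    logp <- -(stats::pnorm(-abs(score), log.p = TRUE) + log(2)) / log(10)
    out <- data.frame(variant_id = vmA$variant_id,
                      chromosome = vmA$chromosome,
                      position_bp = vmA$position_bp,
                      ihh_A = iA$ihh, ihh_B = iB$ihh,
                      raw = raw, score = score, logp = logp,
                      stringsAsFactors = FALSE)[!drop, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "dropped") <- vmA$variant_id[drop]
    attr(out, "n_hap") <- c(A = nrow(panel_A@haplotypes),
                            B = nrow(panel_B@haplotypes))
    class(out) <- c("XPEHHResult", "data.frame")
    out
}

#' Call candidate regions under selection from an XP-EHH scan
#'
#' Slides windows of `window_bp` on a `step_bp` grid along each
#' chromosome; a window qualifies when it holds at least `min_n_extreme`
#' variants with `-log10(p) >= threshold_logp`.  Overlapping or adjacent
#' qualifying windows merge into one region reporting its variant counts,
#' percentage of extreme variants, and the top variant by `|score|`.
#'
#' @param scores An [xpehhScan()] result (or compatible `data.frame`).
#' @param threshold_logp Extreme-variant bound on `-log10(p)` (default 4).
#' @param window_bp Window length in bp (default 1 Mb).
#' @param step_bp Grid step in bp (default 0.1 Mb, the dense grid; region
#'   bounds are aligned to this grid).
#' @param min_n_extreme Minimum extreme variants per qualifying window.
#' @return `data.frame` with one row per region: `chromosome`, `start_bp`,
#'   `end_bp`, `n_variants`, `n_extreme`, `pct_extreme`, `top_variant`,
#'   `top_score`, `top_logp`.
#' @export
callCandidateRegions <- function(scores, threshold_logp = 4,
                                 window_bp = 1e6, step_bp = 1e5,
                                 min_n_extreme = 2) {
    empty <- data.frame(chromosome = character(), start_bp = numeric(),
                        end_bp = numeric(), n_variants = integer(),
                        n_extreme = integer(), pct_extreme = numeric(),
                        top_variant = character(), top_score = numeric(),
                        top_logp = numeric(), stringsAsFactors = FALSE)
    if (nrow(scores) == 0L) return(empty)
    out <- lapply(split(seq_len(nrow(scores)), scores$chromosome),
                  function(ii) {
        s <- scores[ii, , drop = FALSE]
        s <- s[order(s$position_bp), , drop = FALSE]
        ext <- s$position_bp[s$logp >= threshold_logp]
        if (length(ext) < min_n_extreme) return(NULL)
        k0 <- floor((min(ext) - window_bp) / step_bp) + 1
        k1 <- floor(max(ext) / step_bp)
        starts <- (k0:k1) * step_bp
        starts <- starts[starts + window_bp > 0]
        next_in <- vapply(starts, function(w)
            sum(ext >= w & ext < w + window_bp), integer(1))
        qual <- next_in >= min_n_extreme
        if (!any(qual)) return(NULL)
        qs <- starts[qual]
        brk <- c(TRUE, diff(qs) > window_bp)  # gap beyond adjacency
        rid <- cumsum(brk)
        do.call(rbind, lapply(split(qs, rid), function(ws) {
            lo <- min(ws); hi <- max(ws) + window_bp
            inreg <- s$position_bp >= lo & s$position_bp < hi
            sub <- s[inreg, , drop = FALSE]
            nx <- sum(sub$logp >= threshold_logp)
            top <- sub[which.max(abs(sub$score)), ]
            data.frame(chromosome = sub$chromosome[1],
                       start_bp = lo, end_bp = hi,
                       n_variants = nrow(sub), n_extreme = nx,
                       pct_extreme = 100 * nx / nrow(sub),
                       top_variant = top$variant_id,
                       top_score = top$score, top_logp = top$logp,
                       stringsAsFactors = FALSE)
        }))
    })
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(out)) return(empty)
    rownames(out) <- NULL
    out[order(out$chromosome, out$start_bp), , drop = FALSE]
}

#' Write XP-EHH score track and region table to TSV
#'
#' @param scores An [xpehhScan()] result.
#' @param regions A [callCandidateRegions()] result.
#' @param prefix Output path prefix; writes `<prefix>.xpehh.tsv` and
#'   `<prefix>.regions.tsv`.
#' @return `prefix`, invisibly.
#' @export
writeSelectionResults <- function(scores, regions, prefix) {
    utils::write.table(as.data.frame(scores), paste0(prefix, ".xpehh.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(regions, paste0(prefix, ".regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(prefix)
}
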