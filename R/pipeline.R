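## Config-driven orchestration: QC -> PCA covariates -> mixture-model GWAS
## -> locus calling -> risk index -> XP-EHH -> region calling, with a run
## log and per-stage seeds derived deterministically from one global seed.

#' Split a haplotype panel by case/control status
#'
#' @param panel A [HaplotypePanel-class].
#' @param pheno `data.frame` with `sample_id` and binary `status`.
#' @return List with `case` and `control` [HaplotypePanel-class]s.
#' @export
splitPanelByStatus <- function(panel, pheno) {
    st <- pheno$status[match(panel@sampleOf$sample_id, pheno$sample_id)]
    if (anyNA(st)) stop("every panel sample needs a status")
    list(case = panel[st == 1, ], control = panel[st == 0, ])
}

#' Assemble a pipeline configuration
#'
#' Inputs are either files (`bfile` PLINK-binary prefix, `hap` haplotype
#' table prefix, `pheno` TSV) or a [simulationConfig()] under `simulate`.
#'
#' @param input List with `bfile`, `hap`, `pheno` paths (any may be `NULL`
#'   when simulating).
#' @param simulate Optional [simulationConfig()]; when given, the cohort is
#'   generated instead of read.
#' @param qc List of QC thresholds `geno`, `mind`, `maf` (see
#'   [qcFilter()]).
#' @param pca_k Number of principal-component covariates.
#' @param bayesr Arguments for [bayesRConfig()] (seed is supplied by the
#'   pipeline).
#' @param effect_threshold,top_n Effect-variant calling rule (see
#'   [callEffectVariants()]).
#' @param risk_scheme Risk-index weighting, `"count"` or `"half"`.
#' @param xpehh List of scan/region parameters: `cutoff`, `max_gap_bp`,
#'   `threshold_logp`, `window_bp`, `step_bp`, `min_n_extreme`.
#' @param out_dir Output directory (created if absent).
#' @param seed Global seed; per-stage streams are derived from it so
#'   stages can be rerun in isolation.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(input = list(bfile = NULL, hap = NULL,
                                        pheno = NULL),
                           simulate = NULL,
                           qc = list(geno = 0.05, mind = 0.05, maf = 0.05),
                           pca_k = 2,
                           bayesr = list(),
                           effect_threshold = 1e-4, top_n = NULL,
                           risk_scheme = "count",
                           xpehh = list(cutoff = 0.05, max_gap_bp = NULL,
                                        threshold_logp = 4, window_bp = 1e6,
                                        step_bp = 1e5, min_n_extreme = 2),
                           out_dir = "breedscan_out", seed = 1) {
    cfg <- list(input = input, simulate = simulate, qc = qc,
                pca_k = as.integer(pca_k), bayesr = bayesr,
                effect_threshold = effect_threshold, top_n = top_n,
                risk_scheme = risk_scheme, xpehh = xpehh,
                out_dir = out_dir, seed = as.integer(seed))
    if (is.null(cfg$simulate)) {
        for (f in c("bfile", "hap", "pheno")) {
            if (is.null(cfg$input[[f]]))
                stop(sprintf("config field input.%s is required unless simulating", f))
        }
        checks <- c(paste0(cfg$input$bfile, ".bed"),
                    paste0(cfg$input$hap, ".hap.tsv"),
                    cfg$input$pheno)
        names(checks) <- c("input.bfile", "input.hap", "input.pheno")
        for (f in names(checks))
            if (!file.exists(checks[[f]]))
                stop(sprintf("config field %s points to a missing file: %s",
                             f, checks[[f]]))
    } else if (!inherits(cfg$simulate, "SimulationConfig")) {
        stop("simulate must be a simulationConfig()")
    }
    if (!cfg$risk_scheme %in% c("count", "half"))
        stop("risk_scheme must be count or half")
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Read a flat key/value config file
#'
#' One `key = value` pair per line; `#` starts a comment.  Dots in keys
#' nest (`qc.maf = 0.05`), commas make numeric vectors, and unquoted
#' `true`/`false` become logicals.
#'
#' @param file Path to the config file.
#' @return Nested named list.
#' @export
readFlatConfig <- function(file) {
    lines <- readLines(file)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    out <- list()
    for (ln in lines) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        if (length(kv) < 2L) stop("malformed config line: ", ln)
        key <- trimws(kv[1])
        val <- trimws(paste(kv[-1], collapse = "="))
        parts <- strsplit(val, ",", fixed = TRUE)[[1]]
        parts <- trimws(parts)
        num <- suppressWarnings(as.numeric(parts))
        parsed <- if (!anyNA(num)) num
                  else if (all(tolower(parts) %in% c("true", "false")))
                      tolower(parts) == "true"
                  else parts
        path <- strsplit(key, ".", fixed = TRUE)[[1]]
        out <- .assignNested(out, path, parsed)
    }
    out
}

.assignNested <- function(lst, path, value) {
    if (length(path) == 1L) {
        lst[[path]] <- value
        return(lst)
    }
    if (is.null(lst[[path[1]]])) lst[[path[1]]] <- list()
    lst[[path[1]]] <- .assignNested(lst[[path[1]]], path[-1], value)
    lst
}

.logLine <- function(con, stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, msg)
    writeLines(line, con)
    message(line)
}

.stageTry <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
             call. = FALSE))
}

#' Run the full mapping pipeline
#'
#' Sequences QC, PCA covariates, the mixture-model GWAS, locus calling,
#' the risk index, the XP-EHH case/control scan and candidate-region
#' calling.  Every stage writes its outputs as TSV under `out_dir` and is
#' logged with its parameters and derived seed; rerunning with the same
#' config and seed reproduces all outputs.
#'
#' @param cfg A [pipelineConfig()].
#' @return Invisible list with `loci`, `risk_index`, `scores`, `regions`,
#'   `bayesr`, `qc_report` and the paths written.
#' @export
runPipeline <- function(cfg) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    logf <- file.path(cfg$out_dir, "run.log")
    con <- file(logf, "w")
    on.exit(close(con))
    .logLine(con, "init", sprintf("breedscan %s, seed %d",
                                  as.character(utils::packageVersion("breedscan")),
                                  cfg$seed))

    ## stage 1: input
    if (!is.null(cfg$simulate)) {
        sim <- cfg$simulate
        sim$seed <- .stageSeed(cfg$seed, 21L)
        cohort <- .stageTry("simulate", simulateCohort(sim))
        geno <- cohort$genotypes; panel <- cohort$panel
        pheno <- cohort$phenotypes
        .logLine(con, "simulate", sprintf(
            "n=%d m=%d sweep=%s", sim$n_samples, sim$m_variants,
            sim$sweep$group))
    } else {
        geno <- .stageTry("input", readGenotypes(cfg$input$bfile, "plink_binary"))
        panel <- .stageTry("input", readGenotypes(cfg$input$hap, "haplotype_table"))
        pheno <- .stageTry("input", readPhenotypes(cfg$input$pheno, geno))
        .logLine(con, "input", sprintf("%d samples, %d variants",
                                       nSamples(geno), nVariants(geno)))
    }

    ## stage 2: QC
    qc <- .stageTry("qc", qcFilter(geno, cfg$qc$geno, cfg$qc$mind, cfg$qc$maf))
    geno <- qc$genotypes
    utils::write.table(qc$removed, file.path(cfg$out_dir, "qc_removed.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .logLine(con, "qc", sprintf(
        "geno<=%.3g mind<=%.3g maf>=%.3g; kept %d samples x %d variants",
        cfg$qc$geno, cfg$qc$mind, cfg$qc$maf, nSamples(geno), nVariants(geno)))
    keepS <- sampleIDs(geno)
    pheno <- pheno[pheno$sample_id %in% keepS, , drop = FALSE]
    panel <- panel[panel@sampleOf$sample_id %in% keepS,
                   variantMapOf(panel)$variant_id %in%
                       variantMapOf(geno)$variant_id]

    ## stage 3: PCA covariates
    pcs <- .stageTry("pca", pcaCovariates(geno, cfg$pca_k))
    .logLine(con, "pca", sprintf("k=%d", cfg$pca_k))

    ## stage 4: mixture-model GWAS
    bcfg <- do.call(bayesRConfig,
                    c(cfg$bayesr, list(seed = .stageSeed(cfg$seed, 22L))))
    y <- pheno$status[match(sampleIDs(geno), pheno$sample_id)]
    fit <- .stageTry("bayesr", fitBayesR(y, geno, pcs, bcfg))
    writeBayesRResult(fit, file.path(cfg$out_dir, "bayesr"))
    .logLine(con, "bayesr", sprintf(
        "iters=%d burnin=%d chains=%d seed=%d varG=%.4g varE=%.4g",
        bcfg$n_iterations, bcfg$burn_in, bcfg$n_chains, bcfg$seed,
        fit@varG, fit@varE))

    ## stage 5: loci
    ev <- .stageTry("loci", callEffectVariants(fit, cfg$effect_threshold,
                                               cfg$top_n))
    loci <- .stageTry("loci", mergeIntoLoci(ev, geno, pheno, covariates = pcs))
    utils::write.table(loci, file.path(cfg$out_dir, "loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .logLine(con, "loci", sprintf("%d effect variants -> %d loci",
                                  nrow(ev), nrow(loci)))

    ## stage 6: risk index
    ri <- .stageTry("riskindex", computeRiskIndex(geno, loci, cfg$risk_scheme))
    ri$status <- pheno$status[match(ri$sample_id, pheno$sample_id)]
    utils::write.table(ri, file.path(cfg$out_dir, "risk_index.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(loci) && stats::sd(ri$index) > 0) {
        wt <- welchTTest(ri$index[ri$status == 1], ri$index[ri$status == 0])
        .logLine(con, "riskindex", sprintf(
            "scheme=%s t=%.3g df=%.1f p=%.3g means %.3g/%.3g",
            cfg$risk_scheme, wt$t, wt$df, wt$p, wt$mean_x, wt$mean_y))
    } else {
        .logLine(con, "riskindex", "no loci or constant index; test skipped")
    }

    ## stage 7: XP-EHH scan
    halves <- .stageTry("xpehh", splitPanelByStatus(panel, pheno))
    scores <- .stageTry("xpehh", xpehhScan(
        halves$case, halves$control, cutoff = cfg$xpehh$cutoff,
        max_gap_bp = cfg$xpehh$max_gap_bp))
    .logLine(con, "xpehh", sprintf(
        "cutoff=%.3g; %d variants scored, %d dropped", cfg$xpehh$cutoff,
        nrow(scores), length(attr(scores, "dropped"))))

    ## stage 8: candidate regions
    regions <- .stageTry("regions", callCandidateRegions(
        scores, cfg$xpehh$threshold_logp, cfg$xpehh$window_bp,
        cfg$xpehh$step_bp, cfg$xpehh$min_n_extreme))
    writeSelectionResults(scores, regions, file.path(cfg$out_dir, "selection"))
    .logLine(con, "regions", sprintf(
        "logp>=%.3g window=%g step=%g min_extreme=%d -> %d regions",
        cfg$xpehh$threshold_logp, cfg$xpehh$window_bp, cfg$xpehh$step_bp,
        cfg$xpehh$min_n_extreme, nrow(regions)))

    invisible(list(loci = loci, risk_index = ri, scores = scores,
                   regions = regions, bayesr = fit, qc_report = qc$removed,
                   out_dir = cfg$out_dir))
}
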