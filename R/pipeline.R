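#' Default pipeline configuration
#'
#' All stage parameters with their standard defaults: CPM >= 1 in at least
#' half the samples, network QC (at most 7 zero-count samples, mean >= 0.5,
#' SD >= 0.2), top-3500 connectivity pre-selection, scale-free R2 cutoff 0.9,
#' minimum module size 30, eigengene-trait gate |r| > 0.5 with p <= 0.1,
#' membership gate kME 0.6, differential-connectivity powers 4 (HFE) and 20
#' (LFE) with |KDiff| > 0.6, and enrichment padj <= 0.1. The configuration
#' round-trips losslessly through YAML.
#'
#' @param seed global seed; expanded into per-stage child seeds.
#' @return nested named list of class \code{efnetConfig}.
#' @export
defaultRunConfig <- function(seed = 1L) {
    structure(list(
        seed = as.integer(seed),
        simulate = TRUE,
        inputs = list(bw = NULL, dmi = NULL, counts = NULL, lengths = NULL,
                      annotation = NULL),
        phenotypes = list(n_per_group = 20, outlier_k = 2.5),
        prep = list(min_cpm = 1, min_cpm_samples = NULL, max_zero_samples = 7,
                    mean_min = 0.5, sd_min = 0.2,
                    qc_direction = "informative", n_top = 3500,
                    fpkm_quartile = 0.75),
        network = list(beta = NULL, r2_cut = 0.9, min_module_size = 30,
                       cut_quantile = 0.99, r_threshold = 0.5,
                       p_threshold = 0.1, kme_own = 0.6, kme_other = 0.6),
        diffcoexp = list(beta_hfe = 4, beta_lfe = 20, threshold = 0.6),
        enrichment = list(padj_cut = 0.1)), class = "efnetConfig")
}

.mergeConfig <- function(base, user) {
    for (nm in names(user)) {
        if (is.list(base[[nm]]) && is.list(user[[nm]]))
            base[nm] <- list(.mergeConfig(base[[nm]], user[[nm]]))
        else base[nm] <- list(user[[nm]])   # [nm] <- list(): keeps NULLs
    }
    base
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (or takes a list) of overrides and merges it over
#' \code{\link{defaultRunConfig}}, so a config file only needs to state
#' deviations from the defaults.
#'
#' @param config path to a YAML file, or a named list of overrides.
#' @return an \code{efnetConfig} list.
#' @export
loadRunConfig <- function(config = list()) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    stopifnot(is.list(config))
    cfg <- .mergeConfig(defaultRunConfig(), config)
    cfg$seed <- as.integer(cfg$seed)
    structure(cfg, class = "efnetConfig")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> feed-efficiency traits -> expression
#' normalisation and filtering -> co-expression network and modules ->
#' differential connectivity -> term enrichment, from one configuration.
#' When \code{outdir} is given, every stage output is written as TSV along
#' with \code{report.txt} and the resolved configuration
#' (\code{resolved_config.yaml}).
#'
#' @param config an \code{efnetConfig}, a list of overrides, or a YAML path.
#' @param outdir optional output directory.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the phenotype table, expression objects,
#'   soft-threshold scan, network, module set, trait-module table, KDiff
#'   table, enrichment results, per-stage gene counts and the report lines.
#' @export
runPipeline <- function(config = list(), outdir = NULL, quiet = FALSE) {
    cfg <- loadRunConfig(if (inherits(config, "efnetConfig")) unclass(config)
                         else config)
    say <- function(...) if (!quiet) message(sprintf(...))
    report <- character(0)
    log <- function(...) {
        line <- sprintf(...)
        say("%s", line)
        report <<- c(report, line)
    }

    ## ---- inputs -----------------------------------------------------------
    if (isTRUE(cfg$simulate)) {
        trial <- simulateFeedTrial(trialSimConfig(seed = cfg$seed))
        pheno <- trial$phenotypes
    } else {
        ins <- cfg$inputs
        for (f in c("bw", "dmi", "counts", "lengths", "annotation"))
            if (is.null(ins[[f]]) || !file.exists(ins[[f]]))
                stop("input file missing or not found: ", f)
        pheno <- readPhenotypes(ins$bw, ins$dmi)
        trial <- NULL
    }

    ## ---- phenotypes -------------------------------------------------------
    pheno <- computeFeedTraits(pheno, nPerGroup = cfg$phenotypes$n_per_group,
                               outlierK = cfg$phenotypes$outlier_k)
    tr <- feedTraits(pheno)
    log("phenotypes: %d animals, %d excluded (ADG outliers), %d per group",
        nrow(tr), sum(tr$excluded), cfg$phenotypes$n_per_group)

    if (isTRUE(cfg$simulate)) {
        sim <- simulateExpression(exprSimConfig(seed = cfg$seed), pheno)
        counts <- sim$counts
        ann <- simulateAnnotation(
            rownames(counts),
            plantedTermGenes = names(sim$truth$module)[
                sim$truth$module == sim$truth$trait_modules[1]],
            seed = cfg$seed)
        annotation <- ann$annotation
        truth <- list(trial = trial$truth, genes = sim$truth,
                      planted_term = ann$truth$planted_term)
    } else {
        lens <- readGeneLengths(cfg$inputs$lengths)
        counts <- readCounts(cfg$inputs$counts, lengths = lens)
        seqIds <- intersect(colnames(counts), tr$animal_id)
        colData(counts)$group <- tr$group[match(colnames(counts),
                                                tr$animal_id)]
        counts <- as(counts, "ExprMatrix")
        metadata(counts)$unit <- "counts"
        annotation <- readAnnotation(cfg$inputs$annotation)
        truth <- NULL
    }
    log("expression: %d genes x %d samples", nrow(counts), ncol(counts))

    ## ---- normalisation and filters ---------------------------------------
    cpm <- computeCPM(counts)
    minS <- cfg$prep$min_cpm_samples
    if (is.null(minS)) minS <- ceiling(ncol(cpm) / 2)
    cpmKeep <- filterMinCPM(cpm, minCPM = cfg$prep$min_cpm, minSamples = minS)
    log("CPM filter (>= %g CPM in >= %d samples): %d of %d genes kept",
        cfg$prep$min_cpm, minS, sum(cpmKeep), length(cpmKeep))

    fpkm <- computeFPKM(counts, quartile = cfg$prep$fpkm_quartile)
    qcKeep <- qcFilterForNetwork(fpkm,
                                 maxZeroSamples = cfg$prep$max_zero_samples,
                                 meanMin = cfg$prep$mean_min,
                                 sdMin = cfg$prep$sd_min,
                                 direction = cfg$prep$qc_direction)
    fpkmQC <- as(fpkm[qcKeep, ], "ExprMatrix")
    metadata(fpkmQC)$unit <- "FPKM"
    log("network QC filter: %d of %d genes kept", sum(qcKeep), length(qcKeep))

    top <- suppressWarnings(selectTopConnected(fpkmQC, nKeep = cfg$prep$n_top))
    log("connectivity pre-selection: %d genes retained", nrow(top))

    ## ---- co-expression network -------------------------------------------
    scan <- NULL
    beta <- cfg$network$beta
    if (is.null(beta)) {
        scan <- suppressWarnings(
            pickSoftThreshold(top, r2Cut = cfg$network$r2_cut))
        beta <- chosenBeta(scan)
        r2 <- scan@fits$r2[scan@fits$beta == beta]
        log("soft threshold: beta = %g (scale-free R2 = %.3f)", beta, r2)
    } else log("soft threshold: beta = %g (fixed)", beta)
    net <- buildNetwork(top, beta = beta)
    modules <- clusterModules(net,
                              minModuleSize = cfg$network$min_module_size,
                              cutQuantile = cfg$network$cut_quantile)
    labels <- moduleLabels(modules)
    sizes <- sort(table(labels[labels != "grey"]), decreasing = TRUE)
    log("modules: %d detected (sizes: %s); %d genes grey", length(sizes),
        paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
        sum(labels == "grey"))

    me <- moduleEigengenes(top, modules)
    traits <- tr[match(colnames(top), tr$animal_id), c("rfi", "rig")]
    tc <- moduleTraitCorrelation(me, traits)
    sel <- selectTraitModules(tc, rThreshold = cfg$network$r_threshold,
                              pThreshold = cfg$network$p_threshold)
    log("trait-associated modules: %s",
        if (nrow(sel)) paste(sprintf("%s (%s)", sel$module, sel$pattern),
                             collapse = ", ") else "none")
    kme <- moduleMembership(top, me)
    memberGenes <- filterByMembership(kme, labels,
                                      ownMin = cfg$network$kme_own,
                                      otherMax = cfg$network$kme_other)

    ## ---- differential connectivity ---------------------------------------
    kd <- computeKDiff(fpkmQC, betaHFE = cfg$diffcoexp$beta_hfe,
                       betaLFE = cfg$diffcoexp$beta_lfe,
                       threshold = cfg$diffcoexp$threshold)
    dc <- selectDifferentiallyConnected(kd)
    log("differential connectivity: %d HFE-connected, %d LFE-connected (of %d)",
        length(dc$hfe), length(dc$lfe), nrow(kdiffValues(kd)))

    ## ---- enrichment -------------------------------------------------------
    background <- rownames(counts)
    enr <- list()
    for (mod in sel$module) {
        genes <- memberGenes[[mod]]
        if (length(genes))
            enr[[paste0("module_", mod)]] <-
                enrichTerms(genes, background, annotation,
                            padjCut = cfg$enrichment$padj_cut)
    }
    for (side in c("hfe", "lfe"))
        if (length(dc[[side]]))
            enr[[paste0("diffcoexp_", side)]] <-
                enrichTerms(dc[[side]], background, annotation,
                            padjCut = cfg$enrichment$padj_cut)
    nSig <- vapply(enr, function(e) sum(e$significant), integer(1))
    log("enrichment: %s",
        if (length(enr)) paste(sprintf("%s: %d significant terms",
                                       names(enr), nSig), collapse = "; ")
        else "no gene lists to test")

    res <- list(config = cfg, phenotypes = pheno, counts = counts,
                cpm_keep = cpmKeep, fpkm = fpkmQC, top = top, scan = scan,
                network = net, modules = modules, eigengenes = me,
                trait_cor = tc, trait_modules = sel,
                module_genes = memberGenes, kdiff = kd,
                diff_connected = dc, enrichment = enr,
                annotation = annotation, truth = truth, report = report)

    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        writeTSV(tr, file.path(outdir, "traits.tsv"))
        writeTSV(data.frame(gene_id = names(cpmKeep), kept = cpmKeep),
                 file.path(outdir, "cpm_filter.tsv"))
        writeCounts(fpkmQC, file.path(outdir, "fpkm_qc.tsv"))
        writeTSV(data.frame(gene_id = names(labels), module = labels,
                            retained = names(labels) %in%
                                unlist(memberGenes)),
                 file.path(outdir, "modules.tsv"))
        writeTSV(data.frame(sample = rownames(me), me, check.names = FALSE),
                 file.path(outdir, "eigengenes.tsv"))
        tcOut <- tc
        tcOut$selected <- tcOut$module %in% sel$module
        writeTSV(tcOut, file.path(outdir, "module_trait.tsv"))
        writeTSV(kdiffValues(kd), file.path(outdir, "kdiff.tsv"))
        for (nm in names(enr))
            writeTSV(enr[[nm]], file.path(outdir,
                                          paste0("enrich_", nm, ".tsv")))
        writeLines(report, file.path(outdir, "report.txt"))
        yaml::write_yaml(unclass(cfg),
                         file.path(outdir, "resolved_config.yaml"))
    }
    invisible(res)
}
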