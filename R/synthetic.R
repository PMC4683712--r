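#' @importFrom MASS mvrnorm
NULL

# one global seed expands into independent per-component child seeds so that
# adding a component never perturbs the draws of another
.childSeed <- function(seed, offset) {
    (as.numeric(seed) * 48271 + offset * 16807) %% 2147483629
}

#' Feeding-trial simulation configuration
#'
#' Defaults emulate a 70-day trial on 98 steers entering at 376 +/- 29 kg,
#' weighed every 14 days, with intake driven by gain and metabolic weight.
#' The planted intake/gain residual pair is bivariate normal with SDs
#' \code{rfiSD} and \code{rwgSD} and correlation \code{residCor}; these set
#' the joint distribution of the residual feed-intake and residual-gain
#' traits that the downstream regressions recover.
#'
#' @param nAnimals number of animals (default 98).
#' @param weighDays weigh-day offsets, strictly increasing from 0.
#' @param bw0Mean,bw0SD entry body weight mean/SD (kg).
#' @param adgMean,adgSD systematic average daily gain mean/SD (kg/d).
#' @param bwNoiseSD weighing error SD (kg).
#' @param dmiCoefficients intercept, per-unit-ADG and per-unit-MBW^0.75
#'   coefficients of the intake model (kg/d).
#' @param rfiSD SD of the planted intake residual (kg/d, default 0.90).
#' @param rwgSD SD of the planted gain residual (kg/d, default 0.35).
#' @param residCor correlation of the planted residual pair (default -0.60).
#' @param seed integer seed.
#' @return a validated configuration list of class \code{TrialSimConfig}.
#' @export
trialSimConfig <- function(nAnimals = 98,
                           weighDays = c(0, 14, 28, 42, 56, 70),
                           bw0Mean = 376, bw0SD = 29,
                           adgMean = 1.86, adgSD = 0.30,
                           bwNoiseSD = 4,
                           dmiCoefficients = c(intercept = -0.5, adg = 1.5,
                                               mbw075 = 0.09),
                           rfiSD = 0.90, rwgSD = 0.35, residCor = -0.60,
                           seed = 1L) {
    stopifnot(nAnimals > 0, length(weighDays) >= 2,
              all(diff(weighDays) > 0), weighDays[1] == 0,
              bw0SD >= 0, adgSD >= 0, bwNoiseSD >= 0,
              rfiSD >= 0, rwgSD >= 0, abs(residCor) <= 1,
              length(dmiCoefficients) == 3)
    structure(list(nAnimals = nAnimals, weighDays = weighDays,
                   bw0Mean = bw0Mean, bw0SD = bw0SD, adgMean = adgMean,
                   adgSD = adgSD, bwNoiseSD = bwNoiseSD,
                   dmiCoefficients = dmiCoefficients, rfiSD = rfiSD,
                   rwgSD = rwgSD, residCor = residCor,
                   seed = as.integer(seed)),
              class = "TrialSimConfig")
}

#' Draw planted intake/gain residual pairs
#'
#' Samples (RFI, RWG) pairs from the generator's bivariate-normal residual
#' model. These are the ground-truth residuals injected into simulated intake
#' and gain; RIG follows as RWG - RFI.
#'
#' @param n number of animals.
#' @param rfiSD,rwgSD,residCor joint distribution parameters (defaults as in
#'   \code{\link{trialSimConfig}}).
#' @param seed integer seed (NULL to use the current RNG state).
#' @return data.frame with columns rfi, rwg.
#' @export
simulateResidualPairs <- function(n, rfiSD = 0.90, rwgSD = 0.35,
                                  residCor = -0.60, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    Sigma <- matrix(c(rfiSD^2, residCor * rfiSD * rwgSD,
                      residCor * rfiSD * rwgSD, rwgSD^2), 2)
    if (rfiSD == 0 || rwgSD == 0) {
        e <- cbind(stats::rnorm(n, 0, rfiSD), stats::rnorm(n, 0, rwgSD))
    } else {
        e <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = Sigma)
    }
    data.frame(rfi = e[, 1], rwg = e[, 2])
}

#' Simulate a feeding trial
#'
#' Generates per-animal body-weight series and intake. Body weight grows
#' linearly: \code{bw0 + adg * day + weighing noise}, where the realised ADG
#' is the systematic gain plus the planted gain residual. Mean daily intake
#' follows the intake model
#' \code{DMI = b0 + b1 * ADG + b2 * (mean BW)^0.75 + planted intake residual},
#' so the downstream residual-trait regressions recover the planted pair.
#'
#' @param config a \code{\link{trialSimConfig}}.
#' @return list with \code{phenotypes} (a \linkS4class{PhenotypeTable}) and
#'   \code{truth} (data.frame: animal_id, rfi_planted, rwg_planted, adg_sys).
#' @export
simulateFeedTrial <- function(config = trialSimConfig()) {
    stopifnot(inherits(config, "TrialSimConfig"))
    n <- config$nAnimals
    if (n <= 0) stop("nAnimals must be positive")
    if (length(config$weighDays) < 3)
        stop("need at least 3 weigh days for a robust gain slope")
    ids <- sprintf("A%03d", seq_len(n))

    set.seed(.childSeed(config$seed, 1))
    bw0 <- stats::rnorm(n, config$bw0Mean, config$bw0SD)
    adgSys <- stats::rnorm(n, config$adgMean, config$adgSD)

    res <- simulateResidualPairs(n, config$rfiSD, config$rwgSD,
                                 config$residCor,
                                 seed = .childSeed(config$seed, 2))
    # the gain residual enters the observed gain through its intake-orthogonal
    # component only: OLS residuals are orthogonal to the regressors, so any
    # intake-correlated part inside ADG would contaminate the recovered RFI
    gainPart <- if (config$rfiSD > 0)
        res$rwg - (config$residCor * config$rwgSD / config$rfiSD) * res$rfi
    else res$rwg
    adg <- adgSys + gainPart

    days <- config$weighDays
    set.seed(.childSeed(config$seed, 3))
    noise <- matrix(stats::rnorm(n * length(days), 0, config$bwNoiseSD),
                    n, length(days))
    bwMat <- outer(bw0, rep(1, length(days))) + outer(adg, days) + noise
    bw <- data.frame(animal_id = rep(ids, each = length(days)),
                     day = rep(days, n),
                     bw_kg = as.vector(t(bwMat)))

    # intake built from the noiseless growth line, so the planted residual is
    # exactly the deviation from the fitted intake model
    mbw075 <- (bw0 + adg * mean(days))^0.75
    b <- config$dmiCoefficients
    dmi <- b[[1]] + b[[2]] * adg + b[[3]] * mbw075 + res$rfi
    names(dmi) <- ids

    truth <- data.frame(animal_id = ids, rfi_planted = res$rfi,
                        rwg_planted = res$rwg, adg_sys = adgSys,
                        stringsAsFactors = FALSE)
    list(phenotypes = PhenotypeTable(bw, dmi), truth = truth)
}

#' Expression simulation configuration
#'
#' Defaults emulate the study design downstream of the trial: 7 liver RNA-seq
#' samples per efficiency group and module-structured expression. Each module
#' is a list with \code{size}, per-group latent within-correlation
#' \code{cor = c(HFE =, LFE =)} and \code{trait} (correlation of the module
#' factor with the RIG trait; 0 = none). Counts come from a gamma-Poisson
#' (negative-binomial) model on an exponential-of-Gaussian mean driven by the
#' module factors, preserving both correlation structure and count
#' overdispersion.
#'
#' @param nGenes total genes (default 1000).
#' @param nSamplesPerGroup samples per efficiency group (default 7).
#' @param modules list of module specifications (see Details); defaults plant
#'   one trait-linked module, one LFE-specific-connectivity module and one
#'   neutral module.
#' @param nDEGenes differentially expressed background genes (default 8).
#' @param deLog2FC log2 fold change planted in the LFE group (default 1.5).
#' @param baseMeanLog,baseMeanSDLog log-normal parameters of per-gene base
#'   mean counts.
#' @param dispersion negative-binomial dispersion (default 0.05).
#' @param factorScale amplitude (natural-log scale) of the module-gene latent
#'   signal in the count mean (default 0.9).
#' @param bioNoiseSD biological log-scale noise SD of background genes
#'   (default 0.3).
#' @param geneLengthRange gene-length range in bp.
#' @param seed integer seed.
#' @return a configuration list of class \code{ExprSimConfig}.
#' @export
exprSimConfig <- function(nGenes = 1000, nSamplesPerGroup = 7,
                          modules = list(
                              list(size = 100, cor = c(HFE = 0.7, LFE = 0.7),
                                   trait = 0.7),
                              list(size = 50, cor = c(HFE = 0.1, LFE = 0.9),
                                   trait = 0),
                              list(size = 80, cor = c(HFE = 0.7, LFE = 0.7),
                                   trait = 0)),
                          nDEGenes = 8, deLog2FC = 1.5,
                          baseMeanLog = log(150), baseMeanSDLog = 1,
                          dispersion = 0.05, factorScale = 0.9,
                          bioNoiseSD = 0.3,
                          geneLengthRange = c(500, 5000), seed = 1L) {
    sizes <- vapply(modules, `[[`, numeric(1), "size")
    if (sum(sizes) > nGenes) stop("module sizes exceed nGenes")
    cors <- unlist(lapply(modules, `[[`, "cor"))
    stopifnot(all(cors >= 0 & cors <= 1), dispersion > 0,
              nSamplesPerGroup >= 3,
              length(geneLengthRange) == 2, all(geneLengthRange > 0))
    structure(list(nGenes = nGenes, nSamplesPerGroup = nSamplesPerGroup,
                   modules = modules, nDEGenes = nDEGenes,
                   deLog2FC = deLog2FC, baseMeanLog = baseMeanLog,
                   baseMeanSDLog = baseMeanSDLog, dispersion = dispersion,
                   factorScale = factorScale, bioNoiseSD = bioNoiseSD,
                   geneLengthRange = geneLengthRange,
                   seed = as.integer(seed)),
              class = "ExprSimConfig")
}

#' Simulate module-structured RNA-seq counts
#'
#' Picks \code{nSamplesPerGroup} animals from each efficiency group of the
#' phenotype table (the most extreme by RIG, deterministically). For every
#' module, a per-sample latent factor drives member genes with loadings
#' \eqn{\sqrt{cor_G}} set by the requested within-group correlation; a
#' trait-linked module has its factor correlated with standardised RIG at the
#' requested strength. Planted DE genes (drawn from the background) have their
#' LFE mean shifted by \code{deLog2FC}. Counts are negative-binomial around
#' \code{baseMean * exp(factorScale * latent)}.
#'
#' @param config an \code{\link{exprSimConfig}}.
#' @param phenotypes a \linkS4class{PhenotypeTable} with HFE/LFE groups
#'   assigned and RIG populated.
#' @return list with \code{counts} (an \linkS4class{ExprMatrix} of counts
#'   with group labels and gene lengths) and \code{truth} (list: per-gene
#'   module label, trait-linked module ids, per-group planted correlation per
#'   module, DE gene ids, sampled animal ids).
#' @export
simulateExpression <- function(config = exprSimConfig(), phenotypes) {
    stopifnot(inherits(config, "ExprSimConfig"),
              is(phenotypes, "PhenotypeTable"))
    tr <- feedTraits(phenotypes)
    nPer <- config$nSamplesPerGroup
    pick <- function(g, decreasing) {
        sub <- tr[tr$group == g & !tr$excluded, ]
        if (nrow(sub) < nPer) stop("group ", g, " has fewer than ", nPer,
                                   " animals")
        sub$animal_id[order(sub$rig, decreasing = decreasing)][seq_len(nPer)]
    }
    ids <- c(pick("HFE", TRUE), pick("LFE", FALSE))
    group <- rep(c("HFE", "LFE"), each = nPer)
    rig <- tr$rig[match(ids, tr$animal_id)]
    zrig <- as.vector(scale(rig))
    nS <- length(ids)

    nG <- config$nGenes
    genes <- sprintf("G%05d", seq_len(nG))
    sizes <- vapply(config$modules, `[[`, numeric(1), "size")
    labels <- rep("background", nG)
    idx <- 0
    for (m in seq_along(sizes)) {
        labels[idx + seq_len(sizes[m])] <- paste0("mod", m)
        idx <- idx + sizes[m]
    }

    set.seed(.childSeed(config$seed, 12))
    baseMean <- stats::rlnorm(nG, config$baseMeanLog, config$baseMeanSDLog)
    # counting noise attenuates the correlation seen on counts below the
    # latent one; loadings are lifted per gene (delta-method log-scale
    # reliability, capped at 1) so the requested within-group correlation is
    # hit on the generated counts, not just on the latent factors
    a2 <- config$factorScale^2
    reliability <- a2 / (a2 + 1 / baseMean + config$dispersion)

    set.seed(.childSeed(config$seed, 11))
    latent <- matrix(stats::rnorm(nG * nS), nG, nS)   # per-gene noise
    factors <- matrix(stats::rnorm(length(sizes) * nS), length(sizes), nS)
    for (m in seq_along(config$modules)) {
        ts <- config$modules[[m]]$trait
        if (ts != 0)
            factors[m, ] <- ts * zrig + sqrt(1 - ts^2) * factors[m, ]
    }
    for (m in seq_along(config$modules)) {
        rows <- which(labels == paste0("mod", m))
        for (g in c("HFE", "LFE")) {
            cols <- which(group == g)
            l <- pmin(1, sqrt(config$modules[[m]]$cor[[g]] /
                                  reliability[rows]))
            latent[rows, cols] <- l * matrix(factors[m, cols],
                                             length(rows), length(cols),
                                             byrow = TRUE) +
                sqrt(pmax(0, 1 - l^2)) * latent[rows, cols]
        }
    }
    bg <- which(labels == "background")
    if (config$nDEGenes > length(bg))
        stop("not enough background genes for the requested DE set")
    deGenes <- sort(sample(bg, config$nDEGenes))
    shift <- matrix(0, nG, nS)
    shift[deGenes, group == "LFE"] <- config$deLog2FC * log(2)

    amp <- ifelse(labels == "background", config$bioNoiseSD,
                  config$factorScale)
    logMu <- log(baseMean) + amp * latent + shift
    set.seed(.childSeed(config$seed, 13))
    counts <- matrix(stats::rnbinom(nG * nS, mu = exp(logMu),
                                    size = 1 / config$dispersion), nG, nS)
    dimnames(counts) <- list(genes, ids)
    lengths <- round(stats::runif(nG, config$geneLengthRange[1],
                                  config$geneLengthRange[2]))
    names(lengths) <- genes

    truth <- list(
        module = stats::setNames(labels, genes),
        trait_modules = paste0("mod", which(vapply(config$modules, `[[`,
                                                   numeric(1), "trait") != 0)),
        group_cor = lapply(config$modules, `[[`, "cor"),
        de_genes = genes[deGenes],
        samples = ids, groups = stats::setNames(group, ids))
    list(counts = ExprMatrix(counts, unit = "counts", group = group,
                             lengths = lengths),
         truth = truth)
}

#' Simulate a flat gene-term annotation
#'
#' Builds a two-column gene-to-term table in which one designated term
#' annotates exactly the planted gene set, and the remaining terms are random
#' gene sets; a fraction \code{coverage} of all genes receives at least one
#' random term.
#'
#' @param geneIds all gene ids (the annotation universe).
#' @param nTerms number of random terms (default 50).
#' @param plantedTermGenes gene ids annotated by the planted term (subset of
#'   \code{geneIds}).
#' @param coverage fraction of genes with at least one random term (default
#'   0.8).
#' @param seed integer seed.
#' @return list with \code{annotation} (data.frame gene_id, term_id) and
#'   \code{truth} (list with \code{planted_term}).
#' @export
simulateAnnotation <- function(geneIds, nTerms = 50, plantedTermGenes,
                               coverage = 0.8, seed = 1L) {
    if (!length(geneIds)) stop("empty gene list")
    stopifnot(all(plantedTermGenes %in% geneIds), coverage > 0, coverage <= 1)
    set.seed(.childSeed(seed, 21))
    terms <- sprintf("T%04d", seq_len(nTerms))
    planted <- "T_PLANTED"
    covered <- geneIds[stats::runif(length(geneIds)) <= coverage]
    rows <- lapply(covered, function(g)
        data.frame(gene_id = g,
                   term_id = sample(terms, sample(1:3, 1)),
                   stringsAsFactors = FALSE))
    ann <- do.call(rbind, c(rows, list(
        data.frame(gene_id = plantedTermGenes, term_id = planted,
                   stringsAsFactors = FALSE))))
    ann <- unique(ann[order(ann$gene_id, ann$term_id), ])
    rownames(ann) <- NULL
    list(annotation = ann, truth = list(planted_term = planted))
}
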