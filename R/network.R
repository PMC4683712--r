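#' Gene-gene Pearson correlation matrix
#'
#' @param object an \linkS4class{ExprMatrix} or genes x samples matrix with at
#'   least 3 samples; every gene must have positive variance.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(object) {
    m <- if (is(object, "ExprMatrix")) exprValues(object) else as.matrix(object)
    if (ncol(m) < 3) stop("need at least 3 samples")
    sdv <- apply(m, 1, stats::sd)
    if (any(sdv == 0))
        stop("zero-variance gene(s): ",
             paste(rownames(m)[sdv == 0], collapse = ", "))
    cc <- stats::cor(t(m))
    diag(cc) <- 1
    cc
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted adjacency \eqn{a_{ij} = |cor_{ij}|^\beta} with unit
#' diagonal. Raising |cor| to a power suppresses weak correlations smoothly
#' instead of hard-thresholding them.
#'
#' @param cor symmetric correlation matrix.
#' @param beta soft-threshold power (>= 1).
#' @return adjacency matrix in [0, 1].
#' @export
corAdjacency <- function(cor, beta) {
    if (beta < 1) stop("beta must be >= 1")
    a <- abs(cor)^beta
    diag(a) <- 1
    a
}

# scale-free fit: bin connectivity, regress log10(freq) on log10(mean K)
.scaleFreeR2 <- function(k, nBins = 10) {
    if (max(k) == min(k)) return(NA_real_)
    bins <- cut(k, breaks = nBins)
    freq <- tapply(k, bins, length)
    meanK <- tapply(k, bins, mean)
    ok <- !is.na(freq) & freq > 0 & meanK > 0
    if (sum(ok) < 3) return(NA_real_)
    fit <- stats::lm(log10(freq[ok]) ~ log10(meanK[ok]))
    summary(fit)$r.squared
}

#' Pick the soft-threshold power by scale-free fit
#'
#' For each candidate power, computes whole-network connectivity
#' \eqn{K_i = \sum_{j \ne i} |cor_{ij}|^\beta}, bins K and regresses
#' log10(frequency) on log10(mean K per bin); the R-squared of that fit
#' measures how closely the connectivity distribution follows a power law.
#' The chosen power is the smallest candidate reaching \code{r2Cut};
#' when none does, the candidate with the highest R-squared is chosen with a
#' warning.
#'
#' @param object an \linkS4class{ExprMatrix} or expression matrix.
#' @param candidates candidate powers (default 1:20).
#' @param r2Cut scale-free fit cutoff (default 0.9).
#' @param nBins histogram bins for the fit (default 10).
#' @return a \linkS4class{SoftThresholdScan}.
#' @export
pickSoftThreshold <- function(object, candidates = 1:20, r2Cut = 0.9,
                              nBins = 10) {
    cc <- abs(correlationMatrix(object))
    diag(cc) <- 0
    fits <- data.frame(beta = candidates, r2 = NA_real_, mean_k = NA_real_)
    for (i in seq_along(candidates)) {
        k <- rowSums(cc^candidates[i])
        fits$mean_k[i] <- mean(k)
        fits$r2[i] <- .scaleFreeR2(k, nBins)
    }
    ok <- which(!is.na(fits$r2) & fits$r2 >= r2Cut)
    if (length(ok)) {
        beta <- candidates[min(ok)]
    } else {
        if (all(is.na(fits$r2)))
            stop("scale-free fit undefined for every candidate power")
        beta <- candidates[which.max(fits$r2)]
        warning(sprintf(
            "no candidate reached R2 >= %.2f; using beta = %g (R2 = %.3f)",
            r2Cut, beta, max(fits$r2, na.rm = TRUE)))
    }
    new("SoftThresholdScan", fits = fits, beta = as.numeric(beta),
        r2Cut = r2Cut)
}

#' Topological overlap matrix
#'
#' For an unsigned adjacency A, the topological overlap of genes i and j is
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'                       {\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{k_i = \sum_{u \ne i} a_{iu}} and \eqn{TOM_{ii} = 1}. It is 1 when
#' two genes share all their neighbours and 0 when they share none.
#'
#' @param adjacency symmetric adjacency matrix in [0, 1].
#' @return TOM matrix in [0, 1] with unit diagonal.
#' @export
topologicalOverlap <- function(adjacency) {
    bad <- .checkSym01(adjacency, "adjacency", unitDiag = FALSE)
    if (!is.null(bad)) stop(paste(bad, collapse = "; "))
    a <- adjacency
    diag(a) <- 0
    L <- a %*% a          # diag(a) = 0 removes the u = i and u = j terms
    k <- rowSums(a)
    tom <- (L + a) / (outer(k, k, pmin) + 1 - a)
    diag(tom) <- 1
    dimnames(tom) <- dimnames(adjacency)
    tom
}

#' Build the weighted co-expression network
#'
#' Correlation, soft-threshold adjacency and TOM in one object. When
#' \code{beta} is NULL the power is chosen by \code{\link{pickSoftThreshold}}.
#'
#' @param object an \linkS4class{ExprMatrix} or expression matrix.
#' @param beta soft power, or NULL for automatic selection.
#' @param r2Cut scale-free cutoff for automatic selection.
#' @return a \linkS4class{CoexpressionNetwork}.
#' @export
buildNetwork <- function(object, beta = NULL, r2Cut = 0.9) {
    cc <- correlationMatrix(object)
    if (is.null(beta)) beta <- chosenBeta(pickSoftThreshold(object,
                                                            r2Cut = r2Cut))
    adj <- corAdjacency(cc, beta)
    new("CoexpressionNetwork", genes = rownames(cc), cor = cc,
        adjacency = adj, tom = topologicalOverlap(adj),
        beta = as.numeric(beta), mode = "unsigned")
}

# Proportional cut plus recursive local re-cut. Each branch large enough to
# hide two modules is re-cut at the same proportional height of its own
# subtree; the refinement is accepted only when it separates at least two
# clusters of module size. Distinct modules merge near the top of a shared
# branch, so the local cut splits them, while a homogeneous module cannot
# yield two module-sized pieces and is left intact.
.dynamicCut <- function(diss, minSize, cutQuantile, depth = 0L) {
    n <- nrow(diss)
    if (n < 2) return(rep(1L, n))
    hc <- stats::hclust(stats::as.dist(diss), method = "average")
    member <- stats::cutree(hc, h = cutQuantile * max(hc$height))
    if (depth >= 8L) return(member)
    nxt <- max(member)
    for (cl in unique(member)) {
        idx <- which(member == cl)
        if (length(idx) < 2 * minSize) next
        sub <- diss[idx, idx, drop = FALSE]
        subm <- .dynamicCut(sub, minSize, cutQuantile, depth + 1L)
        if (sum(table(subm) >= minSize) >= 2) {
            member[idx] <- nxt + subm
            nxt <- nxt + max(subm)
        }
    }
    member
}

.modulePalette <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
    "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue",
    "darkred", "darkgreen", "darkturquoise", "darkgrey", "orange",
    "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Detect modules from the TOM
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' (1 - TOM), with a simplified dynamic branch cut: the dendrogram is cut at
#' the \code{cutQuantile} quantile of its merge heights, and any branch whose
#' internal height range still exceeds that cut height is re-cut recursively.
#' Clusters smaller than \code{minModuleSize} are set to grey; surviving
#' modules receive colour names in decreasing size order from a fixed palette,
#' so labelling is deterministic.
#'
#' @param network a \linkS4class{CoexpressionNetwork}, or a TOM matrix.
#' @param minModuleSize smallest reportable module (default 30).
#' @param cutQuantile merge-height quantile for the static cut (default 0.99).
#' @return a \linkS4class{ModuleSet} with labels only (eigengenes etc. empty).
#' @export
clusterModules <- function(network, minModuleSize = 30, cutQuantile = 0.99) {
    tom <- if (is(network, "CoexpressionNetwork")) tomMatrix(network)
           else network
    genes <- rownames(tom)
    if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(nrow(tom)))
    if (nrow(tom) < minModuleSize) {
        warning("fewer genes than minModuleSize; all genes set to grey")
        labels <- stats::setNames(rep("grey", nrow(tom)), genes)
        return(new("ModuleSet", labels = labels,
                   eigengenes = matrix(0, 0, 0), traitCor = data.frame(),
                   kME = matrix(0, 0, 0), minModuleSize = minModuleSize))
    }
    member <- .dynamicCut(1 - tom, minModuleSize, cutQuantile)
    sizes <- table(member)
    keep <- names(sizes)[sizes >= minModuleSize]
    labels <- rep("grey", length(member))
    if (length(keep)) {
        ord <- keep[order(-sizes[keep], as.integer(keep))]
        if (length(ord) > length(.modulePalette))
            ord <- ord[seq_along(.modulePalette)]
        for (i in seq_along(ord))
            labels[member == as.integer(ord[i])] <- .modulePalette[i]
    }
    names(labels) <- genes
    new("ModuleSet", labels = labels, eigengenes = matrix(0, 0, 0),
        traitCor = data.frame(), kME = matrix(0, 0, 0),
        minModuleSize = minModuleSize)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardised member-gene expression (per-gene zero mean, unit SD across
#' samples): the single profile explaining the most member variance. Each
#' eigengene is unit-norm and oriented so that its correlation with the module
#' mean profile is non-negative.
#'
#' @param object an \linkS4class{ExprMatrix} or genes x samples matrix.
#' @param modules a \linkS4class{ModuleSet} or named label vector.
#' @return samples x modules matrix of eigengene profiles (grey excluded).
#' @export
moduleEigengenes <- function(object, modules) {
    m <- if (is(object, "ExprMatrix")) exprValues(object) else as.matrix(object)
    labels <- if (is(modules, "ModuleSet")) moduleLabels(modules) else modules
    labels <- labels[rownames(m)]
    mods <- setdiff(unique(labels), "grey")
    mods <- .modulePalette[.modulePalette %in% mods]  # deterministic order
    me <- matrix(NA_real_, ncol(m), length(mods),
                 dimnames = list(colnames(m), mods))
    for (mod in mods) {
        sub <- m[labels == mod, , drop = FALSE]
        if (nrow(sub) < 2) stop("module ", mod, " has fewer than 2 genes")
        sdv <- apply(sub, 1, stats::sd)
        if (any(sdv == 0))
            stop("zero-variance gene in module ", mod, ": ",
                 paste(rownames(sub)[sdv == 0], collapse = ", "))
        z <- t(scale(t(sub)))           # genes x samples, standardised
        sv <- svd(t(z), nu = 1, nv = 0)
        e <- sv$u[, 1]
        if (stats::cor(e, colMeans(z)) < 0) e <- -e
        me[, mod] <- e
    }
    me
}

#' Eigengene-trait correlation
#'
#' Pearson correlation of every module eigengene with every trait column, with
#' two-sided p-values from the t distribution on n - 2 degrees of freedom.
#'
#' @param eigengenes samples x modules matrix (see
#'   \code{\link{moduleEigengenes}}).
#' @param traits data.frame/matrix of trait values with samples in rows,
#'   aligned to the eigengene rows.
#' @return data.frame with columns module, trait, r, p.
#' @export
moduleTraitCorrelation <- function(eigengenes, traits) {
    traits <- as.data.frame(traits)
    n <- nrow(eigengenes)
    if (n < 3) stop("need at least 3 samples")
    stopifnot(nrow(traits) == n)
    out <- expand.grid(module = colnames(eigengenes), trait = names(traits),
                       stringsAsFactors = FALSE)
    out$r <- out$p <- NA_real_
    for (i in seq_len(nrow(out))) {
        r <- stats::cor(eigengenes[, out$module[i]], traits[[out$trait[i]]])
        tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
        out$r[i] <- r
        out$p[i] <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
    out[c("module", "trait", "r", "p")]
}

#' Select trait-associated modules
#'
#' A module is selected when, for at least one of the listed traits, its
#' eigengene-trait correlation is strictly above \code{rThreshold} in absolute
#' value with p at or below \code{pThreshold}. The sign pattern across traits
#' is reported for the selected modules.
#'
#' @param traitCor data.frame from \code{\link{moduleTraitCorrelation}}.
#' @param traits trait names to gate on (default c("rfi", "rig")).
#' @param rThreshold absolute-correlation threshold (default 0.5, strict).
#' @param pThreshold p-value threshold (default 0.1, inclusive).
#' @return data.frame with one row per selected module: module, the per-trait
#'   r values, and a sign pattern string.
#' @export
selectTraitModules <- function(traitCor, traits = c("rfi", "rig"),
                               rThreshold = 0.5, pThreshold = 0.1) {
    tc <- traitCor[traitCor$trait %in% traits, ]
    pass <- abs(tc$r) > rThreshold & tc$p <= pThreshold
    mods <- unique(tc$module[pass])
    if (!length(mods))
        return(data.frame(module = character(), pattern = character()))
    pat <- vapply(mods, function(m) {
        sub <- tc[tc$module == m, ]
        paste(sprintf("%s%s", ifelse(sub$r >= 0, "+", "-"), sub$trait),
              collapse = "/")
    }, character(1))
    data.frame(module = mods, pattern = unname(pat),
               stringsAsFactors = FALSE)
}

#' Module membership (kME)
#'
#' kME of gene g for module m is the Pearson correlation between g's
#' expression profile and module m's eigengene; it measures how central the
#' gene is to the module.
#'
#' @param object an \linkS4class{ExprMatrix} or genes x samples matrix.
#' @param eigengenes samples x modules eigengene matrix.
#' @return genes x modules kME matrix.
#' @export
moduleMembership <- function(object, eigengenes) {
    m <- if (is(object, "ExprMatrix")) exprValues(object) else as.matrix(object)
    stats::cor(t(m), eigengenes)
}

#' Filter module genes by membership
#'
#' Retains a gene for its own module only when its absolute kME with that
#' module is strictly above \code{ownMin} and its absolute kME with every
#' other module is strictly below \code{otherMax} — i.e. the gene is strongly
#' and specifically co-expressed with its module.
#'
#' @param kME genes x modules kME matrix.
#' @param labels named gene -> module label vector.
#' @param ownMin own-module |kME| threshold (default 0.6).
#' @param otherMax cross-module |kME| ceiling (default 0.6).
#' @return named list: module -> character vector of retained gene ids.
#' @export
filterByMembership <- function(kME, labels, ownMin = 0.6, otherMax = 0.6) {
    labels <- labels[rownames(kME)]
    mods <- intersect(colnames(kME), unique(labels))
    out <- stats::setNames(vector("list", length(mods)), mods)
    for (mod in mods) {
        genes <- rownames(kME)[labels == mod]
        own <- abs(kME[genes, mod])
        others <- abs(kME[genes, setdiff(colnames(kME), mod), drop = FALSE])
        maxOther <- if (ncol(others)) apply(others, 1, max) else rep(0, length(genes))
        out[[mod]] <- genes[own > ownMin & maxOther < otherMax]
    }
    out
}
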