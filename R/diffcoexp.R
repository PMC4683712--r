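#' Whole-network connectivity within a sample group
#'
#' \eqn{K_i = \sum_{j \ne i} |cor_{ij}|^\beta} computed over the given
#' samples.
#'
#' @param object an \linkS4class{ExprMatrix} or genes x samples matrix
#'   restricted to one group (>= 3 samples).
#' @param beta soft-threshold power.
#' @return named numeric vector of raw connectivities.
#' @export
groupConnectivity <- function(object, beta) {
    cc <- abs(correlationMatrix(object))^beta
    diag(cc) <- 0
    rowSums(cc)
}

#' Max-normalised connectivity
#'
#' Divides each gene's connectivity by the maximum connectivity in its
#' sub-network, so values lie in [0, 1] with the hub gene at exactly 1.
#'
#' @param k raw connectivity vector with max(k) > 0.
#' @return normalised vector.
#' @export
normalizeConnectivity <- function(k) {
    if (max(k) <= 0) stop("all-zero connectivity cannot be normalised")
    k / max(k)
}

#' Differential connectivity between efficiency groups
#'
#' Builds one sub-network per group by raising the within-group gene-gene
#' Pearson correlations to a group-specific power, computes whole-network
#' connectivity, max-normalises within each sub-network, and takes
#' \deqn{KDiff_i = K^{norm}_{LFE}(i) - K^{norm}_{HFE}(i) \in [-1, 1].}
#' Positive values mark genes more connected in the LFE sub-network, negative
#' values genes more connected in the HFE sub-network. Note the default
#' powers differ between groups (20 for LFE, 4 for HFE), which makes the
#' statistic asymmetric under the null; both are configurable.
#'
#' @param object an \linkS4class{ExprMatrix} with HFE/LFE sample groups, or a
#'   matrix plus \code{groups}.
#' @param groups named sample -> group vector (taken from the object when
#'   absent).
#' @param betaHFE soft power for the HFE sub-network (default 4).
#' @param betaLFE soft power for the LFE sub-network (default 20).
#' @param threshold |KDiff| flagging threshold (default 0.6, strict).
#' @return a \linkS4class{KDiffTable}.
#' @export
computeKDiff <- function(object, groups = NULL, betaHFE = 4, betaLFE = 20,
                         threshold = 0.6) {
    m <- if (is(object, "ExprMatrix")) exprValues(object) else as.matrix(object)
    if (is.null(groups) && is(object, "ExprMatrix"))
        groups <- sampleGroups(object)
    if (is.null(groups)) stop("sample group labels required")
    groups <- groups[colnames(m)]
    if (anyNA(groups))
        stop("group label missing for sample(s): ",
             paste(colnames(m)[is.na(groups)], collapse = ", "))
    for (g in c("HFE", "LFE"))
        if (sum(groups == g) < 3)
            stop("group ", g, " has fewer than 3 samples")
    kH <- groupConnectivity(m[, groups == "HFE", drop = FALSE], betaHFE)
    kL <- groupConnectivity(m[, groups == "LFE", drop = FALSE], betaLFE)
    kHn <- normalizeConnectivity(kH)
    kLn <- normalizeConnectivity(kL)
    kdiff <- kLn - kHn
    flag <- ifelse(kdiff > threshold, "LFE-connected",
                   ifelse(kdiff < -threshold, "HFE-connected", "none"))
    new("KDiffTable",
        table = data.frame(gene = rownames(m), K_HFE = kH, K_LFE = kL,
                           K_HFE_norm = kHn, K_LFE_norm = kLn, kdiff = kdiff,
                           flag = flag, row.names = NULL,
                           stringsAsFactors = FALSE),
        betaHFE = betaHFE, betaLFE = betaLFE, threshold = threshold)
}

#' Differentially connected gene lists
#'
#' Splits a \linkS4class{KDiffTable} by the |KDiff| threshold: genes with
#' KDiff strictly below -threshold are HFE-connected, genes strictly above
#' +threshold are LFE-connected; values exactly at the threshold are in
#' neither list.
#'
#' @param object a \linkS4class{KDiffTable}.
#' @param threshold override the table's threshold (default: as stored).
#' @return list with character vectors \code{hfe} and \code{lfe}.
#' @export
selectDifferentiallyConnected <- function(object, threshold = NULL) {
    if (is.null(threshold)) threshold <- object@threshold
    if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
    t <- kdiffValues(object)
    list(hfe = t$gene[t$kdiff < -threshold],
         lfe = t$gene[t$kdiff > threshold])
}
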