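#' Counts per million
#'
#' Scales every column of a count matrix to counts per million mapped reads:
#' \code{count / library_total * 1e6}.
#'
#' @param object an \linkS4class{ExprMatrix} in counts, or a count matrix.
#' @return an \linkS4class{ExprMatrix} tagged \code{"CPM"}.
#' @export
computeCPM <- function(object) {
    m <- if (is(object, "ExprMatrix")) exprValues(object) else as.matrix(object)
    libs <- colSums(m)
    if (any(libs <= 0))
        stop("zero library size in sample(s): ",
             paste(colnames(m)[libs <= 0], collapse = ", "))
    cpm <- sweep(m, 2, libs, "/") * 1e6
    ExprMatrix(cpm, unit = "CPM",
               group = if (is(object, "ExprMatrix")) sampleGroups(object),
               lengths = if (is(object, "ExprMatrix")) geneLengths(object))
}

#' Minimum-CPM expression filter
#'
#' Keeps a gene when it reaches \code{minCPM} in at least \code{minSamples}
#' samples (default: half the samples, rounded up) — the standard low-count
#' filter applied before expression analysis.
#'
#' @param object an \linkS4class{ExprMatrix} in CPM.
#' @param minCPM CPM threshold (default 1).
#' @param minSamples minimum number of samples at or above the threshold.
#' @return named logical vector, TRUE = gene kept.
#' @export
filterMinCPM <- function(object, minCPM = 1,
                         minSamples = ceiling(ncol(object) / 2)) {
    stopifnot(is(object, "ExprMatrix"))
    if (exprUnit(object) != "CPM") stop("filterMinCPM expects a CPM matrix")
    if (minSamples > ncol(object))
        stop("minSamples exceeds the number of samples")
    m <- exprValues(object)
    rowSums(m >= minCPM) >= minSamples
}

#' Upper-quartile normalised FPKM
#'
#' Fragments per kilobase per million mapped reads:
#' \code{count / (length_kb * library_millions)}, followed by upper-quartile
#' normalisation — each sample is rescaled so that its 75th percentile of
#' non-zero FPKM equals the across-sample mean of those percentiles. The
#' normalisation is invariant to uniform per-sample depth scaling. Set
#' \code{quartile = 0.5} for median scaling.
#'
#' @param object an \linkS4class{ExprMatrix} in counts (with gene lengths), or
#'   a count matrix.
#' @param lengths gene lengths in bp (taken from the object if absent here).
#' @param quartile the scaling quantile (default 0.75).
#' @param normalize apply the quartile scaling (default TRUE).
#' @return an \linkS4class{ExprMatrix} tagged \code{"FPKM"}.
#' @export
computeFPKM <- function(object, lengths = NULL, quartile = 0.75,
                        normalize = TRUE) {
    m <- if (is(object, "ExprMatrix")) exprValues(object) else as.matrix(object)
    if (is.null(lengths) && is(object, "ExprMatrix"))
        lengths <- geneLengths(object)
    if (is.null(lengths)) stop("gene lengths required for FPKM")
    if (!is.null(names(lengths))) lengths <- lengths[rownames(m)]
    if (anyNA(lengths))
        stop("missing length for counted gene(s): ",
             paste(rownames(m)[is.na(lengths)], collapse = ", "))
    libs <- colSums(m)
    fpkm <- m / (lengths / 1e3) %o% (libs / 1e6)
    if (normalize) {
        uq <- apply(fpkm, 2, function(x) stats::quantile(x[x > 0], quartile))
        fpkm <- sweep(fpkm, 2, mean(uq) / uq, "*")
    }
    ExprMatrix(fpkm, unit = "FPKM",
               group = if (is(object, "ExprMatrix")) sampleGroups(object),
               lengths = lengths)
}

#' Network quality-control filter
#'
#' Drops genes unsuitable for co-expression analysis: genes with zero counts
#' in more than \code{maxZeroSamples} samples, and (with the default
#' \code{direction = "informative"}) genes whose mean expression falls below
#' \code{meanMin} or whose SD falls below \code{sdMin} — low-count genes are
#' unreliable and near-constant genes carry no co-expression information.
#' \code{direction = "exclude-high"} inverts the mean/SD rules (drop genes
#' with mean above \code{meanMin} and SD above \code{sdMin}).
#'
#' @param object an \linkS4class{ExprMatrix} (FPKM expected).
#' @param maxZeroSamples tolerated zero-valued samples per gene (default 7).
#' @param meanMin mean threshold (default 0.5).
#' @param sdMin SD threshold (default 0.2).
#' @param direction \code{"informative"} or \code{"exclude-high"}.
#' @return named logical vector, TRUE = gene kept.
#' @export
qcFilterForNetwork <- function(object, maxZeroSamples = 7, meanMin = 0.5,
                               sdMin = 0.2,
                               direction = c("informative", "exclude-high")) {
    direction <- match.arg(direction)
    m <- if (is(object, "ExprMatrix")) exprValues(object) else as.matrix(object)
    nZero <- rowSums(m == 0)
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    keep <- if (direction == "informative")
        mu >= meanMin & sdv >= sdMin
    else
        !(mu > meanMin & sdv > sdMin)
    keep & nZero <= maxZeroSamples
}

#' Pre-select the most connected genes
#'
#' Scores every gene by its whole-network connectivity
#' \eqn{K_i = \sum_{j \ne i} |cor(i, j)|} over the supplied matrix and keeps
#' the \code{nKeep} highest-scoring genes (ties broken by ascending gene id).
#' Hub genes carry most of the network structure, so restricting to them keeps
#' module detection tractable without losing the organised part of the
#' network.
#'
#' @param object an \linkS4class{ExprMatrix}.
#' @param nKeep number of genes to retain (default 3500).
#' @param absolute use |cor| (default TRUE) rather than signed correlation.
#' @return an \linkS4class{ExprMatrix} restricted to the selected genes, with
#'   the connectivity scores in \code{rowData(..)$connectivity}.
#' @export
selectTopConnected <- function(object, nKeep = 3500, absolute = TRUE) {
    stopifnot(is(object, "ExprMatrix"))
    m <- exprValues(object)
    if (ncol(m) < 3) stop("need at least 3 samples to score connectivity")
    if (nrow(m) <= nKeep) {
        if (nrow(m) < nKeep)
            warning("fewer genes (", nrow(m), ") than nKeep; keeping all")
        nKeep <- nrow(m)
    }
    cc <- stats::cor(t(m))
    if (absolute) cc <- abs(cc)
    k <- rowSums(cc) - diag(cc)
    ord <- order(-k, rownames(m))
    sel <- sort(ord[seq_len(nKeep)])
    out <- object[sel, ]
    rowData(out)$connectivity <- k[sel]
    out <- as(out, "ExprMatrix")
    metadata(out)$unit <- exprUnit(object)
    out
}
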