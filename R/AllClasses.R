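#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
NULL

#' Expression matrix container
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' (\code{"exprs"}) of gene-level expression values together with the unit the
#' values are in (\code{"counts"}, \code{"CPM"} or \code{"FPKM"}), the
#' efficiency-group label of each sample (\code{colData$group}) and, when
#' available, gene lengths in bp (\code{rowData$length_bp}).
#'
#' @slot .Data inherited \code{SummarizedExperiment} slots.
#' @export
setClass("ExprMatrix", contains = "SummarizedExperiment")

.validExprMatrix <- function(object) {
    msg <- NULL
    if (!"exprs" %in% names(assays(object)))
        msg <- c(msg, "assay 'exprs' is required")
    unit <- metadata(object)$unit
    if (is.null(unit) || !unit %in% c("counts", "CPM", "FPKM"))
        msg <- c(msg, "metadata unit must be one of 'counts', 'CPM', 'FPKM'")
    if ("exprs" %in% names(assays(object))) {
        v <- assay(object, "exprs")
        if (any(!is.finite(v)))
            msg <- c(msg, "expression values must be finite")
        else if (any(v < 0))
            msg <- c(msg, "expression values must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("ExprMatrix", .validExprMatrix)

#' Construct an ExprMatrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param unit one of \code{"counts"}, \code{"CPM"}, \code{"FPKM"}.
#' @param group optional factor/character of efficiency-group labels
#'   (\code{"HFE"}/\code{"LFE"}), one per sample.
#' @param lengths optional numeric vector of gene lengths in bp, one per gene
#'   (named or in row order).
#' @return an \linkS4class{ExprMatrix}.
#' @examples
#' m <- matrix(rpois(20, 10), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' em <- ExprMatrix(m, unit = "counts", group = c("HFE", "HFE", "LFE", "LFE"))
#' exprUnit(em)
#' @export
ExprMatrix <- function(values, unit = c("counts", "CPM", "FPKM"),
                       group = NULL, lengths = NULL) {
    unit <- match.arg(unit)
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("gene%05d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("sample%02d", seq_len(ncol(values)))
    cd <- DataFrame(row.names = colnames(values))
    if (!is.null(group)) {
        stopifnot(length(group) == ncol(values))
        cd$group <- as.character(group)
    }
    rd <- DataFrame(row.names = rownames(values))
    if (!is.null(lengths)) {
        if (!is.null(names(lengths))) lengths <- lengths[rownames(values)]
        stopifnot(length(lengths) == nrow(values), all(lengths > 0))
        rd$length_bp <- as.numeric(lengths)
    }
    se <- SummarizedExperiment(assays = SimpleList(exprs = values),
                               colData = cd, rowData = rd)
    metadata(se)$unit <- unit
    new("ExprMatrix", se)
}

#' Co-expression network
#'
#' Symmetric correlation, adjacency and topological-overlap matrices over a
#' common gene index, together with the soft-threshold power used. The network
#' is unsigned: adjacency is \eqn{|cor|^\beta} with unit diagonal.
#'
#' @slot genes character vector of gene ids.
#' @slot cor symmetric Pearson correlation matrix.
#' @slot adjacency symmetric adjacency matrix in [0, 1], unit diagonal.
#' @slot tom symmetric topological overlap matrix in [0, 1], unit diagonal.
#' @slot beta the soft-threshold power.
#' @slot mode network mode; only \code{"unsigned"} is implemented.
#' @export
setClass("CoexpressionNetwork",
         representation(genes = "character", cor = "matrix",
                        adjacency = "matrix", tom = "matrix",
                        beta = "numeric", mode = "character"))

.checkSym01 <- function(m, what, unitDiag = TRUE) {
    msg <- NULL
    if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
        msg <- c(msg, sprintf("%s must be symmetric", what))
    if (any(m < -1e-12) || any(m > 1 + 1e-12))
        msg <- c(msg, sprintf("%s entries must lie in [0, 1]", what))
    if (unitDiag && any(abs(diag(m) - 1) > 1e-8))
        msg <- c(msg, sprintf("%s must have unit diagonal", what))
    msg
}

setValidity("CoexpressionNetwork", function(object) {
    msg <- NULL
    n <- length(object@genes)
    for (s in c("cor", "adjacency", "tom")) {
        m <- slot(object, s)
        if (!all(dim(m) == c(n, n)))
            msg <- c(msg, sprintf("@%s dimension must match gene index", s))
    }
    msg <- c(msg, .checkSym01(object@adjacency, "adjacency"),
             .checkSym01(object@tom, "TOM"))
    if (object@beta < 1) msg <- c(msg, "beta must be >= 1")
    if (!identical(object@mode, "unsigned"))
        msg <- c(msg, "only unsigned networks are supported")
    if (is.null(msg)) TRUE else msg
})

#' Module set
#'
#' Gene-to-module assignment from TOM-based clustering, with per-module
#' eigengenes, the eigengene-trait correlation table and the module-membership
#' (kME) matrix. Unassigned genes carry the label \code{"grey"}.
#'
#' @slot labels named character vector, gene id -> module colour.
#' @slot eigengenes samples x modules matrix of unit-norm eigengene profiles.
#' @slot traitCor data.frame with columns module, trait, r, p (may be empty).
#' @slot kME genes x modules matrix of gene-eigengene correlations.
#' @slot minModuleSize smallest allowed non-grey module.
#' @export
setClass("ModuleSet",
         representation(labels = "character", eigengenes = "matrix",
                        traitCor = "data.frame", kME = "matrix",
                        minModuleSize = "numeric"))

setValidity("ModuleSet", function(object) {
    msg <- NULL
    tab <- table(object@labels[object@labels != "grey"])
    if (length(tab) && any(tab < object@minModuleSize))
        msg <- c(msg, "every non-grey module must reach minModuleSize")
    if (is.null(names(object@labels)))
        msg <- c(msg, "labels must be named by gene id")
    if (is.null(msg)) TRUE else msg
})

#' Differential-connectivity (KDiff) table
#'
#' Per-gene whole-network connectivity in each efficiency group at the
#' group-specific soft-threshold power, max-normalised within each group, the
#' KDiff statistic (LFE minus HFE, in [-1, 1]) and the differential-connection
#' flag at the configured threshold.
#'
#' @slot table data.frame with columns gene, K_HFE, K_LFE, K_HFE_norm,
#'   K_LFE_norm, kdiff, flag.
#' @slot betaHFE soft power used for the HFE sub-network.
#' @slot betaLFE soft power used for the LFE sub-network.
#' @slot threshold |KDiff| flagging threshold.
#' @export
setClass("KDiffTable",
         representation(table = "data.frame", betaHFE = "numeric",
                        betaLFE = "numeric", threshold = "numeric"))

setValidity("KDiffTable", function(object) {
    t <- object@table
    msg <- NULL
    need <- c("gene", "K_HFE", "K_LFE", "K_HFE_norm", "K_LFE_norm",
              "kdiff", "flag")
    if (!all(need %in% names(t)))
        msg <- c(msg, "table is missing required columns")
    else {
        if (any(t$K_HFE_norm < -1e-12 | t$K_HFE_norm > 1 + 1e-12) ||
            any(t$K_LFE_norm < -1e-12 | t$K_LFE_norm > 1 + 1e-12))
            msg <- c(msg, "normalised connectivities must lie in [0, 1]")
        if (any(abs(t$kdiff) > 1 + 1e-12))
            msg <- c(msg, "kdiff must lie in [-1, 1]")
        if (!all(t$flag %in% c("LFE-connected", "HFE-connected", "none")))
            msg <- c(msg, "invalid flag value")
    }
    if (object@threshold <= 0 || object@threshold > 1)
        msg <- c(msg, "threshold must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Soft-threshold scan
#'
#' Scale-free-topology fit for each candidate power and the chosen power: the
#' smallest candidate whose fit R-squared reaches \code{r2Cut}, otherwise the
#' candidate with the largest R-squared (with a warning at scan time).
#'
#' @slot fits data.frame with columns beta, r2, mean_k.
#' @slot beta the chosen power.
#' @slot r2Cut the R-squared cutoff used.
#' @export
setClass("SoftThresholdScan",
         representation(fits = "data.frame", beta = "numeric",
                        r2Cut = "numeric"))

setMethod("show", "ExprMatrix", function(object) {
    cat(sprintf("ExprMatrix: %d genes x %d samples [%s]\n",
                nrow(object), ncol(object), metadata(object)$unit))
    if ("group" %in% names(colData(object))) {
        tab <- table(colData(object)$group)
        cat("groups:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
    }
    invisible(object)
})

setMethod("show", "CoexpressionNetwork", function(object) {
    cat(sprintf("CoexpressionNetwork: %d genes, %s, beta = %g\n",
                length(object@genes), object@mode, object@beta))
    invisible(object)
})

setMethod("show", "ModuleSet", function(object) {
    tab <- sort(table(object@labels), decreasing = TRUE)
    cat(sprintf("ModuleSet: %d genes in %d modules (+ grey)\n",
                length(object@labels),
                sum(names(tab) != "grey")))
    print(tab)
    invisible(object)
})

setMethod("show", "KDiffTable", function(object) {
    tab <- table(factor(object@table$flag,
                        c("HFE-connected", "none", "LFE-connected")))
    cat(sprintf(
        "KDiffTable: %d genes (beta HFE = %g, beta LFE = %g, |KDiff| > %g)\n",
        nrow(object@table), object@betaHFE, object@betaLFE, object@threshold))
    print(tab)
    invisible(object)
})

setMethod("show", "SoftThresholdScan", function(object) {
    cat(sprintf("SoftThresholdScan: chosen beta = %g (R2 cut %.2f)\n",
                object@beta, object@r2Cut))
    invisible(object)
})

#' Accessors for efnet containers
#'
#' \code{exprUnit} returns the unit tag of an \linkS4class{ExprMatrix};
#' \code{exprValues} the expression matrix; \code{sampleGroups} the per-sample
#' group labels; \code{geneLengths} the gene lengths (bp) or NULL;
#' \code{moduleLabels}, \code{eigengenes}, \code{moduleTraitTable} and
#' \code{kmeMatrix} unpack a \linkS4class{ModuleSet}; \code{kdiffValues}
#' returns the per-gene table of a \linkS4class{KDiffTable};
#' \code{chosenBeta} the power picked by a \linkS4class{SoftThresholdScan}
#' (or stored in a network).
#'
#' @param x the container.
#' @name accessors
NULL

#' @rdname accessors
#' @export
exprUnit <- function(x) metadata(x)$unit

#' @rdname accessors
#' @export
exprValues <- function(x) assay(x, "exprs")

#' @rdname accessors
#' @export
sampleGroups <- function(x) {
    cd <- colData(x)
    if (!"group" %in% names(cd)) return(NULL)
    stats::setNames(as.character(cd$group), rownames(cd))
}

#' @rdname accessors
#' @export
geneLengths <- function(x) {
    rd <- rowData(x)
    if (!"length_bp" %in% names(rd)) return(NULL)
    stats::setNames(as.numeric(rd$length_bp), rownames(rd))
}

#' @rdname accessors
#' @export
moduleLabels <- function(x) x@labels

#' @rdname accessors
#' @export
eigengenes <- function(x) x@eigengenes

#' @rdname accessors
#' @export
moduleTraitTable <- function(x) x@traitCor

#' @rdname accessors
#' @export
kmeMatrix <- function(x) x@kME

#' @rdname accessors
#' @export
kdiffValues <- function(x) x@table

#' @rdname accessors
#' @export
chosenBeta <- function(x) x@beta

#' @rdname accessors
#' @export
adjacencyMatrix <- function(x) x@adjacency

#' @rdname accessors
#' @export
tomMatrix <- function(x) x@tom
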