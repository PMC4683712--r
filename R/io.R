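#' Read and write efnet tables
#'
#' Plain-text readers and writers for the formats the workflow exchanges:
#' a counts TSV (gene rows, sample columns, header row), a gene-length TSV
#' (gene_id, length_bp), long-format body-weight CSV (animal_id, day, bw_kg),
#' an intake CSV (animal_id, dmi_kg_d) and a flat annotation TSV
#' (gene_id, term_id).
#'
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @param group optional sample group labels passed to
#'   \code{\link{ExprMatrix}}.
#' @param lengths optional gene lengths passed to \code{\link{ExprMatrix}}.
#' @export
readCounts <- function(path, group = NULL, lengths = NULL) {
    m <- as.matrix(utils::read.delim(path, row.names = 1,
                                     check.names = FALSE))
    ExprMatrix(m, unit = "counts", group = group, lengths = lengths)
}

#' @rdname io
#' @export
readGeneLengths <- function(path) {
    d <- utils::read.delim(path)
    stats::setNames(d$length_bp, d$gene_id)
}

#' @rdname io
#' @param bwPath body-weight CSV, \code{dmiPath} intake CSV.
#' @param dmiPath intake CSV.
#' @export
readPhenotypes <- function(bwPath, dmiPath) {
    bw <- utils::read.csv(bwPath)
    dmi <- utils::read.csv(dmiPath)
    PhenotypeTable(bw, stats::setNames(dmi$dmi_kg_d,
                                       as.character(dmi$animal_id)))
}

#' @rdname io
#' @export
readAnnotation <- function(path) {
    d <- utils::read.delim(path,
                           colClasses = c("character", "character"))
    names(d)[1:2] <- c("gene_id", "term_id")
    d
}

#' @rdname io
#' @param object the object to write (matrix or ExprMatrix for
#'   \code{writeCounts}; data.frame for \code{writeTSV}).
#' @export
writeCounts <- function(object, path) {
    m <- if (is(object, "ExprMatrix")) exprValues(object) else object
    d <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io
#' @export
writeTSV <- function(object, path) {
    utils::write.table(object, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Write a full simulated dataset to disk
#'
#' Emits counts.tsv, gene_lengths.tsv, bw.csv, dmi.csv, annotation.tsv and
#' the ground-truth tables (truth_phenotypes.tsv, truth_genes.tsv) for a
#' simulation produced by the generator functions.
#'
#' @param trial output of \code{\link{simulateFeedTrial}}.
#' @param expression output of \code{\link{simulateExpression}}.
#' @param annotation output of \code{\link{simulateAnnotation}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeSimulation <- function(trial, expression, annotation, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ph <- trial$phenotypes
    utils::write.csv(ph@bw, file.path(dir, "bw.csv"), row.names = FALSE)
    utils::write.csv(data.frame(animal_id = names(ph@dmi),
                                dmi_kg_d = unname(ph@dmi)),
                     file.path(dir, "dmi.csv"), row.names = FALSE)
    writeCounts(expression$counts, file.path(dir, "counts.tsv"))
    len <- geneLengths(expression$counts)
    writeTSV(data.frame(gene_id = names(len), length_bp = unname(len)),
             file.path(dir, "gene_lengths.tsv"))
    writeTSV(annotation$annotation, file.path(dir, "annotation.tsv"))
    writeTSV(trial$truth, file.path(dir, "truth_phenotypes.tsv"))
    tg <- expression$truth
    writeTSV(data.frame(gene_id = names(tg$module), module = unname(tg$module),
                        de = names(tg$module) %in% tg$de_genes),
             file.path(dir, "truth_genes.tsv"))
    invisible(dir)
}
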