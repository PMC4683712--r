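#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least \code{k} annotated genes in a study set
#' of size \code{n} drawn from a background of \code{N} genes of which
#' \code{K} carry the term: \eqn{P(X \ge k)} for
#' \eqn{X \sim Hypergeometric(N, K, n)}.
#'
#' @param k study hits.
#' @param n study-set size.
#' @param K term size in the background.
#' @param N background size.
#' @return p-value in (0, 1].
#' @export
hypergeometricP <- function(k, n, K, N) {
    if (any(k < 0) || any(n > N) || any(K > N) || any(k > pmin(n, K)))
        stop("inconsistent hypergeometric counts")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: \eqn{padj_{(i)} = \min_{j \ge i} m p_{(j)} / j},
#' capped at 1. A thin wrapper over \code{p.adjust(method = "BH")} kept for a
#' stable surface.
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p) {
    if (!length(p)) stop("empty p-value vector")
    stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis against a flat annotation
#'
#' For every annotation term with at least one study hit (or every term when
#' \code{minHits = 0}), computes the upper-tail hypergeometric p-value of the
#' overlap between the study set and the term's genes, using the supplied
#' background as the universe, then applies Benjamini-Hochberg FDR. The
#' annotation is taken as a flat gene-to-term table; no term-hierarchy
#' propagation is performed. Duplicate study ids are dropped with a warning.
#'
#' @param study character vector of study gene ids (subset of background).
#' @param background character vector: the gene universe.
#' @param annotation data.frame with columns gene_id, term_id (rows outside
#'   the background are ignored).
#' @param padjCut significance cutoff on the adjusted p (default 0.1).
#' @param minHits minimum study hits for a term to be tested (default 1).
#' @return data.frame sorted by p: term_id, hits, study_size, term_size,
#'   background_size, p, padj, significant.
#' @export
enrichTerms <- function(study, background, annotation, padjCut = 0.1,
                        minHits = 1) {
    if (!length(study)) stop("empty study set")
    if (anyDuplicated(study)) {
        warning("duplicate study gene ids removed")
        study <- unique(study)
    }
    background <- unique(background)
    if (!all(study %in% background))
        stop("study genes outside the background: ",
             paste(utils::head(setdiff(study, background), 5), collapse = ", "))
    ann <- annotation[annotation$gene_id %in% background, c("gene_id", "term_id")]
    ann <- unique(ann)
    N <- length(background)
    n <- length(study)
    termGenes <- split(ann$gene_id, ann$term_id)
    K <- lengths(termGenes)
    k <- vapply(termGenes, function(g) sum(study %in% g), integer(1))
    keep <- k >= minHits
    res <- data.frame(term_id = names(termGenes)[keep], hits = k[keep],
                      study_size = n, term_size = K[keep],
                      background_size = N, row.names = NULL,
                      stringsAsFactors = FALSE)
    res$p <- hypergeometricP(res$hits, n, res$term_size, N)
    res$padj <- if (nrow(res)) bhAdjust(res$p) else numeric(0)
    res$significant <- res$padj <= padjCut
    res[order(res$p, res$term_id), ]
}
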