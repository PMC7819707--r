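#' Sample-level QC filter
#'
#' Flags samples passing the detected-gene thresholds: somata pass with at
#' least \code{soma_min_genes} detected (non-ERCC, count > 0) genes,
#' dendrites with at least \code{dendrite_min_genes}; empty cuts never pass.
#' The operation is idempotent and order-independent over samples.
#'
#' @param x a \linkS4class{UmiExperiment}.
#' @param soma_min_genes,dendrite_min_genes detection thresholds (defaults
#'   700 and 55 genes).
#' @return \code{x} with \code{qc_pass} set in \code{colData}, plus
#'   \code{genes_detected} and \code{total_umi} columns.
#' @export
qcFilter <- function(x, soma_min_genes = 700L, dendrite_min_genes = 55L) {
    cmp <- compartment(x)
    bad <- setdiff(unique(cmp), c("soma", "dendrite", "empty"))
    if (length(bad))
        stop("unknown compartment label(s): ", paste(bad, collapse = ", "))
    gd <- genesDetected(x)
    pass <- rep(FALSE, ncol(x))
    pass[cmp == "soma"] <- gd[cmp == "soma"] >= soma_min_genes
    pass[cmp == "dendrite"] <- gd[cmp == "dendrite"] >= dendrite_min_genes
    cd <- SummarizedExperiment::colData(x)
    cd$genes_detected <- as.integer(gd)
    cd$total_umi <- as.integer(totalUmi(x))
    cd$qc_pass <- pass
    SummarizedExperiment::colData(x) <- cd
    x
}

#' Flag non-neuronal / low-quality clusters by marker score
#'
#' Scores each cluster by the mean expression of a marker set (e.g. glial or
#' apoptotic markers) and flags clusters whose mean score strictly exceeds
#' the \code{score_quantile} quantile of cluster means. Samples in flagged
#' clusters are marked \code{qc_pass = FALSE}.
#'
#' @param x a \linkS4class{UmiExperiment} carrying the expression assay.
#' @param labels cluster labels, one per sample of \code{x}.
#' @param marker_sets named list of marker gene sets.
#' @param score_quantile quantile of cluster means above which a cluster is
#'   flagged.
#' @param assay assay used for scoring.
#' @return list with \code{flagged} (cluster ids) and \code{experiment}
#'   (\code{x} with \code{qc_pass} updated).
#' @export
flagNonNeuronal <- function(x, labels, marker_sets, score_quantile = 0.9,
                            assay = "residuals") {
    if (!length(marker_sets) || any(!lengths(marker_sets)))
        stop("empty marker set")
    mat <- SummarizedExperiment::assay(x, assay)
    labels <- as.character(labels)
    flagged <- character(0)
    for (set in marker_sets) {
        genes <- intersect(set, rownames(mat))
        if (!length(genes)) stop("marker set has no genes in the data")
        score <- colMeans(mat[genes, , drop = FALSE])
        cl_mean <- tapply(score, labels, mean)
        thr <- stats::quantile(cl_mean, score_quantile, names = FALSE)
        flagged <- union(flagged, names(cl_mean)[cl_mean > thr])
    }
    if (length(flagged)) {
        qp <- qcPass(x)
        qp[labels %in% flagged] <- FALSE
        qcPass(x) <- qp
    }
    list(flagged = flagged, experiment = x)
}
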