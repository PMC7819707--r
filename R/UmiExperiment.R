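#' UmiExperiment: UMI counts for subcellular samples
#'
#' S4 container for genes x samples UMI count matrices from subcellular
#' (soma / dendrite / empty-cut) single-neuron RNA-seq, extending
#' \linkS4class{SingleCellExperiment}. Rows are genes (with ERCC spike-in
#' rows flagged via \code{rowData(x)$is_ercc}), columns are samples with
#' per-sample metadata in \code{colData}: \code{compartment} (one of
#' \code{"soma"}, \code{"dendrite"}, \code{"empty"}), \code{cell_id}
#' (shared by the soma and dendrite of the same neuron; \code{NA} for
#' empty cuts), \code{plate}, and \code{qc_pass}.
#'
#' @aliases UmiExperiment-class
#' @exportClass UmiExperiment
setClass("UmiExperiment", contains = "SingleCellExperiment")

setValidity("UmiExperiment", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        v <- if (methods::is(cts, "sparseMatrix")) cts@x else as.numeric(cts)
        if (length(v) && (any(v < 0) || any(v != round(v))))
            msg <- c(msg, "counts must be non-negative integers")
    }
    if (!"is_ercc" %in% colnames(SummarizedExperiment::rowData(object)))
        msg <- c(msg, "rowData column 'is_ercc' is required")
    cd <- SummarizedExperiment::colData(object)
    if ("compartment" %in% colnames(cd)) {
        bad <- setdiff(unique(as.character(cd$compartment)),
                       c("soma", "dendrite", "empty"))
        if (length(bad))
            msg <- c(msg, paste0("unknown compartment label(s): ",
                                 paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (is.null(msg)) TRUE else msg
})

#' Construct a UmiExperiment
#'
#' @param counts genes x samples matrix (dense or sparse) of non-negative
#'   integer UMI counts, with gene ids as rownames and sample ids as colnames.
#' @param sampleData data.frame of per-sample metadata (one row per column of
#'   \code{counts}); recognised columns are \code{compartment}, \code{cell_id},
#'   \code{plate}, \code{qc_pass}. Missing columns are filled with defaults.
#' @param isErcc logical per-gene flag marking ERCC spike-in rows. Defaults to
#'   gene ids starting with \code{"ERCC-"}.
#'
#' @return A \linkS4class{UmiExperiment}.
#' @export
UmiExperiment <- function(counts, sampleData = NULL, isErcc = NULL) {
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have gene ids as rownames and sample ids as colnames")
    if (is.null(isErcc))
        isErcc <- startsWith(rownames(counts), "ERCC-")
    if (is.null(sampleData))
        sampleData <- data.frame(row.names = colnames(counts))
    if (is.null(rownames(sampleData)))
        rownames(sampleData) <- colnames(counts)
    if (!"compartment" %in% colnames(sampleData))
        sampleData$compartment <- "soma"
    if (!"cell_id" %in% colnames(sampleData))
        sampleData$cell_id <- NA_character_
    if (!"qc_pass" %in% colnames(sampleData))
        sampleData$qc_pass <- NA
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(sampleData),
        rowData = S4Vectors::DataFrame(is_ercc = as.logical(isErcc)))
    methods::new("UmiExperiment", sce)
}

#' @describeIn UmiExperiment logical flag of ERCC spike-in rows
#' @param x a UmiExperiment
#' @export
setMethod("isErcc", "UmiExperiment", function(x)
    SummarizedExperiment::rowData(x)$is_ercc)

#' @describeIn UmiExperiment per-sample compartment labels
#' @export
setMethod("compartment", "UmiExperiment", function(x)
    as.character(SummarizedExperiment::colData(x)$compartment))

#' @describeIn UmiExperiment per-sample cell-of-origin ids
#' @export
setMethod("cellId", "UmiExperiment", function(x)
    as.character(SummarizedExperiment::colData(x)$cell_id))

#' @describeIn UmiExperiment per-sample QC flag
#' @export
setMethod("qcPass", "UmiExperiment", function(x)
    SummarizedExperiment::colData(x)$qc_pass)

#' @describeIn UmiExperiment set the per-sample QC flag
#' @param value replacement logical vector
#' @export
setMethod("qcPass<-", "UmiExperiment", function(x, value) {
    SummarizedExperiment::colData(x)$qc_pass <- value
    x
})

#' @describeIn UmiExperiment number of non-ERCC genes detected (count > 0)
#'   per sample
#' @export
setMethod("genesDetected", "UmiExperiment", function(x) {
    cts <- SummarizedExperiment::assay(x, "counts")[!isErcc(x), , drop = FALSE]
    Matrix::colSums(cts > 0)
})

#' @describeIn UmiExperiment total non-ERCC UMI count per sample
#' @export
setMethod("totalUmi", "UmiExperiment", function(x) {
    cts <- SummarizedExperiment::assay(x, "counts")[!isErcc(x), , drop = FALSE]
    Matrix::colSums(cts)
})

setMethod("show", "UmiExperiment", function(object) {
    cmp <- table(factor(compartment(object),
                        levels = c("soma", "dendrite", "empty")))
    cat("UmiExperiment:", sum(!isErcc(object)), "genes +",
        sum(isErcc(object)), "ERCC species x", ncol(object), "samples\n")
    cat("  compartments:", paste(names(cmp), cmp, sep = "=", collapse = " "),
        "\n")
    if (!all(is.na(qcPass(object))))
        cat("  qc_pass:", sum(qcPass(object), na.rm = TRUE), "of",
            ncol(object), "\n")
    cat("  assays:",
        paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
})

#' Read / write a UmiExperiment as MatrixMarket + TSV sidecars
#'
#' The on-disk layout is \code{matrix.mtx} (genes x samples sparse counts),
#' \code{genes.tsv} (columns \code{gene_id}, \code{is_ercc}) and
#' \code{samples.tsv} (\code{sample_id}, \code{compartment}, \code{cell_id},
#' \code{plate}, \code{qc_pass}).
#'
#' @param dir directory containing (or to receive) the three files.
#' @return \code{readUmiMtx} returns a \linkS4class{UmiExperiment};
#'   \code{writeUmiMtx} returns \code{dir} invisibly.
#' @export
readUmiMtx <- function(dir) {
    m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
    genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                               stringsAsFactors = FALSE)
    samples <- utils::read.delim(file.path(dir, "samples.tsv"),
                                 stringsAsFactors = FALSE)
    rownames(m) <- genes$gene_id
    colnames(m) <- samples$sample_id
    rownames(samples) <- samples$sample_id
    samples$sample_id <- NULL
    UmiExperiment(m, sampleData = samples, isErcc = genes$is_ercc)
}

#' @rdname readUmiMtx
#' @param x a UmiExperiment
#' @export
writeUmiMtx <- function(x, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    m <- methods::as(methods::as(
        SummarizedExperiment::assay(x, "counts"), "CsparseMatrix"),
        "generalMatrix")
    Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
    utils::write.table(
        data.frame(gene_id = rownames(x), is_ercc = isErcc(x)),
        file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    cd <- SummarizedExperiment::colData(x)
    utils::write.table(
        data.frame(sample_id = colnames(x),
                   compartment = compartment(x),
                   cell_id = cellId(x),
                   plate = if ("plate" %in% colnames(cd)) cd$plate else NA,
                   qc_pass = qcPass(x)),
        file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(dir)
}
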