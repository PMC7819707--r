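#' Downsample samples to a fixed molecular total
#'
#' Draws \code{target_total} molecules without replacement from the multiset
#' of each sample's UMIs (a multivariate hypergeometric draw), so column
#' totals equal the target exactly and composition is preserved in
#' expectation. Samples whose total is below the target are left unchanged
#' with a warning (or raise an error with \code{strict = TRUE}).
#'
#' @param x a \linkS4class{UmiExperiment} or counts matrix.
#' @param target_total target total UMI per sample.
#' @param seed integer seed.
#' @param samples optional selector restricting which samples are
#'   downsampled (default: all).
#' @param strict error instead of warn when a sample is below target.
#' @return object of the same class with downsampled counts. For a
#'   \linkS4class{UmiExperiment} only the biological (non-ERCC) rows are
#'   downsampled; spike-in rows are left untouched, since they never enter
#'   the expression analyses whose depth is being matched.
#' @export
downsampleCounts <- function(x, target_total, seed = 1L, samples = NULL,
                             strict = FALSE) {
    isUE <- methods::is(x, "UmiExperiment")
    full <- if (isUE) as.matrix(SummarizedExperiment::assay(x, "counts"))
            else as.matrix(x)
    rows <- if (isUE) which(!isErcc(x)) else seq_len(nrow(full))
    m <- full[rows, , drop = FALSE]
    sel <- if (is.null(samples)) seq_len(ncol(m)) else
        seq_len(ncol(m))[samples]
    set.seed(seed)
    low <- integer(0)
    for (j in sel) {
        tot <- sum(m[, j])
        if (tot < target_total) { low <- c(low, j); next }
        if (tot == target_total) next
        mol <- rep.int(seq_len(nrow(m)), m[, j])
        kept <- mol[sample.int(length(mol), target_total)]
        m[, j] <- tabulate(kept, nbins = nrow(m))
    }
    if (length(low)) {
        msg <- sprintf("%d sample(s) below target total; left unchanged",
                       length(low))
        if (strict) stop(msg) else warning(msg)
    }
    full[rows, ] <- m
    if (isUE) {
        SummarizedExperiment::assay(x, "counts") <- full
        x
    } else full
}

#' Sequencing-saturation curve
#'
#' Downsamples each sample to fractions of its observed total and records
#' the mean number of detected (count > 0, non-ERCC) genes, averaged over
#' replicates; the curve is non-decreasing in expectation.
#'
#' @param x a \linkS4class{UmiExperiment} or counts matrix (genes x samples).
#' @param fractions depth fractions in (0, 1].
#' @param reps random replicates per fraction.
#' @param seed integer seed.
#' @return data.frame with columns \code{fraction} and
#'   \code{mean_genes_detected} (mean over samples and replicates).
#' @export
saturationCurve <- function(x, fractions = c(0.05, 0.1, 0.25, 0.5, 0.75, 1),
                            reps = 3L, seed = 1L) {
    stopifnot(all(fractions > 0), all(fractions <= 1))
    m <- if (methods::is(x, "UmiExperiment"))
        as.matrix(SummarizedExperiment::assay(x, "counts")[!isErcc(x), ,
                                                           drop = FALSE])
    else as.matrix(x)
    tot <- colSums(m)
    out <- vapply(seq_along(fractions), function(k) {
        f <- fractions[k]
        if (f == 1) return(mean(colSums(m > 0)))
        mean(vapply(seq_len(reps), function(r) {
            mm <- m
            set.seed(.subSeed(seed, k * 1000L + r))
            for (j in seq_len(ncol(m))) {
                t_j <- floor(f * tot[j])
                mol <- rep.int(seq_len(nrow(m)), m[, j])
                kept <- mol[sample.int(length(mol), t_j)]
                mm[, j] <- tabulate(kept, nbins = nrow(m))
            }
            mean(colSums(mm > 0))
        }, numeric(1)))
    }, numeric(1))
    data.frame(fraction = fractions, mean_genes_detected = out)
}

#' Log-normalized expression
#'
#' Classic library-size log normalization,
#' \code{ln(count / total * scale_factor + 1)}, with totals over non-ERCC
#' genes. This is the expression currency of the logistic-regression DE and
#' marker tests; variance-stabilized residuals from
#' \code{\link{sctNormalize}} are the currency of PCA and clustering.
#'
#' @param x a \linkS4class{UmiExperiment} or counts matrix.
#' @param scale_factor library-size scale factor.
#' @return For a UmiExperiment, \code{x} with a \code{"lognorm"} assay
#'   (ERCC rows set to zero); for a matrix, the normalized matrix.
#' @export
logNormalize <- function(x, scale_factor = 1e4) {
    if (methods::is(x, "UmiExperiment")) {
        m <- as.matrix(SummarizedExperiment::assay(x, "counts"))
        tot <- totalUmi(x)
        ln <- log1p(sweep(m, 2, pmax(tot, 1), "/") * scale_factor)
        ln[isErcc(x), ] <- 0
        SummarizedExperiment::assay(x, "lognorm") <- ln
        x
    } else {
        m <- as.matrix(x)
        log1p(sweep(m, 2, pmax(colSums(m), 1), "/") * scale_factor)
    }
}
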