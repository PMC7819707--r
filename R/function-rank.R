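#' Representation score ranking of a compartment
#'
#' Ranks genes by their representation score, the product of detection
#' frequency (fraction of the compartment's samples with raw count > 0) and
#' mean normalized expression. Ties are broken alphabetically by gene id.
#'
#' @param x a \linkS4class{UmiExperiment} carrying the normalized assay.
#' @param compartment \code{"soma"} or \code{"dendrite"}.
#' @param assay non-negative expression assay used for the mean (the
#'   corrected-count assay by default; raw \code{"counts"} is available).
#' @param qc_only restrict to QC-passing samples when \code{qc_pass} is set.
#' @return \link[S4Vectors]{DataFrame} sorted by decreasing score with
#'   columns \code{gene}, \code{detection}, \code{mean_expr}, \code{score};
#'   the compartment is kept in \code{metadata}.
#' @export
representationRank <- function(x, compartment = c("dendrite", "soma"),
                               assay = "corrected", qc_only = TRUE) {
    compartment <- match.arg(compartment)
    cmp <- somadendrite::compartment(x)
    sel <- cmp == compartment
    if (qc_only && !all(is.na(qcPass(x)))) sel <- sel & qcPass(x) %in% TRUE
    if (!any(sel)) stop("no samples in compartment ", compartment)
    bio <- !isErcc(x)
    cts <- as.matrix(SummarizedExperiment::assay(x, "counts"))[bio, sel,
                                                               drop = FALSE]
    expr <- as.matrix(SummarizedExperiment::assay(x, assay))[bio, sel,
                                                             drop = FALSE]
    detection <- rowMeans(cts > 0)
    mean_expr <- rowMeans(expr)
    score <- detection * mean_expr
    ord <- order(-score, rownames(cts))
    out <- S4Vectors::DataFrame(gene = rownames(cts)[ord],
                                detection = detection[ord],
                                mean_expr = mean_expr[ord],
                                score = score[ord])
    S4Vectors::metadata(out)$compartment <- compartment
    out
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (tab-separated: term, description, genes ...).
#' @return named list of character gene vectors; descriptions are kept as
#'   the \code{"description"} attribute.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[`, character(1), 1L)
    attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
    sets
}

#' Write a ranked gene list in RNK format
#'
#' @param ranked result of \code{\link{representationRank}} (or any table
#'   with \code{gene} and \code{score} columns).
#' @param path output path.
#' @export
writeRnk <- function(ranked, path) {
    utils::write.table(data.frame(ranked$gene, ranked$score), path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

# weighted running-sum enrichment score of a set given scores sorted
# descending; hit increments proportional to |score|^weight, miss
# decrements 1/(N - |S|); ES is the maximum deviation of the running sum
.gseaEs <- function(scores, hit, weight) {
    N <- length(scores)
    nh <- sum(hit)
    if (nh == 0L || nh == N) return(NA_real_)
    w <- abs(scores)^weight
    inc <- numeric(N)
    sw <- sum(w[hit])
    if (sw == 0) inc[hit] <- 1 / nh else inc[hit] <- w[hit] / sw
    inc[!hit] <- -1 / (N - nh)
    rs <- cumsum(inc)
    rs[which.max(abs(rs))]
}

#' Preranked gene set enrichment analysis
#'
#' Weighted running-sum GSEA on a pre-ranked list: hit increments are
#' proportional to |score|^weight, miss decrements 1/(N - |S|), and the
#' enrichment score (ES) is the maximum deviation of the running sum. The
#' null is gene-label permutation (random sets of matched size); NES is ES
#' divided by the mean magnitude of same-sign null ES, and the FDR q-value
#' follows the same-sign ratio convention (pooled null NES across all
#' tested sets). Only sets with \code{min_size <= size < max_size} after
#' intersection with the ranked genes are tested; significance is
#' conventionally called at FDR < 0.25.
#'
#' @param ranked result of \code{\link{representationRank}} or a data.frame
#'   with \code{gene} and \code{score} columns (any order; re-sorted).
#' @param sets named list of gene sets (see \code{\link{readGmt}}).
#' @param weight score-weighting exponent (1 = the conventional weighted
#'   scheme; 0 = the classic Kolmogorov-Smirnov statistic).
#' @param n_perm number of label permutations (< 100 draws a warning).
#' @param seed integer seed.
#' @param min_size,max_size set-size filter after intersection.
#' @return \link[S4Vectors]{DataFrame} with one row per tested set:
#'   \code{term}, \code{size}, \code{es}, \code{nes}, \code{p_perm},
#'   \code{fdr_q}, \code{degenerate} (set spans the whole list).
#' @export
gseaPreranked <- function(ranked, sets, weight = 1, n_perm = 1000L,
                          seed = 1L, min_size = 15L, max_size = 500L) {
    if (n_perm < 100L) warning("n_perm < 100: unstable NES/FDR estimates")
    ord <- order(-ranked$score, ranked$gene)
    genes <- as.character(ranked$gene)[ord]
    scores <- as.numeric(ranked$score)[ord]
    N <- length(genes)
    sizes <- vapply(sets, function(s) length(intersect(s, genes)),
                    integer(1))
    use <- sizes >= min_size & sizes < max_size
    if (!any(use)) stop("no gene set passes the size filter after ",
                        "intersection with the ranked genes")
    sets <- sets[use]
    sizes <- sizes[use]

    es <- vapply(seq_along(sets), function(i)
        .gseaEs(scores, genes %in% sets[[i]], weight), numeric(1))
    degenerate <- is.na(es)
    es[degenerate] <- 0

    set.seed(seed)
    usz <- sort(unique(sizes[!degenerate]))
    null_es <- matrix(NA_real_, n_perm, length(usz),
                      dimnames = list(NULL, usz))
    for (b in seq_len(n_perm)) {
        perm <- sample.int(N)
        for (j in seq_along(usz)) {
            hit <- logical(N)
            hit[perm[seq_len(usz[j])]] <- TRUE
            null_es[b, j] <- .gseaEs(scores, hit, weight)
        }
    }

    nes <- p_perm <- rep(NA_real_, length(sets))
    null_nes <- vector("list", length(usz))
    for (j in seq_along(usz)) {
        nv <- null_es[, j]
        mpos <- mean(nv[nv > 0]); mneg <- mean(abs(nv[nv < 0]))
        # one-sided null ES distributions (possible for strongly skewed
        # score lists): normalize the missing side by the overall magnitude
        if (!is.finite(mpos)) mpos <- mean(abs(nv))
        if (!is.finite(mneg)) mneg <- mean(abs(nv))
        nn <- ifelse(nv > 0, nv / mpos, nv / mneg)
        null_nes[[j]] <- nn
        for (i in which(sizes == usz[j] & !degenerate)) {
            if (es[i] >= 0) {
                nes[i] <- es[i] / mpos
                p_perm[i] <- (sum(nv >= es[i]) + 1) / (sum(nv >= 0) + 1)
            } else {
                nes[i] <- es[i] / mneg
                p_perm[i] <- (sum(nv <= es[i]) + 1) / (sum(nv < 0) + 1)
            }
        }
    }
    pool <- unlist(null_nes)
    fdr <- rep(NA_real_, length(sets))
    for (i in which(!degenerate)) {
        if (nes[i] >= 0) {
            num <- mean(pool[pool >= 0] >= nes[i])
            den <- mean(nes[!degenerate & nes >= 0] >= nes[i])
        } else {
            num <- mean(pool[pool < 0] <= nes[i])
            den <- mean(nes[!degenerate & nes < 0] <= nes[i])
        }
        fdr[i] <- min(1, num / max(den, 1e-12))
    }
    nes[degenerate] <- 0
    S4Vectors::DataFrame(term = names(sets), size = sizes, es = es,
                         nes = nes, p_perm = p_perm, fdr_q = fdr,
                         degenerate = degenerate)
}

#' Relative dendritic enrichment distributions per complex
#'
#' For each gene the relative dendritic enrichment is the average over
#' neurons of the dendrite:soma expression ratio (pseudocount 0.1 on both
#' sides), computed only over neurons in which the gene is detected in the
#' soma. Per term, the distribution of its genes' enrichments is summarized
#' by quantiles and compared against the all-gene background by a rank-sum
#' test.
#'
#' @param x a \linkS4class{UmiExperiment} carrying the normalized assay.
#' @param pairs pair table as in \code{\link{pairedEnrichment}}.
#' @param sets named list of gene sets (complex terms).
#' @param assay non-negative expression assay for the ratios;
#'   \code{"depthnorm"} (default) rescales raw counts to the median library
#'   size, the depth correction under which a planted concentration ratio
#'   is recovered directly.
#' @param pseudocount added to numerator and denominator of each ratio.
#' @param min_genes terms with fewer detected genes are skipped with a note.
#' @return list with \code{summary} (\link[S4Vectors]{DataFrame}: term,
#'   n_genes, quantiles, median ratio of the background, rank-sum p),
#'   \code{ratios} (per-term named numeric vectors),
#'   \code{background} (all-gene enrichments) and \code{skipped}.
#' @export
complexDistribution <- function(x, pairs = NULL, sets, assay = "depthnorm",
                                pseudocount = 0.1, min_genes = 5L) {
    if (is.null(pairs)) pairs <- derivePairs(x)
    bio <- !isErcc(x)
    cts <- as.matrix(SummarizedExperiment::assay(x, "counts"))[bio, ,
                                                               drop = FALSE]
    expr <- if (identical(assay, "depthnorm")) {
        tot <- pmax(colSums(cts), 1)
        sweep(cts, 2, stats::median(tot) / tot, "*")
    } else as.matrix(SummarizedExperiment::assay(x, assay))[bio, ,
                                                            drop = FALSE]
    d <- expr[, pairs$dendrite, drop = FALSE]
    s <- expr[, pairs$soma, drop = FALSE]
    det <- cts[, pairs$soma, drop = FALSE] > 0
    ratio <- (d + pseudocount) / (s + pseudocount)
    ratio[!det] <- NA
    rel <- rowMeans(ratio, na.rm = TRUE)
    rel <- rel[rowSums(det) > 0]     # genes never somatically detected drop

    out <- list(); ratios <- list(); skipped <- character(0)
    for (term in names(sets)) {
        g <- intersect(sets[[term]], names(rel))
        if (length(g) < min_genes) { skipped <- c(skipped, term); next }
        v <- rel[g]
        bg <- rel[setdiff(names(rel), g)]
        wt <- if (length(bg) >= 3) stats::wilcox.test(v, bg) else
            list(p.value = NA_real_)
        out[[term]] <- data.frame(
            term = term, n_genes = length(g),
            q25 = stats::quantile(v, 0.25, names = FALSE),
            median = unname(stats::median(v)),
            q75 = stats::quantile(v, 0.75, names = FALSE),
            background_median = if (length(bg))
                unname(stats::median(bg)) else NA_real_,
            ranksum_p = unname(wt$p.value))
        ratios[[term]] <- v
    }
    if (length(skipped))
        message("skipped (fewer than ", min_genes, " detected genes): ",
                paste(skipped, collapse = ", "))
    list(summary = S4Vectors::DataFrame(do.call(rbind, out)),
         ratios = ratios, background = rel, skipped = skipped)
}
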