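# Independent oracles and small fixture builders used across the suite.

# brute-force UMI collapse: full pairwise Hamming distance matrix plus
# union-find over all distance-<=1 links (independent of the package's
# hash-neighbor implementation)
oracleCollapse <- function(umis) {
    uq <- unique(umis)
    n <- length(uq)
    if (n <= 1L) return(n)
    m <- do.call(rbind, strsplit(uq, "", fixed = TRUE))
    d <- matrix(0L, n, n)
    for (j in seq_len(ncol(m))) d <- d + outer(m[, j], m[, j], "!=")
    edges <- which(d <= 1L & upper.tri(d), arr.ind = TRUE)
    parent <- seq_len(n)
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in seq_len(nrow(edges))) {
        ri <- findRoot(edges[e, 1]); rj <- findRoot(edges[e, 2])
        if (ri != rj) parent[ri] <- rj
    }
    length(unique(vapply(seq_len(n), findRoot, integer(1))))
}

# exhaustive running-sum GSEA enrichment score (position-by-position loop)
oracleEs <- function(scores, hit, weight = 1) {
    N <- length(scores)
    nh <- sum(hit)
    if (nh == 0L || nh == N) return(NA_real_)
    sw <- sum(abs(scores[hit])^weight)
    run <- 0; best <- 0
    for (i in seq_len(N)) {
        run <- run + if (hit[i]) abs(scores[i])^weight / sw else -1 / (N - nh)
        if (abs(run) > abs(best)) best <- run
    }
    best
}

# random UMI strata containing planted near-duplicates, for collapse tests
randomStratum <- function(n, len = 10L, dup_frac = 0.4) {
    bases <- c("A", "C", "G", "T")
    k <- max(1L, round(n * (1 - dup_frac)))
    seed_umis <- vapply(seq_len(k), function(i)
        paste(sample(bases, len, replace = TRUE), collapse = ""),
        character(1))
    out <- seed_umis
    while (length(out) < n) {
        s <- sample(seed_umis, 1)
        pos <- sample.int(len, 1)
        b <- substr(s, pos, pos)
        substr(s, pos, pos) <- sample(setdiff(bases, b), 1)
        out <- c(out, s)
    }
    sample(out)
}

# match detected against planted punctum positions at a tolerance
peakScores <- function(peaks, truth, tol = 1) {
    tp <- 0; nref <- 0; fp <- 0
    for (id in names(truth)) {
        ref <- truth[[id]]
        det <- peaks$position_um[peaks$profile_id == id]
        nref <- nref + length(ref)
        if (length(ref) && length(det))
            tp <- tp + sum(vapply(ref, function(p) any(abs(det - p) <= tol),
                                  logical(1)))
        if (length(det))
            fp <- fp + sum(vapply(det, function(p)
                !length(ref) || !any(abs(ref - p) <= tol), logical(1)))
    }
    c(recall = tp / max(nref, 1),
      precision = 1 - fp / max(nrow(peaks), 1))
}

# tiny UmiExperiment from a dense matrix with default soma metadata
tinyUe <- function(counts, compartment = NULL, cell_id = NULL) {
    sd <- data.frame(row.names = colnames(counts))
    if (!is.null(compartment)) sd$compartment <- compartment
    if (!is.null(cell_id)) sd$cell_id <- cell_id
    UmiExperiment(counts, sampleData = sd)
}

assayMat <- function(x, name) as.matrix(SummarizedExperiment::assay(x, name))
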