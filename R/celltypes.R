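# Vectorized per-gene logistic-regression likelihood-ratio test.
# For every row x_g of `mat`, fits  logit P(y=1) = b0 + b1 * x_g  by Newton
# iterations carried simultaneously across genes, and compares against the
# intercept-only model. Complete separation is caught (diverging slope) and
# those genes are refit with a ridge penalty, flagged in the result.
.logisticLrt <- function(mat, y, ridge = 1e-4, max_iter = 50L, tol = 1e-6) {
    ng <- nrow(mat)
    n <- length(y)
    ym <- matrix(y, ng, n, byrow = TRUE)
    s1 <- sum(y)
    pbar <- s1 / n
    dev_null <- -2 * (s1 * log(pbar) + (n - s1) * log(1 - pbar))

    newton <- function(rows, lam) {
        X <- mat[rows, , drop = FALSE]
        Y <- ym[rows, , drop = FALSE]
        k <- length(rows)
        b0 <- rep(stats::qlogis(pbar), k)
        b1 <- rep(0, k)
        for (it in seq_len(max_iter)) {
            eta <- X * b1 + b0
            p <- stats::plogis(eta)
            w <- pmax(p * (1 - p), 1e-10)
            r <- Y - p
            g0 <- rowSums(r)
            g1 <- rowSums(r * X) - 2 * lam * b1
            S0 <- rowSums(w)
            S1 <- rowSums(w * X)
            S2 <- rowSums(w * X * X) + 2 * lam
            det <- pmax(S0 * S2 - S1^2, 1e-12)
            db0 <- (S2 * g0 - S1 * g1) / det
            db1 <- (S0 * g1 - S1 * g0) / det
            db0 <- pmin(pmax(db0, -10), 10)
            db1 <- pmin(pmax(db1, -10), 10)
            b0 <- b0 + db0
            b1 <- b1 + db1
            if (max(abs(db0), abs(db1)) < tol) break
        }
        eta <- X * b1 + b0
        p <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
        dev <- -2 * rowSums(Y * log(p) + (1 - Y) * log(1 - p))
        list(b0 = b0, b1 = b1, dev = dev)
    }

    fit <- newton(seq_len(ng), 0)
    sep <- !is.finite(fit$b1) | abs(fit$b1) > 15 | !is.finite(fit$dev)
    if (any(sep)) {
        refit <- newton(which(sep), ridge)
        fit$b0[sep] <- refit$b0
        fit$b1[sep] <- refit$b1
        fit$dev[sep] <- refit$dev
    }
    lrt <- pmax(dev_null - fit$dev, 0)
    data.frame(slope = fit$b1,
               p_raw = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
               separated = sep)
}

# log fold-change on log-normalized values, toolkit convention:
# ln(mean(expm1(x)) + 1) difference between the two groups
.logFc <- function(mat, idx_in, idx_out) {
    log(rowMeans(expm1(mat[, idx_in, drop = FALSE])) + 1) -
        log(rowMeans(expm1(mat[, idx_out, drop = FALSE])) + 1)
}

# shared prefilter + LR test between two sample index sets
.deCore <- function(mat, idx_in, idx_out, min_pct, min_logfc) {
    pct_in <- rowMeans(mat[, idx_in, drop = FALSE] > 0)
    pct_out <- rowMeans(mat[, idx_out, drop = FALSE] > 0)
    lfc <- .logFc(mat, idx_in, idx_out)
    tested <- pmax(pct_in, pct_out) >= min_pct & abs(lfc) >= min_logfc
    res <- S4Vectors::DataFrame(gene = rownames(mat), log_fc = lfc,
                                pct_in = pct_in, pct_out = pct_out,
                                tested = tested, p_raw = NA_real_,
                                separated = FALSE)
    if (any(tested)) {
        y <- as.numeric(seq_len(ncol(mat)) %in% idx_in)[c(idx_in, idx_out)]
        sub <- mat[tested, c(idx_in, idx_out), drop = FALSE]
        lr <- .logisticLrt(sub, y)
        res$p_raw[tested] <- lr$p_raw
        res$separated[tested] <- lr$separated
    }
    res
}

#' Principal component analysis of normalized residuals
#'
#' Genes are centered and samples projected onto the top principal
#' components. The solver is deterministic; PC signs are fixed by making the
#' largest-magnitude loading of each component positive.
#'
#' @param x a \linkS4class{UmiExperiment} carrying a \code{"residuals"}
#'   assay, or a genes x samples matrix.
#' @param n_pcs number of components (reduced with a warning when it
#'   exceeds the matrix rank).
#' @param assay assay to use when \code{x} is a UmiExperiment.
#' @return list with \code{scores} (samples x PCs),
#'   \code{var_explained}, \code{sdev} and \code{rotation}.
#' @export
runPca <- function(x, n_pcs = 40L, assay = "residuals") {
    mat <- if (methods::is(x, "UmiExperiment"))
        as.matrix(SummarizedExperiment::assay(x, assay)) else as.matrix(x)
    rank_max <- min(dim(mat)) - 1L
    if (n_pcs > rank_max) {
        warning("n_pcs reduced to the matrix rank (", rank_max, ")")
        n_pcs <- rank_max
    }
    pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE,
                        rank. = n_pcs)
    flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
    pc$rotation <- sweep(pc$rotation, 2, flip, "*")
    pc$x <- sweep(pc$x, 2, flip, "*")
    list(scores = pc$x,
         var_explained = pc$sdev[seq_len(n_pcs)]^2 / sum(pc$sdev^2),
         sdev = pc$sdev, rotation = pc$rotation)
}

#' Shared-nearest-neighbor graph
#'
#' Builds the Euclidean k-nearest-neighbor sets (self included, ties broken
#' by sample order) in PC space, connects samples by the Jaccard overlap of
#' their kNN sets, and prunes edges below \code{prune}.
#'
#' @param embedding result of \code{\link{runPca}} or a samples x PCs score
#'   matrix.
#' @param k neighborhood size.
#' @param n_pcs_graph number of leading PCs used for distances.
#' @param prune minimum retained Jaccard weight (default 1/15).
#' @return an undirected weighted \pkg{igraph} graph with one node per
#'   sample; weights in [0, 1], no self-edges.
#' @export
buildSnn <- function(embedding, k = 20L, n_pcs_graph = 23L, prune = 1 / 15) {
    sc <- if (is.list(embedding)) embedding$scores else embedding
    n <- nrow(sc)
    if (k >= n) stop("k must be smaller than the number of samples")
    sc <- sc[, seq_len(min(n_pcs_graph, ncol(sc))), drop = FALSE]
    d <- as.matrix(stats::dist(sc))
    # k nearest including self; order() breaks ties by sample order
    nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
    inc <- matrix(FALSE, n, n)
    for (i in seq_len(n)) inc[i, nn[i, ]] <- TRUE
    ov <- tcrossprod(inc * 1)                    # |N_i intersect N_j|
    jac <- ov / (2 * k - ov)
    diag(jac) <- 0
    jac[jac < prune] <- 0
    g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::V(g)$name <- rownames(sc)
    g
}

#' Louvain clustering of the SNN graph
#'
#' Greedy modularity optimization by Louvain passes; the seed controls
#' tie-breaking so results are reproducible.
#'
#' @param graph an SNN graph from \code{\link{buildSnn}}.
#' @param resolution modularity resolution parameter.
#' @param seed integer seed.
#' @return integer cluster labels named by sample.
#' @export
clusterLouvain <- function(graph, resolution = 0.8, seed = 1L) {
    if (igraph::vcount(graph) == 0L) stop("empty graph")
    set.seed(seed)
    cl <- igraph::cluster_louvain(graph, resolution = resolution)
    stats::setNames(as.integer(igraph::membership(cl)),
                    igraph::V(graph)$name)
}

#' Cluster marker genes by logistic-regression test
#'
#' One-vs-rest marker detection per cluster: genes expressed in at least
#' \code{min_pct} of either group and with absolute log fold-change above
#' \code{min_logfc} are tested by a likelihood-ratio test between logistic
#' models (cluster membership ~ expression vs. ~ 1). P-values are
#' Bonferroni-adjusted over the tested genes (Benjamini-Hochberg via
#' \code{adjust = "BH"}); significance is \code{p_adj < alpha}.
#'
#' @param x a \linkS4class{UmiExperiment} with a \code{"lognorm"} assay, or
#'   an expression matrix.
#' @param labels cluster labels, one per sample.
#' @param min_pct minimum detection fraction in either group.
#' @param min_logfc minimum absolute log fold-change.
#' @param alpha adjusted-p significance cutoff.
#' @param adjust \code{"bonferroni"} or any \code{p.adjust} method.
#' @param assay assay used when \code{x} is a UmiExperiment.
#' @return \link[S4Vectors]{DataFrame} with one row per tested
#'   (cluster, gene): \code{cluster}, \code{gene}, \code{log_fc},
#'   \code{pct_in}, \code{pct_out}, \code{p_raw}, \code{p_adj},
#'   \code{significant}, \code{separated}.
#' @export
markerTest <- function(x, labels, min_pct = 0.25, min_logfc = 0.25,
                       alpha = 0.05, adjust = "bonferroni",
                       assay = "lognorm") {
    mat <- if (methods::is(x, "UmiExperiment"))
        as.matrix(SummarizedExperiment::assay(x, assay)) else as.matrix(x)
    labels <- as.character(labels)
    if (length(labels) != ncol(mat)) stop("one label per sample required")
    cl_sizes <- table(labels)
    if (length(cl_sizes) < 2L) stop("need at least 2 clusters")
    if (any(cl_sizes < 3L)) stop("every cluster needs >= 3 samples")
    out <- lapply(sort(names(cl_sizes)), function(cl) {
        idx_in <- which(labels == cl)
        idx_out <- which(labels != cl)
        res <- .deCore(mat, idx_in, idx_out, min_pct, min_logfc)
        res <- res[res$tested, , drop = FALSE]
        res$tested <- NULL
        res$cluster <- cl
        res
    })
    res <- do.call(rbind, out)
    res$p_adj <- NA_real_
    for (cl in unique(res$cluster)) {
        i <- res$cluster == cl
        res$p_adj[i] <- stats::p.adjust(res$p_raw[i], method = adjust)
    }
    res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
    res[, c("cluster", "gene", "log_fc", "pct_in", "pct_out", "p_raw",
            "p_adj", "significant", "separated")]
}
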