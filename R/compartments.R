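#' CalibrationResult: mock-permutation FDR calibration
#'
#' Holds the pooled mock p-value distribution from label-shuffled reruns of
#' a differential-expression test, the observed p-values, the estimated
#' FDR curve and the selected p-value cutoff. The FDR at a cutoff c is the
#' mean number of mock discoveries at c (pooled count divided by the number
#' of permutations) over the number of observed discoveries at c, clipped
#' to [0, 1]; the selected cutoff is the largest observed p-value whose
#' estimated FDR does not exceed the target (NA when no cutoff qualifies).
#'
#' @slot comparison character label of the comparison.
#' @slot n_perm number of permutations.
#' @slot mock_p pooled mock p-values.
#' @slot observed_p observed p-values.
#' @slot fdr_curve data.frame with columns \code{cutoff}, \code{n_observed},
#'   \code{mean_mock}, \code{fdr}.
#' @slot selected_cutoff selected p-value cutoff (NA when undefined).
#' @slot target_fdr target FDR.
#' @slot seed seed used for the permutations.
#' @aliases CalibrationResult-class
#' @exportClass CalibrationResult
setClass("CalibrationResult",
         representation(comparison = "character", n_perm = "integer",
                        mock_p = "numeric", observed_p = "numeric",
                        fdr_curve = "data.frame",
                        selected_cutoff = "numeric", target_fdr = "numeric",
                        seed = "integer"))

setValidity("CalibrationResult", function(object) {
    msg <- NULL
    if (length(object@selected_cutoff) != 1L)
        msg <- c(msg, "selected_cutoff must be a single value")
    f <- object@fdr_curve$fdr
    if (length(f) && (any(f < 0) || any(f > 1)))
        msg <- c(msg, "FDR values must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn CalibrationResult selected p-value cutoff
#' @param x a CalibrationResult
#' @export
setMethod("selectedCutoff", "CalibrationResult",
          function(x) x@selected_cutoff)

#' @describeIn CalibrationResult estimated FDR curve
#' @export
setMethod("fdrCurve", "CalibrationResult", function(x) x@fdr_curve)

setMethod("show", "CalibrationResult", function(object) {
    cat("CalibrationResult:", object@comparison, "\n")
    cat(" ", length(object@observed_p), "tested genes,", object@n_perm,
        "mock permutations\n")
    if (is.na(object@selected_cutoff)) {
        cat("  no cutoff reaches the target FDR of", object@target_fdr, "\n")
    } else {
        i <- match(object@selected_cutoff, object@fdr_curve$cutoff)
        cat(sprintf("  selected cutoff p <= %.3g (estimated FDR %.3f, %d discoveries) at target %.2f\n",
                    object@selected_cutoff, object@fdr_curve$fdr[i],
                    object@fdr_curve$n_observed[i], object@target_fdr))
    }
})

#' Cross-group differential expression in one compartment
#'
#' Likelihood-ratio logistic-regression test between two same-compartment
#' sample groups, with the cross-cell-type prefilters: genes detected in at
#' least \code{min_pct} of either group and with absolute log fold-change
#' above \code{min_logfc}. Raw p-values are returned; for dendritic
#' comparisons the significance cutoff is decided by
#' \code{\link{mockCalibrate}}, for somatic ones by adjusted p < 0.05.
#'
#' @param x expression matrix (log-normalized) or
#'   \linkS4class{UmiExperiment} with a \code{"lognorm"} assay.
#' @param group_a,group_b sample indices, names, or logical selectors.
#' @param min_pct,min_logfc prefilters (defaults 0.10 and 0.5).
#' @param adjust p-adjustment method for the \code{p_adj} column.
#' @param assay assay used when \code{x} is a UmiExperiment.
#' @return \link[S4Vectors]{DataFrame} of tested genes with \code{log_fc},
#'   \code{pct_a}, \code{pct_b}, \code{p_raw}, \code{p_adj},
#'   \code{separated}.
#' @export
compartmentDe <- function(x, group_a, group_b, min_pct = 0.10,
                          min_logfc = 0.5, adjust = "bonferroni",
                          assay = "lognorm") {
    mat <- if (methods::is(x, "UmiExperiment"))
        as.matrix(SummarizedExperiment::assay(x, assay)) else as.matrix(x)
    ia <- seq_len(ncol(mat))[group_a]
    ib <- seq_len(ncol(mat))[group_b]
    if (is.character(group_a)) ia <- match(group_a, colnames(mat))
    if (is.character(group_b)) ib <- match(group_b, colnames(mat))
    if (length(ia) < 3L || length(ib) < 3L)
        stop("both groups need >= 3 samples")
    res <- .deCore(mat, ia, ib, min_pct, min_logfc)
    res <- res[res$tested, , drop = FALSE]
    res$tested <- NULL
    colnames(res)[colnames(res) == "pct_in"] <- "pct_a"
    colnames(res)[colnames(res) == "pct_out"] <- "pct_b"
    res$p_adj <- stats::p.adjust(res$p_raw, method = adjust)
    res
}

# FDR curve on the observed p-value grid; pooled mock counts averaged over
# permutations, counts at p <= c on both sides
.fdrCurve <- function(observed_p, mock_p, n_perm) {
    cutoffs <- sort(unique(observed_p))
    n_obs <- findInterval(cutoffs, sort(observed_p))
    mean_mock <- findInterval(cutoffs, sort(mock_p)) / n_perm
    fdr <- pmin(pmax(mean_mock / pmax(n_obs, 1), 0), 1)
    data.frame(cutoff = cutoffs, n_observed = n_obs, mean_mock = mean_mock,
               fdr = fdr)
}

#' Mock-permutation FDR calibration of a DE comparison
#'
#' Estimates the p-value cutoff at which a cross-group dendritic DE
#' comparison attains a target false discovery rate. Group labels are
#' shuffled (preserving group sizes) \code{n_perm} times; each permutation
#' reruns the identical test and prefilters, and all mock p-values are
#' pooled. For any cutoff c the estimated FDR is the mean mock discovery
#' count at c divided by the observed discovery count at c; the selected
#' cutoff is the largest observed p-value with estimated FDR at or below
#' \code{target_fdr} (undefined, reported as NA, when no observed p-value
#' qualifies).
#'
#' @inheritParams compartmentDe
#' @param n_perm number of label permutations (values below 50 give
#'   unstable estimates and are rejected unless \code{force = TRUE}).
#' @param target_fdr target FDR.
#' @param seed integer seed for the permutations.
#' @param force allow \code{n_perm < 50}.
#' @param comparison label stored in the result.
#' @return A \linkS4class{CalibrationResult}.
#' @export
mockCalibrate <- function(x, group_a, group_b, min_pct = 0.10,
                          min_logfc = 0.5, n_perm = 1000L, target_fdr = 0.05,
                          seed = 1L, force = FALSE,
                          comparison = "group_a_vs_group_b",
                          assay = "lognorm") {
    if (n_perm < 50L && !force)
        stop("n_perm < 50 gives unstable FDR estimates (use force = TRUE)")
    mat <- if (methods::is(x, "UmiExperiment"))
        as.matrix(SummarizedExperiment::assay(x, assay)) else as.matrix(x)
    ia <- seq_len(ncol(mat))[group_a]
    ib <- seq_len(ncol(mat))[group_b]
    if (is.character(group_a)) ia <- match(group_a, colnames(mat))
    if (is.character(group_b)) ib <- match(group_b, colnames(mat))
    obs <- .deCore(mat, ia, ib, min_pct, min_logfc)
    observed_p <- obs$p_raw[obs$tested]

    pool <- c(ia, ib)
    na <- length(ia)
    set.seed(seed)
    mock_p <- vector("list", n_perm)
    for (b in seq_len(n_perm)) {
        shuf <- sample(pool)
        mk <- .deCore(mat, shuf[seq_len(na)], shuf[-seq_len(na)],
                      min_pct, min_logfc)
        mock_p[[b]] <- mk$p_raw[mk$tested]
    }
    mock_p <- unlist(mock_p)

    curve <- .fdrCurve(observed_p, mock_p, n_perm)
    ok <- curve$fdr <= target_fdr & curve$n_observed > 0
    cutoff <- if (any(ok)) max(curve$cutoff[ok]) else NA_real_
    methods::new("CalibrationResult", comparison = comparison,
                 n_perm = as.integer(n_perm), mock_p = as.numeric(mock_p),
                 observed_p = as.numeric(observed_p), fdr_curve = curve,
                 selected_cutoff = cutoff,
                 target_fdr = as.numeric(target_fdr),
                 seed = as.integer(seed))
}

# Paired Poisson GLM with cell-of-origin fixed effects, profiled exactly:
# with counts y_sc (soma) and y_dc (dendrite) per cell c, offsets log N, and
# rate model log mu = a_c + b * dendrite + log N, the cell intercepts a_c
# profile out so that the LRT on b equals the conditional-binomial LRT of
# y_dc | (y_sc + y_dc) ~ Binom(n_c, p_c), logit p_c = b + log(Nd_c / Ns_c).
# Newton iterations on the scalar b are vectorized across genes.
.pairedPoissonLrt <- function(yd, ys, off, ridge = 1e-4, max_iter = 50L,
                              tol = 1e-10) {
    n <- yd + ys
    O <- matrix(off, nrow(yd), ncol(yd), byrow = TRUE)
    devOf <- function(p) {
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        t1 <- yd * log(pmax(yd, 1) / (n * p))
        t2 <- ys * log(pmax(ys, 1) / (n * (1 - p)))
        2 * rowSums(t1 + t2, na.rm = TRUE)
    }
    newton <- function(lam) {
        b <- rep(0, nrow(yd))
        for (it in seq_len(max_iter)) {
            p <- stats::plogis(b + O)
            grad <- rowSums(yd - n * p) - 2 * lam * b
            info <- rowSums(n * p * (1 - p)) + 2 * lam
            db <- grad / pmax(info, 1e-12)
            db <- pmin(pmax(db, -5), 5)
            b <- b + db
            if (max(abs(db)) < tol) break
        }
        b
    }
    b <- newton(0)
    sep <- !is.finite(b) | abs(b) > 15
    if (any(sep)) b[sep] <- newton(ridge)[sep]
    dev_full <- devOf(stats::plogis(b + O))
    dev_null <- devOf(stats::plogis(O))
    lrt <- pmax(dev_null - dev_full, 0)
    data.frame(effect = b,
               p_raw = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
               separated = sep)
}

#' Paired soma-dendrite enrichment test
#'
#' Per-gene Poisson generalized linear model of raw counts on compartment
#' with cell of origin as a latent (fixed-effect) covariate and log total
#' UMI as offset; the likelihood-ratio test on the compartment coefficient
#' classifies genes as dendrite-enriched or de-enriched. The cell effects
#' are profiled out analytically (see source), which makes the test
#' invariant to global depth rescaling of any single sample. Genes detected
#' in fewer than \code{min_pct} of the paired samples are excluded; a gene
#' with all-zero counts in one compartment is fit with a ridge penalty and
#' flagged.
#'
#' @param x a \linkS4class{UmiExperiment} (raw counts are used; the log
#'   total-UMI offset performs the depth correction within the Poisson
#'   likelihood).
#' @param pairs data.frame with columns \code{cell_id}, \code{soma},
#'   \code{dendrite} (sample ids); derived from \code{colData} when NULL,
#'   using QC-passing samples when \code{qc_pass} is set.
#' @param min_pct minimum detection fraction over the paired samples.
#' @param alpha significance level on adjusted p-values.
#' @param adjust p-adjustment method (Bonferroni default, BH available).
#' @return \link[S4Vectors]{DataFrame} per tested gene: \code{effect} (log
#'   ratio of depth-adjusted dendrite vs. soma rates), \code{direction}
#'   (\code{dendrite-enriched} / \code{de-enriched} / \code{ns}),
#'   \code{pct_detected}, \code{p_raw}, \code{p_adj}, \code{separated}.
#' @export
pairedEnrichment <- function(x, pairs = NULL, min_pct = 0.25, alpha = 0.05,
                             adjust = "bonferroni") {
    if (is.null(pairs)) pairs <- derivePairs(x)
    if (nrow(pairs) < 10L) stop("need >= 10 soma-dendrite pairs")
    cts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
    cts <- cts[!isErcc(x), , drop = FALSE]
    tot <- Matrix::colSums(cts)
    ys <- cts[, pairs$soma, drop = FALSE]
    yd <- cts[, pairs$dendrite, drop = FALSE]
    off <- log(tot[pairs$dendrite] / tot[pairs$soma])
    pct <- rowMeans(cbind(ys, yd) > 0)
    keep <- pct >= min_pct
    if (!any(keep)) stop("no gene passes the detection filter")
    fit <- .pairedPoissonLrt(yd[keep, , drop = FALSE],
                             ys[keep, , drop = FALSE], off)
    p_adj <- stats::p.adjust(fit$p_raw, method = adjust)
    direction <- rep("ns", sum(keep))
    sig <- !is.na(p_adj) & p_adj < alpha
    direction[sig & fit$effect > 0] <- "dendrite-enriched"
    direction[sig & fit$effect < 0] <- "de-enriched"
    S4Vectors::DataFrame(gene = rownames(cts)[keep], effect = fit$effect,
                         direction = direction, pct_detected = pct[keep],
                         p_raw = fit$p_raw, p_adj = p_adj,
                         separated = fit$separated)
}

#' Derive soma-dendrite pairs from sample metadata
#'
#' @param x a \linkS4class{UmiExperiment}.
#' @param qc_only keep only pairs where both samples pass QC (when
#'   \code{qc_pass} has been set).
#' @return data.frame with columns \code{cell_id}, \code{soma},
#'   \code{dendrite}.
#' @export
derivePairs <- function(x, qc_only = TRUE) {
    cmp <- compartment(x)
    cid <- cellId(x)
    ok <- rep(TRUE, ncol(x))
    if (qc_only && !all(is.na(qcPass(x)))) ok <- qcPass(x) %in% TRUE
    soma <- colnames(x)[cmp == "soma" & ok]
    dend <- colnames(x)[cmp == "dendrite" & ok]
    sid <- cid[match(soma, colnames(x))]
    did <- cid[match(dend, colnames(x))]
    common <- intersect(sid, did)
    data.frame(cell_id = common,
               soma = soma[match(common, sid)],
               dendrite = dend[match(common, did)],
               stringsAsFactors = FALSE)
}

#' Dendritic detection as a function of somatic abundance
#'
#' Binomial GLM over genes of the per-gene dendritic detection events (k
#' detected of n paired dendrite samples) on log mean somatic UMI count
#' (pseudocount 1). Reports the slope p-value and McFadden pseudo-R-squared
#' (1 - lnL(model)/lnL(null)).
#'
#' @param x a \linkS4class{UmiExperiment}.
#' @param pairs pair table as in \code{\link{pairedEnrichment}}.
#' @param pseudocount added to the mean somatic count inside the log.
#' @return list with \code{model = "detection-logistic"},
#'   \code{coefficient} (slope), \code{p}, \code{fit} (pseudo-R-squared),
#'   \code{boundary} flag, and the per-gene \code{data}.
#' @export
detectionVsSoma <- function(x, pairs = NULL, pseudocount = 1) {
    if (is.null(pairs)) pairs <- derivePairs(x)
    cts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
    cts <- cts[!isErcc(x), , drop = FALSE]
    if (nrow(cts) < 50L) stop("need >= 50 genes")
    n <- nrow(pairs)
    k <- rowSums(cts[, pairs$dendrite, drop = FALSE] > 0)
    sx <- log(rowMeans(cts[, pairs$soma, drop = FALSE]) + pseudocount)
    boundary <- all(k == n) || all(k == 0) || stats::var(k / n) == 0
    fit <- stats::glm(cbind(k, n - k) ~ sx, family = stats::binomial())
    null <- stats::glm(cbind(k, n - k) ~ 1, family = stats::binomial())
    r2 <- 1 - as.numeric(stats::logLik(fit)) / as.numeric(stats::logLik(null))
    if (!is.finite(r2)) r2 <- 0       # degenerate (constant) response
    r2 <- min(max(r2, 0), 1)
    cf <- summary(fit)$coefficients
    pv <- if ("sx" %in% rownames(cf)) cf["sx", 4] else NA_real_
    list(model = "detection-logistic",
         coefficient = unname(stats::coef(fit)["sx"]), p = pv, fit = r2,
         boundary = boundary,
         data = data.frame(gene = rownames(cts), detected = k, n = n,
                           log_soma = sx))
}

#' Dendritic vs. somatic expression regression
#'
#' Ordinary least squares of mean dendritic on mean somatic normalized
#' expression over genes detected in at least \code{min_dendrite_pct} of
#' the paired dendritic samples.
#'
#' @param x a \linkS4class{UmiExperiment} carrying the normalized assay.
#' @param pairs pair table as in \code{\link{pairedEnrichment}}.
#' @param min_dendrite_pct dendritic detection filter (raw counts > 0).
#' @param assay normalized assay used for the means.
#' @return list with \code{model = "expression-linear"}, \code{coefficient}
#'   (slope), \code{p}, \code{fit} (R-squared) and the per-gene \code{data}.
#' @export
expressionVsSoma <- function(x, pairs = NULL, min_dendrite_pct = 0.20,
                             assay = "corrected") {
    if (is.null(pairs)) pairs <- derivePairs(x)
    cts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
    expr <- as.matrix(SummarizedExperiment::assay(x, assay))
    bio <- !isErcc(x)
    cts <- cts[bio, , drop = FALSE]; expr <- expr[bio, , drop = FALSE]
    pct <- rowMeans(cts[, pairs$dendrite, drop = FALSE] > 0)
    keep <- pct >= min_dendrite_pct
    if (sum(keep) < 10L) stop("fewer than 10 genes pass the filter")
    d <- rowMeans(expr[keep, pairs$dendrite, drop = FALSE])
    s <- rowMeans(expr[keep, pairs$soma, drop = FALSE])
    fit <- stats::lm(d ~ s)
    sm <- summary(fit)
    list(model = "expression-linear",
         coefficient = unname(stats::coef(fit)["s"]),
         p = sm$coefficients["s", 4], fit = sm$r.squared,
         data = data.frame(gene = rownames(cts)[keep], soma = s,
                           dendrite = d))
}
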