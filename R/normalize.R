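#' Regularized negative-binomial residual normalization
#'
#' Corrects UMI counts for technical depth variation using the Pearson
#' residuals of a regularized negative-binomial regression. Per gene, a NB
#' regression of counts on log10 total UMI (intercept + slope; dispersion
#' theta by maximum likelihood given the fitted means) is estimated, then
#' intercept, slope and log theta are regularized across genes by Gaussian
#' kernel smoothing over log10 mean count (bandwidth in dex). The residual
#' of the smoothed model, clipped to +/- sqrt(n_samples), is the normalized
#' expression; "corrected counts" (the expected count at the median depth
#' plus the residual-scaled deviation, floored at 0) are exposed alongside.
#'
#' ERCC rows are excluded, and genes detected in fewer than
#' \code{min_detect_frac} of the samples are excluded from the fit and
#' absent from the result.
#'
#' By default somata and dendrites are normalized jointly in one model, so
#' the depth regressor absorbs the large compartment depth difference; a
#' per-compartment sensitivity mode is available by subsetting the input.
#'
#' @param x a \linkS4class{UmiExperiment}.
#' @param min_detect_frac minimum detection fraction for a gene to be fit.
#' @param bandwidth Gaussian kernel sd on log10 mean count (dex).
#' @param theta_range dispersion bounds used to stabilize the ML estimate.
#' @return \code{x} subset to the fitted genes, with added assays
#'   \code{"residuals"} and \code{"corrected"}, fitted parameters
#'   (\code{nb_intercept}, \code{nb_slope}, \code{nb_theta}) in
#'   \code{rowData}, and the smoothing settings in \code{metadata}.
#' @export
sctNormalize <- function(x, min_detect_frac = 0.05, bandwidth = 0.3,
                         theta_range = c(1e-4, 1e6)) {
    if (ncol(x) < 2L) stop("need at least 2 samples")
    cts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
    bio <- !isErcc(x)
    cts <- cts[bio, , drop = FALSE]
    detfrac <- rowMeans(cts > 0)
    keep <- detfrac >= min_detect_frac & rowSums(cts) > 0
    dropped <- rownames(cts)[!keep]
    cts <- cts[keep, , drop = FALSE]
    if (!nrow(cts)) stop("no genes pass the detection floor")
    n <- ncol(cts)
    depth <- log10(pmax(colSums(cts), 1))
    X <- cbind(1, depth)

    # constant depth (e.g. equal library sizes) makes the slope unidentifiable
    flat_depth <- stats::sd(depth) < 1e-10
    if (flat_depth) X <- X[, 1, drop = FALSE]

    ng <- nrow(cts)
    b0 <- b1 <- th <- numeric(ng)
    for (g in seq_len(ng)) {
        y <- cts[g, ]
        fit <- suppressWarnings(
            stats::glm.fit(X, y, family = stats::poisson()))
        b0[g] <- fit$coefficients[1]
        b1[g] <- if (flat_depth) 0 else fit$coefficients[2]
        if (!is.finite(b1[g])) b1[g] <- 0
        mu <- fit$fitted.values
        th[g] <- tryCatch(
            suppressWarnings(as.numeric(MASS::theta.ml(y, mu, limit = 50))),
            error = function(e) theta_range[2])
        if (!is.finite(th[g])) th[g] <- theta_range[2]
    }
    th <- pmin(pmax(th, theta_range[1]), theta_range[2])

    gm <- log10(rowMeans(cts))
    b0s <- .kernelSmooth(gm, b0, bandwidth)
    b1s <- .kernelSmooth(gm, b1, bandwidth)
    ths <- 10^.kernelSmooth(gm, log10(th), bandwidth)

    mu <- exp(b0s + outer(b1s, depth))          # genes x samples
    sdev <- sqrt(mu + mu^2 / ths)
    res <- (cts - mu) / sdev
    clip <- sqrt(n)
    res[res > clip] <- clip
    res[res < -clip] <- -clip

    med <- stats::median(depth)
    mu_med <- exp(b0s + b1s * med)
    sd_med <- sqrt(mu_med + mu_med^2 / ths)
    corrected <- pmax(mu_med + res * sd_med, 0)

    out <- x[bio, ][keep, ]
    SummarizedExperiment::assay(out, "residuals") <- res
    SummarizedExperiment::assay(out, "corrected") <- corrected
    rd <- SummarizedExperiment::rowData(out)
    rd$nb_intercept <- b0s
    rd$nb_slope <- b1s
    rd$nb_theta <- ths
    rd$detect_frac <- detfrac[keep]
    SummarizedExperiment::rowData(out) <- rd
    S4Vectors::metadata(out)$sct <- list(
        bandwidth = bandwidth, min_detect_frac = min_detect_frac,
        median_log10_depth = med, dropped_genes = dropped)
    out
}
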