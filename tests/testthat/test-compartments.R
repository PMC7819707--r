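test_that("cross-group DE p-values are uniform on a split null population", {
    set.seed(7)
    sim <- simulateDendriteGroups(n_genes = 2000, n_a = 33, n_b = 33,
                                  de_frac = 0, seed = 7)
    ln <- logNormalize(sim$counts)
    res <- compartmentDe(ln, 1:33, 34:66, min_pct = 0.10, min_logfc = 0)
    ks <- stats::ks.test(res$p_raw, "punif")
    expect_gt(ks$p.value, 0.01)
    # detection prefilter: a gene below 10% detection in both groups is out
    m <- ln
    m["gene00001", ] <- 0
    m["gene00001", c(1, 2, 34, 35)] <- 1   # ~6% detection per group
    res2 <- compartmentDe(m, 1:33, 34:66, min_pct = 0.10, min_logfc = 0)
    expect_false("gene00001" %in% res2$gene)
    expect_error(compartmentDe(ln, 1:2, 3:66), ">= 3 samples")
})

test_that("the FDR estimator reproduces its defining ratio on constructed data", {
    # 50 observed genes at p <= 0.001 out of 1000; uniform mock p-values:
    # FDR(0.001) = (1000 * 0.001) / 50 = 0.02
    observed <- c(seq(1e-6, 0.001, length.out = 50),
                  seq(0.002, 1, length.out = 950))
    n_perm <- 200
    mock <- rep(seq(0.0005, 0.9995, by = 0.001), n_perm)  # exactly uniform
    curve <- somadendrite:::.fdrCurve(observed, mock, n_perm)
    fdr_at <- curve$fdr[curve$cutoff == 0.001]
    expect_equal(fdr_at, (1000 * 0.001) / 50, tolerance = 1e-6)
})

test_that("mock calibration is reproducible and monotone in its target", {
    sim <- simulateDendriteGroups(n_genes = 400, n_a = 18, n_b = 15,
                                  de_frac = 0.15, seed = 21)
    ln <- logNormalize(sim$counts)
    ia <- 1:18; ib <- 19:33
    cal1 <- mockCalibrate(ln, ia, ib, n_perm = 60, seed = 5, force = TRUE)
    cal2 <- mockCalibrate(ln, ia, ib, n_perm = 60, seed = 5, force = TRUE)
    expect_identical(fdrCurve(cal1), fdrCurve(cal2))
    expect_identical(selectedCutoff(cal1), selectedCutoff(cal2))
    # cutoff is monotone non-increasing in the target FDR
    curve <- fdrCurve(cal1)
    cuts <- vapply(c(0.01, 0.05, 0.10, 0.25), function(t) {
        ok <- curve$fdr <= t & curve$n_observed > 0
        if (any(ok)) max(curve$cutoff[ok]) else 0
    }, numeric(1))
    expect_true(all(diff(cuts) >= 0))
    expect_error(mockCalibrate(ln, ia, ib, n_perm = 10), "unstable")
})

test_that("mock calibration matches the analytic curve for uniform tests", {
    # with no prefilters and null data the test p-values are ~U(0,1), so
    # FDR(c) ~ G*c / #{p <= c}
    sim <- simulateDendriteGroups(n_genes = 300, n_a = 15, n_b = 15,
                                  de_frac = 0, depth_mean = 3000, seed = 31)
    ln <- logNormalize(sim$counts)
    cal <- mockCalibrate(ln, 1:15, 16:30, min_pct = 0, min_logfc = 0,
                         n_perm = 150, seed = 2)
    curve <- fdrCurve(cal)
    g <- length(cal@observed_p)
    mid <- curve[curve$cutoff > 0.2 & curve$cutoff < 0.8, ]
    analytic <- g * mid$cutoff / mid$n_observed
    expect_lt(stats::median(abs(mid$fdr - pmin(analytic, 1))), 0.1)
})

test_that("paired Poisson LRT equals the reference GLM fit", {
    set.seed(9)
    np <- 12
    ys <- stats::rpois(np, 40); yd <- stats::rpois(np, 8)
    Ns <- stats::rpois(np, 4000) + 1000; Nd <- stats::rpois(np, 500) + 100
    cts <- rbind(gene1 = c(ys, yd), filler = c(Ns - ys, Nd - yd))
    colnames(cts) <- c(paste0("s", 1:np), paste0("d", 1:np))
    ue <- tinyUe(cts, compartment = rep(c("soma", "dendrite"), each = np),
                 cell_id = rep(paste0("c", 1:np), 2))
    pe <- pairedEnrichment(ue, min_pct = 0)
    dat <- data.frame(y = c(ys, yd), comp = rep(c(0, 1), each = np),
                      cell = factor(rep(1:np, 2)), off = log(c(Ns, Nd)))
    f1 <- stats::glm(y ~ comp + cell + offset(off), stats::poisson, dat)
    f0 <- stats::glm(y ~ cell + offset(off), stats::poisson, dat)
    lrt <- stats::anova(f0, f1, test = "Chisq")
    expect_equal(pe$p_raw[pe$gene == "gene1"], lrt$`Pr(>Chi)`[2],
                 tolerance = 1e-6)
    expect_equal(pe$effect[pe$gene == "gene1"],
                 unname(stats::coef(f1)["comp"]), tolerance = 1e-6)
})

test_that("paired enrichment tolerates depth rescaling of single samples", {
    cfg <- simConfig(n_cell_types = 2, cells_per_type = 10,
                     paired_fraction = 1, n_genes = 300,
                     n_markers_per_type = 10, n_empty = 0, seed = 33)
    sim <- simulateExperiment(cfg)
    ue <- sim$experiment
    pe1 <- pairedEnrichment(ue, derivePairs(ue, qc_only = FALSE))
    # double every count of one dendrite sample: the offset absorbs it
    cts <- assayMat(ue, "counts")
    j <- which(compartment(ue) == "dendrite")[1]
    cts[, j] <- cts[, j] * 2L
    ue2 <- UmiExperiment(cts, as.data.frame(SummarizedExperiment::colData(ue)))
    pe2 <- pairedEnrichment(ue2, derivePairs(ue2, qc_only = FALSE))
    common <- intersect(pe1$gene, pe2$gene)
    expect_gt(stats::cor(pe1$effect[match(common, pe1$gene)],
                         pe2$effect[match(common, pe2$gene)]), 0.98)
})

test_that("an all-zero compartment is flagged as penalized, not dropped", {
    np <- 12
    cts <- rbind(gene1 = c(rep(5L, np), rep(0L, np)),
                 filler = rep(500L, 2 * np))
    colnames(cts) <- c(paste0("s", 1:np), paste0("d", 1:np))
    ue <- tinyUe(cts, compartment = rep(c("soma", "dendrite"), each = np),
                 cell_id = rep(paste0("c", 1:np), 2))
    pe <- pairedEnrichment(ue, min_pct = 0)
    row <- pe[pe$gene == "gene1", ]
    expect_true(row$separated)
    expect_true(is.finite(row$effect))
    expect_lt(row$effect, 0)
})

test_that("detection-vs-soma model reports McFadden fit with boundaries", {
    # identical detection fractions: null model equals full model
    np <- 20; ng <- 80
    cts <- matrix(5L, ng, 2 * np,
                  dimnames = list(sprintf("g%03d", 1:ng),
                                  c(paste0("s", 1:np), paste0("d", 1:np))))
    ue <- tinyUe(cts, compartment = rep(c("soma", "dendrite"), each = np),
                 cell_id = rep(paste0("c", 1:np), 2))
    dv <- suppressWarnings(detectionVsSoma(ue))  # saturated-fit warning
    expect_lt(dv$fit, 1e-8)
    expect_true(dv$boundary)
    # detection generated by the logistic law: fit near the analytic value
    set.seed(11)
    soma_mu <- stats::rlnorm(300, 2, 1.5)
    a <- -3; b <- 1.2
    p <- stats::plogis(a + b * log(soma_mu + 1))
    k <- stats::rbinom(300, np, p)
    cts2 <- rbind(
        t(vapply(soma_mu, function(m) stats::rpois(np, m) + 1L,
                 numeric(np))),      # soma counts (detected everywhere)
        matrix(0, 300, np))
    # dendrite detection exactly k of np samples per gene
    dend <- t(vapply(seq_len(300), function(g) {
        v <- integer(np); if (k[g] > 0) v[seq_len(k[g])] <- 1L; v
    }, integer(np)))
    cts2 <- cbind(t(vapply(soma_mu, function(m) stats::rpois(np, m) + 1L,
                           numeric(np))), dend)
    dimnames(cts2) <- list(sprintf("g%03d", 1:300),
                           c(paste0("s", 1:np), paste0("d", 1:np)))
    ue2 <- tinyUe(cts2, compartment = rep(c("soma", "dendrite"), each = np),
                  cell_id = rep(paste0("c", 1:np), 2))
    dv2 <- detectionVsSoma(ue2)
    # analytic McFadden: plug the true probabilities into the likelihoods
    ll_true <- sum(stats::dbinom(k, np, p, log = TRUE))
    ll_null <- sum(stats::dbinom(k, np, mean(k / np), log = TRUE))
    analytic <- 1 - ll_true / ll_null
    expect_lt(abs(dv2$fit - analytic), 0.1)
    expect_lt(dv2$p, 1e-6)
})

test_that("expression-vs-soma regression recovers planted variance fractions", {
    set.seed(13)
    ng <- 2000
    s <- stats::rnorm(ng, 5, 2)
    # slope 0.5 with noise chosen so that var explained = 50%
    noise_sd <- sqrt(0.25 * stats::var(s))
    d <- 0.5 * s + stats::rnorm(ng, 0, noise_sd)
    fakeRel <- function(vals) {
        np <- 4
        cts <- matrix(1L, ng, 2 * np)
        dimnames(cts) <- list(sprintf("g%04d", 1:ng),
                              c(paste0("s", 1:np), paste0("d", 1:np)))
        ue <- tinyUe(cts, compartment = rep(c("soma", "dendrite"),
                                            each = np),
                     cell_id = rep(paste0("c", 1:np), 2))
        corr <- cbind(matrix(rep(vals$s, 4), ng),
                      matrix(rep(vals$d, 4), ng))
        dimnames(corr) <- dimnames(cts)
        SummarizedExperiment::assay(ue, "corrected") <- corr
        ue
    }
    ev <- expressionVsSoma(fakeRel(list(s = s, d = d)),
                           min_dendrite_pct = 0)
    expect_lt(abs(ev$fit - 0.5), 0.05)
    expect_lt(abs(ev$coefficient - 0.5), 0.05)
    # exact equality: slope 1, R^2 = 1
    ev1 <- suppressWarnings(expressionVsSoma(fakeRel(list(s = s, d = s)),
                                             min_dendrite_pct = 0))
    expect_equal(ev1$fit, 1, tolerance = 1e-10)
    expect_equal(ev1$coefficient, 1, tolerance = 1e-10)
    # independent means: R^2 near zero
    ev0 <- expressionVsSoma(fakeRel(list(s = s,
                                         d = stats::rnorm(ng, 5, 2))),
                            min_dendrite_pct = 0)
    expect_lt(ev0$fit, 0.05)
})
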