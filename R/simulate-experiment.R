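#' Configuration for the synthetic soma-dendrite experiment
#'
#' Builds the parameter list consumed by \code{\link{simulateExperiment}}.
#' The defaults emulate the statistical structure of a subcellular
#' single-neuron LCM/scRNA-seq study at desk scale: five neuronal cell types
#' with marker genes, lognormal gene abundance, a roughly 10:1 soma:dendrite
#' sequencing-depth ratio, gene-specific dendritic enrichment and
#' de-enrichment factors acting on within-cell relative abundance,
#' near-empty negative-control cuts, and a 92-species ERCC spike-in panel
#' captured binomially at a known per-molecule efficiency.
#'
#' Depths are scaled down (soma 5,000 / dendrite 500 expected UMI, versus
#' tens of thousands in a real run) so that simulations run in seconds; the
#' soma:dendrite ratio is preserved.
#'
#' @param n_cell_types number of planted neuronal types.
#' @param cells_per_type neurons per type.
#' @param n_genes number of biological (non-ERCC) genes.
#' @param n_markers_per_type genes boosted in each type (disjoint sets).
#' @param marker_log2_boost log2 abundance boost of a marker in its own type.
#' @param type_sdlog lognormal sd of the type-specific global expression
#'   jitter: beyond their markers, cell types differ mildly across the whole
#'   transcriptome (between-type log-expression correlation about 0.96 at
#'   the default), as neuronal types do in tissue atlases.
#' @param soma_depth_mean expected total UMI per soma.
#' @param depth_cv lognormal coefficient of variation of per-sample depth.
#' @param dendrite_depth_fraction expected dendrite/soma depth ratio.
#' @param paired_fraction fraction of neurons that contribute a dendrite
#'   sample in addition to their soma.
#' @param enrich_frac,deenrich_frac fractions of genes with dendritic
#'   enrichment / de-enrichment.
#' @param enrich_log2,deenrich_log2 log2 dendrite:soma concentration-ratio
#'   effect sizes for the two planted classes.
#' @param nb_dispersion negative-binomial size parameter of counts
#'   (\code{Inf} gives the Poisson limit).
#' @param n_empty number of empty-cut negative controls.
#' @param empty_contamination_mean expected total UMI per empty cut.
#' @param ercc_panel data.frame with columns \code{species_id} and
#'   \code{copies_per_sample} (see \code{\link{erccPanel}}).
#' @param capture_efficiency probability that one spiked molecule yields a
#'   UMI.
#' @param gene_sdlog lognormal sd (natural log) of baseline gene abundance.
#' @param seed integer seed; a fixed seed makes all outputs identical.
#'
#' @return A named list of validated parameters (class \code{"SimConfig"}).
#' @export
simConfig <- function(n_cell_types = 5, cells_per_type = 40, n_genes = 2000,
                      n_markers_per_type = 25, marker_log2_boost = 3,
                      type_sdlog = 0.3,
                      soma_depth_mean = 5000, depth_cv = 0.3,
                      dendrite_depth_fraction = 0.10, paired_fraction = 0.55,
                      enrich_frac = 0.10, deenrich_frac = 0.15,
                      enrich_log2 = 1, deenrich_log2 = -1,
                      nb_dispersion = 10, n_empty = 16,
                      empty_contamination_mean = 41,
                      ercc_panel = erccPanel(), capture_efficiency = 0.44,
                      gene_sdlog = 1.5, seed = 1L) {
    cfg <- as.list(environment())
    fr <- c(dendrite_depth_fraction = dendrite_depth_fraction,
            paired_fraction = paired_fraction, enrich_frac = enrich_frac,
            deenrich_frac = deenrich_frac,
            capture_efficiency = capture_efficiency)
    if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
        stop("fractions and efficiencies must be finite and in [0, 1]")
    if (enrich_frac + deenrich_frac > 1)
        stop("enrich_frac + deenrich_frac must not exceed 1")
    pos <- c(soma_depth_mean, empty_contamination_mean, nb_dispersion,
             gene_sdlog, depth_cv)
    if (!is.finite(type_sdlog) || type_sdlog < 0)
        stop("type_sdlog must be finite and non-negative")
    if (any(is.na(pos)) || any(pos <= 0))
        stop("depths, dispersion and spread parameters must be positive")
    if (!is.finite(soma_depth_mean))
        stop("soma_depth_mean must be finite")
    ints <- c(n_cell_types, cells_per_type, n_genes, n_markers_per_type,
              n_empty)
    if (any(!is.finite(ints)) || any(ints < 0) || any(ints != round(ints)))
        stop("counts of types, cells and genes must be non-negative integers")
    if (n_cell_types * n_markers_per_type > n_genes)
        stop("marker sets exceed the gene pool")
    class(cfg) <- "SimConfig"
    cfg
}

# NB draw with Poisson limit at size = Inf
.rcounts <- function(n, mu, size) {
    if (is.infinite(size)) stats::rpois(n, mu) else
        stats::rnbinom(n, mu = mu, size = size)
}

#' Simulate two dendritic sample groups with planted differential genes
#'
#' Generates dendrite-compartment UMI counts for two cell-type groups with
#' a planted fraction of truly differential genes (relative fold shifts on
#' the compositional gene abundances), the input of the mock-permutation
#' FDR calibration study. Group sizes default to the dendritic group sizes
#' of the motivating comparison (36 and 30 dendrites) and the expected
#' total UMI per dendrite defaults to 6800, the observed mean dendritic
#' molecule count of the emulated protocol.
#'
#' @param n_genes number of genes.
#' @param n_a,n_b samples per group.
#' @param de_frac fraction of genes truly differential.
#' @param fold relative fold shift of differential genes in group B.
#' @param depth_mean expected total UMI per dendrite.
#' @param depth_cv lognormal CV of per-sample depth.
#' @param nb_dispersion NB size (Inf = Poisson).
#' @param gene_sdlog lognormal spread of baseline abundance.
#' @param seed integer seed.
#' @return list with \code{counts} (genes x samples), \code{group} (factor
#'   \code{"A"}/\code{"B"} per sample) and \code{de_genes} (character).
#' @export
simulateDendriteGroups <- function(n_genes = 2000L, n_a = 36L, n_b = 30L,
                                   de_frac = 0.10, fold = 2,
                                   depth_mean = 6800, depth_cv = 0.3,
                                   nb_dispersion = 10, gene_sdlog = 1.5,
                                   seed = 1L) {
    stopifnot(de_frac >= 0, de_frac <= 1, fold > 0, depth_mean > 0)
    set.seed(seed)
    mu <- stats::rlnorm(n_genes, 0, gene_sdlog)
    p_a <- mu / sum(mu)
    n_de <- round(de_frac * n_genes)
    de <- sample.int(n_genes, n_de)
    shift <- rep(1, n_genes)
    if (n_de) shift[de] <- fold
    p_b <- p_a * shift
    p_b <- p_b / sum(p_b)
    sdl <- sqrt(log(1 + depth_cv^2))
    depth <- stats::rlnorm(n_a + n_b, log(depth_mean) - sdl^2 / 2, sdl)
    cts <- vapply(seq_len(n_a + n_b), function(i) {
        p <- if (i <= n_a) p_a else p_b
        .rcounts(n_genes, p * depth[i], nb_dispersion)
    }, numeric(n_genes))
    rownames(cts) <- sprintf("gene%05d", seq_len(n_genes))
    colnames(cts) <- sprintf("dend%03d", seq_len(n_a + n_b))
    list(counts = cts,
         group = factor(rep(c("A", "B"), c(n_a, n_b))),
         de_genes = rownames(cts)[sort(de)])
}

#' Simulate a paired soma-dendrite UMI-count experiment
#'
#' Generates one soma sample per simulated neuron and, for a configurable
#' subset of neurons, one paired dendrite sample sharing the same
#' \code{cell_id}. Per-type somatic gene means are drawn lognormal with
#' marker boosts; dendritic expected counts apply the planted per-gene
#' log2 enrichment factors to the within-cell relative abundance
#' (compositional), renormalize, and scale by the (lower) dendritic depth.
#' Counts are negative-binomial. Empty cuts draw shallow counts from the
#' mean ambient composition, and ERCC spike-ins are added to every
#' non-empty sample as Binomial(copies, capture_efficiency) molecule counts.
#'
#' @param config a \code{\link{simConfig}} list.
#' @return A list with elements \code{experiment}
#'   (\linkS4class{UmiExperiment}), and \code{truth}, a list with
#'   \code{cell_type_labels} (named by cell id), \code{marker_genes} (list
#'   per type), \code{enrichment_factor} (named log2 dendrite:soma
#'   concentration ratios), \code{de_genes} (per one-vs-rest comparison),
#'   and \code{ercc_truth} (copies per sample per species).
#' @export
simulateExperiment <- function(config = simConfig()) {
    if (!inherits(config, "SimConfig")) config <- do.call(simConfig, config)
    set.seed(config$seed)
    ng <- config$n_genes
    nt <- config$n_cell_types
    genes <- sprintf("gene%05d", seq_len(ng))
    types <- paste0("type", seq_len(nt))

    base_mu <- stats::rlnorm(ng, meanlog = 0, sdlog = config$gene_sdlog)
    marker_idx <- if (config$n_markers_per_type > 0) {
        pool <- sample.int(ng, nt * config$n_markers_per_type)
        split(pool, rep(seq_len(nt), each = config$n_markers_per_type))
    } else rep(list(integer(0)), nt)
    type_mu <- matrix(base_mu, ng, nt) *
        matrix(stats::rlnorm(ng * nt, 0, config$type_sdlog), ng, nt)
    for (t in seq_len(nt))
        type_mu[marker_idx[[t]], t] <-
            type_mu[marker_idx[[t]], t] * 2^config$marker_log2_boost
    type_p <- sweep(type_mu, 2, colSums(type_mu), "/")

    enr <- numeric(ng)
    n_up <- round(config$enrich_frac * ng)
    n_dn <- round(config$deenrich_frac * ng)
    pick <- sample.int(ng, n_up + n_dn)
    if (n_up) enr[pick[seq_len(n_up)]] <- config$enrich_log2
    if (n_dn) enr[pick[n_up + seq_len(n_dn)]] <- config$deenrich_log2
    names(enr) <- genes

    n_cells <- nt * config$cells_per_type
    cell_type <- rep(seq_len(nt), each = config$cells_per_type)
    cell_ids <- sprintf("cell%04d", seq_len(n_cells))
    n_paired <- round(config$paired_fraction * config$cells_per_type)
    paired <- unlist(lapply(split(seq_len(n_cells), cell_type), function(i)
        if (n_paired) sort(sample(i, n_paired)) else integer(0)))

    sdl <- sqrt(log(1 + config$depth_cv^2))
    soma_depth <- stats::rlnorm(n_cells, log(config$soma_depth_mean) -
                                sdl^2 / 2, sdl)
    dend_depth <- stats::rlnorm(n_cells,
                                log(config$soma_depth_mean *
                                    config$dendrite_depth_fraction) -
                                sdl^2 / 2, sdl)

    soma_counts <- matrix(0L, ng, n_cells)
    dend_counts <- matrix(0L, ng, length(paired))
    for (i in seq_len(n_cells)) {
        p <- type_p[, cell_type[i]]
        soma_counts[, i] <- .rcounts(ng, p * soma_depth[i],
                                     config$nb_dispersion)
    }
    for (j in seq_along(paired)) {
        i <- paired[j]
        q <- type_p[, cell_type[i]] * 2^enr
        q <- q / sum(q)
        dend_counts[, j] <- .rcounts(ng, q * dend_depth[i],
                                     config$nb_dispersion)
    }

    ambient <- rowMeans(type_p)
    empty_counts <- matrix(stats::rpois(ng * config$n_empty,
                                        rep(ambient, config$n_empty) *
                                        config$empty_contamination_mean),
                           ng, config$n_empty)

    panel <- config$ercc_panel
    n_bio <- n_cells + length(paired)
    ercc_counts <- matrix(stats::rbinom(nrow(panel) * n_bio,
                                        size = rep(panel$copies_per_sample,
                                                   n_bio),
                                        prob = config$capture_efficiency),
                          nrow(panel), n_bio)
    ercc_empty <- matrix(0L, nrow(panel), config$n_empty)

    counts <- cbind(rbind(soma_counts, ercc_counts[, seq_len(n_cells),
                                                   drop = FALSE]),
                    rbind(dend_counts,
                          ercc_counts[, n_cells + seq_along(paired),
                                      drop = FALSE]),
                    rbind(empty_counts, ercc_empty))
    rownames(counts) <- c(genes, panel$species_id)
    soma_ids <- paste0("soma_", cell_ids)
    dend_ids <- if (length(paired)) paste0("dend_", cell_ids[paired]) else
        character(0)
    empty_ids <- sprintf("empty%03d", seq_len(config$n_empty))
    colnames(counts) <- c(soma_ids, dend_ids, empty_ids)

    plates <- paste0("plate",
                     (seq_len(ncol(counts)) - 1L) %% 12L + 1L)
    sd <- data.frame(
        compartment = c(rep("soma", n_cells),
                        rep("dendrite", length(paired)),
                        rep("empty", config$n_empty)),
        cell_id = c(cell_ids, cell_ids[paired],
                    rep(NA_character_, config$n_empty)),
        plate = plates,
        row.names = colnames(counts))

    ue <- UmiExperiment(counts, sampleData = sd)

    marker_genes <- lapply(marker_idx, function(i) genes[i])
    names(marker_genes) <- types
    truth <- list(
        cell_type_labels = stats::setNames(types[cell_type], cell_ids),
        marker_genes = marker_genes,
        enrichment_factor = enr,
        de_genes = stats::setNames(marker_genes,
                                   paste0(types, "_vs_rest")),
        ercc_truth = stats::setNames(panel$copies_per_sample,
                                     panel$species_id))
    list(experiment = ue, truth = truth)
}
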