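test_that("simConfig rejects invalid parameter values", {
    expect_error(simConfig(dendrite_depth_fraction = 1.5), "fractions")
    expect_error(simConfig(capture_efficiency = -0.1), "fractions")
    expect_error(simConfig(soma_depth_mean = 0), "positive")
    expect_error(simConfig(soma_depth_mean = Inf), "finite")
    expect_error(simConfig(nb_dispersion = -1), "positive")
    expect_error(simConfig(n_genes = 10.5), "integers")
    expect_error(simConfig(n_genes = 10, n_markers_per_type = 3,
                           n_cell_types = 5), "marker sets")
})

test_that("identical config and seed give byte-identical outputs", {
    cfg <- simConfig(n_cell_types = 2, cells_per_type = 4, n_genes = 80,
                     n_markers_per_type = 8, soma_depth_mean = 400,
                     ercc_panel = erccPanel(10), seed = 31)
    a <- simulateExperiment(cfg)
    b <- simulateExperiment(cfg)
    expect_identical(assayMat(a$experiment, "counts"),
                     assayMat(b$experiment, "counts"))
    expect_identical(a$truth, b$truth)
    d1 <- file.path(tempdir(), "mtx_a"); d2 <- file.path(tempdir(), "mtx_b")
    writeUmiMtx(a$experiment, d1); writeUmiMtx(b$experiment, d2)
    expect_identical(readLines(file.path(d1, "matrix.mtx")),
                     readLines(file.path(d2, "matrix.mtx")))
})

test_that("perfect capture in the Poisson limit returns exact spike counts", {
    panel <- data.frame(species_id = sprintf("ERCC-%05d", 1:6),
                        copies_per_sample = rep(10L, 6))
    cfg <- simConfig(n_cell_types = 2, cells_per_type = 10, n_genes = 50,
                     n_markers_per_type = 5, nb_dispersion = Inf,
                     capture_efficiency = 1, ercc_panel = panel,
                     n_empty = 0, seed = 2)
    sim <- simulateExperiment(cfg)
    ercc <- assayMat(sim$experiment, "counts")[isErcc(sim$experiment), ]
    expect_true(all(ercc == 10L))
})

test_that("zero enrichment factors leave dendrite:soma proportions flat", {
    cfg <- simConfig(n_cell_types = 1, cells_per_type = 200, n_genes = 300,
                     n_markers_per_type = 0, paired_fraction = 1,
                     enrich_frac = 0, deenrich_frac = 0, n_empty = 0,
                     seed = 17)
    sim <- simulateExperiment(cfg)
    ue <- sim$experiment
    cts <- assayMat(ue, "counts")[!isErcc(ue), ]
    soma <- cts[, compartment(ue) == "soma"]
    dend <- cts[, compartment(ue) == "dendrite"]
    ps <- rowMeans(sweep(soma, 2, colSums(soma), "/"))
    pd <- rowMeans(sweep(dend, 2, colSums(dend), "/"))
    # moderately expressed genes: the proportion ratio should center on 1
    keep <- ps > stats::quantile(ps, 0.25)
    ratio <- pd[keep] / ps[keep]
    se <- stats::sd(ratio) / sqrt(length(ratio))
    expect_lt(abs(mean(ratio) - 1), 3 * se + 0.02)
})

test_that("depth structure matches the configured soma:dendrite ratio", {
    cfg <- simConfig(n_cell_types = 2, cells_per_type = 60, n_genes = 400,
                     n_markers_per_type = 10, paired_fraction = 1,
                     dendrite_depth_fraction = 0.10, n_empty = 0, seed = 8)
    sim <- simulateExperiment(cfg)
    ue <- sim$experiment
    tot <- totalUmi(ue)
    cid <- cellId(ue)
    soma <- tot[compartment(ue) == "soma"]
    names(soma) <- cid[compartment(ue) == "soma"]
    dend <- tot[compartment(ue) == "dendrite"]
    names(dend) <- cid[compartment(ue) == "dendrite"]
    ratio <- stats::median(soma[names(dend)] / dend)
    expect_lt(abs(ratio - 10) / 10, 0.25)
})

test_that("ground truth refers to emitted genes and samples and is complete", {
    cfg <- simConfig(n_cell_types = 3, cells_per_type = 5, n_genes = 120,
                     n_markers_per_type = 6, enrich_frac = 0.1,
                     deenrich_frac = 0.1, seed = 4)
    sim <- simulateExperiment(cfg)
    ue <- sim$experiment
    tr <- sim$truth
    genes <- rownames(ue)[!isErcc(ue)]
    expect_true(all(unlist(tr$marker_genes) %in% genes))
    expect_true(all(names(tr$enrichment_factor) %in% genes))
    expect_true(all(names(tr$cell_type_labels) %in% cellId(ue)))
    expect_true(all(lengths(tr$marker_genes) > 0))
    expect_gt(sum(tr$enrichment_factor > 0), 0)
    expect_gt(sum(tr$enrichment_factor < 0), 0)
    expect_true(all(names(tr$ercc_truth) %in% rownames(ue)[isErcc(ue)]))
})

test_that("profile simulation honours rate, noise and determinism contracts", {
    # zero rate, zero noise: all-zero profiles and empty truth
    p0 <- simulateProfiles(n_profiles = 5, length_um = 20, punctum_rate = 0,
                           noise_sd = 0, seed = 3)
    expect_true(all(p0$profiles$intensity[p0$profiles$channel == "gene"]
                    == 0))
    expect_true(all(lengths(p0$truth$punctum_positions) == 0))
    # constant rate: mean puncta per profile matches the Poisson mean
    pr <- simulateProfiles(n_profiles = 500, length_um = 100,
                           punctum_rate = 0.2, noise_sd = 0, seed = 9)
    m <- mean(lengths(pr$truth$punctum_positions))
    expect_lt(abs(m - 20), 3 * sqrt(20 / 500))
    # determinism
    pa <- simulateProfiles(n_profiles = 4, seed = 12)
    pb <- simulateProfiles(n_profiles = 4, seed = 12)
    expect_identical(pa, pb)
    # invalid psf rejected
    expect_error(simulateProfiles(psf_sigma_um = 0), "psf_sigma_um")
})

test_that("decaying punctum rates concentrate density proximally", {
    rate <- function(x) 0.3 * 2^(-x / 20)
    hits <- vapply(1:10, function(b) {
        pr <- simulateProfiles(n_profiles = 100, length_um = 60,
                               punctum_rate = rate, noise_sd = 0,
                               seed = 100 + b)
        pos <- unlist(pr$truth$punctum_positions)
        sum(pos < 20) > sum(pos >= 20 & pos < 40)
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("read simulation is conservative and annotates corrupt classes", {
    cfg <- simConfig(n_cell_types = 2, cells_per_type = 2, n_genes = 25,
                     n_markers_per_type = 4, soma_depth_mean = 120,
                     n_empty = 0, ercc_panel = erccPanel(6),
                     paired_fraction = 1, seed = 21)
    sim <- simulateExperiment(cfg)
    r1 <- tempfile(fileext = ".fastq.gz")
    r2 <- tempfile(fileext = ".fastq.gz")
    info <- simulateReads(sim$experiment, r1, r2, error_rate = 0,
                          corrupt = list(low_q_barcode = 0.05,
                                         short_insert = 0.05,
                                         homopolymer = 0.05,
                                         umi_dup = 0.05),
                          seed = 5)
    cts <- assayMat(sim$experiment, "counts")
    n_umi <- sum(cts[!isErcc(sim$experiment), ])
    tr <- info$truth
    expect_identical(sum(tr$class == "clean"), as.integer(n_umi))
    for (cl in c("low_q_barcode", "short_insert", "homopolymer", "umi_dup"))
        expect_identical(sum(tr$class == cl), as.integer(round(0.05 * n_umi)))
    # same seed: byte-identical FASTQ
    r1b <- tempfile(fileext = ".fastq.gz")
    r2b <- tempfile(fileext = ".fastq.gz")
    simulateReads(sim$experiment, r1b, r2b, error_rate = 0,
                  corrupt = list(low_q_barcode = 0.05, short_insert = 0.05,
                                 homopolymer = 0.05, umi_dup = 0.05),
                  seed = 5)
    con1 <- gzfile(r1, "rb"); con2 <- gzfile(r1b, "rb")
    expect_identical(readBin(con1, "raw", 1e6), readBin(con2, "raw", 1e6))
    close(con1); close(con2)
})

test_that("an empty count matrix yields an empty FASTQ without error", {
    cts <- matrix(0L, 3, 2, dimnames = list(paste0("g", 1:3),
                                            paste0("s", 1:2)))
    ue <- tinyUe(cts)
    r1 <- tempfile(fileext = ".fastq")
    r2 <- tempfile(fileext = ".fastq")
    expect_no_error(simulateReads(ue, r1, r2, seed = 1))
    expect_identical(length(readLines(r1)), 0L)
})

test_that("index collisions in a user-supplied whitelist are rejected", {
    cts <- matrix(1L, 2, 2, dimnames = list(paste0("g", 1:2),
                                            paste0("s", 1:2)))
    wl <- data.frame(index = c("ACGTACGT", "ACGTACGT"),
                     sample_id = c("s1", "s2"))
    expect_error(simulateReads(tinyUe(cts), tempfile(), tempfile(),
                               whitelist = wl), "collision")
})
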