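q30 <- function(n) strrep(rawToChar(as.raw(63L)), n)

test_that("filterAndTrim trims homopolymer tails and rejects short reads", {
    core <- strrep("ACGT", 7)                       # 28 nt
    read31 <- paste0(core, "CGC")                   # 31 nt, non-A terminus
    # 7 terminal A (> 6): the whole run is stripped, read retained at 31 nt
    res <- filterAndTrim(paste0(read31, strrep("A", 7)), q30(18))
    expect_identical(res$seq, read31)
    expect_true(res$pass)
    # exactly 6 terminal A: tolerated, untouched
    res6 <- filterAndTrim(paste0(read31, strrep("A", 6)), q30(18))
    expect_identical(res6$seq, paste0(read31, strrep("A", 6)))
    # 29 nt after trimming: rejected as too short
    res29 <- filterAndTrim(paste0(substr(read31, 1, 29), strrep("A", 8)),
                           q30(18))
    expect_false(res29$pass)
    expect_identical(res29$cause, "too_short")
    # clean full-quality read passes unchanged
    tag <- paste0(strrep("ACGT", 14), "AC")          # 58 nt, no homopolymer
    resid <- filterAndTrim(tag, q30(18))
    expect_identical(resid$seq, tag)
    expect_true(resid$pass)
})

test_that("filterAndTrim rejects low-quality barcodes and low complexity", {
    tag <- paste0(strrep("ACGT", 14), "AC")
    lowq <- paste0(strrep(rawToChar(as.raw(8L + 33L)), 1), q30(17))
    expect_identical(filterAndTrim(tag, lowq)$cause, "low_q_barcode")
    # dinucleotide repeat has 1 bit/nt: below a 1.2 bits/nt floor
    rep2 <- strrep("AC", 20)
    expect_identical(filterAndTrim(rep2, q30(18),
                                   min_entropy = 1.2)$cause,
                     "low_complexity")
    # adapter trimming cuts at the adapter start
    withad <- paste0(strrep("ACGT", 10), "AGATCGGAAGAG")
    resa <- filterAndTrim(withad, q30(18), adapter = "AGATCGGAAGAG")
    expect_identical(resa$seq, strrep("ACGT", 10))
})

test_that("demultiplex resolves exact and single-mismatch barcodes", {
    set.seed(1)
    wl <- generateWhitelist(paste0("s", 1:8), seed = 3)
    expect_identical(demultiplex(wl$index[3], wl), "s3")
    # one mismatch off entry 3: still >= 2 away from all others by invariant
    bc <- wl$index[3]
    substr(bc, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                substr(bc, 5, 5))[1]
    d_all <- vapply(wl$index, function(w)
        sum(strsplit(w, "")[[1]] != strsplit(bc, "")[[1]]), numeric(1))
    expect_identical(unname(which(d_all <= 1)), 3L)   # brute-force check
    expect_identical(demultiplex(bc, wl), "s3")
    # two mismatches from everything: rejected
    bc2 <- wl$index[3]
    for (p in c(1, 2)) substr(bc2, p, p) <-
        setdiff(c("A", "C", "G", "T"), substr(bc2, p, p))[1]
    expect_true(all(vapply(wl$index, function(w)
        sum(strsplit(w, "")[[1]] != strsplit(bc2, "")[[1]]),
        numeric(1)) >= 2))
    expect_true(is.na(demultiplex(bc2, wl)))
    # whitelist violating the distance invariant is a configuration error
    bad <- data.frame(index = c("AAAAAAAA", "AAAAAAAT"),
                      sample_id = c("a", "b"))
    expect_error(demultiplex("AAAAAAAA", bad), "invariant")
    expect_error(demultiplex("AAAAAAAA",
                             data.frame(index = c("AAAAAAAA", "AAAAAAAA"),
                                        sample_id = c("a", "b"))),
                 "duplicated")
})

test_that("assignGene assigns within tolerance and returns NA beyond it", {
    set.seed(2)
    tx <- generateTranscriptome(paste0("g", 1:20), seed = 7)
    expect_identical(assignGene(tx$tag[4], tx), "g4")
    # two mismatches: still uniquely g4 (tags are >= 10 apart)
    r <- tx$tag[4]
    for (p in c(3, 9)) substr(r, p, p) <-
        setdiff(c("A", "C", "G", "T"), substr(r, p, p))[1]
    expect_identical(assignGene(r, tx), "g4")
    # distance 6 from its own tag (max_mismatch + 1) and > 5 from the rest
    r6 <- tx$tag[4]
    for (p in seq(1, 26, by = 5)) substr(r6, p, p) <-
        setdiff(c("A", "C", "G", "T"), substr(r6, p, p))[1]
    d <- vapply(tx$tag, function(t)
        sum(strsplit(t, "")[[1]] != strsplit(r6, "")[[1]]), numeric(1))
    expect_true(min(d) == 6)
    expect_true(is.na(assignGene(r6, tx)))
})

test_that("UMI collapse merges by connected components at distance 1", {
    df <- function(umis) data.frame(sample_id = "s1", gene_id = "g1",
                                    umi = umis)
    # exact duplicates count once
    expect_identical(collapseUmis(df(rep("AAAAAAAAAA", 5)))["g1", "s1"], 1L)
    # one near-duplicate pair plus one distant singleton
    expect_identical(collapseUmis(df(c("AAAAAAAAAA", "AAAAAAAAAT",
                                       "GGGGGGGGGG")))["g1", "s1"], 2L)
    # transitive chain of distance-1 links merges into one molecule
    expect_identical(collapseUmis(df(c("AAAAAAAAAA", "AAAAAAAAAT",
                                       "AAAAAAAATT")))["g1", "s1"], 1L)
    # strata are independent across samples and genes
    two <- rbind(data.frame(sample_id = "s1", gene_id = "g1",
                            umi = "AAAAAAAAAA"),
                 data.frame(sample_id = "s2", gene_id = "g1",
                            umi = "AAAAAAAAAT"))
    cc <- collapseUmis(two)
    expect_identical(unname(cc["g1", c("s1", "s2")]), c(1L, 1L))
})

test_that("collapse equals the union-find oracle and is monotone", {
    set.seed(42)
    for (r in 1:40) {
        umis <- randomStratum(sample(2:80, 1))
        got <- collapseUmis(data.frame(sample_id = "s", gene_id = "g",
                                       umi = umis))["g", "s"]
        expect_identical(got, as.integer(oracleCollapse(umis)))
    }
    # adding reads never decreases a cell; counts are bounded sensibly
    umis <- randomStratum(60)
    base <- collapseUmis(data.frame(sample_id = "s", gene_id = "g",
                                    umi = umis))["g", "s"]
    more <- collapseUmis(data.frame(sample_id = "s", gene_id = "g",
                                    umi = c(umis, randomStratum(10))))["g", "s"]
    expect_gte(more, base)
    expect_lte(base, length(unique(umis)))
})

test_that("directional collapse respects the count-ratio rule", {
    # 10 reads of one UMI seed 1 read of a neighbor: merged directionally
    df <- data.frame(sample_id = "s", gene_id = "g",
                     umi = c(rep("AAAAAAAAAA", 10), "AAAAAAAAAT"))
    expect_identical(collapseUmis(df, directional = TRUE)["g", "s"], 1L)
    # 5 vs 4 reads: neither side dominates, kept separate
    df2 <- data.frame(sample_id = "s", gene_id = "g",
                      umi = c(rep("AAAAAAAAAA", 5), rep("AAAAAAAAAT", 4)))
    expect_identical(collapseUmis(df2, directional = TRUE)["g", "s"], 2L)
    expect_identical(collapseUmis(df2, directional = FALSE)["g", "s"], 1L)
})

test_that("clean reads round-trip to the exact simulated count matrix", {
    cfg <- simConfig(n_cell_types = 2, cells_per_type = 3, n_genes = 30,
                     n_markers_per_type = 5, soma_depth_mean = 150,
                     n_empty = 0, ercc_panel = erccPanel(8),
                     paired_fraction = 1, seed = 3)
    sim <- simulateExperiment(cfg)
    ue <- sim$experiment
    r1 <- tempfile(fileext = ".fastq.gz")
    r2 <- tempfile(fileext = ".fastq.gz")
    info <- simulateReads(ue, r1, r2, error_rate = 0, seed = 11)
    res <- countReads(r1, r2, info$whitelist, info$transcriptome,
                      mito_prefix = character(0))
    orig <- assayMat(ue, "counts")[!isErcc(ue), ]
    rec <- assayMat(res$experiment, "counts")[rownames(orig), colnames(orig)]
    expect_equal(unname(rec), unname(orig), ignore_attr = TRUE)
    tl <- res$tally
    expect_identical(tl$reads[tl$cause == "accepted"],
                     tl$reads[tl$cause == "total"])
})

test_that("injected UMI duplicates are removed exactly by collapse", {
    cfg <- simConfig(n_cell_types = 1, cells_per_type = 4, n_genes = 20,
                     n_markers_per_type = 0, soma_depth_mean = 200,
                     n_empty = 0, ercc_panel = erccPanel(6),
                     paired_fraction = 1, seed = 13)
    sim <- simulateExperiment(cfg)
    r1 <- tempfile(fileext = ".fastq.gz")
    r2 <- tempfile(fileext = ".fastq.gz")
    info <- simulateReads(sim$experiment, r1, r2, error_rate = 0,
                          corrupt = list(umi_dup = 0.10), seed = 19)
    res <- countReads(r1, r2, info$whitelist, info$transcriptome,
                      mito_prefix = character(0))
    orig <- assayMat(sim$experiment, "counts")[!isErcc(sim$experiment), ]
    rec <- assayMat(res$experiment, "counts")[rownames(orig), colnames(orig)]
    # duplicates collapse back onto their parents: matrix unchanged
    expect_equal(unname(rec), unname(orig), ignore_attr = TRUE)
    k <- sum(info$truth$class == "umi_dup")
    expect_gt(k, 0)
    tl <- res$tally
    # the duplicates were accepted reads, removed only at the UMI stage
    expect_identical(tl$reads[tl$cause == "accepted"],
                     as.integer(sum(orig) + k))
})

test_that("rejected reads are fully accounted for by cause tallies", {
    cfg <- simConfig(n_cell_types = 1, cells_per_type = 4, n_genes = 15,
                     n_markers_per_type = 0, soma_depth_mean = 100,
                     n_empty = 0, ercc_panel = erccPanel(6),
                     paired_fraction = 0, seed = 23)
    sim <- simulateExperiment(cfg)
    r1 <- tempfile(fileext = ".fastq.gz")
    r2 <- tempfile(fileext = ".fastq.gz")
    simulateReads(sim$experiment, r1, r2, error_rate = 0,
                  corrupt = list(low_q_barcode = 0.1, short_insert = 0.1,
                                 homopolymer = 0.05), seed = 29)
    wl <- generateWhitelist(colnames(sim$experiment)[
        compartment(sim$experiment) != "empty"], seed = somadendrite:::.subSeed(29, 1))
    tx <- generateTranscriptome(rownames(sim$experiment)[
        !isErcc(sim$experiment)], seed = somadendrite:::.subSeed(29, 2))
    res <- countReads(r1, r2, wl, tx, mito_prefix = character(0))
    tl <- stats::setNames(res$tally$reads, res$tally$cause)
    expect_identical(unname(tl["total"]),
                     unname(sum(tl[c("low_q_barcode", "too_short",
                                     "low_complexity", "no_index",
                                     "no_gene", "accepted")])))
    expect_gt(tl[["low_q_barcode"]], 0)
    expect_gt(tl[["too_short"]], 0)
})

test_that("mitochondrial prefixes are dropped from count matrices", {
    wl <- data.frame(index = "ACGTACGT", sample_id = "s1")
    tx <- generateTranscriptome(c("mt-Co1", "Actb"), seed = 5)
    r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
    s1 <- Biostrings::BStringSet(paste0("ACGTACGT", "AAAAACCCCC"))
    names(s1) <- "r1"
    s2 <- Biostrings::BStringSet(tx$tag[1]); names(s2) <- "r1"
    Biostrings::writeXStringSet(s1, r1, format = "fastq",
        qualities = Biostrings::BStringSet(q30(18)))
    Biostrings::writeXStringSet(s2, r2, format = "fastq",
        qualities = Biostrings::BStringSet(q30(58)))
    res <- countReads(r1, r2, wl, tx)
    expect_identical(rownames(res$experiment), "Actb")
})

test_that("malformed Read 1 lengths raise a parse error naming the record", {
    wl <- data.frame(index = "ACGTACGT", sample_id = "s1")
    tx <- generateTranscriptome("g1", seed = 5)
    r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
    s1 <- Biostrings::BStringSet("ACGT")  # truncated read 1
    names(s1) <- "r1"
    Biostrings::writeXStringSet(s1, r1, format = "fastq",
        qualities = Biostrings::BStringSet(q30(4)))
    s2 <- Biostrings::BStringSet(tx$tag[1]); names(s2) <- "r1"
    Biostrings::writeXStringSet(s2, r2, format = "fastq",
        qualities = Biostrings::BStringSet(q30(58)))
    expect_error(countReads(r1, r2, wl, tx), "record 1")
})
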