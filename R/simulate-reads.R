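#' Read structure of the barcoded library
#'
#' Read 1 carries the sample index followed by the UMI (18 nt in total by
#' default, partitioned 8 + 10; the partition is configurable and recorded
#' in output metadata); Read 2 carries the 58-nt gene sequence.
#'
#' @param index_len sample-index length in nt.
#' @param umi_len UMI length in nt.
#' @param read2_len gene-read length in nt.
#' @return list with \code{index_len}, \code{umi_len}, \code{read1_len},
#'   \code{read2_len}.
#' @export
readStructure <- function(index_len = 8L, umi_len = 10L, read2_len = 58L) {
    stopifnot(index_len > 0, umi_len > 0, read2_len > 0)
    list(index_len = as.integer(index_len), umi_len = as.integer(umi_len),
         read1_len = as.integer(index_len + umi_len),
         read2_len = as.integer(read2_len))
}

#' Generate an index whitelist
#'
#' Index sequences are drawn at pairwise Hamming distance >= \code{min_dist}
#' (default 3) so that single-mismatch rescue during demultiplexing is
#' unambiguous.
#'
#' @param sample_ids character vector of sample ids, one index per sample.
#' @param index_len index length in nt.
#' @param min_dist minimum pairwise Hamming distance.
#' @param seed integer seed.
#' @return data.frame with columns \code{index} and \code{sample_id}.
#' @export
generateWhitelist <- function(sample_ids, index_len = 8L, min_dist = 3L,
                              seed = 1L) {
    set.seed(seed)
    data.frame(index = .distinctDna(length(sample_ids), index_len, min_dist),
               sample_id = sample_ids, stringsAsFactors = FALSE)
}

#' Generate a toy transcriptome of gene tag sequences
#'
#' Assigns each gene a unique tag at pairwise Hamming distance >= 10 so that
#' gene assignment with up to 5 mismatches is unambiguous. Stands in for
#' genome alignment, which is out of scope.
#'
#' @param gene_ids character vector of gene ids.
#' @param tag_len tag length in nt (the gene-read length).
#' @param min_dist minimum pairwise Hamming distance between tags.
#' @param seed integer seed.
#' @return data.frame with columns \code{gene_id} and \code{tag}.
#' @export
generateTranscriptome <- function(gene_ids, tag_len = 58L, min_dist = 10L,
                                  seed = 1L) {
    set.seed(seed)
    data.frame(gene_id = gene_ids,
               tag = .distinctDna(length(gene_ids), tag_len, min_dist),
               stringsAsFactors = FALSE)
}

# substitute bases at random positions with the given per-base rate
.addErrors <- function(seqs, rate) {
    if (rate <= 0) return(seqs)
    vapply(seqs, function(s) {
        n <- nchar(s)
        hit <- which(stats::runif(n) < rate)
        if (!length(hit)) return(s)
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        ch[hit] <- vapply(ch[hit], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

# mutate one random position of a sequence
.mutate1 <- function(s) {
    pos <- sample.int(nchar(s), 1)
    b <- substr(s, pos, pos)
    substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    s
}

#' Simulate barcoded paired-end reads from a UMI count matrix
#'
#' Emits one clean read pair per UMI in the input matrix: Read 1 is
#' index || UMI at constant Q30, Read 2 is the gene's tag sequence with
#' substitution errors at \code{error_rate}. UMIs are drawn collision-free
#' within each (sample, gene) stratum (pairwise Hamming distance >= 2), so
#' with \code{error_rate = 0} and no corrupt reads the count matrix is
#' reconstructed exactly by \code{\link{countReads}}. Configurable fractions
#' of corrupt reads are additionally injected, each annotated in the read
#' name: \code{low_q_barcode} (Read 1 qualities at Q8), \code{short_insert}
#' (Read 2 truncated below 30 nt), \code{homopolymer} (truncated tag plus a
#' > 6 nt poly-A tail, rejected as too short after trimming) and
#' \code{umi_dup} (a duplicate molecule whose UMI differs from its parent by
#' exactly one mismatch, removed again by UMI collapse).
#'
#' @param x a \linkS4class{UmiExperiment} (ERCC rows are skipped; reads are
#'   simulated for biological genes only).
#' @param r1_path,r2_path output FASTQ(.gz) paths.
#' @param whitelist data.frame (\code{index}, \code{sample_id}) covering all
#'   samples of \code{x}; generated automatically when \code{NULL}.
#' @param transcriptome data.frame (\code{gene_id}, \code{tag}) covering all
#'   genes; generated automatically when \code{NULL}.
#' @param structure a \code{\link{readStructure}}.
#' @param error_rate per-base substitution rate on Read 2.
#' @param corrupt named list of corrupt-read fractions (relative to the
#'   number of clean reads): \code{low_q_barcode}, \code{short_insert},
#'   \code{homopolymer}, \code{umi_dup}.
#' @param seed integer seed.
#' @return Invisibly, a list with the \code{whitelist}, \code{transcriptome}
#'   and a \code{truth} data.frame (read name, class, sample, gene).
#' @export
simulateReads <- function(x, r1_path, r2_path, whitelist = NULL,
                          transcriptome = NULL,
                          structure = readStructure(), error_rate = 0,
                          corrupt = list(), seed = 1L) {
    set.seed(seed)
    cts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
    cts <- cts[!isErcc(x), , drop = FALSE]
    if (is.null(whitelist))
        whitelist <- generateWhitelist(colnames(cts), structure$index_len,
                                       seed = .subSeed(seed, 1))
    if (anyDuplicated(whitelist$index))
        stop("index collision: two samples share an index")
    if (is.null(transcriptome))
        transcriptome <- generateTranscriptome(rownames(cts),
                                               structure$read2_len,
                                               seed = .subSeed(seed, 2))
    idx_of <- stats::setNames(whitelist$index, whitelist$sample_id)
    tag_of <- stats::setNames(transcriptome$tag, transcriptome$gene_id)

    r1 <- r2 <- nm <- cls <- smp <- gen <- character(0)
    q1 <- character(0)
    k <- 0L
    frac <- function(nm) if (is.null(corrupt[[nm]])) 0 else corrupt[[nm]]
    q30 <- function(n) strrep(rawToChar(as.raw(30L + 33L)), n)
    q8 <- function(n) strrep(rawToChar(as.raw(8L + 33L)), n)

    strata <- list()  # umis per sample:gene, for duplicate injection
    nz <- which(cts > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
        g <- rownames(cts)[nz[r, 1]]
        s <- colnames(cts)[nz[r, 2]]
        n <- cts[nz[r, 1], nz[r, 2]]
        umis <- .distinctDna(n, structure$umi_len, min_dist = 2L)
        strata[[paste(s, g, sep = ":")]] <- umis
        k_new <- k + seq_len(n)
        nm <- c(nm, sprintf("sd:%07d:clean", k_new))
        r1 <- c(r1, paste0(idx_of[[s]], umis))
        r2 <- c(r2, rep(tag_of[[g]], n))
        q1 <- c(q1, rep(q30(structure$read1_len), n))
        cls <- c(cls, rep("clean", n))
        smp <- c(smp, rep(s, n)); gen <- c(gen, rep(g, n))
        k <- k + n
    }
    n_clean <- k
    r2 <- .addErrors(r2, error_rate)

    addCorrupt <- function(type, r1s, r2s, q1s, samples, genes) {
        n <- length(r1s)
        if (!n) return(invisible())
        ks <- k + seq_len(n)
        nm <<- c(nm, sprintf("sd:%07d:%s", ks, type))
        r1 <<- c(r1, r1s); r2 <<- c(r2, r2s); q1 <<- c(q1, q1s)
        cls <<- c(cls, rep(type, n))
        smp <<- c(smp, samples); gen <<- c(gen, genes)
        k <<- k + n
    }

    if (n_clean > 0) {
        # low-quality barcode: valid read, Q8 barcode -> rejected upstream
        n <- round(frac("low_q_barcode") * n_clean)
        if (n) {
            pick <- sample.int(n_clean, n, replace = TRUE)
            addCorrupt("low_q_barcode", r1[pick], r2[pick],
                       rep(q8(structure$read1_len), n), smp[pick], gen[pick])
        }
        # short insert: gene read truncated below 30 nt
        n <- round(frac("short_insert") * n_clean)
        if (n) {
            pick <- sample.int(n_clean, n, replace = TRUE)
            addCorrupt("short_insert", r1[pick],
                       substr(r2[pick], 1, 25),
                       rep(q30(structure$read1_len), n), smp[pick], gen[pick])
        }
        # homopolymer tail: truncated tag + poly-A run, too short after trim
        n <- round(frac("homopolymer") * n_clean)
        if (n) {
            pick <- sample.int(n_clean, n, replace = TRUE)
            addCorrupt("homopolymer", r1[pick],
                       paste0(substr(r2[pick], 1, 25), strrep("A", 10)),
                       rep(q30(structure$read1_len), n), smp[pick], gen[pick])
        }
        # UMI duplicates: one mismatch off a parent molecule's UMI
        n <- round(frac("umi_dup") * n_clean)
        if (n) {
            pick <- sample.int(n_clean, n, replace = FALSE)
            dup_r1 <- character(n)
            for (i in seq_len(n)) {
                p <- pick[i]
                key <- paste(smp[p], gen[p], sep = ":")
                parent <- substr(r1[p], structure$index_len + 1L,
                                 structure$read1_len)
                repeat {
                    cand <- .mutate1(parent)
                    d <- .hammingTo(strata[[key]], cand)
                    # distance 1 from the parent only: collapses back onto it
                    if (sum(d <= 1L) == 1L) break
                }
                strata[[key]] <- c(strata[[key]], cand)
                dup_r1[i] <- paste0(substr(r1[p], 1, structure$index_len),
                                    cand)
            }
            addCorrupt("umi_dup", dup_r1, r2[pick],
                       rep(q30(structure$read1_len), n), smp[pick], gen[pick])
        }
    }

    w2 <- nchar(r2)
    s1 <- Biostrings::BStringSet(r1); names(s1) <- nm
    s2 <- Biostrings::BStringSet(r2); names(s2) <- nm
    Biostrings::writeXStringSet(s1, r1_path, format = "fastq",
                                qualities = Biostrings::BStringSet(q1),
                                compress = grepl("\\.gz$", r1_path))
    Biostrings::writeXStringSet(s2, r2_path, format = "fastq",
                                qualities = Biostrings::BStringSet(
                                    vapply(w2, function(w)
                                        strrep(rawToChar(as.raw(63L)), w),
                                        character(1))),
                                compress = grepl("\\.gz$", r2_path))
    invisible(list(whitelist = whitelist, transcriptome = transcriptome,
                   truth = data.frame(name = nm, class = cls, sample = smp,
                                      gene = gen, stringsAsFactors = FALSE)))
}
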