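#' Quality-filter and trim gene reads
#'
#' Applies the library's read-level filters: a read pair is rejected when any
#' index/UMI base of Read 1 falls below \code{min_barcode_q}; Read 2 is
#' trimmed at the first adapter match and stripped of a terminal
#' single-base run longer than \code{max_homopolymer} nt, then rejected when
#' shorter than \code{min_insert} nt or of Shannon entropy below
#' \code{min_entropy} bits/nt. Each rejection is labelled by cause.
#'
#' @param read2 character vector of gene-read sequences.
#' @param qual1 character vector of Read 1 quality strings (Phred+33).
#' @param min_insert minimum trimmed Read 2 length in nt.
#' @param min_barcode_q minimum Phred quality of every barcode base
#'   (Drop-seq-tools convention, Q10).
#' @param max_homopolymer longest tolerated terminal single-base run.
#' @param adapter optional adapter sequence; Read 2 is cut at its first
#'   exact occurrence.
#' @param min_entropy minimum Shannon entropy in bits/nt.
#' @return data.frame with columns \code{seq} (trimmed Read 2), \code{pass},
#'   and \code{cause} (\code{"pass"}, \code{"low_q_barcode"},
#'   \code{"too_short"} or \code{"low_complexity"}).
#' @export
filterAndTrim <- function(read2, qual1, min_insert = 30L, min_barcode_q = 10L,
                          max_homopolymer = 6L, adapter = NULL,
                          min_entropy = 1.0) {
    n <- length(read2)
    if (length(qual1) != n) stop("read2 and qual1 lengths differ")
    cause <- rep("pass", n)
    # barcode quality: min Phred over Read 1
    minq <- vapply(qual1, function(q)
        if (nchar(q)) min(utf8ToInt(q)) - 33L else 0L, integer(1),
        USE.NAMES = FALSE)
    cause[minq < min_barcode_q] <- "low_q_barcode"
    seq <- read2
    if (!is.null(adapter) && nzchar(adapter)) {
        hit <- regexpr(adapter, seq, fixed = TRUE)
        cut <- hit > 0
        seq[cut] <- substr(seq[cut], 1L, hit[cut] - 1L)
    }
    # strip a terminal homopolymer run longer than max_homopolymer
    seq <- sub(sprintf("(.)\\1{%d,}$", max_homopolymer), "", seq)
    short <- nchar(seq) < min_insert
    cause[cause == "pass" & short] <- "too_short"
    ok <- cause == "pass"
    if (any(ok)) {
        ent <- vapply(seq[ok], .seqEntropy, numeric(1), USE.NAMES = FALSE)
        low <- ent < min_entropy
        cause[which(ok)[low]] <- "low_complexity"
    }
    data.frame(seq = seq, pass = cause == "pass", cause = cause,
               stringsAsFactors = FALSE)
}

#' Demultiplex index barcodes against a whitelist
#'
#' An exact whitelist match wins; otherwise a unique entry within Hamming
#' distance \code{max_mismatch} wins; ambiguity or no hit rejects the read.
#' The whitelist must respect its pairwise-distance invariant
#' (Hamming >= 2 * max_mismatch + 1) so rescue is unambiguous.
#'
#' @param barcodes character vector of observed index sequences.
#' @param whitelist data.frame with columns \code{index}, \code{sample_id}.
#' @param max_mismatch maximum Hamming distance rescued.
#' @return character vector of sample ids (\code{NA} where rejected).
#' @export
demultiplex <- function(barcodes, whitelist, max_mismatch = 1L) {
    if (anyDuplicated(whitelist$index))
        stop("whitelist contains duplicated indexes")
    if (nrow(whitelist) > 1) {
        d <- .hammingMatrix(whitelist$index)
        if (min(d[upper.tri(d)]) < 2L * max_mismatch + 1L)
            stop("whitelist violates its pairwise-distance invariant")
    }
    out <- whitelist$sample_id[match(barcodes, whitelist$index)]
    miss <- which(is.na(out))
    if (length(miss) && max_mismatch > 0) {
        ulen <- unique(nchar(whitelist$index))
        for (i in miss) {
            if (nchar(barcodes[i]) != ulen) next
            d <- .hammingTo(whitelist$index, barcodes[i])
            hit <- which(d <= max_mismatch)
            if (length(hit) == 1L) out[i] <- whitelist$sample_id[hit]
        }
    }
    out
}

#' Assign gene reads to toy-transcriptome tags
#'
#' A read is assigned to the unique tag within \code{max_mismatch}
#' mismatches, else left unassigned (\code{NA}). Distances are Hamming
#' distances over the overlapping prefix when a read was trimmed shorter
#' than the tag. Tags must be pairwise >= 2 * max_mismatch apart.
#' Alignment-specific filters of a real pipeline (multi-mapper removal,
#' excessive soft-clipping) do not apply to this tag matcher.
#'
#' @param reads character vector of (trimmed) gene reads.
#' @param transcriptome data.frame with columns \code{gene_id}, \code{tag}.
#' @param max_mismatch maximum tolerated mismatches.
#' @return character vector of gene ids (\code{NA} where unassigned).
#' @export
assignGene <- function(reads, transcriptome, max_mismatch = 5L) {
    tags <- transcriptome$tag
    tag_mat <- .charMatrix(tags)
    tlen <- ncol(tag_mat)
    out <- rep(NA_character_, length(reads))
    # group reads by sequence to score each distinct read once
    uq <- unique(reads)
    for (u in uq) {
        w <- min(nchar(u), tlen)
        if (w == 0L) next
        ch <- strsplit(substr(u, 1L, w), "", fixed = TRUE)[[1]]
        d <- rowSums(tag_mat[, seq_len(w), drop = FALSE] !=
                     matrix(ch, nrow(tag_mat), w, byrow = TRUE))
        hit <- which(d <= max_mismatch)
        if (length(hit) == 1L)
            out[reads == u] <- transcriptome$gene_id[hit]
    }
    out
}

# connected components of UMIs at Hamming distance <= 1, via neighbor
# enumeration into a hash of observed UMIs plus union-find
.collapseStratum <- function(umis, counts = NULL, directional = FALSE) {
    uq <- unique(umis)
    n <- length(uq)
    if (n <= 1L) return(n)
    idx <- stats::setNames(seq_len(n), uq)
    if (directional && is.null(counts))
        counts <- as.integer(table(umis)[uq])
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    bases <- c("A", "C", "G", "T")
    len <- nchar(uq[1])
    for (pos in seq_len(len)) {
        pre <- substr(uq, 1L, pos - 1L)
        suf <- substr(uq, pos + 1L, len)
        cur <- substr(uq, pos, pos)
        for (b in bases) {
            sel <- which(cur != b)
            if (!length(sel)) next
            nb <- idx[paste0(pre[sel], b, suf[sel])]
            hit <- which(!is.na(nb))
            for (h in hit) {
                i <- sel[h]; j <- nb[h]
                if (directional) {
                    # count-aware merge (UMI-tools style): link only when one
                    # side plausibly seeded the other by PCR/sequencing error
                    if (counts[i] < 2L * counts[j] - 1L &&
                        counts[j] < 2L * counts[i] - 1L) next
                }
                ri <- find(i); rj <- find(j)
                if (ri != rj) parent[ri] <- rj
            }
        }
    }
    length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Collapse UMIs within (sample, gene) strata
#'
#' Within each (sample, gene) stratum, UMIs at edit distance <= 1 are merged
#' and the merged molecules counted: reads with identical UMIs count once,
#' and merging is transitive (connected components of the distance <= 1
#' graph). On fixed-length UMIs edit distance 1 is realised as Hamming
#' distance 1; frame-shifting indels are already rejected by the barcode
#' parser. A directional, count-aware variant (merge a low-count UMI into a
#' neighbor with >= 2n-1 reads) is available via \code{directional = TRUE}.
#'
#' @param tagged data.frame with columns \code{sample_id}, \code{gene_id},
#'   \code{umi} (one row per read).
#' @param directional use the count-aware directional merge instead of plain
#'   connected components.
#' @return genes x samples integer matrix of molecule counts.
#' @export
collapseUmis <- function(tagged, directional = FALSE) {
    stopifnot(all(c("sample_id", "gene_id", "umi") %in% colnames(tagged)))
    genes <- sort(unique(tagged$gene_id))
    samples <- sort(unique(tagged$sample_id))
    out <- matrix(0L, length(genes), length(samples),
                  dimnames = list(genes, samples))
    if (!nrow(tagged)) return(out)
    key <- paste(tagged$gene_id, tagged$sample_id, sep = "\r")
    parts <- split(tagged$umi, key)
    ks <- strsplit(names(parts), "\r", fixed = TRUE)
    for (i in seq_along(parts)) {
        g <- ks[[i]][1]; s <- ks[[i]][2]
        out[g, s] <- .collapseStratum(parts[[i]], directional = directional)
    }
    out
}

#' Count reads into a UMI matrix
#'
#' Full conversion of barcoded paired reads into a per-sample per-gene UMI
#' count matrix: read-level quality filtering and trimming
#' (\code{\link{filterAndTrim}}), index demultiplexing
#' (\code{\link{demultiplex}}), gene-tag assignment
#' (\code{\link{assignGene}}) and edit-distance-1 UMI collapse
#' (\code{\link{collapseUmis}}). Mitochondrially encoded genes (matched by
#' gene-name prefix) are dropped from the count matrix, and every rejected
#' read is accounted for in a per-cause tally.
#'
#' @param r1_path,r2_path FASTQ(.gz) paths for Read 1 (index + UMI) and
#'   Read 2 (gene).
#' @param whitelist data.frame (\code{index}, \code{sample_id}).
#' @param transcriptome data.frame (\code{gene_id}, \code{tag}).
#' @param structure a \code{\link{readStructure}}.
#' @param mito_prefix gene-id prefixes excluded from the matrix (set
#'   \code{character(0)} to keep all genes).
#' @param directional passed to \code{\link{collapseUmis}}.
#' @param ... filter settings passed to \code{\link{filterAndTrim}}.
#' @return list with \code{experiment} (a \linkS4class{UmiExperiment} whose
#'   columns cover all whitelist samples and rows all transcriptome genes)
#'   and \code{tally} (data.frame of per-cause read counts; causes plus
#'   accepted reads sum to the total).
#' @export
countReads <- function(r1_path, r2_path, whitelist, transcriptome,
                       structure = readStructure(),
                       mito_prefix = c("mt-", "Mt-", "MT-"),
                       directional = FALSE, ...) {
    r1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq",
                                       with.qualities = TRUE)
    r2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
    if (length(r1) != length(r2))
        stop("Read 1 and Read 2 files differ in record count")
    n <- length(r1)
    tally <- c(total = n, low_q_barcode = 0L, too_short = 0L,
               low_complexity = 0L, no_index = 0L, no_gene = 0L,
               accepted = 0L)
    mk <- function()
        matrix(0L, nrow(transcriptome), nrow(whitelist),
               dimnames = list(transcriptome$gene_id, whitelist$sample_id))
    finish <- function(cts) {
        if (length(mito_prefix)) {
            drop <- Reduce(`|`, lapply(mito_prefix, startsWith,
                                       x = rownames(cts)))
            cts <- cts[!drop, , drop = FALSE]
        }
        sd <- data.frame(row.names = colnames(cts))
        ue <- UmiExperiment(cts, sampleData = sd)
        S4Vectors::metadata(ue)$read_structure <- structure
        list(experiment = ue,
             tally = data.frame(cause = names(tally),
                                reads = as.integer(tally)))
    }
    if (n == 0L) return(finish(mk()))

    s1 <- as.character(r1)
    if (any(nchar(s1) != structure$read1_len))
        stop(sprintf("malformed FASTQ: record %d has Read 1 length != %d",
                     which(nchar(s1) != structure$read1_len)[1],
                     structure$read1_len))
    q1 <- as.character(S4Vectors::mcols(r1)$qualities)
    ft <- filterAndTrim(as.character(r2), q1, ...)
    tally["low_q_barcode"] <- sum(ft$cause == "low_q_barcode")
    tally["too_short"] <- sum(ft$cause == "too_short")
    tally["low_complexity"] <- sum(ft$cause == "low_complexity")

    keep <- ft$pass
    bc <- substr(s1[keep], 1L, structure$index_len)
    umi <- substr(s1[keep], structure$index_len + 1L, structure$read1_len)
    sample_id <- demultiplex(bc, whitelist)
    tally["no_index"] <- sum(is.na(sample_id))
    ok <- !is.na(sample_id)
    gene_id <- rep(NA_character_, sum(keep))
    gene_id[ok] <- assignGene(ft$seq[keep][ok], transcriptome)
    tally["no_gene"] <- sum(ok & is.na(gene_id))
    use <- ok & !is.na(gene_id)
    tally["accepted"] <- sum(use)

    cts <- mk()
    if (any(use)) {
        coll <- collapseUmis(data.frame(sample_id = sample_id[use],
                                        gene_id = gene_id[use],
                                        umi = umi[use],
                                        stringsAsFactors = FALSE),
                             directional = directional)
        cts[rownames(coll), colnames(coll)] <- coll
    }
    finish(cts)
}
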