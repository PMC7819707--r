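# Internal sequence / numeric helpers shared across modules.

# split equal-length strings into a character matrix (reads x positions)
.charMatrix <- function(x) {
    if (!length(x)) return(matrix(character(), 0, 0))
    n <- unique(nchar(x))
    if (length(n) != 1L) stop("sequences must have equal length")
    matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
           nrow = length(x), byrow = TRUE)
}

# pairwise Hamming distance matrix for equal-length strings
.hammingMatrix <- function(x) {
    m <- .charMatrix(x)
    n <- nrow(m)
    d <- matrix(0L, n, n)
    for (j in seq_len(ncol(m)))
        d <- d + outer(m[, j], m[, j], "!=")
    d
}

# Hamming distance from each string in x (equal length) to a single string
.hammingTo <- function(x, ref) {
    m <- .charMatrix(x)
    r <- strsplit(ref, "", fixed = TRUE)[[1]]
    if (ncol(m) != length(r)) stop("length mismatch")
    rowSums(m != matrix(r, nrow(m), length(r), byrow = TRUE))
}

# Shannon entropy in bits per nucleotide of a single sequence
.seqEntropy <- function(seq) {
    tab <- table(strsplit(seq, "", fixed = TRUE)[[1]])
    p <- tab / sum(tab)
    -sum(p * log2(p))
}

# random DNA strings
.randomDna <- function(n, len) {
    bases <- c("A", "C", "G", "T")
    vapply(seq_len(n), function(i)
        paste(sample(bases, len, replace = TRUE), collapse = ""),
        character(1))
}

# draw n sequences of given length with pairwise Hamming distance >= min_dist
# (greedy rejection; random draws almost always satisfy generous margins)
.distinctDna <- function(n, len, min_dist, max_tries = 1000L) {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
        cand <- .randomDna(1L, len)
        ok <- !length(out) || all(.hammingTo(out, cand) >= min_dist)
        if (ok) {
            out <- c(out, cand)
            tries <- 0L
        } else {
            tries <- tries + 1L
            if (tries > max_tries)
                stop("could not generate sequences at requested distance")
        }
    }
    out
}

# Gaussian local-linear regression of y on x evaluated at x (sd =
# bandwidth); local-linear rather than local-constant so that a trend in
# the parameter over x is not biased at the boundaries or by uneven x
# density
.kernelSmooth <- function(x, y, bandwidth) {
    dx <- outer(x, x, "-")            # row i: x_j - x_i
    w <- exp(-dx^2 / (2 * bandwidth^2))
    s0 <- rowSums(w)
    s1 <- rowSums(w * dx)
    s2 <- rowSums(w * dx^2)
    t0 <- as.numeric(w %*% y)
    t1 <- rowSums(w * dx * matrix(y, length(x), length(x), byrow = TRUE))
    den <- s0 * s2 - s1^2
    out <- (s2 * t0 - s1 * t1) / den
    bad <- !is.finite(out) | den <= 1e-12 * pmax(s0, 1)^2
    out[bad] <- (t0 / s0)[bad]        # fall back to local constant
    out
}

# guard against integer overflow when deriving stream seeds from a user seed
.subSeed <- function(seed, k) {
    (as.numeric(seed) * 1103L + k * 12289L) %% 2147483647
}
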