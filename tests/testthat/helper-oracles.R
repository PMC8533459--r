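# Independent oracles, implemented without touching the code paths they
# check.

# Quadratic-space affine-gap Needleman-Wunsch scorer: match +1,
# mismatch -1, a gap of length L costs 2 + L (opening 2, extension 1 per
# gap column).
oracleAlignScore <- function(a, b) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    NEG <- -1e9
    gapOf <- function(L) -(2 + L)
    M <- matrix(NEG, n + 1, m + 1)
    Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
    Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
    M[1, 1] <- 0
    for (i in seq_len(n)) Ix[i + 1, 1] <- gapOf(i)
    for (j in seq_len(m)) Iy[1, j + 1] <- gapOf(j)
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            s <- if (a[i] == b[j]) 1 else -1
            M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
            Ix[i + 1, j + 1] <- max(M[i, j + 1] - 3, Ix[i, j + 1] - 1)
            Iy[i + 1, j + 1] <- max(M[i + 1, j] - 3, Iy[i + 1, j] - 1)
        }
    }
    max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# k-mer Jaccard distance through a different route (Biostrings
# oligonucleotide counting) than the package's substring sets.
oracleKmerDistance <- function(a, b, k = 8) {
    fa <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(a), k) > 0
    fb <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(b), k) > 0
    inter <- sum(fa & fb); uni <- sum(fa | fb)
    if (uni == 0) 0 else 1 - inter / uni
}

# Exhaustive mutual-best enumeration over a full score matrix, with the
# documented tie rules: ties by higher identity (matrix I), then by
# lexicographic partner name.
oracleMutualBest <- function(S, I = NULL) {
    best <- function(scores, idents, names) {
        top <- which(scores == max(scores))
        if (length(top) > 1 && !is.null(idents))
            top <- top[idents[top] == max(idents[top])]
        if (length(top) > 1) top <- top[order(names[top])]
        top[1]
    }
    pairs <- list()
    for (i in seq_len(nrow(S))) {
        j <- best(S[i, ], if (is.null(I)) NULL else I[i, ], colnames(S))
        i2 <- best(S[, j], if (is.null(I)) NULL else I[, j], rownames(S))
        if (i2 == i)
            pairs[[length(pairs) + 1]] <- c(rownames(S)[i], colnames(S)[j])
    }
    pairs
}

# tolerance at the precision a value was printed with (half an ULP of the
# last printed digit), never below `floor`
printedTol <- function(x, floor = 0.02) {
    ch <- as.character(x)
    dec <- ifelse(grepl("\\.", ch), nchar(sub(".*\\.", "", ch)), 0)
    pmax(floor, 0.5 * 10^(-dec))
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# plant s substitutions at distinct positions
substituteN <- function(x, s) {
    bases <- strsplit(x, "")[[1]]
    pos <- sample(length(bases), s)
    for (p in pos) bases[p] <- setdiff(c("A", "C", "G", "T"), bases[p])[1]
    paste(bases, collapse = "")
}
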