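## Cross-genome homology of cluster core genes: global alignment scoring,
## reciprocal best-hit (RBH) matching, the shared/specific partition with
## raw-read absence evidence, and per-gene synteny identity tables.

NUC_MAT <- NULL  # populated lazily; +1 match / -1 mismatch

nucMat <- function() {
    if (is.null(NUC_MAT)) {
        m <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                      mismatch = -1,
                                                      baseOnly = TRUE)
        utils::assignInMyNamespace("NUC_MAT", m)
    }
    NUC_MAT
}

asDNA <- function(x) {
    if (is(x, "DNAString")) return(x)
    if (is(x, "DNAStringSet")) return(x[[1L]])
    Biostrings::DNAString(as.character(x))
}

#' Score a pair of nucleotide sequences by global alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and affine
#' gap cost 2 + L for a gap of length L (gap opening 2, gap extension 1
#' per gap column). Identity is the fraction of matching columns over all
#' aligned columns, gap columns included, so identical sequences score
#' identity 1 and a pair with s substitutions out of n bases scores
#' (n - s)/n.
#'
#' @param seqA,seqB nucleotide sequences (character, \code{DNAString} or
#'   length-1 \code{DNAStringSet}); must be non-empty.
#' @param queryId,subjectId identifiers recorded in the result.
#' @return a list with elements \code{query_id}, \code{subject_id},
#'   \code{identity} (fraction in \[0, 1\]), \code{aligned_length}
#'   (alignment columns) and \code{score}.
#' @examples
#' scorePair("ACGTACGT", "ACGTACGT")$identity   # 1
#' @export
scorePair <- function(seqA, seqB, queryId = "query", subjectId = "subject") {
    a <- asDNA(seqA); b <- asDNA(seqB)
    if (length(a) == 0L || length(b) == 0L)
        lbgcError("emptySequenceError", "cannot align an empty sequence")
    p <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = nucMat(),
                                       gapOpening = 2, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(p)), "")[[1L]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(p)), "")[[1L]]
    matches <- sum(pa == sa & pa != "-")
    list(query_id = queryId, subject_id = subjectId,
         identity = matches / length(pa),
         aligned_length = length(pa),
         score = Biostrings::score(p))
}

## score-only global alignment of several patterns against one subject
scoreMany <- function(patterns, subject) {
    Biostrings::pairwiseAlignment(patterns, subject, type = "global",
                                  substitutionMatrix = nucMat(),
                                  gapOpening = 2, gapExtension = 1,
                                  scoreOnly = TRUE)
}

## Pairwise score matrix between two core sets. With prefilter = TRUE only
## pairs below the k-mer screen distance are aligned (unrelated random
## sequences sit near distance 1); any core left with no screened partner
## falls back to exhaustive alignment of its row/column so a best hit is
## always defined. Unaligned pairs get -Inf.
coreScoreMatrix <- function(coresA, coresB, prefilter = TRUE,
                            screenDistance = 0.95, k = 8L) {
    nA <- length(coresA); nB <- length(coresB)
    M <- matrix(-Inf, nA, nB, dimnames = list(names(coresA), names(coresB)))
    cand <- matrix(TRUE, nA, nB)
    if (prefilter && nA > 0 && nB > 0) {
        setsA <- lapply(as.character(coresA), kmerSet, k = k)
        setsB <- lapply(as.character(coresB), kmerSet, k = k)
        for (i in seq_len(nA)) for (j in seq_len(nB)) {
            inter <- length(intersect(setsA[[i]], setsB[[j]]))
            uni <- length(setsA[[i]]) + length(setsB[[j]]) - inter
            cand[i, j] <- uni == 0L || (1 - inter / uni) <= screenDistance
        }
        ## cores with no screened partner fall back to exhaustive
        ## alignment of their whole row AND column, so their best hit is
        ## the true best, not the best of an arbitrary subset
        rowEmpty <- rowSums(cand) == 0L
        colEmpty <- colSums(cand) == 0L
        cand[rowEmpty, ] <- TRUE
        cand[, colEmpty] <- TRUE
    }
    for (j in seq_len(nB)) {
        idx <- which(cand[, j])
        if (length(idx))
            M[idx, j] <- scoreMany(coresA[idx], coresB[[j]])
    }
    M
}

## index of the unique best hit in a score row/vector; ties resolved by
## higher identity, then lexicographic name order
bestHit <- function(scores, query, subjects) {
    if (!length(scores) || all(!is.finite(scores))) return(NA_integer_)
    top <- which(scores == max(scores))
    if (length(top) > 1L) {
        idents <- vapply(top, function(j)
            scorePair(query, subjects[[j]])$identity, numeric(1L))
        top <- top[idents == max(idents)]
        if (length(top) > 1L)
            top <- top[order(names(subjects)[top])][1L]
    }
    top
}

#' Reciprocal best-hit matching of cluster core genes
#'
#' A pair (a, b) is reported iff b is a's best-scoring hit among all cores
#' of the other genome, a is b's best-scoring hit, and the aligned identity
#' of the pair reaches \code{minIdentity}. Score ties are broken by higher
#' identity, then lexicographically by subject identifier, so each cluster
#' appears in at most one pair and the result is deterministic. The
#' reciprocity requirement is what defeats paralogy: a within-genome
#' paralog of a shared core finds a good one-way hit, but the hit's own
#' best partner is its true ortholog.
#'
#' By default an alignment-free k-mer screen (Jaccard distance of 8-mer
#' sets) skips alignments of clearly unrelated pairs; \code{prefilter =
#' FALSE} forces exhaustive alignment of all pairs.
#'
#' @param coresA,coresB named \code{DNAStringSet}s of core gene sequences,
#'   names being cluster identifiers (see [coreSequences]).
#' @param minIdentity minimum aligned identity to accept a pair
#'   (default 0.7).
#' @param prefilter use the k-mer screen (default \code{TRUE}).
#' @return a \code{data.frame} with columns \code{cluster_a},
#'   \code{cluster_b}, \code{score}, \code{identity},
#'   \code{aligned_length}, \code{reciprocal} (all \code{TRUE}).
#' @export
reciprocalBestHit <- function(coresA, coresB, minIdentity = 0.7,
                              prefilter = TRUE) {
    empty <- data.frame(cluster_a = character(), cluster_b = character(),
                        score = numeric(), identity = numeric(),
                        aligned_length = integer(), reciprocal = logical())
    if (length(coresA) == 0L || length(coresB) == 0L) return(empty)
    M <- coreScoreMatrix(coresA, coresB, prefilter = prefilter)
    bestAB <- vapply(seq_len(nrow(M)), function(i)
        bestHit(M[i, ], coresA[[i]], coresB), integer(1L))
    bestBA <- vapply(seq_len(ncol(M)), function(j)
        bestHit(M[, j], coresB[[j]], coresA), integer(1L))
    rows <- list()
    for (i in seq_len(nrow(M))) {
        j <- bestAB[i]
        if (is.na(j) || is.na(bestBA[j]) || bestBA[j] != i) next
        sp <- scorePair(coresA[[i]], coresB[[j]],
                        names(coresA)[i], names(coresB)[j])
        if (sp$identity < minIdentity) next
        rows[[length(rows) + 1L]] <- data.frame(
            cluster_a = names(coresA)[i], cluster_b = names(coresB)[j],
            score = M[i, j], identity = sp$identity,
            aligned_length = sp$aligned_length, reciprocal = TRUE,
            stringsAsFactors = FALSE)
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    out[order(out$cluster_a), , drop = FALSE]
}

#' Partition two BGC complements into shared and chemotype-specific
#'
#' Clusters joined by a reciprocal best-hit pair are shared; the rest are
#' candidate chemotype-specific clusters. For each unmatched cluster the
#' other chemotype's raw reads are mapped onto this genome
#' ([mapAndCount]) and the maximum RPKM over the cluster's core gene(s)
#' is recorded as absence evidence. A cluster is called \code{specific}
#' only when that evidence is exactly zero; nonzero cross-coverage flags
#' it \code{ambiguous} instead, since reads of the supposedly missing
#' cluster exist in the other chemotype's raw data.
#'
#' @param genomeA,genomeB [GenomeAnnotation-class] objects.
#' @param matches RBH pairs from [reciprocalBestHit] on these genomes.
#' @param readsA,readsB the chemotypes' raw reads (a \code{DNAStringSet}
#'   or a FASTQ path), or \code{NULL} to skip the read check (evidence
#'   becomes \code{NA} and unmatched clusters are reported specific).
#' @param minReadIdentity read-placement identity threshold passed to
#'   [mapAndCount].
#' @return a [ChemotypeComparison-class].
#' @export
partitionChemotypes <- function(genomeA, genomeB, matches,
                                readsA = NULL, readsB = NULL,
                                minReadIdentity = 0.95) {
    evid <- function(genome, otherReads, unmatchedIds) {
        if (!length(unmatchedIds))
            return(data.frame(cluster_id = character(),
                              absence_evidence = numeric(),
                              status = character()))
        ev <- rep(NA_real_, length(unmatchedIds))
        if (!is.null(otherReads)) {
            reads <- loadReads(otherReads)
            ct <- mapAndCount(reads, genome,
                              minReadIdentity = minReadIdentity)
            ex <- expressionTable(ct, genome)
            ev <- vapply(unmatchedIds, function(id) {
                core <- coreGeneIds(getCluster(genome, id))
                max(ex$rpkm[match(core, ex$gene_id)], 0)
            }, numeric(1L))
        }
        data.frame(cluster_id = unmatchedIds, absence_evidence = ev,
                   status = ifelse(!is.na(ev) & ev > 0,
                                   "ambiguous", "specific"),
                   stringsAsFactors = FALSE)
    }
    idsA <- vapply(clusters(genomeA), clusterId, character(1L))
    idsB <- vapply(clusters(genomeB), clusterId, character(1L))
    specA <- evid(genomeA, readsB, setdiff(idsA, matches$cluster_a))
    specB <- evid(genomeB, readsA, setdiff(idsB, matches$cluster_b))
    new("ChemotypeComparison", sharedPairs = matches,
        specificA = specA, specificB = specB)
}

loadReads <- function(x) {
    if (is(x, "DNAStringSet")) return(x)
    if (is.character(x) && length(x) == 1L) {
        checkFile(x)
        return(Biostrings::readDNAStringSet(x, format = "fastq"))
    }
    lbgcError("configError", "reads must be a DNAStringSet or a FASTQ path")
}

#' Per-gene synteny identity table of a homologous cluster pair
#'
#' Replaces a synteny figure with its underlying numbers: every gene of
#' cluster A is globally aligned against every gene of cluster B and a row
#' is emitted for each pair reaching \code{minIdentityPct} over at least
#' \code{minLength} aligned columns (the drawing thresholds of standard
#' synteny plots). Clusters are oriented so the core genes share
#' direction; whether B was flipped is recorded in the \code{"flipped"}
#' attribute of the result.
#'
#' @param annotationA,annotationB the owning [GenomeAnnotation-class]
#'   objects.
#' @param clusterA,clusterB [BGCluster-class] objects or cluster ids.
#' @param minIdentityPct minimum percent identity for a reported hit
#'   (default 90).
#' @param minLength minimum aligned length in bp (default 50).
#' @return a \code{data.frame} with columns \code{gene_a}, \code{gene_b},
#'   \code{identity_pct}, \code{aligned_length}; attribute
#'   \code{"flipped"} is \code{TRUE} when cluster B was
#'   orientation-flipped.
#' @export
syntenyTable <- function(annotationA, annotationB, clusterA, clusterB,
                         minIdentityPct = 90, minLength = 50) {
    if (is.character(clusterA)) clusterA <- getCluster(annotationA, clusterA)
    if (is.character(clusterB)) clusterB <- getCluster(annotationB, clusterB)
    strandOf <- function(ann, id)
        as.character(GenomicRanges::strand(getGenes(ann, id)))
    flipped <- strandOf(annotationA, coreGeneIds(clusterA)[1L]) !=
        strandOf(annotationB, coreGeneIds(clusterB)[1L])
    seqsA <- geneSequences(annotationA, geneIds(clusterA))
    seqsB <- geneSequences(annotationB, geneIds(clusterB))
    if (flipped)
        seqsB <- Biostrings::reverseComplement(seqsB)[rev(seq_along(seqsB))]
    rows <- list()
    for (i in seq_along(seqsA)) for (j in seq_along(seqsB)) {
        sp <- scorePair(seqsA[[i]], seqsB[[j]],
                        names(seqsA)[i], names(seqsB)[j])
        pct <- 100 * sp$identity
        if (pct >= minIdentityPct && sp$aligned_length >= minLength)
            rows[[length(rows) + 1L]] <- data.frame(
                gene_a = names(seqsA)[i], gene_b = names(seqsB)[j],
                identity_pct = pct, aligned_length = sp$aligned_length,
                stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(gene_a = character(), gene_b = character(),
                   identity_pct = numeric(), aligned_length = integer())
    attr(out, "flipped") <- flipped
    out
}

#' Compare the BGC complements of two chemotypes end to end
#'
#' Convenience wrapper: reciprocal best-hit matching of all cluster core
#' genes followed by the shared/specific partition with read-based absence
#' evidence.
#'
#' @inheritParams partitionChemotypes
#' @param minIdentity RBH identity acceptance threshold (default 0.7).
#' @param prefilter passed to [reciprocalBestHit].
#' @return a [ChemotypeComparison-class].
#' @export
compareChemotypes <- function(genomeA, genomeB, readsA = NULL,
                              readsB = NULL, minIdentity = 0.7,
                              prefilter = TRUE) {
    matches <- reciprocalBestHit(coreSequences(genomeA),
                                 coreSequences(genomeB),
                                 minIdentity = minIdentity,
                                 prefilter = prefilter)
    partitionChemotypes(genomeA, genomeB, matches, readsA, readsB)
}
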