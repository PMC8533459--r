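## Transcription quantification: near-exact read placement onto gene
## models, RPKM normalization, library-size calibration from published
## RPKM values, and within-cluster activity ranking.

#' RPKM: reads per kilobase of gene per million library reads
#'
#' \code{raw / (librarySize / 1e6) / (lengthBp / 1000)}. The library size
#' is the total number of reads in the sample, not the number of mapped
#' reads. RPKM is invariant under scaling counts and library size by a
#' common factor.
#'
#' @param rawCount raw read count(s), >= 0 (vectorised).
#' @param librarySize total reads in the sample (> 0).
#' @param lengthBp gene length(s) in bp (> 0).
#' @return numeric RPKM value(s).
#' @examples
#' rpkm(936, 34591608, 2191)   # ~12.35
#' @export
rpkm <- function(rawCount, librarySize, lengthBp) {
    if (any(librarySize <= 0))
        lbgcError("configError", "librarySize must be positive")
    if (any(lengthBp <= 0))
        lbgcError("configError", "lengthBp must be positive")
    as.vector(rawCount) / (as.vector(librarySize) / 1e6) /
        (as.vector(lengthBp) / 1000)
}

#' Calibrate the library size from published RPKM values
#'
#' Published expression tables print raw counts, gene lengths and RPKM but
#' not the library size. Inverting the RPKM identity, each row with a
#' nonzero printed RPKM implies \code{L = raw * 1e9 / (length * rpkm)};
#' with several rows the least-squares estimate of \code{x = 1/L} under
#' the linear model \code{rpkm_i = (raw_i * 1e9 / length_i) * x} is
#' returned (optionally weighted). With a single usable row this reduces
#' to the exact inversion.
#'
#' @param rows \code{data.frame} with columns \code{raw}, \code{length_bp}
#'   and \code{printed_rpkm}; rows with zero/missing raw count or printed
#'   RPKM carry no information and are dropped.
#' @param weights optional non-negative row weights (recycled).
#' @return the estimated library size (a single number, reads). The
#'   \code{"residuals"} attribute holds the per-row fit: predicted RPKM at
#'   the estimate and the residual against the printed value.
#' @examples
#' calibrateLibrarySize(data.frame(raw = 936, length_bp = 2191,
#'                                 printed_rpkm = 12.35))
#' @export
calibrateLibrarySize <- function(rows, weights = 1) {
    stopifnot(all(c("raw", "length_bp", "printed_rpkm") %in% names(rows)))
    w <- rep_len(weights, nrow(rows))
    use <- !is.na(rows$raw) & !is.na(rows$printed_rpkm) &
        rows$raw > 0 & rows$printed_rpkm > 0
    if (!any(use))
        lbgcError("calibrationError",
                  "no row with nonzero raw count and printed RPKM")
    f <- rows$raw[use] * 1e9 / rows$length_bp[use]
    p <- rows$printed_rpkm[use]
    w <- w[use]
    x <- sum(w * f * p) / sum(w * f^2)
    L <- 1 / x
    fitted <- f * x
    attr(L, "residuals") <- data.frame(
        raw = rows$raw[use], length_bp = rows$length_bp[use],
        printed_rpkm = p, fitted_rpkm = fitted, residual = p - fitted)
    L
}

## ---------------------------------------------------------------------------
## Read placement
## ---------------------------------------------------------------------------

## Seed-and-verify read placement. A full-length ungapped placement with
## at most m mismatches must contain an exact seed of length
## floor(w / (m + 1)) at one of m + 1 disjoint offsets (pigeonhole), so
## seeds of all reads are matched simultaneously against the concatenated
## gene sequences and only seed-hit (read, gene) pairs are verified.
seedCandidates <- function(reads, geneSeqs, minReadIdentity) {
    widths <- Biostrings::width(reads)
    out <- list()
    spacer <- paste(rep("N", 64L), collapse = "")
    glens <- Biostrings::width(geneSeqs)
    offsets <- cumsum(c(1L, utils::head(glens + 64L, -1L)))
    big <- Biostrings::DNAString(
        paste(as.character(geneSeqs), collapse = spacer))
    for (w in unique(widths)) {
        ridx <- which(widths == w)
        m <- floor(w * (1 - minReadIdentity))
        s <- floor(w / (m + 1))
        if (s < 8L)
            lbgcError("configError",
                      "reads too short for the identity threshold")
        sub <- reads[ridx]
        both <- c(sub, Biostrings::reverseComplement(sub))
        starts <- (seq_len(m + 1L) - 1L) * s + 1L
        seeds <- do.call(c, lapply(starts, function(st)
            Biostrings::subseq(both, st, st + s - 1L)))
        names(seeds) <- NULL
        seedRead <- rep(rep(ridx, 2L), times = m + 1L)
        pd <- Biostrings::PDict(seeds)
        mi <- Biostrings::matchPDict(pd, big)
        si <- Biostrings::startIndex(mi)
        hit <- which(lengths(si) > 0L)
        if (!length(hit)) next
        genesHit <- lapply(si[hit], function(p)
            unique(findInterval(p, offsets)))
        df <- data.frame(
            read = rep(seedRead[hit], lengths(genesHit)),
            gene = unlist(genesHit))
        out[[length(out) + 1L]] <- df
    }
    if (!length(out))
        return(data.frame(read = integer(), gene = integer()))
    unique(do.call(rbind, out))
}

## minimum mismatch count of a full-length ungapped placement of `read`
## (either strand) within `gene`; Inf when even the mismatch budget m
## admits no placement
bestPlacementMismatch <- function(read, geneSeq, m) {
    best <- Inf
    for (q in list(read, Biostrings::reverseComplement(read))) {
        v <- Biostrings::matchPattern(q, geneSeq, max.mismatch = m,
                                      with.indels = FALSE)
        if (length(v)) {
            ed <- Biostrings::neditStartingAt(q, geneSeq,
                                              starting.at = BiocGenerics::start(v))
            best <- min(best, min(ed))
        }
    }
    best
}

#' Map reads onto gene models and count per-gene hits
#'
#' Each read is placed full-length and ungapped (either strand) on the
#' gene it matches best. A read is counted for a gene iff its best
#' placement reaches \code{minReadIdentity}; reads whose best identity is
#' tied between two or more genes are discarded (classic multi-mapping
#' exclusion), and reads matching no gene count only toward the library
#' size. Candidate (read, gene) pairs are found by an exact-seed
#' pigeonhole screen, so background reads cost almost nothing.
#'
#' @param reads a \code{DNAStringSet} (or FASTQ path) of reads; all reads
#'   must be shorter than the genes they may hit.
#' @param genome a [GenomeAnnotation-class].
#' @param minReadIdentity minimum placement identity in (0, 1\]
#'   (default 0.95).
#' @return a [CountTable-class] over all genes of the genome with
#'   \code{librarySize = length(reads)}. Attributes \code{"background"}
#'   and \code{"discarded"} count unplaced and tie-discarded reads, so
#'   \code{sum(counts) + background + discarded == librarySize}.
#' @export
mapAndCount <- function(reads, genome, minReadIdentity = 0.95) {
    reads <- loadReads(reads)
    geneSeqs <- geneSequences(genome)
    n <- length(geneSeqs)
    countVec <- stats::setNames(numeric(n), names(geneSeqs))
    background <- 0L; discarded <- 0L
    if (length(reads) == 0L) {
        ct <- CountTable(names(geneSeqs), countVec, librarySize = 0)
        attr(ct, "background") <- 0L; attr(ct, "discarded") <- 0L
        return(ct)
    }
    if (n == 0L) {
        ct <- CountTable(character(), numeric(), length(reads))
        attr(ct, "background") <- length(reads); attr(ct, "discarded") <- 0L
        return(ct)
    }
    cand <- seedCandidates(reads, geneSeqs, minReadIdentity)
    placed <- integer(0)
    if (nrow(cand)) {
        byRead <- split(cand$gene, cand$read)
        for (rn in names(byRead)) {
            i <- as.integer(rn)
            w <- Biostrings::width(reads)[i]
            m <- floor(w * (1 - minReadIdentity))
            mm <- vapply(byRead[[rn]], function(g)
                bestPlacementMismatch(reads[[i]], geneSeqs[[g]], m),
                numeric(1L))
            ok <- is.finite(mm)
            if (!any(ok)) next
            best <- min(mm[ok])
            winners <- byRead[[rn]][ok][mm[ok] == best]
            if (length(winners) > 1L) {
                discarded <- discarded + 1L
            } else {
                countVec[winners] <- countVec[winners] + 1
                placed <- c(placed, i)
            }
        }
        ## reads with no candidates, or candidates but no admissible
        ## placement, are background
        background <- length(reads) - length(placed) - discarded
    } else {
        background <- length(reads)
    }
    ct <- CountTable(names(geneSeqs), countVec, librarySize = length(reads))
    attr(ct, "background") <- background
    attr(ct, "discarded") <- discarded
    ct
}

#' Per-gene expression records (raw counts and RPKM)
#'
#' Joins a count table with the gene models of its genome and computes
#' RPKM per gene. Genes absent from the count table get a raw count of 0.
#'
#' @param countTable a [CountTable-class].
#' @param genome a [GenomeAnnotation-class] (for gene lengths and product
#'   labels).
#' @param librarySize override the library size of \code{countTable}
#'   (e.g. a calibrated full-scale value); default uses the table's own.
#' @return a \code{data.frame} with columns \code{gene_id},
#'   \code{product}, \code{length_bp}, \code{raw_count}, \code{rpkm},
#'   \code{library_size}.
#' @export
expressionTable <- function(countTable, genome,
                            librarySize = NULL) {
    if (is.null(librarySize)) librarySize <- librarySize(countTable)
    g <- genes(genome)
    ids <- S4Vectors::mcols(g)$gene_id
    cts <- counts(countTable)
    raw <- cts$raw_count[match(ids, cts$gene_id)]
    raw[is.na(raw)] <- 0
    len <- GenomicRanges::width(g)
    data.frame(gene_id = ids,
               product = S4Vectors::mcols(g)$product,
               length_bp = len,
               raw_count = raw,
               rpkm = rpkm(raw, librarySize, len),
               library_size = librarySize,
               stringsAsFactors = FALSE)
}

#' Rank transcriptional activity within a cluster
#'
#' Genes are ordered by decreasing RPKM (ties by gene id); a gene is
#' flagged active when its RPKM is positive and at least
#' \code{activityFactor} times the within-cluster median RPKM. The
#' ranking is threshold-free; the active flag is a convenience
#' annotation.
#'
#' @param cluster a [BGCluster-class] or a character vector of gene ids.
#' @param expression a \code{data.frame} with columns \code{gene_id} and
#'   \code{rpkm} (e.g. from [expressionTable]); cluster genes missing
#'   from it are treated as RPKM 0.
#' @param activityFactor multiple of the within-cluster median RPKM a
#'   gene must reach to be called active (default 10).
#' @return the cluster's rows sorted by rank, with columns \code{gene_id},
#'   \code{rpkm}, \code{rank}, \code{active}.
#' @export
rankActivity <- function(cluster, expression, activityFactor = 10) {
    ids <- if (is(cluster, "BGCluster")) geneIds(cluster)
           else as.character(cluster)
    r <- expression$rpkm[match(ids, expression$gene_id)]
    r[is.na(r)] <- 0
    ord <- order(-r, ids)
    med <- stats::median(r)
    data.frame(gene_id = ids[ord], rpkm = r[ord],
               rank = seq_along(ids),
               active = r[ord] > 0 & r[ord] >= activityFactor * med,
               stringsAsFactors = FALSE)
}
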