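## The depside/depsidone candidate filter, the atranorin-cluster rule and
## the divergent HexA/HexB FAS-pair detector.

## Map a free-text product label onto the closed rule vocabulary.
## Matching is case-insensitive and substring-tolerant ("O-methyltransferase"
## and "OMT" both normalize to OMT); labels outside the vocabulary map to
## "unidentified".
normalizeProductLabel <- function(label) {
    vapply(label, function(x) {
        l <- tolower(trimws(x))
        if (grepl("cytp450|cytochrome", l)) return("CytP450")
        if (grepl("^omt$|o-methyltransferase", l)) return("OMT")
        if (grepl("nr-?pks|nrpks", l)) return("NR-PKS")
        if (grepl("red-pks|r-pks", l)) return("R-PKS")
        if (grepl("monooxygenase", l)) return("monooxygenase")
        if (grepl("transporter", l)) return("transporter")
        if (grepl("regulat", l)) return("regulatory")
        if (grepl("halogenase", l)) return("halogenase")
        if (grepl("fas-a|hexa", l)) return("FAS-A")
        if (grepl("fas-b|hexb", l)) return("FAS-B")
        if (grepl("^pks$", l)) return("PKS")
        if (grepl("terpene|nrps|indole", l)) return("core")
        "unidentified"
    }, character(1L), USE.NAMES = FALSE)
}

#' Four-criterion candidate filter for the depside/depsidone cluster
#'
#' A cluster passes iff it (1) is homologous and present in both
#' chemotypes, (2) contains an NR-PKS, (3) contains a CytP450 gene, and
#' (4) its PKS carries two ACP domains. Only these four criteria decide
#' pass/fail. Additional negative evidence is recorded per cluster
#' without affecting the verdict: a cMT domain in the PKS (azaphilone /
#' ss-orcinol character), a missing TE release domain, an
#' O-methyltransferase in the cluster (not required for orcinol depside
#' or depsidone synthesis), an adjacent divergently transcribed R-PKS
#' (suggesting shared regulation with an unrelated product), and a
#' phylogenetic group outside group I (the orcinol depside/depsidone
#' group).
#'
#' @param domains named character vector of PKS domain strings, names
#'   being cluster ids. Clusters without a parsable PKS are skipped with
#'   a notice.
#' @param companions named list (parallel to \code{domains}) of character
#'   vectors of member-gene product labels (free text; normalized
#'   internally).
#' @param sharedIds cluster ids present in both chemotypes (from the
#'   homology partition).
#' @param groups optional named character vector of phylogenetic group
#'   labels per cluster (evidence only).
#' @param divergentRPKSNeighbor optional character vector of cluster ids
#'   whose NR-PKS has an adjacent divergently transcribed R-PKS.
#' @return a \code{data.frame} with one row per evaluated cluster:
#'   \code{cluster_id}, the four criterion columns
#'   (\code{in_both_chemotypes}, \code{has_NR_PKS}, \code{has_CytP450},
#'   \code{two_ACPs}), \code{passed}, \code{negative_evidence}
#'   (comma-separated), \code{narrative}.
#' @examples
#' tab <- pfurNRPKSClusters()
#' v <- evaluateCandidates(
#'     stats::setNames(tab$domains, tab$cluster),
#'     stats::setNames(strsplit(tab$companions, ","), tab$cluster),
#'     sharedIds = as.character(tab$cluster),
#'     groups = stats::setNames(tab$group, tab$cluster))
#' v$cluster_id[v$passed]   # "4"
#' @export
evaluateCandidates <- function(domains, companions, sharedIds,
                               groups = NULL,
                               divergentRPKSNeighbor = character(0)) {
    stopifnot(is.list(companions), !is.null(names(domains)))
    rows <- list()
    for (id in names(domains)) {
        arch <- tryCatch(parseDomainString(domains[[id]]),
                         error = function(e) NULL)
        if (is.null(arch)) {
            message(sprintf("cluster '%s': no parsable PKS, skipped", id))
            next
        }
        prods <- normalizeProductLabel(companions[[id]])
        crit <- c(
            in_both_chemotypes = id %in% sharedIds,
            has_NR_PKS = classifyCategory(arch) == "NR-PKS" ||
                "NR-PKS" %in% prods,
            has_CytP450 = "CytP450" %in% prods,
            two_ACPs = acpCount(arch) >= 2L)
        neg <- character(0)
        if (hasDomain(arch, "cMT")) neg <- c(neg, "has_cMT")
        if ("OMT" %in% prods) neg <- c(neg, "has_OMT_in_cluster")
        if (!hasDomain(arch, "TE")) neg <- c(neg, "lacks_TE")
        if (id %in% divergentRPKSNeighbor)
            neg <- c(neg, "divergent_R_PKS_neighbor")
        if (!is.null(groups) && !is.na(groups[id]) && groups[id] != "I")
            neg <- c(neg, "group_mismatch")
        passed <- all(crit)
        narrative <- if (passed) {
            "passes all four criteria"
        } else {
            sprintf("fails: %s%s",
                    paste(names(crit)[!crit], collapse = ", "),
                    if (length(neg))
                        paste0("; evidence: ", paste(neg, collapse = ", "))
                    else "")
        }
        rows[[length(rows) + 1L]] <- data.frame(
            cluster_id = id,
            in_both_chemotypes = crit[["in_both_chemotypes"]],
            has_NR_PKS = crit[["has_NR_PKS"]],
            has_CytP450 = crit[["has_CytP450"]],
            two_ACPs = crit[["two_ACPs"]],
            passed = passed,
            negative_evidence = paste(neg, collapse = ","),
            narrative = narrative,
            stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows) else NULL
    if (is.null(out))
        out <- data.frame(cluster_id = character(),
                          in_both_chemotypes = logical(),
                          has_NR_PKS = logical(), has_CytP450 = logical(),
                          two_ACPs = logical(), passed = logical(),
                          negative_evidence = character(),
                          narrative = character())
    out
}

#' Evaluate candidate clusters of an annotated genome
#'
#' Convenience wrapper over [evaluateCandidates] that derives the inputs
#' from a [GenomeAnnotation-class], a classification table
#' ([classifyClusters]) and a homology partition: companion labels come
#' from the member genes' product annotations, shared ids from the
#' partition, and divergent R-PKS neighbors from gene geometry (an R-PKS
#' gene immediately adjacent to the cluster's core NR-PKS on the same
#' contig, transcribed head-to-head).
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param classifications \code{data.frame} from [classifyClusters].
#' @param comparison a [ChemotypeComparison-class].
#' @param side which side of the comparison this genome is: \code{"A"}
#'   or \code{"B"}.
#' @return see [evaluateCandidates].
#' @export
evaluateGenomeCandidates <- function(annotation, classifications,
                                     comparison, side = c("A", "B")) {
    side <- match.arg(side)
    shared <- if (side == "A") sharedPairs(comparison)$cluster_a
              else sharedPairs(comparison)$cluster_b
    ids <- classifications$cluster_id
    domains <- stats::setNames(classifications$domains, ids)
    companions <- stats::setNames(lapply(ids, function(id) {
        g <- getGenes(annotation, geneIds(getCluster(annotation, id)))
        S4Vectors::mcols(g)$product
    }), ids)
    groups <- stats::setNames(classifications$group, ids)
    divNbr <- ids[vapply(ids, function(id)
        hasDivergentRPKSNeighbor(annotation, id), logical(1L))]
    evaluateCandidates(domains, companions, shared, groups, divNbr)
}

## TRUE when the cluster's core gene has an immediately adjacent,
## divergently transcribed R-PKS gene on the same contig
hasDivergentRPKSNeighbor <- function(annotation, id) {
    cl <- getCluster(annotation, id)
    core <- getGenes(annotation, coreGeneIds(cl)[1L])
    g <- genes(annotation)
    same <- g[as.character(GenomicRanges::seqnames(g)) ==
              as.character(GenomicRanges::seqnames(core))]
    same <- same[order(GenomicRanges::start(same))]
    i <- which(S4Vectors::mcols(same)$gene_id ==
               S4Vectors::mcols(core)$gene_id)
    for (j in c(i - 1L, i + 1L)) {
        if (j < 1L || j > length(same)) next
        if (normalizeProductLabel(S4Vectors::mcols(same)$product[j]) !=
            "R-PKS") next
        lo <- min(i, j); hi <- max(i, j)
        s1 <- as.character(GenomicRanges::strand(same))[lo]
        s2 <- as.character(GenomicRanges::strand(same))[hi]
        if (s1 == "-" && s2 == "+") return(TRUE)
    }
    FALSE
}

#' Detect the atranorin-type cluster
#'
#' Returns the single shared cluster whose PKS has the atranorin domain
#' complement (SAT, KS, AT, PT, ACP and cMT; the TE release domain is
#' treated as optional because reported atranorin synthases are printed
#' both with and without it), groups phylogenetically in group IX, and
#' whose cluster contains a CytP450, an O-methyltransferase and a
#' transporter gene.
#'
#' @inheritParams evaluateCandidates
#' @param groups named character vector of group labels per cluster
#'   (required here: group IX membership is part of the rule).
#' @return the matching cluster id, or \code{NA_character_} when no
#'   cluster matches.
#' @export
detectAtranorinCluster <- function(domains, companions, sharedIds,
                                   groups) {
    need <- c("SAT", "KS", "AT", "PT", "ACP", "cMT")
    hits <- character(0)
    for (id in names(domains)) {
        arch <- tryCatch(parseDomainString(domains[[id]]),
                         error = function(e) NULL)
        if (is.null(arch)) next
        if (!all(need %in% domainTokens(arch))) next
        if (is.na(groups[id]) || groups[id] != "IX") next
        if (!id %in% sharedIds) next
        prods <- normalizeProductLabel(companions[[id]])
        if (all(c("CytP450", "OMT", "transporter") %in% prods))
            hits <- c(hits, id)
    }
    if (length(hits) > 1L)
        lbgcError("ambiguityError",
                  sprintf("multiple atranorin-type clusters: %s",
                          paste(hits, collapse = ", ")))
    if (length(hits)) hits else NA_character_
}

#' Locate a divergently transcribed gene pair by sequence queries
#'
#' Finds the best-scoring gene hit for each query (global alignment,
#' [scorePair], with a k-mer prescreen to skip unrelated genes) and
#' returns a [FASLocus-class] iff the two hits are immediately adjacent
#' on the same contig (no intervening gene, intergenic distance at most
#' \code{maxIntergenic}) and divergently transcribed. Used to detect the
#' HexA/HexB metabolite FAS locus, whose subunit genes sit head-to-head
#' around a shared control region.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param queryA,queryB query sequences (e.g. HexA and HexB homologs of a
#'   related fungus).
#' @param minIdentity minimum aligned identity for a gene hit
#'   (default 0.7).
#' @param maxIntergenic maximum intergenic distance in bp for adjacency
#'   (default 5000).
#' @return a [FASLocus-class] when the divergent pair is found, otherwise
#'   \code{NULL} (a message reports the reason, including a
#'   non-divergent orientation).
#' @export
findDivergentPair <- function(genome, queryA, queryB, minIdentity = 0.7,
                              maxIntergenic = 5000) {
    bestGene <- function(query) {
        q <- asDNA(query)
        if (length(q) == 0L)
            lbgcError("emptySequenceError", "empty query sequence")
        seqs <- geneSequences(genome)
        if (!length(seqs)) return(NULL)
        qc <- as.character(q)
        qrc <- as.character(Biostrings::reverseComplement(q))
        d <- vapply(as.character(seqs), function(s)
            min(kmerDistance(qc, s), kmerDistance(qrc, s)), numeric(1L))
        idx <- which(d <= 0.95)
        if (!length(idx)) return(NULL)
        sps <- lapply(idx, function(i) {
            fwd <- scorePair(q, seqs[[i]], "query", names(seqs)[i])
            rev <- scorePair(Biostrings::reverseComplement(q), seqs[[i]],
                             "query", names(seqs)[i])
            if (fwd$score >= rev$score) fwd else rev
        })
        scores <- vapply(sps, `[[`, numeric(1L), "score")
        best <- sps[[which.max(scores)]]
        if (best$identity < minIdentity) return(NULL)
        best$subject_id
    }
    hitA <- bestGene(queryA); hitB <- bestGene(queryB)
    if (is.null(hitA) || is.null(hitB)) {
        message("divergent-pair search: a query hit no gene above the ",
                "identity threshold")
        return(NULL)
    }
    gA <- getGenes(genome, hitA); gB <- getGenes(genome, hitB)
    if (as.character(GenomicRanges::seqnames(gA)) !=
        as.character(GenomicRanges::seqnames(gB))) {
        message("divergent-pair search: hits on different contigs")
        return(NULL)
    }
    ## adjacency: consecutive genes on the contig, bounded intergenic gap
    g <- genes(genome)
    same <- g[as.character(GenomicRanges::seqnames(g)) ==
              as.character(GenomicRanges::seqnames(gA))]
    same <- same[order(GenomicRanges::start(same))]
    ids <- S4Vectors::mcols(same)$gene_id
    i <- which(ids == hitA); j <- which(ids == hitB)
    if (abs(i - j) != 1L) {
        message("divergent-pair search: hits are not adjacent genes")
        return(NULL)
    }
    lo <- min(i, j); hi <- max(i, j)
    gap <- GenomicRanges::start(same)[hi] - GenomicRanges::end(same)[lo] - 1L
    if (gap > maxIntergenic) {
        message("divergent-pair search: intergenic distance ", gap,
                " bp exceeds ", maxIntergenic, " bp")
        return(NULL)
    }
    s1 <- as.character(GenomicRanges::strand(same))[lo]
    s2 <- as.character(GenomicRanges::strand(same))[hi]
    orient <- if (s1 == "-" && s2 == "+") "divergent"
              else if (s1 == "+" && s2 == "-") "convergent"
              else "tandem"
    if (orient != "divergent") {
        message("divergent-pair search: pair found but orientation is ",
                orient)
        return(NULL)
    }
    new("FASLocus", geneAId = hitA, geneBId = hitB,
        orientation = orient, intergenicBp = max(gap, 0L))
}
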