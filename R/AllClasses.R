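#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
NULL

## Closed vocabulary for cluster core types (antiSMASH-style categories).
CORE_TYPES <- c("NR-PKS", "R-PKS", "T3-PKS", "NRPS", "NRPS-like",
                "hybrid", "terpene", "indole")

## PKS domain token vocabulary (case-sensitive).
DOMAIN_TOKENS <- c("SAT", "KS", "AT", "PT", "ACP", "cMT", "TE", "TD",
                   "KR", "DH", "ER", "MT")

## NR-PKS phylogenetic groups handled by the group-placement stage.
PKS_GROUPS <- c("I", "II", "V", "VII", "IX")

## ---------------------------------------------------------------------------
## BGCluster
## ---------------------------------------------------------------------------

#' BGCluster: one biosynthetic gene cluster region
#'
#' A cluster is a named genomic region (an antiSMASH-style "Region") with an
#' ordered set of member genes and one or more core backbone genes. Gene
#' coordinates and sequences live in the owning [GenomeAnnotation-class];
#' the cluster references genes by identifier.
#'
#' @slot clusterId cluster identifier, unique within a genome.
#' @slot genomeId identifier of the owning genome.
#' @slot regionLabel free-text region label (e.g. \code{"Region 33.1"}).
#' @slot coreType one of \code{NR-PKS, R-PKS, T3-PKS, NRPS, NRPS-like,
#'   hybrid, terpene, indole}.
#' @slot coreGeneIds identifiers of the core gene(s); must be a subset of
#'   \code{geneIds}.
#' @slot geneIds ordered identifiers of all member genes (non-empty).
#' @exportClass BGCluster
setClass("BGCluster",
    representation(clusterId   = "character",
                   genomeId    = "character",
                   regionLabel = "character",
                   coreType    = "character",
                   coreGeneIds = "character",
                   geneIds     = "character"))

setValidity("BGCluster", function(object) {
    msg <- character(0)
    if (length(object@clusterId) != 1L || !nzchar(object@clusterId))
        msg <- c(msg, "'clusterId' must be a single non-empty string")
    if (length(object@coreType) != 1L || !object@coreType %in% CORE_TYPES)
        msg <- c(msg, sprintf("'coreType' must be one of: %s",
                              paste(CORE_TYPES, collapse = ", ")))
    if (length(object@geneIds) == 0L)
        msg <- c(msg, "a cluster must contain at least one gene")
    if (!all(object@coreGeneIds %in% object@geneIds))
        msg <- c(msg, "'coreGeneIds' must be a subset of 'geneIds'")
    if (length(msg)) msg else TRUE
})

#' Construct a BGCluster
#'
#' @param clusterId,genomeId,regionLabel,coreType,coreGeneIds,geneIds see
#'   the corresponding slots of [BGCluster-class].
#' @return a validated \code{BGCluster}.
#' @examples
#' BGCluster("c1", "gA", "Region 1.1", "NR-PKS", "g2", c("g1", "g2", "g3"))
#' @export
BGCluster <- function(clusterId, genomeId, regionLabel, coreType,
                      coreGeneIds, geneIds) {
    new("BGCluster", clusterId = as.character(clusterId),
        genomeId = as.character(genomeId),
        regionLabel = as.character(regionLabel),
        coreType = as.character(coreType),
        coreGeneIds = as.character(coreGeneIds),
        geneIds = as.character(geneIds))
}

## ---------------------------------------------------------------------------
## GenomeAnnotation
## ---------------------------------------------------------------------------

#' GenomeAnnotation: contigs, gene models and clusters of one genome
#'
#' Genes are held as a \code{GRanges} (1-based inclusive coordinates, the
#' GFF3 convention) whose metadata columns carry \code{gene_id},
#' \code{product} and the strand-corrected nucleotide \code{sequence}
#' (a \code{DNAStringSet}; genes on the minus strand store the
#' reverse-complement of the contig slice).
#'
#' @slot genomeId genome identifier.
#' @slot contigs named \code{DNAStringSet} of contig sequences.
#' @slot genes \code{GRanges} with mcols \code{gene_id}, \code{product},
#'   \code{sequence}.
#' @slot clusters list of [BGCluster-class] objects.
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
    representation(genomeId = "character",
                   contigs  = "DNAStringSet",
                   genes    = "GRanges",
                   clusters = "list"))

setValidity("GenomeAnnotation", function(object) {
    msg <- character(0)
    g <- object@genes
    need <- c("gene_id", "product", "sequence")
    if (!all(need %in% colnames(S4Vectors::mcols(g))))
        return(sprintf("gene mcols must contain: %s",
                       paste(need, collapse = ", ")))
    ids <- S4Vectors::mcols(g)$gene_id
    if (anyDuplicated(ids))
        msg <- c(msg, "duplicate gene_id in annotation")
    if (length(g)) {
        if (!all(as.character(GenomicRanges::strand(g)) %in% c("+", "-")))
            msg <- c(msg, "gene strand must be '+' or '-'")
        if (any(GenomicRanges::start(g) < 1L))
            msg <- c(msg, "gene start below 1 (coordinates are 1-based)")
        ctg <- as.character(GenomicRanges::seqnames(g))
        if (!all(ctg %in% names(object@contigs))) {
            msg <- c(msg, "gene placed on unknown contig")
        } else {
            lens <- Biostrings::width(object@contigs)[match(ctg, names(object@contigs))]
            if (any(GenomicRanges::end(g) > lens))
                msg <- c(msg, "gene extends beyond its contig")
        }
        seqs <- S4Vectors::mcols(g)$sequence
        if (any(Biostrings::width(seqs) != GenomicRanges::width(g)))
            msg <- c(msg, "gene sequence length != end - start + 1")
    }
    for (cl in object@clusters) {
        if (!is(cl, "BGCluster")) {
            msg <- c(msg, "'clusters' must contain BGCluster objects")
            break
        }
        if (!all(cl@geneIds %in% ids)) {
            msg <- c(msg, sprintf("cluster '%s' references unknown gene(s)",
                                  cl@clusterId))
            break
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param genomeId genome identifier.
#' @param contigs named \code{DNAStringSet}.
#' @param genes \code{GRanges} with mcols \code{gene_id}, \code{product},
#'   \code{sequence} (see [GenomeAnnotation-class]).
#' @param clusters list of [BGCluster-class].
#' @return a validated \code{GenomeAnnotation}.
#' @export
GenomeAnnotation <- function(genomeId, contigs, genes,
                             clusters = list()) {
    new("GenomeAnnotation", genomeId = as.character(genomeId),
        contigs = contigs, genes = genes, clusters = clusters)
}

## ---------------------------------------------------------------------------
## CountTable
## ---------------------------------------------------------------------------

#' CountTable: per-gene raw read counts plus the sample library size
#'
#' The library size is the total number of reads in the sample (not the
#' number of mapped reads), so it is always at least the sum of the per-gene
#' counts; the difference is background (intergenic or unassigned) reads.
#'
#' @slot counts \code{data.frame} with columns \code{gene_id} (character)
#'   and \code{raw_count} (non-negative integer).
#' @slot librarySize total reads in the sample (positive integer; stored as
#'   double so that full-scale transcriptome libraries are representable).
#' @exportClass CountTable
setClass("CountTable",
    representation(counts = "data.frame", librarySize = "numeric"))

setValidity("CountTable", function(object) {
    msg <- character(0)
    cts <- object@counts
    if (!all(c("gene_id", "raw_count") %in% names(cts)))
        return("counts must have columns 'gene_id' and 'raw_count'")
    if (any(cts$raw_count < 0))
        msg <- c(msg, "raw counts must be non-negative")
    if (anyDuplicated(cts$gene_id))
        msg <- c(msg, "duplicate gene_id in count table")
    if (length(object@librarySize) != 1L || object@librarySize < 0 ||
        object@librarySize != trunc(object@librarySize))
        msg <- c(msg, "'librarySize' must be a single non-negative integer")
    else if (object@librarySize < sum(cts$raw_count))
        msg <- c(msg, "library size smaller than the sum of gene counts")
    if (length(msg)) msg else TRUE
})

#' Construct a CountTable
#'
#' @param gene_id character vector of gene identifiers.
#' @param raw_count non-negative integer counts, same length.
#' @param librarySize total reads in the sample (>= \code{sum(raw_count)}).
#' @return a validated \code{CountTable}.
#' @examples
#' CountTable(c("g1", "g2"), c(10, 0), librarySize = 1000)
#' @export
CountTable <- function(gene_id, raw_count, librarySize) {
    new("CountTable",
        counts = data.frame(gene_id = as.character(gene_id),
                            raw_count = as.numeric(raw_count),
                            stringsAsFactors = FALSE),
        librarySize = as.numeric(librarySize))
}

## ---------------------------------------------------------------------------
## DomainArchitecture / PKSClassification
## ---------------------------------------------------------------------------

#' DomainArchitecture: ordered PKS domain tokens
#'
#' Tokens come from the closed vocabulary \code{SAT, KS, AT, PT, ACP, cMT,
#' TE, TD, KR, DH, ER, MT}. Derived features (ACP count, presence flags,
#' the reducing flag) are computed by accessors from the token list, never
#' stored, so they cannot drift out of sync. \code{TD} is a terminal
#' reductive release domain distinct from \code{TE}; neither releasing
#' domain counts as a reducing domain (\code{KR/DH/ER} do).
#'
#' @slot tokens ordered character vector of domain tokens.
#' @exportClass DomainArchitecture
setClass("DomainArchitecture", representation(tokens = "character"))

setValidity("DomainArchitecture", function(object) {
    if (length(object@tokens) == 0L)
        return("a domain architecture must contain at least one token")
    bad <- setdiff(object@tokens, DOMAIN_TOKENS)
    if (length(bad))
        return(sprintf("unknown domain token(s): %s",
                       paste(bad, collapse = ", ")))
    TRUE
})

#' PKSClassification: category and phylogenetic group of one PKS
#'
#' @slot category \code{"NR-PKS"}, \code{"R-PKS"} or \code{"other"}.
#' @slot group \code{"I"}, \code{"II"}, \code{"V"}, \code{"VII"},
#'   \code{"IX"} or \code{"unknown"}. A named group is only assigned to an
#'   NR-PKS with a labelled reference within the distance threshold.
#' @slot nearestReferenceId identifier of the nearest reference
#'   (\code{NA} if none was within reach).
#' @slot distance k-mer distance to the nearest reference (\code{NA_real_}
#'   when no reference was supplied).
#' @exportClass PKSClassification
setClass("PKSClassification",
    representation(category = "character",
                   group = "character",
                   nearestReferenceId = "character",
                   distance = "numeric"))

setValidity("PKSClassification", function(object) {
    if (!object@category %in% c("NR-PKS", "R-PKS", "other"))
        return("category must be 'NR-PKS', 'R-PKS' or 'other'")
    if (!object@group %in% c(PKS_GROUPS, "unknown"))
        return("group must be I/II/V/VII/IX or 'unknown'")
    if (object@group != "unknown" && object@category != "NR-PKS")
        return("a named group requires category 'NR-PKS'")
    TRUE
})

## ---------------------------------------------------------------------------
## ChemotypeComparison / FASLocus
## ---------------------------------------------------------------------------

#' ChemotypeComparison: shared/specific partition of two BGC complements
#'
#' @slot sharedPairs \code{data.frame} of reciprocal best-hit pairs with
#'   columns \code{cluster_a}, \code{cluster_b}, \code{identity},
#'   \code{score}, \code{aligned_length}.
#' @slot specificA,specificB \code{data.frame}s with columns
#'   \code{cluster_id}, \code{absence_evidence} (maximum normalized read
#'   coverage, RPKM, of the cluster core in the other chemotype's raw
#'   reads) and \code{status} (\code{"specific"} when the evidence is
#'   exactly zero, otherwise \code{"ambiguous"}).
#' @exportClass ChemotypeComparison
setClass("ChemotypeComparison",
    representation(sharedPairs = "data.frame",
                   specificA = "data.frame",
                   specificB = "data.frame"))

#' FASLocus: an adjacent HexA/HexB fatty-acid-synthase gene pair
#'
#' Orientation is called on ascending coordinates: \code{divergent} means
#' the upstream gene is on the minus strand and the downstream gene on the
#' plus strand (head-to-head, transcribed away from the shared intergenic
#' control region); \code{convergent} is the mirror image; \code{tandem}
#' means both genes point the same way.
#'
#' @slot geneAId,geneBId member gene identifiers (HexA then HexB).
#' @slot orientation \code{"divergent"}, \code{"convergent"} or
#'   \code{"tandem"}.
#' @slot intergenicBp distance in bp between the two genes (>= 0).
#' @exportClass FASLocus
setClass("FASLocus",
    representation(geneAId = "character", geneBId = "character",
                   orientation = "character", intergenicBp = "numeric"))

setValidity("FASLocus", function(object) {
    if (!object@orientation %in% c("divergent", "convergent", "tandem"))
        return("orientation must be divergent/convergent/tandem")
    if (object@intergenicBp < 0)
        return("intergenicBp must be >= 0")
    TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "BGCluster", function(object) {
    cat(sprintf("BGCluster '%s' (%s, %s): %d gene(s), core: %s [%s]\n",
                object@clusterId, object@genomeId, object@regionLabel,
                length(object@geneIds),
                paste(object@coreGeneIds, collapse = ","),
                object@coreType))
})

setMethod("show", "GenomeAnnotation", function(object) {
    cat(sprintf("GenomeAnnotation '%s': %d contig(s), %d gene(s), %d cluster(s)\n",
                object@genomeId, length(object@contigs),
                length(object@genes), length(object@clusters)))
})

setMethod("show", "CountTable", function(object) {
    cat(sprintf("CountTable: %d gene(s), %s assigned reads, library size %s\n",
                nrow(object@counts),
                format(sum(object@counts$raw_count), big.mark = ","),
                format(object@librarySize, big.mark = ",")))
})

setMethod("show", "DomainArchitecture", function(object) {
    cat(sprintf("DomainArchitecture: %s\n",
                paste(object@tokens, collapse = "-")))
})

setMethod("show", "PKSClassification", function(object) {
    cat(sprintf("PKSClassification: %s, group %s (nearest: %s, d = %s)\n",
                object@category, object@group,
                object@nearestReferenceId,
                format(object@distance, digits = 3)))
})

setMethod("show", "ChemotypeComparison", function(object) {
    cat(sprintf(
        "ChemotypeComparison: %d shared pair(s), %d specific in A, %d in B\n",
        nrow(object@sharedPairs), nrow(object@specificA),
        nrow(object@specificB)))
})

setMethod("show", "FASLocus", function(object) {
    cat(sprintf("FASLocus: %s / %s, %s, intergenic %d bp\n",
                object@geneAId, object@geneBId, object@orientation,
                as.integer(object@intergenicBp)))
})
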