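## Accessor generics and methods. Slots are never touched directly by user
## code; derived quantities (domain flags, gene lengths) are computed here.

#' @name accessors
#' @title Accessors for lichenBGC classes
#'
#' @description Read-only accessors for the package's S4 containers.
#' Derived domain-architecture features (\code{acpCount},
#' \code{hasDomain}, \code{hasReducing}) are recomputed from the token
#' list on every call.
#'
#' @param x an object of the documented class.
#' @param token a domain token (e.g. \code{"cMT"}).
#' @return the slot value or derived quantity.
#' @examples
#' arch <- parseDomainString("SAT-KS-AT-ACP-ACP-TE")
#' acpCount(arch)      # 2
#' hasDomain(arch, "cMT")
#' hasReducing(arch)
NULL

#' @rdname accessors
#' @export
setGeneric("clusterId", function(x) standardGeneric("clusterId"))
#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("regionLabel", function(x) standardGeneric("regionLabel"))
#' @rdname accessors
#' @export
setGeneric("coreType", function(x) standardGeneric("coreType"))
#' @rdname accessors
#' @export
setGeneric("coreGeneIds", function(x) standardGeneric("coreGeneIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))
#' @rdname accessors
#' @export
setGeneric("domainTokens", function(x) standardGeneric("domainTokens"))
#' @rdname accessors
#' @export
setGeneric("acpCount", function(x) standardGeneric("acpCount"))
#' @rdname accessors
#' @export
setGeneric("hasDomain", function(x, token) standardGeneric("hasDomain"))
#' @rdname accessors
#' @export
setGeneric("hasReducing", function(x) standardGeneric("hasReducing"))
#' @rdname accessors
#' @export
setGeneric("pksCategory", function(x) standardGeneric("pksCategory"))
#' @rdname accessors
#' @export
setGeneric("pksGroup", function(x) standardGeneric("pksGroup"))
#' @rdname accessors
#' @export
setGeneric("sharedPairs", function(x) standardGeneric("sharedPairs"))
#' @rdname accessors
#' @export
setGeneric("specificClusters", function(x) standardGeneric("specificClusters"))
#' @rdname accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))
#' @rdname accessors
#' @export
setGeneric("intergenicBp", function(x) standardGeneric("intergenicBp"))

setMethod("clusterId", "BGCluster", function(x) x@clusterId)
setMethod("genomeId", "BGCluster", function(x) x@genomeId)
setMethod("genomeId", "GenomeAnnotation", function(x) x@genomeId)
setMethod("regionLabel", "BGCluster", function(x) x@regionLabel)
setMethod("coreType", "BGCluster", function(x) x@coreType)
setMethod("coreGeneIds", "BGCluster", function(x) x@coreGeneIds)
setMethod("geneIds", "BGCluster", function(x) x@geneIds)
setMethod("contigs", "GenomeAnnotation", function(x) x@contigs)
setMethod("genes", "GenomeAnnotation", function(x) x@genes)
setMethod("clusters", "GenomeAnnotation", function(x) x@clusters)
setMethod("counts", "CountTable", function(x) x@counts)
setMethod("librarySize", "CountTable", function(x) x@librarySize)

setMethod("domainTokens", "DomainArchitecture", function(x) x@tokens)
setMethod("acpCount", "DomainArchitecture",
          function(x) sum(x@tokens == "ACP"))
setMethod("hasDomain", "DomainArchitecture", function(x, token) {
    if (!token %in% DOMAIN_TOKENS)
        lbgcError("unknownTokenError",
                  sprintf("unknown domain token '%s'", token))
    token %in% x@tokens
})
setMethod("hasReducing", "DomainArchitecture",
          function(x) any(c("KR", "DH", "ER") %in% x@tokens))

setMethod("pksCategory", "PKSClassification", function(x) x@category)
setMethod("pksGroup", "PKSClassification", function(x) x@group)

setMethod("sharedPairs", "ChemotypeComparison", function(x) x@sharedPairs)

#' @rdname accessors
#' @param genome for \code{specificClusters}, which side: \code{"A"} or
#'   \code{"B"}.
#' @export
setMethod("specificClusters", "ChemotypeComparison", function(x) {
    list(A = x@specificA, B = x@specificB)
})

setMethod("orientation", "FASLocus", function(x) x@orientation)
setMethod("intergenicBp", "FASLocus", function(x) x@intergenicBp)

## ---------------------------------------------------------------------------
## Gene-level helpers on GenomeAnnotation
## ---------------------------------------------------------------------------

#' Look up genes of an annotation by identifier
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param ids character vector of gene identifiers.
#' @return a \code{GRanges} subset in the order of \code{ids}.
#' @export
getGenes <- function(annotation, ids) {
    g <- genes(annotation)
    idx <- match(ids, S4Vectors::mcols(g)$gene_id)
    if (anyNA(idx))
        lbgcError("unknownGeneError",
                  sprintf("unknown gene id(s): %s",
                          paste(ids[is.na(idx)], collapse = ", ")))
    g[idx]
}

#' Nucleotide sequences of genes (strand-corrected)
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param ids gene identifiers; default all genes.
#' @return a named \code{DNAStringSet}.
#' @export
geneSequences <- function(annotation,
                          ids = S4Vectors::mcols(genes(annotation))$gene_id) {
    g <- getGenes(annotation, ids)
    s <- S4Vectors::mcols(g)$sequence
    names(s) <- S4Vectors::mcols(g)$gene_id
    s
}

#' Core gene sequence of each cluster
#'
#' Returns the sequence of the first core gene of every cluster, named by
#' cluster identifier. These are the inputs to reciprocal best-hit
#' matching.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @return a named \code{DNAStringSet}, one entry per cluster.
#' @export
coreSequences <- function(annotation) {
    cls <- clusters(annotation)
    ids <- vapply(cls, function(cl) coreGeneIds(cl)[1L], character(1L))
    s <- geneSequences(annotation, ids)
    names(s) <- vapply(cls, clusterId, character(1L))
    s
}

#' Look up a cluster by identifier
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param id a cluster identifier.
#' @return the matching [BGCluster-class].
#' @export
getCluster <- function(annotation, id) {
    for (cl in clusters(annotation))
        if (clusterId(cl) == id) return(cl)
    lbgcError("unknownGeneError", sprintf("unknown cluster id '%s'", id))
}
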