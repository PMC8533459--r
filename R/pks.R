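## PKS domain-architecture parsing, reducing/non-reducing classification,
## alignment-free group placement against labelled references, and a
## neighbor-joining companion tree for reporting.

#' Parse a PKS domain string
#'
#' Accepts the mixed separators found in practice (hyphens and/or
#' whitespace, e.g. \code{"SAT-KS-AT-ACP ACP-TE"}) and matches tokens
#' case-sensitively against the vocabulary \code{SAT, KS, AT, PT, ACP,
#' cMT, TE, TD, KR, DH, ER, MT}.
#'
#' @param text a single domain string.
#' @return a [DomainArchitecture-class].
#' @examples
#' arch <- parseDomainString("SAT-KS-AT-ACP ACP-TE")
#' acpCount(arch)   # 2
#' @export
parseDomainString <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    tokens <- strsplit(trimws(text), "[-[:space:]]+")[[1L]]
    tokens <- tokens[nzchar(tokens)]
    if (!length(tokens))
        lbgcError("unknownTokenError", "empty domain string")
    bad <- setdiff(tokens, DOMAIN_TOKENS)
    if (length(bad))
        lbgcError("unknownTokenError",
                  sprintf("unknown domain token(s): %s",
                          paste(unique(bad), collapse = ", ")))
    new("DomainArchitecture", tokens = tokens)
}

#' Classify a PKS as reducing, non-reducing or other
#'
#' A PKS carrying any reducing domain (KR, DH or ER) is an R-PKS. A PKS
#' without reducing domains that has at least the minimal KS + AT + ACP
#' catalytic complement is an NR-PKS. Anything else (e.g. a lone ACP
#' fragment) is \code{"other"}.
#'
#' @param arch a [DomainArchitecture-class].
#' @return \code{"NR-PKS"}, \code{"R-PKS"} or \code{"other"}.
#' @export
classifyCategory <- function(arch) {
    stopifnot(is(arch, "DomainArchitecture"))
    if (hasReducing(arch)) return("R-PKS")
    if (all(c("KS", "AT", "ACP") %in% domainTokens(arch))) return("NR-PKS")
    "other"
}

#' Alignment-free k-mer distance between two sequences
#'
#' One minus the Jaccard similarity of the sequences' k-mer sets.
#' Symmetric, zero for identical sequences and 1 for sequences sharing no
#' k-mer. Defaults to k = 8 for nucleotide sequences; use k = 4 for amino
#' acids (the larger alphabet saturates sooner).
#'
#' @param seqA,seqB sequences (character or \code{XString}-like), longer
#'   than \code{k}.
#' @param k k-mer length (default 8).
#' @return distance in \[0, 1\].
#' @export
kmerDistance <- function(seqA, seqB, k = 8L) {
    a <- as.character(seqA); b <- as.character(seqB)
    if (nchar(a) < k || nchar(b) < k)
        lbgcError("configError",
                  sprintf("sequences must be longer than k = %d", k))
    sa <- kmerSet(a, k); sb <- kmerSet(b, k)
    inter <- length(intersect(sa, sb))
    uni <- length(sa) + length(sb) - inter
    if (uni == 0L) return(0)
    1 - inter / uni
}

#' Assign an NR-PKS to a phylogenetic group by nearest labelled reference
#'
#' Fungal NR-PKSs fall into named phylogenetic groups (I, II, V, VII, IX
#' among those handled here); orcinol depside/depsidone synthases sit in
#' group I. Rather than a full phylogeny, the query is placed with the
#' group of its nearest labelled reference under the k-mer distance,
#' provided that distance is within \code{maxDistance}; otherwise the
#' group is \code{"unknown"}. Adding a duplicate of an existing reference
#' never changes the placement.
#'
#' @param pksSeq query sequence (nucleotide or amino acid).
#' @param references named character vector or \code{XStringSet} of
#'   reference sequences.
#' @param referenceGroups character vector of group labels (one of
#'   \code{I, II, V, VII, IX}), parallel to \code{references}.
#' @param maxDistance maximum k-mer distance for a confident placement
#'   (default 0.6).
#' @param k k-mer length (default 8; use 4 for amino acid sequences).
#' @param arch optional [DomainArchitecture-class] of the query; when
#'   given, the category is derived from it, and non-NR-PKS queries are
#'   never assigned a named group.
#' @return a [PKSClassification-class].
#' @export
assignGroup <- function(pksSeq, references, referenceGroups,
                        maxDistance = 0.6, k = 8L, arch = NULL) {
    refs <- stats::setNames(as.character(references), names(references))
    if (length(refs) == 0L)
        lbgcError("configError", "at least one reference is required")
    if (length(referenceGroups) != length(refs))
        lbgcError("configError",
                  "'referenceGroups' must parallel 'references'")
    bad <- setdiff(referenceGroups, PKS_GROUPS)
    if (length(bad))
        lbgcError("configError",
                  sprintf("unknown group label(s): %s",
                          paste(unique(bad), collapse = ", ")))
    category <- if (is.null(arch)) "NR-PKS" else classifyCategory(arch)
    d <- vapply(refs, function(r)
        kmerDistance(pksSeq, r, k = k), numeric(1L))
    ord <- order(d, names(refs))
    nearest <- ord[1L]
    group <- "unknown"
    if (category == "NR-PKS" && d[nearest] <= maxDistance)
        group <- unname(referenceGroups[nearest])
    new("PKSClassification", category = category, group = group,
        nearestReferenceId = names(refs)[nearest],
        distance = unname(d[nearest]))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Companion tree for reporting group placements; standard
#' neighbor-joining (via \pkg{ape}), which recovers additive distance
#' matrices exactly. Deterministic for a given input order.
#'
#' @param d a symmetric distance matrix with zero diagonal (or a
#'   \code{dist}), at least 3 taxa.
#' @return an unrooted \code{phylo} tree.
#' @seealso [ape::nj]
#' @export
njTree <- function(d) {
    m <- as.matrix(d)
    if (nrow(m) < 3L)
        lbgcError("configError", "neighbor joining needs at least 3 taxa")
    if (!isSymmetric(unname(m)) || any(diag(m) != 0))
        lbgcError("configError",
                  "distance matrix must be symmetric with zero diagonal")
    ape::nj(stats::as.dist(m))
}

#' Classify all NR-PKS-bearing clusters of an annotation
#'
#' For every cluster whose domain architecture is known (supplied as a
#' named list/character of domain strings keyed by cluster id), parses the
#' architecture, classifies the category and places NR-PKSs in a group by
#' nearest reference.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param architectures named character vector of PKS domain strings,
#'   names being cluster ids (clusters without an entry are skipped).
#' @inheritParams assignGroup
#' @return a \code{data.frame} with one row per classified cluster:
#'   \code{cluster_id}, \code{domains}, \code{acp_count}, \code{has_cMT},
#'   \code{has_TE}, \code{category}, \code{group}, \code{nearest_reference},
#'   \code{distance}.
#' @export
classifyClusters <- function(annotation, architectures, references,
                             referenceGroups, maxDistance = 0.6, k = 8L) {
    ids <- intersect(vapply(clusters(annotation), clusterId, character(1L)),
                     names(architectures))
    rows <- lapply(ids, function(id) {
        arch <- parseDomainString(architectures[[id]])
        core <- coreGeneIds(getCluster(annotation, id))[1L]
        cls <- assignGroup(geneSequences(annotation, core)[[1L]],
                           references, referenceGroups,
                           maxDistance = maxDistance, k = k, arch = arch)
        data.frame(cluster_id = id,
                   domains = paste(domainTokens(arch), collapse = "-"),
                   acp_count = acpCount(arch),
                   has_cMT = hasDomain(arch, "cMT"),
                   has_TE = hasDomain(arch, "TE"),
                   category = pksCategory(cls),
                   group = pksGroup(cls),
                   nearest_reference = cls@nearestReferenceId,
                   distance = cls@distance,
                   stringsAsFactors = FALSE)
    })
    out <- if (length(rows)) do.call(rbind, rows) else NULL
    if (is.null(out))
        out <- data.frame(cluster_id = character(), domains = character(),
                          acp_count = integer(), has_cMT = logical(),
                          has_TE = logical(), category = character(),
                          group = character(),
                          nearest_reference = character(),
                          distance = numeric())
    out
}
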