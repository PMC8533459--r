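## Readers and writers for the on-disk interchange formats:
##   - contigs:      FASTA
##   - gene models:  GFF3 ("gene" features, ID and product attributes)
##   - clusters:     5-column TSV (see readClusterTable)
##   - counts:       TSV with a "# library_size:" pragma
##   - reports:      deterministic TSV (sorted rows, fixed column order)
##
## Coordinates are 1-based inclusive (the GFF3 convention) everywhere.
## A start of 0 is taken as evidence of 0-based input and rejected, never
## silently shifted.

checkFile <- function(path) {
    if (!file.exists(path))
        lbgcError("missingFileError", sprintf("file not found: %s", path))
    invisible(path)
}

#' Read an annotated genome (FASTA + GFF3 + cluster table)
#'
#' Loads contigs, gene models and the BGC region table into a validated
#' [GenomeAnnotation-class]. Gene sequences are extracted from the contigs
#' honouring strand (minus-strand genes store the reverse complement of the
#' contig slice). Only GFF3 features of type \code{gene} are used; the
#' \code{ID} attribute is the gene identifier and the optional
#' \code{product} attribute the product label (missing products become
#' \code{"unidentified"}).
#'
#' @param fastaPath path to the contig FASTA.
#' @param gff3Path path to the GFF3 gene models (1-based inclusive).
#' @param clusterTablePath path to the cluster TSV (see
#'   [readClusterTable]).
#' @param genomeId genome identifier; default the FASTA basename.
#' @return a [GenomeAnnotation-class].
#' @seealso [writeGenome] for the inverse operation.
#' @export
readGenome <- function(fastaPath, gff3Path, clusterTablePath,
                       genomeId = sub("\\.[^.]*$", "", basename(fastaPath))) {
    checkFile(fastaPath); checkFile(gff3Path); checkFile(clusterTablePath)
    contigs <- Biostrings::readDNAStringSet(fastaPath)
    names(contigs) <- sub("\\s.*", "", names(contigs))

    gff <- tryCatch(
        rtracklayer::import(gff3Path, format = "gff3"),
        error = function(e) lbgcError(
            "coordinateError",
            sprintf("malformed GFF3 coordinates in %s: %s",
                    gff3Path, conditionMessage(e))))
    gff <- gff[S4Vectors::mcols(gff)$type == "gene"]
    ids <- S4Vectors::mcols(gff)$ID
    if (is.null(ids) || anyNA(ids))
        lbgcError("coordinateError",
                  "every gene feature needs an ID attribute")
    if (anyDuplicated(ids))
        lbgcError("duplicateGeneError",
                  sprintf("duplicate gene id(s): %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (any(GenomicRanges::start(gff) < 1L))
        lbgcError("coordinateError",
                  "gene start < 1: coordinates must be 1-based inclusive")
    ctg <- as.character(GenomicRanges::seqnames(gff))
    if (!all(ctg %in% names(contigs)))
        lbgcError("coordinateError",
                  sprintf("gene(s) on unknown contig: %s",
                          paste(unique(setdiff(ctg, names(contigs))),
                                collapse = ", ")))
    lens <- Biostrings::width(contigs)[match(ctg, names(contigs))]
    if (any(GenomicRanges::end(gff) > lens))
        lbgcError("coordinateError",
                  "gene extends beyond its contig")
    if (!all(as.character(GenomicRanges::strand(gff)) %in% c("+", "-")))
        lbgcError("coordinateError", "gene strand must be '+' or '-'")

    product <- S4Vectors::mcols(gff)$product
    if (is.null(product)) product <- rep(NA_character_, length(gff))
    product[is.na(product) | !nzchar(product)] <- "unidentified"

    seqs <- Biostrings::DNAStringSet(lapply(seq_along(gff), function(i) {
        s <- Biostrings::subseq(contigs[[ctg[i]]],
                                GenomicRanges::start(gff)[i],
                                GenomicRanges::end(gff)[i])
        if (as.character(GenomicRanges::strand(gff))[i] == "-")
            s <- Biostrings::reverseComplement(s)
        s
    }))

    g <- GenomicRanges::GRanges(
        seqnames = ctg,
        ranges = IRanges::IRanges(GenomicRanges::start(gff),
                                  GenomicRanges::end(gff)),
        strand = as.character(GenomicRanges::strand(gff)))
    S4Vectors::mcols(g)$gene_id <- as.character(ids)
    S4Vectors::mcols(g)$product <- as.character(product)
    S4Vectors::mcols(g)$sequence <- seqs

    clusterRows <- readClusterTable(clusterTablePath)
    cls <- lapply(seq_len(nrow(clusterRows)), function(i) {
        row <- clusterRows[i, ]
        geneIds <- strsplit(row$gene_ids, ",", fixed = TRUE)[[1L]]
        core <- sub("^\\*", "", geneIds[startsWith(geneIds, "*")])
        geneIds <- sub("^\\*", "", geneIds)
        missing <- setdiff(geneIds, S4Vectors::mcols(g)$gene_id)
        if (length(missing))
            lbgcError("unknownGeneError",
                      sprintf("cluster '%s' references unknown gene(s): %s",
                              row$cluster_id, paste(missing, collapse = ", ")))
        BGCluster(row$cluster_id, row$genome_id, row$region_label,
                  row$core_type, core, geneIds)
    })
    GenomeAnnotation(genomeId, contigs, g, cls)
}

#' Read / write the 5-column cluster table
#'
#' The interchange format for BGC regions is a TSV with columns
#' \code{genome_id}, \code{cluster_id}, \code{region_label},
#' \code{core_type} and \code{gene_ids}; \code{gene_ids} is a
#' comma-separated ordered list in which core genes carry a leading
#' \code{*}.
#'
#' @param path file path.
#' @return \code{readClusterTable}: a \code{data.frame} of the five
#'   columns.
#' @export
readClusterTable <- function(path) {
    checkFile(path)
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = "character", quote = "",
                      comment.char = "")
}

#' @rdname readClusterTable
#' @param clusters list of [BGCluster-class] objects.
#' @return \code{writeClusterTable}: the path, invisibly.
#' @export
writeClusterTable <- function(clusters, path) {
    rows <- lapply(clusters, function(cl) {
        ids <- geneIds(cl)
        flagged <- ifelse(ids %in% coreGeneIds(cl), paste0("*", ids), ids)
        data.frame(genome_id = genomeId(cl), cluster_id = clusterId(cl),
                   region_label = regionLabel(cl), core_type = coreType(cl),
                   gene_ids = paste(flagged, collapse = ","),
                   stringsAsFactors = FALSE)
    })
    df <- if (length(rows)) do.call(rbind, rows) else NULL
    if (is.null(df))
        df <- data.frame(genome_id = character(), cluster_id = character(),
                         region_label = character(), core_type = character(),
                         gene_ids = character())
    writeTsv(df, path, sort = FALSE)
}

#' Write a genome to FASTA + GFF3 + cluster TSV
#'
#' The inverse of [readGenome]. The GFF3 is written by a minimal
#' deterministic emitter (no timestamp headers) so that identical inputs
#' produce byte-identical files.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; default the genome id.
#' @return named character vector of the three file paths, invisibly.
#' @export
writeGenome <- function(annotation, dir, prefix = genomeId(annotation)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(dir, paste0(prefix, ".fasta"))
    gff3 <- file.path(dir, paste0(prefix, ".gff3"))
    clstsv <- file.path(dir, paste0(prefix, ".clusters.tsv"))
    Biostrings::writeXStringSet(contigs(annotation), fasta, width = 80L)
    g <- genes(annotation)
    lines <- c("##gff-version 3",
               sprintf("%s\tlichenBGC\tgene\t%d\t%d\t.\t%s\t.\tID=%s;product=%s",
                       as.character(GenomicRanges::seqnames(g)),
                       GenomicRanges::start(g), GenomicRanges::end(g),
                       as.character(GenomicRanges::strand(g)),
                       S4Vectors::mcols(g)$gene_id,
                       S4Vectors::mcols(g)$product))
    writeLines(lines, gff3)
    writeClusterTable(clusters(annotation), clstsv)
    invisible(c(fasta = fasta, gff3 = gff3, clusters = clstsv))
}

#' Read / write a count table
#'
#' TSV with columns \code{gene_id}, \code{raw_count}; the sample library
#' size (total reads, not mapped reads) is carried in a
#' \code{# library_size: N} pragma on the first line.
#'
#' @param path file path.
#' @return \code{readCountTable}: a [CountTable-class].
#' @export
readCountTable <- function(path) {
    checkFile(path)
    first <- readLines(path, n = 1L)
    lib <- as.numeric(sub("^#\\s*library_size:\\s*", "", first))
    if (is.na(lib))
        lbgcError("configError",
                  "count table must start with '# library_size: N'")
    df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                            colClasses = c("character", "numeric"))
    CountTable(df$gene_id, df$raw_count, lib)
}

#' @rdname readCountTable
#' @param countTable a [CountTable-class].
#' @return \code{writeCountTable}: the path, invisibly.
#' @export
writeCountTable <- function(countTable, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# library_size: %.0f", librarySize(countTable)), con)
    utils::write.table(counts(countTable), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

## ---------------------------------------------------------------------------
## Report TSVs
## ---------------------------------------------------------------------------

#' Write a deterministic TSV report
#'
#' Rows are sorted by \code{cluster_id} then \code{gene_id} (where those
#' columns exist, otherwise by the first column) and columns keep their
#' input order, so repeated runs produce byte-identical files. An empty
#' data frame yields a header-only file.
#'
#' @param df a \code{data.frame}.
#' @param path output file path.
#' @param sort sort rows for determinism (default \code{TRUE}).
#' @return the path, invisibly.
#' @export
writeTsv <- function(df, path, sort = TRUE) {
    if (sort && nrow(df) > 0) {
        keys <- intersect(c("cluster_id", "gene_id"), names(df))
        if (!length(keys)) keys <- names(df)[1L]
        ord <- do.call(order, unname(df[keys]))
        df <- df[ord, , drop = FALSE]
    }
    ok <- tryCatch({
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok)
        lbgcError("missingFileError", sprintf("cannot write to: %s", path))
    invisible(path)
}

#' @rdname writeTsv
#' @return \code{readTsv}: the \code{data.frame} (character columns stay
#'   character; numeric columns are re-typed).
#' @export
readTsv <- function(path) {
    checkFile(path)
    utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                      comment.char = "", stringsAsFactors = FALSE)
}

#' Write objects to a TSV report
#'
#' A generic one-row-per-object serialization with a documented column
#' schema per type. For lists of [BGCluster-class] the schema equals the
#' cluster table of [writeClusterTable] and round-trips through
#' [readClusterTable]/[readGenome]; data frames round-trip through
#' [readTsv].
#'
#' @param objects a \code{data.frame} or a list of [BGCluster-class]
#'   objects (possibly empty).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeReport <- function(objects, path) {
    if (is.data.frame(objects)) return(writeTsv(objects, path))
    if (is.list(objects) &&
        (length(objects) == 0L || all(vapply(objects, is, logical(1L),
                                             "BGCluster")))) {
        cls <- objects
        ord <- order(vapply(cls, clusterId, character(1L)))
        return(writeClusterTable(cls[ord], path))
    }
    lbgcError("configError", "unsupported object type for writeReport")
}
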