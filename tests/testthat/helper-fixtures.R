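# Shared fixtures, generated once per test run and cached in the helper
# environment (helpers are loaded once per test session).

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, maker) {
    if (!exists(key, .fixtureCache))
        assign(key, maker(), .fixtureCache)
    get(key, .fixtureCache)
}

# small two-genome fixture: 10 shared clusters (candidate, atranorin and
# the cluster-5 mirror all present), published specifics, desk-scale reads
smallFixture <- function() {
    cachedFixture("small", function()
        generateFixture(fixtureConfig(seed = 11, n_shared_clusters = 10)))
}

# the full paper-mirror fixture (51 shared clusters)
paperFixture <- function() {
    cachedFixture("paper", function()
        generateFixture(fixtureConfig(seed = 7)))
}

# minimal hand-built annotation: contigs + genes given as a data.frame
# with columns contig, start, end, strand, gene_id, product
toyAnnotation <- function(contigs, genesDf, clusters = list(),
                          genomeId = "toy") {
    ctg <- Biostrings::DNAStringSet(contigs)
    gr <- GenomicRanges::GRanges(
        genesDf$contig,
        IRanges::IRanges(genesDf$start, genesDf$end),
        strand = genesDf$strand)
    seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(genesDf)),
        function(i) {
            s <- substring(contigs[[genesDf$contig[i]]], genesDf$start[i],
                           genesDf$end[i])
            if (genesDf$strand[i] == "-")
                s <- as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(s)))
            s
        }, character(1)))
    S4Vectors::mcols(gr)$gene_id <- genesDf$gene_id
    S4Vectors::mcols(gr)$product <- genesDf$product
    S4Vectors::mcols(gr)$sequence <- seqs
    GenomeAnnotation(genomeId, ctg, gr, clusters)
}

# the printed NR-PKS cluster inventory shaped for evaluateCandidates()
printedClusterInputs <- function() {
    tab <- pfurNRPKSClusters()
    ids <- as.character(tab$cluster)
    list(domains = stats::setNames(tab$domains, ids),
         companions = stats::setNames(strsplit(tab$companions, ","), ids),
         sharedIds = ids,
         groups = stats::setNames(tab$group, ids))
}
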