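test_that("fixture genomes round-trip through FASTA/GFF3/cluster TSV", {
    fx <- smallFixture()
    dir <- withr::local_tempdir()
    writeGenome(fx$genomeA, dir, "g")
    back <- readGenome(file.path(dir, "g.fasta"), file.path(dir, "g.gff3"),
                       file.path(dir, "g.clusters.tsv"),
                       genomeId = genomeId(fx$genomeA))
    expect_identical(length(clusters(back)), length(clusters(fx$genomeA)))
    expect_identical(S4Vectors::mcols(genes(back))$gene_id,
                     S4Vectors::mcols(genes(fx$genomeA))$gene_id)
    # strand-honouring sequence extraction reproduces the planted genes
    expect_identical(as.character(geneSequences(back)),
                     as.character(geneSequences(fx$genomeA)))
    cl <- clusters(back)[[1]]
    orig <- clusters(fx$genomeA)[[1]]
    expect_identical(coreGeneIds(cl), coreGeneIds(orig))
    expect_identical(coreType(cl), coreType(orig))
})

test_that("a minus-strand gene stores the reverse complement of its slice", {
    contig <- paste(rep("ACGTTGCA", 10), collapse = "")
    ann <- toyAnnotation(c(c1 = contig),
                         data.frame(contig = "c1", start = 9, end = 24,
                                    strand = "-", gene_id = "g1",
                                    product = "unidentified"))
    slice <- substring(contig, 9, 24)
    expect_identical(
        as.character(geneSequences(ann, "g1")[[1]]),
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(slice))))
})

test_that("malformed inputs raise distinct named errors", {
    dir <- withr::local_tempdir()
    fa <- file.path(dir, "g.fasta")
    writeLines(c(">c1", strrep("ACGT", 30)), fa)
    cls <- file.path(dir, "g.clusters.tsv")
    writeLines(paste("genome_id", "cluster_id", "region_label", "core_type",
                     "gene_ids", sep = "\t"), cls)
    gffLines <- function(...) c("##gff-version 3", ...)
    gff <- file.path(dir, "g.gff3")

    writeLines(gffLines("c1\tx\tgene\t30\t10\t.\t+\t.\tID=bad"), gff)
    expect_error(readGenome(fa, gff, cls), class = "coordinateError")

    writeLines(gffLines("c1\tx\tgene\t0\t10\t.\t+\t.\tID=zero"), gff)
    expect_error(readGenome(fa, gff, cls), class = "coordinateError")

    writeLines(gffLines("c1\tx\tgene\t1\t200\t.\t+\t.\tID=long"), gff)
    expect_error(readGenome(fa, gff, cls), class = "coordinateError")

    writeLines(gffLines("c1\tx\tgene\t1\t12\t.\t+\t.\tID=dup",
                        "c1\tx\tgene\t20\t40\t.\t-\t.\tID=dup"), gff)
    expect_error(readGenome(fa, gff, cls), class = "duplicateGeneError")

    writeLines(gffLines("c1\tx\tgene\t1\t12\t.\t+\t.\tID=g1"), gff)
    writeLines(c(paste("genome_id", "cluster_id", "region_label",
                       "core_type", "gene_ids", sep = "\t"),
                 paste("g", "c1", "Region 1.1", "NR-PKS", "*ghost",
                       sep = "\t")), cls)
    expect_error(readGenome(fa, gff, cls), class = "unknownGeneError")

    expect_error(readGenome(file.path(dir, "absent.fasta"), gff, cls),
                 class = "missingFileError")
})

test_that("writeReport produces deterministic, round-trippable TSVs", {
    dir <- withr::local_tempdir()
    # empty list -> header-only file
    p0 <- file.path(dir, "empty.tsv")
    writeReport(list(), p0)
    expect_length(readLines(p0), 1L)

    # cluster list: one row per cluster with the core_type column, sorted
    cl <- list(
        BGCluster("c2", "g", "Region 2.1", "terpene", "y1", c("y1", "y2")),
        BGCluster("c1", "g", "Region 1.1", "NR-PKS", "x2", c("x1", "x2")))
    p1 <- file.path(dir, "clusters.tsv")
    writeReport(cl, p1)
    back <- readClusterTable(p1)
    expect_identical(back$cluster_id, c("c1", "c2"))
    expect_identical(back$core_type, c("NR-PKS", "terpene"))
    expect_identical(back$gene_ids, c("x1,*x2", "*y1,y2"))

    # data.frame round trip (write then read equals input, sorted)
    df <- data.frame(cluster_id = c("b", "a"), n = c(2L, 1L),
                     stringsAsFactors = FALSE)
    p2 <- file.path(dir, "df.tsv")
    writeReport(df, p2)
    expect_identical(readTsv(p2),
                     df[order(df$cluster_id), , drop = FALSE] |>
                         `rownames<-`(NULL))

    expect_error(writeReport(df, file.path(dir, "no/such/dir/x.tsv")),
                 class = "missingFileError")
})

test_that("count tables round-trip with their library size", {
    dir <- withr::local_tempdir()
    ct <- CountTable(c("g1", "g2"), c(5, 0), librarySize = 1000)
    p <- file.path(dir, "counts.tsv")
    writeCountTable(ct, p)
    back <- readCountTable(p)
    expect_identical(counts(back), counts(ct))
    expect_identical(librarySize(back), 1000)
})

test_that("class validity enforces the documented invariants", {
    expect_error(BGCluster("c", "g", "r", "mystery", "g1", "g1"),
                 "coreType")
    expect_error(BGCluster("c", "g", "r", "NR-PKS", "zz", "g1"),
                 "subset")
    expect_error(CountTable("g1", 10, librarySize = 5), "library size")
    expect_error(CountTable("g1", -1, librarySize = 5), "non-negative")
})
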