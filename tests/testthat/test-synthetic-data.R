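test_that("the same seed yields byte-identical fixture files", {
    cfg <- fixtureConfig(seed = 3, n_shared_clusters = 4,
                         read_scale = 1e5)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeFixture(generateFixture(cfg), d1)
    writeFixture(generateFixture(cfg), d2)
    f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
    expect_identical(f1, f2)
    for (f in f1)
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = f)
})

test_that("fixture structure matches its manifest", {
    fx <- smallFixture()
    man <- fx$manifest
    expect_identical(nrow(man$pairs), 10L)
    expect_length(man$specific_a, 5L)
    expect_length(man$specific_b, 1L)
    expect_identical(man$candidate_a, "phys_c04")
    cand <- getCluster(fx$genomeA, man$candidate_a)
    expect_length(geneIds(cand), 10L)
    # published candidate gene lengths in order
    lens <- GenomicRanges::width(getGenes(fx$genomeA, geneIds(cand)))
    expect_identical(lens, c(3822L, 306L, 2685L, 2139L, 6294L, 2550L,
                             3284L, 2191L, 492L, 1851L))
    # FAS pair: published lengths, divergent head-to-head, configured gap
    fasGenes <- getGenes(fx$genomeA, man$fas_gene_ids_a)
    expect_identical(GenomicRanges::width(fasGenes), c(5619L, 6285L))
    expect_identical(as.character(GenomicRanges::strand(fasGenes)),
                     c("-", "+"))
    gap <- GenomicRanges::start(fasGenes)[2] -
        GenomicRanges::end(fasGenes)[1] - 1L
    expect_identical(gap, 800L)
})

test_that("sharing nothing yields zero reciprocal pairs", {
    fx <- generateFixture(fixtureConfig(seed = 5, n_shared_clusters = 0,
                                        read_scale = 1e5))
    m <- reciprocalBestHit(coreSequences(fx$genomeA),
                           coreSequences(fx$genomeB))
    expect_identical(nrow(m), 0L)
    expect_length(clusters(fx$genomeA), 5L)   # specifics only
    expect_length(clusters(fx$genomeB), 1L)
})

test_that("homolog identity tracks the configured divergence", {
    meanIdent <- function(d, seed) {
        fx <- generateFixture(fixtureConfig(
            seed = seed, n_shared_clusters = 5, shared_core_divergence = d,
            read_scale = 1e6))
        m <- reciprocalBestHit(coreSequences(fx$genomeA),
                               coreSequences(fx$genomeB))
        mean(m$identity)
    }
    for (seed in c(21, 22)) {
        lo <- meanIdent(0.02, seed)
        hi <- meanIdent(0.12, seed)
        expect_gt(lo, hi)                      # monotone in divergence
        expect_lt(abs(lo - 0.98), 0.02)        # ~ 1 - d (binomial error)
        expect_lt(abs(hi - 0.88), 0.03)
    }
})

test_that("simulateReads emits exactly the requested reads per gene", {
    fx <- smallFixture()
    ct <- CountTable("Pfur33-1_006185", 5, librarySize = 5)
    reads <- simulateReads(fx$genomeA, ct, readLength = 100, seed = 42)
    expect_length(reads, 5L)
    gene <- as.character(geneSequences(fx$genomeA, "Pfur33-1_006185")[[1]])
    for (r in as.character(reads)) {
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(r)))
        expect_true(grepl(r, gene, fixed = TRUE) ||
                    grepl(rc, gene, fixed = TRUE))
    }
    # determinism
    reads2 <- simulateReads(fx$genomeA, ct, readLength = 100, seed = 42)
    expect_identical(as.character(reads), as.character(reads2))
    # read length bound
    expect_error(simulateReads(fx$genomeA,
                               CountTable("phys_c04_g02", 1, 1),
                               readLength = 400),
                 class = "readLengthError")
})

test_that("config validation rejects out-of-range values", {
    expect_error(fixtureConfig(shared_core_divergence = 0.6),
                 class = "configError")
    expect_error(fixtureConfig(cluster4_counts_physodic = rep(-1, 10)),
                 class = "configError")
    expect_error(fixtureConfig(cluster4_gene_lengths = c(100, 200)),
                 class = "configError")
})
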