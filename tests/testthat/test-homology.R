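test_that("scorePair matches hand-computable identities and scores", {
    set.seed(1)
    s <- randomSeq(300)
    sp <- scorePair(s, s)
    expect_equal(sp$identity, 1)
    expect_equal(sp$score, 300)
    expect_equal(sp$aligned_length, 300L)

    s100 <- randomSeq(100)
    mut <- substituteN(s100, 3)
    expect_equal(scorePair(s100, mut)$identity, 0.97)

    expect_error(scorePair("", "ACGT"), class = "emptySequenceError")
})

test_that("scorePair agrees with a brute-force DP oracle on random pairs", {
    set.seed(42)
    for (i in 1:25) {
        na <- sample(20:60, 1); nb <- sample(20:60, 1)
        a <- randomSeq(na); b <- randomSeq(nb)
        expect_equal(scorePair(a, b)$score, oracleAlignScore(a, b),
                     label = sprintf("pair %d (%d x %d)", i, na, nb))
    }
    # symmetry
    a <- randomSeq(50); b <- randomSeq(55)
    expect_equal(scorePair(a, b)$score, scorePair(b, a)$score)
})

test_that("RBH equals exhaustive mutual-best enumeration on small sets", {
    set.seed(7)
    for (rep in 1:5) {
        nA <- sample(3:5, 1); nB <- sample(3:5, 1)
        base <- replicate(min(nA, nB), randomSeq(80))
        # homolog pairs at varying divergence, plus unrelated extras
        A <- character(nA); B <- character(nB)
        for (i in seq_len(min(nA, nB))) {
            A[i] <- substituteN(base[i], sample(2:10, 1))
            B[i] <- substituteN(base[i], sample(2:10, 1))
        }
        if (nA > length(base)) A[(length(base) + 1):nA] <-
            replicate(nA - length(base), randomSeq(80))
        if (nB > length(base)) B[(length(base) + 1):nB] <-
            replicate(nB - length(base), randomSeq(80))
        coresA <- Biostrings::DNAStringSet(stats::setNames(A,
            paste0("a", seq_len(nA))))
        coresB <- Biostrings::DNAStringSet(stats::setNames(B,
            paste0("b", seq_len(nB))))
        S <- outer(seq_len(nA), seq_len(nB), Vectorize(function(i, j)
            scorePair(A[i], B[j])$score))
        ident <- outer(seq_len(nA), seq_len(nB), Vectorize(function(i, j)
            scorePair(A[i], B[j])$identity))
        dimnames(S) <- dimnames(ident) <- list(names(coresA),
                                               names(coresB))
        want <- oracleMutualBest(S, ident)
        got <- reciprocalBestHit(coresA, coresB, minIdentity = 0)
        expect_identical(nrow(got), length(want))
        for (p in want)
            expect_true(any(got$cluster_a == p[1] & got$cluster_b == p[2]))
    }
})

test_that("a planted paralog decoy is defeated by reciprocity", {
    set.seed(13)
    core <- randomSeq(120)
    A <- c(a_true = substituteN(core, 3),
           a_decoy = substituteN(core, 20),   # within-genome paralog
           a_other = randomSeq(120))
    B <- c(b_true = substituteN(core, 3),
           b_other1 = randomSeq(120), b_other2 = randomSeq(120))
    got <- reciprocalBestHit(Biostrings::DNAStringSet(A),
                             Biostrings::DNAStringSet(B),
                             minIdentity = 0.7)
    # the decoy's one-way best hit (b_true) is not reciprocal
    expect_identical(got$cluster_a[got$cluster_b == "b_true"], "a_true")
    expect_false("a_decoy" %in% got$cluster_a)
})

test_that("RBH is invariant under swapping the two genomes", {
    fx <- smallFixture()
    ab <- reciprocalBestHit(coreSequences(fx$genomeA),
                            coreSequences(fx$genomeB))
    ba <- reciprocalBestHit(coreSequences(fx$genomeB),
                            coreSequences(fx$genomeA))
    expect_equal(
        ab[order(ab$cluster_a), c("cluster_a", "cluster_b")],
        stats::setNames(ba[order(ba$cluster_b), c("cluster_b", "cluster_a")],
                        c("cluster_a", "cluster_b")),
        ignore_attr = TRUE)
    expect_equal(ab$identity[order(ab$cluster_a)],
                 ba$identity[order(ba$cluster_b)])
})

test_that("score ties break by identity then lexicographic subject id", {
    q <- c(q1 = "ACGTACGTACGTACGTACGT")
    # two identical subjects: pure lexicographic tie-break, deterministic
    subs <- c(s2 = q[[1]], s1 = q[[1]])
    got <- reciprocalBestHit(Biostrings::DNAStringSet(q),
                             Biostrings::DNAStringSet(subs))
    expect_identical(got$cluster_b, "s1")
})

test_that("partition covers every cluster exactly once, with evidence", {
    fx <- smallFixture()
    cmp <- compareChemotypes(fx$genomeA, fx$genomeB,
                             fx$readsA, fx$readsB)
    spec <- specificClusters(cmp)
    idsA <- vapply(clusters(fx$genomeA), clusterId, character(1))
    idsB <- vapply(clusters(fx$genomeB), clusterId, character(1))
    expect_setequal(c(sharedPairs(cmp)$cluster_a, spec$A$cluster_id), idsA)
    expect_setequal(c(sharedPairs(cmp)$cluster_b, spec$B$cluster_id), idsB)
    # planted specifics have zero cross-read evidence
    expect_setequal(spec$A$cluster_id, fx$manifest$specific_a)
    expect_true(all(spec$A$absence_evidence == 0))
    expect_true(all(spec$A$status == "specific"))
})

test_that("cross-reads planted on a specific cluster flag it ambiguous", {
    fx <- generateFixture(fixtureConfig(seed = 9, n_shared_clusters = 5,
                                        read_scale = 1e5,
                                        plant_cross_reads = 4))
    cmp <- compareChemotypes(fx$genomeA, fx$genomeB,
                             fx$readsA, fx$readsB)
    spec <- specificClusters(cmp)
    flagged <- spec$A[spec$A$cluster_id == fx$manifest$cross_read_source, ]
    expect_identical(flagged$status, "ambiguous")
    expect_gt(flagged$absence_evidence, 0)
    others <- spec$A[spec$A$cluster_id != fx$manifest$cross_read_source, ]
    expect_true(all(others$status == "specific"))
})

test_that("synteny table reports gene pairs above the drawing thresholds", {
    fx <- smallFixture()
    # cluster vs itself: one row per gene at identity 100
    self <- syntenyTable(fx$genomeA, fx$genomeA, "phys_c04", "phys_c04")
    diag <- self[self$gene_a == self$gene_b, ]
    expect_identical(nrow(diag), 10L)
    expect_true(all(diag$identity_pct == 100))

    # the candidate pair at 3% divergence: all 10 homologous gene pairs
    cand <- syntenyTable(fx$genomeA, fx$genomeB, "phys_c04", "oliv_c04")
    expect_identical(nrow(cand), 10L)
    expect_true(all(cand$identity_pct >= 90))
    expect_true(all(abs(cand$identity_pct - 97) < 2))
    expect_false(attr(cand, "flipped"))

    # a pair at 15% divergence falls below the 90% threshold entirely
    fx15 <- generateFixture(fixtureConfig(seed = 15, n_shared_clusters = 4,
                                          shared_core_divergence = 0.15,
                                          read_scale = 1e6))
    far <- syntenyTable(fx15$genomeA, fx15$genomeB, "phys_c04", "oliv_c04")
    expect_identical(nrow(far), 0L)
})
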