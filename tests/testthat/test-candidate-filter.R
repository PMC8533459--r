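test_that("the printed NR-PKS inventory yields exactly one candidate", {
    inp <- printedClusterInputs()
    v <- evaluateCandidates(inp$domains, inp$companions, inp$sharedIds,
                            inp$groups)
    expect_identical(nrow(v), 8L)
    expect_identical(v$cluster_id[v$passed], "4")
    # the winner is the two-ACP SAT-KS-AT-ACP-ACP-TE cluster with CytP450
    expect_match(inp$domains[["4"]], "ACP ACP")
    expect_true(v$has_CytP450[v$cluster_id == "4"])

    # cluster 1: cMT in the PKS, no CytP450
    v1 <- v[v$cluster_id == "1", ]
    expect_false(v1$passed)
    expect_false(v1$has_CytP450)
    expect_match(v1$negative_evidence, "has_cMT")

    # clusters 7/8 have two ACPs but no CytP450; OMT recorded as evidence
    for (id in c("7", "8")) {
        vi <- v[v$cluster_id == id, ]
        expect_true(vi$two_ACPs)
        expect_false(vi$has_CytP450)
        expect_match(vi$negative_evidence, "has_OMT_in_cluster")
    }
})

test_that("single-criterion toggles flip exactly that criterion", {
    inp <- printedClusterInputs()
    # remove the CytP450 from the passing cluster
    companions <- inp$companions
    companions[["4"]] <- setdiff(companions[["4"]], "CytP450")
    v <- evaluateCandidates(inp$domains, companions, inp$sharedIds,
                            inp$groups)
    v4 <- v[v$cluster_id == "4", ]
    expect_false(v4$passed)
    expect_false(v4$has_CytP450)
    expect_true(v4$in_both_chemotypes && v4$has_NR_PKS && v4$two_ACPs)

    # drop it from the shared set instead
    v2 <- evaluateCandidates(inp$domains, inp$companions,
                             setdiff(inp$sharedIds, "4"), inp$groups)
    v24 <- v2[v2$cluster_id == "4", ]
    expect_false(v24$passed)
    expect_false(v24$in_both_chemotypes)
    expect_true(v24$has_CytP450 && v24$two_ACPs)
})

test_that("verdicts are a pure function of the inputs (order invariance)", {
    inp <- printedClusterInputs()
    perm <- c("5", "2", "8", "4", "1", "7", "3", "6")
    v1 <- evaluateCandidates(inp$domains, inp$companions, inp$sharedIds,
                             inp$groups)
    v2 <- evaluateCandidates(inp$domains[perm], inp$companions[perm],
                             inp$sharedIds, inp$groups)
    expect_identical(v2$cluster_id, perm)
    expect_equal(v1[order(v1$cluster_id), ], v2[order(v2$cluster_id), ],
                 ignore_attr = TRUE)
})

test_that("an unparsable cluster is skipped with a notice, not an error", {
    expect_message(
        v <- evaluateCandidates(c(ok = "SAT-KS-AT-ACP-ACP-TE",
                                  bad = "no PKS here"),
                                list(ok = "CytP450", bad = character(0)),
                                sharedIds = c("ok", "bad")),
        "skipped")
    expect_identical(v$cluster_id, "ok")
})

test_that("the atranorin rule finds its unique cluster", {
    inp <- printedClusterInputs()
    # cluster 6 as printed lacks the OMT; the rule requires it
    expect_identical(detectAtranorinCluster(inp$domains, inp$companions,
                                            inp$sharedIds, inp$groups),
                     NA_character_)
    # with the full atranorin companion set, it is detected
    companions <- inp$companions
    companions[["6"]] <- c(companions[["6"]], "O-methyltransferase")
    expect_identical(detectAtranorinCluster(inp$domains, companions,
                                            inp$sharedIds, inp$groups),
                     "6")
    # removing the OMT again: none
    companions[["6"]] <- setdiff(companions[["6"]], "O-methyltransferase")
    expect_identical(detectAtranorinCluster(inp$domains, companions,
                                            inp$sharedIds, inp$groups),
                     NA_character_)
    # two qualifying clusters: ambiguity error listing both
    companions[["6"]] <- c(companions[["6"]], "O-methyltransferase")
    domains <- inp$domains
    domains[["1"]] <- "SAT-KS-AT-PT-ACP-cMT-TE"
    companions[["1"]] <- c("CytP450", "OMT", "transporter")
    groups <- inp$groups; groups[["1"]] <- "IX"
    err <- tryCatch(detectAtranorinCluster(domains, companions,
                                           inp$sharedIds, groups),
                    error = identity)
    expect_s3_class(err, "ambiguityError")
    expect_match(conditionMessage(err), "1.*6|6.*1")
})

test_that("fixture atranorin-mirror cluster is detected from the genome", {
    fx <- smallFixture()
    cls <- classifyClusters(fx$genomeA, fx$architecturesA,
                            fx$references, fx$referenceGroups)
    ids <- cls$cluster_id
    companions <- stats::setNames(lapply(ids, function(id) {
        g <- getGenes(fx$genomeA, geneIds(getCluster(fx$genomeA, id)))
        S4Vectors::mcols(g)$product
    }), ids)
    got <- detectAtranorinCluster(stats::setNames(cls$domains, ids),
                                  companions, ids,
                                  stats::setNames(cls$group, ids))
    expect_identical(got, fx$manifest$atranorin_a)
})

test_that("the divergent FAS pair is found with the published lengths", {
    fx <- smallFixture()
    loc <- findDivergentPair(fx$genomeA, fx$hexQueries[[1]],
                             fx$hexQueries[[2]])
    expect_s4_class(loc, "FASLocus")
    expect_identical(orientation(loc), "divergent")
    lens <- GenomicRanges::width(getGenes(fx$genomeA,
                                          c(loc@geneAId, loc@geneBId)))
    expect_identical(lens, c(5619L, 6285L))
    expect_equal(intergenicBp(loc), 800)
    # genome B carries its own pair
    locB <- findDivergentPair(fx$genomeB, fx$hexQueries[[1]],
                              fx$hexQueries[[2]])
    expect_s4_class(locB, "FASLocus")
})

test_that("a tandem pair is reported as such and yields no locus", {
    fx <- generateFixture(fixtureConfig(seed = 23, n_shared_clusters = 0,
                                        fas_orientation = "tandem",
                                        read_scale = 1e6))
    expect_message(
        loc <- findDivergentPair(fx$genomeA, fx$hexQueries[[1]],
                                 fx$hexQueries[[2]]),
        "tandem")
    expect_null(loc)
})

test_that("hits on different contigs yield no locus", {
    set.seed(77)
    gA <- randomSeq(600); gB <- randomSeq(700)
    ann <- toyAnnotation(
        c(c1 = paste0(randomSeq(100), gA, randomSeq(100)),
          c2 = paste0(randomSeq(100), gB, randomSeq(100))),
        data.frame(contig = c("c1", "c2"), start = c(101, 101),
                   end = c(100 + nchar(gA), 100 + nchar(gB)),
                   strand = c("-", "+"), gene_id = c("x", "y"),
                   product = "unidentified"))
    expect_message(
        loc <- findDivergentPair(ann, gA, gB),
        "different contigs")
    expect_null(loc)
})
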