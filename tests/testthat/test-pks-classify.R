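test_that("domain strings parse with mixed separators and derive flags", {
    a1 <- parseDomainString("SAT-KS-AT-ACP-ACP-TE")
    expect_identical(acpCount(a1), 2L)
    expect_false(hasDomain(a1, "cMT"))
    expect_true(hasDomain(a1, "TE"))
    expect_false(hasReducing(a1))

    a2 <- parseDomainString("SAT-KS-AT-PT-ACP-cMT-TE")
    expect_true(hasDomain(a2, "cMT"))
    expect_true(hasDomain(a2, "PT"))

    # the mixed hyphen/space form that occurs in printed tables
    a3 <- parseDomainString("SAT-KS-AT-ACP ACP-TE")
    expect_identical(domainTokens(a3),
                     c("SAT", "KS", "AT", "ACP", "ACP", "TE"))

    err <- tryCatch(parseDomainString("XYZ-KS"), error = identity)
    expect_s3_class(err, "unknownTokenError")
    expect_match(conditionMessage(err), "XYZ")
})

test_that("category: reducing domains beat everything, NR needs KS+AT+ACP", {
    expect_identical(classifyCategory(
        parseDomainString("SAT-KS-AT-ACP-ACP-TE")), "NR-PKS")
    expect_identical(classifyCategory(
        parseDomainString("KS-AT-DH-KR-ACP")), "R-PKS")
    expect_identical(classifyCategory(parseDomainString("ACP")), "other")
    # TD is a releasing domain, not a reducing one
    expect_identical(classifyCategory(
        parseDomainString("SAT-KS-AT-ACP cMT-TD")), "NR-PKS")
})

test_that("kmerDistance matches a set-arithmetic oracle", {
    set.seed(5)
    expect_equal(kmerDistance("ACGTACGTACGT", "ACGTACGTACGT"), 0)
    # no shared 8-mer
    expect_equal(kmerDistance(strrep("A", 20), strrep("C", 20)), 1)
    for (i in 1:10) {
        a <- randomSeq(sample(50:200, 1))
        b <- if (i %% 2) substituteN(a, 5) else randomSeq(nchar(a))
        expect_equal(kmerDistance(a, b), oracleKmerDistance(a, b),
                     label = paste("pair", i))
        expect_equal(kmerDistance(a, b), kmerDistance(b, a))
    }
    expect_error(kmerDistance("ACG", "ACGTACGT"), class = "configError")
})

test_that("group placement by nearest labelled reference", {
    set.seed(8)
    refs <- c(refI = randomSeq(600), refII = randomSeq(600),
              refV = randomSeq(600))
    groups <- c(refI = "I", refII = "II", refV = "V")

    # a reference itself: its own group at distance 0
    self <- assignGroup(refs[["refI"]], refs, groups)
    expect_identical(pksGroup(self), "I")
    expect_equal(self@distance, 0)
    expect_identical(self@nearestReferenceId, "refI")

    # a query mutated 5% from the group-I reference stays in group I
    q <- substituteN(refs[["refI"]], 30)
    expect_identical(pksGroup(assignGroup(q, refs, groups)), "I")

    # far from everything: unknown
    far <- assignGroup(randomSeq(600), refs, groups)
    expect_identical(pksGroup(far), "unknown")

    # duplicating a reference never changes the placement
    refs2 <- c(refs, refI_copy = refs[["refI"]])
    groups2 <- c(groups, refI_copy = "I")
    expect_identical(pksGroup(assignGroup(q, refs2, groups2)), "I")

    # an R-PKS query is never given a named group
    rArch <- parseDomainString("KS-AT-DH-KR-ACP")
    expect_identical(pksGroup(assignGroup(refs[["refI"]], refs, groups,
                                          arch = rArch)), "unknown")
})

test_that("reference distance is monotone in the mutation rate", {
    set.seed(31)
    ref <- randomSeq(800)
    for (i in 1:4) {
        q1 <- substituteN(ref, 16)   # 2%
        q2 <- substituteN(ref, 80)   # 10%
        d1 <- kmerDistance(q1, ref); d2 <- kmerDistance(q2, ref)
        expect_lt(d1, d2)
    }
})

test_that("neighbor joining recovers additive trees", {
    # 3 taxa: the single unrooted topology
    d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
                 dimnames = list(letters[1:3], letters[1:3]))
    t3 <- njTree(d3)
    expect_s3_class(t3, "phylo")
    expect_identical(ape::Ntip(t3), 3L)

    # additive matrices from random trees, 4-6 taxa, recovered exactly
    set.seed(99)
    for (n in 4:6) {
        tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
        D <- ape::cophenetic.phylo(tr)
        got <- njTree(D)
        expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(got)), 0,
                     ignore_attr = TRUE)
        # permuting taxa leaves the unrooted topology unchanged
        perm <- sample(rownames(D))
        got2 <- njTree(D[perm, perm])
        expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(got2)),
                     0, ignore_attr = TRUE)
    }

    expect_error(njTree(matrix(0, 2, 2)), class = "configError")
    bad <- matrix(c(0, 1, 2, 0), 2)
    expect_error(njTree(matrix(c(0, 1, 2, 1, 0, 3, 2.5, 3, 0), 3)),
                 class = "configError")
})

test_that("classifyClusters places the fixture NR-PKSs in planted groups", {
    fx <- smallFixture()
    cls <- classifyClusters(fx$genomeA, fx$architecturesA,
                            fx$references, fx$referenceGroups)
    expect_identical(nrow(cls), 8L)
    planted <- unlist(fx$manifest$groups)
    expect_identical(stats::setNames(cls$group, cls$cluster_id),
                     planted[cls$cluster_id])
    expect_true(all(cls$category == "NR-PKS"))
    # the candidate core is nearest to the group-I reference it derives from
    expect_identical(cls$nearest_reference[cls$cluster_id == "phys_c04"],
                     "PKS16")
})
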