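test_that("RPKM reproduces the published worked examples", {
    # library size calibrated from the gene8 row (raw 936, 2191 bp, 12.35)
    L <- calibrateLibrarySize(data.frame(raw = 936, length_bp = 2191,
                                         printed_rpkm = 12.35))
    expect_lt(abs(L - 34594000) / 34594000, 0.005)
    # gene7 and the FAS alpha subunit under that one library size
    expect_lt(abs(rpkm(1035, L, 3284) - 9.11), 0.005)
    expect_lt(abs(rpkm(3143, L, 5619) - 16.17), 0.005)
    expect_identical(rpkm(0, L, 1234), 0)
})

test_that("one library size fits the whole physodic column", {
    # a single least-squares library size reproduces every nonzero
    # physodic value to within 0.02 (at the precision each value was
    # printed with; one value is printed without decimals)
    ex <- pfurClusterExpression()
    nz <- !is.na(ex$raw_phys) & ex$rpkm_phys > 0
    L <- calibrateLibrarySize(data.frame(raw = ex$raw_phys[nz],
                                         length_bp = ex$length_bp[nz],
                                         printed_rpkm = ex$rpkm_phys[nz]))
    fit <- rpkm(ex$raw_phys[nz], as.numeric(L), ex$length_bp[nz])
    tol <- printedTol(ex$rpkm_phys[nz])
    expect_true(all(abs(fit - ex$rpkm_phys[nz]) <= tol))
})

test_that("calibration is a least-squares fit with residual report", {
    # two mutually inconsistent rows: closed-form weighted mean oracle
    rows <- data.frame(raw = c(100, 100), length_bp = c(1000, 1000),
                       printed_rpkm = c(10, 20))
    L <- calibrateLibrarySize(rows)
    f <- rows$raw * 1e9 / rows$length_bp
    oracle <- 1 / (sum(f * rows$printed_rpkm) / sum(f * f))
    expect_equal(as.numeric(L), oracle)
    res <- attr(L, "residuals")
    expect_identical(nrow(res), 2L)
    expect_equal(res$residual, rows$printed_rpkm - f / as.numeric(L))
    # the same fit through a numeric optimizer, independently
    sse <- function(Lx) sum((rows$printed_rpkm - f / Lx)^2)
    opt <- stats::optimize(sse, c(1e6, 1e8))$minimum
    expect_lt(abs(as.numeric(L) - opt) / opt, 1e-3)

    expect_error(calibrateLibrarySize(
        data.frame(raw = 5, length_bp = 100, printed_rpkm = 0)),
        class = "calibrationError")
})

test_that("RPKM is exactly scale invariant", {
    raw <- c(0, 1, 936, 111226); len <- c(300, 2191, 2191, 6294)
    for (k in c(10, 1000, 1e6)) {
        expect_equal(rpkm(raw, 34594000, len),
                     rpkm(raw * k, 34594000 * k, len),
                     tolerance = 1e-12)
    }
})

test_that("mapping planted reads recovers the manifest counts exactly", {
    fx <- smallFixture()
    ct <- mapAndCount(fx$readsA, fx$genomeA)
    got <- stats::setNames(counts(ct)$raw_count, counts(ct)$gene_id)
    want <- unlist(fx$manifest$scaled_counts_a)
    expect_equal(got[names(want)], want)
    # conservation: gene counts + background + discarded == total reads
    expect_identical(sum(counts(ct)$raw_count) + attr(ct, "background") +
                     attr(ct, "discarded"), as.numeric(length(fx$readsA)))
    expect_identical(librarySize(ct), as.numeric(length(fx$readsA)))
})

test_that("background-only reads count toward the library size only", {
    fx <- smallFixture()
    # reads drawn from intergenic sequence of a FAS-only count table
    bgOnly <- simulateReads(fx$genomeA,
                            CountTable(character(), numeric(), 50),
                            readLength = 100, seed = 3)
    ct <- mapAndCount(bgOnly, fx$genomeA)
    expect_identical(sum(counts(ct)$raw_count), 0)
    expect_identical(librarySize(ct), 50)
    expect_identical(attr(ct, "background"), 50L)

    # empty read set: empty table with library size 0
    ct0 <- mapAndCount(Biostrings::DNAStringSet(), fx$genomeA)
    expect_identical(librarySize(ct0), 0)
})

test_that("a read matching two identical genes is discarded as tied", {
    set.seed(55)
    gene <- randomSeq(400)
    ctgs <- c(c1 = paste0(randomSeq(50), gene, randomSeq(50), gene,
                          randomSeq(50)))
    ann <- toyAnnotation(ctgs, data.frame(
        contig = "c1", start = c(51, 501), end = c(450, 900),
        strand = "+", gene_id = c("twin1", "twin2"),
        product = "unidentified"))
    read <- Biostrings::DNAStringSet(substring(gene, 100, 199))
    names(read) <- "r1"
    ct <- mapAndCount(read, ann)
    expect_identical(sum(counts(ct)$raw_count), 0)
    expect_identical(attr(ct, "discarded"), 1L)
})

test_that("near-exact placement honours the identity threshold", {
    set.seed(56)
    gene <- randomSeq(500)
    ann <- toyAnnotation(
        c(c1 = paste0(randomSeq(60), gene, randomSeq(60))),
        data.frame(contig = "c1", start = 61, end = 560, strand = "+",
                   gene_id = "g1", product = "unidentified"))
    clean <- substring(gene, 201, 300)
    mut3 <- substituteN(clean, 3)    # 97% identity: accepted at 0.95
    mut9 <- substituteN(clean, 9)    # 91% identity: rejected at 0.95
    ct <- mapAndCount(Biostrings::DNAStringSet(c(a = mut3, b = mut9)), ann,
                      minReadIdentity = 0.95)
    expect_identical(sum(counts(ct)$raw_count), 1)
})

test_that("activity ranking reproduces the published top-three sets", {
    ex <- pfurClusterExpression()
    cl <- ex$gene[1:10]
    phys <- data.frame(gene_id = cl,
                       rpkm = ifelse(is.na(ex$rpkm_phys[1:10]), 0,
                                     ex$rpkm_phys[1:10]))
    rp <- rankActivity(cl, phys)
    expect_identical(rp$gene_id[1:3], c("gene5", "gene6", "gene4"))
    # the three active genes are the NR-PKS, the CytP450 and gene6
    expect_identical(sort(rp$gene_id[rp$active]),
                     c("gene4", "gene5", "gene6"))

    oliv <- data.frame(gene_id = cl,
                       rpkm = ifelse(is.na(ex$rpkm_oliv[1:10]), 0,
                                     ex$rpkm_oliv[1:10]))
    ro <- rankActivity(cl, oliv)
    expect_identical(ro$gene_id[1:3], c("gene6", "gene4", "gene5"))

    # all-zero cluster: no active genes, ties ranked by gene id
    z <- rankActivity(c("b", "a"), data.frame(gene_id = character(),
                                              rpkm = numeric()))
    expect_identical(z$gene_id, c("a", "b"))
    expect_false(any(z$active))
})
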