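## End-to-end orchestration: simulate (or load) -> compare -> classify ->
## filter -> quantify -> scheme -> report, as one reproducible run.

#' RunConfig: configuration of a full pipeline run
#'
#' Holds either a fixture seed (the two genomes are generated) or a
#' fixture directory (a [writeFixture] layout is loaded), plus every
#' threshold of the downstream stages. Round-trips through YAML via
#' [readRunConfig]/[writeRunConfig].
#'
#' @slot fixtureSeed seed for the generated fixture (ignored when
#'   \code{inputDir} is set).
#' @slot inputDir optional fixture directory (\code{NA} = generate).
#' @slot outDir output directory for the stage TSVs and summary.
#' @slot minIdentity RBH identity acceptance threshold in \[0, 1\].
#' @slot minReadIdentity read placement identity threshold in (0, 1\].
#' @slot activityFactor multiple of the cluster-median RPKM for the
#'   active flag.
#' @slot fasMaxIntergenic adjacency bound (bp) for the FAS pair.
#' @slot groupMaxDistance k-mer distance threshold for group placement.
#' @slot readLength simulated read length (generated fixtures).
#' @slot nSharedClusters number of shared cluster pairs of a generated
#'   fixture (default 51, the published complement).
#' @exportClass RunConfig
setClass("RunConfig",
    representation(fixtureSeed = "integer", inputDir = "character",
                   outDir = "character", minIdentity = "numeric",
                   minReadIdentity = "numeric", activityFactor = "numeric",
                   fasMaxIntergenic = "numeric",
                   groupMaxDistance = "numeric", readLength = "integer",
                   nSharedClusters = "integer"))

setValidity("RunConfig", function(object) {
    msg <- character(0)
    if (object@minIdentity < 0 || object@minIdentity > 1)
        msg <- c(msg, "minIdentity must lie in [0, 1]")
    if (object@minReadIdentity <= 0 || object@minReadIdentity > 1)
        msg <- c(msg, "minReadIdentity must lie in (0, 1]")
    if (object@groupMaxDistance < 0 || object@groupMaxDistance > 1)
        msg <- c(msg, "groupMaxDistance must lie in [0, 1]")
    if (object@activityFactor <= 0)
        msg <- c(msg, "activityFactor must be positive")
    if (object@fasMaxIntergenic < 0)
        msg <- c(msg, "fasMaxIntergenic must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#'
#' @param fixtureSeed fixture seed (default 7).
#' @param outDir output directory.
#' @param inputDir optional fixture directory to load instead of
#'   generating.
#' @param minIdentity,minReadIdentity,activityFactor,fasMaxIntergenic,groupMaxDistance,readLength
#'   stage thresholds; see [RunConfig-class] for meanings and ranges.
#' @param nSharedClusters shared-cluster count of a generated fixture.
#' @return a validated [RunConfig-class].
#' @export
runConfig <- function(fixtureSeed = 7L, outDir = tempfile("lichenBGC_run"),
                      inputDir = NA_character_, minIdentity = 0.7,
                      minReadIdentity = 0.95, activityFactor = 10,
                      fasMaxIntergenic = 5000, groupMaxDistance = 0.6,
                      readLength = 150L, nSharedClusters = 51L) {
    new("RunConfig", fixtureSeed = as.integer(fixtureSeed),
        inputDir = as.character(inputDir), outDir = as.character(outDir),
        minIdentity = minIdentity, minReadIdentity = minReadIdentity,
        activityFactor = activityFactor,
        fasMaxIntergenic = fasMaxIntergenic,
        groupMaxDistance = groupMaxDistance,
        readLength = as.integer(readLength),
        nSharedClusters = as.integer(nSharedClusters))
}

#' Read / write a RunConfig as YAML
#'
#' @param path YAML file path.
#' @return \code{readRunConfig}: a [RunConfig-class].
#' @export
readRunConfig <- function(path) {
    checkFile(path)
    vals <- yaml::read_yaml(path)
    do.call(runConfig, vals)
}

#' @rdname readRunConfig
#' @param config a [RunConfig-class].
#' @return \code{writeRunConfig}: the path, invisibly.
#' @export
writeRunConfig <- function(config, path) {
    vals <- list(fixtureSeed = config@fixtureSeed,
                 outDir = config@outDir,
                 inputDir = config@inputDir,
                 minIdentity = config@minIdentity,
                 minReadIdentity = config@minReadIdentity,
                 activityFactor = config@activityFactor,
                 fasMaxIntergenic = config@fasMaxIntergenic,
                 groupMaxDistance = config@groupMaxDistance,
                 readLength = config@readLength,
                 nSharedClusters = config@nSharedClusters)
    yaml::write_yaml(vals, path)
    invisible(path)
}

stage <- function(name, expr) {
    message(sprintf("[%s] ...", name))
    tryCatch(expr, lichenBGC_error = function(e) stop(e),
             error = function(e)
        lbgcError("stageError",
                  sprintf("stage '%s' failed: %s", name,
                          conditionMessage(e)),
                  stage = name))
}

#' Run the full chemotype-comparison pipeline
#'
#' Executes simulate/load, cross-genome comparison (RBH + partition with
#' read evidence), PKS classification, the candidate filter, the
#' atranorin rule, the FAS-pair search, read quantification with activity
#' ranking, and the biosynthesis scheme; writes \code{pairs.tsv},
#' \code{specific.tsv}, \code{classifications.tsv}, \code{verdicts.tsv},
#' \code{synteny.tsv} (the candidate cluster pair), \code{expression.tsv},
#' \code{scheme.json} and \code{summary.json} under \code{outDir}.
#'
#' @param config a [RunConfig-class] (or the default).
#' @return the summary list, invisibly; its counts are all recomputable
#'   from the stage TSVs.
#' @export
runPipeline <- function(config = runConfig()) {
    validObject(config)
    dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)

    fx <- stage("inputs", {
        if (!is.na(config@inputDir)) readFixture(config@inputDir)
        else generateFixture(fixtureConfig(
            seed = config@fixtureSeed, read_length = config@readLength,
            n_shared_clusters = config@nSharedClusters))
    })

    cmp <- stage("compare", {
        matches <- reciprocalBestHit(coreSequences(fx$genomeA),
                                     coreSequences(fx$genomeB),
                                     minIdentity = config@minIdentity)
        partitionChemotypes(fx$genomeA, fx$genomeB, matches,
                            fx$readsA, fx$readsB,
                            minReadIdentity = config@minReadIdentity)
    })
    writeTsv(sharedPairs(cmp), file.path(config@outDir, "pairs.tsv"))
    spec <- specificClusters(cmp)
    specDf <- rbind(
        if (nrow(spec$A)) cbind(genome = genomeId(fx$genomeA), spec$A),
        if (nrow(spec$B)) cbind(genome = genomeId(fx$genomeB), spec$B))
    if (is.null(specDf))
        specDf <- data.frame(genome = character(), cluster_id = character(),
                             absence_evidence = numeric(),
                             status = character())
    writeTsv(specDf, file.path(config@outDir, "specific.tsv"))
    message(sprintf("[compare] %d shared, %d + %d specific",
                    nrow(sharedPairs(cmp)), nrow(spec$A), nrow(spec$B)))

    cls <- stage("classify", {
        classifyClusters(fx$genomeA, fx$architecturesA, fx$references,
                         fx$referenceGroups,
                         maxDistance = config@groupMaxDistance)
    })
    writeTsv(cls, file.path(config@outDir, "classifications.tsv"))

    verdicts <- stage("filter", {
        evaluateGenomeCandidates(fx$genomeA, cls, cmp, side = "A")
    })
    writeTsv(verdicts, file.path(config@outDir, "verdicts.tsv"))
    candidate <- verdicts$cluster_id[verdicts$passed]

    atr <- stage("atranorin", {
        ids <- cls$cluster_id
        companions <- stats::setNames(lapply(ids, function(id) {
            g <- getGenes(fx$genomeA, geneIds(getCluster(fx$genomeA, id)))
            S4Vectors::mcols(g)$product
        }), ids)
        detectAtranorinCluster(stats::setNames(cls$domains, ids),
                               companions, sharedPairs(cmp)$cluster_a,
                               stats::setNames(cls$group, ids))
    })

    fas <- stage("fas", {
        list(A = findDivergentPair(fx$genomeA, fx$hexQueries[[1L]],
                                   fx$hexQueries[[2L]],
                                   minIdentity = config@minIdentity,
                                   maxIntergenic = config@fasMaxIntergenic),
             B = findDivergentPair(fx$genomeB, fx$hexQueries[[1L]],
                                   fx$hexQueries[[2L]],
                                   minIdentity = config@minIdentity,
                                   maxIntergenic = config@fasMaxIntergenic))
    })

    synteny <- stage("synteny", {
        if (length(candidate) == 1L) {
            pairRow <- sharedPairs(cmp)[
                sharedPairs(cmp)$cluster_a == candidate, ]
            syntenyTable(fx$genomeA, fx$genomeB, candidate,
                         pairRow$cluster_b[1L])
        } else data.frame(gene_a = character(), gene_b = character(),
                          identity_pct = numeric(),
                          aligned_length = integer())
    })
    writeTsv(synteny, file.path(config@outDir, "synteny.tsv"), sort = FALSE)

    expr <- stage("quantify", {
        ctA <- mapAndCount(fx$readsA, fx$genomeA,
                           minReadIdentity = config@minReadIdentity)
        ctB <- mapAndCount(fx$readsB, fx$genomeB,
                           minReadIdentity = config@minReadIdentity)
        exA <- expressionTable(ctA, fx$genomeA)
        exB <- expressionTable(ctB, fx$genomeB)
        rbind(cbind(genome = genomeId(fx$genomeA), exA),
              cbind(genome = genomeId(fx$genomeB), exB))
    })
    writeTsv(expr, file.path(config@outDir, "expression.tsv"))

    activity <- stage("activity", {
        if (length(candidate) == 1L) {
            exA <- expr[expr$genome == genomeId(fx$genomeA), ]
            rankActivity(getCluster(fx$genomeA, candidate), exA,
                         activityFactor = config@activityFactor)
        } else NULL
    })

    schemeOut <- stage("scheme", {
        oliv <- assembleDepside(buildRing(6, 4), buildRing(6, 3))
        list(olivetoric_acid = compoundToList(oliv),
             physodic_acid = compoundToList(depsidonize(oliv)),
             lecanoric_acid = compoundToList(
                 assembleDepside(buildRing(2, 3), buildRing(2, 3))))
    })
    jsonlite::write_json(schemeOut,
                         file.path(config@outDir, "scheme.json"),
                         pretty = TRUE, auto_unbox = TRUE, digits = NA)

    nrpksShared <- sum(cls$category == "NR-PKS" &
                       cls$cluster_id %in% sharedPairs(cmp)$cluster_a)
    summary <- list(
        shared = nrow(sharedPairs(cmp)),
        specific_a = nrow(spec$A), specific_b = nrow(spec$B),
        ambiguous_a = sum(spec$A$status == "ambiguous"),
        ambiguous_b = sum(spec$B$status == "ambiguous"),
        nrpks_shared = nrpksShared,
        candidates = length(candidate),
        candidate_id = if (length(candidate) == 1L) candidate
                       else NA_character_,
        candidate_gene_count = if (length(candidate) == 1L)
            length(geneIds(getCluster(fx$genomeA, candidate)))
            else 0L,
        atranorin_id = atr,
        fas_locus_a = !is.null(fas$A), fas_locus_b = !is.null(fas$B),
        top_active_genes = if (!is.null(activity))
            activity$gene_id[seq_len(min(3L, nrow(activity)))]
            else character(0))
    jsonlite::write_json(summary,
                         file.path(config@outDir, "summary.json"),
                         pretty = TRUE, auto_unbox = TRUE, digits = NA)
    message(sprintf("[done] summary written to %s", config@outDir))
    invisible(summary)
}
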