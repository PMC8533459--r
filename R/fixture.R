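## Synthetic two-genome fixture generator. The defaults mirror the
## published cluster inventory of the two Pseudevernia furfuracea
## chemotypes: 51 shared clusters (8 of them NR-PKS clusters with the
## published domain strings and companion genes), 5 physodic-only and
## 1 olivetoric-only cluster, the ten-gene candidate cluster with the
## published gene lengths and read counts, and one adjacent divergently
## transcribed HexA/HexB FAS pair per genome. Chemotype-specific clusters
## carry decoy paralog cores (diverged copies of shared cores of the same
## genome) so that reciprocal best-hit matching is exercised against
## paralogy, exactly the failure mode reciprocity exists to defeat.

## evaluate expr with a locally seeded RNG, restoring the caller's state
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

## the shared-cluster core-type template at full (published) size
sharedTypeTemplate <- function(n) {
    template <- c(rep("NR-PKS", 8L), rep("R-PKS", 14L), "T3-PKS",
                  rep("hybrid", 7L), rep("NRPS", 7L),
                  rep("NRPS-like", 7L), rep("terpene", 5L),
                  rep("indole", 2L))
    if (n <= length(template)) template[seq_len(n)]
    else c(template, rep("R-PKS", n - length(template)))
}

## published regions / reference wiring of the eight shared NR-PKS
## clusters (cluster 6 companions include the O-methyltransferase and
## transporter of the atranorin-type cluster composition)
nrpksFixtureSpec <- function() {
    tab <- pfurNRPKSClusters()
    tab$region <- c("Region 12.3", "Region 18.1", "Region 44.1",
                    "Region 33.1", "Region 2.2", "Region 9.3",
                    "Region 3.1", "Region 69.1")
    tab$reference <- c("PKS_VII", "PKS20", "PKS15", "PKS16", "PKS27",
                       "PKS23", "PKS13", "PKS14")
    tab$companions[6L] <- paste(
        "alkyl hydroperoxide reductase/Thiol specific,PKS,CytP450",
        "O-methyltransferase,drug resistance transporter", sep = ",")
    tab
}

#' Configuration of the synthetic two-genome fixture
#'
#' All defaults reproduce the published study conditions; they are the
#' fixture, not tuning knobs. Library sizes default to the values
#' calibrated from the published RPKM table ([calibrateLibrarySize]):
#' the physodic size from the single gene8 row, the olivetoric size as
#' the least-squares fit over all its nonzero rows.
#'
#' @param seed RNG seed for the whole fixture.
#' @param n_shared_clusters number of homologous cluster pairs
#'   (default 51).
#' @param specific_physodic,specific_olivetoric core types of the
#'   chemotype-specific clusters (defaults: the published 5 and 1).
#' @param shared_core_divergence substitution rate between homologous
#'   gene copies of the two genomes (default 0.03).
#' @param decoy_paralog_divergence substitution rate of the within-genome
#'   decoy paralog cores planted in specific clusters (default 0.15).
#' @param reference_divergence substitution rate between an NR-PKS core
#'   and its labelled group reference (default 0.05).
#' @param core_gene_length_bp length of generic core genes (default
#'   3000).
#' @param cluster4_gene_lengths the candidate cluster's ten gene lengths
#'   (defaults: the published values).
#' @param cluster4_counts_physodic,cluster4_counts_olivetoric raw read
#'   counts of the candidate cluster's genes (defaults: the published
#'   values; genes reported without hits are 0).
#' @param fas_counts_physodic,fas_counts_olivetoric raw counts of the
#'   HexA/HexB genes.
#' @param fas_lengths HexA and HexB gene lengths (default 5619, 6285).
#' @param fas_intergenic_bp intergenic distance of the divergent FAS
#'   pair (default 800).
#' @param fas_orientation \code{"divergent"} (default),
#'   \code{"convergent"} or \code{"tandem"} - variants exercise the
#'   orientation rule.
#' @param library_sizes named pair \code{c(physodic=, olivetoric=)} of
#'   total sample reads; \code{NULL} (default) uses the calibrated
#'   values.
#' @param read_length simulated read length in bp (default 150).
#' @param read_scale the simulated libraries are the full-scale count
#'   tables divided by this factor (default 1000); RPKM is scale
#'   invariant so the desk-scale libraries preserve all normalized
#'   values.
#' @param indel_rate per-position indel rate between homologs
#'   (default 0; substitution-only divergence keeps identity arithmetic
#'   exact).
#' @param plant_cross_reads number of reads copied from the first
#'   physodic-specific cluster core into the olivetoric read set
#'   (default 0; nonzero plants contrary absence evidence).
#' @return a validated list of class \code{"FixtureConfig"}.
#' @export
fixtureConfig <- function(seed = 7L,
                          n_shared_clusters = 51L,
                          specific_physodic = c("R-PKS", "R-PKS", "hybrid",
                                                "R-PKS", "terpene"),
                          specific_olivetoric = "terpene",
                          shared_core_divergence = 0.03,
                          decoy_paralog_divergence = 0.15,
                          reference_divergence = 0.05,
                          core_gene_length_bp = 3000L,
                          cluster4_gene_lengths = c(3822L, 306L, 2685L,
                                                    2139L, 6294L, 2550L,
                                                    3284L, 2191L, 492L,
                                                    1851L),
                          cluster4_counts_physodic = c(38, 0, 0, 8677,
                                                       111226, 13690,
                                                       1035, 936, 0, 46),
                          cluster4_counts_olivetoric = c(0, 1, 19, 1222,
                                                         1265, 6304, 118,
                                                         205, 12, 19),
                          fas_counts_physodic = c(3143, 1971),
                          fas_counts_olivetoric = c(944, 911),
                          fas_lengths = c(5619L, 6285L),
                          fas_intergenic_bp = 800L,
                          fas_orientation = c("divergent", "convergent",
                                              "tandem"),
                          library_sizes = NULL,
                          read_length = 150L,
                          read_scale = 1000,
                          indel_rate = 0,
                          plant_cross_reads = 0L) {
    fas_orientation <- match.arg(fas_orientation)
    rates <- c(shared_core_divergence, decoy_paralog_divergence,
               reference_divergence, indel_rate)
    if (any(rates < 0) || any(rates >= 0.5))
        lbgcError("configError", "divergence rates must lie in [0, 0.5)")
    if (any(c(cluster4_counts_physodic, cluster4_counts_olivetoric,
              fas_counts_physodic, fas_counts_olivetoric) < 0))
        lbgcError("configError", "read counts must be non-negative")
    if (any(c(core_gene_length_bp, cluster4_gene_lengths, fas_lengths,
              read_length) <= 0))
        lbgcError("configError", "lengths must be positive")
    if (length(cluster4_gene_lengths) != 10L)
        lbgcError("configError", "the candidate cluster has ten genes")
    if (is.null(library_sizes)) {
        ex <- pfurClusterExpression()
        phys <- calibrateLibrarySize(data.frame(
            raw = 936, length_bp = 2191, printed_rpkm = 12.35))
        oliv <- calibrateLibrarySize(data.frame(
            raw = ex$raw_oliv, length_bp = ex$length_bp,
            printed_rpkm = ex$rpkm_oliv))
        library_sizes <- c(physodic = round(as.numeric(phys)),
                           olivetoric = round(as.numeric(oliv)))
    }
    cfg <- list(seed = as.integer(seed),
                n_shared_clusters = as.integer(n_shared_clusters),
                specific_physodic = specific_physodic,
                specific_olivetoric = specific_olivetoric,
                shared_core_divergence = shared_core_divergence,
                decoy_paralog_divergence = decoy_paralog_divergence,
                reference_divergence = reference_divergence,
                core_gene_length_bp = as.integer(core_gene_length_bp),
                cluster4_gene_lengths = as.integer(cluster4_gene_lengths),
                cluster4_counts_physodic = cluster4_counts_physodic,
                cluster4_counts_olivetoric = cluster4_counts_olivetoric,
                fas_counts_physodic = fas_counts_physodic,
                fas_counts_olivetoric = fas_counts_olivetoric,
                fas_lengths = as.integer(fas_lengths),
                fas_intergenic_bp = as.integer(fas_intergenic_bp),
                fas_orientation = fas_orientation,
                library_sizes = library_sizes,
                read_length = as.integer(read_length),
                read_scale = read_scale,
                indel_rate = indel_rate,
                plant_cross_reads = as.integer(plant_cross_reads))
    class(cfg) <- "FixtureConfig"
    cfg
}

## one gene blueprint
bpGene <- function(id, product, length, strand, seq) {
    list(id = id, product = product, length = length,
         strand = strand, seq = seq)
}

## mutate a blueprint gene list into the homologous genome-B copy
mutateGenes <- function(genesA, rate, indelRate, renameTo = NULL) {
    lapply(seq_along(genesA), function(i) {
        g <- genesA[[i]]
        s <- mutateSequence(g$seq, rate)
        if (indelRate > 0) s <- applyIndels(s, indelRate)
        id <- if (is.null(renameTo)) g$id else renameTo[i]
        bpGene(id, g$product, nchar(s), g$strand, s)
    })
}

applyIndels <- function(x, rate) {
    bases <- strsplit(x, "", fixed = TRUE)[[1L]]
    keep <- stats::runif(length(bases)) >= rate / 2
    bases <- bases[keep]
    ins <- which(stats::runif(length(bases)) < rate / 2)
    if (length(ins)) {
        newb <- sample(DNA_BASES4, length(ins), replace = TRUE)
        out <- character(0)
        prev <- 0L
        for (k in seq_along(ins)) {
            out <- c(out, bases[(prev + 1L):ins[k]], newb[k])
            prev <- ins[k]
        }
        if (prev < length(bases)) out <- c(out, bases[(prev + 1L):length(bases)])
        bases <- out
    }
    paste(bases, collapse = "")
}

## assemble cluster blueprints + standalone genes into a GenomeAnnotation
assembleGenome <- function(genomeId, prefix, clusterBps, fasGenes,
                           flank = 400L, intergenic = 300L) {
    contigSeqs <- character(0)
    granges <- list()
    addContig <- function(name, genesBp, spacing = intergenic) {
        pos <- flank
        rows <- list()
        parts <- randomDnaString(flank)
        for (g in genesBp) {
            placed <- if (g$strand == "-") revcompChar(g$seq) else g$seq
            rows[[length(rows) + 1L]] <- data.frame(
                contig = name, start = pos + 1L,
                end = pos + g$length, strand = g$strand,
                gene_id = g$id, product = g$product, seq = g$seq,
                stringsAsFactors = FALSE)
            parts <- paste0(parts, placed, randomDnaString(spacing))
            pos <- pos + g$length + spacing
        }
        parts <- paste0(parts, randomDnaString(flank))
        contigSeqs[[name]] <<- parts
        granges[[length(granges) + 1L]] <<- do.call(rbind, rows)
    }
    for (cb in clusterBps) addContig(cb$contig, cb$genes)
    addContig(paste0(prefix, "_tigFAS"), fasGenes$genes,
              spacing = fasGenes$intergenic)
    df <- do.call(rbind, granges)
    gr <- GenomicRanges::GRanges(df$contig,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    S4Vectors::mcols(gr)$gene_id <- df$gene_id
    S4Vectors::mcols(gr)$product <- df$product
    S4Vectors::mcols(gr)$sequence <- Biostrings::DNAStringSet(df$seq)
    clusters <- lapply(clusterBps, function(cb) {
        BGCluster(cb$cluster_id, genomeId, cb$region, cb$core_type,
                  cb$core_id, vapply(cb$genes, `[[`, character(1L), "id"))
    })
    GenomeAnnotation(genomeId,
                     Biostrings::DNAStringSet(unlist(contigSeqs)),
                     gr, clusters)
}

## FAS gene pair blueprint honoring the configured orientation
fasBlueprint <- function(ids, lengths, orientation, intergenic) {
    strands <- switch(orientation,
                      divergent = c("-", "+"),
                      convergent = c("+", "-"),
                      tandem = c("+", "+"))
    genes <- list(
        bpGene(ids[1L], "FAS-A", lengths[1L], strands[1L],
               randomDnaString(lengths[1L])),
        bpGene(ids[2L], "FAS-B", lengths[2L], strands[2L],
               randomDnaString(lengths[2L])))
    list(genes = genes, intergenic = intergenic)
}

#' Generate the paper-mirror two-genome fixture
#'
#' Builds two annotated genomes (physodic-mirror "A" and
#' olivetoric-mirror "B"), their full-scale count tables, desk-scale
#' simulated read sets, the labelled PKS reference set, HexA/HexB query
#' sequences, and a manifest of every planted truth (homolog pairs,
#' specific clusters, candidate and atranorin cluster ids, FAS loci,
#' scaled counts), so downstream tests read expectations from the
#' manifest rather than from constants.
#'
#' @param config a [fixtureConfig] (default configuration when omitted).
#' @return a list with elements \code{genomeA}, \code{genomeB}
#'   ([GenomeAnnotation-class]), \code{countsA}, \code{countsB}
#'   ([CountTable-class], full scale), \code{readsA}, \code{readsB}
#'   (\code{DNAStringSet}, desk scale), \code{references}
#'   (\code{DNAStringSet}), \code{referenceGroups} (named character),
#'   \code{hexQueries} (\code{DNAStringSet} of 2), \code{config} and
#'   \code{manifest} (list).
#' @export
generateFixture <- function(config = fixtureConfig()) {
    stopifnot(inherits(config, "FixtureConfig"))
    withSeed(config$seed, generateFixtureImpl(config))
}

generateFixtureImpl <- function(config) {
    nShared <- config$n_shared_clusters
    types <- sharedTypeTemplate(nShared)
    nrSpec <- nrpksFixtureSpec()
    nNR <- sum(types == "NR-PKS")

    ## labelled references (PKS16 at the candidate core's length)
    refLens <- c(PKS16 = config$cluster4_gene_lengths[5L], PKS27 = 3000L,
                 PKS15 = 3000L, PKS13 = 3000L, PKS14 = 3000L,
                 PKS20 = 3000L, PKS23 = 3000L, PKS_VII = 3000L)
    refSeqs <- vapply(refLens, randomDnaString, character(1L))
    refGroups <- c(PKS16 = "I", PKS27 = "I", PKS15 = "II", PKS13 = "II",
                   PKS14 = "II", PKS20 = "V", PKS23 = "IX",
                   PKS_VII = "VII")

    companionLen <- function() sample(900:1500, 1L)

    ## --- genome A shared clusters -------------------------------------
    clustersA <- vector("list", nShared)
    archA <- character(0)
    for (i in seq_len(nShared)) {
        type <- types[i]
        cid <- sprintf("phys_c%02d", i)
        contig <- sprintf("phys_tig%02d", i)
        if (type == "NR-PKS" && i <= nrow(nrSpec)) {
            spec <- nrSpec[i, ]
            coreSeq <- mutateSequence(refSeqs[[spec$reference]],
                                      config$reference_divergence)
            if (i == 4L) {
                lens <- config$cluster4_gene_lengths
                prods <- c("unidentified", "unidentified", "unidentified",
                           "CytP450", "NR-PKS", "unidentified",
                           "unidentified", "unidentified", "unidentified",
                           "monooxygenase")
                strands <- c("+", "-", "+", "-", "+", "+", "-", "+",
                             "-", "+")
                genes <- lapply(1:10, function(j) {
                    id <- if (j == 5L) spec$pks_id
                          else sprintf("%s_g%02d", cid, j)
                    seq <- if (j == 5L) coreSeq
                           else randomDnaString(lens[j])
                    bpGene(id, prods[j], lens[j], strands[j], seq)
                })
                coreId <- spec$pks_id
            } else {
                comp <- strsplit(spec$companions, ",", fixed = TRUE)[[1L]]
                comp <- comp[!grepl("NR-?PKS|^PKS$", comp)]
                nComp <- spec$total_genes - 1L
                prods <- c(comp, rep("unidentified",
                                     max(0L, nComp - length(comp))))[
                                         seq_len(nComp)]
                coreAt <- min(3L, nComp + 1L)
                genes <- list()
                j <- 1L
                for (slot in seq_len(nComp + 1L)) {
                    if (slot == coreAt) {
                        genes[[slot]] <- bpGene(spec$pks_id, "NR-PKS",
                                                nchar(coreSeq), "+",
                                                coreSeq)
                    } else {
                        len <- companionLen()
                        genes[[slot]] <- bpGene(
                            sprintf("%s_g%02d", cid, j), prods[j], len,
                            sample(c("+", "-"), 1L), randomDnaString(len))
                        j <- j + 1L
                    }
                }
                ## cluster 5 mirror: R-PKS companion immediately upstream
                ## of the core, transcribed head-to-head
                if (i == 5L) {
                    rp <- which(normalizeProductLabel(
                        vapply(genes, `[[`, character(1L),
                               "product")) == "R-PKS")[1L]
                    if (!is.na(rp)) {
                        g <- genes[[rp]]; g$strand <- "-"
                        genes <- append(genes[-rp], list(g), coreAt - 1L -
                                        (rp < coreAt))
                    }
                }
                coreId <- spec$pks_id
            }
            archA[cid] <- spec$domains
            clustersA[[i]] <- list(cluster_id = cid, contig = contig,
                                   region = spec$region, core_type = type,
                                   core_id = coreId, genes = genes)
        } else {
            len1 <- companionLen(); len3 <- companionLen()
            coreId <- sprintf("%s_core", cid)
            genes <- list(
                bpGene(sprintf("%s_g01", cid), "unidentified", len1,
                       sample(c("+", "-"), 1L), randomDnaString(len1)),
                bpGene(coreId, type, config$core_gene_length_bp,
                       sample(c("+", "-"), 1L),
                       randomDnaString(config$core_gene_length_bp)),
                bpGene(sprintf("%s_g03", cid), "unidentified", len3,
                       sample(c("+", "-"), 1L), randomDnaString(len3)))
            clustersA[[i]] <- list(cluster_id = cid, contig = contig,
                                   region = sprintf("Region %d.1", i),
                                   core_type = type, core_id = coreId,
                                   genes = genes)
        }
    }

    ## --- genome B homologs --------------------------------------------
    clustersB <- lapply(clustersA, function(cb) {
        cid <- sub("^phys_", "oliv_", cb$cluster_id)
        rename <- vapply(cb$genes, function(g) {
            if (startsWith(g$id, "phys_")) sub("^phys_", "oliv_", g$id)
            else g$id
        }, character(1L))
        genes <- mutateGenes(cb$genes, config$shared_core_divergence,
                             config$indel_rate, rename)
        coreId <- if (startsWith(cb$core_id, "phys_"))
            sub("^phys_", "oliv_", cb$core_id) else cb$core_id
        list(cluster_id = cid,
             contig = sub("^phys_", "oliv_", cb$contig),
             region = cb$region, core_type = cb$core_type,
             core_id = coreId, genes = genes)
    })
    archB <- stats::setNames(archA, sub("^phys_", "oliv_", names(archA)))

    ## --- chemotype-specific clusters with decoy paralog cores ----------
    specificRegionsA <- c("Region 7.2", "Region 25.1", "Region 60.2",
                          "Region 65.1", "Region 27.1")
    specificRegionsB <- "Region 10.1"
    makeSpecific <- function(clustersOwn, typesSpec, prefix, startIdx,
                             regions, divergence) {
        out <- list()
        usedDonor <- character(0)
        for (k in seq_along(typesSpec)) {
            type <- typesSpec[k]
            idx <- startIdx + k - 1L
            cid <- sprintf("%s_c%02d", prefix, idx)
            donors <- Filter(function(cb) cb$core_type == type &&
                             !cb$cluster_id %in% usedDonor, clustersOwn)
            coreSeq <- if (length(donors)) {
                usedDonor <- c(usedDonor, donors[[1L]]$cluster_id)
                donorCore <- Filter(function(g)
                    g$id == donors[[1L]]$core_id, donors[[1L]]$genes)[[1L]]
                mutateSequence(donorCore$seq, divergence)
            } else randomDnaString(config$core_gene_length_bp)
            coreId <- sprintf("%s_core", cid)
            len1 <- companionLen(); len3 <- companionLen()
            genes <- list(
                bpGene(sprintf("%s_g01", cid), "unidentified", len1,
                       sample(c("+", "-"), 1L), randomDnaString(len1)),
                bpGene(coreId, type, nchar(coreSeq),
                       sample(c("+", "-"), 1L), coreSeq),
                bpGene(sprintf("%s_g03", cid), "unidentified", len3,
                       sample(c("+", "-"), 1L), randomDnaString(len3)))
            out[[k]] <- list(cluster_id = cid,
                             contig = sprintf("%s_tig%02d", prefix, idx),
                             region = regions[min(k, length(regions))],
                             core_type = type, core_id = coreId,
                             genes = genes)
        }
        out
    }
    specA <- makeSpecific(clustersA, config$specific_physodic, "phys",
                          nShared + 1L, specificRegionsA,
                          config$decoy_paralog_divergence)
    specB <- makeSpecific(clustersB, config$specific_olivetoric, "oliv",
                          nShared + length(specA) + 1L, specificRegionsB,
                          config$decoy_paralog_divergence)

    ## --- FAS loci -------------------------------------------------------
    fasA <- fasBlueprint(c("FUN_004275", "FUN_004276"), config$fas_lengths,
                         config$fas_orientation, config$fas_intergenic_bp)
    fasB <- list(genes = mutateGenes(fasA$genes,
                                     config$shared_core_divergence,
                                     config$indel_rate,
                                     c("FUN_005930", "FUN_005931")),
                 intergenic = config$fas_intergenic_bp)

    genomeA <- assembleGenome("physodic", "phys", c(clustersA, specA),
                              fasA, intergenic = 300L)
    genomeB <- assembleGenome("olivetoric", "oliv", c(clustersB, specB),
                              fasB, intergenic = 300L)

    ## --- count tables (full scale) --------------------------------------
    candGeneIds <- function(genome, prefix) {
        cl <- getCluster(genome, sprintf("%s_c04", prefix))
        geneIds(cl)
    }
    libA <- config$library_sizes[["physodic"]]
    libB <- config$library_sizes[["olivetoric"]]
    fasIdsA <- c("FUN_004275", "FUN_004276")
    fasIdsB <- c("FUN_005930", "FUN_005931")
    haveCand <- nShared >= 4L && types[4L] == "NR-PKS"
    idsA <- c(if (haveCand) candGeneIds(genomeA, "phys"), fasIdsA)
    idsB <- c(if (haveCand) candGeneIds(genomeB, "oliv"), fasIdsB)
    ctsA <- c(if (haveCand) config$cluster4_counts_physodic,
              config$fas_counts_physodic)
    ctsB <- c(if (haveCand) config$cluster4_counts_olivetoric,
              config$fas_counts_olivetoric)
    countsA <- CountTable(idsA, ctsA, libA)
    countsB <- CountTable(idsB, ctsB, libB)

    ## --- desk-scale reads ------------------------------------------------
    scale <- config$read_scale
    scaledA <- CountTable(idsA, round(ctsA / scale), round(libA / scale))
    scaledB <- CountTable(idsB, round(ctsB / scale), round(libB / scale))
    readsA <- simulateReads(genomeA, scaledA, config$read_length,
                            seed = config$seed + 101L)
    readsB <- simulateReads(genomeB, scaledB, config$read_length,
                            seed = config$seed + 202L)
    crossSource <- NULL
    if (config$plant_cross_reads > 0L && length(specA)) {
        src <- Filter(function(g) g$id == specA[[1L]]$core_id,
                      specA[[1L]]$genes)[[1L]]
        starts <- sample(nchar(src$seq) - config$read_length + 1L,
                         config$plant_cross_reads, replace = TRUE)
        cross <- Biostrings::DNAStringSet(substring(
            src$seq, starts, starts + config$read_length - 1L))
        names(cross) <- sprintf("crossread_%04d",
                                seq_len(config$plant_cross_reads))
        readsB <- c(readsB, cross)
        crossSource <- specA[[1L]]$cluster_id
    }

    ## --- references / queries -------------------------------------------
    references <- Biostrings::DNAStringSet(refSeqs)
    hexA <- Filter(function(g) g$product == "FAS-A", fasA$genes)[[1L]]
    hexB <- Filter(function(g) g$product == "FAS-B", fasA$genes)[[1L]]
    hexQueries <- Biostrings::DNAStringSet(c(
        HexA_query = mutateSequence(hexA$seq, 0.02),
        HexB_query = mutateSequence(hexB$seq, 0.02)))

    manifest <- list(
        seed = config$seed,
        genome_a = "physodic", genome_b = "olivetoric",
        pairs = data.frame(
            cluster_a = vapply(clustersA, `[[`, character(1L), "cluster_id"),
            cluster_b = vapply(clustersB, `[[`, character(1L), "cluster_id"),
            divergence = rep(config$shared_core_divergence,
                             length(clustersA)),
            stringsAsFactors = FALSE),
        specific_a = vapply(specA, `[[`, character(1L), "cluster_id"),
        specific_b = vapply(specB, `[[`, character(1L), "cluster_id"),
        nrpks_clusters_a = names(archA),
        architectures_a = as.list(archA),
        architectures_b = as.list(archB),
        groups = as.list(stats::setNames(
            nrSpec$group[seq_len(min(nNR, nrow(nrSpec)))],
            names(archA))),
        candidate_a = if (haveCand) "phys_c04" else NA_character_,
        candidate_b = if (haveCand) "oliv_c04" else NA_character_,
        candidate_gene_ids_a = if (haveCand) candGeneIds(genomeA, "phys"),
        candidate_gene_ids_b = if (haveCand) candGeneIds(genomeB, "oliv"),
        atranorin_a = if (nNR >= 6L) "phys_c06" else NA_character_,
        fas_gene_ids_a = fasIdsA, fas_gene_ids_b = fasIdsB,
        fas_lengths = config$fas_lengths,
        fas_orientation = config$fas_orientation,
        library_sizes = as.list(config$library_sizes),
        scaled_counts_a = as.list(stats::setNames(counts(scaledA)$raw_count,
                                                  counts(scaledA)$gene_id)),
        scaled_counts_b = as.list(stats::setNames(counts(scaledB)$raw_count,
                                                  counts(scaledB)$gene_id)),
        scaled_library_sizes = list(physodic = librarySize(scaledA),
                                    olivetoric = librarySize(scaledB)),
        cross_read_source = crossSource,
        reference_groups = as.list(refGroups))

    list(genomeA = genomeA, genomeB = genomeB,
         countsA = countsA, countsB = countsB,
         readsA = readsA, readsB = readsB,
         references = references, referenceGroups = refGroups,
         hexQueries = hexQueries,
         architecturesA = archA, architecturesB = archB,
         config = config, manifest = manifest)
}

#' Simulate an error-free read set from a count table
#'
#' Emits exactly \code{raw_count} reads per gene, drawn uniformly from
#' the gene body with random strand, plus \code{librarySize - sum(counts)}
#' background reads drawn from non-gene (intergenic) sequence. Reads are
#' error-free; qualities (when written to FASTQ) are uniformly "I".
#'
#' @param genome a [GenomeAnnotation-class].
#' @param countTable a [CountTable-class] whose genes exist in
#'   \code{genome}.
#' @param readLength read length in bp; must not exceed the shortest
#'   gene with a nonzero count.
#' @param seed optional seed (the caller's RNG state is preserved).
#' @return a named \code{DNAStringSet} of reads.
#' @export
simulateReads <- function(genome, countTable, readLength = 150L,
                          seed = NULL) {
    withSeed(seed, {
        cts <- counts(countTable)
        cts <- cts[cts$raw_count > 0, , drop = FALSE]
        seqs <- geneSequences(genome, cts$gene_id)
        if (nrow(cts) && readLength > min(Biostrings::width(seqs)))
            lbgcError("readLengthError",
                      "readLength exceeds the shortest counted gene")
        chunks <- list()
        for (i in seq_len(nrow(cts))) {
            s <- as.character(seqs[[i]])
            n <- cts$raw_count[i]
            starts <- sample.int(nchar(s) - readLength + 1L, n,
                                 replace = TRUE)
            r <- Biostrings::DNAStringSet(
                substring(s, starts, starts + readLength - 1L))
            flip <- stats::runif(n) < 0.5
            r[flip] <- Biostrings::reverseComplement(r[flip])
            chunks[[length(chunks) + 1L]] <- r
        }
        nBackground <- librarySize(countTable) - sum(cts$raw_count)
        if (nBackground > 0) {
            gaps <- intergenicWindows(genome, readLength)
            if (!nrow(gaps))
                lbgcError("readLengthError",
                          "no intergenic window long enough for background reads")
            navail <- gaps$end - gaps$start - readLength + 2L
            wi <- sample.int(nrow(gaps), nBackground, replace = TRUE,
                             prob = navail)
            off <- floor(stats::runif(nBackground) * navail[wi])
            starts <- gaps$start[wi] + off
            ctgSeqs <- contigs(genome)
            bg <- Biostrings::DNAStringSet(rep("", nBackground))
            for (nm in unique(gaps$contig[wi])) {
                sel <- which(gaps$contig[wi] == nm)
                bg[sel] <- Biostrings::extractAt(
                    ctgSeqs[[nm]],
                    IRanges::IRanges(starts[sel], width = readLength))
            }
            flip <- stats::runif(nBackground) < 0.5
            bg[flip] <- Biostrings::reverseComplement(bg[flip])
            chunks[[length(chunks) + 1L]] <- bg
        }
        out <- if (length(chunks)) do.call(c, chunks)
               else Biostrings::DNAStringSet()
        names(out) <- sprintf("r%07d", seq_along(out))
        out
    })
}

## intergenic windows of at least `minWidth` bp per contig
intergenicWindows <- function(genome, minWidth) {
    g <- genes(genome)
    ctgs <- contigs(genome)
    rows <- list()
    for (nm in names(ctgs)) {
        len <- Biostrings::width(ctgs)[match(nm, names(ctgs))]
        on <- g[as.character(GenomicRanges::seqnames(g)) == nm]
        occ <- IRanges::reduce(IRanges::IRanges(
            GenomicRanges::start(on), GenomicRanges::end(on)))
        free <- BiocGenerics::setdiff(IRanges::IRanges(1L, len), occ)
        free <- free[IRanges::width(free) >= minWidth]
        if (length(free))
            rows[[length(rows) + 1L]] <- data.frame(
                contig = nm, start = BiocGenerics::start(free),
                end = BiocGenerics::end(free), stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(data.frame(contig = character(), start = integer(),
                          end = integer()))
    do.call(rbind, rows)
}

#' Write a generated fixture to a directory
#'
#' Emits, per genome, FASTA + GFF3 + cluster TSV ([writeGenome]), a count
#' TSV ([writeCountTable]) and a FASTQ of simulated reads, plus the
#' labelled reference FASTA with a group TSV, the HexA/HexB query FASTA,
#' and the JSON manifest. Output is byte-deterministic for a given
#' configuration.
#'
#' @param fixture the result of [generateFixture].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pA <- writeGenome(fixture$genomeA, dir, "physodic")
    pB <- writeGenome(fixture$genomeB, dir, "olivetoric")
    cA <- file.path(dir, "physodic.counts.tsv")
    cB <- file.path(dir, "olivetoric.counts.tsv")
    writeCountTable(fixture$countsA, cA)
    writeCountTable(fixture$countsB, cB)
    fqA <- file.path(dir, "physodic.reads.fastq")
    fqB <- file.path(dir, "olivetoric.reads.fastq")
    writeReadsFastq(fixture$readsA, fqA)
    writeReadsFastq(fixture$readsB, fqB)
    refFa <- file.path(dir, "references.fasta")
    Biostrings::writeXStringSet(fixture$references, refFa, width = 80L)
    refTsv <- file.path(dir, "reference_groups.tsv")
    writeTsv(data.frame(reference_id = names(fixture$referenceGroups),
                        group = unname(fixture$referenceGroups)),
             refTsv, sort = FALSE)
    hexFa <- file.path(dir, "hex_queries.fasta")
    Biostrings::writeXStringSet(fixture$hexQueries, hexFa, width = 80L)
    archTsv <- file.path(dir, "architectures.tsv")
    writeTsv(data.frame(
        cluster_id = c(names(fixture$architecturesA),
                       names(fixture$architecturesB)),
        domains = c(unname(fixture$architecturesA),
                    unname(fixture$architecturesB))), archTsv, sort = FALSE)
    manifestJson <- file.path(dir, "manifest.json")
    jsonlite::write_json(fixture$manifest, manifestJson, pretty = TRUE,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    invisible(c(pA, pB, counts_a = cA, counts_b = cB, reads_a = fqA,
                reads_b = fqB, references = refFa,
                reference_groups = refTsv, hex_queries = hexFa,
                architectures = archTsv, manifest = manifestJson))
}

## FASTQ writer with constant "I" qualities
writeReadsFastq <- function(reads, path) {
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = quals)
    invisible(path)
}

#' Read a fixture directory back into memory
#'
#' @param dir a directory written by [writeFixture].
#' @return a list with the same shape as [generateFixture] (minus the
#'   config; the manifest is re-read from JSON).
#' @export
readFixture <- function(dir) {
    groups <- readTsv(file.path(dir, "reference_groups.tsv"))
    arch <- readTsv(file.path(dir, "architectures.tsv"))
    archVec <- stats::setNames(arch$domains, arch$cluster_id)
    list(
        genomeA = readGenome(file.path(dir, "physodic.fasta"),
                             file.path(dir, "physodic.gff3"),
                             file.path(dir, "physodic.clusters.tsv"),
                             genomeId = "physodic"),
        genomeB = readGenome(file.path(dir, "olivetoric.fasta"),
                             file.path(dir, "olivetoric.gff3"),
                             file.path(dir, "olivetoric.clusters.tsv"),
                             genomeId = "olivetoric"),
        countsA = readCountTable(file.path(dir, "physodic.counts.tsv")),
        countsB = readCountTable(file.path(dir, "olivetoric.counts.tsv")),
        readsA = Biostrings::readDNAStringSet(
            file.path(dir, "physodic.reads.fastq"), format = "fastq"),
        readsB = Biostrings::readDNAStringSet(
            file.path(dir, "olivetoric.reads.fastq"), format = "fastq"),
        references = Biostrings::readDNAStringSet(
            file.path(dir, "references.fasta")),
        referenceGroups = stats::setNames(groups$group,
                                          groups$reference_id),
        hexQueries = Biostrings::readDNAStringSet(
            file.path(dir, "hex_queries.fasta")),
        architecturesA = archVec[startsWith(names(archVec), "phys_")],
        architecturesB = archVec[startsWith(names(archVec), "oliv_")],
        manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                       simplifyVector = TRUE))
}
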