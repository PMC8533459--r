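## Published worked-example data for the two Pseudevernia furfuracea
## chemotypes: the per-gene expression of the candidate depside/depsidone
## cluster (plus the HexA/HexB FAS subunit genes) and the shared NR-PKS
## cluster inventory. These printed values are the desk-scale inputs for
## calibration, candidate filtering and activity ranking.

#' Published expression of the candidate cluster and FAS genes
#'
#' Raw transcriptome read counts, gene lengths and RPKM-normalized counts
#' reported for the ten genes of the candidate depside/depsidone cluster
#' and for the HexA (FAS alpha) and HexB (FAS beta) genes, in both the
#' physodic acid and the olivetoric acid chemotype. Genes reported with
#' no aligned reads in a chemotype carry \code{NA} raw counts and a
#' \code{TRUE} in the corresponding \code{no_data} column; they are
#' treated as zero counts downstream but stay distinguishable from an
#' assessed zero.
#'
#' @return a \code{data.frame} with one row per gene: \code{gene},
#'   \code{product}, \code{length_bp}, \code{raw_phys}, \code{rpkm_phys},
#'   \code{raw_oliv}, \code{rpkm_oliv}, \code{no_data_phys},
#'   \code{no_data_oliv}.
#' @examples
#' head(pfurClusterExpression())
#' @export
pfurClusterExpression <- function() {
    df <- data.frame(
        gene = c(paste0("gene", 1:10), "FAS-A", "FAS-B"),
        product = c("unidentified", "unidentified", "unidentified",
                    "CytP450", "NR-PKS", "unidentified", "unidentified",
                    "unidentified", "unidentified", "monooxygenase",
                    "FAS-A", "FAS-B"),
        length_bp = c(3822, 306, 2685, 2139, 6294, 2550, 3284, 2191, 492,
                      1851, 5619, 6285),
        raw_phys = c(38, NA, NA, 8677, 111226, 13690, 1035, 936, NA, 46,
                     3143, 1971),
        rpkm_phys = c(0, NA, NA, 117.29, 511, 155.25, 9.11, 12.35, NA,
                      0.71, 16.17, 9.06),
        raw_oliv = c(NA, 1, 19, 1222, 1265, 6304, 118, 205, 12, 19,
                     944, 911),
        rpkm_oliv = c(NA, 0, 0, 17.4, 6.33, 75.38, 1.125, 1.98, 0.73,
                      0.307, 5.12, 4.42),
        stringsAsFactors = FALSE)
    df$no_data_phys <- is.na(df$raw_phys)
    df$no_data_oliv <- is.na(df$raw_oliv)
    df
}

#' Published inventory of the eight shared NR-PKS clusters
#'
#' The NR-PKS clusters found in both chemotypes: the core PKS gene, its
#' domain string (as printed, with mixed hyphen/space separators), the
#' phylogenetic group of the PKS, the total gene count of the cluster and
#' the identified companion genes. This table is the direct input to the
#' four-criterion candidate filter and the atranorin-cluster rule.
#'
#' @return a \code{data.frame} with one row per cluster: \code{cluster},
#'   \code{pks_id}, \code{group}, \code{domains}, \code{total_genes},
#'   \code{companions} (comma-separated product labels).
#' @examples
#' pfurNRPKSClusters()[, c("cluster", "domains", "group")]
#' @export
pfurNRPKSClusters <- function() {
    data.frame(
        cluster = 1:8,
        pks_id = c("Pfur12-3_001319", "Pfur18-1_002705", "Pfur44-1_008033",
                   "Pfur33-1_006185", "Pfur2-2_003072", "Pfur9-3_011125",
                   "Pfur3-1_005530", "Pfur69-1_010133"),
        group = c("VII", "V", "II", "I", "I", "IX", "II", "II"),
        domains = c("SAT-KS-AT-ACP cMT-TD",
                    "SAT-KS-AT-PT-ACP",
                    "SAT-KS-AT-PT-ACP ACP-TE",
                    "SAT-KS-AT-ACP ACP-TE",
                    "SAT-KS-AT-PT-ACP-TE",
                    "SAT-KS-AT-PT-ACP cMT",
                    "SAT-KS-AT-PT-ACP-ACP-TE",
                    "SAT-KS-AT-PT-ACP-ACP-TE"),
        total_genes = c(12, 16, 11, 10, 13, 11, 13, 9),
        companions = c(
            "regulatory gene,NR-PKS",
            "metallo-beta-lactamase family protein,NR-PKS,halogenase",
            "PKS,dehydrogenase/reductase (KR)",
            "CytP450,PKS,monooxygenase",
            paste("O-methyltransferase,CytP450",
                  "crotonyl-CoA reductase/alcohol dehydrogenase",
                  "red-PKS,NR-PKS,GATase_7", sep = ","),
            paste("alkyl hydroperoxide reductase/Thiol specific,PKS",
                  "CytP450,drug resistance transporter", sep = ","),
            paste("serine/threonine protein kinase",
                  "drug resistance transporter",
                  "monooxygenase FAD-binding,NR-PKS",
                  "short-chain dehydrogenase/reductase SDR",
                  "O-methyltransferase,transcription regulator", sep = ","),
            paste("drug resistance transporter,O-methyltransferase",
                  "halogenase,monooxygenase FAD-binding",
                  "adh_short (DH-KR),NR-PKS",
                  "monooxygenase FAD-binding", sep = ",")),
        stringsAsFactors = FALSE)
}
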