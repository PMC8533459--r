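---
title: "Comparing BGC complements of lichen chemotypes: methods and design"
author: "lichenBGC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing BGC complements of lichen chemotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many lichen-forming fungi occur as chemotypes: individuals of one species
with different secondary-metabolite profiles. The model system behind this
package is *Pseudevernia furfuracea*, whose two chemotypes produce either
the depside olivetoric acid or the corresponding depsidone physodic acid —
two compounds that differ only by one ether bond. Because the compounds
are so closely related, the interesting genomic questions are
comparative: do the two chemotypes carry the same complement of
biosynthetic gene clusters (BGCs)? Which cluster is the plausible
producer of the depside/depsidone pair? Is a dedicated metabolite fatty
acid synthase (FAS) present to supply the hexanoyl starters that the
compounds' C5/C7 side chains require?

`lichenBGC` implements that comparative workflow as reusable, tested
functions: cross-genome matching of cluster core genes, polyketide
synthase (PKS) domain-architecture classification and group placement, a
four-criterion candidate filter, detection of the divergently transcribed
HexA/HexB FAS locus, RPKM transcription quantification, and a
combinatorial rule model of orcinol depside/depsidone assembly. A
synthetic fixture generator reproduces the published cluster inventory so
every stage can be exercised end to end without downloads.

## Homologous clusters by reciprocal best hit

Cluster prediction itself (antiSMASH and gene calling) is outside the
package's scope; its inputs are annotated genomes (FASTA + GFF3) plus a
plain five-column cluster table naming each region's genes and core
gene(s). Two clusters in different genomes are called homologous when
their core genes are reciprocal best hits (RBH): each is the other's
best-scoring match among all core genes of the other genome, mirroring
the reciprocal BLAST design of the original analysis. Reciprocity is the
point — a within-genome paralog finds a good one-way hit, but the hit's
own best partner is its true ortholog, so paralogs drop out.

Scoring is global (Needleman–Wunsch) nucleotide alignment with match +1,
mismatch −1 and affine gap cost 2 + *L* for a gap of length *L*
(`Biostrings::pairwiseAlignment`; the test suite checks the scorer
against an independently written dynamic-programming oracle). Identity is
the fraction of matching columns over all aligned columns. Global rather
than local alignment is the default because cluster core genes are
full-length homologs; the choice matters only for badly truncated
annotations.

Three numeric choices deserve explanation:

* **RBH acceptance identity, default 0.7.** The original analysis
  confirmed homologs against an external database rather than by a
  numeric cutoff; an external database dependency is out of scope, so a
  conservative identity floor stands in. Fixture homologs sit near 0.97
  and decoys near 0.83, both far from the cutoff; the parameter exists
  for real data, where it is configurable.
* **Tie breaking.** Best hits tie first on score, then on higher
  identity, then lexicographically on subject identifier, making results
  order-independent and deterministic.
* **k-mer prescreen.** Aligning every core against every core is
  quadratic in cluster count with 3–6 kb sequences. An alignment-free
  screen (Jaccard distance of 8-mer sets, threshold 0.95) skips pairs
  that are clearly unrelated: unrelated random 3 kb sequences sit near
  distance 0.977, homologs near 0.35, diverged paralogs near 0.88. Any
  core with no screened partner falls back to exhaustive alignment of its
  whole row and column, so a best hit is never computed over an
  arbitrary subset. `prefilter = FALSE` forces exhaustive alignment; the
  tests verify the screened path against exhaustive mutual-best
  enumeration.

Unmatched clusters become chemotype-specific candidates, but only after a
negative read check: the other chemotype's raw reads are mapped onto the
cluster's core gene and the maximum normalized coverage (RPKM) is
recorded as absence evidence. A cluster is reported `specific` only when
that evidence is exactly zero — the same "no reads of the missing BGC in
the raw data" argument the original study used to exclude sequencing
depth as an explanation — and `ambiguous` otherwise.

For homologous pairs, `syntenyTable()` replaces a synteny figure with its
numbers: all-vs-all global alignments of the two clusters' genes,
reported where identity ≥ 90% over ≥ 50 aligned columns (the drawing
thresholds conventionally used for such plots), after orienting the
clusters so the core genes share direction.

## PKS classification and group placement

Fungal iterative type I PKS domain strings are parsed from the closed
vocabulary SAT, KS, AT, PT, ACP, cMT, TE, TD, KR, DH, ER, MT; printed
tables mix hyphen and space separators, and the parser accepts both. A
PKS with any reducing domain (KR/DH/ER) is an R-PKS; otherwise KS + AT +
ACP make it an NR-PKS. TD is treated as a terminal release domain
distinct from TE; neither counts as reducing.

NR-PKSs fall into named phylogenetic groups (I, II, V, VII, IX among
those handled here); orcinol depside/depsidone synthases belong to group
I. The decision the pipeline needs is the group label, not branch
lengths, so instead of a maximum-likelihood phylogeny the package places
a query with the group of its nearest labelled reference under the k-mer
Jaccard distance (k = 8 for nucleotide, k = 4 recommended for amino acid
sequences, whose larger alphabet saturates k-mer sets sooner). The
default placement threshold of 0.6 admits queries within roughly 5–10%
sequence divergence of a reference while rejecting unrelated sequences
(which sit near 1.0); beyond it the group is `unknown`. A
neighbor-joining tree (`njTree()`, via `ape::nj`) is produced for
reporting and sanity checking only — the tests confirm it recovers
additive distance matrices exactly.

## The candidate filter

Four criteria decide pass/fail, exactly as in the published design: the
cluster (1) is homologous and present in both chemotypes, (2) contains an
NR-PKS, (3) contains a CytP450 gene — the enzyme class that forms the
depsidone ether bond — and (4) its PKS carries two ACP domains, the
feature associated with depside-forming PKSs that build and esterify two
rings. Everything else the original exclusion arguments used — a cMT
domain (azaphilone/ß-orcinol character), a missing TE, an
O-methyltransferase in the cluster, an adjacent divergently transcribed
R-PKS, a phylogenetic group other than I — is recorded per cluster as
*negative evidence* without affecting the verdict. Treating those as
evidence rather than additional hard criteria keeps the filter exactly
the four printed rules while preserving the reasoning trail; on the
published eight-cluster inventory the four rules alone already select a
single cluster.

The atranorin-type cluster is detected by a separate rule: SAT, KS, AT,
PT, ACP and cMT in the PKS, group IX, and a CytP450, an
O-methyltransferase and a transporter in the cluster. The TE domain is
treated as optional because published atranorin synthase architectures
appear both with and without it. More than one match raises an ambiguity
error rather than picking silently.

The HexA/HexB metabolite FAS locus is located by sequence queries: the
best-scoring gene hit for each query, accepted when the two hits are
immediately adjacent on one contig (no intervening gene, intergenic
distance ≤ 5000 bp — the source material gives the orientation but no
distance, so the bound is deliberately generous for fungal intergenic
spacing) and divergently transcribed, i.e. head-to-head around a shared
control region. Convergent or tandem arrangements are reported but do
not qualify.

## Transcription quantification

Reads are placed full length and ungapped on either strand; a read
counts for the gene of its best placement when identity reaches the
threshold (default 0.95), reads tied between genes are discarded
(standard multi-mapping exclusion), and everything else counts only
toward the library size. Candidate (read, gene) pairs come from an
exact-seed pigeonhole screen — a placement with at most *m* mismatches
must contain an exact seed of length ⌊w/(m+1)⌋ at one of m+1 disjoint
offsets — so the dominant cost, background reads, is near zero. This
replaces a spliced aligner deliberately: fixture reads are error-free
and ungapped by construction, and the counting contract (best placement,
identity floor, tie discard) is what downstream stages depend on.

RPKM follows the published normalization exactly:

rpkm = raw / (librarySize / 10^6) / (length / 1000)

with librarySize the *total* reads in the sample, not the mapped reads —
the fixtures make that distinction testable. Published tables print raw
counts, lengths and RPKM but never the library size;
`calibrateLibrarySize()` recovers it by least squares on the inverted
RPKM identity (exact inversion for a single row). Within a cluster,
genes are ranked by RPKM; an `active` flag marks genes at ≥ 10× the
within-cluster median (no numeric activity rule exists in the source
material, so the flag is a convenience and all cross-chemotype claims in
the tests use the threshold-free rank order).

The published olivetoric-chemotype RPKM column is internally
inconsistent: no single library size reproduces it (the gene6 and gene8
rows imply sizes differing by ~40%). The package therefore uses only
rank order on that column. The physodic column is consistent: one
least-squares library size reproduces every nonzero value to within 0.02
at the precision each value was printed with (one value is printed
without decimals and can only be checked to ±0.5).

## The synthetic fixture

`generateFixture()` builds two annotated genomes mirroring the published
inventory, and its defaults are the study conditions, not tuning knobs:

* 51 shared clusters — 8 NR-PKS clusters carrying the published domain
  strings, companion genes, and group-labelled reference derivations
  (including the ten-gene candidate cluster with the published gene
  lengths), 14 R-PKS, 1 type III PKS, 7 hybrid, 14 NRPS/NRPS-like,
  5 terpene and 2 indole clusters;
* 5 physodic-only clusters (R-PKS ×3, hybrid, terpene) and 1
  olivetoric-only terpene cluster, whose cores are *decoy paralogs*:
  copies of same-genome shared cores mutated at 15%. Planting the decoys
  inside the specific clusters keeps the published 5 + 1 counts while
  making RBH genuinely non-trivial — a naive one-way best hit would pair
  each decoy with its donor's homolog;
* homologous gene copies diverged by substitution at rate 0.03
  (generic cores 3 kb), NR-PKS cores derived from their labelled
  references at rate 0.05 — values chosen so that homologs, paralogs
  and unrelated sequences occupy clearly separated identity bands
  (0.97 / 0.83 / ~0.5), as intraspecific vs. paralogous divergence in
  fungal genomes would;
* one HexA/HexB pair per genome (5619 and 6285 bp), head-to-head with an
  800 bp intergenic control region — the source material fixes the
  orientation and lengths but not the distance;
* count tables with the published raw read counts, and library sizes
  calibrated from the published RPKM values at run time.

Mutation is substitution-only by default (an indel-rate option exists but
defaults to 0) so that identity arithmetic stays exact: a pair generated
at rate *d* aligns gap-free at identity ≈ 1 − *d*, which the tests
verify within binomial error. Reads are simulated error-free at the
published counts divided by 1000, with library sizes divided equally —
RPKM's exact scale invariance makes the desk-scale libraries carry the
same normalized values, and the full-scale printed counts are exercised
through the count-table entry point instead of read simulation. The
generator writes a JSON manifest of every planted truth, and downstream
tests read expectations from the manifest rather than from constants.

What the fixture does *not* emulate — and hence what passing tests do
not show about real data: sequencing error and quality variation,
indels and rearrangements between chemotypes, paired-end reads,
spliced transcripts, partial or mispredicted gene models, and
contamination. The pipeline's thresholds are all configurable for that
reason.

All problem sizes in the shipped tests were chosen as the smallest that
still exercise every planted structure: most stages run on a 10-cluster
fixture, and the full 51-cluster mirror is generated once for the
end-to-end recovery checks.

## Assembly scheme

The depside/depsidone rule model is purely combinatorial. An orcinol
ring is described by its starter (C2 acetyl-CoA or C4/C6/C8 acyl chains)
and its malonyl-CoA extension count (3 or 4); the ring side chain is
starter + 2·(extensions − 3) − 1 carbons, always odd, and a fourth
extension leaves a ß-keto group on the side chain. Two rings joined by
the constitutive ester bond make a depside; the CytP450-catalyzed ether
bond turns it into the depsidone with ring specifications preserved
exactly. Starter provenance encodes the heterologous-host observation:
the PKS default accepts free acetyl-CoA only, so rings needing longer
starters are reachable only when a dedicated metabolite FAS delivers the
acyl chain protein-to-protein — absent that FAS the model flags them
unreachable, which is why a yeast host yields the C1-side-chain depside.
Stereochemistry, masses and kinetics are deliberately out of scope: the
underlying scheme is qualitative and anything further would be
invention.

## Source-material discrepancies, resolved as design choices

* The published genome-statistics table reports 4 NR-PKSs per genome
  while the cluster inventory discusses eight shared NR-PKS clusters
  (some presumably inside hybrid regions); the fixture follows the
  eight-cluster inventory.
* The prose count of physodic-specific R-PKS clusters ("four") differs
  from the corresponding table (three R-PKS rows plus one hybrid); the
  fixture follows the table.
* The printed atranorin-cluster companion list omits the
  O-methyltransferase that the accompanying text requires; the detection
  rule follows the text (OMT required), so on the table as printed it
  correctly reports no match, and the fixture's atranorin mirror carries
  the OMT.
* One cluster's group label differs between table ("V") and prose
  ("VII"); the package follows the table.

## Known limitations

Alignment is nucleotide-only (no translated comparison), read placement
is ungapped, the group placement is a nearest-reference heuristic rather
than a phylogeny, and the candidate filter inherits the four published
criteria verbatim — it will not generalize to compound families whose
clusters violate them. External reference databases (MIBiG similarity
annotation) are out of scope.
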