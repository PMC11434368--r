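# eetkit

Comparative genomics of extracellular electron transfer (EET) potential
across bacterial families, as a tested, desk-scale R pipeline.

Dissimilatory metal-reducing bacteria — *Geobacter*- and *Shewanella*-like
iron reducers and *Desulfovibrio*-like sulfate reducers — move respiratory
electrons across the cell envelope through chains of multi-heme c-type
cytochromes, porin–cytochrome conduits and, in some lineages, soluble
shuttles such as riboflavin. Comparing genomes for this capability involves
a recurring set of analyses that `eetkit` packages as composable,
individually tested stages:

1. **Heme-motif census** — scan every protein for the c-type cytochrome
   heme-binding motifs `CXXCH` and `CXXXCH`, classify proteins as mono-
   (1), bi- (2) or multi-heme (≥ 3 motifs), join PSORTb-style subcellular
   localization predictions, and summarize per family.
2. **Orthogroup profiling** — parse OrthoFinder-style `Orthogroups.tsv`
   tables (or infer a stand-in clustering by reciprocal best hits), count
   universal / species-specific / family-exclusive orthogroups, select the
   single-copy core for phylogenomic supermatrices, map a curated EET
   marker database (PpcA, OmpJ, CymA, Cbc- and riboflavin-biosynthesis
   genes, …) to orthogroups, and build genome × marker copy-number
   matrices with per-family prevalence.
3. **Similarity network** — select all members of orthogroups containing
   at least one extracellular or outer-membrane multi-heme cytochrome,
   align all pairs (exact Smith–Waterman, BLOSUM62, affine gaps 11/1),
   keep edges with E ≤ 1e−40, identity ≥ 30% and coverage ≥ 70%, and
   detect communities with a weighted Louvain algorithm
   (Q = Σ_c [W_c/m − γ(K_c/2m)²], resolution γ = 1 by default).
4. **Mobilome census** — aggregate normalized per-element tables
   (prophages by completeness class, CRISPR arrays, integrons
   complete/In0/CALIN, insertion-sequence hits filtered at > 700 bp and
   E ≤ 1e−6, ICE conjugation-system types) into per-genome profiles and
   per-family prevalence/density summaries.
5. **Feature PCA** — assemble a fixed 13-variable genomic feature table
   (genome size, GC%, mobilome counts, total cytochromes per Mbp, EET
   marker copies) and decompose its correlation matrix.

Because the original study design depends on externally downloaded RefSeq
genomes and web detection tools, `eetkit` ships a seeded synthetic-study
generator (`generate_study()`) that emits every input format with known
truth tables — planted gene families with controlled within/between-family
identity, planted heme motifs, marker copy numbers, mobilome counts and
community structure — so the whole pipeline is testable offline.

## Worked example

```r
library(eetkit)
set_log_level("warning")

## a self-contained toy study: 3 families x 4 genomes, 20 gene families
cfg   <- synth_config(seed = 7, n_gene_families = 20,
                      genome_length_mean_mbp = 0.05)
study <- generate_study(cfg, "demo_study")

## motif scanning
scan_heme_motifs("MACADCHVWCLPCHAACRWCH")
#>   start pattern
#> 1     2   CXXCH
#> 2     9   CXXCH
#> 3    16   CXXCH

## per-family heme census
gids <- names(study$truth$genome_length_bp)
gs   <- load_genome_set(setNames(file.path("demo_study/proteome",
                                           paste0(gids, ".faa")), gids),
                        "demo_study/metadata.tsv")
loc  <- read_table("demo_study/localization.tsv", "localization")
ann  <- annotate_proteome(gs, loc)
family_heme_summary(ann, gs)[, c("family", "n_genomes",
                                 "mean_heme_proteins", "pct_both",
                                 "n_multi")]
#>     family n_genomes mean_heme_proteins pct_both n_multi
#> 1 Family01         4              16.25 16.92308      12
#> 2 Family02         4              14.50  8.62069       7
#> 3 Family03         4              16.00 15.62500       7

## extracellular-cytochrome similarity network + Louvain communities
og  <- parse_orthogroups("demo_study/orthogroups.tsv")
sel <- select_network_sequences(og, ann)
net <- partition_ssn(build_ssn(gs, protein_ids = sel, og = og), seed = 1)
cs  <- community_summary(net)
#> network: 56 nodes, 375 edges, 4 communities (4 with >= 2 nodes), Q = 0.703
```

Here `mean_heme_proteins` is the mean number of motif-bearing proteins per
genome of the family, `pct_both` the share of those carrying both motif
types, and `n_multi` the family's multi-heme (≥ 3 motifs) protein count.
The network's four communities are the four gene families that contained a
qualifying extracellular/outer-membrane multi-heme cytochrome; the
modularity Q = 0.703 reflects their clean separation.

`run_pipeline(study_dir, out_dir, seed)` chains all eight stages
(QC → orthogroups → heme scan → marker profile → network → mobilome →
features → PCA) and writes per-stage TSVs plus a `manifest.json` with MD5
hashes of every output; reruns with the same seed are byte-identical.

A thin shell wrapper is installed at
`system.file("scripts/eetkit-pipeline.R", package = "eetkit")` with
`simulate` and `run` subcommands.

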