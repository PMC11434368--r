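---
title: "Profiling extracellular electron transfer potential: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling extracellular electron transfer potential: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`eetkit` implements a comparative-genomics workflow for assessing
extracellular electron transfer (EET) potential across bacterial genomes:
a heme-motif cytochrome census, orthogroup-based profiling of EET marker
genes, a similarity network over candidate extracellular cytochromes with
Louvain community detection, a mobile-genetic-element census, and a PCA of
genomic features. This vignette explains the models and procedures, the
parameters that matter, the synthetic data the test suite relies on, and
the design decisions taken where the methodology was genuinely open.

## The heme-motif census

c-type cytochromes attach heme covalently at the motif **CXXCH**, with a
less common **CXXXCH** variant; proteins carrying three or more such
motifs (multi-heme cytochromes) are the workhorses of EET. The scanner
classifies every protein as `none`, `mono` (1 motif), `bi` (2) or `multi`
(≥ 3) and flags proteins carrying both motif types.

Two well-defined overlap policies are provided, because scripted regex
scans leave the overlap semantics implicit:

* `nonoverlap_greedy` (default): scan left to right, try `CXXCH` before
  `CXXXCH` at each position, and consume the matched window so that no
  residue serves two motifs. This mirrors the global-match semantics of a
  regex alternation while being fully specified.
* `all_matches`: every satisfying window is reported, overlaps allowed;
  useful for sensitivity analysis.

Unknown residues (`X`, introduced by alphabet normalization of RefSeq-like
proteomes) may occupy the wildcard positions of a motif but never the
anchor positions C, C, H: the anchors define the heme ligation chemistry,
the wildcards do not. Both policies are property-tested against an
independent brute-force window oracle on a thousand random sequences.

In family summaries, the counting unit is the protein: a protein with both
motif types counts once in the mutually exclusive categories
CXXCH-only / CXXXCH-only / both. "Extracellular" means the PSORTb-style
category `extracellular`; the localization vocabulary is fixed to
extracellular, outer membrane, periplasmic, cytoplasmic membrane,
cytoplasmic, plus unknown for proteins absent from the prediction table.

## Orthogroup profiling

Orthogroup tables are consumed in the OrthoFinder `Orthogroups.tsv`
dialect. The pipeline reports: orthogroups present in every genome
(universal core), orthogroups confined to one genome (species-specific),
family-exclusive orthogroups, and per-family-pair exclusive sharing.
"Family-exclusive" is defined here as members from exactly one family *and
at least two genomes*; the threshold is an argument
(`min_genomes_exclusive`) because the literature rarely pins this down,
and without it species-specific orthogroups would inflate the exclusive
counts.

EET markers map to orthogroups by membership when the reference protein
was part of the orthology run, otherwise by best Smith–Waterman hit
against all orthogroup members at the network thresholds (30% identity,
70% coverage) — one threshold vocabulary across the package. Copy number
is the count of a genome's proteins in the marker's orthogroup. Presence
is the derived view `copy ≥ 1`. The paper-style statistics (per-family
prevalence percentages, mean copies per genome) average over *all* genomes
of a family, zeros included.

A self-contained orthology fallback (`infer_orthogroups_rbh()`) exists so
the package has no external tool dependency: reciprocal best
Smith–Waterman hits between genome pairs form a graph whose connected
components are orthogroups. Two deliberate choices:

* **Paralog attachment** (on by default): only one of several
  within-genome paralogs can be a genome pair's reciprocal best hit, so
  leftover copies are attached to the orthogroup of their best passing
  hit. Without this step, multi-copy gene families can never be fully
  assigned by an RBH graph.
* Even with attachment, a gene family carrying ≥ 2 copies in several
  genomes may legitimately resolve into parallel ortholog sets (the RBH
  graph sees a duplication). Exact recovery of planted families is
  therefore only asserted for single-copy structure; for Poisson copy
  numbers the tests assert partition agreement (adjusted Rand index) on
  co-assigned proteins instead. This is a property of best-hit orthology,
  not an implementation artifact.

Unassigned proteins form no singleton orthogroups, mirroring the
"unassigned genes" accounting of standard orthology tools.

## The similarity network

Candidate sequences are all members of every orthogroup containing at
least one multi-heme protein predicted extracellular or outer-membrane —
whole orthogroups are carried, so sequences that did not individually pass
the localization filter ride along with their family, which is the
behavior that makes the network informative about near relatives.

All sequence pairs are aligned with an exact affine-gap Smith–Waterman
(BLOSUM62, gap open 11, extend 1; a gap of length L costs 11 + L). This
replaces a heuristic BLASTP search with the optimal score, which is
affordable at desk scale (up to a few thousand sequences) and exactly
testable against an independent DP oracle. E-values use Karlin–Altschul
statistics, `E = K·m·n·e^(−λS)` with the published gapped BLOSUM62/11-1
constants λ = 0.267, K = 0.041 and no length-adjusted effective search
space (a documented simplification).

Edge filters are `E ≤ 1e−40`, identity ≥ 0.30 (identical columns over all
alignment columns, gaps in the denominator) and coverage ≥ 0.70. Coverage
is alignment columns over the *shorter* sequence length by default;
query-based and mutual alternatives are provided because "minimum
coverage" does not name its reference sequence. One edge per pair is kept;
each pair is aligned once in a fixed lexicographic order because
co-optimal tracebacks need not be symmetric under argument swap (the
optimal score is). Edge weight is the bit score rather than −log E, since
E-values saturate numerically near 1e−308 while bit scores do not.

### Louvain community detection

Weighted modularity at resolution γ is
`Q = Σ_c [W_c/m − γ(K_c/2m)²]`. The implementation is the standard
two-phase algorithm — seeded-shuffle local moving until no gain, then
aggregation of communities into supernodes with self-loops, repeated until
convergence — and returns the partition, its Q, and the Q trace after
every completed sweep (non-decreasing by construction, and asserted in the
tests). Ties prefer staying, then the smallest community label, making a
fixed seed byte-reproducible. Isolated nodes become singleton communities;
singletons count toward the community total, and the ≥ 2-node count is
reported separately. Correctness is checked three ways: exhaustive
partition enumeration on a 6-node two-triangle graph (optimum Q = 0.5),
agreement of the modularity function with an independent implementation,
and recovery of planted partitions (8 blocks × 25 nodes, p_in = 0.3,
p_out = 0.01) at adjusted Rand index ≥ 0.9 over 5 seeds.

## Mobilome aggregation

Detection tools are *not* run; their reports are consumed as normalized
TSV tables (prophages with intact/questionable/incomplete completeness
classes, CRISPR arrays, integrons as complete/In0/CALIN elements, IS blast
hits, ICE conjugation-system types). Insertion-sequence hits are kept when
the alignment length is strictly over 700 bp and E ≤ 1e−6 — "over 700 bp"
is read as a strict inequality and the boundary is tested. The ICE metric
is the number of *distinct* conjugation-system types per genome. Prophage
density is prophages per Mbp of genome; whether the numerator is total or
intact-only prophages is a knob (`density_numerator`, default total, since
the conventional phrasing "prophages per Mbp" does not restrict the
class).

## Genome statistics and PCA

Genome QC keeps completeness > 98% and contamination < 5%, both strict.
Genome length counts all bases including N; GC excludes ambiguous bases
from the denominator.

The feature table has 13 fixed columns: genome size (Mbp), GC (%),
prophages, total cytochromes per Mbp, complete integrons, CRISPR arrays,
IS count, ICE types, and the marker copies ppcA, ompJ, Cbc (category
sum), cymA, Rib (category sum). "Total cytochromes per Mbp" is interpreted
as heme-motif-bearing proteins per Mbp — the only cytochrome census the
pipeline computes — and is configurable to multi-heme-only.

PCA standardizes columns (z-scores, n−1 denominator) by default and
decomposes the resulting correlation matrix by symmetric
eigendecomposition: the 13 variables mix Mbp, percentages and counts, so
unstandardized PCA would be dominated by scale. A `standardize = FALSE`
mode preserves the covariance alternative. Constant columns are dropped
with a warning. The sign convention orients each loading vector so its
largest-magnitude entry is positive. Tests assert exact variance
accounting (sums to 100 within 1e−9), exact reconstruction of the
standardized matrix (max abs error < 1e−8), permutation equivariance, and
recovery of a planted two-factor structure within 5° of principal angle.

## The synthetic study generator

`generate_study()` emits a complete toy cohort — metadata, CheckM-style
QC, proteome and nucleotide FASTA, orthogroup, localization, marker and
mobilome tables — together with truth tables, all deterministic in the
seed.

What it emulates, and how the defaults were chosen:

* **Cohort structure**: 3 families × 4 genomes by default (a miniature of
  a multi-family comparative study); two subclades per family; isolation
  sources drawn from typical environmental categories.
* **Gene families**: 50 by default, each from a random ancestor of
  150–450 residues. Per-genome copies mutate a fraction `1 − √w` of
  positions so that two copies share expected identity `w` (default 0.85,
  comfortably above the 30% network/orthology threshold). Distinct gene
  families use independent ancestors, so between-family identity is
  *bounded above* by its target (default 0.20) rather than calibrated to
  it; tests assert the within-family target to ±3% and the between-family
  bound, with identity measured as SW matches over the shorter length.
  The substitution model is uniform over non-identical residues — adequate
  for threshold testing, not a phylogenetic model.
* **Heme motifs**: per-protein Poisson counts (mean 1.0, split 85/15
  between CXXCH and CXXXCH, matching the strong predominance of the
  shorter motif in real proteomes) are planted at non-overlapping
  positions *after* mutation, and the truth table records the counts the
  scanner actually realizes — so mutation or chance motifs can never
  silently invalidate the truth.
* **Markers**: a fraction of gene families (default 0.3) become markers
  with fixed ids (ppcA, ompJ, cymA, cbcA/cbcB, ribB/ribE, omcA, …) and
  category labels; marker reference sequences are the family ancestors,
  emitted as an external FASTA so the best-hit mapping path is exercised.
* **Mobilome**: Poisson counts per element with defaults set to
  per-strain averages representative of the families this pipeline
  targets (intact 0.48, questionable 0.24, incomplete 1.97 prophages per
  strain; 2 CRISPR arrays; 5 IS hits; decoy IS rows that fail the length
  or E-value filter are planted deliberately).
* **Genomes**: nucleotide filler with controlled length (default 3.9 Mbp)
  and GC (55–65%) only — no gene coordinates, since no stage maps
  proteins to genomic positions.

What it does **not** emulate: indels and domain architecture, rate
heterogeneity, genuine orthology complications (fusions, horizontal
transfer), realistic localization signals (labels are sampled, not
predicted), or tool-specific report formats. Passing tests therefore
demonstrate correct bookkeeping, filtering, and recovery under controlled
signal — not robustness to the full messiness of real proteomes.

## Determinism and the pipeline

`run_pipeline()` executes qc → orthogroups → heme_scan → profile → ssn →
mobilome → features → pca, writing TSVs per stage and a JSON manifest of
MD5 hashes. All randomness flows from one base seed through per-stage
derived seeds (stage-name hashing, kept below 2³¹), so reruns are
byte-identical and stage reordering cannot silently change results. The
Louvain node shuffle uses an isolated RNG stream that never perturbs the
caller's RNG state.

## Problem sizes

The test suite runs the full study at 3 families × 4 genomes, 30 gene
families and 0.02-Mbp filler genomes; the acceptance script uses 50 gene
families and 0.5-Mbp genomes. These sizes were chosen so a complete run
exercises every code path — multi-copy families, orphan proteins, decoy
IS rows, empty-element genomes — while a laptop-class single core
completes the suite in about two minutes. Genome length only enters size
and density columns, so scaling it does not change any pass/fail
behavior.

## Known limitations

* Smith–Waterman is exact but quadratic; beyond a few thousand network
  sequences an external aligner's tabular output should be substituted
  (the graph builder only needs scores, identities and coverages).
* E-values lack BLAST's composition-based and length-adjusted
  corrections; absolute E-values differ from BLAST's, though the 1e−40
  filter operates in a regime where both agree that hits are
  overwhelmingly significant.
* The RBH fallback is not a replacement for a dedicated orthology tool on
  real data (no MCL, no species-tree awareness).
* Louvain is the only community algorithm offered, by design; the
  resolution parameter is exposed but no multi-resolution sweep is
  automated.
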