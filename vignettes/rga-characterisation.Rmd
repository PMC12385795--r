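---
title: "Characterising resistance gene analogues: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising resistance gene analogues: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgascape)
```

# The problem

Plant genomes carry hundreds to thousands of resistance gene analogues
(RGAs): genes whose predicted domain architecture matches the known
classes of disease-resistance genes. Intracellular NLR receptors carry
an NB-ARC nucleotide-binding domain with TIR, coiled-coil or RPW8
N-terminal domains and C-terminal leucine-rich repeats; cell-surface
receptors carry a transmembrane segment with an ectodomain, with (RLK)
or without (RLP) a cytoplasmic kinase; TM-CC proteins pair a
transmembrane segment with a coiled-coil. A genome-wide survey asks
where these genes sit, how they cluster, which are homologous to
functionally validated R genes, and which co-locate with mapped
disease-resistance QTL. rgascape implements that survey as a tested
pipeline over a single container, `RGAGenome` (assembly + gene
`GRanges` + protein `AAStringSet` + domain-call table).

# The classification model

`classifyDomains()` is a total, deterministic decision table over the
nine-label domain vocabulary (`TIR`, `NBARC`, `LRR`, `CC`, `RPW8`,
`TM`, `KINASE`, `LYSM`, `OTHER_ECTO`). Precedence runs NBS-based > TX >
RLK > RLP > standalone RPW8 > TM-CC > NONE, which resolves
multi-signature genes in favour of the NLR side — the convention under
which the classes are mutually exclusive in a count table. Within the
NBS side, the subtype comes from the TIR/CC/LRR complement (TIR wins
over CC when both are present), and the RPW8 reclassification then
rewrites NBS → RN, NL → RNL and any of TNL/CNL/CN/TN (and TX) → OTHER.
TNL, CNL and RNL are flagged typical, everything else atypical.

Design points that were genuinely open:

* **TX among NLRs.** TIR-only genes lack NB-ARC, but the field's own
  groupings count TX among the NLR-side subtypes and in the atypical
  aggregate; the annotation does the same (`rga_class = "NLR"`,
  `nlr_subtype = "TX"`).
* **Bare NBS.** A gene carrying only NB-ARC keeps the distinct subtype
  mark `NBS` in the per-gene annotation, but the count-table layout has
  no NBS column, so `rgaCountTable()` tabulates it under OTHER. Whether
  published OTHER columns include bare-NBS genes is not stated
  anywhere we could check; the raw annotation preserves the
  distinction so either reading can be recovered.
* **Standalone RPW8** is a class of its own because published count
  tables carry a nonzero RPW8 column.
* **RLP** requires a transmembrane segment plus at least one ectodomain
  (LRR, LysM or other) and no kinase and no NB-ARC.

The classifier is exercised by exhaustive enumeration of all 512 domain
subsets; every subset must map to exactly one verdict, order of the
input labels never matters, and the structural invariants (subtype
assigned iff NLR-side, subclass assigned iff receptor, superfamily
TM-LRR iff receptor) hold on every subset.

# Landscape statistics and rounding

Densities are count/Mbp; percentages and means are reported with
round-half-even at 2 decimals. Published tables occasionally appear to
truncate instead (e.g. a class share of 272/1625 = 16.7385 printed as
16.73 where half-even gives 16.74); such values are cosmetic
differences and are not asserted anywhere. The per-chromosome mean
excludes contig rows — that is the only rule under which the published
per-species means (1613/8 = 201.62, 1622/9 = 180.22, 1246/12 = 103.83)
are reproduced.

The pairwise size-versus-count comparison counts unordered chromosome
pairs where the larger chromosome has **no more** RGAs than the smaller
one: ties in count are counted. This tie rule is the unique one that
reproduces all three published counts (11/10/30) from the packaged
tables, which contain two exact count ties.

Genes are assigned to 1-Mb windows (last window short) by their start
coordinate — the simplest convention, stated here because midpoint
assignment would differ for boundary-straddling genes. The end-bias
fraction is the share of genes whose start lies in the two distal 25 %
segments of their chromosome; uniform placement gives 0.5 in
expectation.

# Physical and similarity clustering

Physical clusters are maximal runs of genes (per chromosome, sorted by
start) whose consecutive **end-to-start** gaps are all ≤ the threshold
(default 10 kb), boundary inclusive; at least two members make a
cluster. Gap measured between neighbouring gene bodies — not
start-to-start — is the natural reading of an intergenic distance
threshold; both the threshold and the gene subset (all RGAs or one
family) are parameters. The sweep is verified against a brute-force
all-pairs transitive closure on random gene sets.

Sequence similarity uses global alignment with a deliberately simple,
fully stated scoring (match +1, mismatch −1, linear gap −2 via
`Biostrings::pairwiseAlignment`) and similarity = matching columns /
alignment columns. The original analysis' alignment parameters are not
recoverable, so this scoring is explicit, configurable, and never used
as a numerical target; it exists to expose relative similarity
structure to the average-linkage dendrogram, which `cutree` cuts into a
user-chosen *k* (the published dendrograms used 4 or 5 colour groups;
how that threshold was chosen is not stated, so *k* is a parameter with
default 4).

# Homologue filtering

The CDRH chain keeps a hit iff all three hold: E-value ≤ 1e-45
(reported E-values of zero, "E0", are the strong end of that range and
pass), similarity ≥ 60 %, alignment length ≥ 148 aa. The length cutoff
mirrors the smallest protein in the cloned R-gene reference set
(148 aa); whether the original rule applied to alignment length or
subject length is ambiguous, so the filter applies it to alignment
length by default and the threshold is a parameter. No best-hit
selection is applied — homologue relations are many-to-many, and the
summaries (R genes with ≥ 1 homologue, multiplicity both ways, disease
rollup with per-disease deduplication) are defined on that basis.

The packaged R-gene catalogue is a **synthetic stand-in**: the file
keeps the R-gene names and disease associations that are printed in the
source literature and fills the remainder with clearly named synthetic
placeholders to reach the catalogue size of 49. Analyses that only need
identifiers and disease codes (filtering, rollups, simulation) are
unaffected; anyone with the real catalogue can drop it in via
`readRGeneCatalog(file)`.

# QTL co-localisation

Containment, not overlap: a gene is "within" a QTL iff
`qtl_start ≤ gene_start` and `gene_end ≤ qtl_end` on 1-based closed
coordinates (an `"overlap"` mode exists for sensitivity analysis).
Genes and QTL must share one coordinate system; the packaged table of
57 published Brassica QTL carries its coordinates exactly as printed on
their original assemblies, and a user-supplied chromosome-name map is
the only translation applied — coordinate lift-over between assemblies
is explicitly out of scope and must happen upstream. QTL on chromosomes
absent from the assembly are skipped with a warning rather than an
error, since a partial co-localisation is still meaningful.

# Phylogenetics

Distances are pairwise-deletion p-distances (columns where either
sequence is gapped are dropped per pair) corrected with the 20-state
Jukes-Cantor protein formula d = −(19/20)·ln(1 − (20/19)·p), which is
undefined at saturation p ≥ 19/20 — saturated pairs are an error, and
bootstrap replicates that hit saturation are skipped with the support
denominator adjusted. Pairwise deletion (rather than complete deletion)
keeps ragged receptor alignments usable.

UPGMA is implemented directly: size-weighted average linkage, merge
height = pair distance / 2, and ties broken by the lexicographically
smallest label pair (a cluster is labelled by its smallest leaf), which
makes topologies platform-independent. `stats::hclust` with average
linkage serves as an independent reference in the tests: on random
matrices the cophenetic matrices must agree to 1e-8, and on ultrametric
input the generating tree is reconstructed exactly. Bootstrap support
is the percentage of column-resampled replicates containing a rooted
clade with the same leaf set. Newick export goes through ape, whose
dialect replaces whitespace with underscores rather than quoting; the
original labels remain on the tree object.

# The synthetic generator

`generateGenome()` defines the study conditions under which the
pipeline is validated:

* **Class composition** defaults to the per-class totals of the
  packaged *B. nigra* count table (e.g. 325/1625 LRR-RLK,
  119/1625 TNL, 11/1625 RPW8), planted as exact canonical domain sets
  so the decision table inverts the planting — label recovery is
  therefore a sharp 100 % test, not a statistical one.
* **Positions** are drawn from a symmetric Beta(α, α) scaled to the
  chromosome, α = 0.5 by default. The end-accumulation of RGAs is
  reported only qualitatively in the literature, so the Beta law is the
  simplest symmetric stand-in, not a claim about real genomes; its
  closed-form distal-quarter mass (2·F(0.25) = 2/3 at α = 0.5)
  calibrates the end-bias statistic.
* **Chromosome sizes** default to the study genome's eight chromosomes
  scaled 1:10 (5.1-7.4 Mbp), keeping coordinates realistic in shape but
  simulations small.
* **Clusters** are planted with bounded inter-gene gaps and a 25-kb
  isolation guard zone in which no other gene is placed, so the 10-kb
  ground truth is unambiguous. Randomly placed genes may form
  additional clusters of their own; recovery is asserted as "every
  planted cluster appears exactly", not "no other clusters exist".
* **Proteins** are per-superfamily consensus blocks (90 aa) derived
  from one shared ancestral block with 40 % of positions resampled per
  superfamily, then 10 % per-gene mutation and a random tail. Shared
  ancestry keeps every cross-family p-distance below Jukes-Cantor
  saturation while leaving within-family similarity clearly higher —
  enough structure for the dendrogram and tree stages to recover
  families. No attempt is made to model real protein evolution, codon
  structure or synteny.
* **Homologue hits** for planted pairs are drawn inside the filter's
  acceptance region (one pair pinned at E-value 0 to exercise the E0
  boundary); decoys violate exactly one named rule each, so filter
  failures localise.
* **One integer seed** drives every draw; identical profiles produce
  byte-identical files.

What passing on synthetic data does **not** show: performance on real
annotations with noisy or partial domain calls (the generator plants
exact canonical sets), on overlapping gene models beyond what random
placement produces, or on real BLAST score distributions. The
synthetic results validate the algorithms' logic, not the upstream
domain-prediction quality.

# Problem sizes and determinism

The default validation sizes — 1000 planted RGAs plus 200 non-RGAs for
recovery runs, 10,000 positions for end-bias calibration, 100 random
matrices of up to 6 taxa for the tree oracle, 100-1000 bootstrap
replicates — were chosen as the smallest sizes at which each check is
sharp (multinomial and binomial noise well inside the asserted bands).
The quadratic pairwise-alignment stage runs on bounded subsets
(`similarity_n_max`, default 40) in the pipeline. All randomness flows
from explicit integer seeds; `runPipeline()` records its seed in
`summary.json` and two runs with one configuration are byte-identical.

# Known limitations

* Real-genome results depend on upstream domain prediction, which is
  out of scope here; the package consumes normalised domain calls.
* The similarity scoring and the dendrogram cut *k* are conventions,
  not inferences; conclusions about cluster membership should not rest
  on their defaults.
* Cross-assembly QTL coordinates are used as printed; without a proper
  lift-over the co-localisation of genes from a different assembly is
  approximate by construction.
* The packaged R-gene catalogue is partly synthetic (see above).
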