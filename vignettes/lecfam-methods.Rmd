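---
title: "Cataloguing lectin receptor-like kinase families: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing lectin receptor-like kinase families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lecfam)
```

# Scope

`lecfam` implements the classic genome-wide receptor-kinase cataloguing
workflow for lectin receptor-like kinases (LecRLKs): homolog collection by
percent-similarity screening, dual-domain family definition with G/L/C
lectin typing, transmembrane (TM) orientation classes, tandem-duplication
clusters, distance-based phylogenetics with bootstrap supports, and
FPKM-based tissue-specificity zones. External annotation engines (Pfam/
InterPro-style domain scans, TMHMM/SignalP-style topology prediction,
RNA-seq quantification) are deliberately *inputs*, consumed as tables;
maximum-likelihood tree inference and conserved-motif discovery are out of
scope. A synthetic-catalogue generator with complete ground truth makes the
whole chain testable without any downloads.

# Pairwise alignment and the homology screen

Alignment is exact affine-gap dynamic programming (Gotoh's three-state
recursion) over BLOSUM62 with gap open 10 and gap extend 0.2; a gap of
length $L$ costs $10 + 0.2L$. Both local (Smith–Waterman) and global
(Needleman–Wunsch) modes are implemented in C++ and are checked in the test
suite against a brute-force alignment enumerator on short peptides and
against `Biostrings::pairwiseAlignment` on random pairs (agreement to
single-precision rounding).

**Percent similarity** is defined as the number of alignment columns whose
substitution score is positive divided by the total number of alignment
columns, gaps included. This "positives over columns" definition is the
standard reading of percent similarity in alignment reports; whether gap
columns belong in the denominator is not recoverable from typical report
formats, so the choice is fixed here and documented. Identity uses the same
denominator.

The homolog search starts from one seed protein per expected lectin type,
collects all proteome entries with local-alignment similarity ≥ 0.30, and
re-queries with the highest-similarity hit not yet used as a query until no
new hits appear (bounded by `max_rounds`, default 5). This generalises the
manual two-to-three-round reciprocal protocol into a deterministic fixed
point.

Two significance gates accompany the similarity cut, and they matter. With
gap extension as cheap as 0.2, the optimal local alignment of two
*unrelated* proteins typically spans half their length, and its
percent-positives lands around 0.17–0.34 — the 0.30 threshold sits inside
the noise band of the similarity statistic itself. Real database screens
never face this because an alignment-significance filter (score/E-value)
runs first. `reciprocal_expand` therefore also requires (i) the
residue–residue columns to cover at least `min_coverage = 0.5` of the
shorter sequence and (ii) an alignment score of at least
`min_score_density = 1.0` per residue–residue column. Homologous
alignments in the regimes this package exercises score roughly 3–5 per
column, unrelated ones about 0.25, so the gate separates signal from noise
by an order of magnitude. Both gates are tunable and can be disabled; a
genuine homolog whose similarity hovers right at the 30 % floor would fail
the density gate, which is the documented trade-off.

Isoform handling follows the usual rule: the longest sequence per locus is
kept, with length ties broken by the lexicographically smallest identifier
for determinism.

# Domain model and typing

A protein is a family member iff it carries at least one lectin-role domain
hit *and* at least one kinase hit; everything else is rejected with a
reason (`no_lectin`, `no_kinase`, `neither`). The lectin role determines
the type: bulb (mannose-binding) lectin → G, legume lectin → L,
calcium-dependent lectin → C. A protein with two distinct lectin roles is
surfaced as an `ambiguous_type` error state, never silently resolved — no
such case occurs in curated catalogues, so it is treated as a data problem.

The default accession → role vocabulary uses Pfam-style names (`B_lectin`,
`Lectin_legB`, `Lectin_C`, `Pkinase`/`Pkinase_Tyr`, `S_locus_glycop`,
`EGF`/`EGF_CA`, `PAN_1`/`PAN_2`, `DUF3403`) and is fully overridable from
YAML, since published catalogues name domains rather than accessions.

A hit is **truncated** when it is at least 10 residues shorter than its
domain model (`end − start + 1 ≤ model_length − 10`). The 10-residue rule
is stated for lectin domains in the source literature; applying the same
rule to kinase domains is an extrapolation made here for symmetry, and
truncation is always reported rather than filtered — truncated-kinase
members remain members.

# Topology and the eight orientation classes

Topology models are ordered inside/membrane/outside segments tiling the
sequence. Membrane segments need probability ≥ 0.8 to be accepted; when one
is rejected, downstream side labels flip so sides keep alternating. A
signal peptide with score ≥ 0.7 that overlaps the first TM takes priority:
that TM is reinterpreted as the signal peptide, leaves the TM count, and
the mature chain starts extracellular. The priority rule is applied
*before* counting TMs; whether the original analysis counted such a TM
cannot be determined from the text, so this ordering is fixed and
documented. When no cleavage position is supplied, a conventional maximal
signal length of 40 residues is assumed.

A domain's side is the side (outside → extracellular, inside →
intracellular) covering a strict majority of its residues; an exact 50/50
split is `membrane_spanning`. Classes then follow the observed patterns:
one TM → I (lectin out / kinase in), II (in/out), III (out/out); two TMs →
IV (out/out), V (in/out), VI (out/in); three TMs → VII (out/in) and VIII
(in/out). Zero accepted TMs is `NO_TM`. Every other combination — e.g. one
TM with both domains inside, four or more TMs, or a membrane-spanning
domain — is `UNCLASSIFIED`, because the published table enumerates only the
eight observed patterns; the classifier is a total function and the test
suite verifies this by exhaustive enumeration. Multi-copy architectures
(the fused two-lectin/two-kinase protein of class VII) are classified from
the first lectin and first kinase by coordinate, with multiplicity kept in
the architecture string — this reproduces the published description without
inventing a voting rule.

The built-in fallback predictor (for proteomes without a topology table) is
a sliding-window Kyte–Doolittle hydropathy score (window 19, truncated at
the ends) squashed by a logistic centred at mean hydropathy 1.6; maximal
runs above 0.5 become membrane segments scored by their peak window, and
the side before the first TM is chosen by the positive-inside rule
(higher Arg+Lys fraction). It is a calibrated stand-in validated on
constructed fixtures, not a reimplementation of an HMM topology predictor,
and its thresholds are calibrated only against the package's own fixtures.

# Tandem clusters

The operational definition of "tandem repeat" is rarely stated in catalogue
papers, so it is fixed here as a dual criterion, both sides configurable:
two family genes are adjacent when they share a chromosome AND (at most
`max_intervening = 5` non-family genes lie between them OR their bp gap is
at most `max_gap_bp = 100000`). Clusters are maximal chains with ≥ 2
members; more than 20 members makes a **super tandem repeat region**.
Because both adjacency measures are monotone along the gene order, closure
over rank-consecutive family genes equals closure over all pairs; the test
suite verifies `find_clusters` against a brute-force union-find oracle over
all pairs on hundreds of random layouts. Scaffold-placed genes are excluded
from clustering but kept in the catalogue and reported separately,
mirroring the chromosome/scaffold split of published locus counts.

# Phylogenetics

The progressive MSA uses p-distances from pairwise global alignments, a
UPGMA (average-linkage) guide tree, and profile–profile merges where a
column pair scores the expected substitution score between residue
frequency profiles (gap frequency contributes zero) under the same affine
gap costs. Children at each merge are ordered by their smallest sequence
identifier and inputs are sorted internally, so the alignment is invariant
to input order.

Distances between aligned rows are $p$ = mismatches over shared non-gap
columns, corrected by the 20-state protein Jukes–Cantor analogue
$d = -\tfrac{19}{20}\ln(1 - \tfrac{20}{19}p)$, defined for $p < 19/20$;
saturated pairs are an error state. Neighbor joining is the classical
Saitou–Nei agglomeration; ties in the Q criterion take the lowest (i, j)
index pair, negative branch estimates are clamped to zero with the
pre-clamp lengths and total deficit preserved as attributes. On additive
matrices NJ recovers the generating topology and branch lengths exactly;
the acceptance suite checks 100 random trees of 4–12 taxa for exact
topological recovery (verified independently with `phangorn::RF.dist` and
`ape::nj` in the unit tests) and pre-clamp lengths to 1e-9.

Bootstrap supports resample alignment columns with replacement, rebuild the
distance+NJ tree per replicate, and report for each internal bipartition of
the full-data tree the fraction of replicates containing it. Replicates in
which some pair loses all shared columns (or saturates) are redrawn and
counted. On a constructed zero-homoplasy alignment every true clade reaches
support 1.0, and supports are bitwise reproducible under a fixed seed.
Maximum-likelihood inference is intentionally absent: the distance/NJ/
bootstrap path is the validation route the catalogue literature itself
uses, and reports the two approaches as nearly identical clusterings.

# Expression zones

A gene is *expressed* in a tissue type when FPKM ≥ 1 in **at least one**
sample of that type. Whether the original zoning used an any-sample or
all-samples rule within multi-sample tissue types is not stated; any-sample
is the default because zoning treats a tissue type as a unit, and a strict
`all_samples` mode is exposed as a flag. Zones over the four standard
types: I (no type expressed — equivalently FPKM < 1 everywhere, with
all-zero genes sub-flagged "undetectable"), II (all four), III (root only),
IV (bud only); everything else falls into the one-/two-/three-tissue
categories of the specificity table, whose rows and columns partition the
gene set and whose marginals are asserted on every call. Reproductive
(female/male) specificity applies the same rule to the two reproductive
types only. Which of the atlas samples count as standard-condition samples
is a concern of the grouping file, not hard-coded.

# The synthetic-catalogue generator

The generator emulates all five study inputs with configurable ground
truth. Domain "sequences" are fixed synthetic signature blocks with
distinct residue compositions per role (so the homology screen can find
them without real Pfam models); TM blocks are hydrophobic 21-mers and
linkers hydrophilic, so the fallback hydropathy predictor sees realistic
contrast. A (type, class) pair fixes a block layout whose domain
coordinates and topology segments are consistent by construction; class
VII/VIII layouts (three TMs, duplicated or reversed architectures) are
restricted to G-type members, matching the published catalogue, and a
config requesting them without G members is rejected. Family members are
the archetype mutated at `divergence_rate` (uniform substitution over the
19 other residues, so the expected p-distance to the archetype equals the
rate exactly — the closed form the tests use). Background proteins are
uniform random sequences; a configurable fraction carries a single decoy
domain, never a lectin and a kinase together, guaranteeing the dual-domain
filter's negative set.

Counts follow largest-remainder apportionment, so per-type, per-class and
per-zone counts equal the configured proportions exactly. Tandem clusters
are planted as consecutive loci with background spacer genes and > 100 kb
belts insulating everything else; scaffold genes are placed on unanchored
scaffolds. FPKM values realise the designed zones: designed-expressed
gene × tissue states draw a mean uniformly from `fpkm_expressed_range`
(default 5–100 FPKM; the lower bound must be ≥ 1 so designed states satisfy
the detection cutoff) with multiplicative log-normal replicate noise of SD
`fpkm_noise_sd`; designed-not-expressed samples are uniform draws on
[0, 1) — the sub-detection noise floor — and zone-I genes are exactly 0
(undetectable). The noise model is a stand-in (replicate noise is not
described for the source atlas): log-normal noise on expressed values is
the conventional RNA-seq variability model, while additive noise on the
[0, 1) floor would make the ≥ 1 rule flip a large fraction of
designed-silent tissues at any realistic SD, which no atlas shows. Defaults
mirror the published study conditions: 231 members (180 G / 50 L / 1 C),
the observed class mix including 45 members without TM, zone mix
78/28/22/45/58, one 21-member super cluster plus an 8-member L-type cluster
and smaller G clusters (the real genome carried three super regions; more
can be planted via `tandem_cluster_sizes`), 36 scaffold genes, a 12-sample
standard panel (2 root, 3 leaf, 2 stem, 5 bud) plus 2 female and 2 male
reproductive samples, 21 G + 9 L female-only and 9 G + 1 L male-only
genes, divergence 0.05 and FPKM noise SD 0.1. Everything is byte-identical
under a fixed config and seed.

What the generator does **not** emulate: indels and rate heterogeneity in
protein evolution, read-level RNA-seq noise, annotation errors, and real
inter-family sequence similarity structure. Passing the recovery tests
therefore demonstrates the pipeline's internal correctness — each stage
inverts the generative design exactly — not its robustness to the full
messiness of real genomes.

# Pipeline, problem sizes and numerical choices

`run_pipeline` composes the stages in order (isoforms → homology → domains
→ topology → tandem → phylogeny → expression → summary), logs one
structured line per stage, aborts with the stage name on failure, and
asserts cross-table marginal consistency in every summary. The provenance
block records all thresholds, the seed and an input fingerprint.

The tree stage caps its taxon set at `phylo_max_taxa` (default 60), taking
a deterministic subsample spread across types: the progressive alignment's
pairwise-distance phase is quadratic in family size, and a capped tree
keeps a full 250-member catalogue run under a minute on one core while the
monophyly questions the package answers (cluster clades) concern small gene
sets. Set the cap above the family size for a full tree. The acceptance
script runs the study-scale catalogue (250 members) clean and noisy,
100 NJ exactness cases and a 1000-replicate bootstrap, all chosen to
exercise the published problem scale.

Tie-breaks and degenerate inputs are fixed throughout: alignment traceback
prefers substitution over gaps; isoform ties take the smallest id; NJ Q
ties take the lowest index pair; identical sequences give zero-length
branches; empty catalogues flow through every stage and produce all-zero
tables; a protein with no topology model is UNCLASSIFIED; tissue types and
zones validate their label sets eagerly.

# Known limitations

* The homology screen's significance gates (coverage, score density) are
  package design choices; real screens tuned to marginal (~30 % positive)
  homologs would need the gates relaxed and a proper E-value model instead.
* The fallback topology predictor is intentionally simple; use a real
  predictor's table for production topology calls.
* The progressive MSA has no iterative refinement; for publication-grade
  alignments feed an external MSA to the distance/NJ/bootstrap stack.
* Group/subgroup labels of published phylogenies were drawn by eye on ML
  trees; automated group labelling is not attempted — monophyly checks are
  the supported primitive.
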