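---
title: "Surveying type VI secretion systems in annotated genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying type VI secretion systems in annotated genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

The type VI secretion system (T6SS) is a contact-dependent injection
apparatus that many bacteria use to deliver toxic effector proteins into
neighbouring cells. Comparative surveys of T6SS repertoires across a genome
panel ask a recurring set of questions: where are the T6SS gene clusters,
which of the five described subtypes does each belong to, what lives in the
variable genomic island that hosts a cluster in some strains but not others,
are there unusual sheath-gene architectures, and which genes look like known
effectors. `t6sscan` implements that survey as a reusable, deterministic
pipeline over standard annotated-genome inputs (GFF3 + FASTA or GenBank flat
files, plus HMMER-style family hit tables), with a synthetic-data generator
that plants known answers so every stage can be scored exactly.

# Pipeline stages and their models

## Gene-family assignment

Genes map to a closed vocabulary: the 13 core structural families
`tssA`–`tssM`, accessory families (PAAR, FHA, Pkinase, PP2C, DUF4150,
*tasL*, *tasR*, *vasH*, *impE*, *tagF*), and the two sheath Pfam domains
VipA (PF05591, small subunit) and VipB (PF05943, large subunit). Hits come
from an external HMMER3 `domtblout` table (an adapter parses the per-domain
lines; profile names map to family tokens through an optional name map), or
— for fixture-scale work — from `naive_assign()`, which locally aligns every
protein against one consensus sequence per family and keeps hits at
alignment identity ≥ 0.5 and E ≤ 1e−5. Each gene keeps at most one core
label (highest score; ties resolve alphabetically so results are
order-independent) and any number of accessory labels. Domain hits on one
protein are kept position-sorted; of any pair overlapping more than half of
the shorter hit, only the higher-scoring survives, which yields the clean
"two VipA + one VipB" strings the fusion caller consumes.

## Cluster calling

A T6SS cluster is a maximal run of core-labelled genes in which adjacent
core genes are separated by at most `max_gap = 10` non-core genes, retained
when it contains at least `min_core = 4` *distinct* core families. Counting
distinct families (not gene copies) is deliberate: a tandem array of *hcp*
copies must not satisfy the rule, which is what lets the scan skip auxiliary
effector/immunity clusters. The cluster's gene list runs from its first to
its last core gene, inclusive of intervening non-core genes; accessory genes
within `max_gap` genes beyond the ends are reported separately as flanking
accessory content. An incomplete cluster lying closer than `max_gap` genes
to a contig end is flagged truncated (left/right/both) — incompleteness next
to an assembly break is attributed to the break, not to gene loss; a
complete 13/13 cluster is never flagged. Both parameters are plain config
values; the gap rule counts genes, not base pairs.

Two properties are worth stating because they are tested: the scan is
symmetric (reversing a contig mirrors the clusters exactly), and while the
cluster count is monotone non-increasing in `min_core`, it is *not* monotone
in `max_gap` — a larger allowance can merge two valid clusters into one. The
quantities that are monotone in `max_gap` are containment (each cluster of
the stricter call lies inside one cluster of the looser call) and the set of
covered genes; the test suite asserts those forms against an independent
exhaustive segmentation oracle.

## Sheath phylotyping

Each cluster's TssB and TssC sequences are concatenated (TssB first; among
multiple tssC copies the one nearest the 506-aa reference length is used, so
a 1,684-aa fusion gene never displaces the true sheath subunit) and compared
by global alignment; the distance is one minus the alignment-column
identity. Subtype assignment is nearest-labelled-reference under that
distance with an `unclassified` cutoff at 0.7; ties resolve to the
alphabetically first reference id, making the result independent of
reference order. A neighbor-joining tree over the same distances (via
`ape::nj`, behind a pluggable `nj_tree()` contract) provides the clade
picture; on additive matrices NJ reproduces the input path lengths exactly,
which the tests check to 1e−9. Distances from pairwise global alignment
rather than a multiple alignment, and NJ rather than maximum likelihood, are
desk-scale design choices: deterministic, dependency-light, and sufficient
for placement against labelled references; an external ML tree can be
substituted through the same contract. Optional bootstrap support resamples
alignment columns (100 replicates, seeded, off by default).

## Island genotyping

The genomic island is delimited by two flanking marker genes — mannose-6-
phosphate isomerase (*manA*) and tRNA-Gly by default — located by product
token, never by coordinates, since draft assemblies reorder contigs. Both
flanks on one contig give a `resolved` island (length is flank-inclusive:
first base of flank A to last base of flank B). Flanks on two contigs are
accepted when the region is split by exactly one assembly break; which side
of each flank belongs to the island follows gene orientation (the island
runs downstream of flank A and upstream of flank B, the fixed polarity of a
marker/tRNA-delimited insertion site), and each island side must reach its
contig edge. Anything else is `unresolved` and excluded downstream.

Island proteins cluster into homolog families greedily, longest protein
first: a protein joins the first family whose exemplar it matches at local
identity ≥ 0.7 with mutual coverage ≥ 0.8, else founds a new family; tRNAs
group by product token. The resulting binary genome × family matrix is
clustered with average-linkage hierarchical clustering on binary Jaccard
distances. The number of genotypes is chosen by maximum mean silhouette over
k = 2…8, with one deliberate refinement: the mean is taken over genomes in
clusters of size ≥ 2. The silhouette of a singleton cluster is 0 by
convention, so a plain mean can never prefer a partition that isolates a
genuinely rare genotype — and rare island classes are expected here (one
archetype in the study conditions is a single genome in 34). Excluding
singletons from the score lets a rare genotype stand while still penalising
gratuitous splitting, since breaking a homogeneous cluster produces
zero-silhouette members, not singletons. Genotype indices are deterministic
(archetype order, then size).

Each genotype is labelled by rules evaluated per member island: a complete
T6SS cluster inside the island ⇒ `complete_T6SS2_plus_genes`; an incomplete
one ⇒ `incomplete_T6SS2_plus_genes`; no cluster but more than `min_genes =
3` non-flank genes ⇒ `no_T6SS2_with_genes`; otherwise `near_empty`.
Disagreeing members yield the majority label with a flag.

## Sheath architecture and effector screen

A protein's ordered VipA/VipB domain string classifies it: ≥ 2 VipA and
≥ 1 VipB is the TssC_L fusion signature; VipA only is TssB-like; VipB only
is TssC-like; a single VipA plus VipB is `other`, flagged for review rather
than guessed. For a fusion inside a cluster that also has standalone TssB
and TssC, each fused domain instance (extracted by its hit envelope, not by
fixed offsets) is globally aligned to the corresponding standalone domain
and reported with identity and E-value. Cluster repertoires follow: fusion
if any TssC_L; duplication if two or more TssC-like proteins and no fusion
(pairwise identity reported, with no evolutionary claim attached);
standard for exactly one TssB-like plus one TssC-like.

The effector screen locally aligns every query protein against a reference
effector database and keeps hits with alignment identity ≥ 30% and
E ≤ 1e−6, both inclusive, one best hit per query–subject pair. E-values are
BLAST-style, `E = m·n·2^(−bit)` with the bit score from the Karlin–Altschul
conversion using the standard gapped BLOSUM62 constants λ = 0.267,
K = 0.041 (config-overridable). The threshold is applied to identity; the
stricter reading of "similarity" as identity is intentional, since counting
positive-scoring substitutions would only loosen the filter.

## Alignment engine

Global (Needleman–Wunsch) and local (Smith–Waterman) alignment with affine
gaps run on `Biostrings::pairwiseAlignment` behind the package's own
surface, at BLASTP defaults: BLOSUM62, gap open 11, gap extend 1, a gap of
length L costing 11 + L. A local alignment with no positive-scoring pair
returns the empty alignment with score 0. Percent identity supports two
denominators — alignment columns (default; gap columns count) and shorter
sequence — because published identity figures rarely state theirs. The test
suite verifies both modes against a hand-written Gotoh three-state DP and,
for very short strings, against exhaustive enumeration of all alignments.

## ANI species assignment

ANI computation is out of scope; a FastANI-style long table is an input.
Queries join the species of their maximal-ANI labelled reference when that
ANI is ≥ 95 (inclusive), otherwise stay unassigned; query pairs at ANI 100
are flagged as likely clones; tables asymmetric beyond 0.5 ANI points are
rejected.

# The synthetic study conditions

The generator's defaults are the study conditions, not tuning knobs. The
default panel holds 34 island-panel genomes whose manA…tRNA-Gly genotypes
are apportioned by largest remainder over the archetype proportions
52.9 / 2.9 / 11.8 / 11.7 / 20.6% (the gene-bearing, cluster-free class split
across two archetypes), yielding counts 18 / 1 / 4 / 4 / 7, plus 6
roseobacter-style genomes (4 fusion, 2 duplication). Every genome carries:

* a chromosome-1-style T6SS (11/13 cores, missing *tssD* and *tssI*, with
  PP2C/Pkinase/FHA accessories) in the island panel, or a 12/13 cluster
  missing *tssJ* with PAAR/FHA/impE in the roseobacter set;
* an island realisation per genotype: the complete-cluster genotype carries
  all 13 cores plus tasL/tasR/vasH/FHA/Pkinase/DUF4150 and shared island
  gene pools; the incomplete genotype is an assembly-broken twin (contig
  break after *tssJ*, three cores lost at the break, island joined across
  one break); two gene-bearing genotypes carry disjoint shared pools; the
  near-empty genotype realises the 11.2-kbp lower bound of the island size
  range, with the other genotypes padded into the reported 11.2–106.2 kbp
  span;
* one planted effector homolog (60% identity to a database entry) and
  composition-matched random decoy genes.

Sequence-level control comes from `mutate_sequence()`, a substitution-only
mutant with an exact positional identity (`round(target × length)/length`
matches). Family genes are per-genome mutants at identity 0.92 of a fixed
reference panel, so within-family pairwise identity (~0.85) sits safely
above the 0.7 homolog threshold while cross-family identity (random
sequences) sits far below. Sheath genes derive from per-set bases: two
clades at 0.80 and 0.72 identity to the subtype-1 reference (so the two
chromosome systems form two clades within one subtype) and a roseobacter
clade at 0.80 to subtype 3. TssC_L fusions are composed per genome from
that genome's own TssB/TssC at the planted domain identities 0.86 / 0.26 /
0.31, so the identity report has an exact target; duplicated tssC copies
are planted at 0.35.

All randomness flows from the single config seed; the generator writes
byte-identical output under a fixed seed, and the truth JSON is sufficient
to score every stage.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: indels and codon-level evolution (mutants are
substitution-only, so alignment identities are exact rather than estimated),
profile-HMM search behaviour (hits are planted or produced by the naive
aligner), horizontal transfer signatures, paralogy outside the planted
duplications, annotation errors, and auxiliary Hcp/VgrG satellite clusters
(explicitly out of scope for the scan). Real-data runs should treat the hit
table and its thresholds as the main sensitivity knobs.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GFF/GenBank serialisation is
  1-based inclusive, so `length = end − start` holds internally everywhere.
* Deterministic tie-breaks throughout: gene ordering by (start, end, id);
  core-label ties alphabetical; subtype ties by reference id; multiple tssC
  copies by distance to the 506-aa reference length then id; genotype
  indices by archetype then size.
* Traceback ties in alignment are delegated to the engine; scores (which are
  tie-free) are what the oracles check.
* Degenerate inputs: empty contigs scan to empty cluster sets; fewer than 3
  taxa yield a degenerate single-edge tree with a warning; an all-identical
  presence matrix returns one genotype with a warning; a zero-length local
  alignment has undefined (NA) identity, distinct from 0.
* Problem sizes are chosen for a single-CPU desk run: the exhaustive
  cluster-rule sweep covers all 4-token family strings to length 6 under two
  parameter settings where both rules bind (the rule is degenerate for short
  strings at the defaults — no string under 13 genes can contain a gap above
  10), plus seeded random contigs to length 26 at the defaults; NJ
  consistency uses 50 random additive matrices on 4–8 taxa; subtype recovery
  uses 120 simulated queries; determinism is double-run on a reduced
  10-genome panel.

# Known limitations

Subtype assignment is nearest-neighbour against user-supplied references,
not clade inference: a query deeper than the reference radiation can be
assigned to the nearest subtype without genuinely belonging to it — the 0.7
cutoff is the only guard. Homolog families use greedy single-linkage through
exemplars, which can chain in dense identity landscapes (not in the planted
conditions, where identity is bimodal). The E-value model uses fixed
Karlin–Altschul constants rather than sequence-composition corrections, so
absolute E-values are indicative, not BLAST-identical. The GenBank parser
covers the flat-file subset the pipeline itself writes (single-interval
CDS/tRNA features with translations), not the full format.
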