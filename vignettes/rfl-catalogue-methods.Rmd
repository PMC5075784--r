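---
title: "Cataloguing restorer-of-fertility-like PPR genes: models and methods"
author: "RFLfinder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing restorer-of-fertility-like PPR genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Restorer-of-fertility (RF) proteins suppress the expression of
mitochondrial open reading frames that cause cytoplasmic male sterility
(CMS), the trait that underpins hybrid seed production in rice and other
cereals. Almost all cloned RF proteins belong to the
restorer-of-fertility-like (RFL) clade of P-class pentatricopeptide
repeat (PPR) proteins: RNA-binding proteins built from tandem arrays of,
typically, 15 to 20 degenerate 35-amino-acid helical repeats. RFL genes
sit in fast-evolving genomic clusters, are essentially intronless, and
diverge by point mutation plus motif-scale duplication, deletion,
insertion and unequal crossing over.

Because the genes are intronless, they can be annotated directly from
six-frame translations of genomic DNA, without gene models. `RFLfinder`
implements that annotation pipeline end to end, together with the
downstream analyses that characterise an RFL catalogue: subfamily
identification by independent clustering and phylogenetic strategies,
genomic cluster statistics, PPR-code recognition statistics and
motif-level event histories. A synthetic-genome generator with full
ground truth makes every stage testable against planted answers.

## ORF extraction

`sixFrameOrfs()` enumerates maximal stop-free codon runs (stop-to-stop;
runs truncated by contig edges are included) in all six frames and keeps
runs of at least `minCodons = 93` codons — ORFs strictly longer than 92
codons. There is no start-codon requirement: a tandem-repeat gene's
reading frame is the object of interest, not its translational start,
and requiring ATG would fragment the catalogue. Codons containing N
translate to X; X never terminates a run but scores as a mismatch during
motif scanning. Coordinates are held as `GRanges` (1-based, closed, on
the forward strand), which maps one-to-one onto GFF3 output.

## Motif model and tiling

The P motif is modelled as a position-specific log-odds profile
(`buildProfile()`). For residue $a$ in column $i$,

$$\mathrm{logOdds}[i][a] = \log_2
\frac{(c_{ia} + \kappa b_a)/(n_i + \kappa)}{b_a},$$

with $c_{ia}$ the residue count, $n_i$ the non-gap count of the column,
$\kappa$ the pseudocount mass (default 1) and $b_a$ the background
frequency (default uniform). Scores are in bits; they are analogous to,
but not identical with, profile-HMM bit scores, so score distributions
should be compared as shapes and orderings, not absolute values.
Columns with less than 50% occupancy are rejected rather than guessed.

`scanAndTile()` scores every offset of every profile, keeps candidates
at or above the hit threshold (default 8 bits), and selects the
non-overlapping subset maximising total score by weighted-interval
scheduling. Eight bits is deliberately permissive: the profile is meant
to detect the whole P-class family, including anciently diverged
paralogs, and false candidate hits are removed by the tiling step and
the downstream 10-motif retention rule, not by the threshold. Score
ties are broken toward earlier starts, then P over L over S, making the
tiling deterministic. No maximum gap between adjacent motifs is
enforced — tandem-ness is characterised downstream, not assumed.

Classification: a protein is *P-class* when it carries at least 10 P
motifs and at most 2 L/S motifs — the retention rule of the pipeline,
chosen because RFL proteins carry 15–20 motifs and shorter six-frame
fragments are overwhelmingly pseudogene debris. *PLS-class* requires at
least two consecutive P,L,S triplets; this is a documented
simplification (the pipeline only needs the P-class filter), and
PLS-subclass domain detection is out of scope.

## RFL identification

Three strategies isolate the RFL subfamily within the P-class set, and
a consensus report partitions their union by membership signature.

**Pairwise identity.** All strategies rest on `pairwiseIdentity()`:
Needleman–Wunsch global alignment under match +1, mismatch 0, affine
gaps (open −10, extend −0.5). Identity is matches over the columns in
which *both* sequences have a residue; coverage is the fraction of the
shorter sequence aligned opposite residues of the longer. Counting
identity over aligned residue columns (rather than all alignment
columns) mirrors the local-identity semantics of CD-Hit's `-G0` mode
and keeps a motif-level deletion from diluting the identity of the
repeats that still align — without it, a 10-motif paralog of an
18-motif gene scores ~0.5 against its own ancestor.

**Greedy identity clustering** processes sequences by decreasing length
(ties lexicographic) and joins the first cluster whose founder matches
at ≥ 40% identity with ≥ 10% coverage of the shorter sequence — the
published CD-Hit thresholds (`-c 0.4 -aS 0.1`). The k-mer prefilter of
CD-Hit is a speed device, not semantics, and is omitted. A single run
across divergent species fails to merge their RFLs (cross-species RFL
identity falls below 40%); per-species invocation is the documented
remedy.

**Orthogroup clustering** builds the all-vs-all similarity graph with
edge weight identity × coverage, prunes edges below 0.25, adds self
loops, and runs Markov clustering (inflation 1.5, convergence at 1e-6,
at most 100 iterations); clusters are the connected components of the
converged flow matrix. The pruning and inflation defaults are exposed
in configuration.

**Phylogenetic clade extraction** builds a neighbor-joining tree on the
distance 1 − identity (same-family, intronless proteins align
globally), midpoint-roots it, and returns the smallest clade containing
all reference RFLs. NJ with midpoint rooting replaces the
MAFFT + approximate-ML tooling used at genome scale: at desk scale the
deliverable is clade membership, not branch support, and NJ on additive
distances is exact. Negative NJ branch lengths are clamped to zero.

For the clustering strategies, the RFL set is the union of clusters
containing at least one reference, minus the references; the pipeline's
final RFL set is the consensus core (ids found by every method).

## Genomic clusters

A genomic cluster is two or more RFL genes at one chromosomal location.
`callClusters()` chains loci whose inter-locus gap is at most `maxGap`
(default 300 kb): large enough that the genes of one ~500-kb cluster
window chain together, small enough that clusters on opposite
chromosome arms stay separate. Percentages of genes in clusters are
reported as nearest integers (half away from zero). `regionAssign()`
labels loci lying strictly between ordered flanking anchor genes (the
Rf-region intervals of the rice chromosome-10 cluster).

## PPR-code statistics

The amino acids at motif positions 5 and 35 (1-based within the 35-mer)
specify the RNA base a P motif binds. `extractCombos()` tallies the
(aa5, aa35) pairs per group; `comboEnrichment()` applies a two-sided
Fisher exact test to each of the 25 most frequent P-class combinations
(combo vs rest × group vs group), flagging p < 0.01 with no
multiple-testing correction — the bare p-threshold is the documented
choice, and both the test and the correction policy are configurable.
`predictTargets()` maps motifs N-terminal-first to bases (the amino
terminus contacts the 5′ end of the target); unknown combinations yield
N. `baseComposition()` takes combinations in decreasing frequency until
their cumulative frequency reaches 50%, maps them through the code
table, drops N and renormalises.

The shipped code table contains the canonical purine pairs TD→G, TN→A,
SD→G, SN→A and the C-recognising NS and NT, plus ND→U, GD→G and GN→A
flagged as extended entries: GD/GN are treated as purine-recognising in
line with their accepted code assignments, and users may supply their
own 3-column TSV instead.

## Motif evolution

`motifDistanceTree()` computes p-distances (Hamming fraction over the
35 positions) between motif instances and hands them to NJ.
`labelMotifs()` discretises motif relatedness by single-linkage
clustering at ≥ 80% identity — high enough that recent duplicates share
a label, low enough that anciently diverged motifs do not.
`diffArchitectures()` formalises event calling between two label
strings: if the strings are permutations of each other, a displaced
block is reported as a *transposition* first; remaining differences are
resolved by a minimal insertion/deletion script (unit costs, via
longest-common-subsequence alignment), and an insertion adjacent to an
identical label is upgraded to a *duplication*. The event vocabulary
has no substitution operation, so minimality is with respect to
indel-only edit distance. Every emitted script replays exactly:
`applyEvents(a, events)` reproduces `b`.

## The synthetic generator

`generateGenome()` produces the study conditions all end-to-end tests
run under. Defaults: five 160-kb chromosomes; three RFL clusters of 3–5
intronless genes grown from a sampled ancestral architecture of 15–20
motifs by tandem duplication within a window; two singlet RFL genes;
six dispersed background P-class PPR genes of 10–14 motifs; and a light
scatter (0.02/kb) of non-PPR ORFs of 100–200 residues. Each placed gene
derives from its ancestor by motif-level events (duplication 0.15,
deletion 0.15, insertion 0.05, transposition 0.05, unequal crossover
0.10 per gene — modest rates that make events common across a cluster
but keep most architectures interpretable) followed by point mutations
(0.05 per variable residue). Proteins are reverse-translated with
uniformly sampled synonymous codons, which makes in-frame stops
impossible by construction, and are placed on either strand with
probability 1/2. Each RFL cluster or singlet occupies its own
chromosome, mirroring the one-cluster-per-chromosome organisation of
the real genomes and keeping planted clusters from chaining into one
call.

Motif positions are modelled in three tiers. A six-position structural
core is never touched by family-level divergence, so every PPR gene —
background families included — remains detectable by one scanning
profile, exactly as a family-wide profile HMM detects anciently
diverged paralogs. The code positions 5 and 35 are drawn per motif from
group-specific combination biases (`defaultComboBias()`): the P-class
background is dominated by TD/TN with common NS/NT, while the RFL bias
doubles SD and SN, makes GD/GN unusually common and NS/NT rare —
reproducing the purine shift of RFL target predictions. Redrawing the
code positions in every gene copy models the diversifying selection
that makes these two positions the fastest-evolving sites of the motif.
The remaining variable positions carry family divergence (default 1.0:
background families are unrelated to the RFL flavour at these sites),
ancestral motif heterogeneity (0.15, so tandem motifs are
distinguishable and label-able) and the per-gene point mutations.

These tiers were chosen to give the planted families a clean
within/between identity separation (roughly 0.6–0.9 within the RFL
family versus ~0.2 across families) while keeping background motifs
~20–30 bits above the hit threshold. The training alignment for the
scanning profile (`simulateMotifAlignment()`: 150 motifs, 95% core
conservation, 80% variable-position divergence, code positions from a
50/50 bias mixture) emulates the diversity of a family-wide motif
collection rather than a single clade.

What the generator does *not* emulate: introns and spliced gene models,
transposable elements, codon-usage bias, GC heterogeneity, assembly
gaps, real HMMER bit scores, and the deep coalescent structure of
multi-species data (its "species" tag is a single label). Passing
end-to-end tests therefore demonstrates that the pipeline's logic
recovers planted structure under realistic geometry and divergence —
not that its thresholds are optimal for any particular real genome.

## Numerical choices and problem sizes

All randomness flows through explicit seeds; `generateGenome()` is
byte-reproducible for a fixed spec. The tiling DP breaks score ties
toward earlier starts, then class priority; greedy clustering breaks
length ties lexicographically; MCL is deterministic. The test suite
runs the default generator spec (about 0.8 Mb of genome, ~900 candidate
ORFs, ~20 P-class proteins) once and a larger spec (eight clusters,
45 background genes, ≥ 500 motifs per group) once for the
frequency-convergence and enrichment checks; these sizes keep every
property exercised at full depth while the whole suite stays
desk-scale. Known degenerate inputs are handled explicitly: empty
FASTA, contigs shorter than a codon, proteins shorter than a motif,
empty groups in summaries, zero-locus species (warned, reported as 0%),
and all-N code predictions (an error rather than a silent 0/0).

## Limitations

The profile model has no insert/delete states, so motifs interrupted by
indels score as mismatch runs; E-values are not calibrated, and the
8-bit threshold is a calibration knob, not a significance statement.
The greedy clustering reproduces CD-Hit's thresholds but not its exact
alignment heuristics, and the orthogroup method is a desk-scale
analogue of BLAST-graph Markov clustering, not a reimplementation of
any specific tool. Event calling between architectures reports one
minimal script; co-optimal scripts exist and the chosen one is a
convention (left-to-right, duplication preferred over insertion when
adjacent). Recombination-event detection within genes and synteny
visualisation are out of scope; the package emits the underlying locus
and region tables instead.
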