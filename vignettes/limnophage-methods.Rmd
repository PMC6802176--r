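---
title: "Models and methods behind limnophage"
author: "limnophage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind limnophage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(limnophage)
```

# Scope

limnophage re-implements the bespoke computational stages used to mine
complete phage genomes from deeply sequenced freshwater metagenomes and
to follow them through a stratified-lake time series: circular-contig
discovery, dereplication of near-identical genomes, a whole-proteome
("proteomic") tree, multi-channel host prediction, and
fragment-recruitment abundance profiling. A synthetic-community
generator produces every input the pipeline consumes together with a
machine-readable ground-truth ledger, so each stage can be validated
against planted truth.

Read preprocessing, assembly, phage-confirmation screens, MAG binning
and taxonomy, gene-sharing network classification, and functional
annotation are deliberately out of scope; the discovery stage accepts
an external keep-list to emulate a confirmation filter where one is
available.

# Sequence primitives

## Seed-and-extend aligner

All genome-scale nucleotide comparisons go through one local aligner:
exact k-mer seeds (default 13 bp) shared between query and subject are
grouped per diagonal, and each seeded diagonal is scanned ungapped with
+1/-2 scoring. The match profile along a diagonal is segmented wherever
a mismatch run alone would exceed the X-drop (default 30, i.e. 16
consecutive mismatches), and each candidate segment is reduced to its
maximal-scoring subsegment, which sheds low-identity random flanks
exactly as X-drop extension would. Collinear segments on nearby
diagonals (shift of at most 50, separation under 100 bp) are chained
into gapped hits with affine penalties. Both subject strands are
scanned; the query strand is always "+".

This design is adequate here because every downstream threshold is
high-identity (95-97%), where exact 13-mer seeding loses essentially
nothing: at 95% identity the expected spacing between exact 13-mers is
far below the minimum alignment lengths in use. The aligner makes no
claim of sensitivity in the twilight zone and is not a general BLAST
replacement.

Translated comparisons translate all six reading frames (translation
table 11) of both sequences, seed with exact 4-mers of amino acids, and
score seeded diagonals with BLOSUM45. A two-hit rule (two seeds within
40 residues on one diagonal, or at least three seeds) gates extension,
as in standard translated search; segments are split where a negative
stretch alone exceeds the X-drop (default 40) and reduced to their
best-scoring subsegment. Hits are kept at expectation <= 1e-3.

## Expectation values

Significance uses the Karlin-Altschul form E = K m n exp(-lambda S)
with fixed, documented constants per scoring scheme: (K = 0.46, lambda
= 1.28) for +1/-2 nucleotide scoring, (K = 0.0924, lambda = 0.229) for
ungapped BLOSUM45, and (K = 0.032, lambda = 0.195) — the published
gapped BLOSUM45 (14/2) constants — for the gapped protein alignments
used in marker detection. Exact calibration is not required: every use
is a threshold comparison at a generous margin (real signals in this
problem sit orders of magnitude below the cutoffs; chance alignments
orders of magnitude above).

## ORF calling

A deliberately simple ORF caller stands in for a dedicated gene
predictor: maximal ORFs in all six frames, starts ATG/GTG/TTG (all
translated as M), table 11, minimum 30 aa, ending at a stop codon or
the sequence end. Circular genomes are scanned on their doubled
sequence so ORFs may span the origin. On synthetic gene-dense genomes
this recovers every planted gene; on real data a dedicated predictor
would be preferred, and the stand-in status is documented on the
function.

# Discovery of complete phage genomes

A contig assembled from a circular template carries a terminal direct
repeat. `detectCircularity()` anchors candidate repeat lengths with
exact prefix words (tried at three offsets, so a single mismatch in the
first word cannot hide a repeat), verifies the full repeat allowing at
most 1 mismatch per 100 bp, and trims the trailing copy so each genome
base is counted once. The default minimum overlap of 20 bp is the
standard assembler-overlap signature; the underlying study cites an
external procedure without printing parameters, so the value is
configurable. Candidates must exceed 10,000 bp after trimming
(strictly, matching the printed "> 10 Kb"), and are annotated with GC,
ORF count and size class: miniphage below 15 kb, megaphage above
200 kb, both strict.

# Dereplication

Pairs of genomes are compared with the nucleotide aligner; hits at
e-value < 1e-3 and > 95% identity (both strict, matching the printed
filters) contribute their merged interval union to per-genome aligned
coverage, so coverage never exceeds 1. Where the source text prints
">= 95%" for coverage and "> 95%" for identity, each is applied at its
printed strictness. Genomes with mutual coverage >= 95% are linked and
clusters are single-linkage connected components; the longest member
represents each cluster, with equal lengths broken by lexicographically
smallest id for deterministic output. Whether coverage should count
merged intervals or summed hit lengths is not printed; the merged-
interval union is used because it is bounded by 1.

# Proteomic tree

For each unordered genome pair the scores of all significant translated
hits (e <= 1e-3, BLOSUM45) are summed into a comparison score S(A,B);
self-comparisons S(A,A) include every significant self-hit, paralogous
off-diagonal hits included, exactly as the summation rule implies. The
Dice coefficient 2 S(A,B) / (S(A,A) + S(B,B)) is subtracted from 1 to
give a distance in [0, 1], clamped against small numerical excursions.
Reciprocal-frame overlap in the hit sets is not deduplicated — all
significant hits are summed as printed.

Trees come from canonical neighbor joining. To emulate the cited
relaxed-NJ generation of many equally valid topologies, seeded runs
permute the leaf order and draw each join uniformly among pairs whose
Q-criterion lies within epsilon (default 1e-9 times the largest
distance) of the minimum. The default of 100 alternative topologies is
a desk-scale stand-in for the study's 10,000 and is configurable.
Negative branch lengths are clamped to zero. The consensus is strict
majority rule: bipartitions present in more than half of the input
trees (counted directly; majority bipartitions are always mutually
compatible) with support equal to their observed frequency. The source
does not print its consensus rule; strict majority is the conventional
choice.

# Host prediction

Four evidence channels, in decreasing precedence:

* **CRISPR spacers** (strain resolution). A CRT-style detector finds
  at least 3 near-identical repeats of 23-47 bp (at most 1 mismatch to
  the column-majority consensus) separated by 26-50 bp spacers; the
  bounds follow CRT-family defaults because the study names its tool
  without parameters. Spacers are matched against phages at the printed
  stringent cutoffs: alignment >= 30 bp, identity >= 97%, spacer
  coverage >= 97%, e <= 1e-5.
* **tRNA/attB integration sites** (strain). tRNA loci are consumed as
  annotations (BED/GFF3) rather than detected de novo — tRNA scanning
  is outside the described computation. Phage-host hits passing the
  printed cutoffs count only when they overlap an annotated locus by at
  least 20 bp (a chosen, documented minimum).
* **Shared nucleotide sequence** (strain). The same per-hit cutoffs
  applied to the whole-genome comparison. The printed ">= 97% query
  coverage" is meaningful for a spacer query but would exclude a
  prophage-like region that covers a fraction of a whole-phage query,
  so for this channel the length/identity/e-value cutoffs are applied
  per hit; the ambiguity is noted here deliberately.
* **Marker genes** (phylum only). Phage ORFs are aligned to
  taxon-labelled marker proteins (WhiB-family transcription factors in
  the motivating system); evidence requires >= 30% identity over
  >= 70% of the marker with e <= 1e-5. The study states only that the
  marker's presence is characteristic; these thresholds are package
  choices, documented and configurable.

`assignHost()` resolves the channels with the precedence above; within
the winning channel the host with most evidence records wins, ties are
reported as ambiguous, and the call is a pure function of the evidence
multiset. Spacer hits are not required to be unique to one host before
assignment — all links are reported and resolved at the call step.

# Abundance profiling

Reads are recruited to genomes by exact 21-mer seeds at several offsets
along the read (both orientations), verified base-by-base at the seeded
placement; a read counts for a genome only when its best placement has
identity > 95% over >= 50 bp, the printed recruitment cutoffs. The
ungapped verification is appropriate for short substitution-dominated
reads. Mates are treated independently, as the read-wise mapper named
in the study implies. Reads tying across genomes go to the first genome
with a warning (configurable to count-all); probabilistic multi-mapping
resolution is a non-goal.

"Coverage per gigabase" is interpreted as mean per-base depth over
unmasked positions divided by the sample size in gigabases — the only
reading consistent with cross-sample comparability of the published
heatmaps. rRNA intervals are masked to N before recruitment and
excluded from both depth and breadth denominators. A genome is present
only above 80% breadth (strict). Read subsampling (the 20-million-read
cap) applies to the microbial-genome path; phage profiling uses full
read sets; both behaviours are flag-controlled. Z-scores are computed
per genome across samples with the population standard deviation
(constant rows map to zero), and profiles are clustered with average
linkage on 1 minus Spearman rank correlation, rows pre-sorted by id for
deterministic output.

# Protein catalog

Greedy longest-first clustering (CD-HIT style): proteins sorted by
decreasing length join the first cluster whose representative they
match at the identity level (30% and 60% are the canonical levels) over
at least 80% of the shorter sequence; the coverage criterion is not
printed in the source and is documented and configurable here.
Cluster-level dataset uniqueness (all members from one dataset) gives
the per-habitat novelty counts.

# Synthetic communities

The generator's defaults are the study conditions, fixed once:

* 20 phage genomes, of which four replicate groups (sizes 3, 3, 2, 2)
  model repeated capture of persistent phages; copies carry 1%
  substitutions (the dereplication regime spans 0-2% in tests).
* genome lengths from a two-mode log-normal mixture (modes 15 kb and
  40 kb — the two most frequently recovered sizes — weights 0.45/0.55,
  sdlog 0.06/0.35) truncated to the printed extremes 13,500-446,000 bp.
* per-genome GC drawn from N(0.45, 0.05) clipped to [0.30, 0.65],
  matching the habitat-mirroring GC range of freshwater phages.
* 5 host genomes of 200 kb. Real host genomes are megabase-scale; the
  reduced length keeps desk-scale runtimes and costs nothing in
  validity because every detection step (CRISPR arrays, attB loci,
  shared regions, alignment thresholds) is length-independent.
* planted host links on replicate-group founders or singletons only
  (so the link ledger maps one-to-one onto dereplicated
  representatives): spacer links to hosts 1-2, an attB link (45 bp of
  a tRNA 3' end) to host 3, a 5 kb prophage-like shared region with
  host 4, and WhiB-like marker genes (one phage with a single copy,
  one with two) for host 5's phylum.
* paired 2 x 151 bp reads with substitution errors at 0.005 — indel
  realism is unnecessary for threshold-driven stages, so the error
  model is substitution-only by design.
* a ten-sample time series (five epilimnion, five hypolimnion; the
  first and last dates are mixis) with three abundance regimes:
  boom-bust epilimnion peaks (15x in at most two samples), persistent
  hypolimnion presence (8x with 30% spread across most hypolimnion
  samples), and mixis-shared appearance (10x in the mixed-column
  samples). Background is 0.05x, far below the presence threshold.

Genomes are built gene-dense (random codon genes of 80-400 aa with
short intergenic spacers) so that translated comparisons, ORF calling
and marker planting operate on realistic coding content; origins are
rotated before link planting so ledger coordinates refer to the emitted
linearisation; contigs append a planted terminal repeat of 80-150 bp.

What the generator does *not* emulate — assembly artefacts, chimeras,
strain microdiversity gradients, uneven coverage, indels, quality-score
structure — bounds what green tests mean: they demonstrate correctness
of the implemented rules and thresholds on data that satisfies the
stated assumptions, not robustness to real-metagenome pathology.

# Numerical and design choices

* Coordinates are 0-based half-open internally and 1-based inclusive in
  all emitted files; minus-strand subject hits are written with
  sstart > send, the common tabular alignment dialect.
* Translated hits report protein-level alignment length; consumers
  needing base pairs multiply by 3.
* Ties everywhere break deterministically (lexicographic ids, row-major
  first minimum) unless a seed explicitly requests randomised
  tie-breaking.
* Dereplication clustering is invariant to input order, and
  dereplicating representatives is idempotent; both are tested.
* The test and validation problem sizes (3.5-4 kb genomes for the
  50-genome dereplication oracle, 20 kb contigs for the circularity
  trials, the 20-phage default community end to end) are the package's
  chosen desk-scale conditions; the underlying study operated on
  terabases, and its headline counts are expressly not reproducible at
  this scale.

# Known limitations

* The aligner's segment-wise best-subsegment extension can split one
  moderate-identity alignment into several hits where true X-drop DP
  would keep one; at the >= 95% regimes in use this does not occur.
* E-values are calibrated by fixed constants, not by simulation per
  scoring scheme; they are honest to within the margins the thresholds
  allow, and no decision in the pipeline is sensitive to factor-level
  e-value error.
* CRISPR repeat extension requires exact agreement across copies while
  extending (mismatch tolerance is enforced against the consensus);
  heavily degenerate repeats would need a dedicated detector.
* Host genomes and marker families in the generator are idealised; the
  marker channel's false-positive behaviour on real, diverse proteomes
  is not characterised here.
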