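---
title: "Splice-event quantification in psiquant: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-event quantification in psiquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`psiquant` quantifies alternative splicing as *events* on a per-gene
splice graph rather than as isoform abundances.  The procedure has four
stages.

**1. Graph construction.**  All protein-coding transcripts of a gene are
overlaid and their exon intervals fragmented at every distinct transcript
boundary — donors, acceptors, and transcript start/end positions alike.
The resulting *exon parts* are pairwise disjoint and jointly cover the
gene's exonic territory, so each genomic base belongs to exactly one
part.  Fragmenting at transcript termini (not only at splice sites) is
what guarantees this uniqueness when alternative first or last exons have
staggered ends.  Parts that are genomically contiguous form one exonic
*region* and share an ordinal, with sub-labels in transcription order
(`2.1`, `2.2`); regions are numbered 1, 2, 3, … in transcription order,
i.e. in reverse genomic order on the minus strand.  Splices are derived
from each transcript's consecutive exon pairs.  Internally all
coordinates are 0-based half-open; GTF input and every exported table use
the 1-based inclusive convention, so the conversion lives at one tested
I/O boundary.

A part is flagged coding if any transcript's CDS overlaps it.  Genes with
a single transcript still get a graph (and an empty event catalog), so
downstream handling is uniform.  Transcripts that disagree on chromosome
or strand within one gene model (e.g. trans-spliced annotations) are
rejected with a warning rather than guessed at.

**2. Event enumeration.**  Seven detectors read the graph topology:

* **ES** — a splice A→C bridging a path A→…→C whose first and last steps
  are splices; the intermediate parts and their entry/exit junctions are
  include evidence, the bridging splice is exclude evidence.  A splice
  over two tandem exons yields a single event covering both.
* **AD / AA** — two or more splices leaving (entering) one exonic region
  at different sub-part boundaries toward (from) the same anchor part.
  With more than two alternatives, events are emitted pairwise against
  the longest (most-included) form, which keeps every shorter form
  measurable against a fixed reference.
* **RI** — a splice whose two ends fall in the same contiguous region;
  the spanned intronic sub-parts are include evidence.
* **ME** — two internal regions fed from a common upstream anchor and
  draining to a common downstream anchor that never co-occur on any
  transcript path.  Include is the transcription-order-first alternative.
* **AT / AL** — distinct first (last) exon regions across transcript
  paths that converge to (diverge from) shared parts.  Events are
  emitted pairwise against a canonical form: the transcription-order
  *first* first exon for AT and the transcription-order *last* last exon
  for AL.  The mirrored definitions keep the catalog symmetric under a
  flip of reading direction (AT↔AL, AD↔AA, with ES/RI/ME preserved), a
  property the test suite checks for every pattern.  We chose pairwise
  emission over one-event-per-alternative because with exactly two
  promoters the two per-alternative events are complements
  (PSI₂ = 1 − PSI₁ on identical coverage) and a k-alternative pattern is
  fully described by k − 1 contrasts — the same logic the AD/AA
  detectors use.  Three promoters therefore yield two AT events, each
  against the canonical promoter.

Nested or overlapping patterns are all emitted independently; no
de-duplication is attempted, since each elementary contrast is separately
interpretable.  Complex mixtures (say a skip inside an alternate-donor
region) are reported as their elementary parts rather than given compound
labels.

**3. Read attribution and PSI.**  Each primary alignment supports exactly
one interpretation of its placement:

* a spliced read (reference-skip in its CIGAR) counts toward every
  junction it spans with ≥ `min_anchor` aligned bases on both sides, and
  never toward exon bodies;
* an unspliced read counts toward every exon part it overlaps by
  ≥ `min_anchor` bases.

The alternative — letting junction reads also increment the flanking
exon parts — double-counts them in any event whose include set contains
both the exon and its junctions, and makes the canonical exon-skip
arithmetic (4 body + 2 + 2 junction reads vs 2 skip reads → PSI 0.8)
impossible to reproduce from real alignments.  Disjoint attribution is
therefore the only counting rule consistent with the event definitions.

PSI for an event is the sum of raw include-element counts over the sum of
include plus exclude counts, withheld unless the total reaches
`min_coverage` = 8 reads.  Raw counts (not length-normalized values)
enter the ratio: the worked arithmetic above is exact only in raw counts.
Normalized observations — reads per 1000 exonic bases per million aligned
reads for parts, reads per million for junctions — are computed and
exported for expression displays but never feed the PSI ratio.

One consequence worth understanding: for events whose include side
carries exon-body evidence (ES, RI, ME with unequal exon sizes), PSI is
not an unbiased estimate of the underlying isoform fraction — the include
side accumulates evidence proportional to exon length + read length
while a bare junction accumulates ∝ read length − 2·anchor + 1.  This is
a property of the event *definition*, not of the implementation; PSI
remains a well-defined, monotone, within-event-comparable measure, which
is how it is used across samples.  Where the two forms have symmetric
geometry (equal-length mutually exclusive exons), PSI is exactly a
binomial estimate of the isoform fraction, and that is the geometry the
parameter-recovery tests use.

**4. Novel junctions.**  Junctions present in the alignments but absent
from the annotation are added to the graph as novel splices when both
endpoints fall on existing part boundaries or strictly inside existing
parts (which are then split and renumbered); junctions reaching outside
all known exonic territory are discarded — novel exons are never
inferred.  Discovery operates on the spliced alignments already in the
input file; re-aligning unmapped reads is an aligner's job, not this
package's, and the contract (find unannotated splices, never exons) is
the same.  Because novel junctions can be spurious or trace amounts, any
event involving one is reported at cohort level only if the novel
splice's reads are ≥ `min_fraction` = 1% of the event's covering reads in
≥ `min_samples` = 10 samples.  "Share of the event's covering reads" is
our operational reading of "expressed in ≥ 1% of transcripts": within an
event, covering reads are the transcript sample the ratio is taken over.

## Cohort summaries

Group means are unweighted means of non-missing PSI over each group's
*tumor* samples; adjacent-normal means and the per-group delta
(tumor − normal) are reported where both strata exist.  No minimum
per-group n is imposed, but n is always reported so users can filter.
The tissue-difference ranking sorts events by the sample variance of
per-group means across the selected groups — variance of group means,
not of individual samples, because the question is variation *between*
tumor types; groups contributing no data are excluded, and at least two
informative groups are required.  The tumor-normal ranking scores each
event by the maximum absolute per-group delta (a `mean` aggregation is
available); the maximum favors events with a striking shift in at least
one tissue, which is what a discovery list is for.  Ties in either
ranking break lexicographically by event id, making orderings fully
deterministic.  Exports write PSI at 17 significant digits so that a
write/read round trip is bit-exact.

## The fixture generator

Test data are generated, never downloaded.  A recipe lists event
patterns; the generator lays them along a gene in transcription order,
separated by shared linker exons so patterns cannot interact, and
realizes them with two isoforms (A carries the inclusion/long/first form
of each internal pattern).  Defaults: 100-base exons and introns, 60-base
donor/acceptor extensions, 50-base reads, a 50/50 isoform mixture, and
`depth` scaled so each junction expects about `depth` covering reads.
Reads are sampled uniformly along each isoform, isoform counts drawn
multinomially with probability ∝ mixture fraction × number of valid start
positions (the molar-fraction × length weighting of shotgun RNA-seq), and
emitted as coordinate-sorted SAM with `N` CIGAR operations at introns.
A truth table tracks, by direct transcript-coordinate arithmetic (a code
path independent of the BAM/CIGAR pipeline), the exact count each graph
element must receive; the suite asserts exact equality.

What the simulator does *not* model: sequencing error, indels, coverage
bias (GC, 3′), mapping ambiguity or multi-mapping, paired-end structure,
or overdispersion across samples.  Passing tests therefore demonstrate
correctness of the graph/event/counting logic under clean alignments —
they do not certify robustness to noisy real-world mapping, which is the
upstream aligner's territory.

## Numerical and degenerate-input choices

* `min_anchor` = 4 bases for junction anchors and body overlaps: small
  enough to keep evidence, large enough to reject 1–3-base spurious
  overhangs.  Configurable everywhere it applies.
* `min_coverage` = 8 covering reads for a reported PSI; the boundary is
  exact (7 → NA, 8 → value) and tested.
* Junction matching is exact on intron coordinates; near-miss junctions
  (off-by-one gaps) count nothing.
* Reads on chromosomes absent from the graphs are skipped silently but
  still count toward the per-million normalization denominator.
* Only primary, mapped, non-supplementary alignments are counted.
* Empty transcript sets, mixed-strand genes, zero aligned reads, and
  unknown gene symbols in exports raise immediate errors; missing PSI is
  a value (NA), never an error.
* Determinism: identical inputs give identical graphs, labels, catalogs
  and (under a fixed seed) identical simulated SAM bytes.

Test problem sizes are deliberately small — cohorts of 12–60 samples,
genes of 3–20 parts, read depths of 40–150 covering reads — chosen so
the full suite exercises every pipeline stage, including binomial
parameter recovery at p ∈ {0.1, 0.5, 0.8}, in well under five minutes on
one CPU.

## Known limitations

* Events, not isoforms: no transcript-abundance deconvolution, and PSI
  values of overlapping events on one gene are not independent.
* Overlapping genes are processed independently per gene id; a read in
  shared territory counts for each gene's graph it overlaps.
* Only protein-coding transcripts enter by default; non-coding RNAs are
  excluded unless `coding_only = FALSE`.
* Group comparisons are descriptive (means, variances, shifts); no
  hypothesis testing or multiple-testing control is provided, by design.
* Adjacent-normal tissue is an imperfect comparator — tissue-composition
  differences between tumor and normal samples confound splicing
  comparisons, and no purity correction is attempted.
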