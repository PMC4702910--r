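# psiquant

Alternative mRNA splicing lets one gene produce many transcript isoforms,
and shifts in splicing are a hallmark of development and disease —
RNA-seq cohorts (tumor versus adjacent normal tissue in particular) are
routinely mined for them.  `psiquant` is an R toolkit for quantifying
alternative splicing from spliced, genome-aligned RNA-seq reads at the
level of *splice events* rather than whole isoforms.  It is aimed at
bioinformaticians who want per-sample, per-event inclusion measurements
they can feed into integrative analyses, plus the cohort summaries needed
to find the most variable events across sample groups.

## What it computes

**Unified splice graph.**  Each gene's protein-coding transcripts (from a
GTF annotation) are fragmented at every transcript boundary into *exon
parts*, so that every genomic base of the gene belongs to exactly one
part and every read placement is unambiguous.  Parts are numbered in
transcription order (`1, 2, 3, ...`), with sub-parts (`2.1, 2.2`) where
transcript boundaries split an exonic region.  Splices (junctions) connect
parts according to each transcript's intron structure.

**Event catalog.**  Seven event types are enumerated from graph topology:
exon skip (ES), alternate donor (AD), alternate acceptor (AA), retained
intron (RI), mutually exclusive exons (ME), alternate first (AT) and
alternate last (AL) exon.  Each event names two disjoint element sets:
reads on *include* elements evidence the presence of the affected
transcript element, reads on *exclude* elements evidence its absence.

**Percent Spliced In.**  For event *e* in a sample,

    PSI(e) = include reads / (include reads + exclude reads)

where a spliced read counts toward every junction it spans with at least
`min_anchor` (default 4) aligned bases on each side, and an unspliced
read counts toward every exon part it overlaps by at least `min_anchor`
bases.  PSI is withheld (NA) unless at least 8 reads cover the event.
For the classic exon-skip picture — 8 reads on the exon body and its two
flanking junctions, 2 reads on the skipping junction — PSI is 8/10 = 0.8:
80% of the sample's transcripts include the exon.

Junctions observed in the alignments but absent from the annotation are
added to the graph as *novel splices* (never novel exons); at the cohort
level, events that depend on a novel splice are reported only if the
splice accounts for ≥ 1% of the event's covering reads in ≥ 10 samples.
Raw counts are also normalized to reads per 1000 exonic bases per million
aligned reads for expression-style export.

## Worked example

The bundled fixture generator builds genes with known event patterns and
simulates spliced reads from a known isoform mixture — here 70%
exon-including isoform A, 30% isoform B:

```r
library(psiquant)

spec  <- fixture_spec(events = c("ES", "ME"), mixture = c(A = 0.7, B = 0.3),
                      depth = 60, seed = 42)
model <- generate_gene_model(spec)
write_gtf(model, "demo.gtf")
write_sam(simulate_reads(model, sample_id = "demo"), "demo.sam")

graph  <- build_splice_graphs(read_gene_models("demo.gtf"))[[1]]
events <- detect_events(graph)
counts <- normalize_counts(count_reads("demo.sam", graph, sample_id = "demo"))
psi_table(events, counts)[, c("event_id", "event_type", "psi",
                              "include_reads", "exclude_reads")]
```

```
      event_id event_type       psi include_reads exclude_reads
1   GENE1_ES_2         ES 0.8947368           136            16
2 GENE1_ME_4|5         ME 0.7262570           130            49
```

The ME event's PSI (0.73) tracks the 70% isoform-A mixture: its two
alternative exons have identical geometry, so include and exclude
evidence accumulate symmetrically.  The ES event reads higher (0.89)
because its include side counts exon-body reads in addition to two
junctions — a property of the event definition itself, discussed in the
methods vignette.  `exons` labels ("2", "4|5") refer to the transcription-
order exon numbering exported by `export_exon_reference()`.

Cohort tools then assemble many samples into an events-by-samples matrix
and rank events:

```r
pm <- assemble_psi_matrix(per_sample_tables, sample_sheet)
s  <- summarize_groups(pm)                # per-group means, tumor-normal deltas
rank_tissue_difference(s)                 # highest cross-group variance first
rank_tumor_normal(s)                      # largest tumor-normal shift first
export_psi_download(pm, "psi.tsv", gene = "GENE1", event_type = "ME")
```

A thin command-line wrapper with the same pipeline lives at
`inst/cli/psiquant` (subcommands `model`, `events`, `quantify`, `cohort`,
`simulate`).

## Scope notes

The package quantifies event-level inclusion; it does not estimate
isoform abundances, test hypotheses about group differences, or annotate
protein impact.  Only protein-coding transcripts enter the graphs by
default.  See `vignettes/psiquant-methods.Rmd` for the model, parameter
choices and known limitations.
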