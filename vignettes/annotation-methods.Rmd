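---
title: "Annotating genomic and transcriptomic intervals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating genomic and transcriptomic intervals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intervanno)
```

## The problem

High-throughput experiments deliver lists of coordinates: ChIP or CLIP
peaks, variants, RNA structure probing signals, predicted miRNA target
sites. Interpreting them means asking which genes, transcripts, CDS and
UTRs each interval touches. Two complications make this harder than a
plain interval intersection. First, transcript-oriented pipelines
(structure probing, degradome sequencing, target prediction) report
positions *along the spliced transcript*, not on the genome, and no
widely used annotation tool consumes those directly. Second, the
results usually arrive as ad hoc delimited tables rather than BED or
VCF, and analysts want the annotation appended to their table, not a
replacement for it.

`intervanno` addresses both. It builds a queryable relational store
from any GTF or GFF3 annotation and then annotates intervals given
either in genomic coordinates (reference = chromosome) or in spliced
transcript coordinates (reference = transcript ID), reading BED, VCF or
arbitrary column-based tables and appending its results as extra
columns without touching the original content.

## The annotation model

**Database.** A GTF/GFF3 file is parsed into three relational tables:
features (type, span, strand, parent link), attributes (feature, key,
value) and the observed type hierarchy. Feature types and attribute
*keys* are lowercased so all later matching is case-insensitive;
attribute *values* are stored verbatim, because they carry identifiers
(accessions such as `CDY69014`) whose case is meaningful. GTF files
from producers that omit explicit gene/transcript records get those
records synthesized from the `gene_id`/`transcript_id` attributes of
their children. The store is persisted as a single file and reopens
with byte-identical query behaviour, so it is built once per
annotation. Overlap queries run through `GenomicRanges::findOverlaps`
on 1-based closed intervals.

**Genomic mode.** Each interval is intersected with all transcript
records on its chromosome (any overlap by default; an optional full-
containment policy requires the interval to lie inside the feature).
Every overlapping transcript produces one output row carrying its gene,
its genomic span, one yes/no column per child feature type (exon, CDS,
UTRs — "y" or "."), the selected attributes, and a region label (below).
Intervals overlapping no transcript are marked `intergenic` and
annotated with the closest gene on either side. "Up/downstream" is
deliberately reported as genomic *left/right* with both neighbours'
strands included, because strand-aware directionality is ambiguous when
the two flanking genes disagree; users can derive it from the reported
strands. Distances are differences of closed-interval boundaries, so
adjacent features are at distance 1.

**Transcriptomic mode.** The reference column names a transcript;
matching is a case-insensitive ID lookup, never a positional search.
Child features are re-expressed in spliced transcript coordinates and
intersected with the interval there. Transcript coordinates are
5'-anchored: position 1 is the first transcribed base, which for a
minus-strand transcript is the exonic base with the *highest* genomic
coordinate. This is the only convention under which positions reported
by transcript-oriented tools (e.g. target predictors) make biological
sense. An unknown transcript ID yields the row unannotated (all ".")
with a warning rather than an error, so one stale accession does not
kill a run; an interval end beyond the spliced length is clamped and
flagged in the `annotated_note` column.

## Region labels

Within each matched transcript the interval receives a coarse relative
location, computed from the quartiles of its start and end positions
along the spliced length $L$. The quartile of position $p$ is
$\lceil 4p/L \rceil$ clamped to $1..4$ (a position exactly at $L/4$
belongs to the lower quartile). With $q_s, q_e$ the start/end quartiles
and $\ell = e - s + 1$ the interval length, rules are evaluated in
order:

| label     | rule |
|-----------|------|
| `full`    | $q_s = 1$, $q_e = 4$, $\ell > 0.9L$ |
| `whole`   | $q_s = 1$, $q_e = 4$, $\ell \le 0.9L$ |
| `5 prime` | $q_s = 1$, $q_e \le 2$ |
| `3 prime` | $q_s \ge 3$, $q_e = 4$ |
| `middle`  | $q_s, q_e \in \{2, 3\}$ |

The long-span rules come first because their quartile patterns subsume
the directional ones. The 90% comparison is computed as
$10\ell > 9L$ in integer arithmetic, so no floating-point tie can flip
a label. Three design points the rule table leaves open are resolved
as follows and tested exhaustively:

* an interval covering the entire transcript is always `full`, even for
  transcripts shorter than four bases, where position 1 does not fall
  in the first quartile;
* quartile patterns matched by no rule (e.g. start in Q1, end in Q3)
  fall back to the quartile of the interval midpoint (Q1 → `5 prime`,
  Q2/Q3 → `middle`, Q4 → `3 prime`), which keeps the classifier total —
  an exhaustive sweep over every (start, end, L ≤ 40) triple confirms
  no unlabeled configuration;
* in genomic mode the label is computed on the interval's *spliced
  projection* into the transcript; an interval lying entirely inside an
  intron has an empty projection and is labelled `intronic` instead of
  being forced into the five-way scheme.

## Coordinate arithmetic

All internal arithmetic is 1-based end-inclusive (the GTF/GFF native
convention); BED's 0-based half-open and any user-declared custom
convention are converted exactly once at the I/O boundary, and the
conversion is an exact bijection (`normalize_interval()` /
`denormalize_interval()` round-trip to identity on all inputs).
Projection of a genomic interval onto a transcript counts exonic bases
per exon with precomputed cumulative lengths; the inverse mapping
returns the per-exon genomic blocks, whose lengths always sum to the
transcript-interval length. Intronic genomic positions map to a
*spliced offset* — the count of exonic bases 5' of the position — so
downstream code always has a defined anchor. Transcripts listed without
exon records are treated as one pseudo-exon spanning the transcript
record, which makes unspliced annotations (bacteria, some ncRNA-only
GTFs) work unchanged.

## Input and output contracts

Readers keep every input line verbatim. The writer emits the original
line plus the appended columns (fixed, documented order; `"."` encodes
absence), so stripping the appended columns reconstructs the input
byte-for-byte — comment lines (`#`, and `track`/`browser` in BED) pass
through unannotated at their original positions, CRLF endings are
preserved inside the line. When the input had no header, a single
header line with generic `col1..colN` names plus the annotation column
names is prepended. Unparseable rows are kept, flagged, and counted; a
file more than half unparseable aborts with a summary. VCF records
span `POS .. POS + nchar(REF) - 1` and records without an ID get
`chrom:POS`. Multi-allelic records are annotated once per record, not
per allele.

Statistics (`summarize_annotation()`) are tallied over *output* rows —
after the one-row-per-overlapping-transcript expansion — with both the
input and output totals reported so the distinction stays visible, and
are written to standard error or a side file, never interleaved with
the annotated table.

## The synthetic genome generator

Tests and the acceptance script run against synthetic annotations from
`generate_annotation()`: a seeded, fully deterministic gene space with
configurable chromosome/gene counts, transcripts per gene (default
1–3), exons per transcript (1–5), exon lengths 60–300 bp, introns
40–400 bp, UTR lengths 0–150/0–200 bp, intergenic gaps 0.3–3 kb and
balanced strands — compact, plant-like gene models matching the scale
of the miRNA-target use case the tool is aimed at. The generator emits
the identical feature set as both GTF and GFF3 and records ground truth
(exon chains, spliced lengths, child features in both coordinate
systems) by construction.

Expected annotations come from two *naive reference annotators*
(`oracle_annotate_genomic()`, `oracle_annotate_transcriptomic()`) that
share no code with the engine: linear scans over all transcripts,
per-base enumeration of exonic positions for region labels, their own
quartile arithmetic. The headline test compares engine and reference
exactly over 200 randomized instances in both modes and both
containment policies.

What the generator does **not** emulate: overlapping genes on opposite
strands sharing exons, trans-splicing, attribute edge cases of
real-world GFF (quoted semicolons, URL escapes), scaffold-heavy
assemblies. Passing tests therefore demonstrate the correctness of the
coordinate arithmetic and annotation logic, not robustness to every
wild-type annotation file; the parser is additionally cross-checked
against `rtracklayer::import` on the fixtures.

## Numerical and procedural choices

* Quartile and 90% computations are integer-only (see above).
* Deterministic output order everywhere: input row order first, then
  gene ID, then transcript ID; count tables by descending count, then
  value. Two runs on identical inputs are byte-identical.
* Duplicate feature IDs (legal in real-world GFF) keep the first
  occurrence untouched and suffix later ones; parents referencing a
  duplicated ID attach to the first. Dangling parent references warn
  and keep the feature with no parent.
* Full-containment semantics apply uniformly to transcript matching and
  child flags. In genomic mode a child feature split across exons (a
  multi-part CDS) is containment-checked per part; in transcript space
  the parts of one child type are contiguous, so flags there use the
  per-type union span.
* The disk-direct build parses the attribute column in chunks with
  intermediate spill files, trading time for a lower peak; its output
  is bit-identical to the in-memory build and tested as such.
* Problem sizes in the test suite: oracle equivalence uses 200
  instances of up to 20 genes × 40 intervals; scaling checks fit build
  times over 1k/5k/10k genes and warm-cache annotation times over
  1k/5k/20k intervals to a linear model (R² > 0.95). These sizes were
  chosen to exercise the engine's vectorised paths well past fixture
  scale while keeping the default check quick on a laptop.

## Known limitations

* No set-algebraic operations (union/subtract/merge à la BEDTools);
  the tool annotates, it does not manipulate interval sets.
* One database per annotation file; merging several GTF/GFF sources
  into one store is not supported.
* GFF3 ontology terms are not validated against the Sequence Ontology;
  the hierarchy reflects the file as written.
* CIGAR-based projection (through alignments) and fusion transcripts
  are out of scope.
* The region fallback for rule-uncovered quartile patterns is a
  documented local convention; other tools may label those rare
  configurations differently.
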