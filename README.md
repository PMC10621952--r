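# intervanno

Flexible annotation of genomic **and** transcriptomic intervals against
GTF/GFF3 genome annotations.

## The problem

Interval lists produced by high-throughput pipelines — peaks, variants,
RNA structure signals, predicted miRNA binding sites — need to be placed
in the context of known genes, transcripts, CDSs and UTRs before they
mean anything. Standard interval tools (BEDTools, BEDOPS, Homer) handle
genomic coordinates well, but transcript-oriented experiments report
positions *along the spliced transcript* with a transcript accession as
the reference, and their results usually arrive in custom delimited
tables rather than BED/VCF. `intervanno` annotates both kinds of
coordinates, reads standard and custom tables, and appends its results
as extra columns without altering the original file content.

For whom: anyone annotating transcript-coordinate results (structure
probing, degradome data, target prediction output) or who wants
intergenic intervals annotated with their flanking genes instead of
being silently dropped.

## The method in brief

* A GTF/GFF3 file is parsed once into a persistent relational feature
  store (features, attributes, type hierarchy; types and attribute keys
  lowercased for case-insensitive querying, values kept verbatim).
* **Genomic mode:** each interval is matched to every overlapping
  transcript (partial overlap by default, full containment optionally);
  each match reports the gene, per-child-feature overlap flags
  (`y`/`.`), selected attributes and a relative region label.
  Intervals hitting nothing are marked `intergenic` with the closest
  gene on either side and boundary distances.
* **Transcriptomic mode:** the reference is a transcript ID; child
  features are recalculated to spliced transcript coordinates
  (5'-anchored, strand-aware) and intersected with the interval there.
* The region label places the interval within the transcript by the
  quartiles of its start/end positions: `5 prime` (start Q1, end
  ≤ Q2), `middle` (both in Q2–Q3), `3 prime` (start ≥ Q3, end Q4),
  `whole` (Q1→Q4, length ≤ 90% of the spliced length L) and `full`
  (Q1→Q4, length > 90% of L), with quartile(p) = ⌈4p/L⌉.
* Summary statistics (biotype, CDS/UTR, region distributions) are
  tallied over the annotated rows on request.

See `vignettes/annotation-methods.Rmd` for the full model, the design
decisions and their rationale.

## Worked example

The package ships a deterministic synthetic-genome generator used by
its own test suite; it doubles as a quick demo:

```r
library(intervanno)

tr <- generate_annotation(genome_spec(seed = 42, n_genes = 6), "demo")
db <- build_db(tr$gtf, output_path = "demo/features.db")
print(db)
#> <annotation database: 108 features, 6 types, memory-first build from demo/annotation.gtf>
inspect_hierarchy(db)
#> gene (6)
#>     attributes: gene_biotype, gene_id, gene_name
#> └── transcript (11)
#>     attributes: gene_biotype, gene_id, transcript_biotype, transcript_id
#>     └── cds (30)
#>     ...
```

Annotate one site given in spliced transcript coordinates, keeping only
the CDS/UTR flags and the transcript biotype:

```r
annotate_transcriptomic("site1", "SYNT00001", 150, 180, db,
  annotation_options("transcriptomic",
                     feature_types = c("cds", "five_prime_utr", "three_prime_utr"),
                     attributes = "transcript_biotype"))
#>   annotated_gene_id annotated_transcript_id ... cds five_prime_utr three_prime_utr transcript_biotype feature_region
#> 1         SYNG00001               SYNT00001 ...   y              .               .     protein_coding         middle
```

Positions 150–180 of transcript `SYNT00001` fall inside its CDS (`y`),
outside both UTRs (`.`), and land in the middle half of the spliced
transcript. A genomic interval that overlaps no gene is annotated with
its neighbours instead:

```r
annotate_genomic("peak1", "chr1", 5000, 5200, db)
#>   annotated_feature_type annotated_left_gene annotated_left_distance annotated_right_gene annotated_right_distance
#> 1             intergenic           SYNG00003                       1            SYNG00005                     2024
```

The closest gene to the left ends 1 bp before the interval; the closest
to the right starts 2024 bp after it.

### Command line

The same workflow as a two-command tool (script installed under
`system.file("cli", "intervanno", package = "intervanno")`):

```sh
intervanno create_db -a annotation.gtf -d features.db
intervanno annotate -d features.db -i sites.bed > annotated.tsv
# custom table, e.g. psRNATarget output: ID in col 1, transcript in col 2,
# start/end in cols 7/8, 1-based
intervanno annotate -d features.db -i targets.tsv -f custom \
    --id-col 1 --ref-col 2 --start-col 7 --end-col 8 \
    -m transcriptomic --stats - > annotated.tsv
```

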