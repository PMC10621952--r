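# Fixture builders and comparison helpers shared across the suite.
# All fixtures are generated in code; nothing is read from disk except
# files the helpers themselves write into tempdir().

# minimal three-feature GFF3: gene > mRNA > exon
write_minimal_gff3 <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t2000\t.\t+\t.\tID=g1;gene_id=g1",
    "chr1\ttest\tmRNA\t1000\t2000\t.\t+\t.\tID=t1;Parent=g1;transcript_id=t1",
    "chr1\ttest\texon\t1000\t2000\t.\t+\t.\tID=t1:exon:1;Parent=t1"
  ), path)
  path
}

# hand-written GTF: one plus-strand gene whose transcript has a UTR/CDS/UTR
# partition in transcript coordinates (single exon, so transcript position
# equals offset from the transcript start)
write_partitioned_gtf <- function(path = tempfile(fileext = ".gtf"),
                                  gene_start = 2001L, L = 1244L,
                                  utr5 = 200L, utr3 = 244L,
                                  tx_id = "CDY69014", gene_id = "GSBRNA2T00082020001") {
  ge <- gene_start + L - 1L
  cds_s <- gene_start + utr5
  cds_e <- ge - utr3
  a <- function(extra = "") sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "protein_coding"; transcript_biotype "protein_coding";%s',
                                    gene_id, tx_id, extra)
  writeLines(c(
    sprintf("LK038451\ttest\tgene\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; gene_biotype \"protein_coding\";",
            gene_start, ge, gene_id),
    sprintf("LK038451\ttest\ttranscript\t%d\t%d\t.\t+\t.\t%s", gene_start, ge, a()),
    sprintf("LK038451\ttest\texon\t%d\t%d\t.\t+\t.\t%s", gene_start, ge, a(' exon_number "1";')),
    sprintf("LK038451\ttest\tfive_prime_utr\t%d\t%d\t.\t+\t.\t%s", gene_start, cds_s - 1L, a()),
    sprintf("LK038451\ttest\tCDS\t%d\t%d\t.\t+\t.\t%s", cds_s, cds_e, a()),
    sprintf("LK038451\ttest\tthree_prime_utr\t%d\t%d\t.\t+\t.\t%s", cds_e + 1L, ge, a())
  ), path)
  path
}

# two-exon transcript used throughout the coordinate tests:
# exons (101,200) and (301,400), spliced length 200
two_exon_model <- function(strand = "+") {
  transcript_model("tx1", "g1", "chr1", strand,
                   exons = data.frame(start = c(101L, 301L), end = c(200L, 400L)))
}

# random transcript model with k disjoint exons
random_model <- function(k = NULL, strand = NULL) {
  if (is.null(k)) k <- sample(1:6, 1L)
  if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
  lens <- sample(5:120, k, replace = TRUE)
  gaps <- sample(10:200, k, replace = TRUE)
  starts <- 1000L + cumsum(gaps + data.table::shift(lens, fill = 0L))
  transcript_model("rtx", "rg", "chrR", strand,
                   exons = data.frame(start = starts, end = starts + lens - 1L))
}

# engine output vs oracle output, canonical genomic-mode comparison
flag_columns <- function(x)
  intersect(c("cds", "exon", "five_prime_utr", "three_prime_utr"), names(x))

canon_genomic <- function(got, exp) {
  fc <- flag_columns(exp)
  g <- got[, c("idx", "annotated_transcript_id", "annotated_gene_id", fc,
               "feature_region", "annotated_left_gene", "annotated_left_distance",
               "annotated_right_gene", "annotated_right_distance"), with = FALSE]
  e <- exp[, c("idx", "transcript_id", "gene_id", fc, "region",
               "left_gene", "left_distance", "right_gene", "right_distance"),
           with = FALSE]
  data.table::setnames(e, names(g))
  data.table::setorderv(g, names(g))
  data.table::setorderv(e, names(e))
  list(got = as.data.frame(g), exp = as.data.frame(e))
}

canon_tx <- function(got, exp) {
  fc <- flag_columns(exp)
  g <- got[, c("idx", "annotated_transcript_id", "annotated_gene_id", fc,
               "feature_region"), with = FALSE]
  e <- exp[, c("idx", "transcript_id", "gene_id", fc, "region"), with = FALSE]
  data.table::setnames(e, names(g))
  data.table::setorderv(g, names(g))
  data.table::setorderv(e, names(e))
  list(got = as.data.frame(g), exp = as.data.frame(e))
}

# one randomized oracle-equivalence instance; returns TRUE when the
# engine output matches the naive reference exactly
oracle_instance_matches <- function(seed, mode, containment, n_genes = NULL,
                                    n_intervals = 40L) {
  if (is.null(n_genes)) n_genes <- sample(3:20, 1L)
  tr <- generate_annotation(genome_spec(seed = seed, n_genes = n_genes))
  db <- build_db(tr$gtf)
  iv <- suppressWarnings(
    generate_intervals(tr, mode, n = n_intervals, seed = seed + 5000L,
                       containment = containment))
  got <- suppressWarnings(annotate_intervals(
    iv$records, db, annotation_options(mode, containment = containment)))
  cmp <- if (mode == "genomic") canon_genomic(got, iv$expected)
         else canon_tx(got, iv$expected)
  isTRUE(all.equal(cmp$got, cmp$exp, check.attributes = FALSE))
}
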