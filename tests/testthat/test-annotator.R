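test_that("a mid-gene interval is annotated with its transcript and region", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tt\tgene\t1000\t2000\t.\t+\t.\tgene_id "gA";',
    'chr1\tt\ttranscript\t1000\t2000\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\tt\texon\t1000\t2000\t.\t+\t.\tgene_id "gA"; transcript_id "tA";'
  ), gtf)
  db <- build_db(gtf)
  r <- annotate_genomic("iv1", "chr1", 1500, 1600, db)
  expect_equal(nrow(r), 1L)
  expect_equal(r$annotated_gene_id, "gA")
  expect_equal(r$annotated_transcript_id, "tA")
  # spliced positions 501..601 of L = 1001 -> Q3/Q3 -> middle
  expect_equal(r$feature_region, "middle")
})

test_that("intergenic intervals report closest left/right genes with boundary distances", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tt\tgene\t1000\t2000\t.\t+\t.\tgene_id "geneA";',
    'chr1\tt\tgene\t8000\t9000\t.\t-\t.\tgene_id "geneB";'
  ), gtf)
  db <- build_db(gtf)
  r <- annotate_genomic("iv", "chr1", 5000, 5100, db)
  expect_equal(nrow(r), 1L)
  expect_equal(r$annotated_feature_type, "intergenic")
  expect_equal(r$annotated_left_gene, "geneA")
  expect_equal(r$annotated_left_distance, "3000")
  expect_equal(r$annotated_right_gene, "geneB")
  expect_equal(r$annotated_right_distance, "2900")
  expect_equal(r$annotated_right_strand, "-")

  nb <- mark_intergenic("chr1", 5000, 5100, db)
  expect_equal(nb$left_distance, "3000")
  expect_equal(nb$right_distance, "2900")

  # second hand-derived layout: A(100-200), B(1000-2000), interval 500-600
  gtf2 <- tempfile(fileext = ".gtf")
  writeLines(c('chr1\tt\tgene\t100\t200\t.\t+\t.\tgene_id "A";',
               'chr1\tt\tgene\t1000\t2000\t.\t+\t.\tgene_id "B";'), gtf2)
  db2 <- build_db(gtf2)
  nb2 <- mark_intergenic("chr1", 500, 600, db2)
  expect_equal(c(nb2$left_gene, nb2$left_distance), c("A", "300"))
  expect_equal(c(nb2$right_gene, nb2$right_distance), c("B", "400"))
  # interval before every gene: no left neighbor
  nb3 <- mark_intergenic("chr1", 10, 20, db2)
  expect_equal(nb3$left_gene, ".")
  expect_equal(nb3$right_gene, "A")
  # adjacent feature => distance 1
  nb4 <- mark_intergenic("chr1", 201, 210, db2)
  expect_equal(nb4$left_distance, "1")
})

test_that("unknown sequence names yield an intergenic row with no neighbors", {
  db <- build_db(write_minimal_gff3())
  r <- annotate_genomic("iv", "chrZ", 10, 20, db)
  expect_equal(nrow(r), 1L)
  expect_equal(r$annotated_feature_type, "intergenic")
  expect_equal(r$annotated_left_gene, ".")
  expect_equal(r$annotated_right_gene, ".")
})

test_that("transcript-coordinate annotation sets child flags and the region label", {
  # spliced length 1244 with 5'UTR 1-200, CDS 201-1000, 3'UTR 1001-1244
  db <- build_db(write_partitioned_gtf(L = 1244L, utr5 = 200L, utr3 = 244L))
  r <- annotate_transcriptomic("s1", "CDY69014", 682, 702, db)
  expect_equal(nrow(r), 1L)
  expect_equal(r$cds, "y")
  expect_equal(r$five_prime_utr, ".")
  expect_equal(r$three_prime_utr, ".")
  expect_equal(r$feature_region, "middle")
  expect_equal(r$annotated_gene_id, "GSBRNA2T00082020001")

  # interval spanning the 5'UTR/CDS junction flags both (partial overlap)
  r2 <- annotate_transcriptomic("s2", "CDY69014", 150, 250, db)
  expect_equal(r2$five_prime_utr, "y")
  expect_equal(r2$cds, "y")
  # under full containment the junction-spanning interval fits neither
  r3 <- annotate_transcriptomic("s3", "CDY69014", 150, 250, db,
                                annotation_options("transcriptomic",
                                                   containment = "full"))
  expect_equal(r3$five_prime_utr, ".")
  expect_equal(r3$cds, ".")
})

test_that("unknown transcript references emit a fully blank row with a warning", {
  db <- build_db(write_partitioned_gtf())
  expect_warning(r <- annotate_transcriptomic("s", "NOPE123", 1, 10, db),
                 "absent from the database")
  expect_equal(nrow(r), 1L)
  expect_equal(r$annotated_gene_id, ".")
  expect_equal(r$feature_region, ".")
  expect_equal(r$annotated_note, "unknown_reference")
})

test_that("intervals past the spliced end are clamped and flagged", {
  db <- build_db(write_partitioned_gtf(L = 1000L, utr5 = 100L, utr3 = 100L))
  r <- annotate_transcriptomic("s", "CDY69014", 950, 1200, db)
  expect_equal(r$annotated_note, "end_clamped_to_transcript")
  expect_equal(r$feature_region, "3 prime")
})

test_that("gene-level grouping ORs child flags and preserves (interval, gene) pairs", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tt\tgene\t100\t1000\t.\t+\t.\tgene_id "gA";',
    'chr1\tt\ttranscript\t100\t600\t.\t+\t.\tgene_id "gA"; transcript_id "t1";',
    'chr1\tt\texon\t100\t600\t.\t+\t.\tgene_id "gA"; transcript_id "t1";',
    'chr1\tt\tCDS\t100\t400\t.\t+\t.\tgene_id "gA"; transcript_id "t1";',
    'chr1\tt\ttranscript\t100\t1000\t.\t+\t.\tgene_id "gA"; transcript_id "t2";',
    'chr1\tt\texon\t100\t1000\t.\t+\t.\tgene_id "gA"; transcript_id "t2";',
    'chr1\tt\tthree_prime_utr\t450\t1000\t.\t+\t.\tgene_id "gA"; transcript_id "t2";'
  ), gtf)
  db <- build_db(gtf)
  tx_rows <- annotate_genomic("iv", "chr1", 380, 470, db)
  expect_equal(nrow(tx_rows), 2L)     # one row per overlapping transcript
  g_rows <- group_by_gene(tx_rows)
  expect_equal(nrow(g_rows), 1L)
  expect_equal(g_rows$cds, "y")              # from t1
  expect_equal(g_rows$three_prime_utr, "y")  # from t2
  expect_equal(g_rows$annotated_transcript_id, "t1,t2")
  expect_equal(g_rows$annotated_feature_type, "gene")
  # (interval, gene) pair set unchanged
  expect_setequal(unique(tx_rows$annotated_gene_id), unique(g_rows$annotated_gene_id))
  # level = "gene" through the options gives the same grouping
  opt <- annotation_options("genomic", level = "gene")
  g2 <- annotate_genomic("iv", "chr1", 380, 470, db, opt)
  expect_equal(g2$annotated_transcript_id, "t1,t2")
  # grouping a single-transcript gene is the identity apart from the marker
  single <- annotate_genomic("iv", "chr1", 420, 430, db)
  gs <- group_by_gene(single[annotated_transcript_id == "t1"])
  expect_equal(nrow(gs), 1L)
  expect_equal(gs$cds, single[annotated_transcript_id == "t1"]$cds)
})

test_that("column selection restricts output and rejects unknown names upfront", {
  db <- build_db(write_partitioned_gtf())
  opt <- annotation_options("transcriptomic", feature_types = c("CDS"),
                            attributes = c("Transcript_Biotype"))
  cols <- annotation_columns(db, opt)
  expect_true("cds" %in% cols)
  expect_false("five_prime_utr" %in% cols)
  expect_true("transcript_biotype" %in% cols)
  expect_false("gene_biotype" %in% cols)
  r <- annotate_transcriptomic("s", "CDY69014", 500, 520, db, opt)
  expect_equal(setdiff(names(r), "idx"), cols)

  expect_error(
    annotation_columns(db, annotation_options(attributes = "no_such_attr")),
    "available", class = "intervanno_config_error")
  # "all" selection is the identity on the available sets
  expect_equal(annotation_columns(db, annotation_options("transcriptomic")),
               annotation_columns(db, annotation_options("transcriptomic",
                                                         feature_types = "all",
                                                         attributes = "all")))
})

test_that("full-containment matches are a subset of partial-overlap matches", {
  tr <- generate_annotation(genome_spec(seed = 21, n_genes = 12))
  db <- build_db(tr$gtf)
  iv <- generate_intervals(tr, "genomic", n = 50, seed = 22)
  part <- annotate_intervals(iv$records, db, annotation_options("genomic"))
  full <- annotate_intervals(iv$records, db,
                             annotation_options("genomic", containment = "full"))
  key_of <- function(x) paste(x$idx, x$annotated_transcript_id)
  matched_full <- key_of(full[annotated_transcript_id != "."])
  matched_part <- key_of(part[annotated_transcript_id != "."])
  expect_true(all(matched_full %in% matched_part))
})

test_that("every input interval yields at least one output row, extras only from multi-transcript overlap", {
  tr <- generate_annotation(genome_spec(seed = 23, n_genes = 10))
  db <- build_db(tr$gtf)
  iv <- generate_intervals(tr, "genomic", n = 40, seed = 24)
  rows <- annotate_intervals(iv$records, db, annotation_options("genomic"))
  expect_setequal(unique(rows$idx), iv$records$idx)
  per_iv <- table(rows$idx)
  expect_true(all(per_iv >= 1L))
  # row count = inputs + extra transcript matches
  extra <- sum(per_iv - 1L)
  expect_equal(nrow(rows), nrow(iv$records) + extra)
})

test_that("engine output equals the naive reference on randomized instances", {
  set.seed(1203)
  for (trial in 1:6) {
    expect_true(oracle_instance_matches(3000 + trial, "genomic", "partial"))
    expect_true(oracle_instance_matches(3100 + trial, "genomic", "full"))
    expect_true(oracle_instance_matches(3200 + trial, "transcriptomic", "partial"))
    expect_true(oracle_instance_matches(3300 + trial, "transcriptomic", "full"))
  }
})

test_that("annotation output is deterministic across repeated runs", {
  tr <- generate_annotation(genome_spec(seed = 29, n_genes = 8))
  db <- build_db(tr$gtf)
  iv <- generate_intervals(tr, "genomic", n = 30, seed = 30)
  r1 <- annotate_intervals(iv$records, db, annotation_options("genomic"))
  r2 <- annotate_intervals(iv$records, db, annotation_options("genomic"))
  expect_identical(r1, r2)
})
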