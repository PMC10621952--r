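test_that("a minimal GFF3 builds a three-feature database with the full hierarchy", {
  db <- build_db(write_minimal_gff3())
  expect_equal(nrow(db$features), 3L)
  h <- inspect_hierarchy(db)
  expect_setequal(h$types, c("gene", "mrna", "exon"))
  expect_true(nrow(h$edges[parent_type == "gene" & child_type == "mrna"]) == 1L)
  expect_true(nrow(h$edges[parent_type == "mrna" & child_type == "exon"]) == 1L)
  txt <- format(h)
  # each type rendered exactly once, child indented under parent
  expect_equal(sum(grepl("^gene ", txt)), 1L)
  expect_equal(sum(grepl("mrna", txt)), 1L)
  expect_equal(sum(grepl("exon", txt)), 1L)
  expect_true(which(grepl("mrna", txt)) > which(grepl("^gene ", txt)))
})

test_that("feature types and attribute keys are lowercased, values kept verbatim", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tt\tGene\t100\t900\t.\t+\t.\tGene_ID "G1"; Gene_Biotype "Protein_Coding";',
    'chr1\tt\tTranscript\t100\t900\t.\t+\t.\tGene_ID "G1"; Transcript_ID "CDY69014";'
  ), gtf)
  db <- build_db(gtf)
  expect_setequal(db$hierarchy$types, c("gene", "transcript"))
  expect_true(all(db$attributes$key == tolower(db$attributes$key)))
  # value case preserved exactly as in the file
  expect_true("Protein_Coding" %in% db$attributes$value)
  expect_true("CDY69014" %in% db$attributes$value)
  # lowercasing is idempotent: rebuilding from already-lowercase input is a no-op
  expect_identical(tolower(db$features$feature_type), db$features$feature_type)
})

test_that("database feature count matches an independent line-count oracle", {
  tr <- generate_annotation(genome_spec(seed = 31, n_genes = 100, n_chromosomes = 3))
  n_lines <- sum(!startsWith(readLines(tr$gtf), "#"))
  db <- build_db(tr$gtf)
  expect_equal(nrow(db$features), n_lines)
})

test_that("hierarchy attribute lists match a brute-force scan of the raw file", {
  tr <- generate_annotation(genome_spec(seed = 13, n_genes = 15))
  db <- build_db(tr$gtf)
  h <- inspect_hierarchy(db)
  # naive scan: per feature type, collect attribute keys by regex
  lines <- readLines(tr$gtf)
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  types <- tolower(vapply(f, `[`, "", 3L))
  keys <- lapply(f, function(x) {
    m <- regmatches(x[9L], gregexpr('([A-Za-z_]+) "', x[9L]))[[1L]]
    tolower(sub(' "', "", m))
  })
  for (ty in unique(types)) {
    raw_keys <- sort(unique(unlist(keys[types == ty])))
    expect_equal(h$attrs_per_type[[ty]], raw_keys, info = ty)
  }
})

test_that("UTR children of mRNA are listed under the transcript in the hierarchy", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t1000\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t1\t1000\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tt\tfive_prime_UTR\t1\t100\t.\t+\t.\tID=u5;Parent=t1",
    "chr1\tt\tthree_prime_UTR\t901\t1000\t.\t+\t.\tID=u3;Parent=t1"
  ), gff)
  h <- inspect_hierarchy(build_db(gff))
  e <- h$edges
  expect_setequal(e$child_type[e$parent_type == "mrna"],
                  c("five_prime_utr", "three_prime_utr"))
})

test_that("overlap queries use closed-interval arithmetic including boundary touch", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines('chr1\tt\tgene\t1000\t2000\t.\t+\t.\tgene_id "g1";', gtf)
  db <- build_db(gtf)
  expect_equal(fetch_overlapping(db, "chr1", 1500, 1600)$feature_id, "g1")
  expect_equal(fetch_overlapping(db, "chr1", 2000, 2100)$feature_id, "g1")
  expect_equal(nrow(fetch_overlapping(db, "chr1", 2001, 2100)), 0L)
  expect_equal(nrow(fetch_overlapping(db, "chrUnknown", 1, 10)), 0L)
})

test_that("overlap queries equal a brute-force all-pairs oracle on random layouts", {
  set.seed(77)
  for (trial in 1:20) {
    k <- sample(10:50, 1L)
    gs <- sample.int(50000, k)
    ge <- gs + sample.int(2000, k, replace = TRUE)
    gtf <- tempfile(fileext = ".gtf")
    writeLines(sprintf('chr1\tt\tgene\t%d\t%d\t.\t+\t.\tgene_id "g%03d";',
                       gs, ge, seq_len(k)), gtf)
    db <- build_db(gtf)
    for (q in 1:20) {
      qs <- sample.int(55000, 1L)
      qe <- qs + sample.int(3000, 1L)
      got <- fetch_overlapping(db, "chr1", qs, qe)$feature_id
      exp <- sprintf("g%03d", which(gs <= qe & ge >= qs))
      expect_setequal(got, exp)
    }
  }
})

test_that("children come back in genomic order and lookups are case-insensitive", {
  gtf <- write_partitioned_gtf(tx_id = "CDY69014")
  db <- build_db(gtf)
  tx_fid <- db$features[feature_type == "transcript"]$feature_id
  kids <- fetch_children(db, tx_fid)
  expect_true(!is.unsorted(kids$start))
  # case-insensitive transcript lookup returns the same record
  m1 <- fetch_by_transcript_id(db, "cdy69014")
  m2 <- fetch_by_transcript_id(db, "CDY69014")
  expect_equal(m1$transcript_id, m2$transcript_id)
  expect_equal(m1$spliced_length, 1244L)
  # unknown ID: recoverable NULL, no error
  expect_null(fetch_by_transcript_id(db, "no_such_tx"))
})

test_that("persisted databases reopen with identical query results", {
  tr <- generate_annotation(genome_spec(seed = 5, n_genes = 8))
  dbfile <- tempfile(fileext = ".db")
  db1 <- build_db(tr$gtf, output_path = dbfile)
  db2 <- load_db(dbfile)
  expect_identical(db1$features, db2$features)
  expect_identical(db1$attributes, db2$attributes)
  q <- fetch_overlapping(db1, tr$genes$seqid[1], tr$genes$start[1], tr$genes$end[1])
  expect_identical(q, fetch_overlapping(db2, tr$genes$seqid[1], tr$genes$start[1],
                                        tr$genes$end[1]))
  tid <- tr$transcripts$transcript_id[1]
  expect_equal(fetch_by_transcript_id(db1, tid)$exons,
               fetch_by_transcript_id(db2, tid)$exons)
})

test_that("disk-direct builds are identical to memory-first builds", {
  tr <- generate_annotation(genome_spec(seed = 6, n_genes = 12))
  db1 <- build_db(tr$gtf, disk_direct = FALSE)
  db2 <- build_db(tr$gtf, disk_direct = TRUE, chunk_size = 20L)
  expect_identical(db1$features, db2$features)
  expect_identical(db1$attributes, db2$attributes)
  expect_equal(db2$build_mode, "disk-direct")
})

test_that("parse errors name the offending line; dangling parents only warn", {
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tt\tgene\tnot_a_number"), bad)
  expect_error(build_db(bad), "line 3", class = "intervanno_data_error")

  dangle <- tempfile(fileext = ".gff3")
  writeLines(c("chr1\tt\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=missing_gene"), dangle)
  expect_warning(db <- build_db(dangle), "missing parent")
  expect_equal(nrow(db$features), 1L)
  expect_true(is.na(db$features$parent_id))
})

test_that("a trailing FASTA section and comment lines are ignored", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "# a comment",
               "chr1\tt\tgene\t1\t100\t.\t+\t.\tID=g1",
               "##FASTA",
               ">chr1",
               "ACGTACGT"), gff)
  db <- build_db(gff)
  expect_equal(nrow(db$features), 1L)
})

test_that("dialect detection works by extension and by content sniffing", {
  expect_equal(detect_dialect("x.gtf"), "gtf")
  expect_equal(detect_dialect("x.gff3"), "gff3")
  expect_equal(detect_dialect("x.GFF"), "gff3")
  expect_equal(detect_dialect("x.txt", sample_attr = "ID=g1;Parent=t1"), "gff3")
  expect_equal(detect_dialect("x.txt", sample_attr = 'gene_id "g1";'), "gtf")
})

test_that("the parser agrees with rtracklayer on a synthetic GTF", {
  tr <- generate_annotation(genome_spec(seed = 17, n_genes = 10))
  db <- build_db(tr$gtf)
  ref <- rtracklayer::import(tr$gtf)
  expect_equal(nrow(db$features), length(ref))
  expect_equal(sort(unique(db$features$feature_type)),
               sort(unique(tolower(as.character(ref$type)))))
  # spans agree per (type, seqid) after ordering
  got <- db$features[order(feature_type, seqid, start, end),
                     .(feature_type, seqid, start, end)]
  want <- data.table::data.table(
    feature_type = tolower(as.character(ref$type)),
    seqid = as.character(GenomicRanges::seqnames(ref)),
    start = BiocGenerics::start(ref), end = BiocGenerics::end(ref))
  data.table::setorder(want, feature_type, seqid, start, end)
  expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
})

test_that("GTF files lacking gene/transcript lines get them synthesized", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tt\texon\t100\t200\t.\t+\t.\tgene_id "gA"; transcript_id "tA";',
    'chr1\tt\texon\t300\t400\t.\t+\t.\tgene_id "gA"; transcript_id "tA";'
  ), gtf)
  db <- build_db(gtf)
  expect_setequal(db$hierarchy$types, c("gene", "transcript", "exon"))
  m <- fetch_by_transcript_id(db, "tA")
  expect_equal(m$spliced_length, 202L)
  expect_equal(nrow(m$exons), 2L)
})
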