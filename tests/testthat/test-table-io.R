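test_that("BED lines parse as 0-based half-open with the name as interval ID", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tpeak1", bed)
  tab <- read_intervals(bed, table_schema("bed"))
  r <- tab$records
  expect_equal(r$reference, "chr1")
  expect_equal(c(r$start, r$end), c(100L, 200L))
  expect_equal(r$id, "peak1")
  expect_true(r$valid)
})

test_that("VCF records span POS .. POS + nchar(REF) - 1 and synthesize missing IDs", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr2\t1000\trs1\tACG\tA\t.\t.\t.",
               "chr2\t5000\t.\tT\tC\t.\t.\t."), vcf)
  tab <- read_intervals(vcf, table_schema("vcf"))
  r <- tab$records
  expect_equal(r$start, c(1000L, 5000L))
  expect_equal(r$end, c(1002L, 5000L))
  expect_equal(r$id, c("rs1", "chr2:5000"))
  expect_equal(sum(tab$kind == "comment"), 2L)
})

test_that("a psRNATarget-style table parses through the custom schema (cols 1,2,7,8)", {
  tsv <- tempfile(fileext = ".tsv")
  # synthetic stand-in shaped like small-RNA target-prediction output
  writeLines(c(
    paste(c("miRNA_Acc.", "Target_Acc.", "Expectation", "UPE", "miRNA_aligned",
            "Target_aligned", "Target_start", "Target_end"), collapse = "\t"),
    "3-bna-miR156a\tCDY69014\t1.5\t.\tx\tx\t682\t702",
    "67-bna-miR156a\tCDY37684\t2.0\t.\tx\tx\t463\t483"
  ), tsv)
  schema <- table_schema("custom", id_col = 1L, ref_col = 2L,
                         start_col = 7L, end_col = 8L, header = "auto")
  tab <- read_intervals(tsv, schema)
  expect_equal(tab$kind[1L], "header")
  r <- tab$records
  expect_equal(r$id, c("3-bna-miR156a", "67-bna-miR156a"))
  expect_equal(r$reference, c("CDY69014", "CDY37684"))
  expect_equal(r$start, c(682L, 463L))
  expect_equal(r$end, c(702L, 483L))
})

test_that("malformed rows are flagged and counted; mostly-bad files are fatal", {
  f <- tempfile()
  writeLines(c("chr1\t10\t20\ta", "chr1\tbroken", "chr1\t30\t40\tb"), f)
  expect_warning(tab <- read_intervals(f, table_schema("bed")), "1 of 3")
  expect_equal(sum(!tab$records$valid), 1L)
  expect_equal(tab$records$note[2L], "unparseable_row")

  g <- tempfile()
  writeLines(c("chr1\tbroken1", "chr1\tbroken2", "chr1\t30\t40\tb"), g)
  expect_error(suppressWarnings(read_intervals(g, table_schema("bed"))),
               "more than half", class = "intervanno_data_error")
})

test_that("custom schemas demand all four column indices", {
  expect_error(table_schema("custom", id_col = 1, ref_col = 2, start_col = 7),
               "end_col", class = "intervanno_config_error")
})

test_that("stripping appended columns reproduces the input byte-identically", {
  tr <- generate_annotation(genome_spec(seed = 41, n_genes = 8))
  db <- build_db(tr$gtf)

  strip <- function(lines, n_ann) vapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    paste(f[seq_len(length(f) - n_ann)], collapse = "\t")
  }, character(1L), USE.NAMES = FALSE)
  # intervals overlapped by several transcripts repeat their input line
  # once per match; collapsing those consecutive repeats must restore
  # the input byte-identically
  collapse <- function(x) x[c(TRUE, x[-1L] != x[-length(x)])]

  # BED input (no header): output adds one synthesized header line
  iv <- generate_intervals(tr, "genomic", n = 20, seed = 42)
  res <- annotate_file(iv$path, db, iv$schema, annotation_options("genomic"))
  out <- write_annotated(res, file = nullfile())
  expect_identical(collapse(strip(out[-1L], length(res$columns))),
                   readLines(iv$path))

  # headered custom input: header line is extended, data lines preserved
  # (transcriptomic runs emit exactly one row per input line)
  iv2 <- generate_intervals(tr, "transcriptomic", n = 16, seed = 43)
  res2 <- suppressWarnings(annotate_file(iv2$path, db, iv2$schema,
                                         annotation_options("transcriptomic")))
  out2 <- write_annotated(res2, file = nullfile())
  expect_identical(strip(out2, length(res2$columns)), readLines(iv2$path))
})

test_that("CRLF lines and comments survive the round trip unaltered", {
  db <- build_db(write_minimal_gff3())
  f <- tempfile(fileext = ".bed")
  con <- file(f, "wb")
  writeChar("# a comment\r\nchr1\t999\t1200\tiv1\r\ntrack name=x\nchr1\t1500\t1600\tiv2\n",
            con, eos = NULL)
  close(con)
  raw_lines <- readLines(f)
  res <- annotate_file(f, db, table_schema("bed"), annotation_options("genomic"))
  out <- write_annotated(res, file = nullfile())
  # comments at their original positions, bytes untouched (including \r)
  expect_identical(out[1L], raw_lines[1L])
  expect_true("track name=x" %in% out)
  n_ann <- length(res$columns)
  data_out <- out[grepl("^chr1\t", out)]
  strip1 <- strsplit(data_out[1L], "\t", fixed = TRUE)[[1L]]
  expect_identical(paste(strip1[1:4], collapse = "\t"), raw_lines[2L])
})

test_that("output column counts are input columns plus the appended selection", {
  db <- build_db(write_partitioned_gtf())
  tsv <- tempfile()
  writeLines(c(paste0("id\tref\tc3\tc4\tc5\tc6\tstart\tend\tc9\tc10\tc11\tc12\tc13\tc14"),
               paste0("s1\tCDY69014\t.\t.\t.\t.\t100\t140\t.\t.\t.\t.\t.\t.")), tsv)
  schema <- table_schema("custom", id_col = 1, ref_col = 2, start_col = 7,
                         end_col = 8, header = "present")
  opt <- annotation_options("transcriptomic",
                            feature_types = c("cds", "five_prime_utr"),
                            attributes = c("gene_biotype"),
                            convention = convention_gff())
  res <- annotate_file(tsv, db, schema, opt)
  out <- write_annotated(res, file = nullfile())
  expect_equal(length(strsplit(out[2L], "\t", fixed = TRUE)[[1L]]),
               14L + length(res$columns))
})
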