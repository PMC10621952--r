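# Deterministic synthetic genome annotations with by-construction ground
# truth, plus naive reference annotators used as independent oracles in
# the test suite. The oracles deliberately share no code with the
# database or the annotation engine: linear scans, per-base bookkeeping,
# their own quartile arithmetic.

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic genome annotation
#'
#' Defines the shape of a generated annotation: gene count, chromosome
#' count, transcript/exon multiplicities, exon/intron/UTR length ranges
#' and strand balance. The same spec and seed always produce byte-
#' identical files. Ranges are `c(lo, hi)` in bases (or counts) and are
#' sampled uniformly. The defaults emulate a compact plant-like gene
#' space: mostly multi-exonic protein-coding genes with a minority of
#' single-biotype non-coding transcripts.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_chromosomes,n_genes Counts.
#' @param transcripts_per_gene,exons_per_transcript Count ranges.
#' @param exon_length,intron_length,utr5_length,utr3_length,intergenic_gap
#'   Length ranges in bases.
#' @param minus_strand_prob Probability a gene lies on the minus strand.
#' @param ncrna_prob Probability a gene is non-coding (no CDS/UTRs).
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(seed = 1L, n_chromosomes = 2L, n_genes = 20L,
                        transcripts_per_gene = c(1L, 3L),
                        exons_per_transcript = c(1L, 5L),
                        exon_length = c(60L, 300L),
                        intron_length = c(40L, 400L),
                        utr5_length = c(0L, 150L),
                        utr3_length = c(0L, 200L),
                        intergenic_gap = c(300L, 3000L),
                        minus_strand_prob = 0.5,
                        ncrna_prob = 0.15) {
  stopifnot(n_genes >= 1L, n_chromosomes >= 1L,
            is_count_range(transcripts_per_gene), is_count_range(exons_per_transcript))
  structure(as.list(environment()), class = "genome_spec")
}

#' Generate a synthetic annotation (GTF + GFF3) with ground truth
#'
#' Builds a random gene space per the spec and writes it as both a GTF
#' and a GFF3 file describing the identical feature set (genes,
#' transcripts, exons, CDS and UTR parts with matching IDs and
#' attributes). Returns the ground-truth tables — exon chains, spliced
#' lengths, child features in both transcript and genomic coordinates —
#' computed by construction during generation, which the test suite uses
#' as the oracle for coordinate arithmetic.
#'
#' @param spec A [genome_spec()].
#' @param dir Output directory (created if needed).
#' @return A `genome_truth` object: paths `gtf`, `gff3` and tables
#'   `genes`, `transcripts`, `exons`, `children` (transcript
#'   coordinates), `child_blocks` (genomic blocks).
#' @export
generate_annotation <- function(spec, dir = tempfile("synthgenome")) {
  stopifnot(inherits(spec, "genome_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- with_seed(spec$seed, .lay_out_genome(spec))
  gtf <- file.path(dir, "annotation.gtf")
  gff3 <- file.path(dir, "annotation.gff3")
  .write_gtf(truth, gtf)
  .write_gff3(truth, gff3)
  truth$gtf <- gtf
  truth$gff3 <- gff3
  truth$spec <- spec
  structure(truth, class = "genome_truth")
}

.lay_out_genome <- function(spec) {
  ng <- spec$n_genes
  genes <- data.table(
    gi = seq_len(ng),
    gene_id = sprintf("SYNG%05d", seq_len(ng)),
    seqid = sprintf("chr%d", rep_len(seq_len(spec$n_chromosomes), ng)),
    strand = ifelse(stats::runif(ng) < spec$minus_strand_prob, "-", "+"),
    coding = stats::runif(ng) >= spec$ncrna_prob,
    n_tx = draw_range(spec$transcripts_per_gene, ng)
  )
  genes[n_tx < 1L, n_tx := 1L]
  tx <- data.table(gi = rep.int(genes$gi, genes$n_tx))
  tx[, `:=`(ti = .I,
            transcript_id = sprintf("SYNT%05d", .I),
            n_ex = draw_range(spec$exons_per_transcript, .N),
            off = draw_range(c(0L, 30L), .N))]
  tx[n_ex < 1L, n_ex := 1L]
  ex <- data.table(ti = rep.int(tx$ti, tx$n_ex))
  ex[, rank := seq_len(.N), by = ti]
  ex[, len := draw_range(spec$exon_length, .N)]
  ex[, ilen := draw_range(spec$intron_length, .N)]
  ex[rank == 1L, ilen := 0L]
  ex[, rel := cumsum(data.table::shift(len, fill = 0L) + ilen), by = ti]
  tx <- merge(tx, ex[, .(span = rel[.N] + len[.N], L = sum(len)), by = ti],
              by = "ti", sort = FALSE)

  gx <- tx[, .(extent = max(off + span)), by = gi]
  genes <- merge(genes, gx, by = "gi", sort = FALSE)
  genes[, gap := draw_range(spec$intergenic_gap, .N)]
  genes[, start := {
    s <- cumsum(data.table::shift(extent, fill = 0L) + gap) + 1L
    s
  }, by = seqid]
  genes[, end := start + extent - 1L]

  tx <- merge(tx, genes[, .(gi, seqid, strand, gene_id, coding, gstart = start)],
              by = "gi", sort = FALSE)
  tx[, `:=`(start = gstart + off, end = gstart + off + span - 1L)]
  ex <- merge(ex, tx[, .(ti, seqid, strand, start_tx = start)], by = "ti", sort = FALSE)
  ex[, `:=`(es = start_tx + rel, ee = start_tx + rel + len - 1L)]

  # transcript-coordinate span of each exon (5'-anchored numbering)
  ex[, cum_before := cumsum(data.table::shift(len, fill = 0L)), by = ti]
  ex <- merge(ex, tx[, .(ti, L)], by = "ti", sort = FALSE)
  ex[, `:=`(t1 = fifelse(strand == "+", cum_before + 1L, L - cum_before - len + 1L),
            t2 = fifelse(strand == "+", cum_before + len, L - cum_before))]

  # child features: UTR5 / CDS / UTR3 partition of coding transcripts,
  # defined in transcript coordinates and cut into genomic blocks exon
  # by exon
  ctx <- tx[coding == TRUE]
  children <- NULL; blocks <- NULL
  if (nrow(ctx)) {
    u5 <- draw_range(spec$utr5_length, nrow(ctx))
    u3 <- draw_range(spec$utr3_length, nrow(ctx))
    u5 <- pmin(u5, pmax(0L, (ctx$L - 3L) %/% 2L))
    u3 <- pmin(u3, pmax(0L, ctx$L - 3L - u5))
    cdt <- data.table(ti = ctx$ti, u5 = u5, u3 = u3, L = ctx$L)
    children <- rbind(
      cdt[u5 > 0L, .(ti, type = "five_prime_utr", ts = 1L, te = u5)],
      cdt[, .(ti, type = "cds", ts = u5 + 1L, te = L - u3)],
      cdt[u3 > 0L, .(ti, type = "three_prime_utr", ts = L - u3 + 1L, te = L)]
    )
    j <- merge(children, ex[, .(ti, rank, strand, es, t1, t2)], by = "ti",
               allow.cartesian = TRUE)
    j[, `:=`(o1 = pmax(ts, t1), o2 = pmin(te, t2))]
    j <- j[o1 <= o2]
    # map the in-exon transcript sub-span back to genomic coordinates
    j[, `:=`(gs = fifelse(strand == "+", es + (o1 - t1), es + (t2 - o2)),
             ge = fifelse(strand == "+", es + (o2 - t1), es + (t2 - o1)))]
    setorder(j, ti, type, gs)
    j[, part := seq_len(.N), by = .(ti, type)]
    blocks <- j[, .(ti, type, part, gs, ge)]
  }

  setorder(ex, ti, rank)
  list(
    genes = genes[, .(gene_id, seqid, strand, start, end, coding)],
    transcripts = tx[, .(transcript_id, gene_id, seqid, strand, start, end,
                         spliced_length = L, coding)],
    exons = merge(ex, tx[, .(ti, transcript_id)], by = "ti",
                  sort = FALSE)[, .(transcript_id, rank, es, ee, t1, t2)],
    children = if (is.null(children)) data.table(transcript_id = character(),
                                                 type = character(), ts = integer(),
                                                 te = integer())
               else merge(children, tx[, .(ti, transcript_id)], by = "ti",
                          sort = FALSE)[, .(transcript_id, type, ts, te)],
    child_blocks = if (is.null(blocks)) data.table(transcript_id = character(),
                                                   type = character(), part = integer(),
                                                   gs = integer(), ge = integer())
                   else merge(blocks, tx[, .(ti, transcript_id)], by = "ti",
                              sort = FALSE)[, .(transcript_id, type, part, gs, ge)]
  )
}

# shared row layout for both dialects: one record per annotation line, in
# gene -> transcript -> exon/CDS/UTR order
.record_rows <- function(truth) {
  g <- truth$genes; t <- truth$transcripts; e <- truth$exons; b <- truth$child_blocks
  tx_of <- setNames(t$gene_id, t$transcript_id)
  biotype <- function(coding) ifelse(coding, "protein_coding", "ncrna")
  rows <- rbind(
    data.table(gene_id = g$gene_id, transcript_id = NA_character_,
               type = "gene", seqid = g$seqid, start = g$start, end = g$end,
               strand = g$strand, bio = biotype(g$coding), part = 0L),
    data.table(gene_id = t$gene_id, transcript_id = t$transcript_id,
               type = "transcript", seqid = t$seqid, start = t$start, end = t$end,
               strand = t$strand, bio = biotype(t$coding), part = 0L),
    {
      et <- merge(e, t[, .(transcript_id, gene_id, seqid, strand, coding)],
                  by = "transcript_id", sort = FALSE)
      data.table(gene_id = et$gene_id, transcript_id = et$transcript_id,
                 type = "exon", seqid = et$seqid, start = et$es, end = et$ee,
                 strand = et$strand, bio = biotype(et$coding), part = et$rank)
    },
    if (nrow(b)) {
      bt <- merge(b, t[, .(transcript_id, gene_id, seqid, strand, coding)],
                  by = "transcript_id", sort = FALSE)
      data.table(gene_id = bt$gene_id, transcript_id = bt$transcript_id,
                 type = ifelse(bt$type == "cds", "CDS", bt$type),
                 seqid = bt$seqid, start = bt$gs, end = bt$ge,
                 strand = bt$strand, bio = biotype(bt$coding), part = bt$part)
    }
  )
  prio <- c(gene = 1L, transcript = 2L, exon = 3L, CDS = 4L,
            five_prime_utr = 5L, three_prime_utr = 6L)
  gene_start <- setNames(truth$genes$start, truth$genes$gene_id)
  rows[, `:=`(gpos = gene_start[gene_id], tp = prio[type])]
  setorder(rows, seqid, gpos, gene_id, transcript_id, tp, start, na.last = FALSE)
  rows[, `:=`(gpos = NULL, tp = NULL)]
  rows
}

.write_gtf <- function(truth, path) {
  r <- .record_rows(truth)
  attr_str <- ifelse(r$type == "gene",
    sprintf('gene_id "%s"; gene_name "name_%s"; gene_biotype "%s";',
            r$gene_id, lc(r$gene_id), r$bio),
    ifelse(r$type == "transcript",
      sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s"; gene_biotype "%s";',
              r$gene_id, r$transcript_id, r$bio, r$bio),
      ifelse(r$type == "exon",
        sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                r$gene_id, r$transcript_id, r$part),
        sprintf('gene_id "%s"; transcript_id "%s";', r$gene_id, r$transcript_id))))
  writeLines(c("#!genome-build synthetic",
               sprintf("%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       r$seqid, r$type, r$start, r$end, r$strand, attr_str)),
             path)
  invisible(path)
}

.write_gff3 <- function(truth, path) {
  r <- .record_rows(truth)
  # IDs match what the GTF dialect parser synthesizes, so both dialects
  # load to identical databases
  id <- ifelse(r$type == "gene", r$gene_id,
        ifelse(r$type == "transcript", r$transcript_id,
               sprintf("%s:%s:%d", r$transcript_id, lc(r$type), r$part)))
  parent <- ifelse(r$type == "gene", NA_character_,
            ifelse(r$type == "transcript", r$gene_id, r$transcript_id))
  attr_str <- ifelse(r$type == "gene",
    sprintf("ID=%s;gene_id=%s;gene_name=name_%s;gene_biotype=%s",
            id, r$gene_id, lc(r$gene_id), r$bio),
    ifelse(r$type == "transcript",
      sprintf("ID=%s;Parent=%s;gene_id=%s;transcript_id=%s;transcript_biotype=%s;gene_biotype=%s",
              id, parent, r$gene_id, r$transcript_id, r$bio, r$bio),
      ifelse(r$type == "exon",
        sprintf("ID=%s;Parent=%s;gene_id=%s;transcript_id=%s;exon_number=%d",
                id, parent, r$gene_id, r$transcript_id, r$part),
        sprintf("ID=%s;Parent=%s;gene_id=%s;transcript_id=%s",
                id, parent, r$gene_id, r$transcript_id))))
  writeLines(c("##gff-version 3",
               sprintf("%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       r$seqid, r$type, r$start, r$end, r$strand, attr_str)),
             path)
  invisible(path)
}

#' @export
print.genome_truth <- function(x, ...) {
  cat(sprintf("<synthetic genome: %d gene(s), %d transcript(s), %d exon(s) on %d sequence(s)>\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons),
              length(unique(x$genes$seqid))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# interval sampling

#' Generate intervals with expected annotations
#'
#' Samples intervals over a synthetic genome so that every interesting
#' case class is covered — exonic, junction-spanning, intronic and
#' intergenic intervals in genomic mode; every region label plus lengths
#' straddling the 90% whole/full boundary in transcriptomic mode, with an
#' occasional unknown transcript reference. The expected annotation of
#' every interval is computed by the naive reference annotators
#' ([oracle_annotate_genomic()] / [oracle_annotate_transcriptomic()]),
#' which share no code with the annotation engine. A warning lists any
#' case class the requested `n` was too small to cover.
#'
#' @param truth A `genome_truth` from [generate_annotation()].
#' @param mode `"genomic"` or `"transcriptomic"`.
#' @param n Number of intervals.
#' @param seed Integer seed.
#' @param dir Output directory for the written table.
#' @param containment `"partial"` or `"full"`, used for the expected
#'   annotations.
#' @return A list: `path` (BED for genomic mode, headered TSV for
#'   transcriptomic mode), `schema`, `records` (canonical intervals) and
#'   `expected` (oracle annotation).
#' @export
generate_intervals <- function(truth, mode = c("genomic", "transcriptomic"),
                               n = 60L, seed = 1L, dir = tempfile("synthiv"),
                               containment = "partial") {
  mode <- match.arg(mode)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- with_seed(seed + 1L, {
    if (mode == "genomic") .sample_genomic_intervals(truth, n)
    else .sample_tx_intervals(truth, n)
  })
  if (mode == "genomic") {
    path <- file.path(dir, "intervals.bed")
    writeLines(sprintf("%s\t%d\t%d\t%s", recs$reference, recs$start - 1L,
                       recs$end, recs$id), path)
    schema <- table_schema("bed")
    expected <- oracle_annotate_genomic(recs, truth, containment)
  } else {
    path <- file.path(dir, "intervals.tsv")
    writeLines(c(paste(c("site_id", "target_acc", "score", "c4", "c5", "c6",
                         "target_start", "target_end"), collapse = "\t"),
                 sprintf("%s\t%s\t%.2f\tx\tx\tx\t%d\t%d", recs$id, recs$reference,
                         seq_len(nrow(recs)) / 7, recs$start, recs$end)),
               path)
    schema <- table_schema("custom", id_col = 1L, ref_col = 2L, start_col = 7L,
                           end_col = 8L, header = "present")
    expected <- oracle_annotate_transcriptomic(recs, truth, containment)
  }
  missing <- setdiff(unique(recs$class_planned), unique(recs$class_planned[recs$covered]))
  if (length(missing))
    warning("interval classes not covered at n = ", n, ": ",
            paste(missing, collapse = ", "), call. = FALSE)
  list(path = path, schema = schema, records = recs, expected = expected)
}

.sample_genomic_intervals <- function(truth, n) {
  classes <- rep_len(c("exonic", "junction", "intronic", "intergenic",
                       "contained", "spanning"), n)
  ex <- truth$exons
  tx <- truth$transcripts
  multi <- unique(ex$transcript_id[ex$rank > 1L])
  g <- truth$genes[order(seqid, start)]
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    rec <- switch(cl,
      exonic = {
        e1 <- ex[sample(nrow(ex), 1L)]
        s <- sample(e1$es:e1$ee, 1L)
        t1 <- tx[transcript_id == e1$transcript_id]
        list(t1$seqid, s, min(e1$ee, s + sample(5:60, 1L)), TRUE)
      },
      junction = if (length(multi)) {
        ti <- sample(multi, 1L)
        ec <- ex[transcript_id == ti]
        k <- sample(nrow(ec) - 1L, 1L)
        list(tx[transcript_id == ti]$seqid,
             max(ec$es[k], ec$ee[k] - sample(3:40, 1L)),
             min(ec$ee[k + 1L], ec$es[k + 1L] + sample(3:40, 1L)), TRUE)
      } else NULL,
      intronic = if (length(multi)) {
        ti <- sample(multi, 1L)
        ec <- ex[transcript_id == ti]
        k <- sample(nrow(ec) - 1L, 1L)
        is <- ec$ee[k] + 1L; ie <- ec$es[k + 1L] - 1L
        if (ie - is >= 2L)
          list(tx[transcript_id == ti]$seqid, is + 1L,
               min(ie - 1L, is + sample(1:30, 1L) + 1L), TRUE)
        else NULL
      } else NULL,
      intergenic = {
        gg <- g[seqid == sample(unique(g$seqid), 1L)]
        if (nrow(gg) >= 2L) {
          k <- sample(nrow(gg) - 1L, 1L)
          is <- gg$end[k] + 2L; ie <- gg$start[k + 1L] - 2L
          if (ie - is >= 2L) {
            s <- sample(is:(ie - 1L), 1L)
            list(gg$seqid[1L], s, min(ie, s + sample(5:80, 1L)), TRUE)
          } else NULL
        } else NULL
      },
      contained = {
        t1 <- tx[sample(nrow(tx), 1L)]
        s <- sample(t1$start:t1$end, 1L)
        list(t1$seqid, s, min(t1$end, s + sample(10:120, 1L)), TRUE)
      },
      spanning = {
        t1 <- tx[sample(nrow(tx), 1L)]
        list(t1$seqid, max(1L, t1$start - sample(5:50, 1L)),
             t1$end + sample(5:50, 1L), TRUE)
      })
    if (is.null(rec)) {      # infeasible class for this genome; fall back
      t1 <- tx[sample(nrow(tx), 1L)]
      s <- sample(t1$start:t1$end, 1L)
      rec <- list(t1$seqid, s, min(t1$end, s + 20L), FALSE)
    }
    out[[i]] <- data.table(idx = i, id = sprintf("iv%04d", i),
                           reference = rec[[1]], start = rec[[2]], end = rec[[3]],
                           valid = TRUE, class_planned = cl, covered = rec[[4]])
  }
  rbindlist(out)
}

.sample_tx_intervals <- function(truth, n) {
  classes <- rep_len(c("five_prime", "middle", "three_prime", "whole", "full",
                       "boundary_le90", "boundary_gt90", "unknown_ref"), n)
  tx <- truth$transcripts
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    t1 <- tx[sample(nrow(tx), 1L)]
    L <- t1$spliced_length
    se <- switch(cl,
      five_prime = c(1L, max(1L, as.integer(round(0.3 * L)))),
      middle = c(max(1L, as.integer(round(0.4 * L))),
                 max(1L, as.integer(round(0.6 * L)))),
      three_prime = c(max(1L, as.integer(round(0.85 * L))), L),
      whole = c(max(1L, as.integer(round(0.1 * L))),
                max(1L, as.integer(round(0.85 * L)))),
      full = c(1L, L),
      boundary_le90 = c(1L, max(1L, (9L * L) %/% 10L)),       # length <= 90%
      boundary_gt90 = c(1L, min(L, (9L * L) %/% 10L + 1L)),   # length just over
      unknown_ref = c(1L, 10L))
    ref <- if (cl == "unknown_ref") sprintf("NOSUCHTX%03d", i) else
      # exercise case-insensitive matching on a subset of rows
      if (i %% 5L == 0L) lc(t1$transcript_id) else t1$transcript_id
    out[[i]] <- data.table(idx = i, id = sprintf("site%04d", i), reference = ref,
                           start = se[1L], end = max(se), valid = TRUE,
                           class_planned = cl, covered = TRUE)
  }
  rbindlist(out)
}

# ---------------------------------------------------------------------------
# naive reference annotators (the oracles)

.oracle_quartile <- function(p, L) max(1, min(4, as.integer(ceiling(4 * p / L))))

.oracle_region <- function(s, e, L) {
  qs <- .oracle_quartile(s, L); qe <- .oracle_quartile(e, L)
  len <- e - s + 1
  if (qs == 1 && qe == 4 && 10 * len > 9 * L) return("full")
  if (qs == 1 && qe == 4) return("whole")
  if (qs == 1 && qe <= 2) return("5 prime")
  if (qs >= 3 && qe == 4) return("3 prime")
  if (qs >= 2 && qs <= 3 && qe >= 2 && qe <= 3) return("middle")
  qm <- .oracle_quartile((s + e) %/% 2, L)
  c("5 prime", "middle", "middle", "3 prime")[qm]
}

#' Naive reference annotation of genomic intervals
#'
#' A deliberately simple re-derivation of the genomic annotation
#' semantics by linear scans and per-base bookkeeping, used as the
#' independent oracle for the annotation engine. For each interval it
#' scans all transcripts for overlap under the containment policy,
#' derives child-feature flags from the ground-truth genomic blocks,
#' computes the region label by enumerating exonic bases one by one, and
#' finds intergenic neighbors by a full scan over genes.
#'
#' @param records Canonical intervals (`idx`, `id`, `reference`, `start`,
#'   `end`).
#' @param truth A `genome_truth`.
#' @param containment `"partial"` or `"full"`.
#' @return A data.table keyed by (`idx`, `transcript_id`) with flags,
#'   region and intergenic neighbor columns.
#' @export
oracle_annotate_genomic <- function(records, truth, containment = "partial") {
  full <- containment == "full"
  tx <- truth$transcripts
  ex <- truth$exons
  bl <- truth$child_blocks
  g <- truth$genes
  child_types <- sort(unique(c("exon", bl$type)))
  out <- list()
  for (r in seq_len(nrow(records))) {
    s <- records$start[r]; e <- records$end[r]; sq <- records$reference[r]
    hits <- character(0L)
    for (t in seq_len(nrow(tx))) {
      if (tx$seqid[t] != sq) next
      ok <- if (full) s >= tx$start[t] && e <= tx$end[t]
            else s <= tx$end[t] && e >= tx$start[t]
      if (ok) hits <- c(hits, tx$transcript_id[t])
    }
    if (length(hits)) {
      for (ti in hits) {
        t1 <- tx[transcript_id == ti]
        flags <- setNames(rep(NA_TOKEN, length(child_types)), child_types)
        ec <- ex[transcript_id == ti]
        for (k in seq_len(nrow(ec)))
          if (if (full) s >= ec$es[k] && e <= ec$ee[k]
              else s <= ec$ee[k] && e >= ec$es[k]) flags["exon"] <- "y"
        bc <- bl[transcript_id == ti]
        for (k in seq_len(nrow(bc)))
          if (if (full) s >= bc$gs[k] && e <= bc$ge[k]
              else s <= bc$ge[k] && e >= bc$gs[k]) flags[bc$type[k]] <- "y"
        # region by per-base enumeration of exonic positions
        gpos <- unlist(lapply(seq_len(nrow(ec)), function(k) ec$es[k]:ec$ee[k]))
        tpos <- if (t1$strand == "+") seq_along(gpos) else rev(seq_along(gpos))
        inside <- gpos >= s & gpos <= e
        region <- if (!any(inside)) "intronic"
                  else .oracle_region(min(tpos[inside]), max(tpos[inside]),
                                      t1$spliced_length)
        out[[length(out) + 1L]] <- data.table(
          idx = records$idx[r], transcript_id = ti, gene_id = t1$gene_id,
          t(flags), region = region,
          left_gene = NA_TOKEN, left_distance = NA_TOKEN,
          right_gene = NA_TOKEN, right_distance = NA_TOKEN)
      }
    } else {
      lg <- NA_TOKEN; ld <- NA_TOKEN; rg <- NA_TOKEN; rd <- NA_TOKEN
      best_l <- -Inf; best_r <- Inf
      for (t in seq_len(nrow(g))) {
        if (g$seqid[t] != sq) next
        if (g$end[t] < s && (g$end[t] > best_l ||
                             (g$end[t] == best_l && g$gene_id[t] < lg))) {
          best_l <- g$end[t]; lg <- g$gene_id[t]; ld <- as.character(s - g$end[t])
        }
        if (g$start[t] > e && (g$start[t] < best_r ||
                               (g$start[t] == best_r && g$gene_id[t] < rg))) {
          best_r <- g$start[t]; rg <- g$gene_id[t]; rd <- as.character(g$start[t] - e)
        }
      }
      row <- data.table(idx = records$idx[r], transcript_id = NA_TOKEN,
                        gene_id = NA_TOKEN)
      for (ct in child_types) row[, (ct) := NA_TOKEN]
      row[, `:=`(region = NA_TOKEN, left_gene = lg, left_distance = ld,
                 right_gene = rg, right_distance = rd)]
      out[[length(out) + 1L]] <- row
    }
  }
  res <- rbindlist(out, use.names = TRUE, fill = TRUE)
  setorder(res, idx, gene_id, transcript_id)
  res[]
}

#' Naive reference annotation of transcript-coordinate intervals
#'
#' @inheritParams oracle_annotate_genomic
#' @return A data.table with one row per input interval.
#' @export
oracle_annotate_transcriptomic <- function(records, truth, containment = "partial") {
  full <- containment == "full"
  tx <- truth$transcripts
  ch <- truth$children
  child_types <- sort(unique(c("exon", ch$type)))
  out <- vector("list", nrow(records))
  for (r in seq_len(nrow(records))) {
    m <- which(lc(tx$transcript_id) == lc(records$reference[r]))
    if (!length(m)) {
      row <- data.table(idx = records$idx[r], transcript_id = NA_TOKEN,
                        gene_id = NA_TOKEN)
      for (ct in child_types) row[, (ct) := NA_TOKEN]
      row[, region := NA_TOKEN]
      out[[r]] <- row
      next
    }
    t1 <- tx[m[1L]]
    L <- t1$spliced_length
    s <- min(records$start[r], L)
    e <- min(records$end[r], L)
    flags <- setNames(rep(NA_TOKEN, length(child_types)), child_types)
    # in transcript space exons tile the whole transcript, so any valid
    # interval lies within exonic sequence
    flags["exon"] <- "y"
    cc <- ch[transcript_id == t1$transcript_id]
    for (k in seq_len(nrow(cc)))
      if (if (full) s >= cc$ts[k] && e <= cc$te[k]
          else s <= cc$te[k] && e >= cc$ts[k]) flags[cc$type[k]] <- "y"
    row <- data.table(idx = records$idx[r], transcript_id = t1$transcript_id,
                      gene_id = t1$gene_id, t(flags),
                      region = .oracle_region(s, e, L))
    out[[r]] <- row
  }
  res <- rbindlist(out, use.names = TRUE, fill = TRUE)
  setorder(res, idx)
  res[]
}
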