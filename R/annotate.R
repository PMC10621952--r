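# ---------------------------------------------------------------------------
# cached relational views used by the annotator

# transcript-like features with resolved IDs and spliced lengths
.tx_table <- function(db) {
  cc <- .db_cache(db)
  if (!is.null(cc$tx_table)) return(cc$tx_table)
  tt <- transcript_types(db)
  tx <- db$features[feature_type %chin% tt]
  av <- function(fids, k) {
    a <- db$attributes[key == k]
    a$value[match(fids, a$feature_id)]
  }
  txid <- av(tx$feature_id, "transcript_id")
  gid_attr <- av(tx$parent_id, "gene_id")
  tab <- data.table(
    tx_fid = tx$feature_id,
    transcript_id = fifelse(is.na(txid), tx$feature_id, txid),
    gene_fid = tx$parent_id,
    gene_id = fifelse(is.na(gid_attr),
                      fifelse(is.na(tx$parent_id), NA_TOKEN, tx$parent_id), gid_attr),
    seqid = tx$seqid, start = tx$start, end = tx$end,
    strand = fifelse(tx$strand %in% c("+", "-"), tx$strand, "+"),
    feature_type = tx$feature_type
  )
  ex <- .exon_table(db)
  sl <- ex[, .(spliced_length = sum(ee - es + 1L)), by = tx_fid]
  tab <- merge(tab, sl, by = "tx_fid", all.x = TRUE, sort = FALSE)
  setorder(tab, seqid, start, tx_fid)
  cc$tx_table <- tab
  tab
}

# exon chains (pseudo-exon fallback for exonless transcripts), with
# cumulative exonic length before each exon in plus-strand order
.exon_table <- function(db) {
  cc <- .db_cache(db)
  if (!is.null(cc$exon_table)) return(cc$exon_table)
  tt <- transcript_types(db)
  tx <- db$features[feature_type %chin% tt]
  ex <- db$features[feature_type == "exon" & parent_id %chin% tx$feature_id,
                    .(tx_fid = parent_id, es = start, ee = end)]
  no_ex <- tx[!tx$feature_id %chin% ex$tx_fid]
  if (nrow(no_ex))
    ex <- rbind(ex, data.table(tx_fid = no_ex$feature_id, es = no_ex$start,
                               ee = no_ex$end))
  setorder(ex, tx_fid, es)
  ex[, cum_before := cumsum(c(0L, head(ee - es + 1L, -1L))), by = tx_fid]
  cc$exon_table <- ex
  ex
}

# non-exon children with genomic span and spliced-coordinate span
.child_table <- function(db) {
  cc <- .db_cache(db)
  if (!is.null(cc$child_table)) return(cc$child_table)
  tt <- transcript_types(db)
  tx <- .tx_table(db)
  kids <- db$features[parent_id %chin% tx$tx_fid & !feature_type %chin% tt,
                      .(tx_fid = parent_id, child_type = feature_type,
                        gs = start, ge = end)]
  if (nrow(kids)) {
    kids[, pair := .I]
    pr <- .project_pairs(db, kids[, .(pair, tx_fid, gs, ge)])
    kids <- merge(kids, pr[, .(pair, ts, te)], by = "pair", sort = FALSE)
    kids[, pair := NULL]
  } else {
    kids[, `:=`(ts = integer(), te = integer())]
  }
  cc$child_table <- kids
  kids
}

# gene-like features
.gene_table <- function(db) {
  cc <- .db_cache(db)
  if (!is.null(cc$gene_table)) return(cc$gene_table)
  g <- db$features[feature_type %chin% gene_types(db)]
  a <- db$attributes[key == "gene_id"]
  gid <- a$value[match(g$feature_id, a$feature_id)]
  tab <- data.table(gene_fid = g$feature_id,
                    gene_id = fifelse(is.na(gid), g$feature_id, gid),
                    seqid = g$seqid, start = g$start, end = g$end,
                    strand = fifelse(g$strand %in% c("+", "-"), g$strand, "."))
  setorder(tab, seqid, start, gene_fid)
  cc$gene_table <- tab
  tab
}

# child feature types available as overlap-flag columns
.child_flag_types <- function(db) {
  e <- db$hierarchy$edges
  sort(unique(e$child_type[e$parent_type %chin% transcript_types(db)]))
}

# attribute keys available as annotation columns (gene/transcript level),
# with per-transcript values (transcript attribute wins over gene's)
.attr_keys <- function(db) {
  gt <- c(gene_types(db), transcript_types(db))
  keys <- unlist(db$hierarchy$attrs_per_type[gt], use.names = FALSE)
  sort(setdiff(unique(keys), c("gene_id", "transcript_id")))
}

.attr_wide <- function(db) {
  cc <- .db_cache(db)
  if (!is.null(cc$attr_wide)) return(cc$attr_wide)
  tx <- .tx_table(db)
  keys <- .attr_keys(db)
  wide <- data.table(tx_fid = tx$tx_fid)
  if (length(keys)) {
    ta <- db$attributes[key %chin% keys & feature_id %chin% tx$tx_fid]
    ga <- db$attributes[key %chin% keys & feature_id %chin% tx$gene_fid]
    ga <- merge(data.table(tx_fid = tx$tx_fid, feature_id = tx$gene_fid), ga,
                by = "feature_id", allow.cartesian = TRUE)[, .(tx_fid, key, value)]
    ta <- setnames(data.table(tx_fid = ta$feature_id, k = ta$key,
                              value = ta$value), "k", "key")
    long <- rbind(ta, ga)                       # transcript rows first: they win
    long <- unique(long, by = c("tx_fid", "key"))
    w <- dcast(long, tx_fid ~ key, value.var = "value", fill = NA_TOKEN)
    wide <- merge(wide, w, by = "tx_fid", all.x = TRUE, sort = FALSE)
    for (k in keys) {
      if (!k %in% names(wide)) wide[, (k) := NA_TOKEN]
      set(wide, which(is.na(wide[[k]])), k, NA_TOKEN)
    }
  }
  cc$attr_wide <- wide
  wide
}

# Vectorised spliced projection for (transcript, genomic interval) pairs.
# `pairs` needs columns pair, tx_fid, gs, ge; returns one row per pair with
# ts, te (NA when fully intronic), n_exonic, flag.
.project_pairs <- function(db, pairs) {
  ex <- .exon_table(db)
  tx <- .tx_table(db)
  j <- merge(pairs, ex, by = "tx_fid", allow.cartesian = TRUE)
  j[, `:=`(os = pmax(gs, es), oe = pmin(ge, ee))]
  j <- j[os <= oe]
  j[, `:=`(p1 = cum_before + os - es + 1L, p2 = cum_before + oe - es + 1L)]
  agg <- j[, .(lo = min(p1), hi = max(p2), n_exonic = sum(p2 - p1 + 1L)),
           by = pair]
  out <- merge(pairs, agg, by = "pair", all.x = TRUE, sort = FALSE)
  out <- merge(out, tx[, .(tx_fid, strand, spliced_length, txs = start, txe = end)],
               by = "tx_fid", sort = FALSE)
  out[, n_clip := pmin(ge, txe) - pmax(gs, txs) + 1L]
  out[, `:=`(ts = lo, te = hi)]
  minus <- which(out$strand == "-" & !is.na(out$lo))
  if (length(minus)) {
    out[minus, `:=`(ts = spliced_length - hi + 1L, te = spliced_length - lo + 1L)]
  }
  out[, flag := fifelse(is.na(lo), "fully_intronic",
                        fifelse(n_exonic == n_clip, "fully_exonic",
                                "partially_intronic"))]
  out[is.na(n_exonic), n_exonic := 0L]
  setorder(out, pair)
  out[, .(pair, tx_fid, gs, ge, ts, te, n_exonic, flag)]
}

# ---------------------------------------------------------------------------
# options

#' Annotation options
#'
#' Collects every knob of the annotation engine: the coordinate mode, the
#' selection of child feature types and attributes to append, the
#' grouping level and the containment policy. Selected names are matched
#' case-insensitively and validated against the database hierarchy before
#' annotation starts.
#'
#' @param mode `"genomic"` (references are chromosomes) or
#'   `"transcriptomic"` (references are transcript IDs).
#' @param feature_types `"all"` or a character vector of child feature
#'   types to report as overlap-flag columns (e.g. `c("cds",
#'   "three_prime_utr")`).
#' @param attributes `"all"` or a character vector of attribute names to
#'   append (e.g. `"gene_biotype"`).
#' @param level `"transcript"` (default; one output row per overlapping
#'   transcript) or `"gene"` (alternative transcripts grouped into one
#'   row).
#' @param containment `"partial"` (default; any overlap matches) or
#'   `"full"` (the interval must lie entirely within the feature).
#' @param convention The [coord_convention()] of the input coordinates.
#' @return An `annotation_options` object.
#' @export
annotation_options <- function(mode = c("genomic", "transcriptomic"),
                               feature_types = "all",
                               attributes = "all",
                               level = c("transcript", "gene"),
                               containment = c("partial", "full"),
                               convention = convention_gff()) {
  structure(list(
    mode = match.arg(mode),
    feature_types = feature_types,
    attributes = attributes,
    level = match.arg(level),
    containment = match.arg(containment),
    convention = convention
  ), class = "annotation_options")
}

# resolve "all"/user selections against the database; fatal on unknown names
.resolve_selection <- function(db, options) {
  avail_ft <- .child_flag_types(db)
  avail_at <- .attr_keys(db)
  sel_ft <- if (identical(options$feature_types, "all")) avail_ft else {
    want <- lc(options$feature_types)
    bad <- setdiff(want, avail_ft)
    if (length(bad))
      abort_config("unknown feature type(s): ", paste(bad, collapse = ", "),
                   "; available: ", paste(avail_ft, collapse = ", "))
    avail_ft[avail_ft %chin% want]
  }
  sel_at <- if (identical(options$attributes, "all")) avail_at else {
    want <- lc(options$attributes)
    bad <- setdiff(want, avail_at)
    if (length(bad))
      abort_config("unknown attribute(s): ", paste(bad, collapse = ", "),
                   "; available: ", paste(avail_at, collapse = ", "))
    avail_at[avail_at %chin% want]
  }
  list(feature_types = sel_ft, attributes = sel_at)
}

#' Names of the annotation columns a run will append
#'
#' @param db An `annotation_db`.
#' @param options [annotation_options()].
#' @return Character vector of appended column names, in output order.
#' @export
annotation_columns <- function(db, options = annotation_options()) {
  sel <- .resolve_selection(db, options)
  c("annotated_gene_id", "annotated_transcript_id", "annotated_feature_type",
    "annotated_chromosome", "annotated_transcript_start", "annotated_transcript_end",
    sel$feature_types, sel$attributes,
    if (options$mode == "genomic")
      c("annotated_left_gene", "annotated_left_distance", "annotated_left_strand",
        "annotated_right_gene", "annotated_right_distance", "annotated_right_strand"),
    "annotated_note", "feature_region")
}

# ---------------------------------------------------------------------------
# the engine

#' Annotate a table of intervals
#'
#' The core engine behind the `annotate` command. Takes canonical
#' (1-based end-inclusive) intervals and returns one annotation row per
#' (interval, matched transcript) pair — or per gene at gene level — plus
#' exactly one intergenic row for genomic intervals overlapping no
#' transcript, and one unannotated row for unknown transcript references.
#' Output row order is deterministic: input order, then gene ID, then
#' transcript ID.
#'
#' @param records A data.frame with columns `idx` (input row number),
#'   `id`, `reference`, `start`, `end` and logical `valid` (invalid rows
#'   pass through unannotated, flagged in `annotated_note`).
#' @param db An `annotation_db`.
#' @param options [annotation_options()].
#' @return A data.table with column `idx` followed by the columns of
#'   [annotation_columns()], all character.
#' @export
annotate_intervals <- function(records, db, options = annotation_options()) {
  records <- as.data.table(records)
  sel <- .resolve_selection(db, options)
  cols <- annotation_columns(db, options)
  blank <- function(idx, note) {
    if (!length(idx)) return(NULL)
    b <- data.table(idx = idx)
    for (cn in cols) b[, (cn) := NA_TOKEN]
    b[, annotated_note := note]
    b
  }
  bad <- records[valid == FALSE | is.na(valid)]
  rec <- records[valid == TRUE]
  rows <- if (options$mode == "genomic") {
    .annotate_genomic_batch(rec, db, options, sel, cols)
  } else {
    .annotate_tx_batch(rec, db, options, sel, cols)
  }
  out <- rbindlist(list(rows, blank(bad$idx, "malformed_input")), use.names = TRUE)
  if (options$level == "gene") out <- group_by_gene(out)
  setorderv(out, intersect(c("idx", "annotated_gene_id", "annotated_transcript_id"),
                           names(out)))
  out[, intersect(c("idx", cols), names(out)), with = FALSE]
}

.annotate_genomic_batch <- function(rec, db, options, sel, cols) {
  tx <- .tx_table(db)
  full <- options$containment == "full"
  if (!nrow(rec)) return(NULL)
  q <- GRanges(rec$reference, IRanges(rec$start, rec$end))
  tgr <- GRanges(tx$seqid, IRanges(tx$start, tx$end))
  hits <- suppressWarnings(findOverlaps(q, tgr, type = if (full) "within" else "any"))
  pairs <- data.table(rec_i = queryHits(hits), tx_i = subjectHits(hits))
  pairs[, pair := .I]
  ann <- NULL
  if (nrow(pairs)) {
    p <- data.table(pair = pairs$pair,
                    tx_fid = tx$tx_fid[pairs$tx_i],
                    gs = rec$start[pairs$rec_i],
                    ge = rec$end[pairs$rec_i])
    proj <- .project_pairs(db, p)
    region <- rep(REGION_VOCAB[["intronic"]], nrow(proj))
    exonic <- !is.na(proj$ts)
    if (any(exonic)) {
      sl <- tx$spliced_length[pairs$tx_i][exonic]
      region[exonic] <- classify_region(proj$ts[exonic], proj$te[exonic], sl)
    }
    flags <- .child_flags_genomic(db, p, sel$feature_types, full)
    t2 <- tx[pairs$tx_i]
    aw <- .attr_wide(db)
    ann <- data.table(idx = rec$idx[pairs$rec_i],
                      annotated_gene_id = t2$gene_id,
                      annotated_transcript_id = t2$transcript_id,
                      annotated_feature_type = t2$feature_type,
                      annotated_chromosome = t2$seqid,
                      annotated_transcript_start = as.character(t2$start),
                      annotated_transcript_end = as.character(t2$end))
    ann <- cbind(ann, flags)
    for (k in sel$attributes) ann[, (k) := aw[[k]][match(t2$tx_fid, aw$tx_fid)]]
    ann[, `:=`(annotated_left_gene = NA_TOKEN, annotated_left_distance = NA_TOKEN,
               annotated_left_strand = NA_TOKEN, annotated_right_gene = NA_TOKEN,
               annotated_right_distance = NA_TOKEN, annotated_right_strand = NA_TOKEN,
               annotated_note = NA_TOKEN, feature_region = region)]
  }
  # intervals with no transcript match -> one intergenic row each
  unhit <- setdiff(seq_len(nrow(rec)), unique(pairs$rec_i))
  inter <- NULL
  if (length(unhit)) {
    nb <- .closest_genes(db, rec[unhit])
    inter <- data.table(idx = rec$idx[unhit])
    for (cn in cols) inter[, (cn) := NA_TOKEN]
    inter[, `:=`(annotated_feature_type = "intergenic",
                 annotated_chromosome = rec$reference[unhit],
                 annotated_left_gene = nb$left_gene,
                 annotated_left_distance = nb$left_distance,
                 annotated_left_strand = nb$left_strand,
                 annotated_right_gene = nb$right_gene,
                 annotated_right_distance = nb$right_distance,
                 annotated_right_strand = nb$right_strand)]
  }
  rbindlist(list(ann, inter), use.names = TRUE, fill = TRUE)
}

# overlap flags between interval/transcript pairs and the transcripts'
# child features, under the containment policy
.child_flags_genomic <- function(db, p, flag_types, full) {
  kids <- .child_table(db)
  out <- data.table(pair = p$pair)
  for (ft in flag_types) out[, (ft) := NA_TOKEN]
  if (nrow(kids) && nrow(p)) {
    j <- merge(p, kids, by = "tx_fid", allow.cartesian = TRUE,
               suffixes = c("", ".k"))
    ok <- if (full) j$gs >= j$gs.k & j$ge <= j$ge.k
          else j$gs <= j$ge.k & j$ge >= j$gs.k
    j <- j[ok & child_type %chin% flag_types]
    if (nrow(j)) {
      hit <- unique(j[, .(pair, child_type)])
      for (ft in intersect(flag_types, unique(hit$child_type)))
        set(out, which(out$pair %in% hit$pair[hit$child_type == ft]), ft, "y")
    }
  }
  out[, pair := NULL]
  out
}

.annotate_tx_batch <- function(rec, db, options, sel, cols) {
  if (!nrow(rec)) return(NULL)
  tx <- .tx_table(db)
  lk <- .tx_lookup(db)
  fid <- lk$feature_id[match(lc(rec$reference), lk$key)]
  known <- !is.na(fid)
  out <- NULL
  if (any(known)) {
    i <- which(known)
    t2 <- tx[match(fid[i], tx$tx_fid)]
    s <- rec$start[i]
    e <- pmin(rec$end[i], t2$spliced_length)
    oob <- rec$end[i] > t2$spliced_length | rec$start[i] > t2$spliced_length
    s <- pmin(s, t2$spliced_length)
    region <- classify_region(s, e, t2$spliced_length)
    flags <- .child_flags_tx(db, t2$tx_fid, s, e, sel$feature_types,
                             options$containment == "full")
    aw <- .attr_wide(db)
    out <- data.table(idx = rec$idx[i],
                      annotated_gene_id = t2$gene_id,
                      annotated_transcript_id = t2$transcript_id,
                      annotated_feature_type = t2$feature_type,
                      annotated_chromosome = t2$seqid,
                      annotated_transcript_start = as.character(t2$start),
                      annotated_transcript_end = as.character(t2$end))
    out <- cbind(out, flags)
    for (k in sel$attributes) out[, (k) := aw[[k]][match(t2$tx_fid, aw$tx_fid)]]
    out[, `:=`(annotated_note = fifelse(oob, "end_clamped_to_transcript", NA_TOKEN),
               feature_region = region)]
  }
  unknown <- NULL
  if (any(!known)) {
    warning(sprintf("%d interval(s) reference transcript IDs absent from the database",
                    sum(!known)), call. = FALSE)
    unknown <- data.table(idx = rec$idx[!known])
    for (cn in cols) unknown[, (cn) := NA_TOKEN]
    unknown[, annotated_note := "unknown_reference"]
  }
  rbindlist(list(out, unknown), use.names = TRUE, fill = TRUE)
}

# flags from transcript-space intersection with child features
.child_flags_tx <- function(db, tx_fid, s, e, flag_types, full) {
  kids <- .child_table(db)
  out <- data.table(.i = seq_along(tx_fid))
  for (ft in flag_types) out[, (ft) := NA_TOKEN]
  if (nrow(kids)) {
    # in transcript space the parts of one child type are contiguous, so
    # flags are computed on the per-type union span
    ku <- kids[!is.na(ts), .(ts = min(ts), te = max(te)), by = .(tx_fid, child_type)]
    q <- data.table(.i = seq_along(tx_fid), tx_fid = tx_fid, s = s, e = e)
    j <- merge(q, ku, by = "tx_fid", allow.cartesian = TRUE)
    ok <- if (full) j$s >= j$ts & j$e <= j$te else j$s <= j$te & j$e >= j$ts
    j <- j[ok & child_type %chin% flag_types]
    if (nrow(j)) {
      hit <- unique(j[, .(.i, child_type)])
      for (ft in intersect(flag_types, unique(hit$child_type)))
        set(out, which(out$.i %in% hit$.i[hit$child_type == ft]), ft, "y")
    }
  }
  out[, .i := NULL]
  out
}

# closest genes strictly left / right of intervals that hit nothing
.closest_genes <- function(db, rec) {
  g <- .gene_table(db)
  n <- nrow(rec)
  res <- data.table(left_gene = rep(NA_TOKEN, n), left_distance = NA_TOKEN,
                    left_strand = NA_TOKEN, right_gene = NA_TOKEN,
                    right_distance = NA_TOKEN, right_strand = NA_TOKEN)
  for (sq in unique(rec$reference)) {
    gi <- g[seqid == sq]
    ri <- which(rec$reference == sq)
    if (!nrow(gi)) next
    # left neighbor: maximal end < interval start (ties broken by gene_id
    # via the sort order)
    le <- gi[order(end, gene_id)]
    li <- findInterval(rec$start[ri] - 1L, le$end)
    has <- li >= 1L
    if (any(has)) {
      set(res, ri[has], "left_gene", le$gene_id[li[has]])
      set(res, ri[has], "left_distance",
          as.character(rec$start[ri[has]] - le$end[li[has]]))
      set(res, ri[has], "left_strand", le$strand[li[has]])
    }
    # right neighbor: minimal start > interval end
    rs <- gi[order(start, gene_id)]
    ji <- findInterval(rec$end[ri], rs$start) + 1L
    has <- ji <= nrow(rs)
    if (any(has)) {
      set(res, ri[has], "right_gene", rs$gene_id[ji[has]])
      set(res, ri[has], "right_distance",
          as.character(rs$start[ji[has]] - rec$end[ri[has]]))
      set(res, ri[has], "right_strand", rs$strand[ji[has]])
    }
  }
  res
}

# ---------------------------------------------------------------------------
# single-interval wrappers and gene-level grouping

#' Annotate one genomic interval
#'
#' Convenience wrapper around [annotate_intervals()] for a single
#' canonical genomic interval.
#'
#' @param id Interval identifier.
#' @param seqid Chromosome / scaffold.
#' @param start,end Canonical (1-based inclusive) genomic span.
#' @param db An `annotation_db`.
#' @param options [annotation_options()]; the mode is forced to genomic.
#' @return A data.table of annotation rows.
#' @export
annotate_genomic <- function(id, seqid, start, end, db,
                             options = annotation_options()) {
  options$mode <- "genomic"
  annotate_intervals(data.table(idx = 1L, id = id, reference = seqid,
                                start = as.integer(start), end = as.integer(end),
                                valid = TRUE), db, options)
}

#' Annotate one transcript-coordinate interval
#'
#' @param id Interval identifier.
#' @param transcript_id Reference transcript ID (case-insensitive).
#' @param start,end Spliced transcript positions, 1-based inclusive.
#' @inheritParams annotate_genomic
#' @return A data.table with exactly one annotation row.
#' @export
annotate_transcriptomic <- function(id, transcript_id, start, end, db,
                                    options = annotation_options("transcriptomic")) {
  options$mode <- "transcriptomic"
  annotate_intervals(data.table(idx = 1L, id = id, reference = transcript_id,
                                start = as.integer(start), end = as.integer(end),
                                valid = TRUE), db, options)
}

#' Closest genes flanking an intergenic interval
#'
#' For an interval overlapping no gene, reports the closest gene strictly
#' to its left (maximal end below the interval start) and right (minimal
#' start above the interval end) on the same sequence, with closed-
#' interval boundary distances (adjacent features have distance 1) and
#' the neighbors' strands. A side with no gene is reported as `"."`.
#'
#' @param seqid Chromosome / scaffold.
#' @param start,end Canonical genomic span.
#' @param db An `annotation_db`.
#' @return A one-row data.table with left/right gene, distance and strand.
#' @export
mark_intergenic <- function(seqid, start, end, db) {
  .closest_genes(db, data.table(reference = seqid, start = as.integer(start),
                                end = as.integer(end)))
}

#' Collapse transcript-level annotation rows to gene level
#'
#' Alternative transcripts of one gene are grouped into a single row per
#' (interval, gene): transcript IDs are comma-concatenated in the order
#' annotated, child overlap flags are OR-ed ("y" wins over "."), and
#' differing per-transcript values (regions, biotypes) are joined as
#' comma-separated uniques. Intergenic and unannotated rows pass through
#' unchanged. The set of (interval, gene) pairs is preserved exactly.
#'
#' @param rows Annotation rows from a transcript-level run.
#' @return A data.table with one row per (interval, gene).
#' @export
group_by_gene <- function(rows) {
  rows <- as.data.table(rows)
  passthrough <- rows[annotated_gene_id == NA_TOKEN | is.na(annotated_gene_id)]
  gr <- rows[!(annotated_gene_id == NA_TOKEN | is.na(annotated_gene_id))]
  if (!nrow(gr)) return(rows)
  join_vals <- function(v) {
    u <- unique(v[v != NA_TOKEN & !is.na(v)])
    if (!length(u)) NA_TOKEN else paste(u, collapse = ",")
  }
  agg <- gr[, c(list(annotated_transcript_id = paste(annotated_transcript_id,
                                                     collapse = ",")),
                lapply(.SD, function(v) {
                  if (any(v == "y", na.rm = TRUE)) "y" else join_vals(v)
                })),
            by = .(idx, annotated_gene_id),
            .SDcols = setdiff(names(gr), c("idx", "annotated_gene_id",
                                           "annotated_transcript_id"))]
  agg[, annotated_feature_type := "gene"]
  out <- rbindlist(list(agg, passthrough), use.names = TRUE, fill = TRUE)
  setcolorder(out, names(rows))
  setorderv(out, c("idx", "annotated_gene_id"))
  out[]
}
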