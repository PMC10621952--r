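#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Child feature types that must never be mistaken for transcript records
# when a GTF producer omits explicit transcript lines.
.CHILD_TYPES <- c("exon", "cds", "five_prime_utr", "three_prime_utr", "utr",
                  "start_codon", "stop_codon", "intron", "selenocysteine")

# ---------------------------------------------------------------------------
# parsing

#' Detect the annotation dialect of a file
#'
#' GTF and GFF3 share the nine-column layout and differ only in the
#' attribute column: GFF3 uses `key=value` pairs, GTF quoted
#' space-separated pairs. Detection goes by file extension first
#' (`.gtf` vs `.gff`/`.gff3`), falling back to sniffing the attribute
#' column of the first data line.
#'
#' @param path File path.
#' @param sample_attr Optional attribute string to sniff instead of
#'   reading the file.
#' @return `"gtf"` or `"gff3"`.
#' @export
detect_dialect <- function(path, sample_attr = NULL) {
  ext <- lc(tools::file_ext(path))
  if (ext == "gtf") return("gtf")
  if (ext %in% c("gff", "gff3")) return("gff3")
  if (is.null(sample_attr)) {
    for (ln in readLines(path, n = 200L, warn = FALSE)) {
      if (!nzchar(ln) || startsWith(ln, "#")) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(f) >= 9L) { sample_attr <- f[9L]; break }
    }
  }
  if (is.null(sample_attr)) abort_data("cannot detect annotation dialect of ", path)
  if (grepl("\\w+\\s*=", sample_attr) && !grepl("\"", sample_attr)) "gff3" else "gtf"
}

# attribute column -> long table (row, key, value); keys lowercased,
# values kept verbatim apart from GTF quote stripping.
.parse_attr_column <- function(attr, dialect) {
  sp <- strsplit(attr, ";", fixed = TRUE)
  row <- rep.int(seq_along(sp), lengths(sp))
  tok <- trimws(unlist(sp, use.names = FALSE))
  keep <- nzchar(tok)
  row <- row[keep]; tok <- tok[keep]
  if (dialect == "gff3") {
    eq <- regexpr("=", tok, fixed = TRUE)
    ok <- eq > 0L
    dt <- data.table(row = row[ok],
                     k = lc(substr(tok[ok], 1L, eq[ok] - 1L)),
                     value = substr(tok[ok], eq[ok] + 1L, nchar(tok[ok])))
  } else {
    ws <- regexpr("[ \t]", tok)
    ok <- ws > 0L
    val <- trimws(substr(tok[ok], ws[ok] + 1L, nchar(tok[ok])))
    val <- sub("^\"", "", sub("\"$", "", val))
    dt <- data.table(row = row[ok], k = lc(trimws(substr(tok[ok], 1L, ws[ok] - 1L))),
                     value = val)
  }
  setnames(dt, "k", "key")
  dt
}

# Parse a GTF/GFF3 file into raw field + attribute tables. Chunked
# attribute parsing (disk_direct) trades speed for a lower peak by
# spilling per-chunk results to temporary files.
.parse_annotation_file <- function(path, dialect = NULL, disk_direct = FALSE,
                                   chunk_size = 50000L) {
  if (!file.exists(path)) abort_data("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  fasta_at <- which(startsWith(lines, "##FASTA"))
  if (length(fasta_at)) lines <- lines[seq_len(fasta_at[1L] - 1L)]
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) {
    return(list(fields = data.table(), attrs = data.table(), dialect = dialect %||% "gff3"))
  }
  fl <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fl)
  if (any(nf < 9L))
    abort_data("malformed annotation record (", nf[nf < 9L][1L],
               " field(s), expected 9) at line ", lineno[nf < 9L][1L], " of ", path)
  m <- matrix(unlist(lapply(fl, `[`, 1:9), use.names = FALSE), ncol = 9L, byrow = TRUE)
  if (is.null(dialect)) dialect <- detect_dialect(path, sample_attr = m[1L, 9L])
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start) | is.na(end) | start > end)
  if (length(bad))
    abort_data("invalid coordinates at line ", lineno[bad[1L]], " of ", path)
  fields <- data.table(
    row = seq_len(nrow(m)),
    seqid = m[, 1L],
    feature_type = lc(m[, 3L]),
    start = start, end = end,
    strand = ifelse(m[, 7L] %in% c("+", "-"), m[, 7L], "."),
    line = lineno
  )
  n <- nrow(m)
  if (disk_direct && n > chunk_size) {
    tmp <- character(0L)
    for (i in seq(1L, n, by = chunk_size)) {
      j <- min(i + chunk_size - 1L, n)
      part <- .parse_attr_column(m[i:j, 9L], dialect)
      part[, row := row + i - 1L]
      f <- tempfile(fileext = ".rds")
      saveRDS(part, f)
      tmp <- c(tmp, f)
    }
    attrs <- rbindlist(lapply(tmp, readRDS))
    unlink(tmp)
  } else {
    attrs <- .parse_attr_column(m[, 9L], dialect)
  }
  list(fields = fields, attrs = attrs, dialect = dialect)
}

# ---------------------------------------------------------------------------
# database assembly

.assemble_db <- function(parsed, source_path) {
  fields <- parsed$fields
  attrs <- parsed$attrs
  dialect <- parsed$dialect
  n <- nrow(fields)
  if (n == 0L) {
    feats <- data.table(feature_id = character(), feature_type = character(),
                        seqid = character(), start = integer(), end = integer(),
                        strand = character(), parent_id = character())
    return(structure(list(features = feats,
                          attributes = setnames(data.table(feature_id = character(),
                                                  k = character(), value = character()), "k", "key"),
                          hierarchy = .build_hierarchy(feats, feats[0L]),
                          source_path = source_path, dialect = dialect,
                          build_mode = "memory-first"),
                     class = "annotation_db"))
  }
  pick <- function(k_) {
    out <- rep(NA_character_, n)
    sel <- which(attrs$key == k_)
    hit <- attrs[sel]
    hit <- hit[!duplicated(hit$row)]
    out[hit$row] <- hit$value
    out
  }

  if (dialect == "gff3") {
    id <- pick("id")
    parent <- pick("parent")
    parent <- sub(",.*$", "", parent)            # multi-parent: keep the first
    miss <- is.na(id)
    id[miss] <- sprintf("%s:%s:%d-%d", fields$feature_type[miss],
                        fields$seqid[miss], fields$start[miss], fields$end[miss])
    feats <- data.table(feature_id = id, feature_type = fields$feature_type,
                        seqid = fields$seqid, start = fields$start, end = fields$end,
                        strand = fields$strand, parent_id = parent, row = fields$row)
    synth <- NULL
  } else {
    gene_id <- pick("gene_id")
    tx_id <- pick("transcript_id")
    ft <- fields$feature_type
    is_gene <- ft == "gene" | (is.na(tx_id) & !is.na(gene_id))
    is_tx <- !is_gene & !(ft %in% .CHILD_TYPES) &
      (ft == "transcript" | grepl("rna|transcript", ft)) & !is.na(tx_id)
    kind <- ifelse(is_gene, "gene", ifelse(is_tx, "tx", "child"))
    id <- character(n); parent <- rep(NA_character_, n)
    id[is_gene] <- gene_id[is_gene]
    id[is_tx] <- tx_id[is_tx]
    parent[is_tx] <- gene_id[is_tx]
    ch <- which(kind == "child")
    if (length(ch)) {
      key <- paste(tx_id[ch], ft[ch], sep = ":")
      ord <- stats::ave(seq_along(ch), key, FUN = seq_along)
      id[ch] <- sprintf("%s:%s:%d", tx_id[ch], ft[ch], ord)
      parent[ch] <- tx_id[ch]
    }
    noid <- is.na(id) | !nzchar(id)
    id[noid] <- sprintf("%s:%s:%d-%d", ft[noid], fields$seqid[noid],
                        fields$start[noid], fields$end[noid])
    feats <- data.table(feature_id = id, feature_type = ft,
                        seqid = fields$seqid, start = fields$start, end = fields$end,
                        strand = fields$strand, parent_id = parent, row = fields$row)
    # synthesize transcript and gene records absent from the file
    synth <- list()
    need_tx <- setdiff(unique(tx_id[kind == "child" & !is.na(tx_id)]),
                       feats$feature_id[kind == "tx"])
    if (length(need_tx)) {
      chd <- feats[kind == "child" & parent_id %chin% need_tx]
      chd[, gene := gene_id[row]]
      st <- chd[, .(seqid = seqid[1L], start = min(start), end = max(end),
                    strand = strand[1L], gene = gene[1L]), by = parent_id]
      synth$tx <- data.table(feature_id = st$parent_id, feature_type = "transcript",
                             seqid = st$seqid, start = st$start, end = st$end,
                             strand = st$strand, parent_id = st$gene, row = NA_integer_)
      extra <- data.table(feature_id = rep(st$parent_id, 2L),
                          k = rep(c("transcript_id", "gene_id"), each = nrow(st)),
                          value = c(st$parent_id, st$gene))
      setnames(extra, "k", "key")
      synth$tx_attrs <- extra[!is.na(value)]
    }
    all_tx <- rbind(feats[kind == "tx"], synth$tx %||% feats[0L])
    need_gene <- setdiff(unique(all_tx$parent_id[!is.na(all_tx$parent_id)]),
                         feats$feature_id[kind == "gene"])
    if (length(need_gene)) {
      tg <- all_tx[parent_id %chin% need_gene]
      sg <- tg[, .(seqid = seqid[1L], start = min(start), end = max(end),
                   strand = strand[1L]), by = parent_id]
      synth$gene <- data.table(feature_id = sg$parent_id, feature_type = "gene",
                               seqid = sg$seqid, start = sg$start, end = sg$end,
                               strand = sg$strand, parent_id = NA_character_,
                               row = NA_integer_)
      synth$gene_attrs <- setnames(
        data.table(feature_id = sg$parent_id, k = "gene_id", value = sg$parent_id),
        "k", "key")
    }
    if (!is.null(synth$tx)) feats <- rbind(feats, synth$tx)
    if (!is.null(synth$gene)) feats <- rbind(feats, synth$gene)
  }

  # duplicate IDs: keep the first untouched, suffix later occurrences
  dup <- duplicated(feats$feature_id)
  if (any(dup)) {
    warning(sprintf("%d duplicate feature ID(s) in %s; later occurrences suffixed",
                    sum(dup), source_path), call. = FALSE)
    feats[, feature_id := make.unique(feature_id, sep = "..")]
  }

  # attribute store keyed by feature_id; GFF3 structural keys dropped
  attrs2 <- attrs[!(attrs$key %in% c("id", "parent")), ]
  attrs2 <- setnames(
    data.table(feature_id = feats$feature_id[match(attrs2$row, feats$row)],
               k = attrs2$key, value = attrs2$value), "k", "key")
  attrs2 <- attrs2[!is.na(feature_id)]
  if (!is.null(synth) && !is.null(synth$tx_attrs)) attrs2 <- rbind(attrs2, synth$tx_attrs)
  if (!is.null(synth) && !is.null(synth$gene_attrs)) attrs2 <- rbind(attrs2, synth$gene_attrs)
  attrs2 <- unique(attrs2, by = c("feature_id", "key"))

  # dangling parents: warn, keep the feature with a null parent
  dangle <- !is.na(feats$parent_id) & !(feats$parent_id %chin% feats$feature_id)
  if (any(dangle)) {
    warning(sprintf("%d feature(s) in %s reference a missing parent; kept with no parent",
                    sum(dangle), source_path), call. = FALSE)
    feats[dangle, parent_id := NA_character_]
  }
  feats[, row := NULL]
  setkey(attrs2, feature_id)

  structure(list(
    features = feats,
    attributes = attrs2,
    hierarchy = .build_hierarchy(feats, attrs2),
    source_path = source_path,
    dialect = dialect,
    build_mode = "memory-first"
  ), class = "annotation_db")
}

.build_hierarchy <- function(feats, attrs) {
  types <- sort(unique(feats$feature_type))
  if (!nrow(feats)) {
    return(structure(list(types = character(), edges = data.table(
      parent_type = character(), child_type = character(), n = integer()),
      attrs_per_type = list(), counts = integer()), class = "feature_hierarchy"))
  }
  ptype <- feats$feature_type[match(feats$parent_id, feats$feature_id)]
  e <- data.table(parent_type = ptype, child_type = feats$feature_type)[!is.na(parent_type)]
  edges <- e[, .N, by = .(parent_type, child_type)]
  setnames(edges, "N", "n")
  setorder(edges, parent_type, child_type)
  apt <- if (nrow(attrs)) {
    a <- merge(attrs, feats[, .(feature_id, feature_type)], by = "feature_id")
    split(a$key, a$feature_type) |> lapply(\(k) sort(unique(k)))
  } else list()
  if (length(apt)) apt <- apt[order(names(apt))]
  structure(list(types = types, edges = edges,
                 attrs_per_type = apt,
                 counts = table(feats$feature_type)),
            class = "feature_hierarchy")
}

# ---------------------------------------------------------------------------
# public surface

#' Build the annotation database from a GTF/GFF3 file
#'
#' Parses a genome annotation into a relational feature store: a feature
#' table (type, span, strand, parent link), an attribute table and the
#' observed feature-type hierarchy. Feature types and attribute keys are
#' lowercased so later queries are case-insensitive; attribute values are
#' kept verbatim (IDs keep their case). GTF files whose producers omit
#' explicit gene/transcript lines get those records synthesized from the
#' `gene_id`/`transcript_id` attributes of their children. The database
#' can be persisted with `output_path` and reopened with [load_db()]; it
#' only needs to be built once per annotation file.
#'
#' @param annotation_path Path to a GTF or GFF3 file (dialect
#'   auto-detected; a trailing `##FASTA` section is ignored).
#' @param output_path Optional path for the persisted single-file store.
#' @param disk_direct Build by chunked parsing with intermediate spill
#'   files, reducing peak memory at some time cost. The resulting
#'   database is identical to a memory-first build.
#' @param chunk_size Records per chunk for the disk-direct build.
#' @return An object of class `annotation_db`.
#' @export
build_db <- function(annotation_path, output_path = NULL, disk_direct = FALSE,
                     chunk_size = 50000L) {
  parsed <- .parse_annotation_file(annotation_path, disk_direct = disk_direct,
                                   chunk_size = chunk_size)
  db <- .assemble_db(parsed, source_path = annotation_path)
  db$build_mode <- if (disk_direct) "disk-direct" else "memory-first"
  attr(db, "cache") <- new.env(parent = emptyenv())
  if (!is.null(output_path)) save_db(db, output_path)
  db
}

#' @rdname build_db
#' @param db An `annotation_db`.
#' @param path Path of the persisted store.
#' @export
save_db <- function(db, path) {
  stopifnot(inherits(db, "annotation_db"))
  core <- unclass(db)
  attributes(core) <- attributes(core)["names"]
  saveRDS(structure(core, class = "annotation_db"), path)
  invisible(path)
}

#' @rdname build_db
#' @export
load_db <- function(path) {
  if (!file.exists(path)) abort_data("database file not found: ", path)
  db <- readRDS(path)
  if (!inherits(db, "annotation_db")) abort_data(path, " is not an annotation database")
  attr(db, "cache") <- new.env(parent = emptyenv())
  db
}

#' @export
print.annotation_db <- function(x, ...) {
  cat(sprintf("<annotation database: %d features, %d types, %s build from %s>\n",
              nrow(x$features), length(x$hierarchy$types), x$build_mode,
              x$source_path))
  invisible(x)
}

.db_cache <- function(db) {
  cc <- attr(db, "cache")
  if (is.null(cc)) stop("database has no cache environment; load it with load_db()")
  cc
}

# feature GRanges aligned with db$features rows
.feat_gr <- function(db) {
  cc <- .db_cache(db)
  if (is.null(cc$feat_gr))
    cc$feat_gr <- GRanges(db$features$seqid,
                          IRanges(db$features$start, db$features$end))
  cc$feat_gr
}

#' Feature types that act as transcripts or genes
#'
#' Transcript-like types are those observed as parents of exon/CDS
#' records plus any type whose name contains "rna" or "transcript";
#' gene-like types are the parents of transcript-like types plus "gene".
#'
#' @param db An `annotation_db`.
#' @return Character vector of feature types.
#' @export
transcript_types <- function(db) {
  e <- db$hierarchy$edges
  from_edges <- unique(e$parent_type[e$child_type %in% c("exon", "cds")])
  by_name <- db$hierarchy$types[grepl("rna|transcript", db$hierarchy$types) &
                                  !db$hierarchy$types %in% .CHILD_TYPES]
  sort(unique(c(from_edges, by_name)))
}

#' @rdname transcript_types
#' @export
gene_types <- function(db) {
  e <- db$hierarchy$edges
  tt <- transcript_types(db)
  sort(unique(c("gene", e$parent_type[e$child_type %in% tt])))
}

#' Query features overlapping a genomic span
#'
#' Closed-interval (1-based inclusive) overlap, so a query ending exactly
#' at a feature start still touches it. Results come back ordered by
#' start then feature ID; an unknown sequence name yields an empty
#' result, not an error.
#'
#' @param db An `annotation_db`.
#' @param seqid Chromosome / scaffold name.
#' @param start,end Query span, canonical coordinates.
#' @param feature_types Optional character vector restricting the result
#'   (matched case-insensitively).
#' @return A data.table of feature records.
#' @export
fetch_overlapping <- function(db, seqid, start, end, feature_types = NULL) {
  stopifnot(start <= end)
  gr <- .feat_gr(db)
  q <- GRanges(seqid, IRanges(as.integer(start), as.integer(end)))
  # unknown seqid is an empty result, not a condition
  idx <- suppressWarnings(subjectHits(findOverlaps(q, gr)))
  out <- db$features[idx]
  if (!is.null(feature_types)) out <- out[feature_type %chin% lc(feature_types)]
  setorder(out, start, feature_id)
  out[]
}

#' Children of a feature, in genomic order
#'
#' @param db An `annotation_db`.
#' @param parent_feature_id Feature ID of the parent.
#' @return A data.table of feature records sorted by start then ID.
#' @export
fetch_children <- function(db, parent_feature_id) {
  out <- db$features[parent_id %chin% parent_feature_id]
  setorder(out, start, feature_id)
  out[]
}

# lowercased transcript-identifier -> feature_id lookup
.tx_lookup <- function(db) {
  cc <- .db_cache(db)
  if (is.null(cc$tx_lookup)) {
    tt <- transcript_types(db)
    tx <- db$features[feature_type %chin% tt]
    ids <- db$attributes[tx, on = "feature_id"][key == "transcript_id",
                                                .(feature_id, value)]
    lk <- rbind(data.table(k = lc(tx$feature_id), feature_id = tx$feature_id),
                data.table(k = lc(ids$value), feature_id = ids$feature_id))
    setnames(lk, "k", "key")
    cc$tx_lookup <- unique(lk, by = "key")
  }
  cc$tx_lookup
}

#' Look up a transcript by ID and build its model
#'
#' The lookup is case-insensitive and accepts either the feature ID or
#' the `transcript_id` attribute value. Unknown IDs return `NULL` (a
#' recoverable signal: the annotator emits the row unannotated), never an
#' error.
#'
#' @param db An `annotation_db`.
#' @param transcript_id Transcript identifier.
#' @return A [transcript_model()] with the child features attached, or
#'   `NULL` if the ID is unknown.
#' @export
fetch_by_transcript_id <- function(db, transcript_id) {
  lk <- .tx_lookup(db)
  fid <- lk$feature_id[match(lc(transcript_id), lk$key)]
  if (is.na(fid)) return(NULL)
  db_transcript_model(db, fid)
}

#' @rdname fetch_by_transcript_id
#' @param feature_id Internal feature ID of a transcript record.
#' @export
db_transcript_model <- function(db, feature_id) {
  sel <- which(db$features$feature_id == feature_id)
  if (!length(sel)) return(NULL)
  rec <- db$features[sel[1L]]
  kids <- fetch_children(db, feature_id)
  ex <- kids[feature_type == "exon"]
  exons <- if (nrow(ex)) ex[, .(start, end)] else data.table(start = rec$start, end = rec$end)
  a <- db$attributes[db$attributes$feature_id == feature_id]
  txid <- a$value[a$key == "transcript_id"]
  transcript_model(
    transcript_id = if (length(txid)) txid[1L] else rec$feature_id,
    gene_id = rec$parent_id %||% NA_character_,
    seqid = rec$seqid,
    strand = if (rec$strand %in% c("+", "-")) rec$strand else "+",
    exons = exons,
    children = kids[feature_type != "exon"]
  )
}

# ---------------------------------------------------------------------------
# hierarchy inspection

#' Inspect the feature hierarchy of a database
#'
#' Returns the feature-type hierarchy observed in the source file — which
#' types occur, which parent→child relations link them, and which
#' attribute names each type carries — as an object whose `format()`
#' method renders the indented tree printed by the `create_db` command.
#' Every feature type and every attribute name appears exactly once per
#' type in the rendering.
#'
#' @param db An `annotation_db`.
#' @return A `feature_hierarchy` object.
#' @export
inspect_hierarchy <- function(db) db$hierarchy

#' @export
format.feature_hierarchy <- function(x, ...) {
  if (!length(x$types)) return("(empty annotation database: no features)")
  # each type is displayed once, under its most frequent parent type
  e <- x$edges[order(-n, parent_type)]
  shown_parent <- setNames(e$parent_type[!duplicated(e$child_type)],
                           e$child_type[!duplicated(e$child_type)])
  # break accidental cycles: a type is a root if its assigned parent chain
  # never closes on itself
  roots <- setdiff(x$types, names(shown_parent))
  if (!length(roots)) roots <- x$types[1L]
  kids_of <- split(names(shown_parent), shown_parent)
  out <- character(0L)
  emit <- function(type, depth, seen) {
    if (type %in% seen) return(invisible())
    ind <- if (depth == 0L) "" else paste0(strrep("    ", depth - 1L), "└── ")
    n <- x$counts[type]
    out <<- c(out, sprintf("%s%s (%d)", ind, type, n))
    at <- x$attrs_per_type[[type]]
    if (length(at))
      out <<- c(out, sprintf("%s    attributes: %s",
                             if (depth == 0L) "" else strrep("    ", depth - 1L),
                             paste(at, collapse = ", ")))
    for (k in sort(kids_of[[type]] %||% character(0L)))
      emit(k, depth + 1L, c(seen, type))
  }
  for (r in sort(roots)) emit(r, 0L, character(0L))
  # types orphaned by cycle breaking still appear once
  missing <- setdiff(x$types, sub(" .*", "", trimws(gsub("└── ", "", out))))
  for (m in missing) emit(m, 0L, character(0L))
  out
}

#' @export
print.feature_hierarchy <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
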