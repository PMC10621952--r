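#' Input table schema
#'
#' Describes how to pull intervals out of an input table. For BED and VCF
#' the column layout and coordinate convention are fixed by the standard
#' and may not be overridden; a custom table needs the four 1-based
#' column indices (interval ID, reference, start, end), its separator and
#' its declared coordinate convention.
#'
#' @param format `"bed"`, `"vcf"` or `"custom"`.
#' @param sep Field separator (default tab); custom format only.
#' @param id_col,ref_col,start_col,end_col 1-based column indices; custom
#'   format only, all four required.
#' @param convention [coord_convention()] of a custom table (default
#'   1-based end-inclusive).
#' @param header `"auto"` (default: the first line is a header if any
#'   required column fails numeric parsing), `"present"` or `"absent"`.
#' @return A `table_schema` object.
#' @export
table_schema <- function(format = c("custom", "bed", "vcf"), sep = "\t",
                         id_col = NULL, ref_col = NULL, start_col = NULL,
                         end_col = NULL, convention = convention_gff(),
                         header = c("auto", "present", "absent")) {
  format <- match.arg(format)
  header <- match.arg(header)
  if (format == "bed") {
    sep <- "\t"; ref_col <- 1L; start_col <- 2L; end_col <- 3L; id_col <- 4L
    convention <- convention_bed(); header <- "absent"
  } else if (format == "vcf") {
    sep <- "\t"; ref_col <- 1L; start_col <- 2L; id_col <- 3L; end_col <- NA_integer_
    convention <- convention_gff(); header <- "absent"
  } else {
    need <- c(id_col = is.null(id_col), ref_col = is.null(ref_col),
              start_col = is.null(start_col), end_col = is.null(end_col))
    if (any(need))
      abort_config("custom schema requires column indices: ",
                   paste(names(need)[need], collapse = ", "))
  }
  structure(list(format = format, sep = sep,
                 id_col = as.integer(id_col), ref_col = as.integer(ref_col),
                 start_col = as.integer(start_col), end_col = as.integer(end_col),
                 convention = convention, header = header),
            class = "table_schema")
}

.is_comment_line <- function(lines, format) {
  switch(format,
         vcf = startsWith(lines, "#"),
         bed = startsWith(lines, "#") | startsWith(lines, "track") |
           startsWith(lines, "browser"),
         startsWith(lines, "#"))
}

#' Read intervals from a column-based text file
#'
#' Parses BED (0-based half-open), VCF (1-based; the interval covers
#' `POS .. POS + nchar(REF) - 1`) or a custom delimited table per its
#' schema into canonical intervals, while keeping every input line
#' verbatim so the writer can append columns without altering the
#' original content. Comment lines (`#`, and `track`/`browser` in BED)
#' are passed through unannotated. Rows that cannot be parsed are kept,
#' flagged invalid, and counted; a file more than half malformed is a
#' fatal error. CRLF line endings are tolerated (the carriage return
#' stays part of the verbatim line).
#'
#' @param path Input file, or `"-"` for standard input.
#' @param schema A [table_schema()].
#' @return An `interval_table`: verbatim `lines`, their `kind`
#'   (`data`/`comment`/`header`), the parsed `records` (canonical
#'   coordinates, validity flags) and the schema.
#' @export
read_intervals <- function(path, schema = table_schema("bed")) {
  lines <- if (identical(path, "-")) readLines("stdin", warn = FALSE)
           else if (file.exists(path)) readLines(path, warn = FALSE)
           else abort_data("input file not found: ", path)
  kind <- rep("data", length(lines))
  kind[.is_comment_line(lines, schema$format)] <- "comment"
  kind[!nzchar(trimws(lines))] <- "comment"
  data_idx <- which(kind == "data")

  header_fields <- NULL
  if (length(data_idx)) {
    clean <- sub("\r$", "", lines[data_idx])
    fl <- strsplit(clean, schema$sep, fixed = TRUE)
    need <- c(schema$ref_col, schema$start_col, schema$end_col)
    need <- need[!is.na(need)]
    has_header <- switch(schema$header,
      present = TRUE,
      absent = FALSE,
      auto = {
        f1 <- fl[[1L]]
        if (max(need) > length(f1)) TRUE
        else any(is.na(suppressWarnings(as.numeric(
          f1[c(schema$start_col, schema$end_col[!is.na(schema$end_col)])]))))
      })
    if (has_header) {
      kind[data_idx[1L]] <- "header"
      header_fields <- fl[[1L]]
      fl <- fl[-1L]
      data_idx <- data_idx[-1L]
    }
  }

  n <- length(data_idx)
  rec <- data.table(idx = data_idx, id = NA_character_, reference = NA_character_,
                    start = NA_integer_, end = NA_integer_, valid = logical(n),
                    note = NA_character_)
  if (n) {
    get_col <- function(i) vapply(fl, function(f)
      if (!is.na(i) && i <= length(f)) f[[i]] else NA_character_, character(1L))
    ref <- get_col(schema$ref_col)
    s_raw <- suppressWarnings(as.integer(get_col(schema$start_col)))
    if (schema$format == "vcf") {
      refallele <- get_col(4L)
      e_raw <- s_raw + pmax(nchar(refallele), 1L) - 1L
    } else {
      e_raw <- suppressWarnings(as.integer(get_col(schema$end_col)))
    }
    idv <- if (!is.na(schema$id_col)) get_col(schema$id_col) else NA_character_
    cv <- normalize_interval(s_raw, e_raw, schema$convention)
    parse_ok <- !is.na(ref) & nzchar(ref) & !is.na(s_raw) & !is.na(e_raw)
    ok_row <- parse_ok & cv$valid
    idv[is.na(idv) | idv == "."] <-
      paste0(ref, ":", s_raw)[is.na(idv) | idv == "."]
    note_row <- fifelse(ok_row, NA_character_,
                        fifelse(parse_ok, "empty_or_inverted_interval",
                                "unparseable_row"))
    rec[, `:=`(id = idv, reference = ref, start = cv$start, end = cv$end,
               valid = ok_row, note = note_row)]
    n_bad <- sum(!ok_row)
    if (n_bad > 0L)
      warning(sprintf("%d of %d data row(s) malformed; emitted unannotated",
                      n_bad, n), call. = FALSE)
    if (n_bad > n / 2)
      abort_data("more than half of the data rows are malformed (",
                 n_bad, " of ", n, ")")
  }
  structure(list(lines = lines, kind = kind, records = rec,
                 header_fields = header_fields, schema = schema),
            class = "interval_table")
}

#' @export
print.interval_table <- function(x, ...) {
  cat(sprintf("<interval table: %d line(s), %d interval(s), %d invalid, format %s>\n",
              length(x$lines), nrow(x$records), sum(!x$records$valid),
              x$schema$format))
  invisible(x)
}

#' Annotate an input file end to end
#'
#' Reads intervals per the schema, runs the annotation engine, and
#' returns an `annotated_table` holding the verbatim input plus the
#' annotation rows, ready for [write_annotated()] and
#' [summarize_annotation()].
#'
#' @param path Input file path (or `"-"` for standard input).
#' @param db An `annotation_db`.
#' @param schema A [table_schema()].
#' @param options [annotation_options()].
#' @return An `annotated_table` object.
#' @export
annotate_file <- function(path, db, schema = table_schema("bed"),
                          options = annotation_options()) {
  tab <- read_intervals(path, schema)
  rows <- annotate_intervals(tab$records, db, options)
  structure(list(input = tab, rows = rows,
                 columns = setdiff(names(rows), "idx"),
                 options = options),
            class = "annotated_table")
}

#' @export
print.annotated_table <- function(x, ...) {
  cat(sprintf("<annotated table: %d input interval(s) -> %d annotation row(s), %s mode>\n",
              nrow(x$input$records), nrow(x$rows), x$options$mode))
  invisible(x)
}

#' Write the annotated table
#'
#' Emits each input line followed by the appended annotation columns,
#' separated by the input separator. Original lines are reproduced
#' byte-identically; comment lines pass through unchanged at their
#' original positions; a single header line names the appended columns
#' (when the input had no header, generic `col1..colN` names stand in
#' for the original fields). Absence is encoded `"."` throughout.
#'
#' @param x An `annotated_table` from [annotate_file()].
#' @param file A connection or path (default standard output).
#' @return Invisibly, the output lines.
#' @export
write_annotated <- function(x, file = stdout()) {
  tab <- x$input
  sep <- tab$schema$sep
  rows <- x$rows
  ann_str <- if (nrow(rows)) {
    do.call(paste, c(as.list(rows[, x$columns, with = FALSE]), sep = sep))
  } else character(0L)
  ann_header <- paste(x$columns, collapse = sep)

  pieces <- list(
    data.table(pos = which(tab$kind == "comment"), sub = 0L,
               text = tab$lines[tab$kind == "comment"]),
    data.table(pos = which(tab$kind == "header"), sub = 0L,
               text = paste(tab$lines[tab$kind == "header"], ann_header, sep = sep))
  )
  if (nrow(rows)) {
    o <- order(rows$idx)
    idx <- rows$idx[o]
    sub <- sequence(rle(idx)$lengths)
    pieces <- c(pieces, list(data.table(
      pos = idx, sub = sub, text = paste(tab$lines[idx], ann_str[o], sep = sep))))
  }
  # data rows with no annotation row (empty engine output) still appear
  orphans <- setdiff(which(tab$kind == "data"), unique(rows$idx))
  if (length(orphans)) {
    filler <- paste(rep(NA_TOKEN, length(x$columns)), collapse = sep)
    pieces <- c(pieces, list(data.table(
      pos = orphans, sub = 1L, text = paste(tab$lines[orphans], filler, sep = sep))))
  }
  # without an input header, synthesize one with generic original names
  if (!any(tab$kind == "header") && any(tab$kind == "data")) {
    i1 <- which(tab$kind == "data")[1L]
    nf <- length(strsplit(sub("\r$", "", tab$lines[i1]), sep, fixed = TRUE)[[1L]])
    pieces <- c(pieces, list(data.table(
      pos = i1, sub = -1L,
      text = paste(paste(sprintf("col%d", seq_len(nf)), collapse = sep),
                   ann_header, sep = sep))))
  }
  pc <- rbindlist(pieces)
  setorder(pc, pos, sub)
  writeLines(pc$text, con = file)
  invisible(pc$text)
}
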