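#' Summary statistics of an annotation run
#'
#' Tallies the categorical annotation columns of a completed run — child
#' feature overlap flags, selected attributes (biotypes and the like) and
#' the relative transcript region — into one count table per column,
#' ordered by count (descending) then value. Counts are over output rows
#' (after the one-row-per-transcript multiplication), and the totals
#' report both input intervals and output rows so the distinction stays
#' visible. For every table the counts sum to the number of output rows,
#' and annotated + intergenic + unannotated = total output rows.
#'
#' @param x An `annotated_table` from [annotate_file()], or a data.table
#'   of annotation rows.
#' @param columns Columns to tally; default: every appended column except
#'   identifiers, coordinates and distances.
#' @return An `annotation_summary` object.
#' @export
summarize_annotation <- function(x, columns = NULL) {
  if (inherits(x, "annotated_table")) {
    rows <- x$rows
    rows_in <- nrow(x$input$records)
  } else {
    rows <- as.data.table(x)
    rows_in <- length(unique(rows$idx))
  }
  skip <- c("idx", "annotated_gene_id", "annotated_transcript_id",
            "annotated_chromosome", "annotated_transcript_start",
            "annotated_transcript_end", "annotated_left_gene",
            "annotated_left_distance", "annotated_left_strand",
            "annotated_right_gene", "annotated_right_distance",
            "annotated_right_strand", "annotated_note")
  if (is.null(columns)) columns <- setdiff(names(rows), skip)
  tables <- lapply(columns, function(cn) {
    tb <- rows[, .(count = .N), by = setNames(list(get(cn)), "value")]
    setorder(tb, -count, value)
    tb[]
  })
  names(tables) <- columns
  ft <- rows[["annotated_feature_type"]] %||% rep(NA_TOKEN, nrow(rows))
  totals <- c(
    rows_in = rows_in,
    rows_out = nrow(rows),
    intergenic = sum(ft == "intergenic"),
    unannotated = sum(ft == NA_TOKEN | is.na(ft)),
    annotated = sum(ft != "intergenic" & ft != NA_TOKEN & !is.na(ft))
  )
  structure(list(tables = tables, totals = totals), class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Annotation summary: %d interval(s) in, %d row(s) out (%d annotated, %d intergenic, %d unannotated)\n",
              t[["rows_in"]], t[["rows_out"]], t[["annotated"]],
              t[["intergenic"]], t[["unannotated"]]))
  for (cn in names(x$tables)) {
    tb <- x$tables[[cn]]
    cat(sprintf("\n%s:\n", cn))
    for (i in seq_len(nrow(tb)))
      cat(sprintf("  %-30s %d\n", tb$value[i], tb$count[i]))
  }
  invisible(x)
}

#' Write an annotation summary to a file or connection
#'
#' @param x An `annotation_summary`.
#' @param file Path or connection (default standard error, keeping
#'   standard output pipe-safe).
#' @param tsv Emit machine-readable TSV (`column<TAB>value<TAB>count`)
#'   instead of the plain-text report.
#' @return Invisibly, `x`.
#' @export
write_summary <- function(x, file = stderr(), tsv = FALSE) {
  if (tsv) {
    lines <- c("column\tvalue\tcount",
               sprintf("total\t%s\t%d", names(x$totals), unname(x$totals)),
               unlist(lapply(names(x$tables), function(cn) {
                 tb <- x$tables[[cn]]
                 sprintf("%s\t%s\t%d", cn, tb$value, tb$count)
               })))
    writeLines(lines, con = if (is.character(file)) file else file)
  } else {
    if (is.character(file)) {
      con <- file(file, "w"); on.exit(close(con))
      sink(con); print(x); sink()
    } else {
      capture <- utils::capture.output(print(x))
      writeLines(capture, con = file)
    }
  }
  invisible(x)
}
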