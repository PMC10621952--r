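#' Coordinate conventions
#'
#' A coordinate convention pairs a base (0 or 1) with an end style
#' (inclusive or exclusive). BED is 0-based end-exclusive; GTF, GFF3 and
#' VCF are 1-based end-inclusive. Custom tables declare their own
#' convention. All internal arithmetic uses the canonical 1-based
#' end-inclusive form; conversion happens only at the I/O boundary.
#'
#' @param base 0 or 1.
#' @param end_style `"inclusive"` or `"exclusive"`.
#' @return An object of class `coord_convention`.
#' @export
#' @examples
#' coord_convention(0, "exclusive")  # the BED convention
coord_convention <- function(base = 1L, end_style = c("inclusive", "exclusive")) {
  base <- as.integer(base)
  end_style <- match.arg(end_style)
  if (!base %in% c(0L, 1L)) abort_config("coordinate base must be 0 or 1")
  structure(list(base = base, end_style = end_style), class = "coord_convention")
}

#' @rdname coord_convention
#' @export
convention_bed <- function() coord_convention(0L, "exclusive")

#' @rdname coord_convention
#' @export
convention_gff <- function() coord_convention(1L, "inclusive")

#' @export
print.coord_convention <- function(x, ...) {
  cat(sprintf("<coordinate convention: %d-based, end-%s>\n", x$base, x$end_style))
  invisible(x)
}

#' Convert intervals to and from the canonical representation
#'
#' `normalize_interval()` maps start/end pairs declared under an arbitrary
#' convention onto the canonical 1-based end-inclusive form;
#' `denormalize_interval()` is its exact inverse. Both are vectorised.
#' Intervals that are empty or inverted after normalization are reported
#' through the `valid` flag rather than as errors, so that a single bad
#' row does not stop a run.
#'
#' @param start,end Integer vectors of positions under `convention`.
#' @param convention A [coord_convention()].
#' @return A list with integer vectors `start`, `end` (canonical) and a
#'   logical vector `valid`.
#' @export
#' @examples
#' normalize_interval(5, 10, convention_bed())   # canonical (6, 10)
#' normalize_interval(6, 10, convention_gff())   # identity
normalize_interval <- function(start, end, convention = convention_gff()) {
  stopifnot(inherits(convention, "coord_convention"))
  s <- as.integer(start) + (1L - convention$base)
  e <- as.integer(end) + (1L - convention$base) -
    (convention$end_style == "exclusive")
  valid <- !is.na(s) & !is.na(e) & s >= 1L & s <= e
  list(start = s, end = e, valid = valid)
}

#' @rdname normalize_interval
#' @export
denormalize_interval <- function(start, end, convention = convention_gff()) {
  stopifnot(inherits(convention, "coord_convention"))
  s <- as.integer(start) - (1L - convention$base)
  e <- as.integer(end) - (1L - convention$base) +
    (convention$end_style == "exclusive")
  list(start = s, end = e)
}

#' Transcript model
#'
#' A transcript model carries the ordered exon chain of one transcript and
#' is the basis of all spliced-coordinate arithmetic. Exons are genomic
#' 1-based end-inclusive pairs, pairwise disjoint and sorted by start.
#' Transcript coordinates run 1..spliced_length from the transcript 5'
#' end: for a minus-strand transcript, position 1 is the exonic base with
#' the highest genomic coordinate. Transcripts lacking exon records fall
#' back to a single pseudo-exon spanning the transcript.
#'
#' @param transcript_id,gene_id,seqid Character scalars.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of genomic starts/ends.
#' @param children Optional data.frame of child features (type, start, end).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id = NA_character_, seqid = NA_character_,
                             strand = "+", exons, children = NULL) {
  exons <- as.data.frame(exons)[, 1:2]
  names(exons) <- c("start", "end")
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) == 0L) abort_data("transcript model needs at least one exon")
  if (any(exons$end < exons$start)) abort_data("exon with end < start")
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    abort_data("exons overlap or touch; expected a disjoint sorted chain")
  if (!strand %in% c("+", "-")) strand <- "+"
  len <- exons$end - exons$start + 1L
  structure(list(
    transcript_id = transcript_id,
    gene_id = gene_id,
    seqid = seqid,
    strand = strand,
    exons = exons,
    # exonic bases in exons strictly before exon i (plus-strand order)
    cum_before = c(0L, cumsum(len))[seq_len(nrow(exons))],
    spliced_length = sum(len),
    span = c(exons$start[1L], exons$end[nrow(exons)]),
    children = children
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (%s%s) %d exon(s), spliced length %d>\n",
              x$transcript_id, x$seqid, x$strand, nrow(x$exons), x$spliced_length))
  invisible(x)
}

# Number of exonic bases at or before genomic position g (g may be
# intronic or outside the chain); plus-strand counting.
.exonic_bases_upto <- function(model, g) {
  ex <- model$exons
  i <- findInterval(g, ex$start)     # last exon with start <= g
  if (i == 0L) return(0L)
  model$cum_before[i] + min(g, ex$end[i]) - ex$start[i] + 1L
}

#' Map a genomic position into spliced transcript coordinates
#'
#' Exonic positions map to their 1-based position along the spliced
#' transcript (5'-anchored, so numbering is reversed on the minus
#' strand). Intronic positions have no transcript position; they map to
#' the spliced offset, i.e. the count of exonic bases strictly 5' of the
#' position in transcript orientation, and are flagged `"intronic"`.
#'
#' @param model A [transcript_model()].
#' @param g Genomic position within the transcript span.
#' @return A list with `pos` (transcript position, `NA` if intronic),
#'   `offset` (spliced offset, always set) and `type`
#'   (`"exonic"`/`"intronic"`).
#' @export
genomic_to_tx <- function(model, g) {
  g <- as.integer(g)
  if (g < model$span[1L] || g > model$span[2L])
    abort_data("position ", g, " outside transcript span [",
               model$span[1L], ", ", model$span[2L], "]")
  ex <- model$exons
  i <- findInterval(g, ex$start)
  exonic <- i >= 1L && g <= ex$end[i]
  upto <- .exonic_bases_upto(model, g)
  if (exonic) {
    pos <- if (model$strand == "+") upto else model$spliced_length - upto + 1L
    list(pos = pos, offset = pos, type = "exonic")
  } else {
    # exonic bases strictly 5' of g in transcript orientation
    off <- if (model$strand == "+") upto else model$spliced_length - upto
    list(pos = NA_integer_, offset = off, type = "intronic")
  }
}

#' Project a genomic interval onto spliced transcript coordinates
#'
#' Returns the smallest transcript interval containing the transcript
#' positions of all exonic bases of the input. Fully intronic inputs have
#' an empty projection and are reported as the insertion point between
#' spliced positions `offset` and `offset + 1`.
#'
#' @param model A [transcript_model()].
#' @param start,end Genomic interval (1-based inclusive) intersecting the
#'   transcript span.
#' @return A list with `start`, `end` (transcript coordinates, `NA` when
#'   fully intronic), `offset` (insertion point for intronic projections),
#'   `n_exonic` (exonic bases covered) and `flag` (one of
#'   `"fully_exonic"`, `"partially_intronic"`, `"fully_intronic"`).
#' @export
project_to_tx <- function(model, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (end < start) abort_data("inverted interval")
  if (end < model$span[1L] || start > model$span[2L])
    abort_data("interval does not intersect the transcript span")
  ex <- model$exons
  ov_s <- pmax(start, ex$start)
  ov_e <- pmin(end, ex$end)
  hit <- ov_s <= ov_e
  clip_s <- max(start, model$span[1L])
  clip_e <- min(end, model$span[2L])
  n_clip <- clip_e - clip_s + 1L
  if (!any(hit)) {
    off <- genomic_to_tx(model, clip_s)$offset
    return(list(start = NA_integer_, end = NA_integer_, offset = off,
                n_exonic = 0L, flag = "fully_intronic"))
  }
  # plus-strand spliced positions of the covered exonic bases
  p1 <- model$cum_before[hit] + ov_s[hit] - ex$start[hit] + 1L
  p2 <- model$cum_before[hit] + ov_e[hit] - ex$start[hit] + 1L
  lo <- min(p1); hi <- max(p2)
  n_ex <- sum(p2 - p1 + 1L)
  if (model$strand == "-") {
    L <- model$spliced_length
    tmp <- lo; lo <- L - hi + 1L; hi <- L - tmp + 1L
  }
  flag <- if (n_ex == n_clip) "fully_exonic" else "partially_intronic"
  list(start = lo, end = hi, offset = lo - 1L, n_exonic = n_ex, flag = flag)
}

#' Map a transcript interval back to genomic blocks
#'
#' The inverse of [project_to_tx()] for exonic intervals: a spliced
#' transcript interval maps to one or more disjoint genomic blocks (one
#' per exon it touches), returned sorted in genomic order. Block lengths
#' always sum to the transcript-interval length.
#'
#' @param model A [transcript_model()].
#' @param start,end Transcript positions, `1 <= start <= end <= spliced_length`.
#' @return A data.frame with columns `start`, `end` (genomic, ascending).
#' @export
tx_to_genomic <- function(model, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  L <- model$spliced_length
  if (start < 1L || end > L || start > end)
    abort_data("transcript interval [", start, ", ", end,
               "] invalid for spliced length ", L)
  if (model$strand == "-") {
    tmp <- start; start <- L - end + 1L; end <- L - tmp + 1L
  }
  ex <- model$exons
  first <- model$cum_before + 1L
  last <- model$cum_before + (ex$end - ex$start + 1L)
  ov_s <- pmax(start, first)
  ov_e <- pmin(end, last)
  hit <- ov_s <= ov_e
  data.frame(
    start = ex$start[hit] + (ov_s[hit] - first[hit]),
    end = ex$start[hit] + (ov_e[hit] - first[hit])
  )
}
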