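#' Transcript quartile of a spliced position
#'
#' Positions along a spliced transcript of length `L` are binned into four
#' quartiles. The bin is `ceiling(4 * p / L)` clamped to 1..4, computed in
#' integer arithmetic, so a position exactly at `L/4` belongs to the lower
#' quartile.
#'
#' @param p Transcript position(s), `1 <= p <= L`.
#' @param L Spliced transcript length(s).
#' @return Integer vector of quartiles in 1..4.
#' @export
#' @examples
#' tx_quartile(c(1, 25, 26, 100), 100)  # 1 1 2 4
tx_quartile <- function(p, L) {
  p <- as.numeric(p); L <- as.numeric(L)
  if (any(is.na(p) | is.na(L) | p < 1 | p > L))
    abort_data("quartile position out of range 1..L")
  q <- (4 * p + L - 1) %/% L        # ceiling(4p/L) without floats
  as.integer(pmin(pmax(q, 1), 4))
}

# Region labels as written to the feature_region output column.
REGION_VOCAB <- c(
  five_prime = "5 prime",
  middle = "middle",
  three_prime = "3 prime",
  whole = "whole",
  full = "full",
  intronic = "intronic"
)

#' Classify the relative region of an interval within a transcript
#'
#' Assigns one of five categorical labels to an interval in spliced
#' transcript coordinates, based on the quartiles of its start and end
#' and on its length relative to the transcript:
#'
#' * `full`  — start in Q1, end in Q4, and interval length strictly
#'   greater than 90% of the transcript length;
#' * `whole` — start in Q1, end in Q4, length at most 90%;
#' * `5 prime` — start in Q1, end in Q1 or Q2;
#' * `3 prime` — start in Q3 or Q4, end in Q4;
#' * `middle` — start and end both in Q2 or Q3.
#'
#' Rules are evaluated in that order, so the long-span rules win where the
#' quartile patterns overlap. Quartile configurations covered by no rule
#' (an interval starting in Q1 and ending in Q3, for instance) fall back
#' to the quartile of the interval midpoint: Q1 maps to `5 prime`, Q2/Q3
#' to `middle`, Q4 to `3 prime`, keeping the classifier total. The 90%
#' comparison is done as `10 * length` versus `9 * L` in integers, so
#' there are no floating-point ties. All arguments are vectorised.
#'
#' @param start,end Transcript positions, `1 <= start <= end <= L`.
#' @param L Spliced transcript length.
#' @param vocab Return the output vocabulary (`"5 prime"`, ...) when
#'   `TRUE` (default), or internal keys (`"five_prime"`, ...) when `FALSE`.
#' @return Character vector of region labels.
#' @export
#' @examples
#' classify_region(1, 20, 100)    # "5 prime"
#' classify_region(40, 60, 100)   # "middle"
#' classify_region(80, 95, 100)   # "3 prime"
#' classify_region(10, 85, 100)   # "whole"
#' classify_region(2, 98, 100)    # "full"
classify_region <- function(start, end, L, vocab = TRUE) {
  start <- as.numeric(start); end <- as.numeric(end); L <- as.numeric(L)
  n <- max(length(start), length(end), length(L))
  start <- rep_len(start, n); end <- rep_len(end, n); L <- rep_len(L, n)
  if (any(is.na(start) | is.na(end) | is.na(L) |
            start < 1 | end > L | start > end))
    abort_data("interval out of range for classification")
  qs <- tx_quartile(start, L)
  qe <- tx_quartile(end, L)
  len <- end - start + 1
  over90 <- 10 * len > 9 * L

  lab <- rep(NA_character_, n)
  # an interval covering the entire transcript is always "full", even for
  # transcripts too short for position 1 to sit in the first quartile
  lab[start == 1 & end == L] <- "full"
  lab[is.na(lab) & qs == 1L & qe == 4L & over90] <- "full"
  lab[is.na(lab) & qs == 1L & qe == 4L] <- "whole"
  lab[is.na(lab) & qs == 1L & qe <= 2L] <- "five_prime"
  lab[is.na(lab) & qs >= 3L & qe == 4L] <- "three_prime"
  lab[is.na(lab) & qs >= 2L & qs <= 3L & qe >= 2L & qe <= 3L] <- "middle"

  todo <- is.na(lab)
  if (any(todo)) {
    qm <- tx_quartile((start[todo] + end[todo]) %/% 2, L[todo])
    lab[todo] <- c("five_prime", "middle", "middle", "three_prime")[qm]
  }
  if (vocab) unname(REGION_VOCAB[lab]) else lab
}
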