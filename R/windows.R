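## Tiling pairwise alignments into fixed-length windows and scoring each
## window's identity and gap content.

# per-column flags for a whole alignment: match / gap, vectorized once
.column_flags <- function(aln) {
  ca <- strsplit(aln$row_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aln$row_b, "", fixed = TRUE)[[1L]]
  gap <- ca == "-" | cb == "-"
  match <- !gap & ca == cb & ca != "N"
  list(ca = ca, cb = cb, gap = gap, match = match,
       nongap_a = ca != "-", nongap_b = cb != "-")
}

#' Identity and gap statistics of one alignment window
#'
#' A column counts as a gap column if either row holds the gap character.
#' Identity is \code{n_match / window_len}: the denominator is the full
#' window, so gap columns penalize identity. Base comparison is
#' case-insensitive and \code{N} matches nothing.
#'
#' @param cols_a,cols_b character vectors of the window's aligned characters,
#'   one element per column (equal lengths).
#' @return list with \code{n_match}, \code{n_mismatch}, \code{n_gap_cols},
#'   \code{identity}.
#' @examples
#' window_stats(rep("A", 25), rep("A", 25))$identity  # 1
#' @export
window_stats <- function(cols_a, cols_b) {
  if (length(cols_a) != length(cols_b))
    ow_stop_validation("window rows differ in length")
  ca <- toupper(cols_a); cb <- toupper(cols_b)
  ca[ca == "."] <- "-"; cb[cb == "."] <- "-"
  gap <- ca == "-" | cb == "-"
  match <- !gap & ca == cb & ca != "N"
  n <- length(ca)
  n_match <- sum(match); n_gap <- sum(gap)
  list(n_match = n_match, n_mismatch = n - n_match - n_gap,
       n_gap_cols = n_gap, identity = n_match / n)
}

#' Does a window pass the identity/gap filter?
#'
#' Both inequalities are strict: a window is kept only with identity strictly
#' above \code{min_identity} and strictly fewer than \code{max_gap_cols} gap
#' columns.
#'
#' @param stats result of [window_stats()] (or any list/row with
#'   \code{identity} and \code{n_gap_cols}); vectors are accepted.
#' @param config a [filter_config()].
#' @return logical.
#' @export
passes_window_filter <- function(stats, config = filter_config()) {
  stats$identity > config$min_identity & stats$n_gap_cols < config$max_gap_cols
}

#' Tile an alignment into fixed-length windows
#'
#' Windows tile the alignment columns \code{[0, w), [w, 2w), ...}; a terminal
#' partial window is dropped so every window has exactly \code{window_len}
#' columns and identities stay comparable. Each window carries match,
#' mismatch and gap-column counts and the half-open transcript-coordinate
#' interval its non-gap characters cover in each row.
#'
#' @param alignment an \code{ow_alignment}.
#' @param window_len window size in alignment columns (>= 2).
#' @return data.frame with one row per window: \code{pair_id},
#'   \code{window_index} (0-based), \code{col_start}, \code{col_end},
#'   \code{n_match}, \code{n_mismatch}, \code{n_gap_cols}, \code{identity},
#'   \code{tx_start_a}, \code{tx_end_a}, \code{tx_start_b}, \code{tx_end_b}.
#' @examples
#' aln <- pairwise_alignment(strrep("ACGT", 25), strrep("ACGT", 25))
#' nrow(window_alignment(aln, 25))  # 4
#' @export
window_alignment <- function(alignment, window_len = 25L) {
  window_len <- as.integer(window_len)
  if (is.na(window_len) || window_len < 2L)
    ow_stop_validation("window_len must be an integer >= 2")
  n_win <- alignment$n_columns %/% window_len
  empty <- data.frame(pair_id = character(0), window_index = integer(0),
                      col_start = integer(0), col_end = integer(0),
                      n_match = integer(0), n_mismatch = integer(0),
                      n_gap_cols = integer(0), identity = numeric(0),
                      tx_start_a = integer(0), tx_end_a = integer(0),
                      tx_start_b = integer(0), tx_end_b = integer(0),
                      stringsAsFactors = FALSE)
  if (n_win == 0L) return(empty)
  fl <- .column_flags(alignment)
  used <- n_win * window_len
  grp <- rep(seq_len(n_win), each = window_len)
  n_match <- as.integer(tapply(fl$match[seq_len(used)], grp, sum))
  n_gap <- as.integer(tapply(fl$gap[seq_len(used)], grp, sum))
  # transcript coords: cumulative non-gap characters before each boundary
  cum_a <- c(0L, cumsum(fl$nongap_a))
  cum_b <- c(0L, cumsum(fl$nongap_b))
  col_start <- (seq_len(n_win) - 1L) * window_len
  col_end <- col_start + window_len
  data.frame(pair_id = alignment$pair_id,
             window_index = seq_len(n_win) - 1L,
             col_start = col_start, col_end = col_end,
             n_match = n_match,
             n_mismatch = window_len - n_match - n_gap,
             n_gap_cols = n_gap,
             identity = n_match / window_len,
             tx_start_a = cum_a[col_start + 1L], tx_end_a = cum_a[col_end + 1L],
             tx_start_b = cum_b[col_start + 1L], tx_end_b = cum_b[col_end + 1L],
             stringsAsFactors = FALSE)
}

#' Transcript-coordinate footprint of one window
#'
#' For each alignment row, returns the half-open interval of ungapped
#' sequence positions covered by the window's non-gap characters (an empty
#' interval if the row is all gaps within the window).
#'
#' @param alignment an \code{ow_alignment}.
#' @param col_start,col_end 0-based half-open alignment-column interval.
#' @return list with \code{tx_interval_a} and \code{tx_interval_b}, each a
#'   numeric (start, end) pair.
#' @export
window_to_transcript_coords <- function(alignment, col_start, col_end) {
  if (col_start < 0 || col_end > alignment$n_columns || col_start >= col_end)
    ow_stop_validation("window outside alignment bounds")
  fl <- .column_flags(alignment)
  cum_a <- c(0L, cumsum(fl$nongap_a))
  cum_b <- c(0L, cumsum(fl$nongap_b))
  list(tx_interval_a = c(cum_a[col_start + 1L], cum_a[col_end + 1L]),
       tx_interval_b = c(cum_b[col_start + 1L], cum_b[col_end + 1L]))
}
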