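## Pairwise transcript alignments: construction, the built-in aligner, and
## aligned-FASTA input. Gap character is "-" internally; "." is normalized to
## "-" on read, bases are uppercased.

.normalize_row <- function(x) {
  x <- toupper(x)
  gsub(".", "-", x, fixed = TRUE)
}

.degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Construct a pairwise alignment object
#'
#' Validates and wraps two gapped rows of equal length. Enforces the
#' alignment invariants: equal row lengths, at least one column, and no column
#' that is a gap in both rows.
#'
#' @param row_a,row_b gapped sequences (single strings; gap character "-",
#'   "." accepted and normalized).
#' @param pair_id identifier of the ortholog pair.
#' @return An object of class \code{ow_alignment} with elements
#'   \code{pair_id}, \code{row_a}, \code{row_b}, \code{n_columns}.
#' @export
pairwise_alignment <- function(row_a, row_b, pair_id = "pair") {
  if (!is.character(row_a) || length(row_a) != 1L ||
      !is.character(row_b) || length(row_b) != 1L)
    ow_stop_validation("alignment rows must be single character strings")
  row_a <- unname(.normalize_row(row_a))
  row_b <- unname(.normalize_row(row_b))
  if (nchar(row_a) != nchar(row_b))
    ow_stop_validation(sprintf(
      "alignment rows of pair '%s' differ in length (%d vs %d)",
      pair_id, nchar(row_a), nchar(row_b)))
  n <- nchar(row_a)
  if (n == 0L)
    ow_stop_validation(sprintf("alignment of pair '%s' is empty", pair_id))
  ca <- strsplit(row_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(row_b, "", fixed = TRUE)[[1L]]
  bad <- which(ca == "-" & cb == "-")
  if (length(bad) > 0L)
    ow_stop_validation(sprintf(
      "alignment of pair '%s' has an all-gap column (first at column %d)",
      pair_id, bad[1L]))
  ok <- c("A", "C", "G", "T", "N", "-")
  if (!all(ca %in% ok) || !all(cb %in% ok))
    ow_stop_validation(sprintf(
      "alignment of pair '%s' contains non-nucleotide characters", pair_id))
  structure(list(pair_id = pair_id, row_a = row_a, row_b = row_b,
                 n_columns = n),
            class = "ow_alignment")
}

#' @export
print.ow_alignment <- function(x, ...) {
  cat(sprintf("Pairwise alignment '%s': %d columns, %d/%d ungapped bp\n",
              x$pair_id, x$n_columns,
              nchar(.degap(x$row_a)), nchar(.degap(x$row_b))))
  invisible(x)
}

.check_nucleotides <- function(seq, label) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    ow_stop_validation(label, " must be a non-empty sequence string")
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s))
    ow_stop_validation(label, " contains characters outside A/C/G/T/N")
  s
}

#' Globally align two transcript sequences
#'
#' Needleman–Wunsch global alignment with affine gap penalties (Gotoh
#' recursion, implemented in C++). A gap run of length L costs
#' \code{gap_open + (L - 1) * gap_extend}. Traceback ties are broken by
#' preferring a diagonal step, then a gap in the second row, then a gap in
#' the first, so the result is deterministic. \code{N} never matches.
#'
#' The built-in aligner targets fixtures and small inputs; for genome-scale
#' transcript sets, supply precomputed alignments (e.g. from MAFFT) through
#' [read_alignment_fasta()].
#'
#' @param sequence_a,sequence_b ungapped nucleotide sequences (A/C/G/T/N,
#'   case-insensitive).
#' @param match,mismatch,gap_open,gap_extend scoring parameters; penalties
#'   must be negative.
#' @param pair_id identifier carried into the result.
#' @return An \code{ow_alignment}, with the optimal score in attribute
#'   \code{"score"}.
#' @examples
#' aln <- align_pair("ACGTACGT", "ACGACGT")
#' attr(aln, "score")
#' @export
align_pair <- function(sequence_a, sequence_b, match = 2, mismatch = -3,
                       gap_open = -5, gap_extend = -2, pair_id = "pair") {
  a <- .check_nucleotides(sequence_a, "sequence_a")
  b <- .check_nucleotides(sequence_b, "sequence_b")
  if (gap_open > 0 || gap_extend > 0)
    ow_stop_validation("gap penalties must be <= 0")
  res <- .nw_affine(a, b, match, mismatch, gap_open, gap_extend)
  aln <- pairwise_alignment(res$row_a, res$row_b, pair_id = pair_id)
  stopifnot(.degap(aln$row_a) == a, .degap(aln$row_b) == b)
  attr(aln, "score") <- res$score
  aln
}

#' Read a 2-record aligned FASTA file
#'
#' Reads one pairwise alignment from an aligned FASTA file holding exactly two
#' records of equal gapped length. Record order defines which sequence is
#' species a (first) and species b (second).
#'
#' @param path path to the aligned FASTA file.
#' @param pair_id identifier; defaults to the file name without extension.
#' @return An \code{ow_alignment}.
#' @export
read_alignment_fasta <- function(path, pair_id = NULL) {
  if (!file.exists(path)) ow_stop_io("alignment FASTA not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2L)
    ow_stop_validation(sprintf(
      "aligned FASTA '%s' must hold exactly 2 records, found %d",
      path, length(recs)))
  rows <- as.character(recs)
  if (nchar(rows[1L]) != nchar(rows[2L]))
    ow_stop_validation(sprintf(
      "aligned FASTA '%s': records have unequal lengths (%d vs %d)",
      path, nchar(rows[1L]), nchar(rows[2L])))
  if (is.null(pair_id))
    pair_id <- tools::file_path_sans_ext(basename(path))
  pairwise_alignment(rows[1L], rows[2L], pair_id = pair_id)
}

#' Read ungapped transcript sequences from FASTA
#'
#' @param path FASTA file of transcript sequences, record names are gene ids.
#' @return Named character vector of uppercase sequences.
#' @export
read_transcripts_fasta <- function(path) {
  if (!file.exists(path)) ow_stop_io("transcript FASTA not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(recs))
  names(out) <- sub("\\s.*$", "", names(recs))
  out
}

#' Read a two-column 1:1 ortholog pair table
#'
#' @param path TSV with two columns (\code{gene_a}, \code{gene_b}); a header
#'   line is detected and skipped if present.
#' @return data.frame with columns \code{pair_id}, \code{gene_a},
#'   \code{gene_b}; \code{pair_id} is \code{"<gene_a>__<gene_b>"}.
#' @export
read_ortholog_pairs <- function(path) {
  if (!file.exists(path)) ow_stop_io("ortholog pair table not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L)
    ow_stop_validation("ortholog pair table must have two tab-separated columns")
  if (identical(tolower(df[1L, 1L]), "gene_a")) df <- df[-1L, , drop = FALSE]
  out <- data.frame(gene_a = as.character(df[[1L]]),
                    gene_b = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_a) || anyDuplicated(out$gene_b))
    ow_stop_validation("pair table is not 1:1 (a gene id occurs in two pairs)")
  out$pair_id <- paste0(out$gene_a, "__", out$gene_b)
  out[, c("pair_id", "gene_a", "gene_b")]
}

#' Bundle an ortholog pair with sequences and exon models
#'
#' @param pair_id pair identifier.
#' @param gene_a,gene_b gene ids in species a and b.
#' @param sequence_a,sequence_b ungapped transcript sequences.
#' @param exon_model_a,exon_model_b [exon_model()] objects; each transcript
#'   length must equal its sequence length.
#' @param species_a,species_b species labels.
#' @return Object of class \code{ow_ortholog_pair}.
#' @export
ortholog_pair <- function(pair_id, gene_a, gene_b, sequence_a, sequence_b,
                          exon_model_a, exon_model_b,
                          species_a = "species_a", species_b = "species_b") {
  sequence_a <- .check_nucleotides(sequence_a, paste0("sequence of ", gene_a))
  sequence_b <- .check_nucleotides(sequence_b, paste0("sequence of ", gene_b))
  for (side in c("a", "b")) {
    em <- get(paste0("exon_model_", side))
    sq <- get(paste0("sequence_", side))
    if (!inherits(em, "ow_exon_model"))
      ow_stop_validation("exon_model_", side, " must be an ow_exon_model")
    if (em$transcript_length != nchar(sq))
      ow_stop_validation(sprintf(
        "pair '%s': sequence_%s length %d != exon model transcript length %d",
        pair_id, side, nchar(sq), em$transcript_length))
  }
  structure(list(pair_id = pair_id, gene_a = gene_a, gene_b = gene_b,
                 species_a = species_a, species_b = species_b,
                 sequence_a = sequence_a, sequence_b = sequence_b,
                 exon_model_a = exon_model_a, exon_model_b = exon_model_b),
            class = "ow_ortholog_pair")
}
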