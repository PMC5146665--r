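## Exon models and strand-aware transcript <-> genome coordinate mapping.
## All internal coordinates are 0-based half-open; GTF I/O converts to and
## from the 1-based inclusive convention.

#' Construct an exon model
#'
#' An exon model holds one designated transcript of a gene as an ordered set
#' of genomic exon intervals. Exons are 0-based half-open, sorted by genomic
#' start and non-overlapping; transcript coordinates run 5' to 3', so on the
#' minus strand transcript position 0 sits at the highest genomic coordinate.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons two-column matrix or data.frame of (start, end), 0-based
#'   half-open, ascending, non-overlapping.
#' @return Object of class \code{ow_exon_model} with the derived
#'   \code{transcript_length}.
#' @examples
#' em <- exon_model("g1", "chr1", "+", cbind(c(1000, 1500), c(1020, 1600)))
#' em$transcript_length  # 20 + 100
#' @export
exon_model <- function(gene_id, chrom, strand, exons) {
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L || nrow(exons) < 1L)
    ow_stop_validation("exons must be a two-column (start, end) table")
  storage.mode(exons) <- "double"
  colnames(exons) <- c("start", "end")
  if (!strand %in% c("+", "-"))
    ow_stop_validation("strand must be '+' or '-'")
  if (any(exons[, "start"] >= exons[, "end"]))
    ow_stop_validation(sprintf("gene '%s': every exon needs start < end", gene_id))
  if (is.unsorted(exons[, "start"], strictly = TRUE) && nrow(exons) > 1L)
    ow_stop_validation(sprintf("gene '%s': exons must ascend by genomic start", gene_id))
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))
    ow_stop_validation(sprintf("gene '%s': exons overlap", gene_id))
  widths <- exons[, "end"] - exons[, "start"]
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, transcript_length = as.integer(sum(widths))),
            class = "ow_exon_model")
}

#' @export
print.ow_exon_model <- function(x, ...) {
  cat(sprintf("Exon model '%s' %s:%s, %d exon(s), transcript %d bp\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              x$transcript_length))
  invisible(x)
}

#' Map a transcript interval to genomic segments
#'
#' Walks the exon chain 5' to 3' (descending genomic order on the minus
#' strand) and returns the genomic footprint of a transcript interval. An
#' interval spanning an exon junction yields one segment per exon touched.
#'
#' @param tx_interval numeric length-2 vector (start, end), 0-based half-open
#'   transcript coordinates within \code{[0, transcript_length]}.
#' @param model an [exon_model()].
#' @return data.frame of genomic segments (\code{start}, \code{end}), 0-based
#'   half-open, ascending; total width equals the interval width.
#' @examples
#' em <- exon_model("g", "chr1", "+", cbind(1000, 2000))
#' transcript_to_genomic(c(10, 35), em)  # 1010..1035
#' @export
transcript_to_genomic <- function(tx_interval, model) {
  s <- tx_interval[1L]; e <- tx_interval[2L]
  L <- model$transcript_length
  if (is.na(s) || is.na(e) || s > e || s < 0 || e > L)
    ow_stop_validation(sprintf(
      "transcript interval [%s, %s) out of range for '%s' (length %d)",
      format(s), format(e), model$gene_id, L))
  if (s == e)
    return(data.frame(start = numeric(0), end = numeric(0)))
  if (model$strand == "-") {
    # 5'->3' on minus strand == walking the plus-strand layout from the right
    tmp <- c(L - e, L - s)
    s <- tmp[1L]; e <- tmp[2L]
  }
  widths <- model$exons[, "end"] - model$exons[, "start"]
  cum_end <- cumsum(widths)            # transcript coord just past each exon
  cum_start <- cum_end - widths        # transcript coord at each exon start
  hit <- which(cum_end > s & cum_start < e)
  seg_start <- model$exons[hit, "start"] + pmax(0, s - cum_start[hit])
  seg_end <- model$exons[hit, "start"] + pmin(widths[hit], e - cum_start[hit])
  data.frame(start = as.numeric(seg_start), end = as.numeric(seg_end))
}

#' Map genomic segments back to a transcript interval
#'
#' Inverse of [transcript_to_genomic()]: each segment must lie inside the
#' gene's exons, and together the segments must cover one contiguous
#' transcript run.
#'
#' @param segments data.frame with \code{start}, \code{end} (0-based
#'   half-open genomic coordinates).
#' @param model an [exon_model()].
#' @return numeric length-2 vector (start, end) in transcript coordinates.
#' @export
genomic_to_transcript <- function(segments, model) {
  if (nrow(segments) == 0L) return(c(0, 0))
  widths <- model$exons[, "end"] - model$exons[, "start"]
  cum_end <- cumsum(widths)
  cum_start <- cum_end - widths
  L <- model$transcript_length
  tx <- lapply(seq_len(nrow(segments)), function(i) {
    gs <- segments$start[i]; ge <- segments$end[i]
    k <- which(model$exons[, "start"] <= gs & model$exons[, "end"] >= ge)
    if (length(k) != 1L)
      ow_stop_validation(sprintf(
        "segment [%s, %s) of '%s' does not lie inside a single exon",
        format(gs), format(ge), model$gene_id))
    c(cum_start[k] + gs - model$exons[k, "start"],
      cum_start[k] + ge - model$exons[k, "start"])
  })
  ts <- vapply(tx, `[`, numeric(1), 1L)
  te <- vapply(tx, `[`, numeric(1), 2L)
  if (model$strand == "-") {
    tmp <- L - te; te <- L - ts; ts <- tmp
  }
  o <- order(ts)
  ts <- ts[o]; te <- te[o]
  if (length(ts) > 1L && any(abs(ts[-1L] - te[-length(te)]) > 0))
    ow_stop_validation(sprintf(
      "segments of '%s' do not form a contiguous transcript run", model$gene_id))
  c(ts[1L], te[length(te)])
}

#' Read exon models from a GTF/GFF file
#'
#' Imports "exon" features and assembles one [exon_model()] per gene. When a
#' gene carries several transcripts, the transcript with the largest summed
#' exon length is designated (multi-isoform reconciliation is out of scope).
#'
#' @param path GTF or GFF3 file; exon records must carry a \code{gene_id}
#'   (GTF) or be resolvable to one (GFF3 \code{gene_id}/\code{Parent}).
#' @param genes optional character vector restricting the genes returned.
#' @return Named list of \code{ow_exon_model} objects.
#' @export
read_exon_models_gtf <- function(path, genes = NULL) {
  if (!file.exists(path)) ow_stop_io("annotation file not found: ", path)
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  md <- S4Vectors::mcols(gr)
  gene_ids <- if ("gene_id" %in% colnames(md)) as.character(md$gene_id)
              else if ("Parent" %in% colnames(md)) as.character(unlist(md$Parent))
              else ow_stop_validation("no gene_id attribute on exon records in ", path)
  tx_ids <- if ("transcript_id" %in% colnames(md)) as.character(md$transcript_id)
            else gene_ids
  df <- data.frame(gene = gene_ids, tx = tx_ids,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # to 0-based
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(genes)) df <- df[df$gene %in% genes, , drop = FALSE]
  out <- lapply(split(df, df$gene), function(g) {
    tx_len <- tapply(g$end - g$start, g$tx, sum)
    pick <- names(tx_len)[which.max(tx_len)]
    g <- g[g$tx == pick, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    strand <- g$strand[1L]
    if (!strand %in% c("+", "-")) strand <- "+"
    exon_model(g$gene[1L], g$chrom[1L], strand,
               cbind(g$start, g$end))
  })
  out
}
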