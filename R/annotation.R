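## Comparable-region annotation: assembling filtered windows into paired
## per-species genomic segment sets, and GTF/TSV serialization.

.segments_to_string <- function(seg) {
  paste(sprintf("%d-%d", as.integer(seg$start), as.integer(seg$end)),
        collapse = ",")
}

.string_to_segments <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  data.frame(start = as.numeric(vapply(parts, `[`, character(1), 1L)),
             end = as.numeric(vapply(parts, `[`, character(1), 2L)))
}

#' Build the filtered, coordinate-mapped windows of one ortholog pair
#'
#' Tiles the pair's alignment, applies the identity/gap window filter, and
#' maps every retained window to genomic segments in both species. Retained
#' windows keep their original window index, so ids match across species.
#'
#' @param pair an [ortholog_pair()].
#' @param alignment an \code{ow_alignment} of the pair's transcripts; its
#'   degapped rows must reproduce the pair's sequences.
#' @param config a [filter_config()].
#' @return list with \code{windows} (stats of retained windows, plus
#'   \code{len_a}/\code{len_b}) and \code{segments} (one row per genomic
#'   segment: \code{pair_id}, \code{window_index}, \code{species},
#'   \code{gene_id}, \code{chrom}, \code{strand}, \code{start}, \code{end}).
#' @export
build_comparable_windows <- function(pair, alignment, config = filter_config()) {
  if (!inherits(pair, "ow_ortholog_pair"))
    ow_stop_validation("pair must be an ow_ortholog_pair")
  if (.degap(alignment$row_a) != pair$sequence_a ||
      .degap(alignment$row_b) != pair$sequence_b)
    ow_stop_validation(sprintf(
      "pair '%s': alignment rows do not reproduce the transcript sequences",
      pair$pair_id))
  win <- window_alignment(alignment, config$window_len)
  win <- win[passes_window_filter(win, config), , drop = FALSE]
  win$len_a <- win$tx_end_a - win$tx_start_a
  win$len_b <- win$tx_end_b - win$tx_start_b
  seg_list <- vector("list", 2L * nrow(win))
  if (nrow(win) > 0L) {
    for (i in seq_len(nrow(win))) {
      for (side in c("a", "b")) {
        em <- pair[[paste0("exon_model_", side)]]
        tx <- c(win[[paste0("tx_start_", side)]][i],
                win[[paste0("tx_end_", side)]][i])
        seg <- tryCatch(transcript_to_genomic(tx, em), error = function(e)
          ow_stop_validation(sprintf("pair '%s' window %d (%s): %s",
                                     pair$pair_id, win$window_index[i], side,
                                     conditionMessage(e))))
        if (nrow(seg) > 0L)
          seg_list[[2L * (i - 1L) + (side == "b") + 1L]] <- data.frame(
            pair_id = pair$pair_id, window_index = win$window_index[i],
            species = if (side == "a") pair$species_a else pair$species_b,
            gene_id = if (side == "a") pair$gene_a else pair$gene_b,
            chrom = em$chrom, strand = em$strand,
            start = seg$start, end = seg$end, stringsAsFactors = FALSE)
      }
    }
  }
  segments <- do.call(rbind, seg_list[!vapply(seg_list, is.null, logical(1))])
  if (is.null(segments))
    segments <- data.frame(pair_id = character(0), window_index = integer(0),
                           species = character(0), gene_id = character(0),
                           chrom = character(0), strand = character(0),
                           start = numeric(0), end = numeric(0),
                           stringsAsFactors = FALSE)
  list(windows = win, segments = segments)
}

#' Assemble the comparable-region annotation over all ortholog pairs
#'
#' Runs [build_comparable_windows()] for every pair and drops genes retaining
#' fewer than \code{config$min_windows} windows. The result is the paired
#' annotation used by all downstream stages.
#'
#' @param pairs list of [ortholog_pair()] objects.
#' @param alignments list of \code{ow_alignment} objects, parallel to
#'   \code{pairs} (or named by pair_id).
#' @param config a [filter_config()].
#' @return Object of class \code{ow_annotation}: list with \code{genes},
#'   \code{windows}, \code{segments}, \code{excluded}, \code{species}
#'   (named c(a =, b =)), \code{config}.
#' @export
build_annotation <- function(pairs, alignments, config = filter_config()) {
  if (length(pairs) == 0L) {
    return(structure(list(
      genes = data.frame(pair_id = character(0), gene_a = character(0),
                         gene_b = character(0), n_windows = integer(0),
                         stringsAsFactors = FALSE),
      windows = build_comparable_windows_empty(),
      segments = data.frame(pair_id = character(0), window_index = integer(0),
                            species = character(0), gene_id = character(0),
                            chrom = character(0), strand = character(0),
                            start = numeric(0), end = numeric(0),
                            stringsAsFactors = FALSE),
      excluded = data.frame(pair_id = character(0), reason = character(0),
                            stringsAsFactors = FALSE),
      species = c(a = "species_a", b = "species_b"), config = config),
      class = "ow_annotation"))
  }
  if (!is.null(names(alignments)))
    alignments <- alignments[vapply(pairs, `[[`, character(1), "pair_id")]
  win_l <- list(); seg_l <- list(); gene_l <- list(); excl_l <- list()
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    bw <- build_comparable_windows(p, alignments[[k]], config)
    if (nrow(bw$windows) < config$min_windows) {
      excl_l[[length(excl_l) + 1L]] <- data.frame(
        pair_id = p$pair_id, reason = "too_few_windows",
        stringsAsFactors = FALSE)
      next
    }
    win_l[[length(win_l) + 1L]] <- bw$windows
    seg_l[[length(seg_l) + 1L]] <- bw$segments
    gene_l[[length(gene_l) + 1L]] <- data.frame(
      pair_id = p$pair_id, gene_a = p$gene_a, gene_b = p$gene_b,
      n_windows = nrow(bw$windows), stringsAsFactors = FALSE)
  }
  sp <- c(a = pairs[[1L]]$species_a, b = pairs[[1L]]$species_b)
  structure(list(
    genes = if (length(gene_l)) do.call(rbind, gene_l) else
      data.frame(pair_id = character(0), gene_a = character(0),
                 gene_b = character(0), n_windows = integer(0),
                 stringsAsFactors = FALSE),
    windows = if (length(win_l)) do.call(rbind, win_l) else
      build_comparable_windows_empty(),
    segments = if (length(seg_l)) do.call(rbind, seg_l) else
      data.frame(pair_id = character(0), window_index = integer(0),
                 species = character(0), gene_id = character(0),
                 chrom = character(0), strand = character(0),
                 start = numeric(0), end = numeric(0), stringsAsFactors = FALSE),
    excluded = if (length(excl_l)) do.call(rbind, excl_l) else
      data.frame(pair_id = character(0), reason = character(0),
                 stringsAsFactors = FALSE),
    species = sp, config = config), class = "ow_annotation")
}

# empty windows table with the canonical columns
build_comparable_windows_empty <- function() {
  df <- data.frame(pair_id = character(0), window_index = integer(0),
                   col_start = integer(0), col_end = integer(0),
                   n_match = integer(0), n_mismatch = integer(0),
                   n_gap_cols = integer(0), identity = numeric(0),
                   tx_start_a = integer(0), tx_end_a = integer(0),
                   tx_start_b = integer(0), tx_end_b = integer(0),
                   stringsAsFactors = FALSE)
  df$len_a <- integer(0); df$len_b <- integer(0)
  df
}

#' @export
print.ow_annotation <- function(x, ...) {
  cat(sprintf(
    "Comparable-region annotation: %d gene pair(s), %d window(s), %d excluded pair(s)\n",
    nrow(x$genes), nrow(x$windows), nrow(x$excluded)))
  cat(sprintf("  species: a = %s, b = %s\n", x$species["a"], x$species["b"]))
  invisible(x)
}

#' Comparable length per gene and species
#'
#' @param annotation an \code{ow_annotation}.
#' @return matrix (genes x 2) of summed retained-segment lengths, columns
#'   named by the two species.
#' @export
comparable_lengths <- function(annotation) {
  g <- annotation$genes$pair_id
  out <- matrix(0, nrow = length(g), ncol = 2L,
                dimnames = list(g, unname(annotation$species)))
  if (nrow(annotation$segments) > 0L) {
    w <- annotation$segments$end - annotation$segments$start
    agg <- tapply(w, list(annotation$segments$pair_id,
                          annotation$segments$species), sum)
    out[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
  }
  out
}

.gtf_attr <- function(gene, window) {
  sprintf('gene_id "%s"; transcript_id "%s.cmp"; window_id "%d";',
          gene, gene, window)
}

#' Write the paired annotation to disk
#'
#' Produces one GTF per species (feature \code{exon}, one record per genomic
#' segment, 1-based inclusive coordinates, attributes \code{gene_id},
#' \code{transcript_id "<gene>.cmp"} and \code{window_id}) plus a windows TSV
#' holding per-window statistics and the coordinates in both species. The
#' windows TSV is the package's own round-trip format ([read_annotation()]);
#' the GTFs serve external tools.
#'
#' @param annotation an \code{ow_annotation}.
#' @param out_prefix path prefix; writes \code{<prefix>.<species>.gtf} for
#'   both species and \code{<prefix>.windows.tsv}.
#' @return Invisibly, the vector of written paths.
#' @export
write_annotation <- function(annotation, out_prefix) {
  paths <- character(0)
  for (side in c("a", "b")) {
    sp <- annotation$species[[side]]
    seg <- annotation$segments[annotation$segments$species == sp, , drop = FALSE]
    path <- paste0(out_prefix, ".", sp, ".gtf")
    lines <- if (nrow(seg) > 0L) {
      seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
      sprintf("%s\torthowindow\texon\t%d\t%d\t.\t%s\t.\t%s",
              seg$chrom, as.integer(seg$start) + 1L, as.integer(seg$end),
              seg$strand, .gtf_attr(seg$gene_id, seg$window_index))
    } else character(0)
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  win <- annotation$windows
  gene_map <- annotation$genes
  m <- match(win$pair_id, gene_map$pair_id)
  tsv <- data.frame(pair_id = win$pair_id,
                    gene_a = gene_map$gene_a[m], gene_b = gene_map$gene_b[m],
                    window_index = win$window_index,
                    n_match = win$n_match, n_mismatch = win$n_mismatch,
                    n_gap_cols = win$n_gap_cols,
                    identity = round(win$identity, 6),
                    len_a = win$len_a, len_b = win$len_b,
                    coords_a = NA_character_, coords_b = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(win) > 0L) {
    win_key <- paste(win$pair_id, win$window_index)
    for (side in c("a", "b")) {
      sp <- annotation$species[[side]]
      seg_sp <- annotation$segments[annotation$segments$species == sp, , drop = FALSE]
      key_sp <- paste(seg_sp$pair_id, seg_sp$window_index)
      by_key <- split(seq_len(nrow(seg_sp)), key_sp)
      tsv[[paste0("coords_", side)]] <- vapply(win_key, function(k) {
        idx <- by_key[[k]]
        if (is.null(idx)) return("")
        s <- seg_sp[idx, , drop = FALSE]
        sprintf("%s:%s:%s", s$chrom[1L], s$strand[1L], .segments_to_string(s))
      }, character(1), USE.NAMES = FALSE)
    }
  }
  tsv_path <- paste0(out_prefix, ".windows.tsv")
  hdr <- sprintf("# species_a=%s species_b=%s window_len=%d",
                 annotation$species["a"], annotation$species["b"],
                 annotation$config$window_len)
  writeLines(hdr, tsv_path)
  suppressWarnings(write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(c(paths, tsv_path))
}

#' Read an annotation written by [write_annotation()]
#'
#' @param out_prefix the prefix passed to [write_annotation()].
#' @param config optional [filter_config()] to attach (defaults used
#'   otherwise, with the stored window length).
#' @return An \code{ow_annotation}.
#' @export
read_annotation <- function(out_prefix, config = NULL) {
  tsv_path <- paste0(out_prefix, ".windows.tsv")
  if (!file.exists(tsv_path)) ow_stop_io("windows table not found: ", tsv_path)
  hdr <- readLines(tsv_path, n = 1L)
  sp <- c(a = sub(".*species_a=(\\S+).*", "\\1", hdr),
          b = sub(".*species_b=(\\S+).*", "\\1", hdr))
  wl <- as.integer(sub(".*window_len=(\\d+).*", "\\1", hdr))
  if (is.null(config)) config <- filter_config(window_len = wl)
  tsv <- read.table(tsv_path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (nrow(tsv) == 0L)
    return(build_annotation(list(), list(), config))
  seg_l <- list()
  for (side in c("a", "b")) {
    coords <- tsv[[paste0("coords_", side)]]
    parts <- regmatches(coords, regexec("^([^:]+):([+-]):(.+)$", coords))
    for (i in seq_along(coords)) {
      if (length(parts[[i]]) != 4L) next
      seg <- .string_to_segments(parts[[i]][4L])
      seg_l[[length(seg_l) + 1L]] <- data.frame(
        pair_id = tsv$pair_id[i], window_index = tsv$window_index[i],
        species = unname(sp[side]),
        gene_id = tsv[[paste0("gene_", side)]][i],
        chrom = parts[[i]][2L], strand = parts[[i]][3L],
        start = seg$start, end = seg$end, stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, seg_l)
  win <- tsv[, c("pair_id", "window_index", "n_match", "n_mismatch",
                 "n_gap_cols", "identity", "len_a", "len_b")]
  genes <- unique(tsv[, c("pair_id", "gene_a", "gene_b")])
  nw <- table(win$pair_id)
  genes$n_windows <- as.integer(nw[genes$pair_id])
  rownames(genes) <- NULL
  structure(list(genes = genes, windows = win, segments = segments,
                 excluded = data.frame(pair_id = character(0),
                                       reason = character(0),
                                       stringsAsFactors = FALSE),
                 species = sp, config = config),
            class = "ow_annotation")
}
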