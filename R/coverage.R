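## Per-sample depth tracks and replicate-averaged, library-normalized
## per-window coverage profiles.

#' Read a bedGraph depth track
#'
#' Parses a bedGraph file (chrom, start, end, value; 0-based half-open) into
#' a validated depth track. Track definition, browser and comment lines are
#' skipped. Intervals must be non-overlapping with finite non-negative depth.
#'
#' @param path bedGraph file.
#' @param sample_id,species labels attached to the track.
#' @return Object of class \code{ow_depth_track}: list with \code{sample_id},
#'   \code{species}, \code{runs} (data.frame chrom/start/end/depth, sorted)
#'   and \code{total_depth_mass} (sum of depth x width).
#' @export
read_bedgraph <- function(path, sample_id, species) {
  if (!file.exists(path)) ow_stop_io("bedGraph not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^(track|browser|#)", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  if (length(lineno) == 0L) {
    runs <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), depth = numeric(0),
                       stringsAsFactors = FALSE)
    return(structure(list(sample_id = sample_id, species = species,
                          runs = runs, total_depth_mass = 0),
                     class = "ow_depth_track"))
  }
  fields <- strsplit(raw[keep], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    ow_stop_validation(sprintf("%s: malformed bedGraph line %d (need 4 fields)",
                               path, lineno[which(nf < 4L)[1L]]))
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  depth <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(depth) | start < 0 |
                 start >= end | !is.finite(depth))
  if (length(bad) > 0L)
    ow_stop_validation(sprintf("%s: malformed bedGraph line %d",
                               path, lineno[bad[1L]]))
  neg <- which(depth < 0)
  if (length(neg) > 0L)
    ow_stop_validation(sprintf("%s: negative depth at line %d",
                               path, lineno[neg[1L]]))
  o <- order(chrom, start)
  same <- chrom[o][-1L] == chrom[o][-length(o)]
  ovl <- which(same & start[o][-1L] < end[o][-length(o)])
  if (length(ovl) > 0L)
    ow_stop_validation(sprintf("%s: overlapping intervals at line %d",
                               path, lineno[o[ovl[1L] + 1L]]))
  runs <- data.frame(chrom = chrom[o], start = start[o], end = end[o],
                     depth = depth[o], stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, species = species, runs = runs,
                 total_depth_mass = sum(runs$depth * (runs$end - runs$start))),
            class = "ow_depth_track")
}

#' @export
print.ow_depth_track <- function(x, ...) {
  cat(sprintf("Depth track '%s' (%s): %d run(s), depth mass %.4g\n",
              x$sample_id, x$species, nrow(x$runs), x$total_depth_mass))
  invisible(x)
}

# covered depth mass of many segments against a track; segments carries a
# `key` column; returns named vector of masses per key (absent bases = 0)
.segment_masses <- function(track, segments) {
  masses <- setNames(numeric(length(unique(segments$key))),
                     unique(segments$key))
  for (chr in unique(segments$chrom)) {
    seg <- segments[segments$chrom == chr, , drop = FALSE]
    run <- track$runs[track$runs$chrom == chr, , drop = FALSE]
    if (nrow(run) == 0L) next
    ir_seg <- IRanges::IRanges(start = seg$start + 1L, end = seg$end)
    ir_run <- IRanges::IRanges(start = run$start + 1L, end = run$end)
    ov <- IRanges::findOverlaps(ir_seg, ir_run)
    if (length(ov) == 0L) next
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(ir_seg[qi], ir_run[si]))
    contrib <- w * run$depth[si]
    add <- tapply(contrib, seg$key[qi], sum)
    masses[names(add)] <- masses[names(add)] + add
  }
  masses
}

#' Mean per-base depth of one genomic window
#'
#' Sums per-base depth over the window's segments (bases absent from the
#' track count as depth 0) and divides by the window's total length.
#'
#' @param track an \code{ow_depth_track}.
#' @param genomic_window data.frame of segments with columns \code{chrom},
#'   \code{start}, \code{end} (0-based half-open).
#' @return mean depth (numeric scalar).
#' @examples
#' tr <- structure(list(sample_id = "s", species = "x",
#'   runs = data.frame(chrom = "chr1", start = 0, end = 100, depth = 7),
#'   total_depth_mass = 700), class = "ow_depth_track")
#' window_mean_depth(tr, data.frame(chrom = "chr1", start = 10, end = 35))
#' @export
window_mean_depth <- function(track, genomic_window) {
  len <- sum(genomic_window$end - genomic_window$start)
  if (len <= 0) ow_stop_validation("window has zero total length")
  seg <- genomic_window
  seg$key <- "w"
  unname(.segment_masses(track, seg)["w"]) / len
}

#' Replicate-averaged normalized coverage profiles per gene
#'
#' For every retained window of every gene, computes each sample's mean
#' per-base depth, scales it to per-million depth mass
#' (\code{mean_depth * 1e6 / total_depth_mass}) so the downstream sign test
#' is well defined across library sizes, and averages the replicates within
#' each species. Pearson correlation is unaffected by the scaling.
#'
#' @param annotation an \code{ow_annotation}.
#' @param tracks list of \code{ow_depth_track}; species labels must match the
#'   annotation's two species, each with at least one track. Tracks with zero
#'   depth mass are excluded with a warning.
#' @return list with \code{profiles} (data.frame \code{pair_id},
#'   \code{window_index}, \code{a}, \code{b}: the two replicate-averaged
#'   normalized depths) and \code{coverage} (per-sample long table:
#'   \code{pair_id}, \code{window_index}, \code{sample_id}, \code{species},
#'   \code{mean_depth}, \code{norm_depth}).
#' @export
build_species_profiles <- function(annotation, tracks) {
  sp <- annotation$species
  track_sp <- vapply(tracks, `[[`, character(1), "species")
  for (side in c("a", "b"))
    if (!any(track_sp == sp[[side]]))
      ow_stop_validation("no depth track for species '", sp[[side]], "'")
  bad <- vapply(tracks, function(t) t$total_depth_mass <= 0, logical(1))
  if (any(bad)) {
    warning("excluding track(s) with zero depth mass: ",
            paste(vapply(tracks[bad], `[[`, character(1), "sample_id"),
                  collapse = ", "))
    tracks <- tracks[!bad]
    track_sp <- track_sp[!bad]
    for (side in c("a", "b"))
      if (!any(track_sp == sp[[side]]))
        ow_stop_validation("no usable depth track for species '", sp[[side]], "'")
  }
  win <- annotation$windows
  win_key <- paste(win$pair_id, win$window_index)
  cov_l <- list()
  for (t in tracks) {
    seg <- annotation$segments[annotation$segments$species == t$species, ,
                               drop = FALSE]
    seg$key <- paste(seg$pair_id, seg$window_index)
    len <- tapply(seg$end - seg$start, seg$key, sum)
    masses <- .segment_masses(t, seg)
    mean_depth <- as.numeric(masses[win_key]) / as.numeric(len[win_key])
    cov_l[[length(cov_l) + 1L]] <- data.frame(
      pair_id = win$pair_id, window_index = win$window_index,
      sample_id = t$sample_id, species = t$species,
      mean_depth = mean_depth,
      norm_depth = mean_depth * 1e6 / t$total_depth_mass,
      stringsAsFactors = FALSE)
  }
  coverage <- do.call(rbind, cov_l)
  prof <- data.frame(pair_id = win$pair_id, window_index = win$window_index,
                     stringsAsFactors = FALSE)
  for (side in c("a", "b")) {
    cc <- coverage[coverage$species == sp[[side]], , drop = FALSE]
    m <- tapply(cc$norm_depth, paste(cc$pair_id, cc$window_index), mean)
    prof[[side]] <- as.numeric(m[win_key])
  }
  list(profiles = prof, coverage = coverage)
}
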