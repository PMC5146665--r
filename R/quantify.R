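## Fragment counting over comparable regions, TMM/CPM/FPKM normalization,
## fold changes, threshold calls, and validation statistics.

#' Read fragment intervals from a BED file
#'
#' Minimal BED reader for fragment intervals (chrom, start, end; 0-based
#' half-open). Paired mates are expected to be pre-merged to one fragment
#' interval per record. Extra columns are ignored.
#'
#' @param path BED file.
#' @return data.frame with \code{chrom}, \code{start}, \code{end}.
#' @export
read_fragments_bed <- function(path) {
  if (!file.exists(path)) ow_stop_io("fragment BED not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^(track|browser|#)", raw) & nzchar(trimws(raw))
  if (!any(keep))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  lineno <- which(keep)
  fields <- strsplit(raw[keep], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    ow_stop_validation(sprintf("%s: malformed BED line %d (need 3 fields)",
                               path, lineno[which(nf < 3L)[1L]]))
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0L)
    ow_stop_validation(sprintf("%s: malformed BED line %d", path,
                               lineno[bad[1L]]))
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Count fragments over the comparable regions (union mode)
#'
#' A fragment is assigned to a gene when it overlaps (>= 1 bp) retained
#' window segments of exactly one gene; a fragment touching windows of two or
#' more genes is discarded as ambiguous, and a fragment touching no window is
#' unassigned. Each fragment is counted at most once. Fragments on
#' chromosomes absent from the annotation count as unassigned (with a
#' warning). Counting ignores strand.
#'
#' @param fragments named list (by sample id) of fragment data.frames as from
#'   [read_fragments_bed()].
#' @param annotation a finalized \code{ow_annotation}.
#' @param sample_species named character vector mapping sample id to species
#'   label (one of the annotation's two species).
#' @return Object of class \code{ow_counts}: list with \code{counts}
#'   (genes x samples integer matrix), \code{samples} (data.frame
#'   \code{sample_id}, \code{species}), \code{lengths} (genes x 2 comparable
#'   lengths from [comparable_lengths()]), \code{tallies} (per-sample
#'   assigned / ambiguous / unassigned).
#' @export
count_fragments <- function(fragments, annotation, sample_species) {
  sp <- annotation$species
  if (is.null(names(fragments)) || !all(names(fragments) %in% names(sample_species)))
    ow_stop_validation("fragments must be a named list with species labels for each sample")
  genes <- annotation$genes$pair_id
  counts <- matrix(0L, nrow = length(genes), ncol = length(fragments),
                   dimnames = list(genes, names(fragments)))
  tallies <- data.frame(sample_id = names(fragments),
                        assigned = 0L, ambiguous = 0L, unassigned = 0L,
                        stringsAsFactors = FALSE)
  seg_by_sp <- list()
  for (side in c("a", "b")) {
    seg <- annotation$segments[annotation$segments$species == sp[[side]], ,
                               drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = seg$chrom,
      ranges = IRanges::IRanges(start = seg$start + 1L, end = seg$end))
    seg_by_sp[[sp[[side]]]] <- list(gr = gr, gene = seg$pair_id)
  }
  for (j in seq_along(fragments)) {
    sid <- names(fragments)[j]
    species <- sample_species[[sid]]
    if (!species %in% sp)
      ow_stop_validation("sample '", sid, "' has unknown species '", species, "'")
    fr <- fragments[[j]]
    tallies$unassigned[j] <- nrow(fr)
    if (nrow(fr) == 0L) next
    ref <- seg_by_sp[[species]]
    known <- fr$chrom %in% as.character(GenomicRanges::seqnames(ref$gr))
    if (!all(known))
      warning(sprintf("sample '%s': %d fragment(s) on chromosomes absent from the annotation",
                      sid, sum(!known)))
    fr_gr <- GenomicRanges::GRanges(
      seqnames = fr$chrom,
      ranges = IRanges::IRanges(start = fr$start + 1L, end = fr$end))
    suppressWarnings(
      ov <- GenomicRanges::findOverlaps(fr_gr, ref$gr, minoverlap = 1L))
    if (length(ov) == 0L) next
    qh <- S4Vectors::queryHits(ov)
    hit_gene <- ref$gene[S4Vectors::subjectHits(ov)]
    ngene <- tapply(hit_gene, qh, function(g) length(unique(g)))
    first_gene <- tapply(hit_gene, qh, `[`, 1L)
    uniq <- names(ngene)[ngene == 1L]
    amb <- sum(ngene > 1L)
    assigned_genes <- as.character(first_gene[uniq])
    tab <- table(assigned_genes)
    counts[names(tab), j] <- counts[names(tab), j] + as.integer(tab)
    tallies$assigned[j] <- length(uniq)
    tallies$ambiguous[j] <- amb
    tallies$unassigned[j] <- nrow(fr) - length(uniq) - amb
  }
  structure(list(counts = counts,
                 samples = data.frame(sample_id = names(fragments),
                                      species = unname(sample_species[names(fragments)]),
                                      stringsAsFactors = FALSE),
                 lengths = comparable_lengths(annotation),
                 tallies = tallies),
            class = "ow_counts")
}

#' @export
print.ow_counts <- function(x, ...) {
  cat(sprintf("Fragment counts: %d gene(s) x %d sample(s)\n",
              nrow(x$counts), ncol(x$counts)))
  print(x$tallies, row.names = FALSE)
  invisible(x)
}

# upper-quartile rate per sample, used to pick the TMM reference
.uq_rate <- function(counts) {
  lib <- colSums(counts)
  apply(counts, 2L, function(x) quantile(x, 0.75)) / lib
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample against the reference, per-gene
#' log2 rate ratios M and average log2 abundances A are computed over genes
#' with nonzero counts in both samples, doubly trimmed (default 30% on M,
#' 5% on A, each side), and combined as a weighted mean with inverse
#' approximate-variance weights; the factor is 2 to that mean. The reference
#' sample's factor is exactly 1; no gene-length term enters because the
#' compared regions have near-equal lengths by construction.
#'
#' @param x an \code{ow_counts} or a genes x samples count matrix.
#' @param ref_sample reference sample id/column; default: the sample whose
#'   upper-quartile count rate is closest to the mean upper-quartile rate.
#' @param trim_m,trim_a trim fractions (each side) on M and A.
#' @return Object of class \code{ow_norm_factors}: data.frame
#'   (\code{sample_id}, \code{lib_size}, \code{tmm_factor},
#'   \code{effective_size}), reference id in attribute \code{"ref_sample"}.
#' @export
tmm_factors <- function(x, ref_sample = NULL, trim_m = 0.30, trim_a = 0.05) {
  counts <- if (inherits(x, "ow_counts")) x$counts else as.matrix(x)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  lib <- colSums(counts)
  if (any(lib <= 0)) ow_stop_validation("a sample has zero total count")
  if (is.null(ref_sample)) {
    uq <- .uq_rate(counts)
    ref_sample <- colnames(counts)[which.min(abs(uq - mean(uq)))]
  }
  if (!ref_sample %in% colnames(counts))
    ow_stop_validation("ref_sample '", ref_sample, "' not in the matrix")
  yr <- counts[, ref_sample]; Nr <- lib[[ref_sample]]
  f <- setNames(numeric(ncol(counts)), colnames(counts))
  for (s in colnames(counts)) {
    if (s == ref_sample) { f[s] <- 1; next }
    y <- counts[, s]; N <- lib[[s]]
    keep0 <- y > 0 & yr > 0
    if (!any(keep0)) {
      warning("TMM: no gene expressed in both '", s, "' and the reference; factor set to 1")
      f[s] <- 1; next
    }
    M <- log2((y[keep0] / N) / (yr[keep0] / Nr))
    A <- 0.5 * log2((y[keep0] / N) * (yr[keep0] / Nr))
    w <- 1 / ((N - y[keep0]) / (N * y[keep0]) + (Nr - yr[keep0]) / (Nr * yr[keep0]))
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) {
      warning("TMM: all genes trimmed away for '", s, "'; factor set to 1")
      f[s] <- 1; next
    }
    f[s] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  out <- data.frame(sample_id = colnames(counts), lib_size = unname(lib),
                    tmm_factor = unname(f),
                    effective_size = unname(lib * f),
                    stringsAsFactors = FALSE)
  if (inherits(x, "ow_counts")) out$species <- x$samples$species
  attr(out, "ref_sample") <- ref_sample
  class(out) <- c("ow_norm_factors", "data.frame")
  out
}

#' Counts per million over effective library sizes
#'
#' @param x an \code{ow_counts} or count matrix.
#' @param norm_factors an \code{ow_norm_factors} from [tmm_factors()]; when
#'   omitted, factors of 1 are used (plain library-size CPM).
#' @return genes x samples matrix of CPM values.
#' @export
cpm <- function(x, norm_factors = NULL) {
  counts <- if (inherits(x, "ow_counts")) x$counts else as.matrix(x)
  eff <- if (is.null(norm_factors)) colSums(counts) else {
    m <- match(colnames(counts), norm_factors$sample_id)
    norm_factors$effective_size[m]
  }
  if (any(!is.finite(eff)) || any(eff <= 0))
    ow_stop_validation("zero or undefined effective library size")
  sweep(counts, 2L, eff, "/") * 1e6
}

#' Fragments per kilobase of comparable region per million
#'
#' FPKM over the comparable regions: CPM scaled by each gene's comparable
#' length in the sample's own species (the two species' lengths differ by at
#' most the window gap allowance).
#'
#' @param x an \code{ow_counts} (lengths and species labels are required).
#' @param norm_factors an \code{ow_norm_factors}; optional as in [cpm()].
#' @return genes x samples matrix of FPKM values.
#' @export
fpkm <- function(x, norm_factors = NULL) {
  if (!inherits(x, "ow_counts"))
    ow_stop_validation("fpkm needs an ow_counts object (for lengths and species)")
  cc <- cpm(x, norm_factors)
  out <- cc
  for (j in seq_len(ncol(cc))) {
    species <- x$samples$species[j]
    len <- x$lengths[rownames(cc), species]
    out[, j] <- cc[, j] * 1e3 / len
  }
  out
}

#' Log2 fold change with pseudocount
#'
#' @param mean_norm_a,mean_norm_b nonnegative normalized means (vectors ok).
#' @param pseudocount added to both sides (default 0.5, in CPM units).
#' @return \code{log2((mean_norm_a + pc) / (mean_norm_b + pc))}.
#' @export
log2_fold_change <- function(mean_norm_a, mean_norm_b, pseudocount = 0.5) {
  if (pseudocount <= 0) ow_stop_validation("pseudocount must be > 0")
  log2((mean_norm_a + pseudocount) / (mean_norm_b + pseudocount))
}

#' Threshold filter for differential-expression calls
#'
#' Splits records into up / down / not-significant using strict cutoffs:
#' up means \code{adj_p < alpha} and \code{log2fc > log2fc_cutoff}; down is
#' symmetric. Adjusted p-values come from an external DE engine.
#'
#' @param records data.frame with \code{gene_id}, \code{log2fc},
#'   \code{adj_p}.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param log2fc_cutoff fold-change cutoff (default 1, i.e. two-fold).
#' @return list with \code{up}, \code{down} (data.frames) and \code{counts}
#'   (named integer vector up/down/ns/skipped). Records with missing
#'   \code{adj_p} are skipped with a warning.
#' @export
de_threshold_filter <- function(records, alpha = 0.05, log2fc_cutoff = 1) {
  need <- c("gene_id", "log2fc", "adj_p")
  if (!all(need %in% names(records)))
    ow_stop_validation("records need columns gene_id, log2fc, adj_p")
  skip <- is.na(records$adj_p)
  if (any(skip))
    warning(sum(skip), " record(s) without adj_p skipped")
  rec <- records[!skip, , drop = FALSE]
  up <- rec[rec$adj_p < alpha & rec$log2fc > log2fc_cutoff, , drop = FALSE]
  down <- rec[rec$adj_p < alpha & rec$log2fc < -log2fc_cutoff, , drop = FALSE]
  list(up = up, down = down,
       counts = c(up = nrow(up), down = nrow(down),
                  ns = nrow(rec) - nrow(up) - nrow(down),
                  skipped = sum(skip)))
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test via \code{stats::t.test(var.equal = FALSE)} with
#' Welch–Satterthwaite degrees of freedom. Zero variance in both groups is
#' degenerate and raises an error (documented convention).
#'
#' @param x_vector,y_vector numeric vectors, each of length >= 2.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welch_t <- function(x_vector, y_vector) {
  if (length(x_vector) < 2L || length(y_vector) < 2L)
    ow_stop_validation("welch_t: each group needs n >= 2")
  if (sd(x_vector) == 0 && sd(y_vector) == 0)
    ow_stop_validation("welch_t: zero variance in both groups (degenerate)")
  ht <- t.test(x_vector, y_vector, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Sign-test concordance of two sets of direction calls
#'
#' Counts positions where two direction-call vectors agree and returns the
#' one-sided (greater) exact sign-test p-value against the null that calls
#' agree half the time by chance — the standard check that an orthogonal
#' assay (e.g. qRT-PCR) corroborates RNA-seq fold-change directions.
#'
#' @param directions_1,directions_2 equal-length vectors of direction calls
#'   (e.g. "+"/"-").
#' @return list with \code{k_concordant}, \code{n}, \code{one_sided_p}.
#' @examples
#' method_concordance(rep("+", 7), c(rep("+", 6), "-"))$one_sided_p  # 0.0625
#' @export
method_concordance <- function(directions_1, directions_2) {
  if (length(directions_1) != length(directions_2))
    ow_stop_validation("method_concordance: vectors differ in length")
  n <- length(directions_1)
  if (n < 1L) ow_stop_validation("method_concordance: empty input")
  k <- sum(directions_1 == directions_2)
  list(k_concordant = k, n = n, one_sided_p = sign_test(k, n, "greater"))
}
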