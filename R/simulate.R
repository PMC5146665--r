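## Seed-reproducible synthetic data: diverged ortholog pairs with recorded
## true alignments, exon models, replicate coverage tracks and fragment sets,
## with ground-truth labels for every pipeline stage.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' 300 ortholog pairs of which one third are discordant (independent coverage
#' profiles between species), 3 replicates per species, multiplicative
#' lognormal coverage noise with sigma 0.2 on the log scale, per-gene species
#' log2 fold changes drawn from \{-2, 0, +2\}, and 5% of windows given a
#' 5-fold coverage distortion in one species.
#'
#' @param n_genes number of ortholog pairs.
#' @param ancestor_length_range transcript length range (bp) of the ancestor.
#' @param n_exons_range range of exon counts per species (min exon 30 bp).
#' @param substitution_rate per-site substitution probability per species.
#' @param indel_rate per-site indel initiation probability per species.
#' @param indel_length_geometric_p geometric length parameter of indels
#'   (length = 1 + Geom(p)).
#' @param n_replicates replicates per species.
#' @param depth_mean baseline mean per-base depth.
#' @param noise_sigma_log sigma of multiplicative lognormal replicate noise.
#' @param profile_sigma_log sigma of the latent per-window weight profile.
#' @param gene_level_sigma_log sigma of the per-gene expression level spread.
#' @param fraction_discordant fraction of genes with independent (discordant)
#'   coverage profiles between species; the count is rounded to a fixed
#'   number of genes so the condition is exact.
#' @param log2fc_values,log2fc_probs point masses of the per-gene species
#'   log2 fold change (concordant genes).
#' @param bias_window_fraction fraction of windows given artificial coverage
#'   distortion in species a only.
#' @param bias_factor the distortion factor (default 5).
#' @param fragment_length fragment length (bp) for fragment simulation.
#' @param species_a,species_b species labels.
#' @param seed base seed; every per-gene draw uses a stream derived from
#'   (seed, gene index, stage), so per-gene results are stable under
#'   \code{n_genes} changes.
#' @return Object of class \code{ow_sim_config}.
#' @export
sim_config <- function(n_genes = 300L,
                       ancestor_length_range = c(600L, 2000L),
                       n_exons_range = c(1L, 6L),
                       substitution_rate = 0.05,
                       indel_rate = 0.002,
                       indel_length_geometric_p = 0.5,
                       n_replicates = 3L,
                       depth_mean = 50,
                       noise_sigma_log = 0.2,
                       profile_sigma_log = 1,
                       gene_level_sigma_log = 1,
                       fraction_discordant = 1 / 3,
                       log2fc_values = c(-2, 0, 2),
                       log2fc_probs = NULL,
                       bias_window_fraction = 0.05,
                       bias_factor = 5,
                       fragment_length = 100L,
                       species_a = "speciesA", species_b = "speciesB",
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 0L)
    ow_stop_validation("n_genes must be a non-negative integer")
  if (ancestor_length_range[1L] < 30L)
    ow_stop_validation("ancestor transcripts must be at least 30 bp (min exon length)")
  if (ancestor_length_range[1L] > ancestor_length_range[2L])
    ow_stop_validation("ancestor_length_range must be increasing")
  for (nm in c("substitution_rate", "indel_rate", "indel_length_geometric_p",
               "fraction_discordant", "bias_window_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1)
      ow_stop_validation(nm, " must lie in [0, 1]")
  }
  if (is.null(log2fc_probs))
    log2fc_probs <- rep(1 / length(log2fc_values), length(log2fc_values))
  if (length(log2fc_probs) != length(log2fc_values))
    ow_stop_validation("log2fc_probs must match log2fc_values in length")
  structure(list(n_genes = n_genes,
                 ancestor_length_range = as.integer(ancestor_length_range),
                 n_exons_range = as.integer(n_exons_range),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 indel_length_geometric_p = indel_length_geometric_p,
                 n_replicates = as.integer(n_replicates),
                 depth_mean = depth_mean,
                 noise_sigma_log = noise_sigma_log,
                 profile_sigma_log = profile_sigma_log,
                 gene_level_sigma_log = gene_level_sigma_log,
                 fraction_discordant = fraction_discordant,
                 log2fc_values = log2fc_values,
                 log2fc_probs = log2fc_probs,
                 bias_window_fraction = bias_window_fraction,
                 bias_factor = bias_factor,
                 fragment_length = as.integer(fragment_length),
                 species_a = species_a, species_b = species_b,
                 seed = as.integer(seed)),
            class = "ow_sim_config")
}

# derived, collision-sparse per-(gene, stage) seed below 2^31
.gene_seed <- function(seed, gene_index, stage) {
  as.integer((abs(as.numeric(seed)) %% 65011 * 32771 +
                as.numeric(gene_index) * 611 + stage * 97) %% 2147483647)
}

.BASES <- c("A", "C", "G", "T")

# mutate an ancestor character vector for one species; returns the per-site
# kept flag, the (possibly substituted) base, and insertion strings after
# each site
.mutate_species <- function(anc, config) {
  L <- length(anc)
  base <- anc
  sub <- runif(L) < config$substitution_rate
  if (any(sub)) {
    idx <- which(sub)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    base[idx] <- .BASES[(match(anc[idx], .BASES) - 1L + shift) %% 4L + 1L]
  }
  keep <- rep(TRUE, L)
  ins <- character(L)
  ev <- which(runif(L) < config$indel_rate)
  for (i in ev) {
    len <- 1L + rgeom(1L, config$indel_length_geometric_p)
    if (runif(1) < 0.5) {
      keep[i:min(i + len - 1L, L)] <- FALSE
    } else {
      ins[i] <- paste(sample(.BASES, len, replace = TRUE), collapse = "")
    }
  }
  list(keep = keep, base = base, ins = ins)
}

# random exon model for one species: partition length L into k exons of at
# least 30 bp, random intron lengths, deterministic genomic slot per gene
.random_exon_model <- function(gene_id, L, gene_index, config) {
  k_want <- sample(seq(config$n_exons_range[1L], config$n_exons_range[2L]), 1L)
  k <- max(1L, min(k_want, L %/% 30L))
  extra <- L - 30L * k
  lens <- if (k == 1L) L else {
    cuts <- sort(sample.int(extra + 1L, k - 1L, replace = TRUE) - 1L)
    30L + diff(c(0L, cuts, extra))
  }
  introns <- if (k > 1L) sample(200:2000, k - 1L, replace = TRUE) else integer(0)
  start0 <- gene_index * 100000
  starts <- start0 + cumsum(c(0L, lens[-k] + introns))
  exon_model(gene_id, "chr1", sample(c("+", "-"), 1L),
             cbind(starts, starts + lens))
}

#' Simulate one diverged ortholog pair with its true alignment
#'
#' Mutates a random ancestor transcript independently in each species
#' (substitutions at \code{substitution_rate}; insertions/deletions at
#' \code{indel_rate} with geometric lengths) and records the resulting
#' column-level alignment, so downstream windowing can run without an
#' aligner. Exon boundaries are drawn at random per species with a minimum
#' exon length of 30 bp; each gene occupies a deterministic genomic slot.
#'
#' @param config an [sim_config()].
#' @param gene_index 1-based gene index (drives the per-gene RNG stream).
#' @return list with \code{pair} (an [ortholog_pair()]) and \code{alignment}
#'   (the true \code{ow_alignment}).
#' @export
simulate_ortholog_pair <- function(config, gene_index) {
  set.seed(.gene_seed(config$seed, gene_index, 1L))
  L0 <- sample(seq(config$ancestor_length_range[1L],
                   config$ancestor_length_range[2L]), 1L)
  anc <- sample(.BASES, L0, replace = TRUE)
  ma <- .mutate_species(anc, config)
  mb <- .mutate_species(anc, config)
  ca <- ifelse(ma$keep, ma$base, "-")
  cb <- ifelse(mb$keep, mb$base, "-")
  drop <- !ma$keep & !mb$keep          # deleted in both: no column
  ca[drop] <- ""; cb[drop] <- ""
  gaps_for_b <- strrep("-", nchar(mb$ins))
  gaps_for_a <- strrep("-", nchar(ma$ins))
  row_a <- paste(paste0(ca, ma$ins, gaps_for_b), collapse = "")
  row_b <- paste(paste0(cb, gaps_for_a, mb$ins), collapse = "")
  pair_id <- sprintf("g%04d", gene_index)
  aln <- pairwise_alignment(row_a, row_b, pair_id = pair_id)
  seq_a <- .degap(row_a); seq_b <- .degap(row_b)
  gene_a <- sprintf("gA%04d", gene_index)
  gene_b <- sprintf("gB%04d", gene_index)
  em_a <- .random_exon_model(gene_a, nchar(seq_a), gene_index, config)
  em_b <- .random_exon_model(gene_b, nchar(seq_b), gene_index, config)
  pair <- ortholog_pair(pair_id, gene_a, gene_b, seq_a, seq_b, em_a, em_b,
                        species_a = config$species_a,
                        species_b = config$species_b)
  list(pair = pair, alignment = aln)
}

#' Ground-truth gene labels for a simulated dataset
#'
#' Assigns each gene its concordance flag and true species log2 fold change.
#' Exactly \code{round(n_genes * fraction_discordant)} genes (the highest
#' gene indices) are discordant, so the condition counts are exact.
#'
#' @param config an [sim_config()].
#' @return data.frame with \code{pair_id}, \code{gene_index},
#'   \code{concordant}, \code{true_log2fc} (NA for discordant genes).
#' @export
simulate_truth <- function(config) {
  n <- config$n_genes
  n_disc <- round(n * config$fraction_discordant)
  concordant <- c(rep(TRUE, n - n_disc), rep(FALSE, n_disc))
  lfc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!concordant[i]) next
    set.seed(.gene_seed(config$seed, i, 2L))
    lfc[i] <- sample(config$log2fc_values, 1L, prob = config$log2fc_probs)
  }
  data.frame(pair_id = sprintf("g%04d", seq_len(n)),
             gene_index = seq_len(n), concordant = concordant,
             true_log2fc = lfc, stringsAsFactors = FALSE)
}

#' Simulate replicate coverage tracks over an annotation
#'
#' Per gene, a latent lognormal window-weight profile drives the depth of
#' every retained window. Concordant genes share the profile across species,
#' scaled by \code{2^true_log2fc} in species a; discordant genes draw
#' independent profiles per species. Each replicate multiplies every window
#' by lognormal noise, and bias windows (chosen at rate
#' \code{bias_window_fraction}) are additionally distorted by
#' \code{bias_factor} in species a only.
#'
#' @param annotation an \code{ow_annotation}.
#' @param truth output of [simulate_truth()].
#' @param config an [sim_config()].
#' @return list with \code{tracks} (list of \code{ow_depth_track}, one per
#'   replicate per species, sample ids \code{<species>_rep<k>}) and
#'   \code{bias_windows} (data.frame \code{pair_id}, \code{window_index}).
#' @export
simulate_coverage <- function(annotation, truth, config) {
  sp <- annotation$species
  nrep <- config$n_replicates
  sample_ids <- c(outer(paste0(unname(sp), "_rep"), seq_len(nrep), paste0))
  runs <- setNames(vector("list", length(sample_ids)), sample_ids)
  for (s in sample_ids) runs[[s]] <- list()
  bias_l <- list()
  seg_all <- annotation$segments
  for (g in annotation$genes$pair_id) {
    i <- as.integer(sub("^g", "", g))
    tr <- truth[truth$pair_id == g, , drop = FALSE]
    win_idx <- sort(unique(seg_all$window_index[seg_all$pair_id == g]))
    nw <- length(win_idx)
    set.seed(.gene_seed(config$seed, i, 3L))
    w_a <- stats::rlnorm(nw, 0, config$profile_sigma_log)
    w_b <- if (isTRUE(tr$concordant)) w_a else
      stats::rlnorm(nw, 0, config$profile_sigma_log)
    lfc <- if (isTRUE(tr$concordant) && is.finite(tr$true_log2fc))
      tr$true_log2fc else 0
    mean_a <- config$depth_mean * w_a * 2^lfc
    mean_b <- config$depth_mean * w_b
    bias <- runif(nw) < config$bias_window_fraction
    if (any(bias))
      bias_l[[length(bias_l) + 1L]] <- data.frame(
        pair_id = g, window_index = win_idx[bias], stringsAsFactors = FALSE)
    mean_a[bias] <- mean_a[bias] * config$bias_factor
    for (side in c("a", "b")) {
      mu <- if (side == "a") mean_a else mean_b
      seg <- seg_all[seg_all$pair_id == g & seg_all$species == sp[[side]], ,
                     drop = FALSE]
      m <- match(seg$window_index, win_idx)
      for (k in seq_len(nrep)) {
        noise <- stats::rlnorm(nw, 0, config$noise_sigma_log)
        depth <- round(mu * noise, 4)
        sid <- paste0(sp[[side]], "_rep", k)
        runs[[sid]][[length(runs[[sid]]) + 1L]] <- data.frame(
          chrom = seg$chrom, start = seg$start, end = seg$end,
          depth = depth[m], stringsAsFactors = FALSE)
      }
    }
  }
  tracks <- lapply(sample_ids, function(sid) {
    species <- sub("_rep\\d+$", "", sid)
    rr <- if (length(runs[[sid]])) do.call(rbind, runs[[sid]]) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 depth = numeric(0), stringsAsFactors = FALSE)
    rr <- rr[order(rr$chrom, rr$start), , drop = FALSE]
    rownames(rr) <- NULL
    structure(list(sample_id = sid, species = species, runs = rr,
                   total_depth_mass = sum(rr$depth * (rr$end - rr$start))),
              class = "ow_depth_track")
  })
  names(tracks) <- sample_ids
  bias <- if (length(bias_l)) do.call(rbind, bias_l) else
    data.frame(pair_id = character(0), window_index = integer(0),
               stringsAsFactors = FALSE)
  list(tracks = tracks, bias_windows = bias)
}

#' Simulate fragment intervals over an annotation
#'
#' Per gene, sample and replicate, the fragment count is Poisson with mean
#' proportional to the gene's expression level, its comparable length and
#' the species fold change; each fragment starts uniformly within the gene's
#' retained window segments (segment chosen proportional to its length) and
#' extends \code{fragment_length} bp, clipped to the segment end — so every
#' simulated fragment lies inside a comparable window.
#'
#' @param annotation a finalized \code{ow_annotation}.
#' @param truth output of [simulate_truth()].
#' @param config an [sim_config()].
#' @return named list (sample id \code{<species>_rep<k>}) of fragment
#'   data.frames (\code{chrom}, \code{start}, \code{end}).
#' @export
simulate_fragments <- function(annotation, truth, config) {
  sp <- annotation$species
  nrep <- config$n_replicates
  sample_ids <- c(outer(paste0(unname(sp), "_rep"), seq_len(nrep), paste0))
  frags <- setNames(lapply(sample_ids, function(s) list()), sample_ids)
  seg_all <- annotation$segments
  for (g in annotation$genes$pair_id) {
    i <- as.integer(sub("^g", "", g))
    tr <- truth[truth$pair_id == g, , drop = FALSE]
    lfc <- if (isTRUE(tr$concordant) && is.finite(tr$true_log2fc))
      tr$true_log2fc else 0
    set.seed(.gene_seed(config$seed, i, 4L))
    level <- stats::rlnorm(1L, 0, config$gene_level_sigma_log)
    for (side in c("a", "b")) {
      seg <- seg_all[seg_all$pair_id == g & seg_all$species == sp[[side]], ,
                     drop = FALSE]
      if (nrow(seg) == 0L) next
      seg_len <- seg$end - seg$start
      Lcomp <- sum(seg_len)
      lambda <- config$depth_mean * level * Lcomp / config$fragment_length *
        (if (side == "a") 2^lfc else 1)
      for (k in seq_len(nrep)) {
        n_frag <- rpois(1L, lambda)
        if (n_frag == 0L) next
        pick <- sample.int(nrow(seg), n_frag, replace = TRUE,
                           prob = seg_len)
        pos <- floor(seg$start[pick] + runif(n_frag) * seg_len[pick])
        frag_end <- pmin(pos + config$fragment_length, seg$end[pick])
        sid <- paste0(sp[[side]], "_rep", k)
        frags[[sid]][[length(frags[[sid]]) + 1L]] <- data.frame(
          chrom = seg$chrom[pick], start = pos, end = frag_end,
          stringsAsFactors = FALSE)
      }
    }
  }
  lapply(frags, function(fl) {
    if (length(fl) == 0L)
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), stringsAsFactors = FALSE))
    ff <- do.call(rbind, fl)
    ff <- ff[order(ff$chrom, ff$start), , drop = FALSE]
    rownames(ff) <- NULL
    ff
  })
}

.write_fasta <- function(seqs, path) {
  if (length(seqs) == 0L) {
    writeLines(character(0), path)
    return(invisible())
  }
  out <- character(2L * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  out[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(out, path)
}

.write_exon_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(em) {
    sprintf("%s\torthowindow_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
            em$chrom, as.integer(em$exons[, "start"]) + 1L,
            as.integer(em$exons[, "end"]), em$strand, em$gene_id, em$gene_id)
  }))
  writeLines(as.character(lines), path)
}

.write_bedgraph <- function(track, path) {
  r <- track$runs
  writeLines(sprintf("%s\t%d\t%d\t%s", r$chrom, as.integer(r$start),
                     as.integer(r$end), format(r$depth, trim = TRUE,
                                               scientific = FALSE)),
             path)
}

.write_bed <- function(fr, path) {
  writeLines(sprintf("%s\t%d\t%d", fr$chrom, as.integer(fr$start),
                     as.integer(fr$end)), path)
}

#' Generate a complete fixture dataset on disk
#'
#' Writes every input the pipeline (and its CLI) consumes: transcript FASTAs
#' and exon GTFs per species, one aligned FASTA per pair (the recorded true
#' alignment), the ortholog pair table, replicate bedGraph coverage tracks
#' and fragment BEDs with a sample sheet, and a ground-truth table. Identical
#' config and seed produce byte-identical output.
#'
#' @param config an [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param filter a [filter_config()] used to derive the windows the coverage
#'   and fragment simulations are placed on.
#' @return Invisible list with \code{dir}, the in-memory \code{annotation},
#'   \code{truth}, \code{bias_windows}, and the file paths.
#' @export
make_fixture_dataset <- function(config = sim_config(), out_dir,
                                 filter = filter_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln_dir <- file.path(out_dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  sims <- lapply(seq_len(config$n_genes), function(i)
    simulate_ortholog_pair(config, i))
  pairs <- lapply(sims, `[[`, "pair")
  alignments <- lapply(sims, `[[`, "alignment")
  seq_a <- setNames(vapply(pairs, `[[`, character(1), "sequence_a"),
                    vapply(pairs, `[[`, character(1), "gene_a"))
  seq_b <- setNames(vapply(pairs, `[[`, character(1), "sequence_b"),
                    vapply(pairs, `[[`, character(1), "gene_b"))
  .write_fasta(seq_a, file.path(out_dir, paste0("transcripts_", config$species_a, ".fasta")))
  .write_fasta(seq_b, file.path(out_dir, paste0("transcripts_", config$species_b, ".fasta")))
  .write_exon_gtf(lapply(pairs, `[[`, "exon_model_a"),
                  file.path(out_dir, paste0("exons_", config$species_a, ".gtf")))
  .write_exon_gtf(lapply(pairs, `[[`, "exon_model_b"),
                  file.path(out_dir, paste0("exons_", config$species_b, ".gtf")))
  pair_tab <- data.frame(gene_a = vapply(pairs, `[[`, character(1), "gene_a"),
                         gene_b = vapply(pairs, `[[`, character(1), "gene_b"),
                         stringsAsFactors = FALSE)
  write.table(pair_tab, file.path(out_dir, "pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]; a <- alignments[[k]]
    writeLines(c(paste0(">", p$gene_a), a$row_a,
                 paste0(">", p$gene_b), a$row_b),
               file.path(aln_dir, paste0(p$gene_a, "__", p$gene_b, ".fasta")))
  }
  annotation <- build_annotation(pairs, alignments, filter)
  if (length(pairs) == 0L)
    annotation$species <- c(a = config$species_a, b = config$species_b)
  truth <- simulate_truth(config)
  cov <- simulate_coverage(annotation, truth, config)
  frags <- simulate_fragments(annotation, truth, config)
  # paths inside samples.tsv are relative to the dataset directory so the
  # fixture is relocatable and byte-identical across output locations
  sheet_rel <- data.frame(sample_id = names(cov$tracks),
                          species = vapply(cov$tracks, `[[`, character(1), "species"),
                          bedgraph = paste0("cov_", names(cov$tracks), ".bedGraph"),
                          bed = paste0("frag_", names(cov$tracks), ".bed"),
                          stringsAsFactors = FALSE)
  sheet <- sheet_rel
  sheet$bedgraph <- file.path(out_dir, sheet_rel$bedgraph)
  sheet$bed <- file.path(out_dir, sheet_rel$bed)
  for (i in seq_len(nrow(sheet))) {
    .write_bedgraph(cov$tracks[[sheet$sample_id[i]]], sheet$bedgraph[i])
    .write_bed(frags[[sheet$sample_id[i]]], sheet$bed[i])
  }
  write.table(sheet_rel, file.path(out_dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bias_str <- vapply(truth$pair_id, function(g) {
    b <- cov$bias_windows$window_index[cov$bias_windows$pair_id == g]
    paste(b, collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  truth_out <- truth
  truth_out$bias_windows <- bias_str
  write.table(truth_out, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(dir = out_dir, annotation = annotation, truth = truth,
                 bias_windows = cov$bias_windows, samples = sheet,
                 pairs = pairs, alignments = alignments))
}
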