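# small in-code fixture builders shared across test files

# depth track straight from a runs table (bypasses file I/O)
make_track <- function(runs, sample_id = "s1", species = "spA") {
  runs <- runs[order(runs$chrom, runs$start), , drop = FALSE]
  structure(list(sample_id = sample_id, species = species, runs = runs,
                 total_depth_mass = sum(runs$depth * (runs$end - runs$start))),
            class = "ow_depth_track")
}

# ortholog pair of two identical (or given) single-exon sequences
make_simple_pair <- function(seq_a, seq_b = seq_a, pair_id = "p1",
                             strand_a = "+", strand_b = "+",
                             start_a = 1000, start_b = 5000) {
  em_a <- exon_model("ga", "chr1", strand_a,
                     cbind(start_a, start_a + nchar(seq_a)))
  em_b <- exon_model("gb", "chr2", strand_b,
                     cbind(start_b, start_b + nchar(seq_b)))
  ortholog_pair(pair_id, "ga", "gb", seq_a, seq_b, em_a, em_b,
                species_a = "spA", species_b = "spB")
}

# random multi-exon model with total transcript length L
random_exon_model_fixture <- function(gene_id, L, n_exons, strand = "+",
                                      chrom = "chr1", offset = 0) {
  k <- n_exons
  extra <- L - 10 * k
  stopifnot(extra >= 0)
  cuts <- sort(sample(0:extra, k - 1, replace = TRUE))
  lens <- 10 + diff(c(0, cuts, extra))
  introns <- if (k > 1) sample(50:500, k - 1, replace = TRUE) else integer(0)
  starts <- offset + cumsum(c(0, lens[-k] + introns))
  exon_model(gene_id, chrom, strand, cbind(starts, starts + lens))
}

# write a small aligned FASTA and return its path
write_aln_fasta <- function(rows, names = c("a", "b"),
                            path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", names), rows)), path)
  path
}
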