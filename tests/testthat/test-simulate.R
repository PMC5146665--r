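# the synthetic-data generator: determinism, divergence statistics, and
# internal consistency of the emitted files

test_that("zero divergence yields identical sequences and perfect windows", {
  cfg <- sim_config(n_genes = 3, substitution_rate = 0, indel_rate = 0,
                    seed = 2)
  sim <- simulate_ortholog_pair(cfg, 1)
  expect_equal(sim$pair$sequence_a, sim$pair$sequence_b)
  w <- window_alignment(sim$alignment, 25)
  expect_true(all(w$identity == 1))
  expect_true(all(w$n_gap_cols == 0))
})

test_that("mean window identity tracks the substitution divergence", {
  d <- 0.1
  cfg <- sim_config(n_genes = 1, substitution_rate = d, indel_rate = 0,
                    ancestor_length_range = c(10000, 10000), seed = 4)
  sim <- simulate_ortholog_pair(cfg, 1)
  w <- window_alignment(sim$alignment, 25)
  # per-column match probability: both unmutated, or both mutated and equal
  p_match <- (1 - d)^2 + d^2 / 3
  n_cols <- 25 * nrow(w)
  se <- sqrt(p_match * (1 - p_match) / n_cols)
  expect_lt(abs(mean(w$identity) - p_match), 3 * se)
})

test_that("the generator is deterministic and per-gene stable", {
  cfg <- sim_config(n_genes = 5, seed = 13)
  s1 <- simulate_ortholog_pair(cfg, 3)
  s2 <- simulate_ortholog_pair(cfg, 3)
  expect_identical(s1, s2)
  # gene 3 does not change when n_genes does
  cfg2 <- sim_config(n_genes = 50, seed = 13)
  s3 <- simulate_ortholog_pair(cfg2, 3)
  expect_identical(s1$pair$sequence_a, s3$pair$sequence_a)
  # different seeds give different sequences
  s4 <- simulate_ortholog_pair(sim_config(n_genes = 5, seed = 14), 3)
  expect_false(identical(s1$pair$sequence_a, s4$pair$sequence_a))
})

test_that("noise-free concordant coverage gives exactly proportional profiles", {
  cfg <- sim_config(n_genes = 4, substitution_rate = 0, indel_rate = 0,
                    noise_sigma_log = 0, fraction_discordant = 0,
                    bias_window_fraction = 0, seed = 6)
  sims <- lapply(1:4, function(i) simulate_ortholog_pair(cfg, i))
  ann <- build_annotation(lapply(sims, `[[`, "pair"),
                          lapply(sims, `[[`, "alignment"))
  truth <- simulate_truth(cfg)
  cov <- simulate_coverage(ann, truth, cfg)
  prof <- build_species_profiles(ann, cov$tracks)
  conc <- classify_genes(prof$profiles)
  expect_true(all(conc$decision == "retain"))
  expect_true(all(conc$pearson_r > 0.999999))
  expect_equal(nrow(conc), 4L)
})

test_that("simulated fragments all land inside their gene's windows", {
  cfg <- sim_config(n_genes = 5, seed = 8, fraction_discordant = 0,
                    bias_window_fraction = 0)
  sims <- lapply(1:5, function(i) simulate_ortholog_pair(cfg, i))
  ann <- build_annotation(lapply(sims, `[[`, "pair"),
                          lapply(sims, `[[`, "alignment"))
  truth <- simulate_truth(cfg)
  frags <- simulate_fragments(ann, truth, cfg)
  cm <- count_fragments(frags, ann,
                        setNames(sub("_rep\\d+$", "", names(frags)),
                                 names(frags)))
  expect_true(all(cm$tallies$ambiguous == 0))
  expect_true(all(cm$tallies$unassigned == 0))
  expect_equal(sum(cm$tallies$assigned),
               sum(vapply(frags, nrow, integer(1))))
})

test_that("fragment counts are Poisson-consistent with their mean", {
  cfg <- sim_config(n_genes = 1, seed = 10, fraction_discordant = 0,
                    gene_level_sigma_log = 0, noise_sigma_log = 0,
                    substitution_rate = 0, indel_rate = 0,
                    n_replicates = 30,
                    ancestor_length_range = c(1000, 1000))
  sim <- simulate_ortholog_pair(cfg, 1)
  ann <- build_annotation(list(sim$pair), list(sim$alignment))
  truth <- simulate_truth(cfg)
  frags <- simulate_fragments(ann, truth, cfg)
  lfc <- truth$true_log2fc[1]
  Lcomp <- sum(with(ann$segments, end - start)[ann$segments$species == "speciesB"])
  lambda <- cfg$depth_mean * Lcomp / cfg$fragment_length
  nb <- vapply(frags[grep("speciesB", names(frags))], nrow, integer(1))
  # 30 replicates: the mean count sits within 4 standard errors of lambda
  expect_lt(abs(mean(nb) - lambda), 4 * sqrt(lambda / 30))
})

test_that("fixture datasets are complete, consistent and byte-stable", {
  cfg <- sim_config(n_genes = 4, seed = 21, n_replicates = 2)
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  unlink(c(d1, d2), recursive = TRUE)
  f1 <- make_fixture_dataset(cfg, d1)
  f2 <- make_fixture_dataset(cfg, d2)
  rel <- function(d) sort(sub(paste0("^", d, "/?"), "", list.files(d, recursive = TRUE)))
  expect_equal(rel(d1), rel(d2))
  for (f in rel(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  # truth covers every gene; bias windows exist in the annotation
  truth <- read.table(file.path(d1, "truth.tsv"), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(truth), 4L)
  expect_setequal(f1$annotation$genes$pair_id,
                  intersect(truth$pair_id, f1$annotation$genes$pair_id))
  if (nrow(f1$bias_windows) > 0) {
    key_ann <- paste(f1$annotation$windows$pair_id,
                     f1$annotation$windows$window_index)
    expect_true(all(paste(f1$bias_windows$pair_id,
                          f1$bias_windows$window_index) %in% key_ann))
  }
  # the sample sheet points at readable files
  sheet <- read.table(file.path(d1, "samples.tsv"), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(sheet), 4L)  # 2 species x 2 replicates
  expect_true(all(file.exists(file.path(d1, sheet$bedgraph))))
  expect_true(all(file.exists(file.path(d1, sheet$bed))))
  # empty dataset is still schema-valid
  d0 <- file.path(tempdir(), "fix0")
  unlink(d0, recursive = TRUE)
  f0 <- make_fixture_dataset(sim_config(n_genes = 0, seed = 1), d0)
  expect_true(file.exists(file.path(d0, "pairs.tsv")))
  expect_equal(nrow(f0$annotation$genes), 0L)
})
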