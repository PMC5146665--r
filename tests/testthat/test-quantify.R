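# union-mode counting, TMM/CPM/FPKM, fold changes and validation statistics

# tiny two-gene annotation on one chromosome: gene p1 windows at
# [1000,1100), gene p2 windows at [1150,1250) in species spA; species spB
# mirrored on chr2
make_two_gene_annotation <- function() {
  s1 <- random_seq(100); s2 <- random_seq(100)
  em <- function(g, chrom, start) exon_model(g, chrom, "+",
                                             cbind(start, start + 100))
  p1 <- ortholog_pair("p1", "a1", "b1", s1, s1, em("a1", "chr1", 1000),
                      em("b1", "chr2", 1000), "spA", "spB")
  p2 <- ortholog_pair("p2", "a2", "b2", s2, s2, em("a2", "chr1", 1150),
                      em("b2", "chr2", 1150), "spA", "spB")
  build_annotation(list(p1, p2),
                   list(pairwise_alignment(s1, s1, "p1"),
                        pairwise_alignment(s2, s2, "p2")))
}

test_that("union-mode counting assigns, discards ambiguity, and conserves", {
  set.seed(30)
  ann <- make_two_gene_annotation()
  frags <- list(
    sA = data.frame(chrom = "chr1",
                    start = c(1010, 1090, 1300, 1160),
                    end = c(1110, 1160, 1400, 1200)),
    sB = data.frame(chrom = "chr2", start = 1000, end = 1050))
  cm <- count_fragments(frags, ann, c(sA = "spA", sB = "spB"))
  # frag 1 inside p1; frag 2 touches p1 and p2 -> ambiguous; frag 3 outside;
  # frag 4 inside p2
  expect_equal(cm$counts["p1", "sA"], 1L)
  expect_equal(cm$counts["p2", "sA"], 1L)
  expect_equal(cm$counts["p1", "sB"], 1L)
  t <- cm$tallies[cm$tallies$sample_id == "sA", ]
  expect_equal(t$assigned, 2L)
  expect_equal(t$ambiguous, 1L)
  expect_equal(t$unassigned, 1L)
  expect_equal(t$assigned + t$ambiguous + t$unassigned, 4L)
  # fragment on an unknown chromosome counts as unassigned, with warning
  frags2 <- list(sA = data.frame(chrom = "chrZ", start = 1, end = 50))
  expect_warning(cm2 <- count_fragments(frags2, ann, c(sA = "spA")),
                 "absent")
  expect_equal(sum(cm2$counts[, "sA"]), 0L)
})

test_that("fragments in excluded windows of a retained gene are not counted", {
  set.seed(31)
  ann <- make_two_gene_annotation()
  # drop window 1 (genomic [1025,1050) of p1/spA) as if it were an outlier
  keep <- !(ann$segments$pair_id == "p1" & ann$segments$window_index == 1)
  ann$segments <- ann$segments[keep, ]
  ann$windows <- ann$windows[!(ann$windows$pair_id == "p1" &
                                 ann$windows$window_index == 1), ]
  frags <- list(sA = data.frame(chrom = "chr1", start = c(1030, 1060),
                                end = c(1045, 1080)))
  cm <- count_fragments(frags, ann, c(sA = "spA"))
  expect_equal(cm$counts["p1", "sA"], 1L)  # only the window-2 fragment
  t <- cm$tallies
  expect_equal(t$unassigned, 1L)
})

test_that("TMM factors satisfy the exact identities", {
  set.seed(32)
  counts <- matrix(rpois(60, 50) + 1, nrow = 10,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  counts[, 2] <- counts[, 1]
  nf <- tmm_factors(counts, ref_sample = "s1")
  expect_equal(nf$tmm_factor[nf$sample_id == "s2"], 1)
  # doubling every count changes only the library size, not the factor
  counts[, 3] <- counts[, 1] * 2
  nf <- tmm_factors(counts, ref_sample = "s1")
  expect_equal(nf$tmm_factor[nf$sample_id == "s3"], 1)
  expect_equal(nf$tmm_factor[nf$sample_id == "s1"], 1)  # reference
  expect_true(all(nf$tmm_factor > 0))
  expect_equal(nf$effective_size, nf$lib_size * nf$tmm_factor)
})

test_that("TMM equals a step-by-step evaluation on a constructed matrix", {
  counts <- matrix(c(100, 200, 300, 50, 800, 40,
                     110, 180, 620, 60, 790, 45), nrow = 6,
                   dimnames = list(paste0("g", 1:6), c("ref", "s")))
  f <- tmm_factors(counts, ref_sample = "ref")
  expect_equal(f$tmm_factor[f$sample_id == "s"],
               tmm_oracle(counts, "s", "ref"))
  # and a larger random matrix, any trims
  set.seed(33)
  counts <- matrix(rpois(400, 80) + 1, nrow = 100,
                   dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  counts[, 3] <- rpois(100, counts[, 1] * 1.7)
  counts[counts == 0] <- 1
  f <- tmm_factors(counts, ref_sample = "s1")
  for (s in c("s2", "s3", "s4"))
    expect_equal(f$tmm_factor[f$sample_id == s],
                 tmm_oracle(counts, s, "s1"))
})

test_that("TMM agrees with edgeR's calcNormFactors up to its rescaling", {
  set.seed(34)
  counts <- matrix(rpois(600, 60) + 1, nrow = 100,
                   dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  counts[, 4] <- rpois(100, counts[, 1] * 2.5) + 1
  # same reference choice rule as edgeR's default
  uq <- apply(counts, 2, function(x) quantile(x, 0.75)) / colSums(counts)
  ref <- colnames(counts)[which.min(abs(uq - mean(uq)))]
  mine <- tmm_factors(counts, ref_sample = ref)
  ours <- setNames(mine$tmm_factor, mine$sample_id)
  theirs <- edgeR::calcNormFactors(counts, method = "TMM")
  # edgeR rescales factors to geometric mean 1; compare after matching that
  expect_equal(unname(ours / exp(mean(log(ours)))), unname(theirs),
               tolerance = 1e-10)
})

test_that("TMM symmetry: swapping sample and reference inverts the factor", {
  set.seed(35)
  counts <- matrix(rpois(200, 100) + 1, nrow = 100,
                   dimnames = list(paste0("g", 1:100), c("x", "y")))
  fx <- tmm_factors(counts, ref_sample = "x")$tmm_factor[2]
  fy <- tmm_factors(counts, ref_sample = "y")$tmm_factor[1]
  expect_equal(log2(fx), -log2(fy), tolerance = 1e-10)
})

test_that("CPM and FPKM follow their unit definitions", {
  counts <- matrix(c(5, 100), nrow = 2,
                   dimnames = list(c("gA", "gB"), "s1"))
  cm <- structure(list(counts = counts,
                       samples = data.frame(sample_id = "s1", species = "spA",
                                            stringsAsFactors = FALSE),
                       lengths = matrix(c(500, 1000, 500, 1000), nrow = 2,
                                        dimnames = list(c("gA", "gB"),
                                                        c("spA", "spB"))),
                       tallies = NULL), class = "ow_counts")
  nf <- data.frame(sample_id = "s1", lib_size = 105, tmm_factor = 1,
                   effective_size = 1e6)
  class(nf) <- c("ow_norm_factors", "data.frame")
  cc <- cpm(cm, nf)
  expect_equal(cc["gA", "s1"], 5)
  expect_equal(cc["gB", "s1"], 100)
  ff <- fpkm(cm, nf)
  expect_equal(ff["gB", "s1"], 100)        # 100 CPM over 1 kb
  expect_equal(ff["gA", "s1"], 10)         # 5 CPM over 0.5 kb
  # scale invariance: doubling counts and effective sizes leaves CPM fixed
  cm2 <- cm; cm2$counts <- cm$counts * 2
  nf2 <- nf; nf2$effective_size <- 2e6
  expect_equal(cpm(cm2, nf2), cc)
  # with unit factors CPM columns sum to 1e6
  counts3 <- matrix(rpois(30, 40) + 1, nrow = 10)
  expect_equal(unname(colSums(cpm(counts3))), rep(1e6, 3))
  nf_bad <- nf; nf_bad$effective_size <- 0
  expect_error(cpm(cm, nf_bad), "effective")
})

test_that("log2 fold change handles pseudocounts and zeros", {
  expect_equal(log2_fold_change(10, 10), 0)
  expect_equal(log2_fold_change(4000, 1000), 2, tolerance = 1e-3)
  expect_equal(log2_fold_change(0, 0), 0)
  expect_error(log2_fold_change(1, 1, pseudocount = 0), "pseudocount")
})

test_that("DE threshold calls use strict cutoffs", {
  rec <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                    log2fc = c(1.5, 1.0, -3, -1.2, 2),
                    adj_p = c(0.01, 0.04, 0.2, 0.03, NA),
                    stringsAsFactors = FALSE)
  expect_warning(res <- de_threshold_filter(rec), "skipped")
  expect_equal(res$up$gene_id, "g1")       # g2 fails the strict lfc > 1
  expect_equal(res$down$gene_id, "g4")     # g3 fails alpha
  expect_equal(unname(res$counts), c(1L, 1L, 2L, 1L))
})

test_that("Welch's t matches the textbook formulas", {
  r <- welch_t(c(1, 2, 3), c(4, 5, 6))
  o <- welch_textbook(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, o$t)
  expect_equal(r$df, o$df)
  expect_equal(r$p, o$p)
  set.seed(36)
  for (rep in 1:20) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), 1, 2)
    r <- welch_t(x, y); o <- welch_textbook(x, y)
    expect_equal(r$t, o$t); expect_equal(r$df, o$df); expect_equal(r$p, o$p)
  }
  r0 <- welch_t(c(1, 2, 3), c(1, 2, 3) + 0)
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
  expect_error(welch_t(c(2, 2), c(5, 5)), "zero variance")
})

test_that("method concordance reproduces the exact sign-test tail", {
  expect_equal(method_concordance(rep("+", 7),
                                  c(rep("+", 6), "-"))$one_sided_p, 0.0625)
  expect_equal(method_concordance(rep("+", 7), rep("+", 7))$one_sided_p,
               1 / 128)
  r <- method_concordance(rep("+", 4), rep("-", 4))
  expect_equal(r$k_concordant, 0)
  expect_equal(r$one_sided_p, 1)           # P(X >= 0) = 1
  expect_equal(method_concordance(c("+", "-", "+", "-"),
                                  c("+", "-", "-", "-"))$one_sided_p,
               enum_binom_p(3, 4, "greater"))
  expect_error(method_concordance("+", c("+", "-")), "length")
})
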