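# the per-gene concordance decision machinery

test_that("sign test equals exhaustive enumeration for all n <= 12 here", {
  for (n in 1:12) for (k in 0:n) {
    expect_equal(sign_test(k, n, "two_sided"), enum_binom_p(k, n, "two_sided"),
                 info = sprintf("k=%d n=%d", k, n))
    expect_equal(sign_test(k, n, "greater"), enum_binom_p(k, n, "greater"))
    expect_equal(sign_test(k, n, "less"), enum_binom_p(k, n, "less"))
  }
  expect_equal(sign_test(6, 7, "greater"), 0.0625)
  expect_equal(sign_test(10, 10, "two_sided"), 0.001953125)
  expect_equal(sign_test(5, 10, "two_sided"), 1)
  expect_error(sign_test(3, 0), "n must be")
  expect_error(sign_test(5, 4), "0 <= k <= n")
})

test_that("pearson_r matches the textbook formula and flags zero variance", {
  expect_equal(pearson_r(1:10, 1:10), 1)
  expect_equal(pearson_r(1:10, 5 * (1:10) + 2), 1)
  set.seed(9)
  for (rep in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(pearson_r(x, y), pearson_textbook(x, y))
  }
  expect_true(is.na(pearson_r(rep(1, 5), rnorm(5))))
  expect_error(pearson_r(1:4, 1:5), "length")
})

test_that("robust line fit recovers clean lines and resists gross outliers", {
  x <- 1:10
  fit <- robust_line_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-8)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
  expect_equal(fit$scaled_residuals, rep(0, 10))
  # on outlier-free noisy data rlm is close to least squares
  set.seed(10)
  x <- runif(50, 0, 10); y <- 3 * x + 2 + rnorm(50, 0, 0.4)
  fit <- robust_line_fit(x, y)
  ls <- coef(lm(y ~ x))
  expect_equal(fit$slope, unname(ls[2]), tolerance = 0.02)
  expect_equal(fit$intercept, unname(ls[1]), tolerance = 0.1)
  # one gross point barely moves the line and is flagged
  x <- c(1:9, 5); y <- c(1:9, 500)
  fit <- robust_line_fit(x, y)
  expect_lt(abs(fit$slope - 1), 0.1)
  expect_true(10 %in% flag_outliers(fit$scaled_residuals, 2.5))
  expect_error(robust_line_fit(rep(2, 5), 1:5), "zero variance")
})

test_that("outlier flagging uses a strict cutoff", {
  expect_equal(flag_outliers(rep(0, 5)), integer(0))
  r <- c(0.1, -0.2, 10, 0.3)
  expect_equal(flag_outliers(r, 2.5), 3L)
  expect_equal(flag_outliers(c(2.5, -2.5, 2.51), 2.5), 3L)
})

test_that("gene classification follows screen, rescue and outlier rules", {
  cfg <- filter_config()
  set.seed(15)
  # high-correlation gene: retained
  b <- rlnorm(20, 0, 1); a <- 2 * b * exp(rnorm(20, 0, 0.1))
  cl <- classify_gene(a, b, cfg)
  expect_equal(cl$decision, "retain")
  expect_gte(cl$pearson_r, 0.4)
  # uncorrelated but consistently higher in one species: rescued
  b <- rlnorm(15, 0, 1)
  repeat {
    a <- 2 * max(b) + rlnorm(15, 0, 1)
    if (pearson_r(b, a) < 0.4) break
  }
  cl <- classify_gene(a, b, cfg)
  expect_equal(cl$sign_k, 15)
  expect_lt(cl$sign_p, 0.001)
  expect_equal(cl$decision, "retain_rescued")
  expect_equal(cl$retained_windows, 0:14)   # rescue skips outlier removal
  # uncorrelated with balanced signs: excluded
  set.seed(16)
  repeat {
    a <- rlnorm(20, 0, 1); b <- rlnorm(20, 0, 1)
    if (pearson_r(b, a) < 0.4 &&
        sign_test(sum(a > b), sum(a != b), "two_sided") > 0.05) break
  }
  cl <- classify_gene(a, b, cfg)
  expect_equal(cl$decision, "excluded_low_r")
  expect_equal(cl$retained_windows, integer(0))
  # constant profile -> undefined r; balanced signs -> excluded
  cl <- classify_gene(rep(2, 10), rep(c(1, 3), 5), cfg)
  expect_true(is.na(cl$pearson_r))
  expect_equal(cl$decision, "excluded_low_r")
})

test_that("classification is invariant under positive rescaling", {
  set.seed(17)
  b <- rlnorm(30, 0, 1)
  a <- b * exp(rnorm(30, 0, 0.15))
  cfg <- filter_config()
  c0 <- classify_gene(a, b, cfg)
  c1 <- classify_gene(a * 1000, b, cfg)
  c2 <- classify_gene(a, b / 57, cfg)
  expect_equal(c1$decision, c0$decision)
  expect_equal(c2$decision, c0$decision)
  expect_equal(c1$retained_windows, c0$retained_windows)
  expect_equal(c2$retained_windows, c0$retained_windows)
  expect_equal(c1$pearson_r, c0$pearson_r)
})

test_that("shared-profile genes are retained, independent ones excluded", {
  # parameter-recovery property at the profile level, replicate-averaged
  set.seed(18)
  n_genes <- 220
  decide <- function(shared) {
    nw <- sample(24:60, 1)
    noise <- function() exp(rowMeans(matrix(rnorm(nw * 3, 0, 0.25), nw)))
    b <- rlnorm(nw, 0, 1) * noise()
    # shared-profile genes may additionally carry a species fold change;
    # independent profiles have no systematic offset
    a <- if (shared) b * noise() * 2^sample(c(-2, 0, 2), 1) else
      rlnorm(nw, 0, 1) * noise()
    classify_gene(a, b)$decision
  }
  shared <- replicate(n_genes, decide(TRUE))
  indep <- replicate(n_genes, decide(FALSE))
  expect_gte(mean(shared %in% c("retain", "retain_rescued")), 0.95)
  expect_gte(mean(grepl("excluded", indep)), 0.9)
})

test_that("finalization drops excluded genes and outlier windows pairwise", {
  set.seed(20)
  cfg <- sim_config(n_genes = 10, seed = 5, fraction_discordant = 0.3,
                    bias_window_fraction = 0.1)
  sims <- lapply(1:10, function(i) simulate_ortholog_pair(cfg, i))
  ann <- build_annotation(lapply(sims, `[[`, "pair"),
                          lapply(sims, `[[`, "alignment"))
  truth <- simulate_truth(cfg)
  cov <- simulate_coverage(ann, truth, cfg)
  prof <- build_species_profiles(ann, cov$tracks)
  conc <- classify_genes(prof$profiles)
  final <- finalize_annotation(ann, conc)
  dropped <- conc$pair_id[grepl("excluded", conc$decision)]
  expect_true(all(!final$genes$pair_id %in% dropped))
  expect_true(all(!final$segments$pair_id %in% dropped))
  for (g in final$genes$pair_id) {
    seg <- final$segments[final$segments$pair_id == g, ]
    wa <- sort(unique(seg$window_index[seg$species == "speciesA"]))
    wb <- sort(unique(seg$window_index[seg$species == "speciesB"]))
    expect_equal(wa, wb)
    out <- attr(conc, "outlier_windows")[[g]]
    if (conc$decision[conc$pair_id == g] == "retain")
      expect_true(all(!out %in% wa))
  }
  # every annotated gene needs a concordance row
  expect_error(finalize_annotation(ann, conc[-1, ]), "no concordance")
  # all-retain, no-outlier case leaves the annotation unchanged
  keep <- conc$decision == "retain" & conc$n_outliers == 0
  if (any(keep)) {
    g <- conc$pair_id[keep][1]
    expect_equal(sum(final$segments$pair_id == g),
                 sum(ann$segments$pair_id == g))
  }
})

test_that("concordance summaries tally bins and decisions", {
  set.seed(22)
  conc <- data.frame(pair_id = paste0("g", 1:50),
                     pearson_r = runif(50, -1, 1),
                     decision = sample(c("retain", "excluded_low_r"), 50,
                                       replace = TRUE),
                     stringsAsFactors = FALSE)
  s <- concordance_summary(conc, n_bins = 10)
  expect_equal(sum(s$histogram$count), 50L)
  direct <- sum(conc$pearson_r >= -1 & conc$pearson_r <= -0.8)
  expect_equal(s$histogram$count[1], direct)
  expect_equal(as.integer(s$decisions["retain"]),
               sum(conc$decision == "retain"))
  all_one <- data.frame(pair_id = "g", pearson_r = 1, decision = "retain")
  s1 <- concordance_summary(all_one, n_bins = 10)
  expect_equal(s1$histogram$count[10], 1L)
  expect_error(concordance_summary(conc[0, ]), "empty")
})
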