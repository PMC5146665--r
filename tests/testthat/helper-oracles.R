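# Independent oracles: small, slow, written from first principles so they
# share no code path with the package implementation.

# exact Binomial(n, 1/2) tail probabilities by full enumeration
enum_binom_p <- function(k, n, alternative = "two_sided") {
  probs <- choose(n, 0:n) / 2^n
  switch(alternative,
         greater = sum(probs[(0:n) >= k]),
         less = sum(probs[(0:n) <= k]),
         two_sided = min(1, 2 * min(sum(probs[(0:n) >= k]),
                                    sum(probs[(0:n) <= k]))))
}

# score a completed alignment (two gapped rows) under the package's gap
# convention: gap run of length L costs gap_open + (L-1)*gap_extend
score_alignment_rows <- function(ra, rb, match, mismatch, gap_open, gap_extend) {
  ca <- strsplit(ra, "")[[1]]; cb <- strsplit(rb, "")[[1]]
  s <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == "-" || cb[i] == "-") {
      # gap opening if the same row was not gapped in the previous column
      opens <- i == 1 ||
        (ca[i] == "-" && ca[i - 1] != "-") ||
        (cb[i] == "-" && cb[i - 1] != "-")
      s <- s + if (opens) gap_open else gap_extend
    } else if (ca[i] == cb[i] && ca[i] != "N") {
      s <- s + match
    } else {
      s <- s + mismatch
    }
  }
  s
}

# exhaustive alignment enumeration: best score over every global alignment
# (feasible only for very short sequences)
enum_align_score <- function(a, b, match = 2, mismatch = -3,
                             gap_open = -5, gap_extend = -2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ra, rb) {
    if (i > length(ca) && j > length(cb)) {
      s <- score_alignment_rows(ra, rb, match, mismatch, gap_open, gap_extend)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, paste0(ra, ca[i]), paste0(rb, cb[j]))
    if (i <= length(ca)) rec(i + 1, j, paste0(ra, ca[i]), paste0(rb, "-"))
    if (j <= length(cb)) rec(i, j + 1, paste0(ra, "-"), paste0(rb, cb[j]))
  }
  rec(1, 1, "", "")
  best
}

# plain-R three-matrix affine-gap DP, written independently of the C++
# implementation; returns the optimal global score
dp_align_score <- function(a, b, match = 2, mismatch = -3,
                           gap_open = -5, gap_extend = -2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); Up <- matrix(NEG, n + 1, m + 1)
  Le <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Up[i, 1] <- gap_open + (i - 2) * gap_extend
  for (j in 2:(m + 1)) Le[1, j] <- gap_open + (j - 2) * gap_extend
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      sub <- if (ca[i - 1] == cb[j - 1] && ca[i - 1] != "N") match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], Up[i - 1, j - 1], Le[i - 1, j - 1]) + sub
      Up[i, j] <- max(M[i - 1, j] + gap_open, Up[i - 1, j] + gap_extend,
                      Le[i - 1, j] + gap_open)
      Le[i, j] <- max(M[i, j - 1] + gap_open, Le[i, j - 1] + gap_extend,
                      Up[i, j - 1] + gap_open)
    }
  }
  max(M[n + 1, m + 1], Up[n + 1, m + 1], Le[n + 1, m + 1])
}

# textbook moment formula for the sample Pearson correlation
pearson_textbook <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# textbook Welch statistic, Welch-Satterthwaite df, two-sided p
welch_textbook <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# brute-force per-base mean depth of segments against a run-encoded track
perbase_mean_depth <- function(track, segments) {
  total <- 0; len <- 0
  for (i in seq_len(nrow(segments))) {
    for (pos in seq(segments$start[i], segments$end[i] - 1)) {
      r <- track$runs[track$runs$chrom == segments$chrom[i] &
                        track$runs$start <= pos & track$runs$end > pos, ]
      if (nrow(r) == 1) total <- total + r$depth
      len <- len + 1
    }
  }
  total / len
}

# spreadsheet-style TMM evaluation: explicit sorting instead of ranks,
# explicit per-step vectors
tmm_oracle <- function(counts, sample, ref, trim_m = 0.30, trim_a = 0.05) {
  y <- counts[, sample]; yr <- counts[, ref]
  N <- sum(counts[, sample]); Nr <- sum(counts[, ref])
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  M <- log2((y / N) / (yr / Nr))
  A <- 0.5 * log2((y / N) * (yr / Nr))
  w <- 1 / ((N - y) / (N * y) + (Nr - yr) / (Nr * yr))
  n <- length(M)
  keep_m <- keep_a <- rep(FALSE, n)
  lo <- floor(n * trim_m) + 1; hi <- n + 1 - lo
  keep_m[order(M)[seq(lo, hi)]] <- TRUE
  lo <- floor(n * trim_a) + 1; hi <- n + 1 - lo
  keep_a[order(A)[seq(lo, hi)]] <- TRUE
  sel <- keep_m & keep_a
  2^(sum(w[sel] * M[sel]) / sum(w[sel]))
}

# uniformly random nucleotide string
random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
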