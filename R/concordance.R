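## Per-gene interspecies coverage concordance: Pearson screen, exact sign
## test rescue, robust-line outlier removal, and the final annotation.

#' Sample Pearson correlation with a zero-variance flag
#'
#' @param x_vector,y_vector equal-length numeric vectors (length >= 3).
#' @return correlation, or \code{NA_real_} when either vector has zero
#'   variance (the "undefined" flag).
#' @export
pearson_r <- function(x_vector, y_vector) {
  if (length(x_vector) != length(y_vector))
    ow_stop_validation("pearson_r: vectors differ in length")
  if (length(x_vector) < 3L)
    ow_stop_validation("pearson_r: need at least 3 points")
  if (sd(x_vector) == 0 || sd(y_vector) == 0) return(NA_real_)
  cor(x_vector, y_vector)
}

#' Exact binomial sign test
#'
#' Tail probability of k successes out of n under Binomial(n, 1/2), via
#' \code{stats::binom.test}. For the symmetric p = 1/2 null the two-sided
#' p-value equals the doubled smaller tail, capped at 1.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of non-tied trials (>= 1).
#' @param alternative one of \code{"two_sided"}, \code{"greater"},
#'   \code{"less"}.
#' @return the exact p-value.
#' @examples
#' sign_test(6, 7, "greater")  # 0.0625
#' @export
sign_test <- function(k, n, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(n) != 1L || is.na(n) || n < 1L)
    ow_stop_validation("sign_test: n must be >= 1")
  if (is.na(k) || k < 0L || k > n)
    ow_stop_validation("sign_test: k must satisfy 0 <= k <= n")
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[alternative]
  unname(binom.test(round(k), round(n), p = 0.5, alternative = alt)$p.value)
}

#' Robust line fit (Huber M-estimator)
#'
#' Fits \code{y ~ x} with \code{MASS::rlm} (Huber psi, tuning constant
#' 1.345, iteratively reweighted up to 50 iterations). Residuals are scaled
#' by the MAD of the fit residuals (constant 1.4826); with that scale zero
#' (more than half the residuals exactly zero) the standard deviation is
#' used as a fallback, and an all-zero residual vector yields all-zero
#' scaled residuals.
#'
#' @param x_vector,y_vector equal-length numeric vectors (>= 3 points);
#'   \code{x} must have nonzero variance.
#' @return list with \code{slope}, \code{intercept},
#'   \code{scaled_residuals}.
#' @export
robust_line_fit <- function(x_vector, y_vector) {
  if (length(x_vector) != length(y_vector))
    ow_stop_validation("robust_line_fit: vectors differ in length")
  if (length(x_vector) < 3L)
    ow_stop_validation("robust_line_fit: need at least 3 points")
  if (sd(x_vector) == 0)
    ow_stop_validation("robust_line_fit: x has zero variance (degenerate fit)")
  fit <- suppressWarnings(
    MASS::rlm(x = cbind("(Intercept)" = 1, x = x_vector), y = y_vector,
              psi = MASS::psi.huber, k = 1.345, maxit = 50, acc = 1e-8))
  res <- as.numeric(y_vector - fit$fitted.values)
  # numerically exact fits leave residuals at floating-point noise; zero
  # them so the MAD scale does not amplify round-off into fake outliers
  res[abs(res) < 1e-8 * max(abs(y_vector), 1)] <- 0
  scale <- mad(res)                      # 1.4826 * median |res - med(res)|
  if (scale == 0) scale <- sd(res)
  scaled <- if (is.na(scale) || scale == 0) rep(0, length(res)) else res / scale
  list(slope = unname(coef(fit)["x"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       scaled_residuals = scaled)
}

#' Flag robust-fit outlier windows
#'
#' @param scaled_residuals residuals scaled as in [robust_line_fit()].
#' @param outlier_z cutoff; indices with \code{|scaled residual| >
#'   outlier_z} (strict) are flagged.
#' @return integer vector of flagged indices (1-based positions).
#' @export
flag_outliers <- function(scaled_residuals, outlier_z = 2.5) {
  which(abs(scaled_residuals) > outlier_z)
}

#' Concordance decision for one gene
#'
#' Implements the per-gene filter: (i) Pearson correlation of the two
#' species' normalized window profiles and a two-sided exact sign test on the
#' per-window comparison (ties dropped); (ii) genes with \code{r >= min_r}
#' are retained; genes with \code{r < min_r} (or undefined r) are rescued
#' when the sign test is significant (\code{sign_p < sign_alpha}, coverage
#' consistently higher in one species), else excluded; (iii) retained,
#' non-rescued genes get a robust line fit of profile a on profile b and
#' windows with \code{|scaled residual| > outlier_z} are dropped; rescued
#' genes keep all windows; (iv) a gene left with fewer than
#' \code{min_windows} windows is excluded as degenerate.
#'
#' @param profile_a,profile_b equal-length normalized window-depth vectors
#'   (species a and b).
#' @param config a [filter_config()].
#' @param window_index optional window ids parallel to the profiles
#'   (defaults to \code{0:(n-1)}).
#' @return list with \code{n_windows}, \code{pearson_r}, \code{sign_k},
#'   \code{sign_n}, \code{sign_p}, \code{slope}, \code{intercept},
#'   \code{outlier_windows}, \code{retained_windows}, \code{decision}
#'   (one of \code{retain}, \code{retain_rescued}, \code{excluded_low_r},
#'   \code{excluded_degenerate}).
#' @export
classify_gene <- function(profile_a, profile_b, config = filter_config(),
                          window_index = NULL) {
  n <- length(profile_a)
  if (length(profile_b) != n)
    ow_stop_validation("classify_gene: profiles differ in length")
  if (n < config$min_windows)
    ow_stop_validation("classify_gene: fewer windows than config$min_windows")
  if (is.null(window_index)) window_index <- seq_len(n) - 1L
  r <- pearson_r(profile_b, profile_a)
  nontie <- profile_a != profile_b
  sign_n <- sum(nontie)
  sign_k <- sum(profile_a > profile_b)
  sign_p <- if (sign_n == 0L) 1 else sign_test(sign_k, sign_n, "two_sided")
  base <- list(n_windows = n, pearson_r = r, sign_k = sign_k,
               sign_n = sign_n, sign_p = sign_p,
               slope = NA_real_, intercept = NA_real_,
               outlier_windows = integer(0))
  if (is.na(r) || r < config$min_r) {
    if (sign_p < config$sign_alpha) {
      # consistently one-sided coverage: keep the gene, skip outlier removal
      return(c(base, list(retained_windows = window_index,
                          decision = "retain_rescued")))
    }
    return(c(base, list(retained_windows = integer(0),
                        decision = "excluded_low_r")))
  }
  fit <- tryCatch(robust_line_fit(profile_b, profile_a),
                  error = function(e) NULL)
  if (is.null(fit))
    return(c(base, list(retained_windows = integer(0),
                        decision = "excluded_degenerate")))
  out_idx <- flag_outliers(fit$scaled_residuals, config$outlier_z)
  retained <- if (length(out_idx)) window_index[-out_idx] else window_index
  base$slope <- fit$slope; base$intercept <- fit$intercept
  base$outlier_windows <- window_index[out_idx]
  if (length(retained) < config$min_windows)
    return(c(base, list(retained_windows = integer(0),
                        decision = "excluded_degenerate")))
  c(base, list(retained_windows = retained, decision = "retain"))
}

#' Concordance decisions for all genes of a profile table
#'
#' @param profiles data.frame as produced by [build_species_profiles()]
#'   (\code{pair_id}, \code{window_index}, \code{a}, \code{b}).
#' @param config a [filter_config()].
#' @return Object of class \code{ow_concordance}: a data.frame with one row
#'   per gene (\code{pair_id}, \code{n_windows}, \code{pearson_r},
#'   \code{sign_k}, \code{sign_n}, \code{sign_p}, \code{slope},
#'   \code{intercept}, \code{n_outliers}, \code{decision}) and attributes
#'   \code{retained_windows} / \code{outlier_windows} (named lists of window
#'   indices).
#' @export
classify_genes <- function(profiles, config = filter_config()) {
  by_gene <- split(profiles, profiles$pair_id)
  ids <- names(by_gene)
  rows <- vector("list", length(ids))
  retained <- outliers <- setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    p <- by_gene[[i]]
    p <- p[order(p$window_index), , drop = FALSE]
    cl <- classify_gene(p$a, p$b, config, window_index = p$window_index)
    rows[[i]] <- data.frame(
      pair_id = ids[i], n_windows = cl$n_windows,
      pearson_r = cl$pearson_r, sign_k = cl$sign_k, sign_n = cl$sign_n,
      sign_p = cl$sign_p, slope = cl$slope, intercept = cl$intercept,
      n_outliers = length(cl$outlier_windows), decision = cl$decision,
      stringsAsFactors = FALSE)
    retained[[i]] <- cl$retained_windows
    outliers[[i]] <- cl$outlier_windows
  }
  out <- do.call(rbind, rows)
  attr(out, "retained_windows") <- retained
  attr(out, "outlier_windows") <- outliers
  class(out) <- c("ow_concordance", "data.frame")
  out
}

#' @export
print.ow_concordance <- function(x, ...) {
  tab <- table(x$decision)
  cat(sprintf("Gene concordance: %d gene(s)\n", nrow(x)))
  for (nm in names(tab)) cat(sprintf("  %-20s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Finalize the paired annotation after concordance filtering
#'
#' Drops excluded genes entirely and removes outlier windows from both
#' species, so the two final GTFs stay window-for-window paired.
#'
#' @param annotation an \code{ow_annotation}.
#' @param concordances an \code{ow_concordance} covering every annotated
#'   gene.
#' @return A filtered \code{ow_annotation}; the concordance table is carried
#'   in attribute \code{"concordance"}, and newly excluded genes are appended
#'   to \code{$excluded}.
#' @export
finalize_annotation <- function(annotation, concordances) {
  missing <- setdiff(annotation$genes$pair_id, concordances$pair_id)
  if (length(missing) > 0L)
    ow_stop_validation("no concordance for gene(s): ",
                       paste(missing, collapse = ", "))
  ret <- attr(concordances, "retained_windows")
  keep_key <- unlist(lapply(names(ret), function(g)
    if (length(ret[[g]])) paste(g, ret[[g]]) else character(0)))
  out <- annotation
  out$windows <- annotation$windows[
    paste(annotation$windows$pair_id, annotation$windows$window_index) %in%
      keep_key, , drop = FALSE]
  out$segments <- annotation$segments[
    paste(annotation$segments$pair_id, annotation$segments$window_index) %in%
      keep_key, , drop = FALSE]
  kept_genes <- unique(out$windows$pair_id)
  dropped <- setdiff(annotation$genes$pair_id, kept_genes)
  out$genes <- annotation$genes[annotation$genes$pair_id %in% kept_genes, ,
                                drop = FALSE]
  nw <- table(out$windows$pair_id)
  out$genes$n_windows <- as.integer(nw[out$genes$pair_id])
  if (length(dropped) > 0L) {
    m <- match(dropped, concordances$pair_id)
    out$excluded <- rbind(annotation$excluded,
                          data.frame(pair_id = dropped,
                                     reason = concordances$decision[m],
                                     stringsAsFactors = FALSE))
  }
  rownames(out$genes) <- NULL
  attr(out, "concordance") <- concordances
  out
}

#' Summarize concordance decisions and the correlation histogram
#'
#' @param concordances an \code{ow_concordance} (at least one gene).
#' @param n_bins number of equal-width bins over \code{[-1, 1]}.
#' @return list with \code{histogram} (data.frame \code{bin_lo},
#'   \code{bin_hi}, \code{count}; genes with undefined r are not binned) and
#'   \code{decisions} (named counts).
#' @export
concordance_summary <- function(concordances, n_bins = 20L) {
  if (nrow(concordances) == 0L)
    ow_stop_validation("concordance_summary: empty input")
  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  r <- concordances$pearson_r
  r <- r[!is.na(r)]
  counts <- if (length(r)) as.integer(
    table(cut(r, breaks = breaks, include.lowest = TRUE))) else
      integer(n_bins)
  list(histogram = data.frame(bin_lo = breaks[-length(breaks)],
                              bin_hi = breaks[-1L], count = counts),
       decisions = table(factor(concordances$decision,
                                levels = c("retain", "retain_rescued",
                                           "excluded_low_r",
                                           "excluded_degenerate"))))
}
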