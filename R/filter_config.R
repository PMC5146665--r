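#' Filtering configuration for comparable-region construction
#'
#' Bundles every tunable threshold of the annotation pipeline. Defaults follow
#' the published procedure: 25 bp alignment windows retained when identity is
#' strictly above 70% and the window holds strictly fewer than 3 gap columns;
#' genes excluded when the interspecies coverage correlation is below
#' \code{min_r = 0.4} unless the exact sign test is significant at
#' \code{sign_alpha = 0.001}; robust-fit outlier windows flagged at
#' \code{|scaled residual| > outlier_z = 2.5}.
#'
#' @param window_len window size in alignment columns (integer, >= 2).
#' @param min_identity minimum window identity, strict: a window passes only
#'   if \code{identity > min_identity}. Identity is \code{n_match / window_len},
#'   so gap columns count against it.
#' @param max_gap_cols gap allowance, strict: a window passes only if it has
#'   \code{< max_gap_cols} gap columns (default 3, i.e. at most 2 pass).
#' @param min_r Pearson screen: genes with interspecies coverage correlation
#'   \code{r < min_r} are excluded unless rescued by the sign test.
#' @param sign_alpha significance level of the per-gene exact sign test used
#'   to rescue low-correlation genes with consistently one-sided coverage.
#' @param outlier_z cutoff on \code{|residual / (1.4826 * MAD)|} from the
#'   robust line fit beyond which a window is dropped as an outlier.
#' @param min_windows minimum number of retained windows for a gene to be kept
#'   at all (a correlation over fewer points is meaningless).
#'
#' @return An object of class \code{ow_filter_config} (a validated list).
#' @examples
#' cfg <- filter_config()
#' cfg$window_len
#' @export
filter_config <- function(window_len = 25L, min_identity = 0.70,
                          max_gap_cols = 3L, min_r = 0.4,
                          sign_alpha = 0.001, outlier_z = 2.5,
                          min_windows = 4L) {
  window_len <- as.integer(window_len)
  max_gap_cols <- as.integer(max_gap_cols)
  min_windows <- as.integer(min_windows)
  if (is.na(window_len) || window_len < 2L)
    ow_stop_validation("window_len must be an integer >= 2")
  if (!is.finite(min_identity) || min_identity < 0 || min_identity > 1)
    ow_stop_validation("min_identity must be in [0, 1]")
  if (is.na(max_gap_cols) || max_gap_cols < 0L)
    ow_stop_validation("max_gap_cols must be a non-negative integer")
  for (nm in c("min_r", "sign_alpha", "outlier_z")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      ow_stop_validation(nm, " must be a finite number")
  }
  if (is.na(min_windows) || min_windows < 1L)
    ow_stop_validation("min_windows must be a positive integer")
  structure(list(window_len = window_len, min_identity = min_identity,
                 max_gap_cols = max_gap_cols, min_r = min_r,
                 sign_alpha = sign_alpha, outlier_z = outlier_z,
                 min_windows = min_windows),
            class = "ow_filter_config")
}

#' @export
print.ow_filter_config <- function(x, ...) {
  cat("Comparable-region filter configuration\n")
  cat(sprintf("  window length      : %d alignment columns\n", x$window_len))
  cat(sprintf("  window identity    : > %.2f (gap columns penalized)\n", x$min_identity))
  cat(sprintf("  window gap columns : < %d\n", x$max_gap_cols))
  cat(sprintf("  coverage screen    : exclude r < %.2f unless sign p < %g\n",
              x$min_r, x$sign_alpha))
  cat(sprintf("  outlier cutoff     : |scaled residual| > %.2f\n", x$outlier_z))
  cat(sprintf("  min windows / gene : %d\n", x$min_windows))
  invisible(x)
}
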