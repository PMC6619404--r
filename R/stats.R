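#' Tukey fence outlier mask
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`. Quartiles use linear
#' interpolation between order statistics (R's default quantile type 7);
#' this convention is fixed so that exclusions are reproducible.
#'
#' @param values Numeric vector with at least 4 finite values.
#' @param k Fence multiplier (default 1.5).
#' @return Logical inlier mask the length of `values` (`TRUE` = keep);
#'   non-finite entries are `NA`.
#' @examples
#' tukey_outliers(c(1, 2, 3, 4, 100))
#' @export
tukey_outliers <- function(values, k = 1.5) {
  finite <- is.finite(values)
  if (sum(finite) < 4)
    stop("need at least 4 finite values for Tukey fences", call. = FALSE)
  q <- stats::quantile(values[finite], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  mask <- values >= q[1] - k * iqr & values <= q[2] + k * iqr
  mask[!finite] <- NA
  mask
}

#' Fisher-z averaged functional connectivity
#'
#' Pearson correlation for every requested ROI pair, transformed with
#' Fisher's z (`atanh`), arithmetically averaged, and transformed back to
#' the correlation scale. With `set_b` given, pairs run across the two sets
#' (between-system FC); otherwise over all pairs within `set_a`
#' (within-system FC). A pair with `|r| = 1` has infinite z and raises an
#' error: it indicates degenerate (duplicated) input rather than a value to
#' clip.
#'
#' @param signal T x N numeric matrix with named columns, `T >= 3`.
#' @param set_a Column names or indices of the first ROI set (default: all).
#' @param set_b Optional second ROI set for between-system FC.
#' @return Mean functional connectivity on the correlation scale.
#' @export
mean_fc <- function(signal, set_a = NULL, set_b = NULL) {
  signal <- as.matrix(signal)
  if (nrow(signal) < 3) stop("need at least 3 volumes", call. = FALSE)
  if (any(apply(signal, 2, stats::sd) == 0))
    stop("constant signal column", call. = FALSE)
  if (is.null(set_a)) set_a <- seq_len(ncol(signal))
  r <- stats::cor(signal)
  if (is.null(set_b)) {
    sub <- r[set_a, set_a, drop = FALSE]
    rs <- sub[upper.tri(sub)]
  } else {
    rs <- as.vector(r[set_a, set_b, drop = FALSE])
  }
  if (length(rs) == 0) stop("no ROI pairs selected", call. = FALSE)
  if (any(abs(rs) >= 1))
    stop("a ROI pair is perfectly correlated (|r| = 1): Fisher z undefined; ",
         "check for duplicated channels", call. = FALSE)
  tanh(mean(atanh(rs)))
}

#' Efficiency-behavior correlation within a group
#'
#' Pearson correlation between per-participant efficiency scores and
#' behavioral scores, with the sample size actually used. Records with a
#' missing efficiency score are dropped; optionally, Tukey-fence outliers on
#' the efficiency score are excluded first.
#'
#' @param records Tibble/data frame with at least the efficiency and
#'   behavior columns; typically one row per participant.
#' @param efficiency,behavior Column names (default `"efficiency"`,
#'   `"behavior_score"`).
#' @param group Optional value to filter the `group` column on.
#' @param exclude_outliers Apply [tukey_outliers()] to the efficiency scores
#'   before correlating (default `FALSE`).
#' @return One-row tibble: `group`, `n`, `r`, `p_value`.
#' @export
efficiency_behavior_correlation <- function(records,
                                            efficiency = "efficiency",
                                            behavior = "behavior_score",
                                            group = NULL,
                                            exclude_outliers = FALSE) {
  df <- tibble::as_tibble(records)
  if (!is.null(group)) df <- df[df$group == group, , drop = FALSE]
  x <- df[[efficiency]]
  y <- df[[behavior]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (exclude_outliers) {
    inl <- tukey_outliers(x)
    x <- x[inl]; y <- y[inl]
  }
  if (length(x) < 4)
    stop("need at least 4 complete records", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate variance in scores", call. = FALSE)
  ct <- stats::cor.test(x, y)
  tibble::tibble(group = if (is.null(group)) NA_character_ else group,
                 n = length(x),
                 r = unname(ct$estimate),
                 p_value = ct$p.value)
}
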