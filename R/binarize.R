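#' Binary activity matrices
#'
#' A `binary_activity` object is a T x N matrix with entries in \{+1, -1\},
#' one row per volume and one column per ROI, carrying the participant id,
#' ROI names and the row indices at which pooled segments end (so that no
#' transition is ever counted across a concatenation boundary).
#'
#' @param values T x N matrix of +1/-1 entries.
#' @param roi_names Optional character vector of ROI labels.
#' @param participant_id Identifier string.
#' @param boundaries Integer vector of segment-final row indices; a boundary
#'   at row b means rows b and b + 1 belong to different participants. The
#'   final row is never listed.
#' @return A `binary_activity` matrix.
#' @export
binary_activity <- function(values, roi_names = colnames(values),
                            participant_id = NA_character_,
                            boundaries = integer()) {
  values <- as.matrix(values)
  if (!all(values %in% c(-1, 1)))
    stop("binary activity entries must be +1 or -1", call. = FALSE)
  if (ncol(values) < 1) stop("need at least one ROI", call. = FALSE)
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(ncol(values)))
  storage.mode(values) <- "double"
  colnames(values) <- roi_names
  boundaries <- sort(unique(as.integer(boundaries)))
  if (any(boundaries < 1 | boundaries >= nrow(values)))
    stop("boundaries must lie strictly inside the row range", call. = FALSE)
  structure(values,
            participant_id = as.character(participant_id),
            boundaries = boundaries,
            class = c("binary_activity", "matrix", "array"))
}

#' @export
print.binary_activity <- function(x, ...) {
  cat(sprintf("<binary_activity> %d volumes x %d ROIs (participant %s, %d boundaries)\n",
              nrow(x), ncol(x), attr(x, "participant_id"),
              length(attr(x, "boundaries"))))
  invisible(x)
}

segment_boundaries <- function(x) attr(x, "boundaries") %||% integer()

#' Binarize a continuous ROI time series at its per-ROI threshold
#'
#' Each ROI is declared active (+1) at volumes where its signal strictly
#' exceeds that ROI's own threshold and inactive (-1) otherwise. The default
#' threshold is the ROI's temporal mean for the participant, which leaves
#' roughly half the volumes active; quantile thresholds support robustness
#' checks over active fractions away from 0.5.
#'
#' @param signal T x N numeric matrix (or data frame) of continuous signals.
#' @param threshold `"mean"` (default) or a quantile in (0, 1) applied per
#'   ROI.
#' @param participant_id Identifier carried on the result.
#' @return A [binary_activity()] matrix. Values exactly at the threshold map
#'   to -1 (ties have measure zero for continuous signals).
#' @examples
#' binarize_participant(cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1)))
#' @export
binarize_participant <- function(signal, threshold = "mean",
                                 participant_id = NA_character_) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("signal must be numeric", call. = FALSE)
  if (anyNA(signal)) stop("signal contains missing values", call. = FALSE)
  const <- apply(signal, 2, function(col) diff(range(col)) == 0)
  if (any(const))
    stop("constant signal column(s): ",
         paste(which(const), collapse = ", "),
         " (threshold undefined)", call. = FALSE)
  if (identical(threshold, "mean")) {
    thr <- colMeans(signal)
  } else if (is.numeric(threshold) && length(threshold) == 1 &&
             threshold > 0 && threshold < 1) {
    thr <- apply(signal, 2, stats::quantile, probs = threshold, names = FALSE)
  } else {
    stop("`threshold` must be \"mean\" or a single quantile in (0, 1)",
         call. = FALSE)
  }
  values <- ifelse(sweep(signal, 2, thr, `-`) > 0, 1, -1)
  binary_activity(values, roi_names = colnames(signal),
                  participant_id = participant_id)
}

#' Pool binarized participants within a group
#'
#' Row-wise concatenation in the given order. Binarization thresholds are per
#' participant, so pooling after binarization is the intended order; the
#' segment boundaries are recorded so that downstream transition counting
#' never spans two participants.
#'
#' @param matrices List of [binary_activity()] matrices sharing ROI names and
#'   order.
#' @param group_id Identifier for the pooled matrix.
#' @return A [binary_activity()] with `sum(T_p)` rows and one boundary per
#'   internal participant junction.
#' @export
pool_group <- function(matrices, group_id = "group") {
  stopifnot(length(matrices) >= 1)
  if (length(matrices) == 1) return(matrices[[1]])
  rois <- lapply(matrices, colnames)
  if (!all(vapply(rois[-1], identical, logical(1), rois[[1]])))
    stop("all participants must share ROI names and ordering", call. = FALSE)
  lens <- vapply(matrices, nrow, integer(1))
  values <- do.call(rbind, lapply(matrices, unclass))
  inner <- cumsum(lens)[-length(lens)]
  old <- unlist(lapply(seq_along(matrices), function(i) {
    segment_boundaries(matrices[[i]]) + c(0L, cumsum(lens))[i]
  }))
  binary_activity(values, roi_names = rois[[1]], participant_id = group_id,
                  boundaries = sort(unique(c(inner, old))))
}

#' Empirical activity-pattern frequencies
#'
#' Counts how often each of the `2^N` activity patterns is realized and
#' normalizes by the number of volumes.
#'
#' @param matrix A [binary_activity()] matrix with `N <= 14` ROIs.
#' @return Numeric vector of length `2^N`, non-negative and summing to 1;
#'   element `k + 1` is the empirical probability of pattern index `k`.
#' @export
pattern_frequencies <- function(matrix) {
  n <- ncol(matrix)
  check_n_roi(n)
  idx <- pattern_index(unclass(matrix))
  as.vector(tabulate(idx + 1L, nbins = 2^n)) / nrow(matrix)
}

#' Tidy pattern-frequency table
#'
#' @param matrix A [binary_activity()] matrix.
#' @return A tibble with one row per pattern: `pattern` (bit-string, ROI 1
#'   leftmost, "1" = active), `index`, `count`, `probability`.
#' @export
pattern_frequency_table <- function(matrix) {
  n <- ncol(matrix)
  p <- pattern_frequencies(matrix)
  tibble::tibble(
    pattern = pattern_bitstring(0:(2^n - 1), n),
    index = 0:(2^n - 1),
    count = as.integer(round(p * nrow(matrix))),
    probability = p
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
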