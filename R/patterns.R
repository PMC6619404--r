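#' Activity-pattern indexing conventions
#'
#' An activity pattern over `n` ROIs is a vector in \{+1, -1\}^n. Patterns are
#' indexed by an integer `k` in `[0, 2^n)`: ROI 1 occupies the most significant
#' bit, and a set bit means the ROI is active (+1). Index 0 is therefore the
#' all-inactive pattern (s-) and index `2^n - 1` the all-active pattern (s+).
#'
#' @param n_roi Number of ROIs (channels). Enumeration-based operations are
#'   capped at `n_roi <= 14`.
#' @return `all_patterns()`: a `2^n_roi` x `n_roi` matrix of +1/-1 rows, row
#'   `k + 1` holding the pattern with index `k`.
#' @examples
#' all_patterns(2)
#' pattern_index(c(1, -1, 1))
#' pattern_state(5L, 3)
#' @export
all_patterns <- function(n_roi) {
  check_n_roi(n_roi)
  k <- 0:(2^n_roi - 1)
  bits <- vapply(seq_len(n_roi), function(i) k %/% 2^(n_roi - i) %% 2,
                 numeric(length(k)))
  m <- matrix(2 * bits - 1, nrow = length(k), ncol = n_roi)
  storage.mode(m) <- "double"
  m
}

#' @rdname all_patterns
#' @param state A +1/-1 vector, or a matrix with one pattern per row.
#' @return `pattern_index()`: integer index (vector) of the pattern(s).
#' @export
pattern_index <- function(state) {
  if (is.matrix(state)) {
    n <- ncol(state)
    check_n_roi(n)
    drop((state > 0) %*% 2^((n - 1):0))
  } else {
    n <- length(state)
    check_n_roi(n)
    sum((state > 0) * 2^((n - 1):0))
  }
}

#' @rdname all_patterns
#' @param k Pattern index in `[0, 2^n_roi)`.
#' @return `pattern_state()`: the +1/-1 vector for index `k`.
#' @export
pattern_state <- function(k, n_roi) {
  check_n_roi(n_roi)
  stopifnot(k >= 0, k < 2^n_roi)
  2 * (k %/% 2^((n_roi - 1):0) %% 2) - 1
}

#' @rdname all_patterns
#' @return `pattern_bitstring()`: character bit-string ("1" = active), ROI 1
#'   leftmost.
#' @export
pattern_bitstring <- function(k, n_roi) {
  vapply(k, function(ki) {
    paste(ki %/% 2^((n_roi - 1):0) %% 2, collapse = "")
  }, character(1))
}

#' Hamming-distance-1 neighbours of activity patterns
#'
#' Two patterns are adjacent when they agree on all ROIs except one, so every
#' pattern has exactly `n_roi` neighbours.
#'
#' @inheritParams all_patterns
#' @return `neighbor_table()`: a `2^n_roi` x `n_roi` integer matrix; row
#'   `k + 1`, column `i` holds the index of pattern `k` with ROI `i` flipped.
#' @examples
#' pattern_neighbors(7L, 3)        # neighbours of [1, 1, 1]
#' @export
neighbor_table <- function(n_roi) {
  check_n_roi(n_roi)
  k <- 0:(2^n_roi - 1)
  vapply(seq_len(n_roi), function(i) bitwXor(k, 2^(n_roi - i)),
         integer(length(k)))
}

#' @rdname neighbor_table
#' @param k Pattern index.
#' @return `pattern_neighbors()`: integer vector of the `n_roi` neighbour
#'   indices of pattern `k`.
#' @export
pattern_neighbors <- function(k, n_roi) {
  check_n_roi(n_roi)
  stopifnot(k >= 0, k < 2^n_roi)
  bitwXor(as.integer(k), as.integer(2^((n_roi - 1):0)))
}

check_n_roi <- function(n_roi, max_n = 14L) {
  if (length(n_roi) != 1 || is.na(n_roi) || n_roi != round(n_roi) || n_roi < 1)
    stop("`n_roi` must be a single positive integer", call. = FALSE)
  if (n_roi > max_n)
    stop("n_roi = ", n_roi, " exceeds the exact-enumeration capacity of ",
         max_n, " ROIs (2^n patterns must be enumerable)", call. = FALSE)
  invisible(as.integer(n_roi))
}
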