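state_categories <- c("s+", "s-", "b+", "b-", "b_other")

#' Per-volume state categories
#'
#' Classifies every volume of a binarized time series into one of five
#' categories: `s+` (the fully synchronized all-active pattern), `s-` (all
#' inactive), `b+` / `b-` (the attraction basin of `s+` / `s-`, excluding the
#' minimum itself), and `b_other` (any remaining basin). When the landscape
#' has only the two synchronized minima, `b_other` never occurs and the
#' taxonomy has four categories. `s+` and `s-` must both be local minima of
#' the supplied basin map; otherwise the taxonomy is undefined and an error
#' is raised.
#'
#' Basins are typically derived from the *group* landscape while the trace
#' being classified belongs to an individual.
#'
#' @param matrix A [binary_activity()] matrix for one participant (or a
#'   pooled group with recorded boundaries).
#' @param basin_map A [basins()] result over the same `N` ROIs.
#' @return An object of class `category_trace`: list with `labels` (factor
#'   over the five categories), `pattern_index`, `boundaries`,
#'   `participant_id` and `n_roi`.
#' @export
categorize <- function(matrix, basin_map) {
  n <- ncol(matrix)
  if (n != basin_map$n_roi)
    stop("basin map and activity matrix disagree on the number of ROIs",
         call. = FALSE)
  s_plus <- 2L^n - 1L
  s_minus <- 0L
  if (!(s_plus %in% basin_map$minima) || !(s_minus %in% basin_map$minima))
    stop("s+ and s- must both be local minima of the landscape; ",
         "the state taxonomy is undefined otherwise", call. = FALSE)
  idx <- pattern_index(unclass(matrix))
  basin_of <- basin_map$assignment[idx + 1L]
  labels <- dplyr::case_when(
    idx == s_plus ~ "s+",
    idx == s_minus ~ "s-",
    basin_of == s_plus ~ "b+",
    basin_of == s_minus ~ "b-",
    TRUE ~ "b_other"
  )
  category_trace(labels, boundaries = segment_boundaries(matrix),
                 participant_id = attr(matrix, "participant_id"),
                 pattern_index = idx, n_roi = n)
}

#' @rdname categorize
#' @param labels Character or factor vector over
#'   `c("s+", "s-", "b+", "b-", "b_other")`.
#' @param boundaries Segment-final indices across which no transition is
#'   counted.
#' @param participant_id Identifier.
#' @param pattern_index Optional per-volume pattern indices.
#' @param n_roi Optional ROI count.
#' @export
category_trace <- function(labels, boundaries = integer(),
                           participant_id = NA_character_,
                           pattern_index = NULL, n_roi = NA_integer_) {
  labels <- as.character(labels)
  if (!all(labels %in% state_categories))
    stop("labels must be among: ", paste(state_categories, collapse = ", "),
         call. = FALSE)
  boundaries <- sort(unique(as.integer(boundaries)))
  if (any(boundaries < 1 | boundaries >= length(labels)))
    stop("boundaries must lie strictly inside the trace", call. = FALSE)
  structure(list(labels = factor(labels, levels = state_categories),
                 pattern_index = pattern_index,
                 boundaries = boundaries,
                 participant_id = as.character(participant_id),
                 n_roi = n_roi),
            class = "category_trace")
}

#' @export
print.category_trace <- function(x, ...) {
  cat(sprintf("<category_trace> %d volumes (participant %s)\n",
              length(x$labels), x$participant_id))
  print(table(x$labels))
  invisible(x)
}

trace_segments <- function(trace) {
  labs <- as.character(trace$labels)
  starts <- c(1L, trace$boundaries + 1L)
  ends <- c(trace$boundaries, length(labs))
  lapply(seq_along(starts), function(i) labs[starts[i]:ends[i]])
}

#' Rate of direct transitions between the synchronized states
#'
#' Counts completed excursions: the number of times the activity leaves `s+`
#' and arrives at `s-` before revisiting `s+`, plus the reverse, divided by
#' the total number of volumes. Implemented as a last-synchronized-state
#' automaton: a transition is registered each time the synchronized pattern
#' visited differs from the previously visited one. The automaton resets at
#' pooling boundaries, so no excursion spans two participants.
#'
#' @param trace A [category_trace()].
#' @return Direct transition rate per volume (non-negative).
#' @export
direct_transition_rate <- function(trace) {
  direct_transition_count(trace) / length(trace$labels)
}

direct_transition_count <- function(trace) {
  count <- 0L
  for (labs in trace_segments(trace)) {
    last_sync <- ""
    for (lab in labs) {
      if (lab == "s+" || lab == "s-") {
        if (last_sync != "" && lab != last_sync) count <- count + 1L
        last_sync <- lab
      }
    }
  }
  count
}

#' Rates of basin-to-basin and peripheral transitions
#'
#' `basin_transition_rate()` counts consecutive-volume moves between `b+`
#' and `b-` (either direction), never across pooling boundaries, divided by
#' the total number of volumes. The `"excursion"` semantics instead counts
#' completed `b+`/`b-` excursions with the same last-visited automaton used
#' for the synchronized states; the consecutive reading is the default.
#'
#' `peripheral_rate()` is the basin transition rate minus the direct
#' synchronized transition rate: movement between the two basins that does
#' not pass through completing a synchronized excursion. Under the two
#' different counting semantics the difference can come out negative; it is
#' then floored at zero with a warning.
#'
#' @param trace A [category_trace()].
#' @param semantics `"consecutive"` (default) or `"excursion"` counting for
#'   basin-to-basin transitions.
#' @return A rate per volume.
#' @export
basin_transition_rate <- function(trace,
                                  semantics = c("consecutive", "excursion")) {
  semantics <- match.arg(semantics)
  count <- 0L
  for (labs in trace_segments(trace)) {
    if (semantics == "consecutive") {
      if (length(labs) < 2) next
      a <- labs[-length(labs)]
      b <- labs[-1]
      count <- count + sum((a == "b+" & b == "b-") | (a == "b-" & b == "b+"))
    } else {
      last_b <- ""
      for (lab in labs) {
        if (lab == "b+" || lab == "b-") {
          if (last_b != "" && lab != last_b) count <- count + 1L
          last_b <- lab
        }
      }
    }
  }
  count / length(trace$labels)
}

#' @rdname basin_transition_rate
#' @export
peripheral_rate <- function(trace,
                            semantics = c("consecutive", "excursion")) {
  rate <- basin_transition_rate(trace, semantics) -
    direct_transition_rate(trace)
  if (rate < 0) {
    warning("peripheral rate negative (basin rate below direct rate); ",
            "floored at 0", call. = FALSE)
    rate <- 0
  }
  rate
}

#' Per-individual transition summary and efficiency score
#'
#' The efficiency score is the ratio of the rate of transitions between the
#' synchronized states `s+` and `s-` to the rate of peripheral transitions:
#' how often the brain moves between its major activity patterns relative to
#' wandering between their basins. When the peripheral rate is zero the
#' score is undefined and reported as missing (`NA`), not infinity. The
#' summary also reports the fraction of volumes spent in `s+` or `s-`.
#'
#' @inheritParams basin_transition_rate
#' @return One-row tibble of class `transition_summary`: `participant_id`,
#'   `n_volumes`, `direct_rate`, `basin_rate`, `peripheral_rate`,
#'   `efficiency`, `sync_fraction`.
#' @export
efficiency_score <- function(trace,
                             semantics = c("consecutive", "excursion")) {
  semantics <- match.arg(semantics)
  direct <- direct_transition_rate(trace)
  basin <- basin_transition_rate(trace, semantics)
  peripheral <- max(0, basin - direct)
  if (basin - direct < 0)
    warning("peripheral rate negative (basin rate below direct rate); ",
            "floored at 0", call. = FALSE)
  out <- tibble::tibble(
    participant_id = trace$participant_id,
    n_volumes = length(trace$labels),
    direct_rate = direct,
    basin_rate = basin,
    peripheral_rate = peripheral,
    efficiency = if (peripheral > 0) direct / peripheral else NA_real_,
    sync_fraction = mean(trace$labels %in% c("s+", "s-"))
  )
  class(out) <- c("transition_summary", class(out))
  out
}

#' Conditional transition probabilities between state categories
#'
#' Entry (a, b) is the number of consecutive-volume moves from category `a`
#' to category `b` divided by the number of volumes in category `a` that
#' have a successor (the final volume of each pooled segment is excluded, as
#' are boundary-spanning pairs). Rows for categories never visited as an
#' origin are dropped, not zero-filled; defined rows sum to 1.
#'
#' @param trace A [category_trace()].
#' @return Matrix with category dimnames; rows = origin, columns =
#'   destination.
#' @export
conditional_transition_matrix <- function(trace) {
  counts <- matrix(0L, 5, 5, dimnames = list(state_categories,
                                             state_categories))
  for (labs in trace_segments(trace)) {
    if (length(labs) < 2) next
    a <- factor(labs[-length(labs)], levels = state_categories)
    b <- factor(labs[-1], levels = state_categories)
    counts <- counts + table(a, b)
  }
  from_n <- rowSums(counts)
  out <- counts[from_n > 0, , drop = FALSE] / from_n[from_n > 0]
  out
}

#' Metropolis-Hastings dynamics on the energy landscape
#'
#' Simulates a random walk over activity patterns: at each step one of the
#' `N` single-flip neighbours `V_k'` of the current pattern `V_k` is
#' proposed uniformly and accepted with probability
#' `q = min(1, exp(E(V_k) - E(V_k')))`; otherwise the chain stays. The
#' stationary distribution is the Boltzmann distribution of the landscape
#' (the acceptance rule satisfies detailed balance). The default start is
#' the all-active synchronized pattern `s+`.
#'
#' @param landscape An [energy_landscape()].
#' @param steps Number of steps (recorded volumes) to simulate.
#' @param seed Integer seed; the chain is deterministic given the seed.
#' @param start Starting pattern index (default `2^N - 1`, i.e. `s+`).
#' @return A [binary_activity()] matrix of the visited patterns with the
#'   per-volume pattern indices in attribute `"pattern_index"`.
#' @export
simulate_mh <- function(landscape, steps, seed, start = NULL) {
  stopifnot(steps >= 1)
  n <- landscape$n_roi
  e <- landscape$energies
  if (is.null(start)) start <- 2L^n - 1L
  stopifnot(start >= 0, start < 2^n)
  nb <- neighbor_table(n)
  set.seed(seed)
  proposals <- sample.int(n, steps, replace = TRUE)
  u <- stats::runif(steps)
  log_u <- log(u)
  idx <- integer(steps)
  cur <- as.integer(start) + 1L
  for (t in seq_len(steps)) {
    prop <- nb[cur, proposals[t]] + 1L
    if (log_u[t] < e[cur] - e[prop]) cur <- prop
    idx[t] <- cur
  }
  idx <- idx - 1L
  values <- all_patterns(n)[idx + 1L, , drop = FALSE]
  out <- binary_activity(values, roi_names = paste0("roi", seq_len(n)),
                         participant_id = sprintf("mh_seed%d", seed))
  attr(out, "pattern_index") <- idx
  out
}

#' Tidy a category trace
#'
#' @param x A [category_trace()].
#' @param ... Unused.
#' @return Tibble with `volume`, `pattern` (bit-string, if indices are
#'   recorded), `category`, `segment`.
#' @export
tidy.category_trace <- function(x, ...) {
  t_total <- length(x$labels)
  seg <- findInterval(seq_len(t_total) - 1L, c(0L, x$boundaries))
  out <- tibble::tibble(volume = seq_len(t_total),
                        category = as.character(x$labels),
                        segment = seg)
  if (!is.null(x$pattern_index) && !is.na(x$n_roi))
    out <- dplyr::mutate(out,
                         pattern = pattern_bitstring(x$pattern_index, x$n_roi),
                         .after = "volume")
  out
}

#' Plot the category occupancy of a trace over time
#'
#' @param object A [category_trace()].
#' @param ... Unused.
#' @return A ggplot object: category as a step function of volume, with
#'   pooling boundaries marked.
#' @export
autoplot.category_trace <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$volume,
                                        y = .data$category)) +
    ggplot2::geom_point(shape = 124, size = 2) +
    ggplot2::labs(x = "Volume", y = NULL) +
    ggplot2::theme_minimal()
  if (length(object$boundaries))
    p <- p + ggplot2::geom_vline(xintercept = object$boundaries + 0.5,
                                 linetype = "dashed", colour = "grey50")
  p
}
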