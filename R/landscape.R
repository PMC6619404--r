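#' Discrete energy landscape over activity patterns
#'
#' The landscape is the vector of energies of all `2^N` activity patterns
#' together with the Hamming-distance-1 adjacency convention: each pattern
#' has exactly `N` neighbours, obtained by flipping one ROI.
#'
#' @param x An `mem_parameters`/`mem_fit` object, or a numeric vector of
#'   `2^n_roi` energies.
#' @param n_roi Required when `x` is a raw energy vector.
#' @return An object of class `energy_landscape`: list with `energies`
#'   (length `2^N`) and `n_roi`.
#' @export
energy_landscape <- function(x, n_roi = NULL) {
  if (inherits(x, "mem_parameters")) {
    energies <- pattern_energies(x)
    n_roi <- x$n_roi
  } else {
    energies <- as.numeric(x)
    if (is.null(n_roi)) n_roi <- round(log2(length(energies)))
    if (length(energies) != 2^n_roi)
      stop("energy vector length must equal 2^n_roi", call. = FALSE)
  }
  check_n_roi(n_roi)
  if (!all(is.finite(energies)))
    stop("energies must be finite", call. = FALSE)
  structure(list(energies = energies, n_roi = as.integer(n_roi)),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("<energy_landscape> %d ROIs, %d patterns, energy range [%.3g, %.3g]\n",
              x$n_roi, 2^x$n_roi, min(x$energies), max(x$energies)))
  invisible(x)
}

#' Local minima of the energy landscape
#'
#' A local minimum (major activity pattern) has strictly lower energy than
#' all of its `N` single-flip neighbours; such patterns appear more often
#' than all their neighbours. Exact energy ties between adjacent patterns
#' make the landscape degenerate and raise an error: fitted real-valued
#' energies make ties a measure-zero event, so a tie signals a pathological
#' input rather than something to silently break.
#'
#' @param landscape An [energy_landscape()].
#' @return Integer vector of local-minimum pattern indices, ascending by
#'   energy.
#' @export
local_minima <- function(landscape) {
  e <- landscape$energies
  nb <- neighbor_table(landscape$n_roi)
  nbe <- matrix(e[nb + 1L], nrow = nrow(nb))
  if (any(nbe == e))
    stop("degenerate landscape: adjacent patterns with exactly equal energies",
         call. = FALSE)
  mins <- which(rowSums(nbe > e) == landscape$n_roi) - 1L
  mins[order(e[mins + 1L])]
}

#' Disconnectivity tree of the energy landscape
#'
#' For each pair of local minima the barrier is the lowest energy threshold
#' at which the two remain connected in the pattern-adjacency graph when all
#' patterns above the threshold are removed -- equivalently, the minimum over
#' all paths of the maximum energy en route (the saddle energy). The paper's
#' descending-threshold node-removal sweep is run here in reverse: patterns
#' are admitted in ascending energy order and components are merged
#' (union-find); the energy at which two minima's components first join is
#' exactly the largest threshold separating them in the descending sweep.
#'
#' @param landscape An [energy_landscape()]. An exact energy tie between two
#'   *adjacent* patterns is refused (see [local_minima()]); duplicated
#'   energies among non-adjacent patterns are harmless, since the minimax
#'   barrier value does not depend on the order in which equal-energy nodes
#'   are admitted.
#' @return An object of class `disconnectivity_tree`: list with `minima`
#'   (indices), `minima_energies`, `barriers` (M x M matrix, diagonal set to
#'   the minimum's own energy by convention), `merges` (tibble of
#'   agglomeration events: `energy`, `left`, `right`, each a list of minima
#'   indices) and `n_roi`.
#' @export
disconnectivity <- function(landscape) {
  e <- landscape$energies
  mins <- local_minima(landscape)
  m <- length(mins)
  n_pat <- length(e)
  nb <- neighbor_table(landscape$n_roi)
  barriers <- matrix(NA_real_, m, m)
  diag(barriers) <- e[mins + 1L]
  min_slot <- integer(n_pat)             # pattern index + 1 -> minima slot
  min_slot[mins + 1L] <- seq_len(m)

  parent <- seq_len(n_pat)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # minima contained in each component root
  members <- vector("list", n_pat)
  present <- logical(n_pat)
  merges <- list()

  for (k1 in order(e)) {                 # ascending energy
    present[k1] <- TRUE
    if (min_slot[k1] > 0) members[[k1]] <- min_slot[k1]
    for (nk in nb[k1, ] + 1L) {
      if (!present[nk]) next
      r1 <- find(k1); r2 <- find(nk)
      if (r1 == r2) next
      m1 <- members[[r1]]; m2 <- members[[r2]]
      if (length(m1) > 0 && length(m2) > 0) {
        barriers[m1, m2] <- e[k1]
        barriers[m2, m1] <- e[k1]
        merges[[length(merges) + 1L]] <-
          list(energy = e[k1], left = sort(m1), right = sort(m2))
      }
      parent[r2] <- r1
      members[[r1]] <- c(m1, m2)
      members[r2] <- list(NULL)
    }
  }
  merges <- if (length(merges)) {
    tibble::tibble(energy = vapply(merges, `[[`, numeric(1), "energy"),
                   left = lapply(merges, `[[`, "left"),
                   right = lapply(merges, `[[`, "right"))
  } else {
    tibble::tibble(energy = numeric(), left = list(), right = list())
  }
  structure(list(minima = mins, minima_energies = e[mins + 1L],
                 barriers = barriers, merges = merges,
                 n_roi = landscape$n_roi),
            class = "disconnectivity_tree")
}

#' @export
print.disconnectivity_tree <- function(x, ...) {
  cat(sprintf("<disconnectivity_tree> %d local minima over %d ROIs\n",
              length(x$minima), x$n_roi))
  cat("  minima:", paste(pattern_bitstring(x$minima, x$n_roi), collapse = " "),
      "\n")
  invisible(x)
}

#' Attraction basins by steepest descent
#'
#' From every pattern, repeatedly move to the lowest-energy neighbour until a
#' local minimum is reached; the starting pattern belongs to that minimum's
#' basin. A tie in the steepest-descent choice raises an error naming the
#' pattern. Descent strictly decreases energy, so memoizing in ascending
#' energy order resolves every pattern in one pass.
#'
#' @param landscape An [energy_landscape()].
#' @return An object of class `basin_map`: list with `assignment` (length
#'   `2^N` integer vector mapping pattern index + 1 to the pattern index of
#'   its basin minimum), `minima`, `sizes` (named by minimum bit-string) and
#'   `n_roi`.
#' @export
basins <- function(landscape) {
  e <- landscape$energies
  n <- landscape$n_roi
  mins <- local_minima(landscape)
  nb <- neighbor_table(n)
  assignment <- integer(length(e))
  assignment[mins + 1L] <- mins
  is_min <- logical(length(e))
  is_min[mins + 1L] <- TRUE
  for (k1 in order(e)) {
    if (is_min[k1]) next
    nbe <- e[nb[k1, ] + 1L]
    lowest <- which(nbe == min(nbe))
    if (length(lowest) > 1)
      stop("steepest-descent tie at pattern ",
           pattern_bitstring(k1 - 1L, n), call. = FALSE)
    assignment[k1] <- assignment[nb[k1, lowest] + 1L]
  }
  sizes <- table(factor(assignment, levels = mins))
  structure(list(assignment = assignment, minima = mins,
                 sizes = stats::setNames(as.integer(sizes),
                                         pattern_bitstring(mins, n)),
                 n_roi = n),
            class = "basin_map")
}

#' @export
print.basin_map <- function(x, ...) {
  cat(sprintf("<basin_map> %d basins over %d patterns\n",
              length(x$minima), length(x$assignment)))
  print(x$sizes)
  invisible(x)
}

#' Tidy basin map
#'
#' @param x A [basins()] result.
#' @param landscape Optional [energy_landscape()] to include energies.
#' @param ... Unused.
#' @return Tibble with `pattern`, `index`, `energy` (if available), `basin`
#'   (bit-string of the basin minimum).
#' @export
tidy.basin_map <- function(x, landscape = NULL, ...) {
  idx <- seq_along(x$assignment) - 1L
  out <- tibble::tibble(
    pattern = pattern_bitstring(idx, x$n_roi),
    index = idx,
    basin = pattern_bitstring(x$assignment, x$n_roi)
  )
  if (!is.null(landscape))
    out <- dplyr::mutate(out, energy = landscape$energies,
                         .after = "index")
  out
}

tree_nested <- function(tree) {
  # rebuild the nested hierarchy from agglomeration events (ascending energy)
  nodes <- lapply(seq_along(tree$minima), function(i) {
    list(level = tree$minima_energies[i],
         leaves = list(i),
         label = pattern_bitstring(tree$minima[i], tree$n_roi))
  })
  find_node <- function(slot) {
    for (j in seq_along(nodes))
      if (slot %in% unlist(nodes[[j]]$leaves)) return(j)
    stop("internal error: minima slot not found")
  }
  for (r in seq_len(nrow(tree$merges))) {
    i <- find_node(tree$merges$left[[r]][1])
    j <- find_node(tree$merges$right[[r]][1])
    merged <- list(level = tree$merges$energy[r],
                   leaves = c(nodes[[i]]$leaves, nodes[[j]]$leaves),
                   children = list(nodes[[i]], nodes[[j]]))
    nodes[[i]] <- merged
    nodes[[j]] <- NULL
  }
  if (length(nodes) != 1) stop("internal error: tree did not fully merge")
  nodes[[1]]
}

#' Export a disconnectivity tree
#'
#' `tree_newick()` renders the tree as a Newick string with branch lengths
#' equal to energy drops from the parent barrier level; leaf labels are
#' minimum bit-strings prefixed with "m". `write_tree_json()` writes the
#' nested node structure (fields `level`, `label`/`children`) as JSON.
#'
#' @param tree A [disconnectivity()] result.
#' @return `tree_newick()`: a single Newick string.
#' @export
tree_newick <- function(tree) {
  if (length(tree$minima) == 1)
    return(sprintf("m%s;", pattern_bitstring(tree$minima, tree$n_roi)))
  render <- function(node, parent_level) {
    len <- parent_level - node$level
    if (is.null(node$children))
      sprintf("m%s:%.10g", node$label, len)
    else
      sprintf("(%s,%s):%.10g",
              render(node$children[[1]], node$level),
              render(node$children[[2]], node$level),
              len)
  }
  root <- tree_nested(tree)
  sprintf("(%s,%s);",
          render(root$children[[1]], root$level),
          render(root$children[[2]], root$level))
}

#' @rdname tree_newick
#' @param path File path for the JSON export.
#' @export
write_tree_json <- function(tree, path) {
  strip <- function(node) {
    if (is.null(node$children))
      list(level = node$level, label = node$label)
    else
      list(level = node$level, children = lapply(node$children, strip))
  }
  jsonlite::write_json(strip(tree_nested(tree)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Plot a disconnectivity tree
#'
#' Vertical axis is energy; leaves sit at their minimum's energy and branches
#' join at the barrier energy separating the two subtrees. Leaves are ordered
#' by energy.
#'
#' @param object A [disconnectivity()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disconnectivity_tree <- function(object, ...) {
  segs <- list()
  labs <- list()
  place <- function(node, x0, x1, parent_level) {
    xm <- (x0 + x1) / 2
    if (is.null(node$children)) {
      segs[[length(segs) + 1L]] <<-
        tibble::tibble(x = xm, xend = xm, y = parent_level, yend = node$level)
      labs[[length(labs) + 1L]] <<-
        tibble::tibble(x = xm, y = node$level, label = node$label)
      return(xm)
    }
    n_left <- length(unlist(node$children[[1]]$leaves))
    n_right <- length(unlist(node$children[[2]]$leaves))
    xsplit <- x0 + (x1 - x0) * n_left / (n_left + n_right)
    xl <- place(node$children[[1]], x0, xsplit, node$level)
    xr <- place(node$children[[2]], xsplit, x1, node$level)
    segs[[length(segs) + 1L]] <<-
      tibble::tibble(x = xl, xend = xr, y = node$level, yend = node$level)
    if (is.finite(parent_level))
      segs[[length(segs) + 1L]] <<-
        tibble::tibble(x = xm, xend = xm, y = parent_level, yend = node$level)
    xm
  }
  root <- tree_nested(object)
  place(root, 0, 1, Inf)
  segs <- dplyr::bind_rows(segs)
  segs <- dplyr::filter(segs, is.finite(.data$y))
  labs <- dplyr::bind_rows(labs)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       vjust = 1.5, size = 3) +
    ggplot2::labs(x = NULL, y = "Energy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank(),
                   panel.grid.minor.x = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
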