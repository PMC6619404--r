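#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults follow the
#' method's stated values where they exist (learning rate 0.1, per-ROI
#' temporal-mean binarization threshold); the rest are documented package
#' choices.
#'
#' @param threshold Binarization rule passed to [binarize_participant()].
#' @param alpha Moment-matching learning rate.
#' @param tolerance Moment-mismatch convergence threshold.
#' @param max_iterations Fit iteration cap.
#' @param semantics Basin-transition counting semantics, see
#'   [basin_transition_rate()].
#' @param mh_steps Steps for the optional Metropolis-Hastings validation
#'   run (0 = skip).
#' @param seed Seed for the simulation stage.
#' @param exclude_outliers Apply Tukey fences to efficiency scores in the
#'   group summary.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold = "mean", alpha = 0.1,
                            tolerance = 1e-6, max_iterations = 1e5,
                            semantics = c("consecutive", "excursion"),
                            mh_steps = 0, seed = 1,
                            exclude_outliers = TRUE) {
  stopifnot(alpha > 0, tolerance > 0, max_iterations > 0, mh_steps >= 0)
  structure(list(threshold = threshold, alpha = alpha,
                 tolerance = tolerance, max_iterations = max_iterations,
                 semantics = match.arg(semantics),
                 mh_steps = mh_steps, seed = as.integer(seed),
                 exclude_outliers = isTRUE(exclude_outliers)),
            class = "pipeline_config")
}

#' Run the full energy-landscape analysis pipeline
#'
#' Stages: binarize each participant at their own per-ROI threshold; pool
#' participants within each group; fit the pairwise maximum-entropy model
#' per group; derive the group landscape, local minima and basins; classify
#' each participant's own trace against their group's basins; compute
#' per-participant transition summaries and efficiency scores; and attach
#' group-level summaries (mean efficiency, efficiency-behavior correlation,
#' within-system functional connectivity per participant). Dynamics are
#' always computed per individual against the group landscape.
#'
#' @param cohort A [generate_cohort()] result, or a list with elements
#'   `signals` (named list of T x N matrices) and `manifest` (tibble with
#'   `participant_id`, `group` and optionally `behavior_score`).
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, fit parameters
#'   (JSON), fit report, landscape trees (JSON + Newick), basin tables and
#'   participant/group result TSVs are written there.
#' @return An object of class `landscape_analysis`: list with `fits`,
#'   `diagnostics`, `landscapes`, `trees`, `basin_maps` (all per group),
#'   `participants` (tibble, one row per participant) and `groups`
#'   (summary tibble).
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- tibble::as_tibble(cohort$manifest)
  signals <- cohort$signals
  missing_ids <- setdiff(manifest$participant_id, names(signals))
  if (length(missing_ids))
    stop("stage load: no signals for participant(s) ",
         paste(missing_ids, collapse = ", "), call. = FALSE)

  stage <- function(what, who, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s (%s): %s", what, who, conditionMessage(e)),
           call. = FALSE)
    })
  }

  binarized <- lapply(stats::setNames(nm = manifest$participant_id),
                      function(id) {
    stage("binarize", id,
          binarize_participant(signals[[id]], threshold = config$threshold,
                               participant_id = id))
  })

  groups <- unique(manifest$group)
  fits <- list(); diagnostics <- list(); landscapes <- list()
  trees <- list(); basin_maps <- list()
  for (g in groups) {
    ids <- manifest$participant_id[manifest$group == g]
    pooled <- stage("pool", g, pool_group(binarized[ids], group_id = g))
    fit <- stage("fit", g,
                 fit_mem(pooled, alpha = config$alpha,
                         max_iterations = config$max_iterations,
                         tolerance = config$tolerance))
    emp <- pattern_frequencies(pooled)
    diagnostics[[g]] <- stage("fit", g, fit_accuracy(emp, fit))
    ls_g <- energy_landscape(fit)
    fits[[g]] <- fit
    landscapes[[g]] <- ls_g
    trees[[g]] <- stage("landscape", g, disconnectivity(ls_g))
    basin_maps[[g]] <- stage("landscape", g, basins(ls_g))
  }

  participants <- purrr::map_dfr(manifest$participant_id, function(id) {
    g <- manifest$group[manifest$participant_id == id]
    trace <- stage("dynamics", id, categorize(binarized[[id]], basin_maps[[g]]))
    summ <- withCallingHandlers(
      efficiency_score(trace, semantics = config$semantics),
      warning = function(w) invokeRestart("muffleWarning"))
    fc <- stage("stats", id, mean_fc(signals[[id]]))
    dplyr::mutate(summ, group = g, fc_within = fc, .after = "participant_id")
  })
  if ("behavior_score" %in% names(manifest))
    participants <- dplyr::left_join(
      participants,
      manifest[, c("participant_id", "behavior_score")],
      by = "participant_id")

  group_summary <- participants |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_efficiency = mean(.data$efficiency, na.rm = TRUE),
      mean_direct_rate = mean(.data$direct_rate),
      mean_peripheral_rate = mean(.data$peripheral_rate),
      mean_sync_fraction = mean(.data$sync_fraction),
      mean_fc_within = mean(.data$fc_within),
      rD = diagnostics[[.data$group[1]]]$rD,
      .groups = "drop")
  if ("behavior_score" %in% names(participants)) {
    corr <- purrr::map_dfr(groups, function(g) {
      tryCatch(
        efficiency_behavior_correlation(
          participants, group = g,
          exclude_outliers = config$exclude_outliers),
        error = function(e) tibble::tibble(group = g, n = NA_integer_,
                                           r = NA_real_, p_value = NA_real_))
    })
    group_summary <- dplyr::left_join(
      group_summary,
      dplyr::rename(corr, n_correlation = "n", efficiency_behavior_r = "r"),
      by = "group")
  }

  out <- structure(list(fits = fits, diagnostics = diagnostics,
                        landscapes = landscapes, trees = trees,
                        basin_maps = basin_maps,
                        participants = participants,
                        groups = group_summary,
                        config = config),
                   class = "landscape_analysis")
  if (!is.null(output_dir)) write_analysis(out, output_dir)
  out
}

write_analysis <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(x$fits)) {
    write_model_json(x$fits[[g]], file.path(dir, paste0("fit_", g, ".json")))
    write_tree_json(x$trees[[g]], file.path(dir, paste0("tree_", g, ".json")))
    writeLines(tree_newick(x$trees[[g]]),
               file.path(dir, paste0("tree_", g, ".nwk")))
    readr::write_tsv(tidy(x$basin_maps[[g]], landscape = x$landscapes[[g]]),
                     file.path(dir, paste0("basins_", g, ".tsv")))
  }
  report <- purrr::map_dfr(names(x$diagnostics), function(g) {
    d <- x$diagnostics[[g]]
    tibble::tibble(group = g, D1 = d$D1, D2 = d$D2, rD = d$rD,
                   iterations = x$fits[[g]]$iterations,
                   converged = x$fits[[g]]$converged)
  })
  readr::write_tsv(report, file.path(dir, "fit_report.tsv"))
  readr::write_tsv(x$participants, file.path(dir, "participants.tsv"))
  readr::write_tsv(x$groups, file.path(dir, "group_summary.tsv"))
  invisible(dir)
}

#' @export
print.landscape_analysis <- function(x, ...) {
  cat(sprintf("<landscape_analysis> %d groups, %d participants\n",
              length(x$fits), nrow(x$participants)))
  print(x$groups)
  invisible(x)
}

#' Glance at a pipeline result
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return The per-group summary tibble.
#' @export
glance.landscape_analysis <- function(x, ...) x$groups

#' Tidy a pipeline result
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return The per-participant results tibble.
#' @export
tidy.landscape_analysis <- function(x, ...) x$participants

#' @importFrom rlang .data
NULL
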