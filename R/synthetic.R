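#' Ground-truth pairwise model for synthetic data
#'
#' A known bias vector and coupling matrix used to generate exact Boltzmann
#' samples for parameter-recovery tests. Enumeration bounds the model at 14
#' ROIs.
#'
#' @param h Length-N bias vector.
#' @param J N x N symmetric zero-diagonal coupling matrix.
#' @return An object of classes `ground_truth_model` and `mem_parameters`.
#' @export
ground_truth_model <- function(h, J) {
  out <- mem_parameters(h, J)
  check_n_roi(out$n_roi)
  class(out) <- c("ground_truth_model", class(out))
  out
}

#' Exact samples from a pairwise maximum-entropy model
#'
#' Enumerates the full Boltzmann distribution over the `2^N` activity
#' patterns and draws i.i.d. rows from it with a categorical draw, so the
#' sample is exact by construction and independent of any Markov-chain
#' sampler under test.
#'
#' @param model A `ground_truth_model` (or any `mem_parameters`) with
#'   `n_roi <= 14`.
#' @param n_samples Number of rows to draw.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A [binary_activity()] matrix of `n_samples` rows.
#' @export
sample_ising_exact <- function(model, n_samples, seed) {
  check_n_roi(model$n_roi)
  stopifnot(n_samples >= 1)
  p <- model_distribution(model)
  set.seed(seed)
  idx <- sample.int(length(p), n_samples, replace = TRUE, prob = p) - 1L
  values <- all_patterns(model$n_roi)[idx + 1L, , drop = FALSE]
  binary_activity(values, roi_names = paste0("roi", seq_len(model$n_roi)),
                  participant_id = sprintf("ising_seed%d", seed))
}

#' Specification of a synthetic two-group cohort
#'
#' Describes a surrogate study: two groups of participants whose continuous
#' ROI signals follow a latent two-state (all-high / all-low) switching
#' process plus Gaussian noise, so that after mean-binarization the trace
#' alternates between the two fully synchronized patterns at a controllable
#' rate. The `group_effect` scales the log switching probability between
#' the groups (the "high-ease" group switches more), emulating a lower
#' energy barrier between the synchronized states. The noise has a shared
#' low-frequency component, identical in law for every participant, that
#' occasionally pulls the whole pattern towards the basin boundary and so
#' generates peripheral basin-to-basin wandering at an ease-independent
#' rate -- without it, binarized traces would jump between the synchronized
#' patterns in a single volume and the peripheral transition rate would
#' degenerate to zero. `behavior_coupling` is the population correlation
#' between a participant's standardized realized synchronized-transition
#' rate and their behavioral score.
#'
#' @param n_per_group Participants per group (default 28, the study-scale
#'   group size).
#' @param n_volumes Volumes per participant (default 262).
#' @param n_roi Channels (default 7; enumeration-friendly system size).
#' @param group_effect Non-negative scalar; the per-volume latent switch
#'   probability is `base_switch_rate * exp(+/- group_effect / 2)` for the
#'   high-/low-ease group.
#' @param behavior_coupling Correlation in `[-1, 1]` between standardized
#'   switch rate and behavioral score.
#' @param noise_sd Per-channel Gaussian noise sd around the +/-1 latent
#'   amplitude (default 0.8).
#' @param base_switch_rate Baseline per-volume latent switch probability
#'   (default 0.05).
#' @param participant_sd SD of per-participant log-normal variation in the
#'   switch probability (default 0.4), giving within-group individual
#'   differences for the behavior correlation to act on.
#' @param noise_ar Lag-one autocorrelation of the per-channel noise
#'   (default 0.3), emulating the temporal smoothness of band-passed
#'   signals.
#' @param common_sd,common_ar SD (default 0.7) and lag-one autocorrelation
#'   (default 0.4) of the shared low-frequency fluctuation added to every
#'   channel.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 28, n_volumes = 262, n_roi = 7,
                        group_effect = 1, behavior_coupling = 0.6,
                        noise_sd = 0.8, base_switch_rate = 0.05,
                        participant_sd = 0.4, noise_ar = 0.3,
                        common_sd = 0.7, common_ar = 0.4,
                        seed = 1) {
  stopifnot(n_per_group >= 2, n_volumes >= 10,
            behavior_coupling >= -1, behavior_coupling <= 1,
            noise_sd > 0, base_switch_rate > 0, base_switch_rate < 0.5,
            noise_ar >= 0, noise_ar < 1,
            common_sd >= 0, common_ar >= 0, common_ar < 1)
  check_n_roi(n_roi)
  structure(list(n_per_group = as.integer(n_per_group),
                 n_volumes = as.integer(n_volumes),
                 n_roi = as.integer(n_roi),
                 group_effect = group_effect,
                 behavior_coupling = behavior_coupling,
                 noise_sd = noise_sd,
                 base_switch_rate = base_switch_rate,
                 participant_sd = participant_sd,
                 noise_ar = noise_ar,
                 common_sd = common_sd,
                 common_ar = common_ar,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic two-group cohort
#'
#' For each participant, a latent state alternates between +1 (all channels
#' high) and -1 (all channels low) with the participant's switch
#' probability; every channel observes the latent state plus the shared
#' AR(1) fluctuation plus its own AR(1) noise. The realized
#' synchronized-transition rate is then measured on the mean-binarized
#' trace (completed alternations between the all-active and all-inactive
#' patterns per volume), and behavioral scores are its standardized value
#' scaled by `behavior_coupling` plus Gaussian noise with sd
#' `sqrt(1 - behavior_coupling^2)`, so the population correlation between
#' score and realized rate equals the coupling.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `signals` (named
#'   list of T x N matrices), `manifest` (tibble: `participant_id`, `group`,
#'   `behavior_score`, `sync_rate` -- the realized synchronized-transition
#'   rate -- and `switch_prob`) and `spec`. Groups are labeled
#'   `"high_ease"` and `"low_ease"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- c("high_ease", "low_ease")
  signs <- c(high_ease = 1, low_ease = -1)
  ar1 <- function(x, phi) {
    if (phi <= 0) return(x)
    as.numeric(stats::filter(x * sqrt(1 - phi^2), phi,
                             method = "recursive", init = x[1]))
  }
  rows <- list()
  signals <- list()
  for (g in groups) {
    p_group <- spec$base_switch_rate * exp(signs[[g]] * spec$group_effect / 2)
    for (i in seq_len(spec$n_per_group)) {
      id <- sprintf("%s_%02d", g, i)
      p_i <- min(0.4, max(1e-4,
        p_group * exp(stats::rnorm(1, 0, spec$participant_sd))))
      flips <- stats::runif(spec$n_volumes - 1) < p_i
      latent <- cumprod(c(sample(c(-1, 1), 1), ifelse(flips, -1, 1)))
      common <- ar1(stats::rnorm(spec$n_volumes, 0, spec$common_sd),
                    spec$common_ar)
      eps <- matrix(stats::rnorm(spec$n_volumes * spec$n_roi,
                                 0, spec$noise_sd),
                    spec$n_volumes, spec$n_roi)
      if (spec$noise_ar > 0)
        eps <- apply(eps, 2, ar1, phi = spec$noise_ar)
      sig <- latent + common + eps
      colnames(sig) <- paste0("roi", seq_len(spec$n_roi))
      signals[[id]] <- sig
      rows[[id]] <- tibble::tibble(participant_id = id, group = g,
                                   sync_rate = realized_sync_rate(sig),
                                   switch_prob = p_i)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  rho <- spec$behavior_coupling
  manifest <- manifest |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(behavior_score = rho * as.vector(scale(.data$sync_rate)) +
                    sqrt(1 - rho^2) * stats::rnorm(dplyr::n())) |>
    dplyr::ungroup()
  structure(list(signals = signals, manifest = manifest, spec = spec),
            class = "synthetic_cohort")
}

# completed alternations between the all-active and all-inactive patterns of
# the mean-binarized signal, per volume (no basin map needed)
realized_sync_rate <- function(sig) {
  b <- binarize_participant(sig)
  idx <- pattern_index(unclass(b))
  sync <- idx[idx == 0 | idx == 2^ncol(b) - 1]
  if (length(sync) < 2) return(0)
  sum(diff(sync) != 0) / nrow(b)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants x %d volumes x %d ROIs (seed %d)\n",
              length(x$signals), x$spec$n_volumes, x$spec$n_roi, x$spec$seed))
  invisible(x)
}

#' Write / read cohort artifacts
#'
#' `write_cohort()` writes one TSV per participant (columns = ROI names,
#' rows = volumes), a manifest TSV (`participant_id`, `group`,
#' `behavior_score`), and the generating spec as JSON. `read_timeseries()`
#' reads any same-shape TSV back as a numeric matrix.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()`: the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$signals)) {
    readr::write_tsv(tibble::as_tibble(cohort$signals[[id]]),
                     file.path(dir, paste0(id, ".tsv")))
  }
  readr::write_tsv(cohort$manifest, file.path(dir, "manifest.tsv"))
  jsonlite::write_json(unclass(cohort$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @param path Path to a participant TSV.
#' @return `read_timeseries()`: numeric matrix with ROI column names.
#' @export
read_timeseries <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  as.matrix(df)
}

#' Serialize model parameters as JSON
#'
#' Writes fields `h`, `J`, `n_roi` (and, for fits, `alpha`); readable back
#' with [read_model_json()].
#'
#' @param params An `mem_parameters` object.
#' @param path Output path.
#' @export
write_model_json <- function(params, path) {
  out <- list(h = params$h, J = params$J, n_roi = params$n_roi)
  if (!is.null(params$alpha)) out$alpha <- params$alpha
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mem_parameters(h = x$h, J = x$J)
}
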