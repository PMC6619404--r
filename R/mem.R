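#' Empirical first and second moments of binarized activity
#'
#' Computes the temporal mean of each ROI, `(1/T) sum_t sigma_i(t)`, and the
#' pairwise correlation matrix `(1/T) sum_t sigma_i(t) sigma_j(t)` that the
#' pairwise maximum-entropy model is fitted to.
#'
#' @param matrix A [binary_activity()] matrix (or any T x N +1/-1 matrix).
#' @return An object of class `empirical_moments`: list with `means`
#'   (length N), `correlations` (N x N, symmetric, unit diagonal) and
#'   `n_volumes`.
#' @export
empirical_moments <- function(matrix) {
  m <- unclass(as.matrix(matrix))
  if (!all(m %in% c(-1, 1))) stop("matrix must be +1/-1", call. = FALSE)
  structure(list(means = colMeans(m),
                 correlations = crossprod(m) / nrow(m),
                 n_volumes = nrow(m)),
            class = "empirical_moments")
}

#' Pairwise maximum-entropy (Ising) model parameters
#'
#' The model assigns each activity pattern `V_k` the energy
#' `E(V_k) = -sum_i h_i sigma_i - (1/2) sum_ij J_ij sigma_i sigma_j`
#' and the Boltzmann probability `P(V_k) = exp(-E(V_k)) / sum_l exp(-E(V_l))`.
#' `h_i` is the tendency of ROI `i` to be active in isolation; `J_ij` the
#' pairwise interaction strength. `J` is symmetric with zero diagonal.
#'
#' @param h Length-N bias vector.
#' @param J N x N symmetric coupling matrix with zero diagonal.
#' @return An object of class `mem_parameters`.
#' @export
mem_parameters <- function(h, J) {
  h <- as.numeric(h)
  J <- as.matrix(J)
  n <- length(h)
  if (!all(dim(J) == n)) stop("J must be N x N with N = length(h)", call. = FALSE)
  if (max(abs(J - t(J))) > 1e-10) stop("J must be symmetric", call. = FALSE)
  if (any(diag(J) != 0)) stop("J must have zero diagonal", call. = FALSE)
  structure(list(h = h, J = (J + t(J)) / 2, n_roi = n),
            class = "mem_parameters")
}

#' Pattern energies under a pairwise maximum-entropy model
#'
#' @param params An [mem_parameters()] object (fitted models also work).
#' @return Numeric vector of length `2^N`; element `k + 1` is `E(V_k)`.
#' @export
pattern_energies <- function(params) {
  n <- params$n_roi
  check_n_roi(n)
  P <- all_patterns(n)
  drop(-(P %*% params$h) - 0.5 * rowSums((P %*% params$J) * P))
}

#' Boltzmann distribution over all activity patterns
#'
#' Exact enumeration of `P(V_k) = exp(-E(V_k)) / Z`, computed in the log
#' domain so that parameter magnitudes up to about 50 do not overflow.
#'
#' @inheritParams pattern_energies
#' @return Probability vector of length `2^N` summing to 1.
#' @export
model_distribution <- function(params) {
  e <- -pattern_energies(params)
  e <- e - max(e)
  exp(e) / sum(exp(e))
}

model_moments <- function(P, p) {
  list(means = drop(crossprod(P, p)), correlations = crossprod(P, P * p))
}

#' Fit the pairwise maximum-entropy model by moment matching
#'
#' Iterates the gradient-descent updates
#' `h_i <- h_i + alpha * (<sigma_i>_data - <sigma_i>_model)` and
#' `J_ij <- J_ij + alpha * (<sigma_i sigma_j>_data - <sigma_i sigma_j>_model)`,
#' where the model moments are computed by exact enumeration, until the
#' largest absolute moment mismatch falls below `tolerance`. This is gradient
#' descent on the Kullback-Leibler divergence from the data distribution to
#' the model, so the moment mismatch is exactly the quantity the update
#' drives to zero.
#'
#' @param target An [empirical_moments()] object, or a [binary_activity()]
#'   matrix (moments are computed first).
#' @param alpha Learning rate (default 0.1).
#' @param max_iterations Iteration cap (default 1e5).
#' @param tolerance Convergence threshold on the max absolute difference
#'   between target and model moments (default 1e-6).
#' @return An object of classes `mem_fit` and `mem_parameters`: fields `h`,
#'   `J`, `n_roi`, plus `alpha`, `iterations`, `converged` and
#'   `max_mismatch`.
#' @export
fit_mem <- function(target, alpha = 0.1, max_iterations = 1e5,
                    tolerance = 1e-6) {
  if (inherits(target, "binary_activity") ||
      (is.matrix(target) && all(target %in% c(-1, 1))))
    target <- empirical_moments(target)
  stopifnot(inherits(target, "empirical_moments"), alpha > 0, tolerance > 0)
  m_t <- target$means
  C_t <- target$correlations
  n <- length(m_t)
  check_n_roi(n)
  if (any(abs(m_t) >= 1))
    stop("target means must lie strictly inside (-1, 1); a ROI that is ",
         "always active or always inactive is not fittable", call. = FALSE)
  off <- !diag(n)
  P <- all_patterns(n)
  h <- rep(0, n)
  J <- matrix(0, n, n)
  mismatch <- Inf
  iter <- 0L
  while (iter < max_iterations) {
    e <- P %*% h + 0.5 * rowSums((P %*% J) * P)  # -E
    e <- e - max(e)
    p <- exp(e)
    p <- p / sum(p)
    mm <- model_moments(P, drop(p))
    dh <- m_t - mm$means
    dJ <- C_t - mm$correlations
    mismatch <- max(max(abs(dh)), max(abs(dJ[off])))
    if (mismatch < tolerance) break
    iter <- iter + 1L
    h <- h + alpha * dh
    J <- J + alpha * dJ
    J <- (J + t(J)) / 2
    diag(J) <- 0
    if (!all(is.finite(h)) || !all(is.finite(J)))
      stop("fit diverged to non-finite parameters at iteration ", iter,
           call. = FALSE)
  }
  structure(list(h = h, J = J, n_roi = n, alpha = alpha,
                 iterations = iter, converged = mismatch < tolerance,
                 max_mismatch = mismatch),
            class = c("mem_fit", "mem_parameters"))
}

#' Closed-form independent (no-interaction) model
#'
#' The maximum-entropy model restricted to `J = 0` that matches the means:
#' for +1/-1 spins `<sigma_i> = tanh(h_i)`, so `h_i = atanh(<sigma_i>)`.
#' Used as the baseline for the accuracy-of-fit statistic.
#'
#' @param means Length-N vector of means in (-1, 1), or an
#'   `empirical_moments` object.
#' @return An `mem_parameters` object with `J = 0`.
#' @export
fit_independent <- function(means) {
  if (inherits(means, "empirical_moments")) means <- means$means
  if (any(abs(means) >= 1))
    stop("means must lie strictly inside (-1, 1)", call. = FALSE)
  n <- length(means)
  mem_parameters(h = atanh(means), J = matrix(0, n, n))
}

#' Accuracy of fit of the pairwise model
#'
#' Computes `rD = (D1 - D2) / D1`, where `D1` is the Kullback-Leibler
#' divergence (base-2) of the empirical pattern distribution from the
#' independent model (means matched, `J = 0`) and `D2` the divergence from
#' the fitted pairwise model. `rD = 1` when the pairwise model reproduces
#' the empirical distribution exactly; `rD = 0` when the interactions add
#' nothing over the independent model. Empirical cells with zero probability
#' contribute zero (the model has full support, so the reverse case cannot
#' occur).
#'
#' @param empirical Probability vector of length `2^N` (e.g. from
#'   [pattern_frequencies()]).
#' @param fitted An `mem_parameters`/`mem_fit` object.
#' @return An object of class `fit_diagnostics`: list with `D1`, `D2`, `rD`
#'   (all in bits).
#' @export
fit_accuracy <- function(empirical, fitted) {
  stopifnot(abs(sum(empirical) - 1) < 1e-8, all(empirical >= 0))
  n <- fitted$n_roi
  if (length(empirical) != 2^n)
    stop("empirical vector length must be 2^n_roi", call. = FALSE)
  P <- all_patterns(n)
  means <- drop(crossprod(P, empirical))
  indep <- fit_independent(means)
  D1 <- kl_bits(empirical, model_distribution(indep))
  D2 <- kl_bits(empirical, model_distribution(fitted))
  if (D1 <= 0) {
    if (D2 > 1e-12)
      stop("D1 = 0 with D2 > 0: accuracy of fit undefined", call. = FALSE)
    stop("D1 = 0: empirical distribution equals the independent model; ",
         "accuracy of fit undefined", call. = FALSE)
  }
  structure(list(D1 = D1, D2 = D2, rD = (D1 - D2) / D1),
            class = "fit_diagnostics")
}

kl_bits <- function(p, q) {
  pos <- p > 0
  sum(p[pos] * (log2(p[pos]) - log2(q[pos])))
}

#' @export
print.mem_fit <- function(x, ...) {
  cat(sprintf("<mem_fit> %d ROIs, alpha = %g, %d iterations, %s (max moment mismatch %.3g)\n",
              x$n_roi, x$alpha, x$iterations,
              if (x$converged) "converged" else "NOT converged",
              x$max_mismatch))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted pairwise maximum-entropy model
#'
#' @param x An `mem_fit` (or `mem_parameters`) object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term` ("h" or "J"), `roi_i`,
#'   `roi_j` (`NA` for biases), `estimate`.
#' @export
tidy.mem_parameters <- function(x, ...) {
  n <- x$n_roi
  ij <- which(upper.tri(x$J), arr.ind = TRUE)
  dplyr::bind_rows(
    tibble::tibble(term = "h", roi_i = seq_len(n), roi_j = NA_integer_,
                   estimate = x$h),
    tibble::tibble(term = "J", roi_i = ij[, 1], roi_j = ij[, 2],
                   estimate = x$J[ij])
  )
}

#' Glance at a fitted pairwise maximum-entropy model
#'
#' @param x An `mem_fit` object.
#' @param empirical Optional empirical pattern-probability vector; when
#'   supplied the accuracy-of-fit diagnostics are included.
#' @param ... Unused.
#' @return One-row tibble with `n_roi`, `alpha`, `iterations`, `converged`,
#'   `max_mismatch`, and (if `empirical` is given) `D1`, `D2`, `rD`.
#' @export
glance.mem_fit <- function(x, empirical = NULL, ...) {
  out <- tibble::tibble(n_roi = x$n_roi, alpha = x$alpha,
                        iterations = x$iterations, converged = x$converged,
                        max_mismatch = x$max_mismatch)
  if (!is.null(empirical)) {
    d <- fit_accuracy(empirical, x)
    out <- dplyr::mutate(out, D1 = d$D1, D2 = d$D2, rD = d$rD)
  }
  out
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("<fit_diagnostics> D1 = %.4g bits, D2 = %.4g bits, rD = %.4f\n",
              x$D1, x$D2, x$rD))
  invisible(x)
}
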