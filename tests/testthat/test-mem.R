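test_that("empirical moments are the stated temporal averages", {
  allp <- binary_activity(matrix(1, 3, 2, dimnames = list(NULL, c("a", "b"))))
  m <- empirical_moments(allp)
  expect_equal(m$means, c(a = 1, b = 1))
  expect_equal(unname(m$correlations), matrix(1, 2, 2))
  sync <- binary_activity(rbind(c(1, 1), c(-1, -1)),
                          roi_names = c("a", "b"))
  m2 <- empirical_moments(sync)
  expect_equal(unname(m2$means), c(0, 0))
  expect_equal(m2$correlations[1, 2], 1)
  anti <- binary_activity(rbind(c(1, -1), c(-1, 1)), roi_names = c("a", "b"))
  m3 <- empirical_moments(anti)
  expect_equal(unname(m3$means), c(0, 0))
  expect_equal(m3$correlations[1, 2], -1)
})

test_that("model distribution reproduces closed forms and enumeration oracles", {
  # h = 0, J = 0: uniform
  for (n in c(1, 3)) {
    p <- model_distribution(mem_parameters(rep(0, n), matrix(0, n, n)))
    expect_equal(p, rep(1 / 2^n, 2^n))
  }
  # N = 1 closed form
  a <- 0.7
  p1 <- model_distribution(mem_parameters(a, matrix(0, 1, 1)))
  expect_equal(p1[2], exp(a) / (exp(a) + exp(-a)))
  # N = 2 against the independent 4-state enumeration oracle
  for (j in c(0.5, 1, 2)) {
    p2 <- model_distribution(mem_parameters(c(0, 0),
                                            matrix(c(0, j, j, 0), 2)))
    expect_equal(p2, boltzmann2(0, 0, j), tolerance = 1e-12)
  }
  p3 <- model_distribution(mem_parameters(c(0.3, -0.2),
                                          matrix(c(0, 0.8, 0.8, 0), 2)))
  expect_equal(p3, boltzmann2(0.3, -0.2, 0.8), tolerance = 1e-12)
  # log-domain stability at large parameters
  big <- model_distribution(mem_parameters(c(50, -50), matrix(0, 2, 2)))
  expect_true(all(is.finite(big)))
  expect_equal(sum(big), 1)
})

test_that("model distributions are normalized to near machine precision", {
  set.seed(4)
  for (rep in 1:10) {
    gt <- toy_model(5, seed = rep, h_range = 2, j_range = 1)
    expect_lt(abs(sum(model_distribution(gt)) - 1), 1e-12)
  }
})

test_that("fitting uniform-distribution moments returns the zero model", {
  n <- 4
  target <- structure(list(means = rep(0, n),
                           correlations = diag(n),
                           n_volumes = NA),
                      class = "empirical_moments")
  fit <- fit_mem(target)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$h)), 1e-5)
  expect_lt(max(abs(fit$J)), 1e-5)
})

test_that("fitting the exact moments of a known model recovers its parameters", {
  gt <- toy_model(6, seed = 42)
  P <- all_patterns(6)
  p <- model_distribution(gt)
  target <- structure(list(means = drop(crossprod(P, p)),
                           correlations = crossprod(P, P * p),
                           n_volumes = NA),
                      class = "empirical_moments")
  fit <- fit_mem(target, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$h - gt$h)), 1e-5)
  expect_lt(max(abs(fit$J - gt$J)), 1e-5)
  # moment matching at convergence, the definition of success
  pfit <- model_distribution(fit)
  expect_lt(max(abs(drop(crossprod(P, pfit)) - target$means)), 1e-6)
  expect_lt(max(abs(crossprod(P, P * pfit) - target$correlations)[!diag(6)]),
            1e-6)
  expect_true(isSymmetric(fit$J))
  expect_equal(diag(fit$J), rep(0, 6))
})

test_that("fitting empirical moments of exact samples recovers couplings (N = 7)", {
  gt <- toy_model(7, seed = 3)
  samp <- sample_ising_exact(gt, 50000, seed = 11)
  fit <- fit_mem(samp, tolerance = 1e-6)
  expect_true(fit$converged)
  ut <- upper.tri(gt$J)
  expect_gt(cor(fit$J[ut], gt$J[ut]), 0.95)
})

test_that("more exact samples do not worsen coupling recovery", {
  gt <- toy_model(5, seed = 8)
  ut <- upper.tri(gt$J)
  err <- function(n_samp, seed) {
    fit <- fit_mem(sample_ising_exact(gt, n_samp, seed = seed),
                   tolerance = 1e-5)
    median(abs(fit$J[ut] - gt$J[ut]))
  }
  errs <- vapply(1:20, function(s) c(err(2000, s), err(4000, 1000 + s)),
                 numeric(2))
  expect_lte(median(errs[2, ]), median(errs[1, ]))
})

test_that("unattainable targets and divergence are reported as errors", {
  n <- 3
  target <- structure(list(means = c(1, 0, 0), correlations = diag(n),
                           n_volumes = NA),
                      class = "empirical_moments")
  expect_error(fit_mem(target), "strictly inside")
})

test_that("accuracy of fit matches the hand-enumerated KL decomposition", {
  # empirical distribution [0.4, 0.1, 0.1, 0.4] over (--, -+, +-, ++):
  # means are zero so the independent model is uniform, and
  # D1 = 0.8 log2(1.6) + 0.2 log2(0.4) by direct summation
  p_emp <- c(0.4, 0.1, 0.1, 0.4)
  d1_hand <- 0.8 * log2(1.6) + 0.2 * log2(0.4)
  P <- all_patterns(2)
  target <- structure(list(means = drop(crossprod(P, p_emp)),
                           correlations = crossprod(P, P * p_emp),
                           n_volumes = NA),
                      class = "empirical_moments")
  fit <- fit_mem(target)
  d <- fit_accuracy(p_emp, fit)
  expect_equal(d$D1, d1_hand, tolerance = 1e-10)
  expect_equal(d$D1, kl2_oracle(p_emp, rep(0.25, 4)), tolerance = 1e-12)
  expect_lt(abs(d$D2 - kl2_oracle(p_emp, model_distribution(fit))), 1e-10)
  # a 2-ROI pairwise model is saturated for symmetric distributions: rD ~ 1
  expect_gt(d$rD, 0.999)
  expect_true(d$D1 >= 0 && d$D2 >= 0 && d$D2 <= d$D1)
})

test_that("rD hits its anchors: 1 for a perfect model, 0 for a no-gain model", {
  # perfect pairwise model: fit a representable distribution exactly
  gt <- toy_model(3, seed = 2)
  p_emp <- model_distribution(gt)
  expect_equal(fit_accuracy(p_emp, gt)$rD, 1, tolerance = 1e-9)
  # interactions contribute nothing: sampled independent-model data,
  # pairwise model supplied as the independent fit itself
  indep <- ground_truth_model(h = c(0.4, -0.2, 0.1), J = matrix(0, 3, 3))
  samp <- sample_ising_exact(indep, 5000, seed = 21)
  p_samp <- pattern_frequencies(samp)
  means <- empirical_moments(samp)$means
  fit0 <- fit_independent(means)
  d <- fit_accuracy(p_samp, fit0)
  expect_gt(d$D1, 0)
  expect_equal(d$rD, 0)
})

test_that("degenerate D1 = 0 raises an explicit error", {
  indep <- mem_parameters(c(0.5, -0.5), matrix(0, 2, 2))
  p_emp <- model_distribution(indep)
  expect_error(fit_accuracy(p_emp, indep), "D1 = 0")
})

test_that("tidy and glance expose the fitted parameters and diagnostics", {
  gt <- toy_model(3, seed = 6)
  samp <- sample_ising_exact(gt, 2000, seed = 5)
  fit <- fit_mem(samp, tolerance = 1e-5)
  td <- tidy(fit)
  expect_equal(nrow(td), 3 + 3)
  expect_setequal(unique(td$term), c("h", "J"))
  gl <- glance(fit, empirical = pattern_frequencies(samp))
  expect_equal(nrow(gl), 1)
  expect_true(all(c("rD", "D1", "D2", "converged") %in% names(gl)))
  expect_true(gl$rD <= 1 + 1e-9)
})
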