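test_that("Gaussian mean log density matches hand-computed values", {
  one <- tibble::tibble(base = 5, aux = 5)
  r <- gaussian_fit_loglik(one, function(u) rep(1, length(u)))
  expect_equal(r$mean_log_density, -0.5 * log(2 * pi), tolerance = 1e-9)

  two <- tibble::tibble(base = 0, aux = 2)
  r2 <- gaussian_fit_loglik(two, function(u) rep(2, length(u)))
  expect_equal(r2$mean_log_density, log(1 / (2 * sqrt(2 * pi))) - 0.5,
               tolerance = 1e-9)

  # doubling sigma with aux == base costs exactly ln 2 per position
  pairs <- tibble::tibble(base = c(1, 5, 9), aux = c(1, 5, 9))
  a <- gaussian_fit_loglik(pairs, function(u) rep(1, length(u)))
  b <- gaussian_fit_loglik(pairs, function(u) rep(2, length(u)))
  expect_equal(a$mean_log_density - b$mean_log_density, log(2),
               tolerance = 1e-12)

  expect_error(gaussian_fit_loglik(pairs, function(u) u - 5), "positive")
})

test_that("sigma sources are accepted as curve, transform, or function", {
  pairs <- tibble::tibble(base = c(1, 2, 3), aux = c(2, 2, 4))
  curve <- analytic_curve(function(u) u + 1, mu_max = 10)
  by_curve <- gaussian_fit_loglik(pairs, curve)
  by_model <- gaussian_fit_loglik(pairs, log_transform(1))
  by_fn <- gaussian_fit_loglik(pairs, function(u) u + 1)
  expect_equal(by_curve$mean_log_density, by_fn$mean_log_density,
               tolerance = 1e-6)
  expect_equal(by_model$mean_log_density, by_fn$mean_log_density,
               tolerance = 1e-6)
  expect_match(by_model$sigma_source, "log_offset")
})

test_that("variance instability is zero for perfect replicates", {
  x <- withr::with_seed(2, rnorm(300))
  rep_pairs <- tibble::tibble(base = x, aux = x)
  r <- variance_instability(rep_pairs, bin_size = 50)
  expect_equal(r$score, 0)
  expect_equal(r$B, 6L)
})

test_that("instability matches the worked example and the oracle", {
  pairs <- tibble::tibble(base = c(1, 2, 3, 4), aux = c(1, 2, 5, 8))
  r <- variance_instability(pairs, bin_size = 2)
  # v = (0, 20); population variances: var(v) = 100, sigma1^2 = 1.25,
  # sigma2^2 = 7.5 -> 100 / 9.375
  expect_equal(r$v, c(0, 20))
  expect_equal(r$sigma1^2, 1.25)
  expect_equal(r$sigma2^2, 7.5)
  expect_equal(r$score, 100 / (1.25 * 7.5), tolerance = 1e-12)
  expect_equal(r$score, oracle_instability(pairs$base, pairs$aux, 2),
               tolerance = 1e-12)
})

test_that("instability is exactly invariant under joint rescaling", {
  pairs <- random_pairs(400, seed = 6)
  r1 <- variance_instability(pairs, bin_size = 40)
  r7 <- variance_instability(dplyr::mutate(pairs, base = 7 * base,
                                           aux = 7 * aux),
                             bin_size = 40)
  expect_equal(r1$score, r7$score, tolerance = 1e-12)
})

test_that("per-position variant rescales v by the bin size", {
  pairs <- random_pairs(300, seed = 8)
  rs <- variance_instability(pairs, bin_size = 30)
  rm <- variance_instability(pairs, bin_size = 30, per_position = TRUE)
  expect_equal(rm$v, rs$v / 30)
  expect_equal(rm$score, rs$score / 30^2, tolerance = 1e-12)
})

test_that("short inputs and remainders are handled", {
  pairs <- tibble::tibble(base = 1:30, aux = 1:30)
  expect_error(variance_instability(pairs, bin_size = 20), "2 full bins")
  # n = 30, b = 9 -> 3 bins, 3 positions discarded
  r <- variance_instability(tibble::tibble(base = 1:30,
                                           aux = c(2:30, 40)),
                            bin_size = 9)
  expect_equal(r$B, 3L)
  expect_equal(r$score,
               oracle_instability(1:30, c(2:30, 40), 9), tolerance = 1e-12)
})

test_that("glance and tidy summarize the report", {
  pairs <- random_pairs(200, seed = 3)
  r <- variance_instability(pairs, bin_size = 25)
  g <- glance(r)
  expect_equal(g$score, r$score)
  expect_equal(nrow(tidy(r)), r$B)
})

test_that("the diagnostic scatter reflects the noise law's shape", {
  sim <- simulate_replicates(n_positions = 4e4, chroms = "chr21",
                             zero_fraction = 0, peak_fraction = 0,
                             meanlog = log(20), sdlog = 0.8,
                             noise = "poisson", seed = 10)
  pairs <- build_base_aux(sim$replicates)
  diag <- mean_variance_diagnostic(pairs, bin_size = 2e3)
  # Poisson noise: the replicate-pair SD grows like sqrt(mean) (log-log
  # slope near 0.5, clearly between constant-variance 0 and linear 1)
  slope <- function(d) {
    unname(coef(stats::lm(log(sigma) ~ log(mu), data = d))[2])
  }
  expect_gt(slope(diag[diag$mu > 1, ]), 0.35)
  expect_lt(slope(diag[diag$mu > 1, ]), 0.75)

  # after the matching variance-stabilizing transform (2 * sqrt(x) for
  # Poisson), the SD column flattens: slope near 0
  stab <- tibble::tibble(base = 2 * sqrt(pairs$base), aux = 2 * sqrt(pairs$aux))
  sdiag <- mean_variance_diagnostic(stab, bin_size = 2e3)
  expect_lt(abs(slope(sdiag[sdiag$mu > 0.5, ])), 0.25)
  expect_lt(slope(sdiag[sdiag$mu > 0.5, ]) + 0.3, slope(diag[diag$mu > 1, ]))

  # constant signal degenerates to a single bin with zero SD
  const <- tibble::tibble(base = rep(3, 100), aux = rep(3, 100))
  expect_warning(d0 <- mean_variance_diagnostic(const, bin_size = 1e3))
  expect_equal(nrow(d0), 1L)
  expect_equal(d0$sigma, 0)
})
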