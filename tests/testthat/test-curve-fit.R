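make_stats <- function(mu, sigma, count = 1000L, zero = NULL) {
  st <- tibble::tibble(bin = seq_along(mu), mu = mu, sigma2 = sigma^2,
                       sigma = sigma, count = as.integer(count),
                       is_zero_bin = FALSE,
                       smoothed_sigma2 = sigma^2, smoothed_sigma = sigma)
  if (!is.null(zero)) {
    zrow <- tibble::tibble(bin = 0L, mu = zero[1], sigma2 = zero[2]^2,
                           sigma = zero[2], count = as.integer(count),
                           is_zero_bin = TRUE,
                           smoothed_sigma2 = zero[2]^2,
                           smoothed_sigma = zero[2])
    st <- dplyr::bind_rows(zrow, st)
  }
  st
}

test_that("exact linear bin points are recovered within 1%", {
  mu <- seq(0, 100, length.out = 60)
  st <- make_stats(mu, mu + 1)
  curve <- fit_sigma_curve(st)
  u <- seq(2, 98, length.out = 200)
  rel <- abs(predict(curve, u) - (u + 1)) / (u + 1)
  expect_lt(max(rel), 0.01)
})

test_that("constant bin SDs give a constant curve", {
  st <- make_stats(seq(1, 50, length.out = 30), rep(3, 30))
  curve <- fit_sigma_curve(st)
  u <- seq(1, 50, length.out = 100)
  expect_equal(predict(curve, u), rep(3, 100), tolerance = 1e-6)
})

test_that("evaluation is clamped at the sigma floor", {
  # descending SDs crossing zero force the spline below the floor
  mu <- seq(1, 20, length.out = 20)
  sigma <- pmax(10 - mu, 0.001)
  st <- make_stats(mu, sigma)
  curve <- fit_sigma_curve(st, spar = 0.3)
  u <- seq(1, 20, length.out = 500)
  raw <- trackvst:::raw_curve_values(curve, u)
  expect_true(any(raw < curve$sigma_floor))       # the clamp has work to do
  expect_true(all(predict(curve, u) >= curve$sigma_floor))
  expect_gt(curve$clamp_activations, 0)
})

test_that("extrapolation is constant outside the fitted range", {
  st <- make_stats(seq(10, 50, length.out = 20),
                   seq(10, 50, length.out = 20) / 5)
  curve <- fit_sigma_curve(st)
  expect_equal(predict(curve, c(-5, 0, 9)), rep(predict(curve, 10), 3))
  expect_equal(predict(curve, c(51, 500)), rep(predict(curve, 50), 2))
})

test_that("too few distinct means is an error naming the minimum", {
  st <- make_stats(c(1, 2, 3), c(1, 1, 1))
  expect_error(fit_sigma_curve(st), "4")
})

test_that("spar override and zero-bin point are honored", {
  st <- make_stats(seq(5, 50, length.out = 20),
                   sqrt(seq(5, 50, length.out = 20)),
                   zero = c(0.5, 0.2))
  curve <- fit_sigma_curve(st, spar = 0.7)
  expect_equal(curve$spar, 0.7)
  expect_equal(curve$mu_min, 0.5)      # domain starts at the zero-bin mean
  expect_equal(curve$zero_bin$mu0, 0.5)
  expect_equal(curve$zero_bin$sigma0, 0.2)
  # the zero-bin point pulls the left end of the curve down toward sigma0
  no_zero <- fit_sigma_curve(make_stats(seq(5, 50, length.out = 20),
                                        sqrt(seq(5, 50, length.out = 20))),
                             spar = 0.7)
  expect_lt(predict(curve, 0.5), predict(no_zero, 5))
})

test_that("clamp never activates on well-separated data", {
  sim <- simulate_replicates(n_positions = 3e4, chroms = "chr22", seed = 5)
  fit <- train_vst(sim$replicates, b = 1000, beta = 1000)
  expect_equal(fit$info$clamp_activations, 0L)
})

test_that("hyperparameter selection returns the argmax of the grid", {
  sim <- simulate_replicates(n_positions = 2e4, seed = 9)
  grid <- tibble::tibble(b = c(500, 2000), beta = c(1000, 1000))
  res <- select_hyperparameters(sim$replicates, grid = grid,
                                train_chroms = "chr22",
                                test_chroms = "chr21",
                                metric_bin_size = 5000)
  expect_equal(nrow(res$report), 2L)
  best <- which.max(res$report$mean_log_density)
  expect_equal(res$b, res$report$b[best])
  expect_equal(res$beta, res$report$beta[best])

  one <- select_hyperparameters(sim$replicates,
                                grid = tibble::tibble(b = 800, beta = 1000),
                                train_chroms = "chr22", test_chroms = "chr21",
                                metric_bin_size = 5000)
  expect_equal(one$b, 800)

  expect_error(select_hyperparameters(sim$replicates,
                                      train_chroms = "chr21",
                                      test_chroms = "chr21"),
               "disjoint")
})
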