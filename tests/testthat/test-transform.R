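test_that("integral transform matches closed forms for analytic curves", {
  x <- seq(0, 100, length.out = 400)[-1]

  const2 <- build_vst_transform(analytic_curve(function(u) rep(2, length(u))),
                                x_max = 100, n_grid = 4096)
  expect_equal(transform_values(const2, 4), 2, tolerance = 1e-6)
  expect_equal(transform_values(const2, x), x / 2, tolerance = 1e-6)

  lin <- build_vst_transform(analytic_curve(function(u) u + 1),
                             x_max = 100, n_grid = 4096)
  expect_lt(max(abs(transform_values(lin, x) - log(x + 1)) / log(x + 1)), 1e-4)

  hyp <- build_vst_transform(analytic_curve(function(u) sqrt(u^2 + 1)),
                             x_max = 100, n_grid = 4096)
  expect_lt(max(abs(transform_values(hyp, x) - asinh(x)) / asinh(x)), 1e-4)
})

test_that("t(0) = 0 and the transform is strictly monotone", {
  curve <- analytic_curve(function(u) 1 + sqrt(u))
  model <- build_vst_transform(curve, x_max = 120)
  expect_equal(transform_values(model, 0), 0)
  for (m in list(model, log_transform(1), log_affine_transform(2, 3),
                 asinh_transform(), identity_transform())) {
    x <- sort(withr::with_seed(4, runif(100, 0, 150)))
    y <- transform_values(m, x)
    expect_true(all(diff(y) > 0), info = m$kind)
  }
})

test_that("scaling sigma by s scales the transform by 1/s", {
  f <- function(u) 1 + u / 10
  m1 <- build_vst_transform(analytic_curve(f), x_max = 100)
  m2 <- build_vst_transform(analytic_curve(function(u) 2 * f(u)), x_max = 100)
  x <- seq(0, 100, length.out = 57)
  expect_equal(transform_values(m2, x), transform_values(m1, x) / 2,
               tolerance = 1e-14)
})

test_that("values beyond the grid use the linear and reflected extensions", {
  curve <- analytic_curve(function(u) rep(4, length(u)), mu_max = 50)
  model <- build_vst_transform(curve, x_max = 50)
  t50 <- transform_values(model, 50)
  expect_equal(transform_values(model, 60), t50 + 10 / 4, tolerance = 1e-9)
  # below zero: reflected with the boundary slope
  expect_equal(transform_values(model, -8), -8 / 4, tolerance = 1e-9)
})

test_that("apply_transform preserves intervals and flags extensions", {
  track <- make_track(c(0, 1, 5, 200))
  curve <- analytic_curve(function(u) rep(1, length(u)), mu_max = 100)
  model <- build_vst_transform(curve, x_max = 100)
  expect_warning(out <- apply_transform(track, model), "extension")
  expect_equal(out[c("chrom", "start", "end")],
               track[c("chrom", "start", "end")])

  ident <- apply_transform(track, identity_transform())
  expect_equal(ident, track)

  lg <- apply_transform(make_track(c(0, exp(1) - 1)), log_transform(1))
  expect_equal(lg$value, c(0, 1))

  expect_equal(transform_values(asinh_transform(), 0), 0)
  expect_error(transform_values(log_transform(1), c(3, -2)), "undefined")
  expect_error(transform_values(log_affine_transform(1, 0), 0), "undefined")
})

test_that("implied sigma inverts the transform derivative", {
  expect_equal(implied_sigma(log_transform(1), 9), 10)
  expect_equal(implied_sigma(asinh_transform(), 0), 1)
  expect_equal(implied_sigma(identity_transform(), c(0, 7, 1e6)), rep(1, 3))
  expect_equal(implied_sigma(log_affine_transform(2, 4), 3), (2 * 3 + 4) / 2)

  # empirical transform: round trip within 1% at interior points
  f <- function(u) 2 + u / 5 + sin(u / 12)
  curve <- analytic_curve(f, mu_max = 100)
  model <- build_vst_transform(curve, x_max = 100)
  u <- seq(1, 99, length.out = 300)
  rel <- abs(as.numeric(implied_sigma(model, u)) - f(u)) / f(u)
  expect_lt(max(rel), 0.01)

  oob <- implied_sigma(model, c(-5, 50, 150))
  expect_equal(attr(oob, "n_out_of_domain"), 2L)
  expect_equal(as.numeric(oob)[3], 1 / model$slope_right)
})

test_that("x_max below the curve domain or tiny grids are rejected", {
  curve <- analytic_curve(function(u) u + 1, mu_max = 100)
  expect_error(build_vst_transform(curve, x_max = 50), "x_max")
  expect_error(build_vst_transform(curve, n_grid = 10), "n_grid")
})

test_that("the learned transform stabilizes simulated replicate variance", {
  sim <- simulate_replicates(n_positions = 6e4, chroms = "chr22", seed = 21)
  fit <- train_vst(sim$replicates, b = 1000, beta = 1000)
  pairs <- build_base_aux(sim$replicates)
  tp <- tibble::tibble(base = transform_values(fit$transform, pairs$base),
                       aux = transform_values(fit$transform, pairs$aux))
  diag <- mean_variance_diagnostic(tp[tp$base > 0, ], bin_size = 5e3)
  sds <- diag$sigma[!diag$is_zero_bin]
  # after stabilization the bin SDs of the transformed auxiliary signal are
  # flat to within a factor ~2 of their median (sampling noise included)
  expect_lt(max(sds) / median(sds), 2)
  expect_gt(min(sds) / median(sds), 0.5)

  # whereas the raw signal's bin SDs vary by far more
  raw_diag <- mean_variance_diagnostic(pairs[pairs$base > 0, ], bin_size = 5e3)
  raw_sds <- raw_diag$sigma[!raw_diag$is_zero_bin]
  expect_gt(max(raw_sds) / median(raw_sds), 4)
})
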