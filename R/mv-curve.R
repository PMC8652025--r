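#' Fit a smooth mean-variance curve to binned estimates
#'
#' Fits a cubic smoothing spline of the smoothed per-bin SD against the
#' per-bin mean, minimizing the usual penalized least-squares objective
#' `(1 - p) * sum_j w_j (sigma_j - f(mu_j))^2 + p * integral(f'')^2`. Weights
#' `w_j` are the bin counts (full bins count `b`, the partial final bin and
#' the zero bin their actual sizes). The zero bin, when present, contributes
#' one additional (mu_0, sigma_0) point. The smoothing parameter is chosen by
#' (generalized) cross-validation unless `spar` is given.
#'
#' The returned curve is clamped from below at
#' `sigma_floor = max(1e-4, 1e-3 * median(smoothed sigma))`, which keeps the
#' downstream transform integral finite if the spline undershoots near zero,
#' and evaluates with constant extrapolation outside the fitted mean range.
#'
#' @param stats A bin table from [smooth_bin_sigmas()].
#' @param cv Cross-validation flavor passed to [stats::smooth.spline()]:
#'   `FALSE` (default) for generalized cross-validation, `TRUE` for
#'   leave-one-out.
#' @param spar Optional smoothing-parameter override in `smooth.spline`'s
#'   `spar` scale; recorded in the fit metadata.
#' @param train_chroms Optional character vector recorded as provenance.
#' @return An object of class `mv_curve`. Evaluate it with
#'   [predict.mv_curve()]; inspect with [tidy()], [glance()] or
#'   [ggplot2::autoplot()].
#' @export
fit_sigma_curve <- function(stats, cv = FALSE, spar = NULL, train_chroms = NULL) {
  if (!all(c("mu", "smoothed_sigma", "count") %in% names(stats))) {
    stop_data("bin table lacks smoothed sigmas; run smooth_bin_sigmas() first")
  }
  zero <- stats[stats$is_zero_bin, , drop = FALSE]
  nz <- stats[!stats$is_zero_bin, , drop = FALSE]
  # Zero-bin point enters unsmoothed (it is excluded from the window average).
  mu <- c(zero$mu, nz$mu)
  sig <- c(zero$sigma, nz$smoothed_sigma)
  wts <- c(zero$count, nz$count)
  n_distinct_mu <- length(unique(mu))
  if (n_distinct_mu < 4L) {
    stop_data(sprintf(
      "smoothing-spline fit needs at least 4 distinct bin means, got %d",
      n_distinct_mu))
  }
  fit <- fit_spline_robust(mu, sig, wts, cv = cv, spar = spar)
  sigma_floor <- max(1e-4, 1e-3 * median(nz$smoothed_sigma))
  curve <- structure(
    list(
      type = "spline",
      spline = fit,
      mu_min = min(mu),
      mu_max = max(mu),
      sigma_floor = sigma_floor,
      spar = fit$spar,
      b = attr(stats, "bin_size"),
      beta = attr(stats, "beta"),
      zero_bin = if (nrow(zero)) list(mu0 = zero$mu[1], sigma0 = zero$sigma[1]),
      signal_type = attr(stats, "signal_type"),
      train_chroms = train_chroms,
      points = tibble(mu = mu, sigma = sig, weight = wts)
    ),
    class = "mv_curve"
  )
  grid_u <- seq(curve$mu_min, curve$mu_max, length.out = 512)
  curve$clamp_activations <- sum(raw_curve_values(curve, grid_u) < sigma_floor)
  curve
}

# smooth.spline's cross-validation search can step below its smoothing-
# parameter lower bound when bin weights are very uneven (e.g. a heavy zero
# bin); retry with progressively tighter, still-deterministic bounds.
fit_spline_robust <- function(mu, sig, wts, cv = FALSE, spar = NULL) {
  if (!is.null(spar)) {
    return(smooth.spline(mu, sig, w = wts, spar = spar))
  }
  attempts <- list(
    function() smooth.spline(mu, sig, w = wts, cv = cv),
    function() smooth.spline(mu, sig, w = wts, cv = cv,
                             control.spar = list(low = -0.5)),
    function() smooth.spline(mu, sig, w = wts, cv = cv,
                             control.spar = list(low = 0)),
    function() smooth.spline(mu, sig, w = wts, spar = 0.5)
  )
  last <- NULL
  for (f in attempts) {
    fit <- tryCatch(f(), error = function(e) {
      last <<- e
      NULL
    })
    if (!is.null(fit)) {
      return(fit)
    }
  }
  stop_data(paste0("smoothing-spline fit failed: ", conditionMessage(last)))
}

# Spline (or stored grid) evaluation with constant extrapolation but without
# the floor clamp; used to count clamp activations.
raw_curve_values <- function(object, u) {
  u <- pmin(pmax(u, object$mu_min), object$mu_max)
  if (object$type == "spline") {
    predict(object$spline, u)$y
  } else {
    approx(object$grid$mu, object$grid$sigma, u, rule = 2)$y
  }
}

#' Evaluate a fitted mean-variance curve
#'
#' @param object An `mv_curve`.
#' @param u Signal values at which to evaluate the fitted SD.
#' @param ... Unused.
#' @return Numeric vector of SD estimates, each at least the curve's
#'   `sigma_floor`; evaluation outside the fitted mean range returns the
#'   boundary value.
#' @export
predict.mv_curve <- function(object, u, ...) {
  pmax(raw_curve_values(object, u), object$sigma_floor)
}

#' @export
print.mv_curve <- function(x, ...) {
  cat(sprintf(
    "# mv_curve (%s): sigma(u) on [%.4g, %.4g], b = %g, beta = %g, spar = %.4g\n",
    x$type, x$mu_min, x$mu_max, x$b %||% NA, x$beta %||% NA, x$spar %||% NA))
  if (!is.null(x$zero_bin)) {
    cat(sprintf("#   zero bin: mu0 = %.4g, sigma0 = %.4g\n",
                x$zero_bin$mu0, x$zero_bin$sigma0))
  }
  cat(sprintf("#   sigma_floor = %.4g (%d clamp activations on a 512-point grid)\n",
              x$sigma_floor, x$clamp_activations %||% 0L))
  invisible(x)
}

#' @describeIn fit_sigma_curve Tidy the fitted curve: the bin points with
#'   their fitted SDs.
#' @param x An `mv_curve`.
#' @param ... Unused.
#' @export
tidy.mv_curve <- function(x, ...) {
  dplyr::mutate(x$points, .fitted = predict(x, .data$mu))
}

#' @describeIn fit_sigma_curve One-row fit summary.
#' @export
glance.mv_curve <- function(x, ...) {
  tibble(
    n_bins = nrow(x$points),
    mu_min = x$mu_min,
    mu_max = x$mu_max,
    b = x$b %||% NA_real_,
    beta = x$beta %||% NA_real_,
    spar = x$spar %||% NA_real_,
    sigma_floor = x$sigma_floor,
    clamp_activations = x$clamp_activations %||% NA_integer_,
    signal_type = x$signal_type %||% NA_character_
  )
}

#' @export
autoplot.mv_curve <- function(object, n = 512, ...) {
  grid <- tibble(
    mu = seq(object$mu_min, object$mu_max, length.out = n)
  )
  grid$sigma <- predict(object, grid$mu)
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$mu, y = .data$sigma)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "#d95f02") +
    ggplot2::labs(x = "bin mean signal", y = "bin SD of auxiliary signal",
                  title = "Empirical mean-variance relationship")
}

#' Grid search over bin size and bandwidth
#'
#' Fits the mean-variance curve on the training chromosomes for every
#' (b, beta) pair, then scores each fit on held-out test chromosomes by the
#' Gaussian mean log density ([gaussian_fit_loglik()]) and the
#' variance-instability score ([variance_instability()]) of the resulting
#' transform. Returns the pair with the best (largest) mean log likelihood.
#'
#' @param reps A `replicate_set`.
#' @param grid A data frame with columns `b` and `beta`; defaults to the two
#'   standard settings, (1e5, 1e3) for zero-inflated and (1e3, 1e7) for
#'   non-zero-inflated signals.
#' @param train_chroms,test_chroms Disjoint chromosome sets.
#' @param zero_bin Passed to [compute_bin_stats()]; defaults by signal type.
#' @param metric_bin_size Bin size for the instability score (default 1e4).
#' @return A list with elements `b`, `beta` and `report` (a tibble with one
#'   row per grid point and columns `b`, `beta`, `mean_log_density`,
#'   `instability`).
#' @export
select_hyperparameters <- function(reps, grid = NULL, train_chroms, test_chroms,
                                   zero_bin = NULL, metric_bin_size = 1e4) {
  if (length(intersect(train_chroms, test_chroms)) > 0L) {
    stop_usage("train and test chromosome sets must be disjoint")
  }
  if (is.null(grid)) {
    grid <- tibble(b = c(1e5, 1e3), beta = c(1e3, 1e7))
  }
  grid <- as_tibble(grid)
  if (nrow(grid) == 0L) {
    stop_usage("hyperparameter grid is empty")
  }
  train <- filter_chroms(reps, train_chroms)
  test <- filter_chroms(reps, test_chroms)
  test_pairs <- build_base_aux(test)
  scores <- purrr::pmap(grid, function(b, beta) {
    fit <- train_vst(train, b = b, beta = beta, zero_bin = zero_bin)
    ll <- gaussian_fit_loglik(test_pairs, fit$curve)
    tp <- dplyr::mutate(test_pairs,
                        base = transform_values(fit$transform, .data$base),
                        aux = transform_values(fit$transform, .data$aux))
    vi <- variance_instability(tp, bin_size = metric_bin_size)
    tibble(b = b, beta = beta,
           mean_log_density = ll$mean_log_density,
           instability = vi$score)
  })
  report <- dplyr::bind_rows(scores)
  best <- which.max(report$mean_log_density)
  list(b = report$b[best], beta = report$beta[best], report = report)
}
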