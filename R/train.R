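#' Train a variance-stabilizing transform from replicate tracks
#'
#' Runs the full estimation pipeline: enumerate base/aux replicate pairs,
#' bin, smooth across bins, fit the mean-variance spline, and integrate its
#' reciprocal into the transform. Hyperparameters default by signal type:
#' zero-inflated signals (raw counts, fold enrichment) use `b = 1e5`,
#' `beta = 1e3` with a zero bin; LPPV uses `b = 1e3`, `beta = 1e7` without.
#'
#' @param reps A `replicate_set` from [align_replicates()] or
#'   [simulate_replicates()].
#' @param b,beta Bin size and smoothing bandwidth; defaults by signal type.
#' @param zero_bin Use a dedicated zero bin; defaults by signal type.
#' @param spar Optional smoothing-parameter override for the spline fit.
#' @param cv Cross-validation flavor for the spline (see
#'   [fit_sigma_curve()]).
#' @param train_chroms Optional chromosomes to train on (e.g. `"chr22"`);
#'   `NULL` uses all.
#' @param x_max Upper end of the transform's integration grid; defaults to
#'   the maximum signal observed in the training data.
#' @param n_grid Integration grid resolution (default 4096).
#' @return A `vst_fit`: list with elements `curve` (`mv_curve`), `transform`
#'   (`vst_model`), `bins` (the smoothed bin table) and `info` (named list:
#'   counts, dropped bases, clamp activations).
#' @export
train_vst <- function(reps, b = NULL, beta = NULL, zero_bin = NULL,
                      spar = NULL, cv = FALSE, train_chroms = NULL,
                      x_max = NULL, n_grid = 4096) {
  if (!is_replicate_set(reps)) {
    stop_data("train_vst() needs an aligned replicate_set")
  }
  signal_type <- attr(reps, "signal_type")
  defaults <- default_hyperparameters(signal_type)
  b <- b %||% defaults$b
  beta <- beta %||% defaults$beta
  zero_bin <- zero_bin %||% defaults$zero_bin
  train <- filter_chroms(reps, train_chroms)
  if (nrow(train) == 0L) {
    stop_data("no positions on the requested training chromosomes")
  }
  pairs <- build_base_aux(train)
  stats <- compute_bin_stats(pairs, bin_size = b, zero_bin = zero_bin)
  stats <- smooth_bin_sigmas(stats, bin_size = b, beta = beta)
  curve <- fit_sigma_curve(stats, cv = cv, spar = spar,
                           train_chroms = train_chroms)
  x_max <- x_max %||% max(curve$mu_max, pairs$base)
  transform <- build_vst_transform(curve, x_max = x_max, n_grid = n_grid)
  structure(
    list(curve = curve, transform = transform, bins = stats,
         info = list(
           n_positions = attr(pairs, "n_positions"),
           n_pairs = nrow(pairs),
           m_replicates = attr(pairs, "m_replicates"),
           n_bins = sum(!stats$is_zero_bin),
           zero_bin = zero_bin,
           clamp_activations = curve$clamp_activations,
           dropped_bases = attr(reps, "dropped_bases"),
           signal_type = signal_type,
           b = b, beta = beta, spar = curve$spar
         )),
    class = "vst_fit"
  )
}

#' @export
print.vst_fit <- function(x, ...) {
  i <- x$info
  cat(sprintf(
    "# vst_fit: %s signal, %d positions x %d replicates -> %d bins (b = %g, beta = %g, spar = %.4g)\n",
    i$signal_type, i$n_positions, i$m_replicates, i$n_bins, i$b, i$beta, i$spar))
  print(x$curve)
  print(x$transform)
  invisible(x)
}

#' @describeIn train_vst One-row fit summary.
#' @param x A `vst_fit`.
#' @param ... Unused.
#' @export
glance.vst_fit <- function(x, ...) {
  want <- c("signal_type", "n_positions", "n_pairs", "m_replicates",
            "n_bins", "b", "beta", "spar", "clamp_activations",
            "dropped_bases")
  as_tibble(x$info[intersect(want, names(x$info))])
}

#' @describeIn train_vst The fitted bin table with spline-fitted SDs.
#' @export
tidy.vst_fit <- function(x, ...) {
  tidy(x$curve)
}

#' Compare transforms on held-out replicate data
#'
#' Scores a set of transforms on replicate pairs with both evaluation
#' metrics: the Gaussian mean log density under each transform's implied SD
#' (the learned curve itself for the empirical transform) and the
#' variance-instability score of the transformed values.
#'
#' @param reps A `replicate_set` (evaluation data, e.g. a held-out
#'   chromosome).
#' @param fit Optional `vst_fit` providing the learned transform.
#' @param compare Character vector among `"vst"`, `"log"`, `"asinh"`,
#'   `"identity"`.
#' @param metric_bin_size Bin size for the instability metric (default
#'   10 000).
#' @param test_chroms Optional chromosome filter applied before scoring.
#' @param per_position Report per-position (mean) instead of summed squared
#'   differences in the instability bins.
#' @return A tibble with one row per (transform, metric): columns
#'   `transform`, `metric`, `value`, `n`, `parameters`.
#' @export
evaluate_transforms <- function(reps, fit = NULL,
                                compare = c("vst", "log", "asinh", "identity"),
                                metric_bin_size = 1e4,
                                test_chroms = NULL,
                                per_position = FALSE) {
  compare <- match.arg(compare, several.ok = TRUE)
  if ("vst" %in% compare && is.null(fit)) {
    stop_usage("comparing the learned transform requires a fitted model")
  }
  reps <- filter_chroms(reps, test_chroms)
  pairs <- build_base_aux(reps)
  models <- list()
  if ("vst" %in% compare) models$vst <- fit$transform
  if ("log" %in% compare) models$log <- log_transform(1)
  if ("asinh" %in% compare) models$asinh <- asinh_transform()
  if ("identity" %in% compare) models$identity <- identity_transform()

  rows <- purrr::imap(models, function(model, name) {
    sigma <- if (name == "vst") fit$curve else model
    ll <- gaussian_fit_loglik(pairs, sigma)
    tp <- tibble(base = transform_values(model, pairs$base),
                 aux = transform_values(model, pairs$aux))
    vi <- variance_instability(tp, bin_size = metric_bin_size,
                               per_position = per_position)
    params <- switch(name,
      vst = sprintf("b=%g;beta=%g;spar=%.4g", fit$info$b, fit$info$beta,
                    fit$info$spar),
      log = "offset=1", asinh = "", identity = "")
    tibble(
      transform = name,
      metric = c("mean_log_density", "variance_instability"),
      value = c(ll$mean_log_density, vi$score),
      n = c(ll$n_positions, vi$B * vi$bin_size),
      parameters = params
    )
  })
  dplyr::bind_rows(rows)
}
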