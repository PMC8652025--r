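#' Gaussian quality-of-fit of an assumed mean-variance relationship
#'
#' Scores how well a mean-to-SD mapping describes the replicate data: the
#' average over positions of the Gaussian log density of the auxiliary value,
#' with mean equal to the base value and SD given by the mapping evaluated at
#' the base value. The Gaussian appears as the maximum-entropy distribution
#' with the assumed mean and variance; the average log density is maximized
#' when the assumed variance matches the spread of the data.
#'
#' @param pairs A base/aux tibble (see [build_base_aux()]).
#' @param sigma The assumed relationship: an `mv_curve`, a `vst_model` (its
#'   implied SD, see [implied_sigma()]), or a function of the mean.
#' @param sigma_source Optional label describing `sigma`; inferred when
#'   missing.
#' @return A one-row tibble with columns `mean_log_density` (nats per
#'   position), `n_positions` and `sigma_source`.
#' @export
gaussian_fit_loglik <- function(pairs, sigma, sigma_source = NULL) {
  fn <- as_sigma_fn(sigma)
  sigma_source <- sigma_source %||% sigma_label(sigma)
  s <- fn(pairs$base)
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop_data("assumed sigma must be finite and positive at every base value")
  }
  tibble(
    mean_log_density = mean(dnorm(pairs$aux, mean = pairs$base, sd = s, log = TRUE)),
    n_positions = nrow(pairs),
    sigma_source = sigma_source
  )
}

as_sigma_fn <- function(sigma) {
  if (inherits(sigma, "mv_curve")) {
    function(u) predict(sigma, u)
  } else if (inherits(sigma, "vst_model")) {
    function(u) as.numeric(implied_sigma(sigma, u))
  } else if (is.function(sigma)) {
    sigma
  } else {
    stop_data("sigma must be an mv_curve, a vst_model, or a function")
  }
}

sigma_label <- function(sigma) {
  if (inherits(sigma, "mv_curve")) "learned mean-variance curve"
  else if (inherits(sigma, "vst_model")) paste0("implied by ", sigma$kind, " transform")
  else "user function"
}

#' Variance-instability score of transformed replicate signals
#'
#' Sorts positions by the transformed base value, chunks them into bins of
#' `bin_size` positions (discarding the incomplete remainder), computes per
#' bin the sum of squared between-replicate differences `v_j`, and reports the
#' population variance of `v_1..B` scaled by `1 / (sigma1^2 * sigma2^2)`,
#' where `sigma1`, `sigma2` are the population SDs of the two full transformed
#' vectors. The scaling makes the score exactly invariant under joint
#' rescaling of the transformed signal; a perfectly variance-stabilized
#' signal gives a near-constant `v_j` profile and a score near 0.
#'
#' @param pairs A tibble with columns `base` and `aux` holding *transformed*
#'   values (same positions, same transform).
#' @param bin_size Positions per bin (default 10 000). At least two full bins
#'   are required.
#' @param per_position Use the mean instead of the sum of squared differences
#'   within each bin (the two differ by a constant factor `bin_size^2` in
#'   `v`'s variance for full bins).
#' @return An `instability_report`: list with elements `score`, `v` (per-bin
#'   values), `B`, `sigma1`, `sigma2`, `bin_size`, `per_position`. Use
#'   [glance()] for a one-row summary.
#' @export
variance_instability <- function(pairs, bin_size = 1e4, per_position = FALSE) {
  base_t <- pairs$base
  aux_t <- pairs$aux
  n <- length(base_t)
  if (length(aux_t) != n) {
    stop_data("base and aux must have equal length")
  }
  if (n < 2 * bin_size) {
    stop_data(sprintf(
      "need at least 2 full bins (2 * %g positions), got %d", bin_size, n))
  }
  ord <- order(base_t)             # stable radix sort, index breaks ties
  d2 <- (base_t[ord] - aux_t[ord])^2
  n_bins <- floor(n / bin_size)
  keep <- seq_len(n_bins * bin_size)
  idx <- rep(seq_len(n_bins), each = bin_size)
  v <- as.numeric(tapply(d2[keep], idx, sum))
  if (per_position) {
    v <- v / bin_size
  }
  sigma1 <- pop_sd(base_t)
  sigma2 <- pop_sd(aux_t)
  structure(
    list(score = pop_var(v) / (sigma1^2 * sigma2^2),
         v = v, B = n_bins, sigma1 = sigma1, sigma2 = sigma2,
         bin_size = bin_size, per_position = per_position),
    class = "instability_report"
  )
}

#' @export
print.instability_report <- function(x, ...) {
  cat(sprintf("# variance instability: %.6g over %d bins of %g (sigma1 = %.4g, sigma2 = %.4g)\n",
              x$score, x$B, x$bin_size, x$sigma1, x$sigma2))
  invisible(x)
}

#' @describeIn variance_instability One-row summary of the score.
#' @param x An `instability_report`.
#' @param ... Unused.
#' @export
glance.instability_report <- function(x, ...) {
  tibble(score = x$score, n_bins = x$B, bin_size = x$bin_size,
         sigma1 = x$sigma1, sigma2 = x$sigma2,
         per_position = x$per_position)
}

#' @describeIn variance_instability Per-bin squared-difference values.
#' @export
tidy.instability_report <- function(x, ...) {
  tibble(bin = seq_len(x$B), v = x$v)
}

#' @export
autoplot.instability_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$bin, y = .data$v)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "bin (increasing transformed base signal)",
                  y = "sum of squared replicate differences",
                  title = sprintf("Variance instability = %.4g", object$score))
}

#' Mean/SD scatter of replicate pairs for inspection
#'
#' The binned (mean, SD) scatter underlying the mean-variance fit, useful for
#' plotting the relationship before and after transformation: a successfully
#' stabilized signal shows a flat SD column.
#'
#' @param pairs A base/aux tibble (raw or transformed values).
#' @param bin_size Pairs per bin.
#' @param zero_bin Pull out a zero bin first (default `FALSE` here: the
#'   diagnostic is usually run on transformed values where exact zeros carry
#'   no special meaning).
#' @return A tibble with columns `mu`, `sigma`, `count`, `is_zero_bin`.
#' @export
mean_variance_diagnostic <- function(pairs, bin_size = 1e3, zero_bin = FALSE) {
  stats <- compute_bin_stats(pairs, bin_size = bin_size, zero_bin = zero_bin)
  dplyr::select(stats, "mu", "sigma", "count", "is_zero_bin")
}
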