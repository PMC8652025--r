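#' Recovery error of a fitted curve against simulation ground truth
#'
#' Compares the learned SD curve with the simulator's analytic noise law over
#' the central 80% of the latent-mean mass (10th to 90th percentile of the
#' positive latent means), reporting the median relative error against two
#' references: the per-replicate noise SD `sigma_true(mu)`, and the
#' replicate-pair conditional SD `sqrt(2) * sigma_true(mu)` — the spread of
#' one replicate around the other, which is the quantity the base/aux binning
#' actually measures (both replicates carry noise, and conditioning on the
#' noisy base value adds the posterior spread of the latent mean).
#'
#' @param fit A `vst_fit` trained on part of the simulation.
#' @param sim A simulation from [simulate_replicates()].
#' @param chroms Chromosomes of the truth table to evaluate on (typically the
#'   held-out ones); `NULL` for all.
#' @return Named numeric vector with elements `vs_sigma_true` and
#'   `vs_pair_sd` (median relative errors), plus attribute `n_evaluated`.
#' @export
recovery_error <- function(fit, sim, chroms = NULL) {
  truth <- sim$truth
  if (!is.null(chroms)) {
    truth <- truth[truth$chrom %in% chroms, , drop = FALSE]
  }
  mu <- truth$mu[truth$mu > 0]
  sigma_true <- truth$sigma_true[truth$mu > 0]
  qs <- quantile(mu, c(0.1, 0.9))
  keep <- mu >= qs[1] & mu <= qs[2]
  mu <- mu[keep]
  sigma_true <- sigma_true[keep]
  est <- predict(fit$curve, mu)
  out <- c(
    vs_sigma_true = median(abs(est - sigma_true) / sigma_true),
    vs_pair_sd = median(abs(est - sqrt(2) * sigma_true) /
                          (sqrt(2) * sigma_true))
  )
  attr(out, "n_evaluated") <- length(mu)
  out
}
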