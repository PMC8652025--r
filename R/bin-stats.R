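#' Binned mean/SD estimates of the mean-variance relationship
#'
#' Sorts base/auxiliary pairs by base value (stable sort, ties broken by
#' original index), chunks them into consecutive bins of `bin_size` pairs, and
#' computes for each bin the mean and population (1/n) standard deviation of
#' the auxiliary values. Positions left over after chunking form a final
#' smaller bin, weighted by its actual count downstream. When `zero_bin` is
#' `TRUE` the positions with base value exactly 0 are pulled out first into a
#' dedicated zero bin, the standard treatment for zero-inflated coverage-style
#' signals.
#'
#' @param pairs A tibble with columns `base` and `aux` (see
#'   [build_base_aux()]).
#' @param bin_size Number of pairs per bin (`b`), at least 2. Defaults to
#'   1e5 for zero-inflated (raw/FE) signals; use 1e3 for LPPV.
#' @param zero_bin Pull base == 0 positions into a separate bin. Defaults to
#'   `TRUE` unless the pairs carry an `lppv` signal type.
#' @return A tibble of bins, ordered with the zero bin (if any) first and the
#'   remaining bins by increasing base value, with columns `bin`, `mu`
#'   (mean of aux), `sigma2` and `sigma` (population variance/SD of aux),
#'   `count` and `is_zero_bin`. Attributes `bin_size` and `zero_bin` record
#'   the settings.
#' @export
compute_bin_stats <- function(pairs, bin_size = NULL, zero_bin = NULL) {
  zero_bin <- zero_bin %||% !identical(attr(pairs, "signal_type"), "lppv")
  bin_size <- bin_size %||% default_hyperparameters(attr(pairs, "signal_type"))$b
  if (nrow(pairs) == 0L) {
    stop_data("cannot bin an empty base/aux pairing")
  }
  if (bin_size < 2) {
    stop_data("bin_size must be at least 2")
  }
  base <- pairs$base
  aux <- pairs$aux
  rows <- list()
  if (zero_bin) {
    zi <- base == 0
    if (any(zi)) {
      rows[[1]] <- bin_row(aux[zi], bin = 0L, is_zero = TRUE)
    }
    base <- base[!zi]
    aux <- aux[!zi]
  }
  n <- length(base)
  if (n == 0L) {
    if (length(rows) == 0L) {
      stop_data("no positions left to bin")
    }
    warn("all positions have zero base signal; only the zero bin was computed")
    stats <- rows[[1]]
  } else {
    if (n < bin_size) {
      warn(sprintf("fewer pairs (%d) than bin_size (%g); using a single bin",
                   n, bin_size))
    }
    ord <- order(base)          # radix sort: stable, original index breaks ties
    aux_sorted <- aux[ord]
    n_bins <- max(1L, ceiling(n / bin_size))
    bin_idx <- pmin(((seq_len(n) - 1L) %/% bin_size) + 1L, n_bins)
    groups <- split(aux_sorted, bin_idx)
    nz <- purrr::imap(groups, ~ bin_row(.x, bin = as.integer(.y), is_zero = FALSE))
    stats <- dplyr::bind_rows(c(rows, nz))
  }
  attr(stats, "bin_size") <- bin_size
  attr(stats, "zero_bin") <- zero_bin
  attr(stats, "signal_type") <- attr(pairs, "signal_type")
  stats
}

bin_row <- function(aux, bin, is_zero) {
  mu <- mean(aux)
  s2 <- mean((aux - mu)^2)
  tibble(bin = bin, mu = mu, sigma2 = s2, sigma = sqrt(s2),
         count = length(aux), is_zero_bin = is_zero)
}

#' Smooth per-bin variances across neighboring bins
#'
#' Replaces each non-zero bin's variance with an exponentially weighted
#' average of its neighbors: bin j + k receives weight `2^(-b*|k|/beta)`, over
#' a window of half-width `w = round(-beta * ln(0.01) / (b * ln 2))` (the
#' window that keeps all weights >= 0.01), floored at 0. Neighbors beyond the
#' first or last bin are dropped and the remaining weights renormalized. The
#' zero bin, when present, is excluded from every window and is never
#' smoothed.
#'
#' `beta` is a bandwidth: large values spread weight over many bins, small
#' values concentrate it. With the zero-inflated defaults (b = 1e5,
#' beta = 1e3) the window collapses to w = 0 and smoothing is a no-op.
#'
#' @param stats A bin table from [compute_bin_stats()].
#' @param bin_size Bin size `b` used in the weight exponent; defaults to the
#'   `bin_size` attribute of `stats`.
#' @param beta Bandwidth parameter, positive. Defaults to 1e3 for
#'   zero-inflated (raw/FE) signals and 1e7 for LPPV.
#' @return `stats` with added columns `smoothed_sigma2` and `smoothed_sigma`.
#' @export
smooth_bin_sigmas <- function(stats, bin_size = NULL, beta = NULL) {
  bin_size <- bin_size %||% attr(stats, "bin_size")
  beta <- beta %||% default_hyperparameters(attr(stats, "signal_type"))$beta
  if (is.null(bin_size)) {
    stop_data("bin_size not given and not recorded on the bin table")
  }
  if (!is.numeric(beta) || beta <= 0) {
    stop_data("beta must be positive")
  }
  nz <- !stats$is_zero_bin
  s2 <- stats$sigma2[nz]
  b_count <- length(s2)
  w <- smoothing_window(bin_size, beta)
  if (w == 0L || b_count <= 1L) {
    sm <- s2
  } else {
    sm <- vapply(seq_len(b_count), function(j) {
      k <- max(1L, j - w):min(b_count, j + w)
      wt <- 2^(-bin_size * abs(k - j) / beta)
      sum(wt * s2[k]) / sum(wt)
    }, numeric(1))
  }
  stats$smoothed_sigma2 <- stats$sigma2
  stats$smoothed_sigma2[nz] <- sm
  stats$smoothed_sigma <- sqrt(stats$smoothed_sigma2)
  attr(stats, "beta") <- beta
  attr(stats, "bin_size") <- bin_size
  stats
}

# Window half-width: include bins with weight at least 0.01.
smoothing_window <- function(bin_size, beta) {
  max(0L, as.integer(round(-beta * log(0.01) / (bin_size * log(2)))))
}

# Paper-standard hyperparameter defaults by signal type: zero-inflated
# signals (raw counts, fold enrichment) use large bins with a narrow
# bandwidth; LPPV uses small bins with a wide bandwidth and no zero bin.
default_hyperparameters <- function(signal_type = NULL) {
  if (identical(signal_type, "lppv")) {
    list(b = 1e3, beta = 1e7, zero_bin = FALSE)
  } else {
    list(b = 1e5, beta = 1e3, zero_bin = TRUE)
  }
}
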