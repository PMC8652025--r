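# Small builders used across test files. Everything is generated in code; no
# stored fixtures.

make_track <- function(values, chrom = "chr21", width = 100L, start0 = 0L) {
  n <- length(values)
  starts <- start0 + (seq_len(n) - 1L) * width
  tibble::tibble(chrom = chrom, start = starts, end = starts + width,
                 value = as.numeric(values))
}

write_track <- function(values, ..., dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".bedGraph")
  trackvst::write_bedgraph(make_track(values, ...), path)
  path
}

# Aligned replicate set straight from value vectors (bypasses file IO).
make_replicate_set <- function(..., signal_type = "raw", chrom = "chr21") {
  vals <- list(...)
  df <- make_track(vals[[1]], chrom = chrom)
  names(df)[names(df) == "value"] <- "rep1"
  for (i in seq_along(vals)[-1]) {
    df[[paste0("rep", i)]] <- as.numeric(vals[[i]])
  }
  trackvst:::new_replicate_set(df, signal_type = signal_type)
}

# Grid-backed mean-variance curve for an analytic sigma function; exercises
# the same evaluation path as a deserialized model.
analytic_curve <- function(sigma_fn, mu_min = 0, mu_max = 100, n = 4096,
                           sigma_floor = 1e-8) {
  mu <- seq(mu_min, mu_max, length.out = n)
  structure(
    list(type = "grid", grid = list(mu = mu, sigma = sigma_fn(mu)),
         mu_min = mu_min, mu_max = mu_max, sigma_floor = sigma_floor,
         spar = NA_real_, b = NA_real_, beta = NA_real_, zero_bin = NULL,
         signal_type = "raw", train_chroms = NULL,
         points = tibble::tibble(mu = mu, sigma = sigma_fn(mu), weight = 1),
         clamp_activations = 0L),
    class = "mv_curve")
}

# Random base/aux pairing with zero inflation and ties, for oracle checks.
random_pairs <- function(n, seed) {
  withr::with_seed(seed, {
    base <- ifelse(runif(n) < 0.3, 0, rpois(n, 8))
    aux <- ifelse(runif(n) < 0.3, 0, rpois(n, 8))
    tibble::tibble(base = as.numeric(base), aux = as.numeric(aux))
  })
}

# shared helper: median relative error of bin SD vs the analytic law,
# binning by the *true* latent mean so the comparison is uncontaminated
law_check <- function(sim, sigma_of_mu, bin = 1000) {
  mu <- sim$truth$mu
  x <- sim$replicates$rep1
  ord <- order(mu)
  n <- floor(length(mu) / bin) * bin
  idx <- rep(seq_len(n / bin), each = bin)
  mu_bin <- tapply(mu[ord][1:n], idx, mean)
  sd_bin <- tapply(x[ord][1:n], idx, function(v) sqrt(mean((v - mean(v))^2)))
  abs(sd_bin - sigma_of_mu(mu_bin)) / sigma_of_mu(mu_bin)
}
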