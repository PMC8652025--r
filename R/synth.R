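#' Simulate replicate signal tracks with a known mean-variance relationship
#'
#' Generates aligned replicate tracks that emulate zero-inflated,
#' coverage-style genomic signals. Each position draws one latent mean
#' `mu_i`: exactly 0 with probability `zero_fraction` (unmappable or
#' zero-coverage positions), otherwise from a log-normal background
#' component or, with probability `peak_fraction`, from a log-normal peak
#' component. Replicates are then drawn i.i.d. around `mu_i` from the chosen
#' noise model, so the true mean-SD relationship is known exactly:
#' `sqrt(mu)` for Poisson, `sqrt(mu + phi * mu^2)` for the negative binomial,
#' and `sigma_fun(mu)` for Gaussian noise.
#'
#' The defaults emulate a replicated ChIP-seq-like count track: a third of
#' the genome without coverage, a low-rate background (median 2 counts), and
#' a high-signal peak component, with negative-binomial overdispersion
#' `phi = 0.1` — a mean-variance relationship that neither a log nor an
#' asinh transform matches.
#'
#' @param n_positions Positions per chromosome.
#' @param chroms Chromosome names (default `chr21`, `chr22`, mirroring a
#'   train-on-one, test-on-the-other protocol).
#' @param bin_width Interval width in bp (default 25).
#' @param zero_fraction Probability that a position's latent mean is exactly
#'   0, in [0, 1]; the degenerate value 1 produces all-zero tracks (count
#'   noise models), on which downstream fitting fails cleanly.
#' @param meanlog,sdlog Log-mean and log-SD of the background component.
#' @param peak_fraction Probability that a non-zero position draws from the
#'   peak component instead of the background.
#' @param peak_meanlog,peak_sdlog Log-mean and log-SD of the peak component.
#' @param noise One of `"negative_binomial"`, `"poisson"`, `"gaussian"`.
#' @param phi Negative-binomial dispersion (variance `mu + phi * mu^2`);
#'   `phi = 0` falls back to Poisson noise.
#' @param sigma_fun For Gaussian noise, a function mapping the latent mean to
#'   the noise SD; must be positive.
#' @param m_replicates Number of replicates (>= 2).
#' @param seed Integer seed; the full output is a deterministic function of
#'   the configuration and seed.
#' @return A list with elements `replicates` (a `replicate_set`), `truth`
#'   (tibble with `chrom`, `start`, `end`, `mu`, `sigma_true`) and `config`
#'   (the fully-resolved configuration as a named list).
#' @export
simulate_replicates <- function(n_positions = 1e5,
                                chroms = c("chr21", "chr22"),
                                bin_width = 25,
                                zero_fraction = 0.3,
                                meanlog = log(2), sdlog = 0.6,
                                peak_fraction = 0.2,
                                peak_meanlog = log(40), peak_sdlog = 0.8,
                                noise = c("negative_binomial", "poisson", "gaussian"),
                                phi = 0.1,
                                sigma_fun = NULL,
                                m_replicates = 2,
                                seed = 1) {
  noise <- match.arg(noise)
  if (zero_fraction < 0 || zero_fraction > 1) {
    stop_usage("zero_fraction must be in [0, 1]")
  }
  if (peak_fraction < 0 || peak_fraction > 1) {
    stop_usage("peak_fraction must be in [0, 1]")
  }
  if (phi < 0) {
    stop_usage("negative-binomial dispersion phi must be >= 0")
  }
  if (m_replicates < 2) {
    stop_usage("m_replicates must be at least 2")
  }
  if (noise == "gaussian" && !is.function(sigma_fun)) {
    stop_usage("gaussian noise needs a sigma_fun(mu) function")
  }
  n_positions <- as.integer(n_positions)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  per_chrom <- purrr::map(chroms, function(chrom) {
    mu <- draw_means(n_positions, zero_fraction, meanlog, sdlog,
                     peak_fraction, peak_meanlog, peak_sdlog)
    reps <- purrr::map(seq_len(m_replicates),
                       ~ draw_noise(mu, noise, phi, sigma_fun))
    sigma_true <- true_sigma(mu, noise, phi, sigma_fun)
    starts <- (seq_len(n_positions) - 1L) * as.integer(bin_width)
    df <- tibble(chrom = chrom, start = starts,
                 end = starts + as.integer(bin_width))
    for (i in seq_len(m_replicates)) {
      df[[paste0("rep", i)]] <- reps[[i]]
    }
    list(reps = df,
         truth = tibble(chrom = chrom, start = starts,
                        end = starts + as.integer(bin_width),
                        mu = mu, sigma_true = sigma_true))
  })

  signal_type <- if (noise == "gaussian") "lppv" else "raw"
  config <- list(
    n_positions = n_positions, chroms = chroms, bin_width = bin_width,
    zero_fraction = zero_fraction, meanlog = meanlog, sdlog = sdlog,
    peak_fraction = peak_fraction, peak_meanlog = peak_meanlog,
    peak_sdlog = peak_sdlog, noise = noise, phi = phi,
    m_replicates = m_replicates, seed = as.integer(seed)
  )
  list(
    replicates = new_replicate_set(
      dplyr::bind_rows(purrr::map(per_chrom, "reps")), signal_type),
    truth = dplyr::bind_rows(purrr::map(per_chrom, "truth")),
    config = config
  )
}

draw_means <- function(n, zero_fraction, meanlog, sdlog,
                       peak_fraction, peak_meanlog, peak_sdlog) {
  mu <- numeric(n)
  nonzero <- runif(n) >= zero_fraction
  is_peak <- nonzero & (runif(n) < peak_fraction)
  is_bg <- nonzero & !is_peak
  mu[is_bg] <- rlnorm(sum(is_bg), meanlog, sdlog)
  mu[is_peak] <- rlnorm(sum(is_peak), peak_meanlog, peak_sdlog)
  mu
}

draw_noise <- function(mu, noise, phi, sigma_fun) {
  n <- length(mu)
  switch(noise,
    poisson = as.numeric(rpois(n, mu)),
    negative_binomial = {
      if (phi == 0) {
        as.numeric(rpois(n, mu))
      } else {
        as.numeric(rnbinom(n, mu = mu, size = 1 / phi))
      }
    },
    gaussian = rnorm(n, mean = mu, sd = check_sigma(sigma_fun(mu)))
  )
}

true_sigma <- function(mu, noise, phi, sigma_fun) {
  switch(noise,
    poisson = sqrt(mu),
    negative_binomial = sqrt(mu + phi * mu^2),
    gaussian = check_sigma(sigma_fun(mu))
  )
}

check_sigma <- function(s) {
  if (any(!is.finite(s)) || any(s < 0)) {
    stop_data("sigma_fun must return finite, non-negative values")
  }
  s
}

#' Write a simulation to disk
#'
#' Writes `rep1.bedgraph` ... `repM.bedgraph`, `truth.tsv` (per-position
#' latent mean and true SD) and `config.json` into a directory.
#'
#' @param sim A simulation from [simulate_replicates()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- attr(sim$replicates, "m_replicates")
  for (i in seq_len(m)) {
    track <- tibble(chrom = sim$replicates$chrom,
                    start = sim$replicates$start,
                    end = sim$replicates$end,
                    value = sim$replicates[[paste0("rep", i)]])
    write_bedgraph(track, file.path(dir, sprintf("rep%d.bedgraph", i)))
  }
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  jsonlite::write_json(sim$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
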