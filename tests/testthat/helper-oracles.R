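# Direct, unoptimized reference implementations of the binning, smoothing and
# instability definitions. Written as plain loops over the definitions, so the
# package's vectorized code can be checked against them on small inputs.

oracle_bin_stats <- function(base, aux, b, zero_bin) {
  rows <- list()
  if (zero_bin) {
    zero_idx <- which(base == 0)
    if (length(zero_idx)) {
      vals <- aux[zero_idx]
      mu <- sum(vals) / length(vals)
      s2 <- sum((vals - mu)^2) / length(vals)
      rows[[length(rows) + 1]] <- data.frame(
        bin = 0L, mu = mu, sigma2 = s2, sigma = sqrt(s2),
        count = length(vals), is_zero_bin = TRUE)
    }
    keep <- setdiff(seq_along(base), zero_idx)
    base <- base[keep]
    aux <- aux[keep]
  }
  if (length(base)) {
    # stable sort by base, original index as tiebreak
    ord <- order(base, seq_along(base))
    aux <- aux[ord]
    n <- length(aux)
    n_bins <- max(1L, as.integer(ceiling(n / b)))
    for (j in seq_len(n_bins)) {
      lo <- (j - 1L) * b + 1L
      hi <- min(j * b, n)
      vals <- aux[lo:hi]
      mu <- sum(vals) / length(vals)
      s2 <- sum((vals - mu)^2) / length(vals)
      rows[[length(rows) + 1]] <- data.frame(
        bin = j, mu = mu, sigma2 = s2, sigma = sqrt(s2),
        count = length(vals), is_zero_bin = FALSE)
    }
  }
  do.call(rbind, rows)
}

oracle_smooth_sigmas <- function(sigma2, b, beta) {
  w <- max(0L, as.integer(round(-beta * log(0.01) / (b * log(2)))))
  B <- length(sigma2)
  out <- numeric(B)
  for (j in seq_len(B)) {
    num <- 0
    den <- 0
    # neighbors outside [1, B] are dropped, so only iterate the clipped range
    for (jj in max(1L, j - w):min(B, j + w)) {
      wt <- 2^(-b * abs(jj - j) / beta)
      num <- num + wt * sigma2[jj]
      den <- den + wt
    }
    out[j] <- num / den
  }
  out
}

oracle_instability <- function(base_t, aux_t, b, per_position = FALSE) {
  n <- length(base_t)
  ord <- order(base_t, seq_len(n))
  base_s <- base_t[ord]
  aux_s <- aux_t[ord]
  B <- floor(n / b)
  v <- numeric(B)
  for (j in seq_len(B)) {
    acc <- 0
    for (i in ((j - 1) * b + 1):(j * b)) {
      acc <- acc + (base_s[i] - aux_s[i])^2
    }
    v[j] <- if (per_position) acc / b else acc
  }
  pvar <- function(x) sum((x - sum(x) / length(x))^2) / length(x)
  pvar(v) / (pvar(base_t) * pvar(aux_t))
}

# Per-base expansion of a track: one value per covered base pair.
oracle_expand_track <- function(track) {
  out <- list()
  for (r in seq_len(nrow(track))) {
    pos <- seq(track$start[r], track$end[r] - 1L)
    out[[r]] <- data.frame(chrom = track$chrom[r], pos = pos,
                           value = track$value[r])
  }
  do.call(rbind, out)
}
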