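#' Enumerate all ordered replicate pairs as base/auxiliary vectors
#'
#' For M aligned replicates over N positions, every ordered pair of distinct
#' replicates (i, j) contributes replicate i to the base vector and replicate
#' j to the auxiliary vector, so both vectors have length N * M * (M - 1).
#' Pairs are enumerated lexicographically by (i, j) with positions in genomic
#' order inside each pair, which makes the construction deterministic.
#'
#' The base value at a position acts as a noisy estimate of the latent signal
#' mean there; the spread of the auxiliary values among positions with similar
#' base values is what the mean-variance estimator measures.
#'
#' @param reps A `replicate_set` from [align_replicates()] or
#'   [simulate_replicates()].
#' @return A tibble with columns `base` and `aux` and attributes
#'   `n_positions`, `m_replicates` and `signal_type`.
#' @export
build_base_aux <- function(reps) {
  if (!is_replicate_set(reps)) {
    stop_data("build_base_aux() needs an aligned replicate_set; run align_replicates() first")
  }
  m <- attr(reps, "m_replicates")
  if (is.null(m) || m < 2L) {
    stop_data("replicate set must contain at least two replicates")
  }
  if (nrow(reps) == 0L) {
    stop_data("replicate set is empty")
  }
  cols <- purrr::map(seq_len(m), ~ reps[[paste0("rep", .x)]])
  idx <- expand_ordered_pairs(m)
  pairs <- tibble(
    base = unlist(cols[idx$i], use.names = FALSE),
    aux  = unlist(cols[idx$j], use.names = FALSE)
  )
  attr(pairs, "n_positions") <- nrow(reps)
  attr(pairs, "m_replicates") <- m
  attr(pairs, "signal_type") <- attr(reps, "signal_type")
  pairs
}

# Ordered pairs (i, j), i != j, sorted lexicographically.
expand_ordered_pairs <- function(m) {
  g <- expand.grid(j = seq_len(m), i = seq_len(m))
  g <- g[g$i != g$j, c("i", "j")]
  g <- g[order(g$i, g$j), ]
  g
}
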