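#' Read a bedGraph signal track
#'
#' Parses a bedGraph file (four whitespace-delimited columns: chrom, start,
#' end, value; `track`/`browser` lines and `#` comments are permitted) into a
#' tidy interval table. Coordinates are 0-based half-open, the bedGraph
#' convention.
#'
#' @param path Path to a bedGraph file.
#' @param chroms Optional character vector of chromosome names; intervals on
#'   other chromosomes are dropped.
#' @return A tibble with columns `chrom`, `start`, `end`, `value`, sorted by
#'   chromosome and start, with non-overlapping intervals.
#' @examples
#' path <- tempfile(fileext = ".bedGraph")
#' writeLines(c("chr21 0 100 5.0", "chr21 100 200 0.0"), path)
#' read_bedgraph(path)
#' @export
read_bedgraph <- function(path, chroms = NULL) {
  if (!file.exists(path)) {
    stop_data(paste0("file not found: ", path))
  }
  diag <- diagnose_bedgraph(path)
  if (!is.null(diag)) {
    stop_data(diag)
  }
  gr <- tryCatch(
    rtracklayer::import(normalize_bedgraph_delims(path), format = "bedGraph"),
    error = function(e) {
      stop_data(paste0("failed to parse bedGraph '", path, "': ",
                       conditionMessage(e)), parent = e)
    }
  )
  track <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    value = as.numeric(gr$score)
  )
  if (!is.null(chroms)) {
    track <- dplyr::filter(track, .data$chrom %in% chroms)
  }
  track <- dplyr::arrange(track, .data$chrom, .data$start)
  validate_track(track, path = path)
  track
}

# bedGraph is whitespace-delimited but the importer expects tabs; rewrite
# space-separated data lines into a temporary tab-delimited copy when needed.
normalize_bedgraph_delims <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- startsWith(lines, "track") | startsWith(lines, "browser") |
    startsWith(lines, "#")
  if (!any(grepl(" ", lines[!meta], fixed = TRUE))) {
    return(path)
  }
  lines[!meta] <- gsub("[ \t]+", "\t", trimws(lines[!meta]))
  tmp <- tempfile(fileext = ".bedGraph")
  writeLines(lines, tmp)
  tmp
}

# Scan a bedGraph file for the first malformed line so parse errors can name
# the offending line number. Returns NULL if nothing obviously wrong.
diagnose_bedgraph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "track") ||
        startsWith(ln, "browser")) {
      next
    }
    fields <- strsplit(ln, "[ \t]+")[[1]]
    if (length(fields) != 4L) {
      return(sprintf("parse error in '%s' at line %d: expected 4 fields, found %d",
                     path, i, length(fields)))
    }
    nums <- suppressWarnings(as.numeric(fields[2:4]))
    if (anyNA(nums)) {
      return(sprintf("parse error in '%s' at line %d: non-numeric coordinate or value",
                     path, i))
    }
    if (nums[2] <= nums[1]) {
      return(sprintf("invalid interval in '%s' at line %d: end (%s) <= start (%s)",
                     path, i, fields[3], fields[2]))
    }
  }
  NULL
}

# Structural validation shared by the readers and the aligner: sorted,
# non-overlapping, end > start, finite values. Signal-type-specific checks
# (non-negativity for raw/FE) happen at alignment time, when the type is known.
validate_track <- function(track, path = NULL) {
  where <- if (is.null(path)) "track" else paste0("track '", path, "'")
  req <- c("chrom", "start", "end", "value")
  if (!all(req %in% names(track))) {
    stop_data(paste0(where, " must have columns chrom, start, end, value"))
  }
  if (nrow(track) == 0L) {
    return(invisible(track))
  }
  if (any(track$end <= track$start)) {
    bad <- which(track$end <= track$start)[1]
    stop_data(sprintf("%s: interval %d has end (%s) <= start (%s)",
                      where, bad, track$end[bad], track$start[bad]))
  }
  if (any(!is.finite(track$value))) {
    stop_data(paste0(where, ": non-finite signal values"))
  }
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  for (idx in by_chrom) {
    s <- track$start[idx]
    e <- track$end[idx]
    o <- order(s)
    if (any(s[o][-1] < e[o][-length(e)])) {
      stop_data(paste0(where, ": overlapping intervals on ",
                       track$chrom[idx[1]]))
    }
  }
  invisible(track)
}

#' Write a signal track as bedGraph
#'
#' The written file round-trips through [read_bedgraph()] to an equal track
#' (values to full double precision).
#'
#' @param track A tibble with columns `chrom`, `start`, `end`, `value`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  validate_track(track)
  lines <- sprintf("%s\t%d\t%d\t%s",
                   track$chrom, as.integer(track$start),
                   as.integer(track$end),
                   vapply(track$value, format_signal, character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) {
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

# Integers print as integers (keeps count tracks byte-stable across
# platforms); everything else at full double precision.
format_signal <- function(v) {
  if (is.finite(v) && v == round(v) && abs(v) < 2^53) {
    sprintf("%.0f", v)
  } else {
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }
}

#' Align replicate signal tracks onto a common interval grid
#'
#' Re-tiles two or more tracks onto the intersection of their covered regions
#' at the finest interval grid present (interval boundaries of every track are
#' kept; values of coarser intervals are replicated into their sub-intervals).
#' Positions covered by only some tracks are dropped and counted.
#'
#' @param tracks A list of two or more signal-track tibbles
#'   (see [read_bedgraph()]).
#' @param signal_type One of `"raw"`, `"fe"`, `"lppv"`. Raw and
#'   fold-enrichment signals must be non-negative; log Poisson p-value tracks
#'   may take any finite value.
#' @return A `replicate_set`: a tibble with columns `chrom`, `start`, `end`
#'   and one `rep<i>` column per track, plus attributes `signal_type`,
#'   `m_replicates` and `dropped_bases` (bases covered by some but not all
#'   tracks).
#' @export
align_replicates <- function(tracks, signal_type = c("raw", "fe", "lppv")) {
  signal_type <- match.arg(signal_type)
  if (!is.list(tracks) || length(tracks) < 2L) {
    stop_usage("align_replicates() needs at least two replicate tracks")
  }
  purrr::walk(tracks, validate_track)
  if (signal_type %in% c("raw", "fe")) {
    purrr::iwalk(tracks, function(tr, i) {
      if (any(tr$value < 0)) {
        stop_data(sprintf("replicate %s: negative values are invalid for %s signal",
                          i, signal_type))
      }
    })
  }
  grs <- purrr::map(tracks, track_to_granges)
  all_levels <- Reduce(union, purrr::map(grs, GenomeInfoDb::seqlevels))
  grs <- purrr::map(grs, function(gr) {
    GenomeInfoDb::seqlevels(gr) <- all_levels
    gr
  })
  covered <- purrr::map(grs, ~ GenomicRanges::reduce(GenomicRanges::granges(.x)))
  common <- Reduce(GenomicRanges::intersect, covered)
  if (sum(GenomicRanges::width(common)) == 0) {
    stop_data("replicate tracks have no common covered region")
  }
  union_cov <- GenomicRanges::reduce(Reduce(GenomicRanges::union, covered))
  dropped <- sum(GenomicRanges::width(union_cov)) -
    sum(GenomicRanges::width(common))

  # Finest grid: split the common region at every interval boundary present
  # in any track.
  frags <- GenomicRanges::disjoin(c(
    common,
    Reduce(c, purrr::map(grs, ~ GenomicRanges::granges(.x)))
  ))
  frags <- IRanges::subsetByOverlaps(frags, common, type = "within")
  frags <- GenomicRanges::sort(frags)

  values <- purrr::map(grs, function(gr) {
    hit <- GenomicRanges::findOverlaps(frags, gr, type = "within", select = "first")
    as.numeric(gr$score[hit])
  })
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(frags)),
    start = GenomicRanges::start(frags) - 1L,
    end   = GenomicRanges::end(frags)
  )
  for (i in seq_along(values)) {
    out[[paste0("rep", i)]] <- values[[i]]
  }
  new_replicate_set(out, signal_type = signal_type, dropped_bases = dropped)
}

new_replicate_set <- function(df, signal_type, dropped_bases = 0) {
  out <- as_tibble(df)
  attr(out, "signal_type") <- signal_type
  attr(out, "m_replicates") <- sum(grepl("^rep[0-9]+$", names(out)))
  attr(out, "dropped_bases") <- as.numeric(dropped_bases)
  class(out) <- c("replicate_set", class(tibble()))
  out
}

is_replicate_set <- function(x) inherits(x, "replicate_set")

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("# replicate_set: %d positions x %d replicates (%s signal, %g bases dropped)\n",
              nrow(x), attr(x, "m_replicates"), attr(x, "signal_type"),
              attr(x, "dropped_bases")))
  NextMethod()
}

track_to_granges <- function(track) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end)
  )
  gr$score <- track$value
  gr
}

# Restrict a replicate set to a chromosome subset, keeping attributes.
filter_chroms <- function(reps, chroms) {
  if (is.null(chroms)) {
    return(reps)
  }
  out <- reps[reps$chrom %in% chroms, , drop = FALSE]
  new_replicate_set(out, attr(reps, "signal_type"),
                    attr(reps, "dropped_bases"))
}
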