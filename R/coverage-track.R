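#' Remove PCR-duplicate reads
#'
#' Collapses reads that share the same mapped position so that amplification
#' artifacts contribute a single fragment. By default "same position" means
#' the (chromosome, start, strand) triple: reads on opposite strands at one
#' coordinate arise from distinct fragments and are both kept. Set
#' `use_strand = FALSE` for strand-agnostic collapsing.
#'
#' @param reads data.frame with columns `chrom`, `start` (0-based leftmost
#'   aligned base) and `strand` (`"+"` or `"-"`).
#' @param use_strand logical; include strand in the duplicate key.
#' @return The deduplicated reads, sorted by (chrom, start). The number of
#'   removed duplicates is attached as attribute `"n_duplicates_removed"` and
#'   reported via `message()`.
#' @export
deduplicate_reads <- function(reads, use_strand = TRUE) {
  reads <- validate_reads(reads)
  if (nrow(reads) == 0L) {
    attr(reads, "n_duplicates_removed") <- 0L
    return(reads)
  }
  key <- if (use_strand) {
    paste(reads$chrom, reads$start, reads$strand, sep = "\r")
  } else {
    paste(reads$chrom, reads$start, sep = "\r")
  }
  keep <- !duplicated(key)
  out <- reads[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  n_dup <- nrow(reads) - nrow(out)
  message(sprintf("deduplicate_reads: removed %d duplicate read(s) of %d",
                  n_dup, nrow(reads)))
  attr(out, "n_duplicates_removed") <- n_dup
  out
}

validate_reads <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("chrom", "start", "strand") %in% names(reads)))
  reads <- as.data.frame(reads)[, c("chrom", "start", "strand")]
  reads$chrom <- as.character(reads$chrom)
  reads$start <- as.numeric(reads$start)
  if (nrow(reads) > 0L) {
    if (any(reads$start < 0)) stop("read start coordinates must be >= 0")
    if (!all(reads$strand %in% c("+", "-")))
      stop("read strand must be '+' or '-'")
  }
  reads
}

#' Extend reads to the average fragment length
#'
#' Each read is anchored at its 5' end and extended 3'-ward to `ext_len` bp
#' to approximate the sequenced fragment: a plus-strand read at start `s`
#' becomes `[s, s + ext_len)`; a minus-strand read whose alignment spans
#' `[s, s + read_len)` becomes `[s + read_len - ext_len, s + read_len)`.
#' Intervals are clipped to `[0, chromosome length)`. Coordinates are
#' 0-based half-open throughout.
#'
#' @param reads deduplicated reads (see [deduplicate_reads()]).
#' @param ext_len extension length in bp (default 150).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param read_len mapped read length in bp (default 50), used to locate the
#'   3'-most base of minus-strand alignments.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @export
extend_reads <- function(reads, ext_len = 150, chrom_sizes, read_len = 50) {
  reads <- validate_reads(reads)
  stopifnot(ext_len >= 1, read_len >= 1)
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  if (nrow(reads) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  unknown <- setdiff(unique(reads$chrom), names(chrom_sizes))
  if (length(unknown) > 0L) {
    stop("reads on chromosome(s) absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  }
  len <- unname(chrom_sizes[reads$chrom])
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$start, reads$start + read_len - ext_len)
  end <- ifelse(plus, reads$start + ext_len, reads$start + read_len)
  start <- pmax(start, 0)
  end <- pmin(end, len)
  keep <- end > start
  data.frame(chrom = reads$chrom[keep], start = start[keep], end = end[keep])
}

#' Per-base read coverage from extended intervals
#'
#' The signal value at a base is the number of extended reads covering it.
#' Computed per chromosome with a difference-array cumulative sum, so total
#' coverage mass equals the summed interval widths exactly.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), already clipped to chromosome bounds.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param read_starts optional data.frame of deduplicated reads whose `start`
#'   positions populate the track's read-start counts (used by the Poisson
#'   enrichment test); omitted means a zero start-count layer.
#' @return A `SignalTrack`: list with `chrom_sizes`, per-chromosome integer
#'   `counts` (coverage), per-chromosome integer `starts` (read-start counts),
#'   `norm_factor` (NA until [normalize_track()]) and `normalized` (NULL until
#'   then).
#' @export
compute_coverage <- function(intervals, chrom_sizes, read_starts = NULL) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  counts <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    sel <- intervals$chrom == ch
    if (!any(sel)) return(integer(L))
    s <- intervals$start[sel]
    e <- intervals$end[sel]
    if (any(s < 0) || any(e > L) || any(e <= s))
      stop("intervals must be clipped, non-empty and within [0, chrom length)")
    # +1 at each interval start, -1 one past each end, then cumulative sum
    delta <- tabulate(s + 1L, nbins = L + 1L) - tabulate(e + 1L, nbins = L + 1L)
    as.integer(cumsum(delta)[seq_len(L)])
  })
  names(counts) <- names(chrom_sizes)
  starts <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    if (is.null(read_starts)) return(integer(L))
    sel <- read_starts$chrom == ch
    if (!any(sel)) return(integer(L))
    tabulate(read_starts$start[sel] + 1L, nbins = L)
  })
  names(starts) <- names(chrom_sizes)
  structure(list(chrom_sizes = chrom_sizes, counts = counts, starts = starts,
                 norm_factor = NA_real_, normalized = NULL),
            class = "SignalTrack")
}

validate_chrom_sizes <- function(chrom_sizes) {
  stopifnot(is.numeric(chrom_sizes), length(chrom_sizes) > 0,
            !is.null(names(chrom_sizes)), all(chrom_sizes >= 1))
  chrom_sizes
}

#' Build a normalized signal track from aligned reads
#'
#' Convenience wrapper running deduplication, 150-bp read extension, per-base
#' coverage and depth normalization in order.
#'
#' @inheritParams extend_reads
#' @param target_total total normalized signal mass (default 1e9, i.e. the
#'   equivalent of 1 Gbp of sequence per sample).
#' @param dedup logical; collapse PCR duplicates first (default TRUE).
#' @return A normalized `SignalTrack`.
#' @export
build_signal_track <- function(reads, chrom_sizes, ext_len = 150,
                               read_len = 50, target_total = 1e9,
                               dedup = TRUE) {
  if (dedup) reads <- suppressMessages(deduplicate_reads(reads))
  iv <- extend_reads(reads, ext_len = ext_len, chrom_sizes = chrom_sizes,
                     read_len = read_len)
  tr <- compute_coverage(iv, chrom_sizes, read_starts = reads)
  normalize_track(tr, target_total = target_total)
}

#' Depth-normalize a signal track
#'
#' Rescales per-base coverage so the genome-wide signal mass is the same for
#' every sample (default 1e9, "1 Gbp"): `norm_factor = target_total / sum(counts)`.
#'
#' @param track a `SignalTrack` from [compute_coverage()].
#' @param target_total target total signal mass (default 1e9).
#' @return The track with `normalized = counts * norm_factor` and
#'   `norm_factor` filled in.
#' @export
normalize_track <- function(track, target_total = 1e9) {
  stopifnot(inherits(track, "SignalTrack"), target_total > 0)
  total <- sum(vapply(track$counts, function(x) sum(as.numeric(x)), numeric(1)))
  if (total <= 0) stop("empty track cannot be normalized")
  f <- target_total / total
  track$norm_factor <- f
  track$normalized <- lapply(track$counts, function(x) as.numeric(x) * f)
  track
}

#' @export
print.SignalTrack <- function(x, ...) {
  tot <- sum(vapply(x$counts, function(v) sum(as.numeric(v)), numeric(1)))
  cat(sprintf("SignalTrack: %d chromosome(s), %.0f bp, raw mass %.4g, norm_factor %s\n",
              length(x$chrom_sizes), sum(x$chrom_sizes), tot,
              if (is.na(x$norm_factor)) "unset" else format(x$norm_factor)))
  invisible(x)
}

#' Average a track into fixed-width bins
#'
#' Partitions each chromosome into `bin_size`-bp bins (default 100) and takes
#' the arithmetic mean of the normalized per-base signal in each bin. The
#' final partial bin is kept and averaged over its actual width.
#'
#' @param track a normalized `SignalTrack`.
#' @param bin_size bin width in bp (default 100).
#' @return A `BinnedTrack`: list with `bin_size`, `chrom_sizes`, and `values`,
#'   a per-chromosome list of bin means (`ceiling(length / bin_size)` bins).
#' @export
bin_track <- function(track, bin_size = 100) {
  stopifnot(inherits(track, "SignalTrack"))
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (is.null(track$normalized))
    stop("track must be normalized before binning; see normalize_track()")
  bin_size <- as.integer(bin_size)
  values <- lapply(names(track$chrom_sizes), function(ch) {
    bin_means(track$normalized[[ch]], bin_size)
  })
  names(values) <- names(track$chrom_sizes)
  structure(list(bin_size = bin_size, chrom_sizes = track$chrom_sizes,
                 values = values),
            class = "BinnedTrack")
}

# Mean of x over consecutive bins of `bin_size`, partial last bin kept.
bin_means <- function(x, bin_size) {
  L <- length(x)
  nb <- ceiling(L / bin_size)
  cs <- c(0, cumsum(x))
  lo <- (seq_len(nb) - 1L) * bin_size
  hi <- pmin(lo + bin_size, L)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack: %d chromosome(s), bin %d bp, %d bins\n",
              length(x$values), x$bin_size,
              sum(vapply(x$values, length, integer(1)))))
  invisible(x)
}
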