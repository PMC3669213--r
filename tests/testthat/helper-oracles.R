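# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately use naive algorithms and different
# primitives (loops, stats::t.test, direct series summation) from the code
# paths they check.

# Upper-tail Poisson P(X >= k) by direct series summation in log space,
# summed until terms vanish.
oracle_poisson_tail <- function(k, lambda) {
  vapply(k, function(ki) {
    if (lambda == 0) return(if (ki <= 0) 1 else 0)
    if (ki <= 0) return(1)
    i <- ki
    total <- 0
    repeat {
      term <- exp(-lambda + i * log(lambda) - lgamma(i + 1))
      total <- total + term
      i <- i + 1
      if (term < 1e-280 && i > lambda + ki + 10) break
      if (i > lambda + ki + 5000) break
    }
    min(total, 1)
  }, numeric(1))
}

# Per-base coverage by explicit membership counting.
oracle_coverage <- function(starts, ends, L) {
  cov <- integer(L)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) {
      idx <- (starts[i] + 1):ends[i]
      cov[idx] <- cov[idx] + 1L
    }
  }
  cov
}

# Repeat-until-fixed-point interval merging (gap < merge_gap merges).
oracle_merge <- function(df, merge_gap) {
  repeat {
    df <- df[order(df$start), , drop = FALSE]
    changed <- FALSE
    i <- 1
    while (i < nrow(df)) {
      if (df$start[i + 1] - df$end[i] < merge_gap) {
        df$end[i] <- max(df$end[i], df$end[i + 1])
        df <- df[-(i + 1), , drop = FALSE]
        changed <- TRUE
      } else i <- i + 1
    }
    if (!changed) return(df)
  }
}

# Quadratic all-pairs overlap test on 0-based half-open intervals.
oracle_overlaps <- function(s1, e1, s2, e2) {
  sapply(seq_along(s1), function(i) {
    any(s1[i] < e2 & s2 < e1[i])
  })
}

# Paired t p-value for every seed-window start, computed naively with
# mean()/sd(); spot-equal to stats::t.test.
oracle_window_pvalues <- function(a, b, w) {
  n <- length(a) - w + 1
  vapply(seq_len(n), function(i) {
    d <- a[i:(i + w - 1)] - b[i:(i + w - 1)]
    if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
    2 * stats::pt(-abs(mean(d) / (stats::sd(d) / sqrt(w))), w - 1)
  }, numeric(1))
}

# Exhaustive scan oracle: from EVERY significant seed start (not only those
# reached by the linear resume-after walk), slide the seed window while it
# stays significant, capped at max_bins accumulated bins.
oracle_scan_all_seeds <- function(a, b, params) {
  p5 <- oracle_window_pvalues(a, b, params$seed_bins)
  out <- NULL
  for (i in seq_along(p5)) {
    if (p5[i] < params$scan_alpha) {
      j <- i
      while (j + 1 <= length(p5) && p5[j + 1] <= params$scan_alpha &&
             j + 1 - i + params$seed_bins <= params$max_bins) j <- j + 1
      out <- rbind(out, data.frame(first_bin = i,
                                   last_bin = j + params$seed_bins - 1))
    }
  }
  out
}

# The linear left-to-right walk applied to oracle p-values (resume after
# each emitted window), mirroring the scan contract.
oracle_scan_walk <- function(a, b, params) {
  p5 <- oracle_window_pvalues(a, b, params$seed_bins)
  first <- integer(0); last <- integer(0); pv <- numeric(0)
  i <- 1
  while (i <= length(p5)) {
    if (p5[i] < params$scan_alpha) {
      j <- i
      while (j + 1 <= length(p5) && p5[j + 1] <= params$scan_alpha &&
             j + 1 - i + params$seed_bins <= params$max_bins) j <- j + 1
      first <- c(first, i); last <- c(last, j + params$seed_bins - 1)
      pv <- c(pv, min(p5[i:j]))
      i <- j + params$seed_bins
    } else i <- i + 1
  }
  data.frame(first_bin = first, last_bin = last, scan_p = pv)
}

# Assemble a BinnedTrack directly from bin values (one chromosome).
make_binned <- function(values, bin_size = 100, chrom = "chrT") {
  L <- length(values) * bin_size
  structure(list(bin_size = as.integer(bin_size),
                 chrom_sizes = stats::setNames(L, chrom),
                 values = stats::setNames(list(values), chrom)),
            class = "BinnedTrack")
}

# Assemble a SignalTrack directly from per-base vectors (counts and/or
# read-start counts), normalized with factor 1 unless requested.
make_track <- function(counts, starts = NULL, chrom = "chrT",
                       normalize = FALSE) {
  L <- length(counts)
  if (is.null(starts)) starts <- integer(L)
  tr <- structure(list(chrom_sizes = stats::setNames(L, chrom),
                       counts = stats::setNames(list(as.numeric(counts)), chrom),
                       starts = stats::setNames(list(as.numeric(starts)), chrom),
                       norm_factor = 1,
                       normalized = stats::setNames(list(as.numeric(counts)), chrom)),
                  class = "SignalTrack")
  if (normalize) tr <- normalize_track(tr)
  tr
}

# Two matched noisy binned tracks with optional planted offset stretches.
random_binned_pair <- function(nbins, stretches = NULL, sd = 1, base = 10,
                               bin_size = 100) {
  a <- base + stats::rnorm(nbins, sd = sd)
  b <- base + stats::rnorm(nbins, sd = sd)
  if (!is.null(stretches)) {
    for (k in seq_len(nrow(stretches))) {
      idx <- stretches$first[k]:stretches$last[k]
      b[idx] <- b[idx] + stretches$offset[k]
    }
  }
  list(a = make_binned(a, bin_size), b = make_binned(b, bin_size))
}
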