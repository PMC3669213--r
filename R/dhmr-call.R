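#' Parameters for the DHMR scan
#'
#' Bundles the constants of the three-criterion differential-region procedure:
#' the seed-and-extend t-test scan over 100-bp bins (seed of 5 bins grown to
#' at most 50 while p stays at or below `scan_alpha`), the minimum fold change
#' with sub-kilobase gap merging, and the Poisson enrichment test of sliding
#' 100-bp windows against a 10-kb local background. The enrichment alpha is
#' mark-class specific: 1e-5 for punctate (promoter-focused) marks such as
#' H3K4me3/H3K9ac, 1e-3 for broad (domain-scale) marks such as
#' H3K27me3/H3K9me3.
#'
#' @param bin_size bin width in bp.
#' @param seed_bins bins in the seed window.
#' @param max_bins maximum window size in bins.
#' @param scan_alpha t-test significance threshold for seeding/growing.
#' @param min_fold minimum fold change between region means.
#' @param merge_gap regions closer than this many bp are merged.
#' @param background_extent width in bp of the local-background window.
#' @param enrich_window width in bp of the sliding enrichment window.
#' @param enrich_step step in bp of the sliding enrichment window.
#' @param enrich_alpha_punctate,enrich_alpha_broad Poisson p-value thresholds
#'   per mark class.
#' @param pseudocount added to both means in the fold-change ratio
#'   (normalized signal units) so empty regions divide cleanly.
#' @param test either `"paired"` (two-sided paired t-test on per-bin
#'   differences, the default) or `"welch"` (two-sample unequal-variance
#'   variant, for sensitivity analysis).
#' @param enrich_mode `"any"` keeps a region enriched in at least one sample
#'   (default); `"both"` requires enrichment in both.
#' @return A list of class `ScanParams`.
#' @export
scan_params <- function(bin_size = 100L, seed_bins = 5L, max_bins = 50L,
                        scan_alpha = 0.01, min_fold = 2.0, merge_gap = 1000L,
                        background_extent = 10000L, enrich_window = 100L,
                        enrich_step = 1L, enrich_alpha_punctate = 1e-5,
                        enrich_alpha_broad = 1e-3, pseudocount = 1.0,
                        test = c("paired", "welch"),
                        enrich_mode = c("any", "both")) {
  test <- match.arg(test)
  enrich_mode <- match.arg(enrich_mode)
  p <- list(bin_size = as.integer(bin_size), seed_bins = as.integer(seed_bins),
            max_bins = as.integer(max_bins), scan_alpha = scan_alpha,
            min_fold = min_fold, merge_gap = as.integer(merge_gap),
            background_extent = as.integer(background_extent),
            enrich_window = as.integer(enrich_window),
            enrich_step = as.integer(enrich_step),
            enrich_alpha_punctate = enrich_alpha_punctate,
            enrich_alpha_broad = enrich_alpha_broad,
            pseudocount = pseudocount, test = test,
            enrich_mode = enrich_mode)
  stopifnot(p$seed_bins >= 2, p$seed_bins <= p$max_bins, p$bin_size >= 1,
            p$merge_gap >= 0, p$background_extent >= 1,
            p$enrich_window >= 1, p$enrich_step >= 1,
            p$scan_alpha > 0, p$scan_alpha < 1,
            p$enrich_alpha_punctate > 0, p$enrich_alpha_punctate < 1,
            p$enrich_alpha_broad > 0, p$enrich_alpha_broad < 1,
            p$pseudocount >= 0)
  class(p) <- "ScanParams"
  p
}

#' Two-sided t-test on positionally matched bin values
#'
#' The scan statistic: a two-sided paired t-test on the per-bin differences
#' between the two samples (bins are positionally matched on the shared
#' genomic grid). Degenerate inputs follow the limits of the t statistic:
#' zero-variance differences with zero mean give p = 1, zero-variance nonzero
#' mean gives p = 0. A Welch two-sample variant is available via `test`.
#'
#' @param vals_a,vals_b equal-length numeric vectors of bin means.
#' @param test `"paired"` (default) or `"welch"`.
#' @return p-value in \[0, 1\].
#' @export
paired_bin_test <- function(vals_a, vals_b, test = c("paired", "welch")) {
  test <- match.arg(test)
  if (length(vals_a) != length(vals_b)) stop("unequal lengths")
  n <- length(vals_a)
  if (n < 2) stop("need at least 2 bins")
  if (test == "welch") {
    va <- stats::var(vals_a); vb <- stats::var(vals_b)
    if (va + vb <= 0) {
      return(if (mean(vals_a) == mean(vals_b)) 1 else 0)
    }
    se2 <- va / n + vb / n
    tstat <- (mean(vals_a) - mean(vals_b)) / sqrt(se2)
    df <- se2^2 / ((va / n)^2 / (n - 1) + (vb / n)^2 / (n - 1))
    return(2 * stats::pt(-abs(tstat), df))
  }
  d <- vals_a - vals_b
  m <- mean(d)
  v <- stats::var(d)
  scale2 <- mean(d^2)
  if (v <= 1e-13 * max(scale2, .Machine$double.xmin)) {
    return(if (abs(m) <= 1e-13 * sqrt(max(scale2, .Machine$double.xmin))) 1 else 0)
  }
  tstat <- m / sqrt(v / n)
  2 * stats::pt(-abs(tstat), n - 1)
}

# Windowed paired-t p-value from difference cumsums; i = 1-based first bin,
# w = width in bins. Degenerate-variance handling matches paired_bin_test.
window_p_from_cumsums <- function(cum1, cum2, i, w) {
  s1 <- cum1[i + w] - cum1[i]
  s2 <- cum2[i + w] - cum2[i]
  m <- s1 / w
  v <- (s2 - s1 * s1 / w) / (w - 1)
  ms <- s2 / w
  degen <- v <= 1e-13 * pmax(ms, .Machine$double.xmin)
  p <- numeric(length(m))
  if (any(degen)) {
    zm <- abs(m[degen]) <= 1e-13 * sqrt(pmax(ms[degen], .Machine$double.xmin))
    p[degen] <- ifelse(zm, 1, 0)
  }
  if (any(!degen)) {
    tstat <- m[!degen] / sqrt(v[!degen] / w)
    p[!degen] <- 2 * stats::pt(-abs(tstat), w - 1)
  }
  p
}

#' Seed-and-extend scan for differential windows
#'
#' Tests a `seed_bins`-bin window at every bin position, left to right.
#' Wherever the t-test gives p below `scan_alpha`, the window becomes a seed
#' and slides rightward in 1-bin steps, re-testing at each step; the
#' candidate region accumulates the covered bins for as long as each slid
#' window stays at or below `scan_alpha`, stopping when a window exceeds the
#' threshold or the region reaches `max_bins` bins. The region is emitted
#' with `scan_p` = the smallest p among its constituent windows, and
#' scanning resumes at the first bin after it, so emitted regions do not
#' overlap. Because the test always covers the trailing `seed_bins` bins,
#' region ends track the boundary of the differential stretch instead of
#' running on through flat background.
#'
#' @param binned_a,binned_b `BinnedTrack`s on the same bin grid.
#' @param params a [scan_params()] object.
#' @return data.frame of candidate regions: `chrom`, `start`, `end` (bp,
#'   0-based half-open, clipped to the chromosome) and `scan_p`.
#' @export
seed_extend_scan <- function(binned_a, binned_b, params = scan_params()) {
  stopifnot(inherits(binned_a, "BinnedTrack"), inherits(binned_b, "BinnedTrack"))
  if (binned_a$bin_size != binned_b$bin_size ||
      !identical(names(binned_a$values), names(binned_b$values)))
    stop("binned tracks must share the same bin grid")
  out <- lapply(names(binned_a$values), function(ch) {
    a <- binned_a$values[[ch]]
    b <- binned_b$values[[ch]]
    if (length(a) != length(b)) stop("bin grids differ on ", ch)
    reg <- scan_chromosome(a, b, params)
    if (nrow(reg) == 0L) return(NULL)
    L <- binned_a$chrom_sizes[[ch]]
    data.frame(chrom = ch,
               start = (reg$first_bin - 1) * params$bin_size,
               end = pmin(reg$last_bin * params$bin_size, L),
               scan_p = reg$scan_p)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), scan_p = numeric())
  rownames(out) <- NULL
  out
}

# p-value of the test at every seed window start (1..nbins-seed_bins+1).
sliding_window_pvalues <- function(a, b, params) {
  nb <- length(a)
  w0 <- params$seed_bins
  n_seed <- nb - w0 + 1L
  if (n_seed < 1L) return(numeric(0))
  if (params$test == "welch") {
    return(vapply(seq_len(n_seed), function(i) {
      idx <- i:(i + w0 - 1L)
      paired_bin_test(a[idx], b[idx], test = "welch")
    }, numeric(1)))
  }
  d <- a - b
  cum1 <- c(0, cumsum(d))
  cum2 <- c(0, cumsum(d * d))
  window_p_from_cumsums(cum1, cum2, seq_len(n_seed), w0)
}

scan_chromosome <- function(a, b, params) {
  nb <- length(a)
  w0 <- params$seed_bins
  empty <- data.frame(first_bin = integer(), last_bin = integer(),
                      scan_p = numeric())
  if (nb < w0) return(empty)
  seed_p <- sliding_window_pvalues(a, b, params)
  n_seed <- length(seed_p)
  first <- integer(0); last <- integer(0); pv <- numeric(0)
  i <- 1L
  while (i <= n_seed) {
    if (seed_p[i] < params$scan_alpha) {
      j <- i
      # slide while the next window position stays significant and the
      # accumulated region is under the bin cap
      while (j + 1L <= n_seed && seed_p[j + 1L] <= params$scan_alpha &&
             j + 1L - i + w0 <= params$max_bins) {
        j <- j + 1L
      }
      first <- c(first, i)
      last <- c(last, j + w0 - 1L)
      pv <- c(pv, min(seed_p[i:j]))
      i <- j + w0  # resume after the emitted window
    } else {
      i <- i + 1L
    }
  }
  data.frame(first_bin = first, last_bin = last, scan_p = pv)
}

# Mean normalized signal of track over [start, end) per region row.
region_means <- function(track, regions) {
  if (nrow(regions) == 0L) return(numeric(0))
  if (is.null(track$normalized)) stop("track must be normalized")
  out <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    sel <- which(regions$chrom == ch)
    cs <- c(0, cumsum(track$normalized[[ch]]))
    s <- regions$start[sel]; e <- regions$end[sel]
    out[sel] <- (cs[e + 1] - cs[s + 1]) / (e - s)
  }
  out
}

#' Fold-change filter on candidate regions
#'
#' Keeps a region when the larger of the two pseudocounted mean ratios,
#' `max((mean_b + psi) / (mean_a + psi), (mean_a + psi) / (mean_b + psi))`,
#' reaches `min_fold`. Means are over the normalized per-base signal in the
#' region.
#'
#' @param regions data.frame from [seed_extend_scan()].
#' @param track_a,track_b normalized `SignalTrack`s.
#' @param params a [scan_params()] object.
#' @return The surviving regions with `mean_a`, `mean_b` and `fold_change`
#'   columns added.
#' @export
fold_change_filter <- function(regions, track_a, track_b,
                               params = scan_params()) {
  regions$mean_a <- region_means(track_a, regions)
  regions$mean_b <- region_means(track_b, regions)
  psi <- params$pseudocount
  fc <- pmax((regions$mean_b + psi) / (regions$mean_a + psi),
             (regions$mean_a + psi) / (regions$mean_b + psi))
  regions$fold_change <- fc
  out <- regions[fc >= params$min_fold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge nearby candidate regions
#'
#' Transitively merges regions on the same chromosome separated by gaps
#' smaller than `merge_gap` bp, regardless of direction. The surviving gaps
#' are all at least `merge_gap`. The smallest `scan_p` among constituents is
#' retained.
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `scan_p`.
#' @param merge_gap gap threshold in bp (default 1000).
#' @return Merged, coordinate-sorted regions.
#' @export
merge_candidates <- function(regions, merge_gap = 1000L) {
  if (nrow(regions) == 0L) return(regions[, intersect(names(regions),
                                                      c("chrom", "start", "end", "scan_p"))])
  has_p <- "scan_p" %in% names(regions)
  out <- lapply(unique(regions$chrom), function(ch) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = r$start + 1L, end = r$end)
    red <- IRanges::reduce(ir, min.gapwidth = merge_gap)
    hit <- IRanges::findOverlaps(ir, red)
    res <- data.frame(chrom = ch,
                      start = IRanges::start(red) - 1L,
                      end = IRanges::end(red))
    if (has_p) {
      res$scan_p <- as.numeric(tapply(r$scan_p[S4Vectors::queryHits(hit)],
                                      S4Vectors::subjectHits(hit), min))
    }
    res
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Local background read-start rate around a region
#'
#' Estimates the Poisson background as the mean read-start rate in a
#' `extent`-bp window centered on the region (widened to the region itself
#' when the region is larger, clipped at chromosome ends).
#'
#' @param track a `SignalTrack` whose `starts` layer holds per-base
#'   deduplicated read-start counts.
#' @param chrom,start,end region coordinates (0-based half-open).
#' @param extent background window width in bp (default 10000).
#' @return `lambda_bp`, the background rate in read starts per bp.
#' @export
local_background <- function(track, chrom, start, end, extent = 10000L) {
  L <- track$chrom_sizes[[chrom]]
  if (is.null(L)) stop("unknown chromosome: ", chrom)
  cs <- c(0, cumsum(as.numeric(track$starts[[chrom]])))
  local_background_cs(cs, L, start, end, extent)
}

# cs = c(0, cumsum(starts)) for the chromosome; avoids re-summing per region.
local_background_cs <- function(cs, L, start, end, extent) {
  width <- end - start
  if (width >= extent) {
    lo <- start; hi <- end
  } else {
    center <- (start + end) / 2
    lo <- floor(center - extent / 2)
    hi <- lo + extent
  }
  lo <- max(lo, 0); hi <- min(hi, L)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

#' Poisson enrichment of sliding windows within a region
#'
#' Slides an `window`-bp window across the region in `step`-bp steps; the
#' window's read-start count `k` is compared with the background expectation
#' `lambda = lambda_bp * window` via the upper-tail Poisson probability
#' `P(X >= k)`. A window is enriched when that p-value is below `alpha`.
#'
#' @inheritParams local_background
#' @param lambda_bp background rate from [local_background()].
#' @param window,step window width and slide step in bp.
#' @param alpha enrichment p-value threshold.
#' @return list with `enriched` (logical: any enriched window), `windows`
#'   (start coordinates of enriched windows) and `min_p`.
#' @export
poisson_enrich_windows <- function(track, chrom, start, end, lambda_bp,
                                   window = 100L, step = 1L, alpha = 1e-5) {
  cs <- c(0, cumsum(as.numeric(track$starts[[chrom]])))
  poisson_enrich_windows_cs(cs, start, end, lambda_bp, window, step, alpha)
}

poisson_enrich_windows_cs <- function(cs, start, end, lambda_bp,
                                      window, step, alpha) {
  w <- min(window, end - start)
  pos <- seq.int(start, end - w, by = step)
  k <- cs[pos + w + 1] - cs[pos + 1]
  p <- poisson_upper_tail(k, lambda_bp * w)
  enr <- p < alpha
  list(enriched = any(enr), windows = pos[enr],
       min_p = if (length(p)) min(p) else 1)
}

#' Upper-tail Poisson probability P(X >= k)
#'
#' Survival-function form of the Poisson enrichment p-value. For
#' `lambda = 0`: the p-value is 1 when `k = 0` and 0 when `k > 0`.
#'
#' @param k observed count(s).
#' @param lambda Poisson mean.
#' @return `P(X >= k)` under `Poisson(lambda)`.
#' @export
poisson_upper_tail <- function(k, lambda) {
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Enrichment filter producing the final DHMR set
#'
#' Each region is tested for enriched windows in each sample against that
#' sample's own 10-kb local background; regions enriched in neither sample
#' are removed (set `enrich_mode = "both"` in the params to require
#' enrichment in both).
#'
#' @param regions merged, fold-change-passing regions (with `mean_a`,
#'   `mean_b`, `fold_change`, `scan_p`).
#' @param track_a,track_b `SignalTrack`s with read-start layers.
#' @param params a [scan_params()] object.
#' @param alpha Poisson p-value threshold (mark-class specific).
#' @return data.frame of DHMRs with `enriched_a`, `enriched_b` and
#'   `direction` (`"up"` when the signal rises from a to b) columns.
#' @export
enrichment_filter <- function(regions, track_a, track_b,
                              params = scan_params(), alpha) {
  n <- nrow(regions)
  ea <- logical(n); eb <- logical(n)
  cs_a <- list(); cs_b <- list()
  for (ch in unique(regions$chrom)) {
    cs_a[[ch]] <- c(0, cumsum(as.numeric(track_a$starts[[ch]])))
    cs_b[[ch]] <- c(0, cumsum(as.numeric(track_b$starts[[ch]])))
  }
  for (i in seq_len(n)) {
    ch <- regions$chrom[i]; s <- regions$start[i]; e <- regions$end[i]
    L <- track_a$chrom_sizes[[ch]]
    la <- local_background_cs(cs_a[[ch]], L, s, e, params$background_extent)
    lb <- local_background_cs(cs_b[[ch]], L, s, e, params$background_extent)
    ea[i] <- poisson_enrich_windows_cs(cs_a[[ch]], s, e, la,
                                       params$enrich_window,
                                       params$enrich_step, alpha)$enriched
    eb[i] <- poisson_enrich_windows_cs(cs_b[[ch]], s, e, lb,
                                       params$enrich_window,
                                       params$enrich_step, alpha)$enriched
  }
  regions$enriched_a <- ea
  regions$enriched_b <- eb
  keep <- if (params$enrich_mode == "both") ea & eb else ea | eb
  out <- regions[keep, , drop = FALSE]
  out$direction <- ifelse(out$mean_b > out$mean_a, "up", "down")
  rownames(out) <- NULL
  out
}

#' Call differential histone modification regions
#'
#' Runs the full three-criterion pipeline between two normalized tracks:
#' 100-bp binning, seed-and-extend paired t-test scan, fold-change filter,
#' sub-`merge_gap` merging (means and fold change recomputed on merged
#' regions and the fold threshold re-imposed), and the Poisson local-background
#' enrichment filter with the mark-class alpha.
#'
#' @param track_a,track_b normalized `SignalTrack`s on the same chromosomes
#'   (e.g. control and treated).
#' @param mark_class `"punctate"` (H3K4me3/H3K9ac-like; alpha 1e-5) or
#'   `"broad"` (H3K27me3/H3K9me3-like; alpha 1e-3).
#' @param params a [scan_params()] object.
#' @return data.frame of DHMRs sorted by coordinate: `chrom`, `start`, `end`,
#'   `mean_a`, `mean_b`, `fold_change`, `scan_p`, `enriched_a`, `enriched_b`,
#'   `direction`. Per-stage survivor counts are attached as attribute
#'   `"stage_counts"` and reported via `message()`.
#' @export
call_dhmrs <- function(track_a, track_b, mark_class = c("punctate", "broad"),
                       params = scan_params()) {
  mark_class <- match.arg(mark_class)
  stopifnot(inherits(track_a, "SignalTrack"), inherits(track_b, "SignalTrack"))
  if (!identical(track_a$chrom_sizes, track_b$chrom_sizes))
    stop("tracks must share the same chromosome grid")
  alpha <- if (mark_class == "punctate") params$enrich_alpha_punctate
           else params$enrich_alpha_broad
  ba <- bin_track(track_a, params$bin_size)
  bb <- bin_track(track_b, params$bin_size)
  cand <- seed_extend_scan(ba, bb, params)
  fc <- fold_change_filter(cand, track_a, track_b, params)
  mg <- merge_candidates(fc[, c("chrom", "start", "end", "scan_p")],
                         params$merge_gap)
  # merging can join regions through intervening background, so the fold
  # criterion is re-imposed on the merged extents
  mg <- fold_change_filter(mg, track_a, track_b, params)
  dhmr <- enrichment_filter(mg, track_a, track_b, params, alpha)
  dhmr <- dhmr[order(dhmr$chrom, dhmr$start),
               c("chrom", "start", "end", "mean_a", "mean_b", "fold_change",
                 "scan_p", "enriched_a", "enriched_b", "direction")]
  rownames(dhmr) <- NULL
  counts <- c(candidates = nrow(cand), fold_pass = nrow(fc),
              merged = nrow(mg), enriched = nrow(dhmr))
  message(sprintf(
    "call_dhmrs [%s]: %d candidates -> %d fold-pass -> %d merged -> %d DHMRs",
    mark_class, counts[1], counts[2], counts[3], counts[4]))
  attr(dhmr, "stage_counts") <- counts
  dhmr
}
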