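#' Promoter window of a gene
#'
#' The promoter is the window from `flank` bp upstream to `flank` bp
#' downstream of the transcription start site (default 2000, a 4-kb window).
#' The TSS is the first transcribed base: `span_start` for plus-strand genes,
#' `span_end - 1` for minus-strand genes (0-based). Strand only selects which
#' end is the TSS; the window itself is symmetric.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open transcript span).
#' @param flank bp on either side of the TSS (default 2000).
#' @param chrom_sizes named vector of chromosome lengths for clipping.
#' @return data.frame with `gene_id`, `chrom`, `strand`, `tss`,
#'   `start`, `end` of the clipped promoter window.
#' @export
promoter_of <- function(genes, flank = 2000L, chrom_sizes) {
  genes <- validate_genes(genes)
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  L <- unname(chrom_sizes[genes$chrom])
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             strand = genes$strand, tss = tss,
             start = pmax(tss - flank, 0),
             end = pmin(tss + flank, L))
}

validate_genes <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  genes <- as.data.frame(genes)
  if (nrow(genes) > 0L) {
    stopifnot(all(genes$end > genes$start), all(genes$strand %in% c("+", "-")))
  }
  genes
}

#' Map DHMRs to gene promoters (DHMGs)
#'
#' A gene becomes a differential histone modification gene (DHMG) when at
#' least one DHMR overlaps its promoter by one bp or more; one DHMR can
#' annotate several genes. Genes with several distinct TSSs are tested with
#' one promoter per distinct (gene_id, TSS) pair and reported once at the
#' gene level. When a promoter overlaps DHMRs of mixed direction, the gene
#' takes the direction of the DHMR with the largest promoter overlap (ties
#' broken by the larger absolute mean difference).
#'
#' @param dhmrs DHMR data.frame from [call_dhmrs()].
#' @param genes gene models (see [promoter_of()]).
#' @param flank promoter half-width in bp (default 2000).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param mark optional mark label recorded on the output.
#' @return data.frame with one row per DHMG: `gene_id`, `mark`, `n_dhmrs`,
#'   `direction`, `best_overlap_bp`.
#' @export
map_dhmrs_to_genes <- function(dhmrs, genes, flank = 2000L, chrom_sizes,
                               mark = NA_character_) {
  prom <- promoter_of(genes, flank, chrom_sizes)
  prom <- prom[!duplicated(prom[, c("gene_id", "tss")]), , drop = FALSE]
  empty <- data.frame(gene_id = character(), mark = character(),
                      n_dhmrs = integer(), direction = character(),
                      best_overlap_bp = numeric())
  if (nrow(dhmrs) == 0L || nrow(prom) == 0L) return(empty)
  miss <- setdiff(unique(dhmrs$chrom), unique(prom$chrom))
  if (length(miss) > 0L)
    warning("DHMR chromosome(s) not present among gene models: ",
            paste(miss, collapse = ", "))
  gr_d <- GenomicRanges::GRanges(dhmrs$chrom,
                                 IRanges::IRanges(dhmrs$start + 1L, dhmrs$end))
  gr_p <- GenomicRanges::GRanges(prom$chrom,
                                 IRanges::IRanges(prom$start + 1L, prom$end))
  hits <- GenomicRanges::findOverlaps(gr_p, gr_d)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_p)[qi],
                                           IRanges::ranges(gr_d)[si]))
  tab <- data.frame(gene_id = prom$gene_id[qi], dhmr = si, overlap = ov,
                    direction = dhmrs$direction[si],
                    delta = abs(dhmrs$mean_b[si] - dhmrs$mean_a[si]))
  # one row per (gene, dhmr) keeping the widest promoter overlap
  tab <- tab[order(tab$gene_id, tab$dhmr, -tab$overlap), , drop = FALSE]
  tab <- tab[!duplicated(tab[, c("gene_id", "dhmr")]), , drop = FALSE]
  out <- lapply(split(tab, tab$gene_id), function(g) {
    best <- g[order(-g$overlap, -g$delta), , drop = FALSE][1, ]
    data.frame(gene_id = g$gene_id[1], mark = mark, n_dhmrs = nrow(g),
               direction = best$direction, best_overlap_bp = best$overlap)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify drug reversal of treatment-induced promoter changes
#'
#' Cross-matches the DHMGs of the control-vs-treated comparison with those of
#' the control-vs-treated+drug comparison. Genes differential in both
#' comparisons are `common`; common genes whose direction of change flips are
#' `reciprocal`; genes differential only under treatment are `tgf_specific`
#' (their change is absent once the drug is added); genes differential only
#' under treatment+drug are `drug_specific`. The reversed set is
#' `reciprocal` together with `tgf_specific`, and `reversed_fraction` is its
#' share of the treatment DHMGs.
#'
#' @param dhmgs_ct DHMGs of control vs treated (from [map_dhmrs_to_genes()]).
#' @param dhmgs_cts DHMGs of control vs treated+drug.
#' @return list of class `ReversalReport` with the gene-id sets `common`,
#'   `reciprocal`, `tgf_specific`, `drug_specific`, `reversed`, plus
#'   `reversed_fraction` and `common_fraction` (NA with a warning when there
#'   are no treatment DHMGs).
#' @export
classify_reversal <- function(dhmgs_ct, dhmgs_cts) {
  dir_ct <- stats::setNames(dhmgs_ct$direction, dhmgs_ct$gene_id)
  dir_cts <- stats::setNames(dhmgs_cts$direction, dhmgs_cts$gene_id)
  common <- intersect(names(dir_ct), names(dir_cts))
  reciprocal <- common[dir_ct[common] != dir_cts[common]]
  tgf_specific <- setdiff(names(dir_ct), common)
  drug_specific <- setdiff(names(dir_cts), common)
  reversed <- union(reciprocal, tgf_specific)
  n_ct <- nrow(dhmgs_ct)
  if (n_ct == 0L) {
    warning("no treatment DHMGs; reversed_fraction undefined")
    rf <- NA_real_; cf <- NA_real_
  } else {
    rf <- length(reversed) / n_ct
    cf <- length(common) / n_ct
  }
  structure(list(common = common, reciprocal = reciprocal,
                 tgf_specific = tgf_specific, drug_specific = drug_specific,
                 reversed = reversed, reversed_fraction = rf,
                 common_fraction = cf, n_ct = n_ct, n_cts = nrow(dhmgs_cts)),
            class = "ReversalReport")
}

#' @export
print.ReversalReport <- function(x, ...) {
  cat(sprintf(
    paste0("ReversalReport: %d treatment DHMGs, %d drug DHMGs\n",
           "  common %d (reciprocal %d), treatment-specific %d, drug-specific %d\n",
           "  reversed %d (fraction %s)\n"),
    x$n_ct, x$n_cts, length(x$common), length(x$reciprocal),
    length(x$tgf_specific), length(x$drug_specific), length(x$reversed),
    if (is.na(x$reversed_fraction)) "NA" else sprintf("%.3f", x$reversed_fraction)))
  invisible(x)
}

#' Fraction of treatment DHMRs that disappear under the drug
#'
#' The share of control-vs-treated DHMRs not overlapped (by one bp or more)
#' by any control-vs-treated+drug DHMR — the regions whose differential state
#' is no longer detected once the drug is added.
#'
#' @param dhmrs_ct,dhmrs_cts DHMR data.frames on the same genome.
#' @return fraction in \[0, 1\], or NA (with a warning) when `dhmrs_ct` is
#'   empty.
#' @export
dhmr_overlap_fraction <- function(dhmrs_ct, dhmrs_cts) {
  if (nrow(dhmrs_ct) == 0L) {
    warning("no treatment DHMRs; disappearance fraction undefined")
    return(NA_real_)
  }
  gr_ct <- GenomicRanges::GRanges(dhmrs_ct$chrom,
                                  IRanges::IRanges(dhmrs_ct$start + 1L, dhmrs_ct$end))
  if (nrow(dhmrs_cts) == 0L) return(1.0)
  gr_cts <- GenomicRanges::GRanges(dhmrs_cts$chrom,
                                   IRanges::IRanges(dhmrs_cts$start + 1L, dhmrs_cts$end))
  n_hit <- GenomicRanges::countOverlaps(gr_ct, gr_cts)
  mean(n_hit == 0L)
}

#' Metagene signal profile
#'
#' Averages the normalized signal over genes on a common relative coordinate:
#' the 5-kb upstream flank in 25 equal portions, the gene body (TSS to TTS)
#' in 100 portions, and the 5-kb downstream flank in 25 portions, with
#' minus-strand genes flipped so position runs 5' to 3'. Genes shorter than
#' `body_portions` bp are skipped (count reported via `message()`); flank
#' portions falling off a chromosome end are dropped from the average.
#'
#' @param track a normalized `SignalTrack`.
#' @param genes gene models (0-based half-open spans).
#' @param body_portions,flank_portions number of portions for body and each
#'   flank (defaults 100 and 25).
#' @param flank_bp flank width in bp (default 5000).
#' @return data.frame with 150 rows: `position_class`
#'   (upstream/body/downstream), `position_index` (1..150) and `mean_signal`.
#' @export
metagene_profile <- function(track, genes, body_portions = 100L,
                             flank_portions = 25L, flank_bp = 5000L) {
  stopifnot(inherits(track, "SignalTrack"))
  if (is.null(track$normalized)) stop("track must be normalized")
  genes <- validate_genes(genes)
  nb_tot <- body_portions + 2L * flank_portions
  keep <- (genes$end - genes$start) >= body_portions
  n_skip <- sum(!keep)
  if (n_skip > 0)
    message(sprintf("metagene_profile: skipped %d gene(s) shorter than %d bp",
                    n_skip, body_portions))
  genes <- genes[keep, , drop = FALSE]
  if (nrow(genes) == 0L) stop("no genes long enough to profile")
  cs_by_chrom <- lapply(track$normalized, function(x) c(0, cumsum(x)))
  prof <- matrix(NA_real_, nrow = nrow(genes), ncol = nb_tot)
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    L <- track$chrom_sizes[[ch]]
    cs <- cs_by_chrom[[ch]]
    s <- genes$start[i]; e <- genes$end[i]
    up <- segment_means(cs, s - flank_bp, s, flank_portions, L)
    body <- segment_means(cs, s, e, body_portions, L)
    dn <- segment_means(cs, e, e + flank_bp, flank_portions, L)
    v <- c(up, body, dn)
    if (genes$strand[i] == "-") v <- rev(v)
    prof[i, ] <- v
  }
  data.frame(
    position_class = rep(c("upstream", "body", "downstream"),
                         c(flank_portions, body_portions, flank_portions)),
    position_index = seq_len(nb_tot),
    mean_signal = colMeans(prof, na.rm = TRUE))
}

# Mean signal in `n` equal portions of [a, b), from a cumsum vector; portions
# outside [0, L) (or of zero width after integer rounding) give NA.
segment_means <- function(cs, a, b, n, L) {
  edges <- floor(seq(a, b, length.out = n + 1))
  lo <- edges[-(n + 1)]; hi <- edges[-1]
  lo_c <- pmax(lo, 0); hi_c <- pmin(hi, L)
  w <- hi_c - lo_c
  out <- rep(NA_real_, n)
  ok <- w > 0
  out[ok] <- (cs[hi_c[ok] + 1] - cs[lo_c[ok] + 1]) / w[ok]
  out
}

#' Promoter-signal comparison between two samples
#'
#' Computes the mean normalized signal over each gene's promoter (TSS plus or
#' minus `flank`) in both tracks and compares the two per-gene distributions
#' with a two-sample z-test: `z = (mean_x - mean_y) / sqrt(s2_x/n + s2_y/n)`,
#' two-sided p from the normal distribution. The comparison is flagged
#' significant below `alpha` (default 1e-5).
#'
#' @param track_x,track_y normalized `SignalTrack`s.
#' @param genes gene models.
#' @param flank promoter half-width in bp (default 2000).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param alpha significance threshold (default 1e-5).
#' @return list with per-gene `promoter_means` (data.frame), `z`, `p_value`
#'   and `significant`.
#' @export
promoter_signal_ztest <- function(track_x, track_y, genes, flank = 2000L,
                                  chrom_sizes = track_x$chrom_sizes,
                                  alpha = 1e-5) {
  prom <- promoter_of(genes, flank, chrom_sizes)
  prom <- prom[!duplicated(prom[, c("gene_id", "tss")]), , drop = FALSE]
  if (nrow(prom) < 2L) stop("need at least 2 promoters")
  reg <- data.frame(chrom = prom$chrom, start = prom$start, end = prom$end)
  mx <- region_means(track_x, reg)
  my <- region_means(track_y, reg)
  n <- nrow(prom)
  vx <- stats::var(mx); vy <- stats::var(my)
  if (vx + vy <= 0) stop("degenerate z-test: zero variance in both samples")
  z <- (mean(mx) - mean(my)) / sqrt(vx / n + vy / n)
  p <- 2 * stats::pnorm(-abs(z))
  list(promoter_means = data.frame(gene_id = prom$gene_id, mean_x = mx,
                                   mean_y = my),
       z = z, p_value = p, significant = p < alpha)
}
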