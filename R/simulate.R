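#' Configuration for the synthetic ChIP-seq simulator
#'
#' Describes a three-condition (control, treated, treated+drug) ChIP-seq
#' study on a synthetic genome. Read starts follow an inhomogeneous Poisson
#' process: a uniform background rate, mark-specific basal enrichment
#' (promoter-anchored for punctate marks, gene-body domains for broad marks,
#' identical across conditions), and rectangular differential spikes whose
#' rate is multiplied by `spike_fold` in the gained condition. At a
#' `reversal_fraction` share of spikes the third condition follows the
#' control rate (the change is reversed); elsewhere it follows the treated
#' rate (retained). PCR duplicates are injected by re-emitting each read with
#' probability `duplicate_rate`.
#'
#' @param chrom_sizes named vector, the synthetic genome (default one 10-Mb
#'   chromosome).
#' @param marks named character vector mapping mark name to class
#'   (`"punctate"` or `"broad"`).
#' @param n_genes number of gene models to place.
#' @param read_length sequenced read length in bp (default 50, single-end).
#' @param background_rate background read-start rate per bp (default 0.05).
#' @param n_spikes differential spikes per mark (default 100).
#' @param spike_width_bp spike width (default 2000).
#' @param spike_fold rate multiplier in the gained condition (default 4).
#' @param gain_fraction share of spikes gained (vs lost) under treatment.
#' @param reversal_fraction share of spikes at which the third condition
#'   matches control (default 0.5).
#' @param promoter_fraction share of spikes placed inside a gene promoter so
#'   DHMG recovery is testable (default 0.5).
#' @param duplicate_rate probability a read is re-emitted as a PCR duplicate
#'   (default 0.2).
#' @param basal_promoter_fold,basal_domain_fold basal enrichment multipliers
#'   for punctate promoters (TSS +/- 500 bp) and broad gene-body domains.
#' @param merge_gap the caller's merge gap; spikes are spaced at least
#'   `2 * merge_gap` apart so distinct truths cannot merge.
#' @param rng_seed integer seed; a fixed seed makes every output
#'   byte-identical across runs.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(chrom_sizes = c(chrS = 1e7),
                       marks = c(H3K4me3 = "punctate", H3K27me3 = "broad"),
                       n_genes = 200L, read_length = 50L,
                       background_rate = 0.05, n_spikes = 100L,
                       spike_width_bp = 2000L, spike_fold = 4,
                       gain_fraction = 0.5, reversal_fraction = 0.5,
                       promoter_fraction = 0.5, duplicate_rate = 0.2,
                       basal_promoter_fold = 4, basal_domain_fold = 3,
                       merge_gap = 1000L, rng_seed = 1L) {
  cfg <- list(chrom_sizes = chrom_sizes, marks = marks,
              n_genes = as.integer(n_genes),
              read_length = as.integer(read_length),
              background_rate = background_rate,
              n_spikes = as.integer(n_spikes),
              spike_width_bp = as.integer(spike_width_bp),
              spike_fold = spike_fold, gain_fraction = gain_fraction,
              reversal_fraction = reversal_fraction,
              promoter_fraction = promoter_fraction,
              duplicate_rate = duplicate_rate,
              basal_promoter_fold = basal_promoter_fold,
              basal_domain_fold = basal_domain_fold,
              merge_gap = as.integer(merge_gap),
              rng_seed = as.integer(rng_seed))
  stopifnot(all(cfg$marks %in% c("punctate", "broad")),
            cfg$background_rate >= 0, cfg$spike_fold >= 1,
            cfg$reversal_fraction >= 0, cfg$reversal_fraction <= 1,
            cfg$gain_fraction >= 0, cfg$gain_fraction <= 1,
            cfg$promoter_fraction >= 0, cfg$promoter_fraction <= 1,
            cfg$duplicate_rate >= 0, cfg$duplicate_rate < 1,
            cfg$read_length >= 1, cfg$n_spikes >= 0)
  class(cfg) <- "SimConfig"
  cfg
}

#' Small fast preset of the simulator
#'
#' A 200-kb genome with 10 spikes per mark, sized so the full pipeline runs
#' in seconds; used for smoke tests and examples.
#' @param ... overrides passed to [sim_config()].
#' @export
sim_config_smoke <- function(...) {
  defaults <- list(chrom_sizes = c(chrS = 2e5),
                   marks = c(H3K4me3 = "punctate"),
                   n_genes = 8L, n_spikes = 10L, rng_seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

# Deterministic sub-seed per (mark, condition) stream; stays below 2^31.
sub_seed <- function(seed, mark_idx, condition) {
  (as.numeric(seed) * 31L + mark_idx * 7L + condition) %% 2147483647
}

#' Place ground-truth spikes and gene models
#'
#' Allocates one slot per (mark, spike) on the genome and places a
#' jittered spike in each, guaranteeing non-overlap and pairwise gaps of at
#' least `2 * merge_gap` so no two truth regions can be merged by the caller.
#' A `promoter_fraction` share of spikes is positioned inside the promoter of
#' a generated gene; remaining genes are placed in spike-free slots. Gains,
#' losses and reversal status are assigned per spike. Deterministic under
#' `rng_seed`.
#'
#' @param config a [sim_config()].
#' @return list with `truth` (data.frame: `mark`, `chrom`, `start`, `end`,
#'   `direction` gain/loss in treated vs control, `fold`, `reversed`,
#'   `in_promoter`) and `genes` (gene models).
#' @export
plan_spikes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  chrom <- names(config$chrom_sizes)[1]
  L <- config$chrom_sizes[[1]]
  n_marks <- length(config$marks)
  n_slots_needed <- n_marks * config$n_spikes + config$n_genes
  slot_w <- floor(L / max(n_slots_needed, 1))
  pad <- config$merge_gap + 2000L  # keeps spikes (and their promoters) apart
  min_slot <- config$spike_width_bp + 2L * pad
  if (config$n_spikes > 0 && slot_w < min_slot)
    stop(sprintf(
      "genome too small for %d spikes + %d genes: need >= %.0f bp",
      n_marks * config$n_spikes, config$n_genes,
      as.numeric(n_slots_needed) * min_slot))
  with_seed(sub_seed(config$rng_seed, 0L, 0L), {
    slots <- sample(seq_len(max(n_slots_needed, config$n_genes)))
    truth <- NULL
    genes <- NULL
    slot_i <- 1L
    gene_counter <- 0L
    make_gene <- function(tss_pref = NA, slot_lo, slot_hi) {
      gene_counter <<- gene_counter + 1L
      strand <- sample(c("+", "-"), 1L)
      glen <- round(stats::runif(1, 4000, 12000))
      if (is.na(tss_pref)) {
        tss <- round(stats::runif(1, slot_lo + 2500, slot_hi - 2500))
      } else {
        tss <- tss_pref
      }
      if (strand == "+") {
        gs <- tss; ge <- min(tss + glen, L)
      } else {
        ge <- tss + 1; gs <- max(ge - glen, 0)
      }
      data.frame(gene_id = sprintf("G%04d", gene_counter), chrom = chrom,
                 strand = strand, start = gs, end = ge)
    }
    for (mi in seq_len(n_marks)) {
      mk <- names(config$marks)[mi]
      if (config$n_spikes == 0L) next
      n_prom <- round(config$promoter_fraction * config$n_spikes)
      for (si in seq_len(config$n_spikes)) {
        slot <- slots[slot_i]; slot_i <- slot_i + 1L
        lo <- (slot - 1L) * slot_w
        hi <- min(slot * slot_w, L)
        s <- round(stats::runif(1, lo + pad,
                                hi - pad - config$spike_width_bp))
        e <- s + config$spike_width_bp
        in_prom <- si <= n_prom
        if (in_prom) {
          # TSS placed so the spike sits inside [TSS-2000, TSS+2000)
          g <- make_gene(tss_pref = s + config$spike_width_bp %/% 2,
                         slot_lo = lo, slot_hi = hi)
          genes <- rbind(genes, g)
        }
        truth <- rbind(truth, data.frame(
          mark = mk, chrom = chrom, start = s, end = e,
          direction = NA_character_, fold = config$spike_fold,
          reversed = NA, in_promoter = in_prom))
      }
    }
    n_gene_left <- config$n_genes - if (is.null(genes)) 0L else nrow(genes)
    for (gi in seq_len(max(n_gene_left, 0L))) {
      slot <- slots[slot_i]; slot_i <- slot_i + 1L
      lo <- (slot - 1L) * slot_w
      hi <- min(slot * slot_w, L)
      genes <- rbind(genes, make_gene(NA, lo, hi))
    }
    if (is.null(truth)) {
      truth <- data.frame(mark = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          direction = character(), fold = numeric(),
                          reversed = logical(), in_promoter = logical())
    } else {
      n <- nrow(truth)
      truth$direction <- ifelse(stats::runif(n) < config$gain_fraction,
                                "gain", "loss")
      truth$reversed <- stats::runif(n) < config$reversal_fraction
      truth <- truth[order(truth$mark, truth$chrom, truth$start), ,
                     drop = FALSE]
      rownames(truth) <- NULL
    }
    if (is.null(genes)) {
      genes <- data.frame(gene_id = character(), chrom = character(),
                          strand = character(), start = numeric(),
                          end = numeric())
    }
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
    list(truth = truth, genes = genes)
  })
}

# Piecewise-constant read-start rate for one (mark, condition) as a
# data.frame of segments (start, end, rate); condition in 1:3.
condition_rate_segments <- function(config, plan, mark, condition) {
  chrom <- names(config$chrom_sizes)[1]
  L <- config$chrom_sizes[[1]]
  bg <- config$background_rate
  feats <- NULL  # rows: start, end, multiplier (applied multiplicatively)
  mark_class <- config$marks[[mark]]
  genes <- plan$genes
  if (!is.null(genes) && nrow(genes) > 0) {
    if (mark_class == "punctate") {
      tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
      feats <- rbind(feats, cbind(pmax(tss - 500, 0), pmin(tss + 500, L),
                                  config$basal_promoter_fold))
    } else {
      feats <- rbind(feats, cbind(genes$start, genes$end,
                                  config$basal_domain_fold))
    }
  }
  tr <- plan$truth[plan$truth$mark == mark, , drop = FALSE]
  if (nrow(tr) > 0) {
    # which condition carries the elevated rate at each spike
    elevated <- switch(condition,
      `1` = tr$direction == "loss",
      `2` = tr$direction == "gain",
      `3` = ifelse(tr$reversed, tr$direction == "loss", tr$direction == "gain"))
    if (any(elevated))
      feats <- rbind(feats, cbind(tr$start[elevated], tr$end[elevated],
                                  tr$fold[elevated]))
  }
  if (is.null(feats) || nrow(feats) == 0)
    return(data.frame(start = 0, end = L, rate = bg))
  breaks <- sort(unique(c(0, L, feats[, 1], feats[, 2])))
  seg <- data.frame(start = breaks[-length(breaks)], end = breaks[-1])
  rate <- rep(bg, nrow(seg))
  for (i in seq_len(nrow(feats))) {
    hit <- seg$start >= feats[i, 1] & seg$end <= feats[i, 2]
    rate[hit] <- rate[hit] * feats[i, 3]
  }
  seg$rate <- rate
  seg
}

#' Simulate aligned reads for one mark and condition
#'
#' Draws read starts from the condition's piecewise-constant Poisson rate
#' (segment counts are Poisson with mean rate x width; positions uniform
#' within the segment), assigns strands Bernoulli(0.5), injects PCR
#' duplicates, and returns the reads in randomized order. Conditions are
#' 1 = control, 2 = treated, 3 = treated+drug.
#'
#' @param config a [sim_config()].
#' @param plan output of [plan_spikes()].
#' @param mark mark name (must be in `config$marks`).
#' @param condition 1, 2 or 3.
#' @return data.frame of aligned reads (`chrom`, `start`, `strand`).
#' @export
generate_condition_reads <- function(config, plan, mark, condition) {
  stopifnot(inherits(config, "SimConfig"), mark %in% names(config$marks),
            condition %in% 1:3)
  chrom <- names(config$chrom_sizes)[1]
  L <- config$chrom_sizes[[1]]
  seg <- condition_rate_segments(config, plan, mark, condition)
  mi <- match(mark, names(config$marks))
  with_seed(sub_seed(config$rng_seed, mi, condition), {
    n_per_seg <- stats::rpois(nrow(seg), seg$rate * (seg$end - seg$start))
    starts <- unlist(lapply(which(n_per_seg > 0), function(i) {
      floor(stats::runif(n_per_seg[i], seg$start[i], seg$end[i]))
    }))
    if (is.null(starts)) starts <- numeric(0)
    starts <- pmin(starts, L - config$read_length)
    n <- length(starts)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    dup <- stats::runif(n) < config$duplicate_rate
    reads <- data.frame(
      chrom = rep(chrom, n + sum(dup)),
      start = c(starts, starts[dup]),
      strand = c(strand, strand[dup]))
    reads[sample(nrow(reads)), , drop = FALSE]
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Emits, for each (mark, condition), a BED6 read file, plus the chromosome
#' sizes file, the gene models as GTF, the spike truth table as TSV and the
#' configuration as YAML. Regenerating with the same seed reproduces every
#' file byte for byte.
#'
#' @param dir output directory (created if missing).
#' @param config a [sim_config()].
#' @return (invisibly) a list with `paths` (named file list), `plan` and
#'   `config`.
#' @export
write_fixture <- function(dir, config = sim_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plan <- plan_spikes(config)
  paths <- list()
  for (mk in names(config$marks)) {
    for (cond in 1:3) {
      reads <- generate_condition_reads(config, plan, mk, cond)
      f <- file.path(dir, sprintf("reads_%s_cond%d.bed", mk, cond))
      write_reads_bed(reads, f, read_length = config$read_length)
      paths[[sprintf("%s_cond%d", mk, cond)]] <- f
    }
  }
  paths$chrom_sizes <- file.path(dir, "chrom.sizes")
  write_chrom_sizes(config$chrom_sizes, paths$chrom_sizes)
  paths$genes <- file.path(dir, "genes.gtf")
  write_genes_gtf(plan$genes, paths$genes)
  paths$truth <- file.path(dir, "truth.tsv")
  data.table::fwrite(plan$truth, paths$truth, sep = "\t")
  paths$config <- file.path(dir, "config.yaml")
  cfg_out <- unclass(config)
  cfg_out$chrom_sizes <- as.list(cfg_out$chrom_sizes)
  cfg_out$marks <- as.list(cfg_out$marks)
  yaml::write_yaml(cfg_out, paths$config)
  invisible(list(paths = paths, plan = plan, config = config))
}

#' Score called DHMRs against the spike truth
#'
#' A truth spike counts as recovered when some called DHMR covers at least
#' `min_recovery` (default 50%) of it; a called DHMR is a false positive when
#' it overlaps no truth spike by even one bp.
#'
#' @param dhmrs called DHMRs for one mark/comparison.
#' @param truth truth rows for the same mark (only spikes that are
#'   differential in the compared pair should be passed).
#' @param min_recovery minimum covered fraction of a truth spike (default 0.5).
#' @return list with `recall`, `precision`, `n_true`, `n_called`,
#'   `recovered` (logical per truth row).
#' @export
score_recovery <- function(dhmrs, truth, min_recovery = 0.5) {
  n_true <- nrow(truth); n_called <- nrow(dhmrs)
  if (n_true == 0L)
    return(list(recall = NA_real_,
                precision = if (n_called == 0L) NA_real_ else 0,
                n_true = 0L, n_called = n_called, recovered = logical(0)))
  if (n_called == 0L)
    return(list(recall = 0, precision = NA_real_, n_true = n_true,
                n_called = 0L, recovered = rep(FALSE, n_true)))
  gr_t <- GenomicRanges::GRanges(truth$chrom,
                                 IRanges::IRanges(truth$start + 1L, truth$end))
  gr_d <- GenomicRanges::GRanges(dhmrs$chrom,
                                 IRanges::IRanges(dhmrs$start + 1L, dhmrs$end))
  hits <- GenomicRanges::findOverlaps(gr_t, gr_d)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_t)[qi],
                                           IRanges::ranges(gr_d)[si]))
  frac <- ov / (truth$end[qi] - truth$start[qi])
  best <- tapply(frac, qi, max)
  recovered <- rep(FALSE, n_true)
  recovered[as.integer(names(best))] <- best >= min_recovery
  fp <- GenomicRanges::countOverlaps(gr_d, gr_t) == 0L
  list(recall = mean(recovered), precision = mean(!fp), n_true = n_true,
       n_called = n_called, recovered = recovered)
}
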