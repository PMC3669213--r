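#' Read aligned reads from BED6 or SAM
#'
#' BED input uses columns 1 (chrom), 2 (start) and 6 (strand); coordinates
#' are kept 0-based half-open. SAM input (detected from the `.sam` extension)
#' uses RNAME, POS and FLAG bit 0x10 via Rsamtools, with the 1-based POS
#' converted at the boundary.
#'
#' @param path BED6 or SAM file.
#' @return data.frame of aligned reads (`chrom`, `start`, `strand`).
#' @export
read_aligned_reads <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) return(read_sam_reads(path))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (ncol(dt) < 6)
    stop("BED read input needs 6 columns (strand in column 6): ", path)
  data.frame(chrom = as.character(dt[[1]]), start = as.numeric(dt[[2]]),
             strand = as.character(dt[[6]]))
}

read_sam_reads <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("SAM input requires the Rsamtools package")
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = c("rname", "pos", "strand")))[[1]]
  keep <- !is.na(res$pos)
  data.frame(chrom = as.character(res$rname)[keep],
             start = res$pos[keep] - 1,  # SAM POS is 1-based
             strand = as.character(res$strand)[keep])
}

#' Write aligned reads as BED6
#'
#' @param reads data.frame (`chrom`, `start`, `strand`).
#' @param path output path.
#' @param read_length read span written to the BED end column (default 50).
#' @export
write_reads_bed <- function(reads, path, read_length = 50L) {
  dt <- data.table::data.table(
    chrom = reads$chrom, start = as.integer(reads$start),
    end = as.integer(reads$start) + as.integer(read_length),
    name = "read", score = 0L, strand = reads$strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes file
#' @param path TSV with chromosome name and length.
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("chrom sizes file needs 2 columns: ", path)
  stats::setNames(as.numeric(dt[[2]]), as.character(dt[[1]]))
}

#' Write a two-column chromosome sizes file
#' @param chrom_sizes named numeric vector.
#' @param path output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  data.table::fwrite(
    data.table::data.table(names(chrom_sizes), as.integer(chrom_sizes)),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene models from GTF or BED12
#'
#' GTF (1-based closed, converted at the boundary) is parsed with
#' rtracklayer; transcript/gene-level features are used when present,
#' otherwise the span of each `gene_id`'s features. BED12 uses columns
#' 1-4 and 6.
#'
#' @param path GTF (`.gtf`) or BED (`.bed`) file.
#' @return gene models data.frame (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`; 0-based half-open).
#' @export
read_genes <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            data.table = FALSE)
    if (ncol(dt) < 6) stop("BED gene input needs >= 6 columns: ", path)
    return(data.frame(gene_id = as.character(dt[[4]]),
                      chrom = as.character(dt[[1]]),
                      strand = as.character(dt[[6]]),
                      start = as.numeric(dt[[2]]), end = as.numeric(dt[[3]])))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type %in% c("transcript", "gene"))) {
    gr <- gr[gr$type %in% c("transcript", "gene")]
  }
  df <- data.frame(gene_id = as.character(gr$gene_id),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1,  # to 0-based
                   end = GenomicRanges::end(gr))
  # collapse multi-feature genes to the transcript span per (gene_id, strand)
  sp <- split(df, df$gene_id)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end))
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene models as GTF transcript records
#' @param genes gene models data.frame (0-based half-open spans).
#' @param path output path.
#' @export
write_genes_gtf <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end),
    strand = genes$strand, type = "transcript", gene_id = genes$gene_id,
    transcript_id = paste0(genes$gene_id, ".1"))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write a signal track view as bedGraph
#'
#' Runs of equal signal are merged into single 0-based half-open bedGraph
#' intervals; zero-signal runs are omitted.
#'
#' @param track a `SignalTrack`.
#' @param path output path.
#' @param view `"normalized"` (default) or `"counts"`.
#' @export
write_bedgraph <- function(track, path, view = c("normalized", "counts")) {
  view <- match.arg(view)
  vals <- if (view == "counts") track$counts else track$normalized
  if (is.null(vals)) stop("requested view not available on this track")
  rows <- lapply(names(vals), function(ch) {
    r <- rle(as.numeric(vals[[ch]]))
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.table::data.table(chrom = ch, start = s[keep], end = e[keep],
                           value = r$values[keep])
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                     scipen = 50)
  invisible(path)
}

#' Read a bedGraph into a per-base vector set
#'
#' @param path 4-column bedGraph (0-based half-open).
#' @param chrom_sizes named vector of chromosome lengths.
#' @return per-chromosome list of per-base numeric signal.
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  bad <- setdiff(unique(dt$chrom), names(chrom_sizes))
  if (length(bad) > 0)
    warning("bedGraph chromosome(s) not in chrom_sizes (ignored): ",
            paste(bad, collapse = ", "))
  out <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    x <- numeric(L)
    d <- dt[dt$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      x[(d$start[i] + 1):d$end[i]] <- d$value[i]
    }
    x
  })
  names(out) <- names(chrom_sizes)
  out
}

#' Write DHMRs as BED6+ with statistics columns
#'
#' Standard BED columns carry the region, mark label and a capped
#' `-10*log10(scan_p)` score; extra columns carry the per-condition means,
#' fold change, p-value, enrichment flags and direction.
#'
#' @param dhmrs DHMR data.frame from [call_dhmrs()].
#' @param path output path.
#' @param mark mark label for the name column.
#' @export
write_dhmrs_bed <- function(dhmrs, path, mark = "mark") {
  score <- pmin(1000, round(-10 * log10(pmax(dhmrs$scan_p, 1e-300))))
  dt <- data.table::data.table(
    chrom = dhmrs$chrom, start = as.integer(dhmrs$start),
    end = as.integer(dhmrs$end), name = mark, score = score, strand = ".",
    mean_a = dhmrs$mean_a, mean_b = dhmrs$mean_b,
    fold_change = dhmrs$fold_change, scan_p = dhmrs$scan_p,
    enriched_a = dhmrs$enriched_a, enriched_b = dhmrs$enriched_b,
    direction = dhmrs$direction)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a DHMR BED6+ file written by [write_dhmrs_bed()]
#' @param path input path.
#' @return DHMR data.frame.
#' @export
read_dhmrs_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  data.frame(chrom = as.character(dt[[1]]), start = as.numeric(dt[[2]]),
             end = as.numeric(dt[[3]]), mean_a = dt[[7]], mean_b = dt[[8]],
             fold_change = dt[[9]], scan_p = dt[[10]],
             enriched_a = as.logical(dt[[11]]),
             enriched_b = as.logical(dt[[12]]),
             direction = as.character(dt[[13]]))
}
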