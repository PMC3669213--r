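#' Assemble a run configuration
#'
#' Describes a full three-condition run: per-mark read files for the
#' control, treated and treated+drug conditions, the chromosome sizes and
#' gene model files, and any scan-parameter overrides.
#'
#' @param reads nested named list: `reads[[mark]][[condition]]` is a BED6 or
#'   SAM path, with conditions named `control`, `treated`, `treated_drug`.
#' @param marks named character vector mapping mark to
#'   `"punctate"`/`"broad"`.
#' @param chrom_sizes path to a two-column chrom sizes TSV.
#' @param genes path to gene models (GTF or BED).
#' @param out_dir output directory.
#' @param params a [scan_params()] object.
#' @param ext_len,read_len,target_total track-building settings.
#' @param flank promoter half-width in bp.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(reads, marks, chrom_sizes, genes, out_dir,
                       params = scan_params(), ext_len = 150L, read_len = 50L,
                       target_total = 1e9, flank = 2000L) {
  conds <- c("control", "treated", "treated_drug")
  stopifnot(all(names(reads) %in% names(marks)),
            all(marks %in% c("punctate", "broad")))
  for (mk in names(reads)) {
    if (!all(conds %in% names(reads[[mk]])))
      stop("mark ", mk, " must provide paths for all of: ",
           paste(conds, collapse = ", "))
    missing <- !file.exists(unlist(reads[[mk]][conds]))
    if (any(missing))
      stop("missing read file(s) for mark ", mk, ": ",
           paste(unlist(reads[[mk]][conds])[missing], collapse = ", "))
  }
  structure(list(reads = reads, marks = marks, chrom_sizes = chrom_sizes,
                 genes = genes, out_dir = out_dir, params = params,
                 ext_len = ext_len, read_len = read_len,
                 target_total = target_total, flank = flank),
            class = "RunConfig")
}

#' Build a run configuration from a simulated fixture directory
#'
#' @param dir directory written by [write_fixture()].
#' @param out_dir output directory (default `<dir>/results`).
#' @param params a [scan_params()] object.
#' @return A `RunConfig`.
#' @export
run_config_from_fixture <- function(dir, out_dir = file.path(dir, "results"),
                                    params = scan_params()) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  marks <- unlist(cfg$marks)
  reads <- lapply(names(marks), function(mk) {
    list(control = file.path(dir, sprintf("reads_%s_cond1.bed", mk)),
         treated = file.path(dir, sprintf("reads_%s_cond2.bed", mk)),
         treated_drug = file.path(dir, sprintf("reads_%s_cond3.bed", mk)))
  })
  names(reads) <- names(marks)
  run_config(reads, marks, file.path(dir, "chrom.sizes"),
             file.path(dir, "genes.gtf"), out_dir, params = params,
             read_len = cfg$read_length)
}

#' Run the full differential histone modification pipeline
#'
#' For every mark: builds normalized tracks for the three conditions, calls
#' DHMRs for control-vs-treated and control-vs-treated+drug, maps both sets
#' to promoters (DHMGs), classifies the drug reversal, computes the DHMR
#' disappearance fraction, and produces metagene profiles plus
#' promoter-signal z-tests for both comparisons. All artifacts are written
#' under `out_dir` along with a manifest (parameters, input checksums,
#' per-stage survivor counts, output checksums).
#'
#' @param config a [run_config()].
#' @return (invisibly) nested results list, one entry per mark, with
#'   `dhmrs_ct`, `dhmrs_cts`, `dhmgs_ct`, `dhmgs_cts`, `reversal`,
#'   `disappearance_fraction`, `profiles`, `ztests`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
  genes <- read_genes(config$genes)
  manifest <- list(params = unclass(config$params),
                   inputs = manifest_checksums(c(
                     unlist(config$reads), config$chrom_sizes, config$genes)),
                   marks = list())
  results <- list()
  for (mk in names(config$reads)) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("pipeline stage '%s' failed for mark %s: %s",
                     what, mk, conditionMessage(e)), call. = FALSE)
      })
    }
    tracks <- stage("signal", lapply(config$reads[[mk]], function(p) {
      build_signal_track(read_aligned_reads(p), chrom_sizes,
                         ext_len = config$ext_len, read_len = config$read_len,
                         target_total = config$target_total)
    }))
    mark_class <- unname(config$marks[[mk]])
    dhmrs_ct <- stage("call_ct", call_dhmrs(
      tracks$control, tracks$treated, mark_class, config$params))
    dhmrs_cts <- stage("call_cts", call_dhmrs(
      tracks$control, tracks$treated_drug, mark_class, config$params))
    dhmgs_ct <- stage("annotate", map_dhmrs_to_genes(
      dhmrs_ct, genes, config$flank, chrom_sizes, mark = mk))
    dhmgs_cts <- stage("annotate", map_dhmrs_to_genes(
      dhmrs_cts, genes, config$flank, chrom_sizes, mark = mk))
    reversal <- stage("compare", classify_reversal(dhmgs_ct, dhmgs_cts))
    disap <- stage("compare", dhmr_overlap_fraction(dhmrs_ct, dhmrs_cts))
    profiles <- stage("profile", lapply(tracks, metagene_profile,
                                        genes = genes))
    ztests <- stage("profile", list(
      control_vs_treated = promoter_signal_ztest(
        tracks$control, tracks$treated, genes, config$flank, chrom_sizes),
      control_vs_treated_drug = promoter_signal_ztest(
        tracks$control, tracks$treated_drug, genes, config$flank,
        chrom_sizes)))
    outp <- function(name) file.path(config$out_dir, paste0(mk, "_", name))
    write_dhmrs_bed(dhmrs_ct, outp("dhmrs_control_vs_treated.bed"), mk)
    write_dhmrs_bed(dhmrs_cts, outp("dhmrs_control_vs_treated_drug.bed"), mk)
    data.table::fwrite(dhmgs_ct, outp("dhmgs_control_vs_treated.tsv"),
                       sep = "\t")
    data.table::fwrite(dhmgs_cts, outp("dhmgs_control_vs_treated_drug.tsv"),
                       sep = "\t")
    rev_tab <- data.frame(
      mark = mk, n_dhmgs_ct = reversal$n_ct, n_dhmgs_cts = reversal$n_cts,
      common = length(reversal$common),
      reciprocal = length(reversal$reciprocal),
      tgf_specific = length(reversal$tgf_specific),
      drug_specific = length(reversal$drug_specific),
      reversed = length(reversal$reversed),
      reversed_fraction = reversal$reversed_fraction,
      common_fraction = reversal$common_fraction,
      dhmr_disappearance_fraction = disap)
    data.table::fwrite(rev_tab, outp("reversal.tsv"), sep = "\t")
    for (cond in names(profiles)) {
      data.table::fwrite(profiles[[cond]],
                         outp(sprintf("profile_%s.tsv", cond)), sep = "\t")
    }
    manifest$marks[[mk]] <- list(
      stage_counts_ct = as.list(attr(dhmrs_ct, "stage_counts")),
      stage_counts_cts = as.list(attr(dhmrs_cts, "stage_counts")),
      reversal = as.list(rev_tab))
    results[[mk]] <- list(dhmrs_ct = dhmrs_ct, dhmrs_cts = dhmrs_cts,
                          dhmgs_ct = dhmgs_ct, dhmgs_cts = dhmgs_cts,
                          reversal = reversal,
                          disappearance_fraction = disap,
                          profiles = profiles, ztests = ztests)
  }
  manifest$outputs <- manifest_checksums(
    list.files(config$out_dir, full.names = TRUE, pattern = "\\.(bed|tsv)$"))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(results)
}

manifest_checksums <- function(paths) {
  paths <- unlist(paths)
  paths <- paths[file.exists(paths)]
  as.list(stats::setNames(unname(tools::md5sum(paths)), basename(paths)))
}
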