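# Shared fixture cache so expensive simulated runs are built once per test
# session and reused across test files.
.fixture_cache <- new.env(parent = emptyenv())

# Smoke-scale fixture directory (200-kb genome, written once).
smoke_fixture <- function() {
  if (is.null(.fixture_cache$smoke)) {
    dir <- file.path(tempdir(), "dhmrscan-smoke-fixture")
    fx <- write_fixture(dir, sim_config_smoke())
    .fixture_cache$smoke <- list(dir = dir, plan = fx$plan,
                                 config = fx$config, paths = fx$paths)
  }
  .fixture_cache$smoke
}

# One control-vs-treated run of the caller on the default 10-Mb fixture
# (punctate mark) at the given spike fold. Tracks are dropped after use;
# summary masses are kept for conservation checks.
default_fixture_run <- function(fold) {
  key <- paste0("fold_", fold)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- sim_config(spike_fold = fold)
    plan <- plan_spikes(cfg)
    mk <- "H3K4me3"
    r1 <- suppressMessages(deduplicate_reads(
      generate_condition_reads(cfg, plan, mk, 1)))
    r2 <- suppressMessages(deduplicate_reads(
      generate_condition_reads(cfg, plan, mk, 2)))
    iv1 <- extend_reads(r1, 150, cfg$chrom_sizes, cfg$read_length)
    ta <- normalize_track(compute_coverage(iv1, cfg$chrom_sizes, r1))
    tb <- build_signal_track(r2, cfg$chrom_sizes, dedup = FALSE)
    dhmrs <- suppressMessages(call_dhmrs(ta, tb, "punctate"))
    truth <- plan$truth[plan$truth$mark == mk, , drop = FALSE]
    .fixture_cache[[key]] <- list(
      dhmrs = dhmrs, truth = truth,
      score = score_recovery(dhmrs, truth),
      mass = list(counts_a = sum(vapply(ta$counts, sum, numeric(1))),
                  widths_a = sum(iv1$end - iv1$start),
                  norm_a = sum(vapply(ta$normalized, sum, numeric(1))),
                  norm_b = sum(vapply(tb$normalized, sum, numeric(1)))))
  }
  .fixture_cache[[key]]
}
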