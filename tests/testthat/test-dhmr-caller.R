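test_that("bin t-test handles degenerate inputs by the limit rules", {
  expect_equal(paired_bin_test(c(4, 9, 2, 7, 5), c(4, 9, 2, 7, 5)), 1)
  # constant nonzero difference, zero variance
  expect_equal(paired_bin_test(1:5, 3:7), 0)
})

test_that("bin t-test matches the reference paired t-test", {
  a <- c(10, 12, 9, 11, 10)
  b <- c(20, 25, 19, 22, 21)
  ref <- stats::t.test(a, b, paired = TRUE)$p.value
  expect_equal(paired_bin_test(a, b), ref, tolerance = 1e-10)
  set.seed(99)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    x <- stats::rnorm(n, 10); y <- stats::rnorm(n, 10 + stats::runif(1, 0, 2))
    expect_equal(paired_bin_test(x, y),
                 stats::t.test(x, y, paired = TRUE)$p.value, tolerance = 1e-10)
    expect_equal(paired_bin_test(x, y, test = "welch"),
                 stats::t.test(x, y)$p.value, tolerance = 1e-10)
  }
  expect_error(paired_bin_test(1:5, 1:4), "unequal")
})

test_that("scan emits nothing on identical tracks and tight regions on stretches", {
  flat <- make_binned(rep(5, 300))
  expect_equal(nrow(seed_extend_scan(flat, flat)), 0L)

  # a single 20-bin offset stretch against matched noise: exactly one
  # candidate overlaps it and covers approximately those 20 bins (noise
  # seeds may add small unrelated candidates at alpha = 0.01)
  set.seed(5)
  pair <- random_binned_pair(400, data.frame(first = 101, last = 120,
                                             offset = 15))
  got <- seed_extend_scan(pair$a, pair$b)
  hit <- got[got$start < 120 * 100 & got$end > 100 * 100, ]
  expect_equal(nrow(hit), 1L)
  expect_lte(abs(hit$start - 100 * 100), 5 * 100)
  expect_lte(abs(hit$end - 120 * 100), 5 * 100)
  expect_lte(hit$scan_p, 0.01)
  orc <- oracle_scan_walk(pair$a$values$chrT, pair$b$values$chrT, scan_params())
  expect_equal(got$start, (orc$first_bin - 1) * 100)
  expect_equal(got$end, orc$last_bin * 100)

  # a 60-bin stretch is capped at 50 bins per candidate before merging
  set.seed(6)
  pair2 <- random_binned_pair(400, data.frame(first = 101, last = 160,
                                              offset = 15))
  got2 <- seed_extend_scan(pair2$a, pair2$b)
  expect_true(all((got2$end - got2$start) / 100 <= 50))
  expect_gte(nrow(got2), 2L)
})

test_that("scan agrees with the exhaustive-window brute-force oracle", {
  set.seed(21)
  for (rep in 1:6) {
    stretches <- if (rep %% 2 == 0) {
      data.frame(first = c(200, 900), last = c(220, 1000), offset = c(8, -10))
    } else NULL
    pair <- random_binned_pair(1500, stretches)
    got <- seed_extend_scan(pair$a, pair$b)
    walk <- oracle_scan_walk(pair$a$values$chrT, pair$b$values$chrT,
                             scan_params())
    expect_equal(got$start, (walk$first_bin - 1) * 100)
    expect_equal(got$end, walk$last_bin * 100)
    expect_equal(got$scan_p, walk$scan_p, tolerance = 1e-9)
    # no differential stretch found by any-seed enumeration is missed
    all_seeds <- oracle_scan_all_seeds(pair$a$values$chrT,
                                       pair$b$values$chrT, scan_params())
    if (!is.null(all_seeds)) {
      for (k in seq_len(nrow(all_seeds))) {
        os <- (all_seeds$first_bin[k] - 1) * 100
        oe <- all_seeds$last_bin[k] * 100
        expect_true(any(got$start < oe & os < got$end))
      }
    }
  }
})

test_that("scan p-values are invariant under common positive scaling", {
  set.seed(31)
  pair <- random_binned_pair(600, data.frame(first = 301, last = 315,
                                             offset = 9))
  g1 <- seed_extend_scan(pair$a, pair$b)
  pair$a$values$chrT <- 37.5 * pair$a$values$chrT
  pair$b$values$chrT <- 37.5 * pair$b$values$chrT
  g2 <- seed_extend_scan(pair$a, pair$b)
  expect_equal(g1$start, g2$start)
  expect_equal(g1$end, g2$end)
  expect_equal(g1$scan_p, g2$scan_p, tolerance = 1e-9)
})

test_that("fold-change filter applies the pseudocounted ratio rule", {
  mk_reg <- function(ma, mb) {
    ta <- make_track(rep(ma, 500))
    tb <- make_track(rep(mb, 500))
    reg <- data.frame(chrom = "chrT", start = 0, end = 500, scan_p = 1e-4)
    fold_change_filter(reg, ta, tb)
  }
  kept <- mk_reg(10, 25)    # ratio 26/11 = 2.364
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$fold_change, 26 / 11)
  expect_equal(nrow(mk_reg(10, 15)), 0L)  # 16/11 = 1.45
  zero <- mk_reg(0, 5)      # pseudocount guards the division
  expect_equal(zero$fold_change, 6)
})

test_that("merging is transitive below the gap, idempotent, and oracle-equal", {
  r <- data.frame(chrom = "chrT", start = c(0, 900), end = c(200, 1000))
  m <- merge_candidates(r, 1000)
  expect_equal(m[, c("start", "end")], data.frame(start = 0, end = 1000))
  r2 <- data.frame(chrom = "chrT", start = c(0, 1300), end = c(200, 1400))
  expect_equal(nrow(merge_candidates(r2, 1000)), 2L)

  set.seed(13)
  s <- sort(sample(0:100000, 50))
  raw <- data.frame(chrom = "chrT", start = s, end = s + sample(100:2000, 50,
                                                                replace = TRUE))
  got <- merge_candidates(raw, 1000)
  orc <- oracle_merge(raw[, c("start", "end")], 1000)
  expect_equal(got$start, orc$start)
  expect_equal(got$end, orc$end)
  # pairwise gaps >= merge_gap and idempotence
  expect_true(all(diff(got$start) - (got$end[-nrow(got)] - got$start[-nrow(got)]) >= 1000))
  expect_equal(merge_candidates(got, 1000)[, c("start", "end")],
               got[, c("start", "end")])
})

test_that("local background is the read-start rate of the covering 10-kb window", {
  # uniform 0.2 starts/bp
  tr <- make_track(counts = rep(1, 20000),
                   starts = rep(c(1, 0, 0, 0, 0), 4000) * 0 + 0.2)
  expect_equal(local_background(tr, "chrT", 5000, 5200), 0.2)
  # near-edge region: nominal [-4900, 5100) clips to [0, 5100)
  st <- rep(0, 12000); st[1:5100] <- 1   # 5100 starts in the clipped window
  tr2 <- make_track(counts = rep(1, 12000), starts = st)
  expect_equal(local_background(tr2, "chrT", 0, 200), 5100 / 5100)
  # a region wider than the extent is its own background window
  st3 <- rep(0, 40000); st3[20001:32000] <- 1
  tr3 <- make_track(counts = rep(1, 40000), starts = st3)
  expect_equal(local_background(tr3, "chrT", 20000, 32000), 1)
})

test_that("Poisson window enrichment matches the series-summation oracle", {
  expect_equal(poisson_upper_tail(0, 5), 1)
  expect_equal(poisson_upper_tail(20, 10), oracle_poisson_tail(20, 10),
               tolerance = 1e-12)
  # lambda = 0 conventions
  expect_equal(poisson_upper_tail(0, 0), 1)
  expect_equal(poisson_upper_tail(3, 0), 0)

  # window-level call: a dense 100-bp cluster in a sparse background
  st <- rep(0, 20000); st[10001:10100] <- c(rep(1, 30), rep(0, 70))
  tr <- make_track(counts = rep(1, 20000), starts = st)
  lam <- local_background(tr, "chrT", 10000, 10500)
  res <- poisson_enrich_windows(tr, "chrT", 10000, 10500, lam, alpha = 1e-5)
  expect_true(res$enriched)
  expect_equal(res$min_p, oracle_poisson_tail(30, lam * 100), tolerance = 1e-12)
})

test_that("enrichment filter keeps regions enriched in at least one sample", {
  mk_starts <- function(dense) {
    st <- rep(0, 30000)
    if (dense) st[15001:15200] <- 1   # 200 clustered starts
    st
  }
  base <- rep(0, 30000); base[seq(1, 30000, by = 20)] <- 1  # 0.05/bp
  ta <- make_track(counts = rep(1, 30000), starts = base)
  tb <- make_track(counts = rep(4, 30000), starts = base + mk_starts(TRUE))
  reg <- data.frame(chrom = "chrT", start = 15000, end = 15500,
                    scan_p = 1e-6, mean_a = 1, mean_b = 4, fold_change = 2.5)
  out <- enrichment_filter(reg, ta, tb, scan_params(), alpha = 1e-5)
  expect_equal(nrow(out), 1L)
  expect_false(out$enriched_a)
  expect_true(out$enriched_b)
  expect_equal(out$direction, "up")
  # enriched in neither sample: dropped
  tb2 <- make_track(counts = rep(4, 30000), starts = base)
  out2 <- enrichment_filter(reg, ta, tb2, scan_params(), alpha = 1e-5)
  expect_equal(nrow(out2), 0L)
  # strict both-samples mode drops one-sided enrichment
  out3 <- enrichment_filter(reg, ta, tb, scan_params(enrich_mode = "both"),
                            alpha = 1e-5)
  expect_equal(nrow(out3), 0L)
})

test_that("calling is empty on identical tracks and symmetric under swap", {
  fx <- smoke_fixture()
  cs <- read_chrom_sizes(fx$paths$chrom_sizes)
  r1 <- read_aligned_reads(fx$paths$H3K4me3_cond1)
  r2 <- read_aligned_reads(fx$paths$H3K4me3_cond2)
  ta <- build_signal_track(r1, cs)
  tb <- build_signal_track(r2, cs)
  expect_equal(nrow(suppressMessages(call_dhmrs(ta, ta, "punctate"))), 0L)

  ab <- suppressMessages(call_dhmrs(ta, tb, "punctate"))
  ba <- suppressMessages(call_dhmrs(tb, ta, "punctate"))
  expect_equal(ab$start, ba$start)
  expect_equal(ab$end, ba$end)
  expect_equal(ab$direction, ifelse(ba$direction == "up", "down", "up"))
  expect_equal(ab$mean_a, ba$mean_b)
  expect_error(call_dhmrs(ta, tb, "pointy"), "arg")
})

test_that("every emitted DHMR satisfies the record-level contract", {
  fx <- smoke_fixture()
  cs <- read_chrom_sizes(fx$paths$chrom_sizes)
  ta <- build_signal_track(read_aligned_reads(fx$paths$H3K4me3_cond1), cs)
  tb <- build_signal_track(read_aligned_reads(fx$paths$H3K4me3_cond2), cs)
  d <- suppressMessages(call_dhmrs(ta, tb, "punctate"))
  expect_gt(nrow(d), 0L)
  expect_true(all(d$end > d$start))
  expect_true(all(d$fold_change >= 2))
  expect_true(all(d$enriched_a | d$enriched_b))
  if (nrow(d) > 1) {
    gaps <- d$start[-1] - d$end[-nrow(d)]
    expect_true(all(gaps >= 1000))
  }
  counts <- attr(d, "stage_counts")
  expect_true(all(diff(counts) <= 0))  # survivor counts never increase
})
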