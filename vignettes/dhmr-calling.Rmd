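---
title: "Calling differential histone modification regions with dhmrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differential histone modification regions with dhmrscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhmrscan)
```

## The problem

During TGF-β1-induced epithelial–mesenchymal transition (EMT), histone
modifications such as H3K9ac, H3K4me3, H3K27me3 and H3K9me3 are reprogrammed
genome-wide, and drugs like sorafenib can reverse part of that
reprogramming. Quantifying this requires three steps: turning aligned
ChIP-seq reads into comparable signal tracks, finding the genomic regions
where a mark differs between two conditions (differential histone
modification regions, DHMRs), and summarizing those regions at gene
promoters (differential histone modification genes, DHMGs) so that changes
induced by a treatment can be classified as reversed or retained under a
second (drug) condition. `dhmrscan` implements this pipeline for a
three-sample design — control, treated, and treated+drug — together with a
ground-truthed synthetic read generator used to validate every stage.

## From reads to signal tracks

Aligned single-end reads (BED6 or SAM; only chromosome, start and strand
are used) are processed as follows:

1. **Deduplication.** Reads sharing a (chromosome, start, strand) key are
   collapsed to one, removing PCR amplification bias. Strand is part of the
   key because opposite-strand reads at one coordinate come from distinct
   fragments; a strand-agnostic mode exists for libraries where that
   assumption fails.
2. **Extension.** Each read is anchored at its 5′ end and extended 3′-ward
   to 150 bp, the approximate fragment size of a sonicated ChIP library
   sequenced at SE50. Intervals are clipped at chromosome ends.
3. **Coverage.** The signal at a base is the number of extended reads
   covering it, so the total signal mass equals the summed interval widths
   exactly.
4. **Normalization.** Each sample is rescaled so its genome-wide signal
   mass is 10^9 (the equivalent of 1 Gbp of sequence), making tracks
   directly comparable across libraries of different depth. The target is a
   parameter (`target_total`) for sensitivity analyses.

All coordinates are 0-based half-open internally; BED/bedGraph conventions
are preserved on disk and GTF's 1-based closed coordinates are converted
only at the I/O boundary.

## The three-criterion DHMR caller

`call_dhmrs()` compares two normalized tracks with three sequential
criteria.

**Criterion 1 — sliding-window t-test scan.** The genome is partitioned
into 100-bp bins and each bin gets the mean normalized signal. A 5-bin
window is tested at every position with a two-sided *paired* t-test on the
per-bin differences (bins are positionally matched, which is why the paired
form is appropriate; a Welch two-sample variant is available via
`scan_params(test = "welch")` for sensitivity analysis). Where the window's
p-value falls below 0.01 it becomes a seed and slides rightward in 1-bin
steps; the candidate region accumulates covered bins for as long as each
slid window stays at or below 0.01, and stops when a window exceeds the
threshold or the region reaches 50 bins. Scanning resumes after the emitted
region.

Two readings of the "slide until non-significant" rule were considered:
re-testing the *whole growing window* at each step, versus testing the
*current 5-bin window* as it slides. We implement the sliding reading. The
growing-window variant turns out to be degenerate in practice: once a
window contains a strong differential stretch, adding background bins
almost never lifts the whole-window p-value above the threshold, so every
detection runs to the 50-bin cap regardless of the true extent of the
difference. The overshoot then dilutes the region means and causes the
fold-change criterion below to reject genuinely differential regions (a
2-kb four-fold spike embedded in a 5-kb emitted region averages out near
the 2-fold cutoff). Under the sliding reading the trailing test window
always covers the most recent 5 bins, so region boundaries track the actual
end of the differential stretch; on simulated 2-kb spikes the emitted
regions have a median width of about 2.1 kb.

Degenerate windows follow the limits of the t statistic: zero-variance
differences with zero mean give p = 1 (no evidence of difference),
zero-variance nonzero mean gives p = 0. The degeneracy test is relative to
the magnitude of the differences, which keeps scan p-values exactly
invariant under common positive rescaling of both tracks.

**Criterion 2 — fold change and merging.** A candidate is kept when

\[
\max\!\left(\frac{\bar s_b + \psi}{\bar s_a + \psi},
            \frac{\bar s_a + \psi}{\bar s_b + \psi}\right) \ge 2,
\]

where the means are over normalized per-base signal in the region and the
pseudocount ψ (default 1.0 normalized units, roughly 1% of typical
background signal) guards empty regions. Surviving candidates separated by
gaps under 1 kb are merged transitively, irrespective of direction (the
direction of a merged region is recomputed from its overall means).
Because merging can join candidates across intervening background, the
fold criterion is re-imposed on the merged extents, so every reported DHMR
satisfies it record-by-record.

**Criterion 3 — Poisson enrichment against a local background.** A
differential region should also be *enriched* over its neighborhood in at
least one sample, otherwise a mean shift in near-background noise could
pass. For each sample, the background rate λ_bp is the mean read-start
rate in a 10-kb window centered on the region (widened to the region
itself when the region is larger, clipped at chromosome ends). A 100-bp
window slides across the region in 1-bp steps; a window with k read starts
is enriched when the upper-tail Poisson probability P(X ≥ k | λ_bp·100)
falls below the mark-class threshold: 10⁻⁵ for punctate, promoter-focused
marks (H3K4me3, H3K9ac), 10⁻³ for broad, domain-scale marks (H3K27me3,
H3K9me3). The test uses deduplicated read-start counts rather than
extended per-base coverage because extension makes adjacent bases serially
correlated, which would break the Poisson approximation.

A region is kept when it contains at least one enriched window in at least
one sample. Requiring enrichment in *both* samples would discard clean
gain or loss events, which are typically enriched only on their high side;
the strict-both reading is available via `scan_params(enrich_mode =
"both")`. No multiple-testing correction is applied anywhere: the
thresholds (0.01, 10⁻⁵, 10⁻³) are used raw, as fixed operating points of
the procedure.

All constants live in `scan_params()`:

| parameter | default | meaning |
|---|---|---|
| `bin_size` | 100 bp | scan bin width |
| `seed_bins` | 5 | seed window size |
| `max_bins` | 50 | region cap in bins |
| `scan_alpha` | 0.01 | t-test threshold |
| `min_fold` | 2.0 | fold-change cutoff |
| `merge_gap` | 1,000 bp | merge gap |
| `background_extent` | 10,000 bp | Poisson background window |
| `enrich_window`, `enrich_step` | 100 bp, 1 bp | enrichment window/step |
| `enrich_alpha_punctate/broad` | 10⁻⁵ / 10⁻³ | enrichment thresholds |
| `pseudocount` | 1.0 | fold-change guard, normalized units |

## Promoters, DHMGs and reversal

The promoter is the 4-kb window from 2,000 bp upstream to 2,000 bp
downstream of the TSS (strand selects which end of the transcript span is
the TSS). A gene with at least one DHMR overlapping its promoter by ≥1 bp
is a DHMG. When several DHMRs of mixed direction hit one promoter, the
gene takes the direction of the DHMR with the largest promoter overlap,
ties broken by the larger absolute mean difference; genes with multiple
TSSs are tested once per distinct TSS and reported at the gene level.

`classify_reversal()` cross-matches the control-vs-treated DHMGs with the
control-vs-treated+drug DHMGs: genes in both sets are *common*; common
genes whose direction flips are *reciprocal*; genes differential only
under treatment are *treatment-specific* (their change vanishes once the
drug is added). The *reversed* set is reciprocal ∪ treatment-specific, and
its share of the treatment DHMGs is the reversed fraction. Reciprocal
status requires strict direction opposition, not magnitude reversal. At
the region level, `dhmr_overlap_fraction()` reports the share of
treatment DHMRs with no (≥1 bp) overlap among the drug-condition DHMRs —
the regions that "disappear" under the drug. Both set operations use plain
interval overlap rather than reciprocal-fraction overlap: it is the
simplest reading of a Venn construction, and the package's acceptance of
it is validated against ground truth in simulation.

Signal summaries around genes use a common relative coordinate: 25 equal
portions over the 5-kb upstream flank, 100 over the gene body, 25 over the
downstream flank, minus-strand genes flipped. Promoter-level differences
between two samples are assessed with an unpaired large-sample z-test on
per-gene promoter means, z = (x̄ − ȳ)/√(s²_x/n + s²_y/n), flagged at
p < 10⁻⁵.

## What the synthetic generator emulates

`sim_config()` defines a three-condition study on a synthetic genome
(default: one 10-Mb chromosome). Read starts follow an inhomogeneous
Poisson process with:

- a uniform background of 0.05 read starts/bp (≈500,000 reads per 10-Mb
  sample, scaled down from tens of millions of reads on a full genome
  while preserving per-base depth);
- basal, condition-independent enrichment — ×4 at TSS ± 500 bp for
  punctate marks, ×3 over gene bodies for broad marks — so the caller is
  exercised against non-differential structure;
- 100 rectangular differential spikes per mark, 2 kb wide, rate multiplied
  by `spike_fold` (default 4) in the gained condition; half of the spikes
  are gains, half losses, and half sit inside generated gene promoters so
  DHMG recovery is testable;
- a third condition that follows the control rate at a `reversal_fraction`
  share of spikes and the treated rate elsewhere;
- PCR duplicates, each read re-emitted with probability 0.2; and 50-bp
  single-end reads with Bernoulli(0.5) strands.

Spikes are placed in randomized, non-overlapping slots with pairwise gaps
of at least twice the merge gap, so distinct truth regions can never be
merged by the caller and recall/precision scoring is unambiguous: a truth
spike is recovered when a called DHMR covers at least half of it, and a
call is a false positive when it overlaps no truth spike at all. Everything
is deterministic given `rng_seed`, down to byte-identical fixture files.

One consequence of realistic deduplication is worth noting: at an in-spike
start rate of 0.2 reads/bp, about 5% of distinct fragments collide on the
same (position, strand) key and are collapsed, versus about 1% in
background, so the *realized* fold of a nominal 4-fold spike is ≈3.85.
Recovery results should be read against realized, not nominal, folds.

What the generator does **not** emulate: mappability gaps, GC and
chromatin-accessibility bias, fragment-size variation, overdispersed
(clumped) backgrounds, input/IgG control channels, or broad domains with
gradual boundaries. Passing recovery tests therefore demonstrate that the
implementation performs the stated procedure correctly and recovers
rectangular signals at realistic depth — not that the procedure is robust
to every artifact of real chromatin data.

## Numerical choices and degenerate inputs

- Zero-variance t-test windows: p = 1 when the mean difference is zero,
  p = 0 otherwise (limits of the t statistic); the zero test is relative
  (tolerance 10⁻¹³ of the mean square), preserving scale invariance.
- λ = 0 Poisson backgrounds: a window with k > 0 starts has p = 0
  (enriched by convention); k = 0 gives p = 1.
- Empty tracks cannot be normalized (hard error), and an empty treatment
  DHMG set makes the reversed fraction NA with a warning rather than 0.
- Partial terminal bins are kept and averaged over their actual width;
  dropping them would silently truncate chromosomes.
- Promoters, extension intervals and background windows are clipped at
  chromosome boundaries; metagene flank portions falling off an end are
  dropped from the average rather than zero-filled.
- The DHMR BED score is min(1000, −10·log₁₀ scan_p); `scan_p` of a region
  is the smallest p among its constituent scan windows (stable under
  merging, where constituent minima are combined).

## Problem sizes used in the test suite

The shipped tests validate the statistics against independent oracles
(naive enumeration, series summation, `stats::t.test`, quadratic interval
overlap) on small inputs, and run the full pipeline at reduced scale: a
200-kb smoke fixture for end-to-end checks, 2,000-bin track pairs for
exhaustive scan-oracle equivalence, the default 10-Mb fixture at spike
folds 1.5–8 for recovery scoring, and a 4-Mb three-condition fixture for
reversal classification at both extremes of `reversal_fraction`. These
sizes keep a full run in the low minutes on one core while leaving every
stage's statistics at realistic per-base depth.

## Known limitations

- No replicate-aware inference: each condition is a single library, as in
  the three-sample design the pipeline targets; the raw 0.01/10⁻⁵/10⁻³
  thresholds are operating points, not FDR-controlled decisions.
- The Poisson background model underestimates the variance of clumped
  real backgrounds; the generator's overdispersion is deliberately off by
  default so that the enrichment test's assumptions match the data it is
  validated on.
- Input-subtracted or IgG-controlled calling, broad-domain HMM
  segmentation and paired-end data are out of scope.
- Fold changes near the 2.0 cutoff are sensitive to the exact extent of
  the called region; regions whose realized fold straddles the cutoff can
  drop in or out between seeds.
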