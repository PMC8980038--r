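---
title: "Genome-wide differential accessibility from binned ATAC fragment ends"
author: "atacburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide differential accessibility from binned ATAC fragment ends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacburst)
```

## The problem

In ATAC-seq, a hyperactive Tn5 transposase cuts and tags accessible DNA, so
the two termini of every sequenced fragment ("read extremities") are point
estimates of accessible positions. Comparing two genotype groups of tissue
libraries — here, the design is 6 control versus 7 mutant animals, one
library per animal — raises two difficulties that shape the whole method:

1. **Tissue libraries are heterogeneous.** The proportion of subnucleosomal
   (≤ 140 bp), nucleosomal (141–280 bp) and poly-nucleosomal (≥ 281 bp)
   fragments varies strongly between animals. Because the three length
   classes carry subtly different accessibility information, libraries are
   compared on a single class — by default the subnucleosomal subset, the
   cleanest open-chromatin signal — rather than on whole datasets of
   differing composition.
2. **Effects may be small, broad and directional.** Rather than asking which
   individual peaks pass a significance threshold (hopeless at n = 6 vs 7
   with a rank test, see below), the method asks whether the *direction* of
   fold changes at the most significant intervals is biased — a genome-wide
   accessibility shift.

## The procedure

**Binning and counting.** The genome is tiled into fixed 100-bp intervals
(0-based, half-open; the last bin of each chromosome truncated). Each
fragment contributes exactly two extremities, at positions `start` and
`end − 1`; each extremity increments the bin containing it. A mammalian
2.7e9-bp genome yields 2.7e7 bins; the package keeps bins implicit until
counts are materialised. No Tn5 +4/−5 offset is applied: both termini are
already insertion-site estimates at 100-bp resolution, and a constant
offset cannot move an extremity by more than one bin.

**Library exclusion.** Libraries whose total extremity count is far below
their peers lack counts over most of the genome and only add noise; they
are excluded before any interval statistics (`min_reads`, default 1e7
extremities for full-depth mammalian libraries — about the midpoint, on a
log scale, between typical discarded (~1e6–2e6) and kept (~2e7–3e7) tissue
sub-libraries). A group left with fewer than two libraries is an error:
the rank test is undefined.

**Retention filter.** Only bins with a mean of **5 or more** raw read
extremities across kept libraries are retained (inclusive threshold). The
filter runs on raw counts — it is a data-sufficiency rule in the units the
data were observed in — before normalization.

**Normalization.** Median-of-ratios size factors are estimated on the
retained bins: `s_j = median_i(c_ij / geomean_i)` over bins with positive
counts in every library. The factors are rescaled to unit geometric mean.
Plain median-of-ratios is only idempotent up to `geomean(s)`; the rescale
makes re-estimation on a normalized matrix return factors of exactly 1,
and, being a common constant across libraries, changes neither fold
changes nor rank statistics.

**Per-interval testing.** For each retained bin, the fold change is
`FC = mean(mutant) / mean(control)` of normalized counts, and the p-value
is a two-sided Mann–Whitney test on the 6 + 7 per-library normalized
counts: the exact null distribution of U when the row is tie-free and
n ≤ 20, otherwise the mid-rank normal approximation with tie and
continuity correction (numerically identical to `wilcox.test` in both
regimes; verified against brute-force enumeration of all label
assignments in the tests). Bins with a zero control mean have undefined
FC; they are flagged and excluded from the ratio curve. No pseudocount is
added: an FC range of roughly 0.2–4.7 on real data indicates none was
used, and a pseudocount would shrink exactly the strong depletions the
method is looking for.

A structural consequence worth stating plainly: the exact two-sided
p-value floor at (6, 7) is `2 / choose(13, 6) ≈ 1.2e-3`. Far smaller
p-values can only arise from a different unit of replication (e.g. pooling
per-position counts within an interval, which trades animals for
positions). The per-library test is the defensible default; users can pool
and call `mw_test()` themselves if they accept that trade.

**The ratio curve.** Retained bins are ranked by increasing p (ties broken
by decreasing |log2 FC|, then genomic position — a deterministic order).
Over sliding windows of `W = 1000` intervals (step 1), the ratio
`r = (#FC>1) / (#FC<1)` is computed and plotted against the window's
leading p-value. Under the null, r fluctuates around 1 everywhere; a
genome-wide depletion shows as r well below 1 at low p, rising to ≈ 1 at
high p. FC exactly 1 stays in the window but counts on neither side
(measure-zero on normalized data); windows with no repressed interval
have undefined r and are flagged.

**Selection at a ratio cutoff.** "The intervals corresponding to a ratio
cutoff r*" is made operational as a **prefix rule**: all intervals ranked
before the start of the first window whose ratio exceeds r* (default
0.60). The alternative reading — the union of all windows with r ≤ r* —
is available via `mode = "windows"`. The prefix rule is the default
because the selection is then always a contiguous low-p prefix, which is
what a downstream gene-ontology analysis of "the most affected intervals"
wants.

**Annotation.** Selected or retained intervals are intersected
(any-overlap, ≥ 1 bp, half-open semantics: touching intervals do not
overlap) with gene bodies, 20-kb gene flanks, and cCRE catalogs. The
mutually exclusive gene / flank / intergenic partition gives the gene
category precedence — an interval inside a gene and inside another gene's
flank counts as genic — so the three fractions always sum to 1; inclusive
per-feature fractions are reported alongside.

## Spike-train burst metrics

The in vivo half of the package implements the standard dopamine-neuron
burst rule: a burst **opens** when two consecutive spikes are separated by
an inter-spike interval strictly below 80 ms, **extends** while ISIs stay
at or below 160 ms, and **terminates** at the first ISI strictly above
160 ms. ISIs in the 80–160 ms zone can extend an open burst but never open
one; scanning resumes after a closed burst, so a boundary spike cannot
seed the next burst. %SWB is 100 × (spikes in bursts) / (all spikes).
Firing rate and %SWB are measured on 60-s windows overlapping by 45 s
(15-s step) over a 300-s epoch — 17 windows, the arithmetic consequence
of those three constants — and summarised by the unweighted mean; a spike
belongs to a window by its timestamp, so a burst spanning a window edge
contributes only its in-window spikes. Dopamine-neuron identification
requires all four electrophysiological criteria (triphasic waveform,
duration > 2.0 ms, start-to-trough width > 1.1 ms, rate strictly between
1 and 10 Hz), and `delta_f_over_f()` implements the calcium-imaging
`(Ft − F0)/F0`.

## What the synthetic data emulates — and what it does not

`sim_config()` defines the study conditions the tests run under:

* two 5-Mb chromosomes (1e5 bins at 100 bp) — large enough for full
  W = 1000 windows while keeping a pipeline run in seconds;
* 6 control + 7 mutant libraries; optional extra under-sequenced libraries
  (~20-fold fewer fragments) to exercise the exclusion filter;
* 1200 accessible loci of 200–1500 bp with log-normal baseline strength,
  covering ~10% of the genome. The locus count is deliberately large
  relative to the window size: the regime of interest is the one where
  effect-carrying bins are commensurate with W, as in real data where the
  lowest-p windows are dominated by signal. With far fewer signal bins
  than W the first window is mostly null bins and no ranking could
  depress its ratio;
* fragment lengths from the 0.55 / 0.35 / 0.10 subnucleosomal /
  nucleosomal / poly-nucleosomal mixture, uniform within class
  (30–140 / 141–280 / 281–600 bp);
* 2e5–3e5 fragments per kept library, 20% uniform background, fragment
  midpoints jittered around locus centres (sd = width/4);
* the planted effect: 10% of loci with mutant accessibility × 0.6, 5%
  with × 1.4 — depletion-biased, the direction of interest;
* one RNG stream per library derived from the master seed, so outputs are
  byte-stable and adding a library does not perturb the others.

Simulated spike trains interleave pacemaker-like tonic firing (jittered
regular ISIs, 2 Hz) with planted bursts (intra-burst ISI ≈ 30 ms, 4–8
spikes, ≥ 1 s apart) and record exactly which spikes were planted; at
these parameters detection is essentially exact, so the ±3-point recovery
check validates the plumbing, not a noisy estimator.

Deliberately **not** modelled: Tn5 sequence/GC bias, PCR duplicates
(removed upstream in any real pipeline; the simulator is duplicate-free
by construction), mappability, chromatin-state-dependent fragment-length
coupling, and read-level errors. Passing tests therefore demonstrate the
statistical machinery and its wiring, not robustness to those artefacts.

## Numerical choices and degenerate inputs

* Retention threshold inclusive (mean ≥ 5); both the threshold and the
  inclusive/exclusive choice are arguments.
* Exact Mann–Whitney via the exact U null CDF; at `u = mn/2` the doubled
  minimal tail is capped at 1. Constant rows (zero variance) get p = 1.
* `size_factors()` errors when no bin has all-positive counts, pointing
  at the retention filter, rather than silently returning degenerate
  factors.
* Ranking ties broken deterministically (|log2 FC| desc, then position):
  two runs on the same data always produce the same curve and selection.
* Empty spike trains yield rate 0 and %SWB 0 with a message, not an error;
  unsorted spike times are an error, not silently sorted.
* Problem sizes used by the test suite: the 20-seed planted-recovery and
  null-band checks run the full default study conditions (~1.3e6 fragments
  per run); unit tests use scaled-down configs (120–250 loci, 1.5e4–3e4
  fragments) chosen to keep each property legible and the suite quick.

## Known limitations

* The per-library exact rank test cannot reach p below ~1.2e-3 at
  (6, 7); confidence tiers rather than multiple-testing-corrected calls
  are the honest output at this design, and no correction is applied.
* The prefix selection rule is one defensible operationalisation of
  "intervals corresponding to a ratio cutoff"; the windows rule can give
  a (slightly) different set when the curve is non-monotone.
* Interval statistics are per-100-bp-bin; adjacent bins from one locus are
  correlated, so bin counts are not independent discoveries.
* The simulator's locus model is symmetric and unimodal per locus; it is
  a test harness for the statistics, not a generative model of chromatin.
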