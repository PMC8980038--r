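# atacburst

Differential chromatin accessibility between two genotype groups from
paired-end ATAC-seq fragment records, plus in vivo spike-train burst
metrics. The package is aimed at labs comparing small groups of animal
tissue libraries (e.g. 6 control vs 7 mutant brain punches), where
per-peak significance is out of reach and the scientific question is a
*genome-wide directional shift* in accessibility.

## The method

Fragment termini ("read extremities") mark accessible positions. The
pipeline:

1. classifies fragments by length — subnucleosomal (ℓ ≤ 140 bp),
   nucleosomal (141–280 bp), poly-nucleosomal (ℓ ≥ 281 bp) — and analyses
   one class (default subnucleosomal);
2. counts the two extremities of each fragment (positions `start` and
   `end − 1`) over fixed 100-bp genome bins;
3. excludes under-sequenced libraries, retains bins with a mean of ≥ 5 raw
   extremities, normalizes with median-of-ratios size factors
   `s_j = median_i(c_ij / (∏_k c_ik)^{1/n})` (rescaled to unit geometric
   mean), and computes per bin the fold change
   `FC = mean(mutant)/mean(control)` with an exact two-sided Mann–Whitney
   p-value on the per-library normalized counts;
4. ranks bins by increasing p and slides a window of W = 1000 intervals
   over the ranking, computing the enhanced/repressed ratio
   `r = (#FC>1)/(#FC<1)` per window. Under no effect r ≈ 1 everywhere;
   sustained r < 1 at low p demonstrates a genome-wide accessibility
   decrease in the mutant. Intervals ranked before the first window with
   r above a cutoff (default r\* = 0.60) form the selection for downstream
   annotation;
5. annotates intervals against genes, 20-kb gene flanks and cCREs with
   half-open any-overlap semantics.

The companion electrophysiology functions implement the dopamine-neuron
burst rule (burst onset: two spikes within < 80 ms; termination: ISI
> 160 ms), %SWB (percent spikes within bursts), firing rate and %SWB on
60-s windows with 45-s overlap over 300 s (17 windows), the four-criterion
dopamine-neuron identification, and ΔF/F = (Ft − F0)/F0.

A synthetic-data module generates the full study design — 6 + 7 libraries,
fragment-length mixture, library-depth variation, planted depletion-biased
effects, bursty/tonic spike trains of known composition — so every stage
is testable end to end without downloads.

## Worked example

```r
library(atacburst)

cfg <- sim_config(seed = 42)              # 6 control vs 7 mutant libraries
sim <- simulate_fragments(cfg)            # planted: 10% loci x0.6, 5% x1.4
run <- run_pipeline(sim$libraries, sim$groups, sim$chrom_sizes,
                    min_reads = 1e5)
run
#> accessibility_run
#>   13 libraries (13 kept), 1e+05 bins, 9822 retained intervals
#>   ratio at lowest p: 0.582; 11 intervals selected at r* = 0.60
run$diff
#> Differential accessibility fit
#>   libraries: 6 control vs 7 mutant (0 excluded for low counts)
#>   intervals retained (mean >= 5): 9822 of 100000 (9.82%)
#>   fold-change range: 0.32 - 2.55; p-value range: 0.0012 - 1
run$curve
#> ratio_curve: 8823 windows of 1000 p-ranked intervals (step 1)
#>   ratio at lowest p: 0.582; range 0.582 - 1.469
```

9,822 of 1e5 bins carry enough signal to compare. The ratio at the
lowest-p windows is 0.582 — a clear excess of repressed over enhanced
intervals among the most significant bins, the planted genome-wide
depletion — and rises toward 1 along the ranking (`plot(run$curve)` draws
the curve against log10 p). The 11 intervals ranked before the first
window crossing r\* = 0.60 form the selection. On a null simulation
(`f_dep = 0, f_enh = 0`) the same curve stays inside the binomial
fluctuation band around 1 and the selection is empty.

```r
st <- simulate_spike_trains(n_neurons = 2, seed = 42)
detect_bursts(st$trains[[1]])
#> burst_segmentation: 45 burst(s) over 811 spikes
windowed_metrics(st$trains[[1]])
#> windowed_metrics: 17 windows; mean rate 2.70 Hz; mean %SWB 34.2 (overall 34.3); 45 bursts
```

The recovered %SWB matches the planted burst fraction recorded in
`st$truth`.

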