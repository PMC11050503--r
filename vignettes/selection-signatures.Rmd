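---
title: "Detecting selection signatures in multi-population genotype data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection signatures in multi-population genotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

# Scope and model

`sweepscan` scans multi-population diploid SNP data for footprints of
selection. It was designed around the classic livestock setting: a handful of
breeds (here, three chicken populations of 17–20 males each) genotyped at
high marker density, compared by three complementary statistics, and the
agreeing regions annotated against gene and QTL intervals.

Three signals are computed from one shared in-memory genotype
representation:

1. **Windowed ZFst.** Per-SNP Weir–Cockerham (1984) FST between a pair of
   populations, averaged over 50 kb windows sliding by 10 kb, then
   genome-wide Z-standardised: `ZFst = (Fst - mean) / sd` over all retained
   windows of the scan. Windows in the top 0.1% of ZFst are outliers, and
   outlier windows that overlap or abut are merged into blocks; a block
   needs at least two member windows.
2. **FLK.** Allele-frequency differentiation in excess of neutral drift
   under a population tree. Reynolds distances are neighbour-joined,
   midpoint-rooted, and converted into the drift covariance `F` (shared
   branch length from the root). For marker frequencies `p`,
   `p0 = (1'F^-1 p)/(1'F^-1 1)` estimates the ancestral frequency and
   `T = (p - p0)' [p0(1-p0) F]^-1 (p - p0)` is chi-squared with
   `n_pops - 1` degrees of freedom under neutrality. Markers below a
   `p < 1e-5` cutoff are merged into regions; a stringent tier applies the
   Bonferroni cutoff (e.g. `-log10(0.05/1786000) = 7.55` at the scale of a
   resequencing study).
3. **ROH.** Consecutive-run detection of runs of homozygosity: a run must
   hold at least 50 SNPs, span at least 0.5 Mb, contain at most 21
   heterozygous and 21 missing calls, and have no adjacent-SNP gap over
   1 Mb. FROH is the summed run length over the SNP-covered autosomal
   length. ROH islands are maximal marker runs where more than half of a
   population's individuals lie inside a run.

Consensus regions are connected components of overlapping evidence intervals
supported by **two or more methods, or two or more distinct population
pairs**; they are then intersected (at ≥ 1 bp) with gene and QTL intervals
and QTL hits are tallied by trait class.

# The synthetic-data generator

No genotype data are bundled; every test and experiment simulates its own
dataset with a known truth set.

* **Drift.** Each population's allele frequency at a marker is a Beta draw
  with mean equal to the ancestral frequency (uniform on `[0.05, 0.95]`)
  and variance `F p (1-p)` — the Balding–Nichols model. `F` is exactly the
  expected pairwise FST scale, which the test suite verifies by Monte Carlo
  (mean Weir–Cockerham estimate within ±0.02 of `F = 0.1` over ~50k
  markers).
* **Markers.** Positions are a Poisson process per chromosome (sorted,
  deduplicated), at densities of 0.4–2 SNPs/kb in the shipped experiments.
* **Sweeps.** Inside a sweep interval the target population's frequency is
  forced to `post_sweep_frequency` (default 0.98), oriented per marker so
  that differentiation from the other populations increases. Background
  windows are untouched because the orientation flips reference/alternate
  bookkeeping rather than other populations' frequencies.
* **Autozygosity.** Tracts are implanted per individual by copying one
  haplotype onto the other, with lengths drawn from the 0.5–2 / 2–4 /
  4–8 Mb class mixture and uniform genomic positions; the truth file
  records every tract.
* **What it does not emulate.** There is no linkage disequilibrium outside
  implanted tracts (an optional adjacent-allele copy probability `rho`
  exists, default 0), no recombination map, no coalescent ancestry and no
  genotyping-error model. Passing tests therefore demonstrate correctness
  of the statistics and the recovery machinery under drift + Hardy–Weinberg
  sampling, not robustness to LD structure in real resequencing data. The
  LD-decay diagnostic illustrates this honestly: on simulated data it
  recommends the smallest window from the first distance bin.

Defaults declared once: `missing_rate = 0.01` and a uniform ancestral
frequency spectrum (the emulated study reports neither quantity); sample
sizes 20/20/17 mirror the study design.

# Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| window / step | 50 kb / 10 kb | window of the emulated design, chosen there by LD decay |
| `top_fraction` | 0.001 | "top 0.1%" outlier rule |
| `min_snps_per_window` | 10 | sparse windows give unstable means; dropped windows are counted |
| FLK `maf_min` | 0.05 | rare pooled alleles break the chi-squared approximation |
| ROH `min_snp`, `min_length_bp` | 50, 0.5 Mb | excludes short chance runs; the Lencz/Purfield-style formula `l = ceil(ln(alpha/(ns*ni))/ln(1-het))` is exposed for comparison |
| ROH `max_opp_run`, `max_miss_run` | 21, 21 | per-run totals (consecutive-method convention) |
| ROH `max_gap_bp` | 1 Mb | convention of the consecutive-run implementations |
| islands threshold | 0.5 (strict `>`) | "more than half of samples" |
| bootstrap `n_boot` | 1000 | percentile CI over loci for uFIS |
| hapcluster `K`, window, `n_perm` | 5, 20 markers, 1000 | see below |

A practical interaction worth knowing: with per-run totals fixed at 21, the
expected number of missing calls in a run grows with SNP density, so at
~2 SNPs/kb and 1% missingness runs fragment at roughly 1 Mb. The analysis
scripts use deep-coverage-like missingness (0.2%) for the showcase dataset
so implanted 4–8 Mb tracts survive intact; the recovery experiments use the
default 1% and measure coverage, which is robust to fragmentation.

# Design choices that were genuinely open

* **FST estimator and windowing.** Weir–Cockerham (1984) per SNP, window
  mean of per-SNP ratios (not ratio of sums), negative estimates retained
  so window means stay unbiased; `sigma` of the Z-transform is the sample
  (n−1) standard deviation. A two-population closed form is used; an
  independently coded textbook implementation must agree to 1e-12 in the
  tests.
* **Outlier threshold.** Nearest-rank: the `ceiling(f * n)` largest window
  Z-scores are selected, ties at the threshold included. Whether the top
  0.1% is taken per pair or pooled across pairs is not decidable from the
  emulated design; per pair is implemented.
* **Kinship rooting.** The three breeds contain no outgroup, so the
  Reynolds-distance NJ tree is midpoint-rooted. Midpoint rooting
  equalises root-to-tip paths and can misallocate drift between an
  isolated, strongly drifted population and the rest; this shifts `F` but
  not the null point `T = 0`, and the FLK calibration experiment uses the
  known simulation kinship precisely to separate statistic calibration
  from kinship estimation.
* **Haplotype-level test.** The fastPHASE LD-model clustering of hapFLK is
  not reimplemented. The window statistic here clusters haplotypes by
  k-medoids on Hamming distance, sums single-cluster FLK statistics, and
  calibrates by permuting individuals across populations:
  `p = (1 + #{perm >= obs})/(1 + n_perm)`. It is named as a
  haplotype-cluster analogue everywhere, never as hapFLK.
* **Evidence merging.** The "two pairs of breeds" disjunct counts distinct
  population pairs (records tagged with a pair, i.e. the pairwise ZFst
  scans); a duplicate of the same pair does not qualify. Overlap threshold
  for merging is ≥ 1 bp — none is stated in the emulated design.
* **Mb lengths.** `(end - start)/1e6`, rounded half-up to 3 decimals. This
  reproduces every printed region and island length the package's tests
  assert; the +1 bp of inclusive coordinates is below rounding resolution.
* **uFIS.** Ratio of means (`1 - mean(Ho)/mean(uHE)`), matching the
  behaviour of the standard diversity packages; per-locus ratio averaging
  is unstable at low-diversity loci. The bootstrap resamples loci, not
  individuals, and the reported SE for the diversity table is the SD over
  loci divided by `sqrt(#loci)`, labelled as such.

# Numerical and degenerate-input conventions

* `z_transform` errors on constant window means; outputs re-standardise to
  mean 0 / sd 1 within 1e-9 by construction.
* `flk_stat` skips (and counts) markers whose GLS ancestral-frequency
  estimate lands on 0 or 1; a singular kinship matrix is an error.
* The ROH scan is greedy left-to-right with restart after each emitted run
  (advance-by-one otherwise); its equivalence to a brute-force oracle that
  re-evaluates every interval under the same acceptance rule is a
  property-style test over hundreds of random instances, targeting
  implementation faults rather than alternative run semantics.
* ROH length classes are left-open/right-closed — a 2 Mb run belongs to
  0.5–2 Mb; segments above the last bound go to a logged overflow class.
  Run length is `end - start + 1` internally; reporting rounds to 3
  decimals, below which the convention is invisible.
* Negative NJ branch lengths are clamped to zero and counted.
* PCA mean-imputes missing genotypes after centering (deterministic,
  standard GRM practice) and drops monomorphic markers.
* Rarefaction size `g` defaults to the minimum *typed* gene-copy count over
  loci and populations, so the subsample is always well defined with
  missing data.

# Experiment scales

The shipped experiments are sized for a single CPU: ROH oracle equivalence
on 500 instances of ≤ 200 SNPs; sweep recovery on one 50 Mb chromosome at
2 SNPs/kb (three 70 kb sweeps, 3 × 20 samples); neutral false-positive
behaviour over 100 seeded 2-population scans of ~5000 windows; FLK
calibration on ~20k markers; FROH recovery with ~35% implanted coverage;
uFIS CI calibration over 50 replicates of 10k loci. One deliberate design
detail: the recovery sweeps are 70 kb and aligned to the 10 kb window grid,
so each sweep saturates exactly three 50 kb windows and the two sweeps
competing within a breed pair together fill that pair's top-0.1% budget
(~6 windows of ~5000) — partially covered shoulder windows cannot displace
either cluster, which makes truth recovery a property of the method rather
than of a lucky seed.

# Known limitations

* Single-SNP FLK becomes anticonservative under strong drift (heavy-tailed
  Beta frequency distributions) and with small sample sizes, since the
  drift covariance ignores binomial sampling of individuals; the stringent
  Bonferroni tier and the consensus rule absorb most of the excess. The
  calibration experiment feeds population frequencies, where the chi-squared
  null holds.
* Midpoint rooting (above) biases `F` when one population is much more
  drifted than the rest.
* Blocks and regions carry the population pair, not a single attributed
  breed; no attribution heuristic is implemented.
* ROH islands require > 50% incidence within a population of ≥ 2 samples;
  with uniformly placed tracts, islands are rare unless autozygosity is
  heavy — matching the biology the threshold encodes.
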