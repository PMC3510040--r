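---
title: "Detecting regions of homozygosity from re-sequencing data"
author: "rohscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting regions of homozygosity from re-sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscape)
```

## The model

A diploid individual whose two haplotypes are identical by descent over a
segment shows essentially no heterozygous calls there. `rohscape` treats
ROH detection as a one-dimensional segmentation problem on a per-bin
heterozygosity signal, with three features that distinguish it from naive
thresholding:

1. **Coverage correction.** At ~8× depth a substantial fraction of bases
   fails the per-site depth window `[min_dp, max_dp]`, and heterozygous
   calls at those bases are untrustworthy and discarded. Dividing the raw
   count by the covered fraction (`snpbin = snp_count * bin_size /
   covered_bp`) makes bins with different effective coverage comparable.
   The correction is unbiased as long as coverage is independent of
   heterozygosity, which holds for mapping-driven dropout; it inflates
   noise in poorly covered bins, which is why bins under `cov_frac` (10%)
   covered bases are excluded from every average rather than corrected.
2. **An individual-relative threshold.** All thresholds are multiples of
   the individual's own genomic average snpbin, not population allele
   frequencies. Individuals differ greatly in background heterozygosity
   and sampling across populations is uneven, so an individual-relative
   yardstick is the only one that treats a diverse and an inbred genome
   symmetrically. The absolute floor `fdr_per_bin + mu_per_bin` exists
   because for very homozygous genomes a quarter of the genomic average
   would drop below the spurious-call rate of variant calling itself.
3. **Local error tolerance.** Assembly and alignment artefacts produce
   isolated bins with high apparent heterozygosity inside genuine ROHs,
   and true autozygous tracts accumulate new mutations over time. The
   relaxation rule retains an aberrant bin (or a contiguous run of them)
   when three conditions hold; otherwise the stretch splits at that bin.

The caller composes `candidate_bins` (windows below the average, forward
and reverse), `concatenate_stretches`, `apply_threshold_and_relaxation`,
`apply_coverage_rules` and `classify_roh`; `call_rohs` is that
composition.

## Parameters

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `bin_size` | bp | 10 000 | resolution/noise compromise at ~8×: ~17 het SNPs per bin at 1.7 SNPs/kb |
| `window_len` | bins | 10 | candidate windows of 100 kb smooth Poisson noise without erasing medium ROHs |
| `rel_threshold` | × genomic average | 0.25 | calibrated: observed stretches diverge from genome-wide permutations only below this relative level (see below) |
| `fdr_per_bin` | SNPs/bin | 2.0 | expected spurious heterozygous calls per bin; estimable from array-vs-sequence genotype discordance and configurable |
| `mu_per_bp` | mutations/bp | 2.5e-8 | mammalian-scale mutation rate; contributes `2.5e-4` SNPs per 10-kb bin |
| `relax_bin_cap_factor` | × average | 2 | an aberrant bin above twice the average is no longer plausibly a local artefact |
| `relax_window_cap_factor` | × average | 2/3 | its 10-bin neighbourhood must still be clearly below-average terrain |
| `max_uncovered_frac` | fraction | 2/3 | at low coverage, stricter limits fragment true ROHs; looser ones fabricate them from missingness |
| `cov_frac` | fraction of bin | 0.10 | same trade-off at the bin level |
| `min_roh_bp` | bp | 10 000 | one bin; smaller calls are unidentifiable at this resolution |
| size classes | bp | <1e5, >5e6 | small/medium/large; strict outer bounds, both boundaries belong to medium |

`depth_filter()` defaults to `min_dp = 7` with `max_dp` resolved to twice
the individual's length-weighted mean track depth, excluding collapsed
repeats; indels are never counted.

## Calibration of the relative threshold

`permutation_calibration()` shuffles the covered bins' snpbin values
genome-wide (the coverage mask stays in place, so the null preserves the
missingness structure) and compares candidate-stretch length
distributions per 0.05-wide level of the stretch mean relative to the
genomic average, using the two-sample Kolmogorov–Smirnov distance. Two
numerical choices matter:

* Candidate runs are additionally broken at covered bins that are not
  themselves below the genomic average. Without this, every stretch
  absorbs average-level flanking bins (about half of all background bins
  sit in some below-average window), diluting all stretch means toward 1
  and masking the separation the calibration is meant to display.
* Levels with no stretches on either side report distance 0; levels with
  stretches on one side only report `NA` — an asymmetry is itself
  informative and should not be averaged away as a distance.

On constant grids the calibration is exactly 0 everywhere (no window is
strictly below a constant average), and it is deterministic given a seed.

## Numerical conventions and degenerate inputs

* All intervals (bins, ROHs, tracts, genes, regions) are 0-based
  half-open; VCF positions and PLINK `.hom` coordinates are converted on
  ingest. IRanges conversions happen only at call sites.
* The terminal bin of a chromosome keeps its true (shorter) width;
  coverage flags compare `covered_bp` against the actual width, while the
  snpbin correction still scales to `bin_size` so that units stay "per
  10 kb covered".
* Strict inequality for candidate windows (`< average`): a constant
  genome yields no candidates.
* The relaxation decision for one aberrant run excludes *all* aberrant
  bins from the "surrounding stretch" mean, making the accept/split
  decision independent of evaluation order; condition (b) enumerates only
  windows inside the stretch, with a stretch shorter than `window_len`
  acting as its own single window. Runs of adjacent aberrant bins are
  evaluated jointly.
* Chromosomes shorter than `window_len` bins yield no ROHs; stretches
  shorter than the window can still be candidates through windows
  extending beyond them.
* Reported window means use half-away-from-zero rounding for display
  (e.g. 4.25 → 4.3); all comparisons use full precision.
* A genomic average of zero (no heterozygosity anywhere) stops the caller
  with a diagnostic — every relative threshold would be degenerate.
  `pi_outside` over a genome fully inside ROHs returns `NA` with a
  warning. `compare_methods` with fewer than two usable pairs reports an
  `NA` R².
* `window_mode = "anchored"` (forward/reverse windows anchored at the
  bin) is the default; `"any"` (any window containing the bin) is a
  strictly more permissive superset exposed for comparison.

## Open design choices

* **Threshold scope.** The per-bin reading (a cap on each ROH bin, with
  relaxation) and the per-stretch reading (a cap on the stretch mean) are
  both enforced — the conservative intersection of the two.
* **μ per bin.** With defaults, `mu_per_bin = mu_per_bp × bin_size =
  2.5e-4`. Documentation of this method family also circulates a value of
  `0.0025` for a 10-kb bin; `detection_params(mu_per_bin = 0.0025)`
  reproduces that arithmetic exactly, and the worked-example tests use
  it. The distinction is immaterial in practice: the floor is dominated
  by `fdr_per_bin`.
* **FROH denominator.** Total autosomal length by default ("proportion of
  the genome"); `froh_denominator = "covered"` is exposed because at low
  coverage the covered-length denominator is arguably fairer.
* **Sharing.** "Shared" means intersected across *all* group members;
  `min_members = k` relaxes to k-of-n. "Exclusive" regions subtract every
  base covered by any outsider ROH after intersecting the in-group.
  A region counts genes at ≥ 1 bp overlap.
* **Array comparison.** R² is the squared Pearson correlation of paired
  per-individual cumulative sizes (the plotted fitted line's statistic is
  not otherwise pinned down); sequence calls are filtered to > 5 Mb
  because the array resolves only the large class.
* **Recombination rates** are interval ratios `ΔcM/ΔMb` assigned to both
  flanking markers and averaged over all markers in a relative-position
  bin ("both" rather than left- or right-assignment); zero-Δbp marker
  pairs are skipped. GC and π profiles average per chromosome first, then
  across chromosomes, so long chromosomes do not dominate.

## The synthetic-data generator

`simulate_individual()` emulates exactly the statistical structure the
analysis assumes: heterozygous sites as a Poisson process at `theta`
(default 1.7e-3/bp, i.e. 1.7 SNPs/kb) outside planted tracts and
`tract_residual_frac × theta` (default 5%) inside; tract counts Poisson,
lengths log-normal, placement uniform or biased toward low recombination
(`tract_bias_recomb`, probability ∝ 1/rate); depth drawn
negative-binomially per 200-bp block around a mean of 8 with
exponential-length dropout segments of depth zero; each variant's `DP` is
read off its block. Random tract draws whose total mass would exceed 90%
of a chromosome are trimmed (largest first) so cohort generation never
aborts; explicitly supplied `fixed_tracts` that exceed the chromosome are
an error instead. The reference has a U-shaped GC gradient, the genetic
map the U-shaped rate profile `recomb_min + recomb_amp (2x−1)²` (defaults
0.3 and 2.7 cM/Mb — low centres, high ends), and the annotation is
uniform random genes.

What the generator does *not* emulate: linkage structure and phase,
coalescent genealogies, ascertainment bias, sequence-context-dependent
error, repeat-driven coverage artefacts correlated with GC, or real gene
clustering. Passing tests therefore demonstrate that the implementation
performs the stated computation and recovers truth under its own model
assumptions — not that the thresholds are optimal for any particular real
dataset.

Group presets (`eu-wild`, `eu-domestic`, `as-domestic`, `as-wild`) encode
the qualitative regimes of interest — many moderate tracts with low
background diversity, many tracts at moderate diversity, few large
tracts, few tracts at high diversity — with background heterozygosity
1.4–2.2 SNPs/kb around the 1.7 anchor.

## Problem sizes used in the test suite

The default cohort is 4 presets × 3 individuals on five 20-Mb autosomes
(100 Mb per genome), the size at which per-group statistics stabilise
while a full simulate–bin–call–score cycle for the cohort stays around
two minutes on one core. Oracle-equivalence checks run the full caller
against a literal loop implementation of the rules on 100 random grids of
up to 1 000 bins; calibration and landscape checks use 2 000-bin genomes
and a 4 × 1 biased-placement cohort respectively.

## Known limitations

* Sex chromosomes are out of scope; the method assumes autosomal diploidy.
* The caller is threshold-based, not probabilistic: it reports no
  per-ROH confidence, and boundary placement is bin-quantised (the
  recovery report measures ~0.4 bins mean boundary error on synthetic
  data).
* π here is within-individual heterozygosity per kb; it is not a
  population-level π across haplotype samples.
* The hypergeometric enrichment takes a user-supplied term map at face
  value: no ontology propagation, no ortholog mapping.
* `read_vcf_variants` reads one sample per call; multi-sample cohort VCFs
  should be split upstream (e.g. `bcftools view -s`).
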