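---
title: "Methods: nucleosome occupancy and TF footprints in cell-free DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome occupancy and TF footprints in cell-free DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfdnafoot)
library(dplyr)
```

## The model

Plasma cell-free DNA (cfDNA) is released mostly by apoptosis, and nucleases
spare DNA that is physically protected by chromatin. Fragment sizes therefore
carry a chromatin signature: DNA wrapped by a chromatosome (nucleosome core
plus linker histone) survives at ~165 bp, the nucleosome core particle alone
protects ~150 bp, and a bound transcription factor (TF) shields only ~50 bp.
Sequencing coverage of nucleosome-sized fragments over a locus ("occupancy")
is thus a readout of chromatin protection in the tissues shedding cfDNA, and
a dip in coverage at a TF's binding-site centers is a footprint of that TF's
activity. In a cancer patient the tumor contributes only a fraction of the
cfDNA (the *tumor fraction*), so tumor-specific chromatin signals are diluted
accordingly.

`cfdnafoot` implements the window-level and binding-site-level analyses on
this model for low-pass (~0.1x) whole-genome cfDNA sequencing:

1. **Occupancy tracks.** Fragments of 120-180 bp (nucleosome protection,
   bounds inclusive) are counted as per-bp coverage, averaged within fixed
   10-kb genomic windows, and divided by the sample's genome-wide mean
   coverage. Every normalized track has width-weighted mean 1, making samples
   of different depth directly comparable.
2. **Differential occupancy.** For each condition (pre-treatment,
   post-treatment) with at least two samples, a window is *stable* when the
   relative deviation (sample standard deviation / mean, `RSD`) of the
   normalized occupancies across samples is strictly below 0.5. For windows
   stable in both conditions the relative change of the condition means,
   `(mean_post - mean_pre) / mean_pre`, is computed; windows with change
   strictly above +0.4 are *gained-nucleosome* regions, strictly below -0.4
   *lost-nucleosome* regions. There are no p-values: the procedure is purely
   threshold-based, and no multiple-testing correction is applied.
3. **TF binding-site analysis.** Around site centers (optionally the top 50%
   of sites by strength score), depth-normalized coverage is averaged over
   sites into an aggregate profile, strand-oriented and offset-binned. Per
   sample, the TF *activity score* is the mean normalized coverage within
   +/-15 bp of the site centers. The sign convention runs through the whole
   package: higher center read depth means less TF binding, predicting less
   expression of the TF's program. Scores are related to tumor expression
   (Spearman or Pearson), tumor fraction (Pearson), and clinical groups
   (two-sided Mann-Whitney U).
4. **Fragment-size metrics.** From the 1-bp length histogram, the modal
   length within three disjoint search windows (30-80, 140-157, 158-180 bp)
   and the chromatosome/nucleosome and chromatosome/TF peak-height ratios.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `bin_size` | 10,000 | bp | occupancy window; windows are consecutive non-overlapping tiles |
| `min_len`, `max_len` | 120, 180 | bp | nucleosome-protection filter, inclusive bounds |
| `rsd_max` | 0.5 | - | within-condition stability (strict `<`) |
| `change_min` | 0.4 | - | between-condition relative change (strict `>`) |
| `half_width` | 15 | bp | center-depth window around TFBS centers |
| `flank`, `step` | 2000, 10 | bp | aggregate-profile extent and resolution |
| `top_fraction` | 0.5 | - | strongest-site selection (ceiling rule, positional tie-break) |
| `min_mapq` | 20 | - | BAM read filter (with duplicate/secondary/supplementary exclusion) |

Windows are tiles rather than overlapping sliding windows: the region-count
semantics of the differential caller presume a fixed partition, and a genuine
sliding analysis can be emulated by re-tiling at an offset. The relative
change uses the pre-treatment mean as denominator and is applied signed; the
symmetric alternative (mean of the two condition means) is available via
`denominator = "mean"`. The RSD uses the n-1 standard deviation. Windows with
zero mean in either condition are unstable by definition (no relative change
can be formed). Called regions are single windows; adjacent calls are not
merged, so region counts are window counts.

The center-depth score uses a +/-15 bp window rather than the literal single
center base because at 0.1x coverage a single-bp depth is almost always 0 or
1; `half_width = 0` restores the literal reading. Scores average over sites
within a sample (one value per sample per TF), profiles average sites with
equal weight and then samples with equal weight. Strand `"."` is treated as
`"+"`. Sites whose profile window would cross a chromosome end are dropped.

## The synthetic cohort generator

Headline cohort-scale results in this field derive from controlled-access
patient data, so the package ships a generator that reproduces the
*statistical structure* the analysis relies on, plus a truth table for every
downstream assertion. The reference configuration (`sim_config()` defaults)
is: a 2 x 10 Mb two-chromosome genome; 6 pre-treatment and 6 post-treatment
samples at 0.1x target coverage with tumor fractions 0.3-0.5; fragment
lengths from a three-component truncated-normal mixture - chromatosome
N(165, 5) at weight 0.55, core N(150, 5) at 0.35, TF footprint N(50, 10) at
0.10, truncated to [30, 400] bp (weights chosen to reflect the
mononucleosome-dominated composition of real cfDNA); 30 gained and 30 lost
windows planted at relative effect +/-0.6; two TFs with 1000 sites each and
condition-dependent activities; and expression linked negatively to expected
center depth (`max(0, 10 - 10 * depth + N(0, 0.5))`).

Three design choices deserve explanation.

**Where the planted window effect lives.** By default the planted effect is
the *observable* cohort-level relative change: post-treatment (and
progression) samples draw fragments at intensity `1 + effect` in planted
windows. A tumor-dilution variant (`dilute_by_tumor_fraction = TRUE`) places
the effect only in the tumor-derived compartment, so the observable shift
becomes `tumor_fraction * effect` and vanishes at tumor fraction zero. The
undiluted default keeps the planted effect interpretable against the caller's
`change_min` threshold (a planted 0.6 is a testable 0.6); the diluted variant
is used to verify that a tumor-free cohort yields no calls. TF footprint
dips, by contrast, always scale with `tumor_fraction x activity` - dilution
of the binding-site signal is exactly what the activity score must cope with,
and the tests assert the dip's monotonicity in both knobs.

**Variance-controlled allocation.** Per-window fragment counts are allocated
by largest-remainder rounding of expected counts, the protection-mode
composition of each window is allocated the same way, and fragment lengths
are drawn by stratified inverse-CDF sampling of the truncated normals
(equal-probability strata, one jittered draw per stratum, in random order -
the marginal law of every draw is the exact truncated normal). An explicit
multiplicative lognormal window noise term (`window_noise_rsd`, default 0.1)
is then the dominant variance component, so the realized between-sample
window RSD sits near the configured value instead of being inflated by
multinomial sampling noise, and the realized size histogram tracks the
configured mixture closely at any sample size. With iid sampling at 0.1x
coverage (~7 fragments per 10-kb window), counting noise alone would impose a
window RSD near 0.4, drowning the noise the configuration asks for.

**Footprint mechanism.** A site is "open" in the tumor compartment with
probability equal to the TF's condition activity (drawn once per site and
condition, shared across samples). Tumor-derived fragments covering an open
site's center are replaced by short TF-protected fragments (truncated
N(50, 10), clipped to [30, 80] bp) placed beside the center. One mechanism
thus produces both the center coverage dip (depth proportional to
`tumor_fraction x activity`, because replacement fragments neither cover the
center nor survive the 120-180 bp filter) and the ~50 bp component of the
size distribution. Nucleosome phasing (periodic positioning around dyads) is
not simulated: window-level analyses do not need it, and aggregate profiles
consequently show a flat unit baseline with a central dip rather than the
oscillatory flanks of real data.

Randomness flows from a single master seed; each sample consumes a child
stream derived from its position in the sample table, so appending a sample
leaves existing samples byte-identical.

What the generator does *not* emulate - and what passing tests therefore do
not establish about real data: GC and mappability bias, blacklist artifacts,
copy-number structure (CNV segments are consumed as an input, never
simulated), nucleosome phasing, inter-patient biological variability beyond
the lognormal window noise, and any sequence-level effects (fragments are
born aligned; no FASTQ, no aligner).

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open internally; BED/bedGraph dialects at the
  I/O boundary. Fragments are strand-agnostic.
- Both calling thresholds are strict inequalities: an RSD of exactly 0.5 is
  unstable, a relative change of exactly 0.4 is not called.
- Histogram peak ties resolve to the smallest length; an all-zero search
  window yields an undefined peak and undefined dependent ratios (`NA`),
  never zero. Fragments longer than the histogram support accumulate in an
  open overflow bin outside every search window.
- Top-fraction selection keeps `ceiling(fraction * n)` sites with ties broken
  by genomic position, so repeated runs select identical sets.
- The empty fragment file is a valid empty sample; an all-zero coverage track
  refuses normalization ("no coverage"); correlation requires >= 3 complete
  pairs and reports `NA` for constant vectors rather than erroring.
- Windowed occupancy splits boundary-spanning fragments proportionally, so
  coverage mass is conserved exactly: the width-weighted sum of window values
  equals total fragment base pairs.

## Scale of the shipped checks

The test suite and the verification script run entirely on synthetic data at
desk scale: toy genomes of 0.1-20 Mb, cohorts of 6-30 samples at 0.1x
coverage, 100-1000 sites per TF, and one million fragment lengths for the
size-mixture calibration. Oracle comparisons (windowed occupancy and center
depth against brute-force per-bp counting) use 200-500 fragments on 100-kb
genomes where exhaustive computation is exact. The full cohort-scale
differential analysis of real patient data runs with the same functions and
the same defaults via `run_pipeline()`; only data access separates the two.

## Known limitations

- The stability filter reacts to coverage: deeply lost windows (large
  negative effects at low coverage) can fail the within-condition RSD
  criterion and escape calling - a property of the published procedure, not
  of this implementation.
- No GC or mappability correction of coverage is performed; GC content and
  CNV overlap are offered as post-hoc confounder checks only.
- Expression and tumor fractions are consumed as provided (TMM-FPKM and
  external estimates respectively); the package neither normalizes expression
  nor estimates tumor fraction.
- Aggregate profiles average equally over sites and samples; no
  coverage-weighted or shrinkage estimators are provided.
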