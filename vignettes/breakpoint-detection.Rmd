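---
title: "Detecting CNV breakpoints from read depth and split reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting CNV breakpoints from read depth and split reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernbreak)
```

## The problem

A copy-number-variable region (CNVR) is a genomic interval in which
individuals carry different numbers of copies of the underlying sequence.
At many disease-associated loci the same CNVR hosts several distinct
ancestral events — nested deletions of different sizes, duplications
overlapping deletions — and it is the *breakpoints* of each event, not
just its presence, that determine which genes or regulatory elements are
disrupted. Read-depth methods find CNVRs robustly but only at the
resolution of their counting window (hundreds of bp); split-read
methods are base-precise but starve at low coverage, where a single
sample may have no read spanning a junction at all.

kernbreak combines the two signals across *multiple samples*. Samples
carrying the same event share the same breakpoints, so the package first
groups samples by copy-number genotype and then pools each group's
evidence: read depth to bracket the breakpoints, soft-clipped reads to
pin them down. A group with twenty 1–3x samples can still recover
base-precise breakpoints from the handful of junction reads scattered
across its members — breakpoints are *imputed* from the group to every
member, including samples with no informative reads of their own.

## The pipeline

1. **Windowed read depth.** Reads are counted in non-overlapping windows
   (default 500 bp) by leftmost aligned base, after discarding unmapped,
   secondary, supplementary and (optionally) duplicate-flagged reads.
2. **Bias correction and standardization.** Counts are corrected for GC
   content (and optionally mappability) by median-ratio scaling within
   annotation bins of width 0.01, then divided by the sample's median
   window count and decreased by 1, so 0 is diploid, about −0.5 a
   hemizygous deletion, −1 a homozygous deletion, +1 a full-dosage
   tandem duplication.
3. **Segmentation.** Each sample's standardized signal is fitted as a
   piecewise-constant function (details below). The union of all
   samples' change-points partitions the region into *sub-regions* on
   which every sample's fit is constant, giving an M samples × N
   sub-regions matrix of segmentation values.
4. **CNVR calling.** A sub-region is a duplication for a sample if its
   value exceeds `dup_threshold` (default +0.25) and a deletion below
   `del_threshold` (default −0.25); consecutive sub-regions where any
   sample is non-normal merge into a CNVR, and CNVRs carried by fewer
   than `count_threshold` samples are dropped.
5. **Genotype grouping.** Within each CNVR, samples are clustered on
   their segmentation values with a Gaussian mixture model constrained
   to spherical, equal-volume components (the mclust "EII" model),
   with the component count chosen by BIC over 1–9.
6. **Read-depth breakpoints.** Each group's sub-matrix is padded with a
   zero-valued flanking sub-region on each side (the neighbourhood of a
   CNVR is assumed copy-neutral) and every boundary position is scored
   with a Gaussian-kernel sum of absolute between-sub-region jumps
   across the group's samples (kernel sd `sigma_rd`, one third of the
   window size). Bootstrap resampling of the group's samples
   (`n_resample`, default 100) yields `MedLeft` and `MedRight`, the
   medians of each replicate's two top-scoring positions.
7. **Split-read refinement.** Soft-clip positions are read directly from
   CIGAR strings (no re-alignment), pooled over the group, and scored
   with a near-delta Gaussian kernel (`sigma_sr` = 0.5 bp) inside
   `MedLeft/MedRight ± epsilon_open` (one window). Clip orientation must
   match the junction: at a deletion's left breakpoint reads run off the
   junction rightwards, so only right-side clips qualify there (and only
   left-side clips at its right breakpoint); at a tandem-duplication
   junction the orientations are mirrored. A side with no qualifying
   clip keeps its read-depth coordinate, flagged `source = "RD"`.

The final report gives each sample its group's breakpoints and state,
subject to a per-sample verification: the sample's own mean segmentation
value between the group's breakpoints must cross the calling threshold,
otherwise the sample is reported normal. Group evidence localizes the
event; each sample's copy-number status remains its own. This guards
against mixed components when the mixture's component cap binds.

## The segmentation engine

No change-point package is assumed; the engine is self-contained and
swappable. It is a least-squares scan in the spirit of circular binary
segmentation: each segment scan considers both the best single split and
the best *interior sub-segment* — two change-points tested jointly —
and recurses on whatever it accepts. The joint test matters: a short
event inside a long flat stretch contributes almost nothing to any
single split's gain (the gain scales with the square of the event length
over the signal length), while the joint statistic sees it at full
strength.

Penalties are Bonferroni/SIC-style and multiplicity-matched:
`2·sigma²·log(n)` for the n single-split candidates and
`2·sigma²·log(n(n−1)/2)` for the interior-segment candidates. These sit
at the simulated null 99th percentile for signals of a few thousand
windows, i.e. roughly a 1% false-call rate per scan — the conventional
operating point for read-depth segmentation.

Two properties of windowed sequencing data shape the noise model:

* **Serial correlation from read pairs.** Mates land one mate-span
  (read length + inner distance, about one window) apart, so
  neighbouring window counts are positively correlated (lag-1
  autocorrelation near 0.4 at the default geometry). The marginal noise
  variance is therefore estimated from the MAD of *lag-3* differences,
  which straddle the mate correlation but still cancel the piecewise
  mean structure; and each candidate's gain is deflated by the
  moving-average variance-inflation factor
  `1 + 2·rho1·(1 − 1/m) + 2·rho2·(1 − 2/m)` of its shorter side, with
  the short-lag correlations estimated from the lag-1/lag-2 difference
  MADs. For single-end data the estimated correlations are near zero
  and the scan reduces to the iid case.
* **Robustness limits.** The MAD-of-differences estimator assumes
  events occupy a modest fraction of the region; on very short signals
  where one event dominates most lag-3 differences the noise scale is
  overestimated and small events can be missed. At realistic region
  sizes (hundreds to thousands of windows) this is immaterial.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_size` | 500 bp | read-depth resolution; smaller windows are noisier, larger ones miss events near the window size |
| `dup_threshold`, `del_threshold` | ±0.25 | CNVR call thresholds on the standardized scale; ±0.5 would be the noise-free ideal but boundary windows mix states |
| `sigma_rd` | `window_size/3` | read-depth kernel sd; wide enough to pool jittered per-sample boundaries, narrow enough to separate nearby junctions |
| `sigma_sr` | 0.5 bp | split-read kernel sd; nearly a delta so only clips within a base or two reinforce each other |
| `epsilon_open` | `window_size` | half-width of the split-read search window around the read-depth estimate |
| `n_resample` | 100 | bootstrap replicates; medians stabilise well below this |
| `count_threshold` | 1 | minimum carriers per CNVR; set near 10% of the sample size for population cohorts so only common events are reported |
| `min_clip_len` | 10 bp | minimum terminal soft-clip; suppresses 1–2 bp clip noise from base errors |

## The simulator

`sim_reference()`, `sim_sample()` and `sim_cohort()` generate benchmark
inputs without an external read simulator or aligner. A donor genome is
built per sample by applying its deletion/tandem-duplication events to
the reference; read (or fragment) starts are drawn uniformly on the
donor at the requested coverage (Poisson read counts); and each read is
mapped back to reference coordinates *analytically*: reads inside
unbroken blocks become full matches, and reads spanning a junction align
to the block holding the majority of their bases with the remainder
soft-clipped. Deletion junctions therefore produce right-side clips at
the first deleted base and left-side clips just after it; tandem
duplications the mirrored pattern. A read crossing the downstream edge
of a tandem duplication is reference-contiguous and correctly emitted as
a full match.

The default cohort layout realizes seven event configurations (nested
deletions of 84,780 / 20,000 / 5,000 / 1,000 bp and tandem duplications
of 50,000 / 20,000 / 10,000 bp in the middle of a 1 Mb region) plus a
normal class, in 15 samples each with coverages sweeping 1–15x —
120 samples, paired-end 100 bp reads with a 500 bp inner distance and a
0.001 substitution rate, or single-end on request.

What the simulator deliberately does *not* model, and what that means
for test results on real data:

* Events are full-dosage on the simulated genome (deletions reach −1,
  duplications +1 on the standardized scale), not heterozygous (−0.5 /
  +0.5); ploidy dosage is not a parameter of real events either, but
  mixtures of carriers at different zygosities will sit between the
  simulated extremes.
* Base errors are substitutions applied to emitted bases only; since
  placement is analytic they can never move a clip or misalign a read,
  whereas a real aligner loses or shifts some junction evidence —
  particularly at low coverage, where every junction read counts.
  Benchmarks on this simulator therefore bound the method's aligner-era
  performance from above in the lowest coverage classes.
* No mapping ambiguity: the random reference has no repeats, so
  mappability correction is exercised only through synthetic tracks.
* Read starts taper within one fragment length of the region ends
  (fragments must fit inside the segment), which depresses standardized
  depth at the extreme edges; analyses should focus on interior
  intervals, as the evaluation harness does.

## Evaluation

`evaluate_calls()` scores per-sample calls against per-sample truth with
a ±10 bp matching radius — the scale of the micro-insertions observed at
real deletion junctions. A predicted breakpoint is true if it falls
within the radius of the same sample's truth breakpoint of the same side
and state, matched one-to-one greedily by distance; TPR is true
predicted breakpoints over all truth breakpoints, FDR falsely predicted
over all predicted, CR events with both breakpoints true over all true
events. `resample_experiment()` re-runs the cohort-level stages on
sub-cohorts drawn without replacement (per-sample profiles are reused —
they do not depend on cohort composition) and reports TPR/FDR quartiles
per sample size.

## Numerical choices and degenerate inputs

* Score ties in the read-depth stage break toward the smallest
  coordinate; in the split-read stage toward the position closest to the
  read-depth estimate, then smallest.
* The split-read search window is closed at both endpoints.
* Reported breakpoints follow the convention left = first affected
  base, right = last affected base; clip junction coordinates on the
  right side (first base after the event) are shifted down by one.
* A group whose CNVR sub-matrix admits no bracketable candidate pair,
  or whose between-breakpoint mean is inside the thresholds, is called
  normal. Components left empty by the mixture fit are skipped.
* Identical rows collapse to one cluster without invoking the mixture
  machinery; one-dimensional sub-matrices use the 1-D equal-variance
  mixture model, the analogue of the spherical multivariate constraint.
* GC bins holding fewer than 10 windows pass through uncorrected (and
  flagged): a bin median estimated from a handful of windows is
  dominated by those windows' own copy-number signal — in the extreme a
  singleton bin is forced to the sample median, erasing its signal.
* Zero-coverage samples fail fast (no median), as do signals with
  missing values.

## A compact example

```{r example, eval = FALSE}
ref <- sim_reference(2e5, seed = 1)
layout <- data.frame(label = c("del", "dup", "normal"),
                   type = c("DEL", "DUP", "NORMAL"),
                   start = c(50000, 120000, NA),
                   end = c(70000, 140000, NA), n_samples = 6)
coh <- sim_cohort(ref, layout, dir = tempfile(), paired = TRUE, seed = 1)

grid <- window_grid("sim1", 1, 2e5, 500)
res <- kernbreak(coh$manifest$file, grid, kb_config(seed = 1), gc = ref,
                 sample_ids = coh$manifest$sample)
summary(res)
evaluate_calls(res, coh$truth, radius = 10,
               focus = cohort_focus(layout))
```

## Problem sizes used in the test suite

The package's own checks run the full 120-sample, 1 Mb benchmark
(paired- and single-end, three seeds), a 40-sample low-coverage
re-analysis, and a sample-size resampling experiment with 50 replicates
per size — sizes chosen so the entire suite completes in well under half
an hour on a single core while still exercising the method at the scale
its defaults were designed for. Smaller cohorts (15–24 samples on
150–300 kb) back the per-module tests.

## Known limitations

* The equal-volume spherical mixture constraint shares one variance
  across all genotype groups. When a cohort holds only a few genotype
  groups with very unequal dispersions — e.g. duplication carriers
  (whose standardized depth carries counting noise) alongside
  dispersion-free deletion carriers and normals — the BIC search can
  fragment the noisier group into small sub-groups, and a fragment
  holding a single sample loses the pooling advantage. With the
  benchmark's eight-configuration layout the component cap (G = 9)
  leaves no room for this, and fragments that do arise usually inherit
  correct breakpoints; but analyses of small cohorts with one or two
  event types should treat multiple reported groups with near-identical
  breakpoints as one biological event.
* One event per group per CNVR: the two top-scoring positions are taken
  as the group's left and right breakpoints, so a genotype group whose
  samples carry two disjoint events inside one CNVR would need to be
  separated by the clustering to be called correctly.
* Paired-end insert-size (discordant-pair) evidence is not used; the
  method is deliberately pair-agnostic so single-end cohorts are first-
  class inputs.
* Micro-homology or inserted sequence at junctions is not
  reconstructed; it motivates the ±10 bp evaluation radius but is
  otherwise out of scope.
* Copy-number states are reported as duplication/deletion/normal, not
  integer copy numbers.
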