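---
title: "Consensus discovery of copy number variable regions from SNP-array signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus discovery of copy number variable regions from SNP-array signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcnvr)
```

## The signal model

Genotyping arrays summarise each SNP probe by two normalised quantities.
The Log R Ratio (LRR) measures total hybridisation intensity on a log2
scale relative to a diploid reference: it sits near 0 at two copies,
drops for deletions and rises for duplications. The B Allele Frequency
(BAF) is the fraction of signal attributable to the B allele: at two
copies it clusters at 0, 0.5 and 1 (genotypes AA, AB, BB), and the
cluster set shifts with copy number — a hemizygous deletion has no
heterozygous cluster ({0, 1}), a three-copy state clusters at
{0, 1/3, 2/3, 1}, and a homozygous deletion has no genotype at all, so
its BAF is uninformative (modelled uniform).

`snpcnvr` uses one shared cluster model for both simulation and calling.
The LRR state means default to the widely used values CN0 = −3.5,
CN1 = −0.66, CN2 = 0, CN3 = +0.40, CN4 = +0.68 (`lrr_state_means()`);
array vendors do not publish emission parameters, so these are stated,
configurable defaults. BAF cluster weights are Hardy–Weinberg at a
population B-allele frequency of 0.5; linkage disequilibrium between SNP
alleles is not modelled because it does not affect the intensity signal
a CNV leaves.

## The three callers

CNV calling from array signal is notoriously caller-dependent, which is
why the pipeline's defining step is consensus across three independent
detectors:

* **`hmm_call()`** — a five-state hidden Markov model over copy numbers
  0–4, emissions being the product of the LRR Gaussian and the BAF
  cluster mixture of each state. Transition off-diagonal mass is scaled
  by $1 - e^{-d/D}$ for inter-probe distance $d$ (decay length
  $D = 100$ kb by default), so dense probe runs resist state flips
  while distant probes are nearly independent. Maximal runs of a
  constant non-diploid state spanning at least three probes become
  calls. Viterbi ties are broken toward the smaller copy-number change.
  The copy-neutral LOH state of six-state array HMMs is deliberately
  omitted: this package detects copy number changes only. When parent
  tracks are available the decoder runs per individual and a trio pass
  follows: an offspring call is dropped when both parents' signal
  likelihood-ratio contradicts any non-diploid state over the interval,
  and a confident parental call whose interval shows positive but
  sub-threshold support in the offspring is rescued. This approximates
  joint trio decoding at a fraction of its complexity; the consensus
  stage, not the individual caller, carries the pipeline's guarantees.
* **`sbl_call()`** — sparse Bayesian learning on the step basis: the
  LRR vector is modelled as piecewise constant, each candidate
  breakpoint weight carrying a Gaussian–Gamma prior with shape
  `a_alpha = 0.8` and rate `b_alpha = 0.2`. EM shrinks spurious steps;
  backward elimination then repeatedly removes the breakpoint with the
  smallest t-like score (segment mean difference over its standard
  error) until all scores reach the critical value `T = 8` and every
  segment spans at least 3 probes. With the default rate hyperparameter
  the Gamma prior bounds the precisions, so the EM stage shrinks rather
  than prunes and backward elimination performs the actual selection;
  setting `b_alpha` near zero makes the EM itself sparse. The shape
  interpretation of the sparseness hyperparameter is adopted. Noise
  scale is estimated robustly from successive LRR differences
  (MAD/√2), floored at 10⁻⁴ so noiseless input stays finite.
* **`partition_call()`** — recursive binary segmentation accepting each
  split while its Gaussian log-likelihood gain exceeds
  `bic_penalty × log(n)` (default penalty 2.0), then thresholding
  segment means at −0.25 (loss) and +0.20 (gain) with a minimum probe
  count of three. Because CN1 and CN3 have no heterozygous BAF cluster,
  a segment with a substantial heterozygous fraction (BAF within 0.5 ±
  0.06 in more than 20% of probes) is vetoed — this is what
  distinguishes an intensity artifact such as a GC wave from a real
  deletion. The thresholds are stated defaults: the commercial
  partitioning tool this stands in for is proprietary, and no attempt
  is made to replicate it bit-for-bit.

Missing probe values are dropped from all likelihoods, never imputed.
Calls never span a chromosome boundary, because every caller operates
per chromosome.

## Consensus CNVRs

The region-building rules are the pipeline's core contract. Within one
sample, calls of the *same direction* from at least two distinct callers
whose intervals pairwise overlap are merged into one consensus event
whose interval is the **intersection** of the supporting calls; the
intersection must span at least three consecutive SNPs of the map.
Opposite directions never corroborate each other — a loss and a gain
call over the same interval are contradictory evidence in one genome.
Maximal supporting sets are enumerated via the Helly property of
intervals (every pairwise-overlapping family shares a common point), so
a three-caller agreement yields one consensus event, not three pairs.

Across samples, overlapping consensus events are clustered by single
linkage per chromosome; clusters carried by at least two animals become
CNVRs whose span is the **union** of member intervals, with status Loss,
Gain, or Loss-Gain according to the carrier directions. Union is the
right cross-sample rule here because carrier counts are reported per
region and published region spans far exceed any plausible multi-animal
intersection. Intersection-within-sample and union-across-samples are
both configurable choices of the operations, not hidden behaviour.

Coordinates are 1-based; an interval's length in bp is `end − start`,
and overlap means at least one shared base under that convention
(half-open semantics). The probe count of an interval counts map
positions inclusively at both ends, since call boundaries are themselves
probe coordinates. This convention is what makes published CNVR tables
arithmetically self-consistent — the shipped 49-region porcine catalogue
(`pig_cnvr_catalog()`) reproduces its printed kb lengths from its
coordinates to two decimals, and its headline overall size statistic
(754.6 kb) is the arithmetic mean of the length column (the true median
of the printed lengths is 170.96 kb).

## What the simulator emulates — and what it does not

`simulate_cohort()` generates a pedigreed cohort in the style of an
Iberian × Landrace intercross: founder boars and sows, F1, F2 and
backcross generations. Each CNV locus carries an allele space of
per-haplotype copy counts (0 for a deletion allele, 2–3 for duplication
alleles, 1 for the normal haplotype) with per-population founder
frequencies; offspring inherit one haplotype from each parent, so
Mendelian transmission holds by construction and the segregation module
can be tested against a known-true answer. The default inter-probe
spacing is exponential with mean 39.61 kb, the average autosomal SNP
distance of the porcine 60k chip. Sex chromosomes are excluded
throughout, as array CNV analyses routinely do.

Noise defaults are `lrr_sd = 0.2`, `baf_sd = 0.03`, with an optional
heavy-tailed contamination fraction. No public estimate of the real
chip's noise exists, so these are simulator parameters, not chip
estimates. The simulator does **not** model GC-content waviness, probe-
specific biases, linkage disequilibrium, or raw-intensity (IDAT) level
artifacts; a pipeline that passes these tests is validated for its
*logic* — segmentation, consensus arithmetic, segregation, validation
statistics — not for robustness to every artifact of real chip data.

The standard benchmark (`benchmark_cohort()`) plants ten loci on three
200-probe chromosomes in a 32-animal pedigree: six deletion loci 12–16
probes wide and four duplication loci 28–30 probes wide at founder
frequencies 0.3–0.4. The width asymmetry is a power calculation, fixed
before any measurement: a duplication carrier shifts the LRR by +0.40
(vs −0.66 for a deletion), so at `lrr_sd = 0.2` and a backward-
elimination critical value of 8 the breakpoint t-score
$|\Delta\mu|/(\sigma\sqrt{1/n_L + 1/n_R})$ of a five-probe duplication
sits near 4.5 — below threshold — and only spans of roughly 25 probes or
more put all three callers in their sensitive regime. Both widths are
realistic: published array CNVRs span from a handful to hundreds of
probes (up to 10.7 Mb in the porcine catalogue). Problem sizes
throughout (200-probe chromosomes, ~30 animals) are desk-scale choices
that keep the full three-caller benchmark comfortably interactive.

## Segregation checking

Array intensities are unphased, so a total copy number is compatible
with several ordered haplotype pairs. `trio_consistent()` therefore
decides Mendelian consistency *existentially*: a trio is consistent iff
some genotype of the offspring can be assembled from one transmissible
component of each parent, with all genotypes drawn from the allele space
implied by the CNVR status — {0,1} per haplotype for Loss regions,
{1,2,3} for Gain, {0,…,3} for Loss-Gain. Tying the allele space to the
status is what keeps the check non-vacuous: over an unrestricted space
nearly every copy-number triple is consistent. The enumeration is
exhaustive (the spaces are tiny) and symmetric in sire and dam. Apparent
de novo events are reported as violations, treating non-Mendelian
patterns as evidence of calling artifacts rather than mutation; totals
above four copies are reported as "4", matching the five-state caller.
Families are handled trio by trio; no pedigree-wide likelihood is
attempted.

## qPCR validation

`relative_quantify()` implements the 2^−ΔΔCt comparative method: for
each sample, ΔCt = mean target Ct − mean single-copy-reference Ct, and
ΔΔCt subtracts the calibrator sample's ΔCt, so the calibrator's relative
quantification (RQ) is exactly 1 and RQ = 2^−ΔΔCt estimates copy number
relative to the calibrator's two copies. PCR efficiency is assumed
exactly 2, reflecting the usual practice of verifying comparable target
and reference efficiencies experimentally before applying the method.
The standard error uses the delta method, se(RQ) = RQ · ln 2 · se(ΔΔCt),
with se(ΔΔCt) from the replicate variances of both samples added in
quadrature. Samples with replicate ranges above 0.5 cycles are flagged
but never dropped.

`classify_copy_number()` maps RQ to an integer CN as the nearest integer
to 2·RQ, capped at 4, with a ±0.25 guard band around each half-integer
boundary flagged "ambiguous". The guard band is this package's explicit
stand-in for the by-eye classification typical of validation figures; no
numeric criterion is standard. `validation_rates()` then counts a
predicted carrier that classifies at the calibrator's copy number as a
false positive (FDR = FP / carriers tested) and a control with any copy
change as a false negative (FNR = changed / controls tested), reporting
exact fractions alongside whole-percent figures, per population when
labels are available.

## Numerical choices and degenerate inputs

* Robust noise estimation (MAD of successive differences / √2) with a
  10⁻⁴ floor keeps noiseless fixtures finite and makes segmentation
  scores scale-free.
* The BAF mixture density carries a 1% uniform floor so clipped values
  at 0/1 or stray outliers cannot zero a likelihood.
* Viterbi ties break toward the smaller copy-number change; backward
  elimination repairs under-length segments before applying the score
  threshold, removing the weakest flanking breakpoint first.
* Empty inputs are defined everywhere: an empty call set gives an empty
  consensus, an empty CNVR set summarises to zeros, a founders-only
  pedigree yields a no-trio report with an NA rate, and a caller with
  no raw calls has an NA confirmation rate.
* All randomness flows from one integer seed; rendering uses seed + 1 so
  truth generation and signal noise are decoupled but jointly
  reproducible, and identical seeds give byte-identical outputs.

## Known limitations

The callers are desk-scale reimplementations configured with published
parameter values, not replicas of PennCNV, GADA or cnvPartition; their
raw call counts on real data would differ, which is precisely why only
consensus-level quantities are treated as reproducible. The SBL EM stage
is O(m³) in the number of active breakpoints per chromosome and is the
pipeline's runtime bottleneck beyond a few thousand probes per
chromosome. Gene annotation is by local interval overlap against a
user-supplied BED/GFF3; no online database queries are performed.
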