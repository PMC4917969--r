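---
title: "Copy-number analysis of shallow whole-genome plasma sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number analysis of shallow whole-genome plasma sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Cell-free DNA (cfDNA) in blood plasma carries a tumour-derived fraction
(ctDNA) in cancer patients. Sequencing plasma DNA at very shallow depth
(~0.1-0.2x) and counting reads in genomic bins yields a noisy but unbiased
readout of somatic copy-number alterations (SCNAs): a region present at
tumour copy number $c$ in a sample with tumour fraction $f$ is observed at
mixture copy number $b(1-f) + cf$ over baseline $b$, i.e. at log2 ratio

$$\ell(c, f, b) = \log_2\!\frac{b(1-f) + cf}{b}.$$

Everything downstream of this identity — dilution limits, serial
comparisons, focal-event amplitudes — follows from it, and
`expected_log2()` implements it directly. On the male X chromosome the
baseline is $b = 1$, which is why a 13-copy AR amplicon has a pure-tumour
amplitude of $\log_2 13 \approx 3.7$ and remains above the 0.2 calling
threshold down to $f = 0.05$ ($\ell = \log_2 1.6 \approx 0.68$) but not at
$f = 0.01$ ($\ell = \log_2 1.12 \approx 0.16$).

# Pipeline

1. **Binning.** Reads are counted in ~50,000 bins that each contain the
   same number of mappable positions (~56 kbp average span on a masked
   male hg19-like genome). `build_bin_grid()` constructs such grids for
   arbitrary genome models; bins never cross chromosomes, and only the
   last bin of a chromosome may deviate from the common mappable length.
2. **GC correction.** Counts are normalized by the library total and
   divided by a robust local-linear regression (lowess) of value against
   GC fraction. One wide-span pass (span 0.75) underfits a strongly
   curved bias, so the fit-and-divide step is iterated (alternating with
   a half-span refinement pass) until a primary-span pass finds less than
   0.05% RMS structure; this makes the operation idempotent to within the
   smoother's noise floor. The fit uses unmasked autosomal bins only.
3. **Control normalization.** GC-corrected values are divided by the
   per-bin mean of (default 10) non-tumour cfDNA controls processed the
   same way, and log2-transformed. Bins whose panel mean falls below 10%
   of the genome median are masked instead of producing infinities. For
   tumour tissue the same operation runs against a constitutional-DNA
   panel — configuration, not separate code.
4. **Segmentation.** A native circular binary segmentation: per
   chromosome, the maximal two-sample t-statistic over all admissible
   arcs is located; significance is assessed by permutation
   ($p = (1+\text{exceedances})/(1+n_{\text{perm}})$, accepted when
   $p < \alpha$), and the search recurses into the resulting pieces.
   Defaults: $\alpha = 0.01$, 1,000 permutations, minimum width 3 bins,
   post-hoc merging of adjacent segments whose means differ by < 0.05.
5. **Calling.** Segments with mean log2 ratio strictly above 0.2 are
   gains, strictly below −0.2 losses. A sample is copy-number aberrant
   when its cumulative gained or lost genomic length exceeds the control
   mean by more than 3 SDs (one-sided, OR of the two tests).
6. **Focal events.** Seven amplification rules (size < 20 Mb; mean > 0.2;
   contains ≥ 1 but ≤ 100 genes; exceeds the length-weighted mean of the
   neighbouring 20 Mb on each side by > 0.2 with a known driver gene,
   > 0.58 without; segmental-duplication coverage ≤ 50%; germline-CNV
   rule) and the mirrored deletion rules, which additionally require a
   gene from the curated 42-gene deletion list. A log2 ratio of 0.58 at
   diploid baseline is about three copies, which is what the stricter
   non-driver margin encodes.
7. **Serial analysis.** Consecutive samples are compared only when their
   per-bin segmented profiles correlate with Spearman rho > 0.85 (similar
   ctDNA content). The tumour-content ratio $r$ between two samples is the
   grid point in $[0, 10]$ (step 0.01) minimizing
   $\sum_b (r\,s_A(b) - s_B(b))^2$; differential bins are those with
   $|s_B - r\,s_A| > 0.2$, merged into same-sign runs. Profiles cluster by
   Manhattan distance with average linkage; plasma-tissue concordance uses
   Pearson correlation on autosomes only (tissue controls are mixed-sex).

# The synthetic data generator

No external sequencing data is attached, so every stage is exercised
against simulated samples with known truth (`simulate_sample()`,
`simulate_controls()`, `simulate_dilution_series()`,
`simulate_serial_scenario()`). The generator emulates:

* a male genome (all subjects male): X and Y at baseline copy 1, Y
  pseudo-autosomal regions masked, Y excluded from calling;
* ~50,000 equal-mappability bins at a mean of ~120 reads per diploid bin
  (~0.1x coverage), Poisson-distributed by default (negative binomial
  optional via a dispersion parameter) — with ~120 reads per bin the
  Poisson CV of ~9% dominates, and real per-bin overdispersion at this
  depth is modest;
* a smooth unimodal GC bias, modeled as a quadratic in GC fraction peaking
  at 0.45. The default strength (coefficient −20) makes raw counts
  correlate with GC at |Spearman rho| ≈ 0.4, i.e. GC is a first-order
  effect that the correction step must genuinely remove, as in uncorrected
  shallow WGS;
* per-bin GC fractions drawn once per grid as a spatially correlated field
  (mean 0.41, SD 0.05, 31-bin smoothing window), so GC bias produces
  megabase-scale coverage waves rather than white noise;
* tumour fraction, dilution series (per-level seeds derived as
  seed + index), and serial scenarios with added/removed events and
  recorded differential truth.

What the generator does **not** emulate: fragment-length biology,
mappability artefacts beyond the masked intervals, replication-timing
waves, subclonal mixtures within one sample, and real germline CNV /
segmental-duplication landscapes (tracks are supplied explicitly, empty by
default in simulations). A green test therefore establishes algorithmic
correctness and statistical behaviour under the stated noise model, not
robustness to every artefact of real plasma libraries.

# Numerical choices and edge cases

* **Strict thresholds.** Gains/losses use strict inequalities at ±0.2
  (a segment at exactly 0.2 is balanced), consistent with the focal rule
  "must be > 0.2". Differential bins likewise require |d| strictly > 0.2.
* **Permutation p-values** are computed as
  $(1+\text{exceed})/(1+n_{\text{perm}})$ — exact and never zero.
  Permutations stop early only on the non-significant side (once
  exceedances make $p \ge \alpha$ inevitable), which cannot bias accepted
  splits. An $O(n)$ envelope bound (from the permutation-invariant
  maximum deviation and the range of the centred prefix walk) proves most
  permutations of a strongly significant region cannot exceed the
  observed statistic without running the $O(n^2)$ arc scan.
* **Noiseless regions** (zero variance) cannot be split by a t-statistic;
  any non-zero mean difference is then accepted directly, so noiseless
  step profiles are recovered exactly.
* **Masked bins** (chrY, zero/low panel mean, GC outside fitted support)
  carry NA and never re-enter computation; segments bridge them in bp but
  not in bin count.
* **Flank windows** truncate at chromosome ends; a target with one empty
  flank uses the other side alone; with both empty the flank mean is 0.
* **Gene containment** is any ≥ 1 bp overlap with the gene body.
* **Germline-CNV rule.** Taken literally, "no overlap with known germline
  CNV entries" would remove essentially every call, since published
  germline-CNV catalogues tile most of the genome. The caller instead
  disqualifies a segment when germline-CNV entries cover ≥ 50% of it,
  mirroring the segmental-duplication rule; the fraction is configurable
  (`focal_criteria(dgv_max_frac = )`).
* **Ratio grid ties** break toward smaller r (the grid is scanned in
  ascending order); the closed-form slope through the origin is attached
  to every fit for audit.
* **Minimum differential run length** defaults to 5 bins to suppress
  single-bin noise at ~0.1x coverage; 1 reproduces the literal rule.
* **Tie-breaking in clustering** follows `stats::hclust` (average
  linkage), which is deterministic given input order.

# Design decisions taken where the method was open

* **CBS is the canonical segmenter.** The original analysis combined CBS
  with a second gain/loss analysis inside an external framework whose
  consensus rule is unpublished; reimplementing an unspecified consensus
  would be guesswork, so segmentation is CBS alone, implemented natively
  (C++) with the permutation test described above.
* **GC fit scale.** The local regression is fitted on linear-scale
  normalized counts (not log counts). The iterated fit makes the choice
  nearly immaterial for bias removal; linear scale keeps the fit's
  weighting aligned with the count noise.
* **Aberrance uses one-sided exceedance** above the control mean
  ("3 SDs higher"), not absolute deviation.
* **Cumulative lengths** are measured in unmasked genomic bp of
  gain/loss segments.
* **Serial adjustment order:** the earlier sample is scaled by r and
  subtracted from the later one, $d = s_B - r\,s_A$; scaling acts on log2
  values. Bin-wise (not segment-wise) flagging is used.
* **Eligibility rho** is computed genome-wide minus Y.
* **Driver lists** ship as name lists assembled from the printed
  amplification-mapping genes and the 42 deletion genes; the packaged
  coordinates file covers a key-gene subset with approximate hg19
  gene-body positions and is labelled synthetic. Simulation-facing
  annotation is built in code (`ar_annotation()`), with AR at its hg19
  position on Xq12.
* **"Any sample per patient"** is used when counting driver-aberration
  frequency; single-sample-per-patient counting is available via
  `count_focal_per_sample(one_per_patient = TRUE)`.

# Statistical tests

`mann_whitney_u()` enumerates all group assignments exactly for combined
n ≤ 12 without ties and otherwise uses the normal approximation with tie
and continuity correction. `fisher_exact_2x2()` sums hypergeometric
probabilities of all tables no more likely than the observed one
(minimum-likelihood two-sided convention, matching the environment whose
p-value floor of 2.2e-16 the reported AR table reflects). Both are
cross-checked in the test suite against exhaustive enumeration and against
the independent implementations in `stats`.

# Scale choices in the test suite

Unit and property tests run on a scaled-down genome (4 autosomes + X,
~1,200 bins) so the suite stays fast; the properties they check (label
partitioning, classifier specificity, oracle equivalence, ratio recovery)
are scale-free. Tests of quantities that are *not* scale-free — the ~56 kbp
bin span, GC-correction residual correlation, GC-fit idempotence, the
c=4 event amplitude, and the dilution detection limit — run on the full
50,000-bin male genome. The aberrance false-positive-rate check (200 null
samples against an independent 50-control panel) runs at the reduced scale
for budget reasons; the classifier compares cumulative lengths against
control statistics computed on the same genome, so its error rate does not
depend on genome size.

# Known limitations

* Segment-level significance is per-split; no cohort-level significance
  (GISTIC-style) is computed, by scope.
* At ~0.1x coverage the per-bin log2 noise SD is ~0.14; marginal 3-10-bin
  segments at ±0.2-0.3 occasionally pass the permutation test, and serial
  comparisons of such profiles show small noise-level differential
  regions. The focal criteria (gene content, flank margins) are what
  suppress these in event calling, exactly as in the original design.
* Absolute copy number / ploidy is not modeled; the tumour-content ratio
  fit is a relative adjustment, not a purity estimate.
* The Poisson default is an assumption; real plasma libraries show mild
  overdispersion, available via the negative-binomial option.
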