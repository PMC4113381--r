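---
title: "Mapping transcriptional correspondence between zones of layered cartilage tissues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transcriptional correspondence between zones of layered cartilage tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonecor)
```

## The problem

Articular cartilage (superficial and intermediate/deep zones, SZ and IDZ)
and growth plate cartilage (resting, proliferative, and hypertrophic zones,
RZ, PZ, HZ) are layered tissues that arise from a common cartilaginous
condensation. A natural question is which zones of one tissue are
transcriptionally most similar to which zones of the other. When the two
tissues are profiled in separate experiments on different microarray
platforms, absolute expression levels cannot be compared across datasets;
what *can* be compared is whether a gene is spatially regulated — whether it
is called up in one zone versus an adjacent zone within its own dataset.
zonecor implements that comparison end to end: spatial
differential-expression calling within each tissue, cross-platform
directional gene-list overlap testing between tissues, marker-set
localization, exploratory sample structure, and ΔΔCT qPCR validation
statistics, all driven by a seeded synthetic-data generator so the whole
chain is testable without any external data.

## The model and procedure

**Spatial regulation.** Within a tissue, a gene is *spatially regulated*
between zones $a$ and $b$ when its group means differ by a linear fold
change of at least 2 **and** the one-way ANOVA false discovery rate
(Benjamini–Hochberg, computed across all genes of that zone-pair family)
is below 0.05. The ANOVA runs on log2 expression values; with two groups it
is identical to a pooled-variance t-test ($F = t^2$). Group means are
antilogged (geometric means on the raw scale) before the ratio, which is
what makes the package's fold changes reproduce raw-signal arithmetic such
as 940 vs 39 → 24-fold. Each zone pair yields two disjoint *directional
lists* (genes up on each side).

**Overlap testing.** For tissue A directional list $L_A$ and tissue B
directional list $L_B$, both restricted to the universe of $N$ genes
present on both platforms (case-insensitive symbol match), membership forms
a 2×2 table with cells $(k,\; n_A-k,\; n_B-k,\; N-n_A-n_B+k)$. Under
independence the expected overlap is $n_A n_B / N$. The statistic is the
Pearson chi-square without continuity correction (df = 1); the expected
cell counts in the intended regime (thousands of shared genes) are large,
so the continuity correction would only bias the test conservative. All
$2 \times 6 = 12$ comparisons between one articular zone pair and three
growth-plate zone pairs are tested, and the family of raw p-values is
Holm–Šidák corrected: sorted ascending,
$\tilde p_{(i)} = 1 - (1 - p_{(i)})^{m-i+1}$, then made monotone and capped
at 1. A comparison is reported *more than* or *less than expected by
chance* only when its adjusted p-value clears $\alpha = 0.05$; otherwise it
is non-significant, mirroring the three-way outcome such analyses report.

**Marker localization.** A zone's known marker set, restricted to the
universe ($K$ markers), is intersected with each directional list
($k_{up}$ of $K$) and assessed with the same chi-square overlap test.
Marker sets are tested individually, without family correction — they are
reported as separate per-set results, not as one decision family; both
choices are arguments.

**Structure.** PCA operates on gene-centered log2 values (samples as
observations); `mode = "standardize"` switches to correlation-mode PCA.
Hierarchical clustering uses Euclidean distance on per-gene z-scores with
average linkage. Neither choice is forced by the method being emulated —
analysis suites differ here — so both are explicit, documented arguments,
and sample ids are sorted before clustering so ties break deterministically
and the tree is invariant to input column order.

**qPCR.** Relative expression is
$2^{-(C_{T,i} - C_{T,ref})} \times 10^6$ against the 18S rRNA housekeeping
gene; the $10^6$ factor only scales the numbers and cancels in every
comparison. Technical triplicates are averaged at the CT level before
biological statistics — averaging at the relative-expression level instead
would weight wells unequally after the antilog. Zone comparisons run on
log2 relative expression: a one-way repeated-measures ANOVA (zone within
animal, tested against the animal × zone residual) followed by two-sided
paired t-tests for the predetermined pairs SZ–IDZ, RZ–PZ, PZ–HZ, RZ–HZ. No
sphericity correction is applied (a limitation; with n = 4 animals and at
most 5 zones the correction is poorly estimated anyway).

**Probe-level summarization.** For probe-set data the package provides the
two normalization components of RMA that operate on a probe-by-sample
matrix: quantile normalization (every column mapped to the per-rank
cross-column means; ties receive the mean of the tied reference values,
making the map idempotent and rank-preserving) and median-polish
summarization per gene (rows = probes, columns = samples; the per-sample
summary is grand effect + column effect). Median polish sweeps rows first,
then columns, stopping when the largest effect update falls below
`tol = 1e-6` or after `max_iter = 10` sweeps — enough for the short, wide
blocks probe sets produce. Probe-level background correction is out of
scope: it needs raw CEL-level data this package does not consume.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions every
recovery claim is made under.

* **Design.** Two tissues with ordered zones (articular SZ/IDZ;
  growth-plate RZ/PZ/HZ in `study_design()`), **n = 4 replicate samples
  per zone**, matching the zonal microdissection design being emulated.
* **Baselines.** Per-gene baseline log2 means are Uniform(5, 12), the
  intensity range implied by raw signals of roughly 25–13,700 in published
  zonal array tables.
* **Noise.** Gaussian replicate noise with sigma = 0.35 log2 units. Zonal
  variance estimates are not published for this design, so sigma is a
  declared default, chosen to give high power for 2-fold effects at n = 4 —
  the detection regime the calling rule presumes.
* **Programs.** A zone program is a gene set with a log2 effect per zone.
  Per-gene effect magnitudes are the program's base effect times
  Uniform(1, 2.5): real zonal programs show fold changes spanning 2–25, not
  a single value. The recorded truth lists exactly the genes whose planted
  effect difference for a zone pair reaches the declared fold threshold.
* **Platforms.** Both tissues' gene universes are sampled from a shared
  synthetic symbol pool with a platform_overlap fraction (default 0.9) in
  common, mirroring the cross-platform intersection step.
* **Sharing.** Linked programs (IDZ↔RZ and SZ↔HZ by default) draw a
  fraction rho (default 0.8) of their genes from the platform intersection
  and plant them in both tissues; the remaining genes are drawn
  independently per tissue, so rho = 0 is an exact independence null for
  the overlap test.
* **Seeding.** One master seed; universes/program assignment and each
  tissue's matrix use documented substreams derived from it, so a single
  design reproduces every output byte for byte.
* **qPCR.** CT values follow the standard relation of one cycle per log2
  unit: ct = base CT − planted effect + noise (default 0.3 cycles), in
  triplicate, with the reference gene measured per (animal, zone).

What the generator does *not* emulate: probe-level optical background and
GC effects, correlated biological pathway structure among planted genes,
array-specific batch effects, and heavy-tailed noise. Passing recovery
tests therefore show that the inference chain is correct and calibrated
under its own assumptions — not that those assumptions hold on any
particular real dataset.

## Numerical choices and degenerate inputs

* Gene identity is case-folded symbol match throughout; duplicate rows
  collapse to the smallest DE p-value when DE context exists, else the
  highest mean expression (probe-set to gene collapse conventions are
  rarely stated; this one is declared and tested).
* Zero within-group variance with unequal means is reported as p = 0 with
  a warning and a degenerate flag; all-identical values give F = 0, p = 1.
* Overlap tables with a zero or full margin are flagged degenerate (p = NA,
  no direction) rather than tested.
* Constant genes z-score to zero rows with a warning.
* BH is computed within each zone-pair family rather than pooled across
  pairs, since each pair is treated as its own comparison; the Holm–Šidák
  family is the 12 cross-tissue comparisons.

## Problem sizes used in validation

The test suite and the acceptance script exercise the pipeline at sizes
chosen to make every claim measurable in seconds: spatial-DE recovery on
10,000 genes with 500 planted ≥2.5-fold genes (recall ≥ 0.90, empirical
FDR ≤ 0.10 at sigma = 0.35, n = 4); correspondence recovery on 2,000-gene
platforms with 150-gene programs at rho = 0.8; and null calibration of the
familywise error over hundreds of rho = 0 replicates at 1,000 genes
(observed rate ≈ 0.03–0.05 against the [0.02, 0.08] acceptance band).
These are scaled-down stand-ins for a full array experiment (~20,000+
probe sets); the statistical machinery is identical and none of the
operations' complexity depends on anything but gene count.

## Known limitations

* The per-pair two-group ANOVA is the literal reading of the calling rule;
  an alternative is a joint ANOVA across all zones with per-pair contrasts,
  which would share variance estimates. The package fits per pair.
* No moderated (shrinkage) variance estimation; at n = 4 a limma-style
  estimator would add power on real data, but it is not part of the
  procedure being implemented.
* Chi-square overlap tests are asymptotic; for small universes or tiny
  lists a Fisher exact test would be preferable, and degenerate margins
  are flagged rather than approximated.
* Published counts that depend on the actual deposited arrays (the
  12,593-gene shared universe, specific marker-localization counts, the
  68.3% retained PCA variance) require the original platform annotation
  and are deliberately not reproduced here; the package validates the
  machinery on synthetic truth instead.
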