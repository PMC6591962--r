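---
title: "Methods: mapping the tissue of origin of plasma cfDNA from methylation marker counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping the tissue of origin of plasma cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfdecon)
library(dplyr)
```

## The problem

Plasma cell-free DNA (cfDNA) is released by dying cells throughout the
body. In healthy adults it is overwhelmingly hematopoietic (white blood
cells, WBC), but solid tissues contribute small fractions that rise when
those tissues are injured. Because every cell type carries a distinctive
DNA methylation pattern, methylation can identify which tissue a cfDNA
molecule came from, and — with a reference panel of tissue methylomes — how
much of the plasma pool each tissue contributes.

`cfdecon` implements this analysis for targeted methylation sequencing of
CpG-island loci anchored at the 7-mer CGCGCGG. The assayed unit is a
(site, downstream CpG index) pair: a sequenced molecule counts at index
*j* only when **every** CpG from the anchor through *j* is methylated (a
fully methylated molecule, FMM). Counting FMMs rather than average
methylation suppresses the partially methylated background that
hematopoietic DNA produces at hypermethylated CpG islands.

## Quantification: MePM

For sample *s* and marker *(site, j)*,

$$\mathrm{MePM} = \frac{\#\mathrm{FMM}(site, j, s)}{\text{total uniquely mapped reads}(s)} \times 10^6 ,$$

"methylated alleles per million mapped reads". MePM is non-increasing in
*j* by construction (a prefix property), which the package asserts on all
outputs. The denominator counts read pairs (molecules); this convention is
applied consistently on both the plasma and the reference side, so any
constant factor cancels in the mixture model. Matched sample pairs can be
brought to a common effective PCR duplication rate before comparison;
`normalize_duplication()` downsamples duplicate reads of the higher-rate
member (preserving the count nature of the data) or, alternatively,
rescales the denominator; downsampling is the default because MePM values
stay realizable count ratios.

## Marker selection

Tissue-specific hypermethylation markers are selected per candidate
marker from per-tissue mean MePM profiles with five rules, applied in a
fixed order so each rejection is attributed to exactly one rule:

1. **(v)** the marker CpG lies < 60 bp from the anchor (longer amplicons
   are unreliable in short cfDNA fragments);
2. **(iii)** the 90th-percentile MePM over a training cohort of 29 WBC
   samples equals 0 — the nearest-rank (type-1) percentile is used so the
   equality test is exact on count data;
3. **(ii)** MePM > 10 in the most hypermethylated tissue;
4. **(i)** tissue-specificity index
   $\tau = \sum_i (1 - x_i/\max(x)) / (N-1) > 0.9$ (strictly greater);
5. **(iv)** mean liver MePM < 1 when the top tissue is not the liver (the
   liver dominates healthy plasma cfDNA, so liver-leaky markers of other
   tissues would inflate their estimates).

Ties for the most hypermethylated tissue are broken by a fixed tissue
order (liver first); ties only arise on degenerate all-equal profiles. For
lung and muscle — tissues with weak CpG-island hypermethylation — a panel
built with all five rules can come out empty; in that case selection for
those tissues is re-run without the $\tau$ rule, keeping rules (ii)–(v)
unchanged.

For carcinoma applications, `filter_hcc_safe_markers()` drops markers
hypermethylated in liver tumors: liver markers are kept when a one-tailed
(tumor greater) Mann–Whitney–Wilcoxon test against adjacent non-cancerous
tissue gives P > 0.05, other markers when the tumor 90th-percentile MePM
is below 10.

## The mixture model and its solver

With $\overline{MT}_{ik}$ the reference MePM of marker *i* in tissue *k*
and $\overline{MP}_i$ its plasma MePM, the mixture model is linear:

$$\overline{MP}_i = \sum_k \overline{MT}_{ik} \, P_k, \qquad 0 \le P_k \le 1 .$$

WBC is deliberately not a component: the markers are selected to be silent
in WBC, so the hematopoietic majority contributes (approximately) nothing
to the left-hand side. To stabilize the system, each tissue's markers are
aggregated into a single combined marker by summing all but the strongest
one. The excluded marker is fixed by the reference panel (largest
source-tissue mean), **not** per sample: dropping a per-sample maximum
would make the aggregate a non-linear statistic of the counts and break
the linearity the solver relies on (both modes are available in
`aggregate_markers()`). This yields one equation per tissue — an 8×8
system for the default panel.

The system is solved by particle swarm optimization (PSO) minimizing the
sum of squared residuals — the objective is not dictated by the model, but
least squares is the standard choice for an overdetermined linear system
and makes the solution comparable to constrained least squares, which the
test suite uses as an independent oracle. Settings: 50 particles, 500
iterations, constriction coefficients (inertia 0.729, cognitive = social =
1.49445), box constraints $[0,1]^8$, and the element-wise **median of 10
independent runs** as the readout, which suppresses the occasional stray
run. All settings are exposed in `pso_config()`.

**Bound handling.** Particles that leave the box are reflected (position
mirrored at the wall, velocity reversed and damped by 0.5). Absorbing
walls — clamping with velocity zeroing — were tried first and stagnate: in
realistic plasma samples the optimum sits in a corner region where most
fractions are zero and the non-zero ones are a few 10<sup>-3</sup>, and a
swarm absorbed at the origin loses all velocity there and never resolves
fractions of that size. With reflection, the median-of-10 readout matches
box-constrained least squares to ~10<sup>-9</sup> on noiseless systems.

The oracle-equivalence tests draw random systems with the structure that
marker aggregation actually produces — a strong source-tissue diagonal
(tens to thousands of MePM) and near-zero off-target entries (bounded by
the selection rules). Dense matrices with large correlated off-diagonal
entries are not a regime the marker pipeline can emit.

## Background correction and absolute levels

Deconvolving pure WBC samples yields small spurious tissue fractions.
Correction is two-step, per tissue: measured fractions below a zeroing
threshold (the WBC-cohort mean + 3 SD) are set to zero, and the WBC mean
is subtracted from the survivors. The threshold is tested on the *raw*
fraction and subtraction applied afterwards; testing on the subtracted
value instead would shift decisions only within one background mean of the
threshold. Defaults are the constants estimated from fourteen healthy
paired WBC samples (`wbc_background_model()`); `estimate_wbc_background()`
recomputes them from any WBC cohort.

Corrected fractions convert to absolute levels as

$$\mathrm{GE/mL} = P_k \times \frac{\text{cfDNA (ng/mL)} \times 1000}{3.3\ \mathrm{pg/GE}},$$

haploid genome equivalents per millilitre of plasma; 3.3 pg per haploid
genome is the conventional constant and is configurable.

## The synthetic-data generator

`generate_reference_panel()` and `simulate_mixture_series()` emulate the
study design the pipeline targets, and their defaults *are* those
conditions: 8 tissues (liver, lung, stomach, colon, kidney, pancreas,
muscle, skin) with 59/8/9/20/13/18/11/8 markers, source-tissue MePM
uniform on [10, 100], essentially zero off-target signal (uniform on
[0, 0.5]) and zero WBC leak, a 29-sample WBC training cohort, 14
WBC/plasma pairs with a 1.3% liver fraction in plasma (the healthy-adult
scale), and 3×10⁶ mapped reads per sample.

FMM counts are Poisson with mean
$\text{reads}/10^6 \times \sum_k f_k \overline{MT}_{ik}$ — the natural
model for independently sampled rare molecules; the mixing is done at the
count level since molecule-level mixing of real reads is not reproducible
without the raw data. Each FMM is emitted as a molecule record methylated
through the marker's CpG index, plus partially methylated background
molecules (default rate 1 MePM) that exercise the FMM filter without ever
counting at the marker index. Optional decoy markers stress the selection
rules: far-CpG decoys (≥ 60 bp), shared-tissue decoys (a second tissue at
80–100% of the source signal, τ ≤ 0.9), and WBC-leaky decoys.

What the generator does **not** emulate: real fragment-length and
duplication structure, bisulfite conversion errors, inter-individual
variability of the tissue references, correlated (non-Poisson) counts, and
genuine low-level WBC methylation at marker loci. Passing tests therefore
demonstrate the pipeline's statistical machinery under the assay's design
assumptions, not its performance on any particular clinical cohort.

## Spike-in accuracy and detection limits

`spikein_benchmark()` runs the accuracy experiment end to end: tissue DNA
spiked into WBC background at 0.25–16% (doubling grid), 10 replicates per
level plus 10 WBC-only replicates, deconvolved, then evaluated by

* **recovery** — OLS of estimated on true fraction per tissue (slope,
  intercept, R²), and
* **detection limit** — the smallest level whose estimates differ from the
  WBC-only replicates by a two-tailed t test at P < 0.05. The test is run
  on estimated fractions (not marker MePM), since fractions are the
  quantity reported downstream.

The package's own benchmark and acceptance runs use 3×10⁵ reads per
sample — a tenth of the default depth — with the full 146-marker panel and
the full 7-level × 10-replicate series; at this depth a liver spike-in
gives R² ≈ 0.98 and a 0.25% detection limit, and the whole experiment (80
PSO deconvolutions, 800 swarm runs) completes in well under a minute.
Deeper simulation sharpens the low end of the dilution series but does not
change the conclusions.

## The hepatocyte-turnover worked example

`hepatocyte_turnover()` converts a liver cfDNA fraction into a daily cell
loss. With cfDNA at 1000 diploid genome equivalents per mL, a liver
fraction of 1–2%, a DNA distribution volume of 60–70 mL/kg in a 70-kg
adult, and first-order clearance with a 1-hour half-life, the circulating
liver-derived pool is replaced $\ln 2 / t_{1/2}$ times per hour:

$$\text{cells/day} = \underbrace{1000 \times f_{liver} \times V}_{\text{pool}} \times \frac{\ln 2}{t_{1/2}} \times 24 .$$

At midpoint parameters this gives ≈ 1.1×10⁶ hepatocytes per day — about
0.0005% of the ~2.4×10¹¹ hepatocytes in the liver — and the parameter
interval spans ≈ 0.7–1.6×10⁶, bracketing the round figure of ~1.2×10⁶
usually quoted. A "pool replaced once per half-life" mode is not offered:
first-order kinetics is what a stated half-life means.

```{r turnover}
hepatocyte_turnover()
```

## Numerical choices and degenerate inputs

* **Fold change with zero means** (`identify_dm_sites()`): both group
  means get a pseudocount (default 0.1 MePM) before the ratio; WBC means
  of 0 are routine, and reporting finite fold changes requires some
  regularization. The value is configurable and its exact choice moves
  only loci that are borderline on the fold-change axis.
* **MWW p-values**: exact null distribution when both groups have ≤ 8
  tie-free observations, normal approximation with tie correction
  otherwise; two groups with all values identical give p = 1.
* **FDR**: Benjamini–Hochberg step-up (`bh_fdr()`), the standard "FDR
  analog of the p-value".
* **Expression z-scores** for tissue-specific genes are computed across
  tissues on log2(x+1) means; expression distributions are heavy-tailed
  and a linear-scale z-score would be driven by a single tissue's
  magnitude rather than its rank among tissues.
* **Intragenic windows** are strand-aware: [TSS+300, TES+300) in
  transcription direction, so promoter-proximal CpGs are excluded.
* **Degenerate inputs**: zero-read samples yield an empty molecule table
  with a warning (MePM undefined); all-zero τ profiles, empty groups,
  empty marker lists and single-replicate detection tests raise typed
  errors (`cfdecon_domain_error` and friends) rather than propagating NaN.

## Known limitations

* The reference panel enters as per-tissue mean MePM; uncertainty in the
  reference is not propagated into the fraction estimates.
* The linear model ignores inter-marker dependence within a tissue
  (aggregation makes this mild but not zero).
* Detection limits are grid-resolved: the reported limit is the smallest
  *tested* fraction that separates from the null.
* Lung and muscle markers selected via the τ-free fallback are less
  specific by construction; their fractions should be read with that in
  mind, as should any tissue whose equation was dropped for lack of
  markers.
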