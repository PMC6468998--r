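---
title: "Methods and design notes for liquidlens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for liquidlens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`liquidlens` implements the computational stages of a multi-analyte
liquid biopsy: copy-number instability (CNI) scoring of shallow
whole-genome cfDNA sequencing, PCA-LDA classification of drop-deposited
plasma Raman spectra, circulating-tumour-cell (CTC) enumeration
statistics, and a blood expression-signature filter. This vignette is the
package's own account of the models behind each stage, the parameters
that matter, the numerical choices made where the method leaves them
open, and what the synthetic-data generators do and do not emulate.

# Copy-number instability scoring

## Model

Aligned cfDNA fragments are binned into a fixed genome-wide window frame
(default 701 windows over the hg19 autosomes). For a sample with
`totalReads` fragments, the per-window log2 read ratio is

```
ratio_w = log2((count_w + pc) / (expected_w + pc)),
expected_w = totalReads * len_w / total_bp
```

with pseudocount `pc = 0.5` so zero-count windows stay finite. A
reference panel of normal cfDNA profiles supplies the null model: the
per-window sample mean `mu_w` and SD `sigma_w` of the panel's log2
ratios, with `sigma_w` floored at `1e-4` so a degenerate panel cannot
blow up the standardisation

```
z_w = (ratio_w - mu_w) / sigma_w.
```

Windows rejecting equality to the reference at a two-sided per-window
false-positive rate `alpha = 0.002` contribute to the score. The default
`cdf_sum` convention sums the standard-normal CDF of the absolute
Z-values over rejected windows; `abs_z_sum` sums `|z_w|` instead. The
phrase "summing the absolute values of the Gaussian CDF" is genuinely
ambiguous between the two, so both are implemented and the convention is
recorded in every `CNIResult`; neither is asserted to be "the" published
variant.

## Finite-panel calibration

With panel mean and SD estimated from `n` samples, the exact null
distribution of `z_w` is not standard normal but `sqrt(1 + 1/n) * t_{n-1}`.
At `n = 133` and `alpha = 0.002` the plain normal cutoff
`qnorm(1 - alpha/2) = 3.09` would reject about 0.25% of null windows
instead of the stated 0.2%. `cniScore()` therefore uses the calibrated
threshold

```
z_crit = sqrt(1 + 1/n) * qt(1 - alpha/2, n - 1)
```

whenever the Z-profile carries its panel size (the default path through
`zProfile()`), and the plain normal quantile when it does not. The
acceptance suite verifies the realised rate against 0.2% within three
Monte-Carlo standard errors.

## Window construction

The window count is taken as authoritative: 701 windows at ~5.5 Mbp
quoted together are mutually inconsistent with the hg19 length, and a
single fixed span with truncated chromosome ends cannot hit an exact
total (the per-chromosome ceilings overshoot by roughly one window per
two chromosomes). `partitionGenome(nWindows = )` therefore apportions
windows to chromosomes by the largest-remainder rule proportional to
length (each chromosome gets at least one) and tiles each chromosome
with near-equal integer windows, guaranteeing the exact count and exact
coverage. The `spanBp` mode keeps literal fixed-span tiling. Sex
chromosomes are excluded by default because a mixed-sex panel makes X/Y
ratios bimodal; `includeSex = TRUE` overrides. All coordinates are
0-based half-open (BED dialect); fragments are assigned to the window
containing their midpoint. No GC-content or mappability correction is
applied; this is a deliberate extension point, not an oversight.

Tissue profiles use a different normalisation — log2 of counts over the
median window count — with gains above +0.15 and losses below −0.15, the
conventional display thresholds for tumour material.

# Raman classification

## Preprocessing

Each spectrum (one map average) is processed independently: baseline
subtraction followed by standard normal variate (SNV) normalisation
(subtract the spectrum mean, divide by its SD). Because both operations
use no cross-spectrum statistics, preprocessing cannot leak information
across cross-validation folds; only the PCA centre/loadings and the
discriminant are fold-specific.

The baseline method is not dictated by the measurement itself, so two
standard estimators are provided. The default is asymmetric least
squares (Eilers-style: second-difference smoothness penalty
`lambda = 1e5`, asymmetry `p = 0.01`, 10 reweighting iterations), the
usual choice for the broad fluorescence background of NIR-excited
biofluid spectra; an iterative polynomial fit (order 5) is the config
alternative. Both reproduce a pure linear ramp to numerical precision
and recover a synthetic peak's area within 5% on a curved background
(tested).

## PCA-LDA with participant-level cross-validation

PCA retains the smallest number of components explaining 95% of training
variance, capped at 20; a fixed `k` overrides. The cap keeps the
discriminant's within-class scatter estimable on folds with 29 training
participants. The two-class Fisher discriminant is the closed form
`w = Sw^{-1}(mu1 - mu0)` with `Sw` regularised by `1e-6 * trace/dim` on
the diagonal; the decision threshold is the midpoint of the projected
class means, and a score exactly at the threshold is called control
(conservative tie-break). Cancer is the positive class for sensitivity;
control is the negative class for specificity.

Cross-validation is leave-one-participant-out: all spectra of one
participant form the test fold, the remaining participants train the
fold's PCA and LDA, and every spectrum is predicted exactly once. A fold
whose training set loses a class is skipped with a warning and recorded.
With the default 30-participant design this yields 30 folds of 174
training spectra each.

# CTC enumeration

The gate is a pure per-event rule: AF488 (pan-cytokeratin) above
threshold, CD45 at or below threshold (inclusive, so the rule
partitions), DRAQ5 above threshold; an optional pixel-area min/max gate
is off by default. Numeric thresholds are instrument- and
staining-dependent and are configuration, not constants — the defaults in
`defaultGates()` are calibrated to the synthetic generator's populations
(separated by > 4 SDs per channel) and are documented as fixture values.
Counts are reported per 10,000 captured cells, table rows being taken as
captured events. ROC curves sweep every unique score value with
prediction positive at-or-above threshold; the trapezoid AUC then equals
the Mann–Whitney U statistic over class pairs (ties counting one half),
hence is invariant under monotone transforms. Group comparison is
classical one-way ANOVA with Tukey HSD contrasts at p < 0.05;
Mann–Whitney is available as a config alternative
(`groupTest(..., method = "wilcox")`) for two-group count data; ANOVA
remains the default.

# Expression signature

Tiering partitions genes into strict (p < 5e-5, |log2FC| > 2), moderate
(p < 0.05, |log2FC| > 2, not strict) and unchanged. The blood signature
filter requires all three gates simultaneously: case expression above
5 FPKM (the conventional floor for calling a protein-coding gene
transcribed), significance at p < 0.05, and log2FC > +2 — up-regulation
only, since the filter targets genes overexpressed in patient blood.
"Significant" is read as the p-value at the moderate-tier alpha;
q-value gating is available (`useQ = TRUE`) but off by default. The
tissue/blood overlap is counted on |log2FC|-defined DE sets, both
directions, because most shared genes are down-regulated. Fold-change
sign convention is case over control, as produced upstream.

# Synthetic-data generators

Every generator is a pure function of its parameters and seed, and
returns ground truth alongside the data.

**cfDNA (`simCfdna`)**: per-window Poisson counts with rate proportional
to window length, a per-sample lognormal window effect (SD 0.05 in log2
units — a modest inter-sample noise chosen in the absence of a stated
noise model), and, in test samples, the copy-ratio mixture
`1 + tf*(r - 1)` over aberrant windows. Default depth is 1e6 reads so
the suite runs at desk speed; the study-scale 3e7 is an argument away.
At 1e6 reads the combined per-window null SD is ~0.063 log2 units
(lognormal 0.05 plus Poisson ~0.038), which sets the detection limit:
a single-copy gain (ratio 1.5) at tumour fraction 0.2 sits near z = 2.2
per window and is *not* reliably flagged; by tumour fraction 0.4 the
per-window power is ~87% and a 3-window lesion is flagged in ~99.8% of
replicates (the recovery test uses this interior point).
`cfdnaExpectedProfile()` returns the noise-free expectation profile,
used to show CNI = 0 at null and strict growth along a tumour-fraction
grid with a graded-amplitude lesion (the CDF-sum convention saturates in
double precision for |z| > ~8, so only a lesion whose shoulders cross
the threshold one after another makes strict monotonicity a
well-posed deterministic claim).

**Raman (`simRaman`)**: spectrum = smooth exponential fluorescence
baseline + seven fixed biological peaks (850–1660 cm⁻¹) + three
carotenoid bands whose amplitude is multiplied by `1 - depletionEffect`
in the cancer class. The band centres 1008/1158/1524 cm⁻¹ are canonical
carotenoid Raman bands adopted as fixture constants — the source
measurements highlight three depleted bands without printing
wavenumbers, so these are explicitly fixture values, not reported ones.
Hierarchy follows the study design (20 cancer / 10 control × 3 drops ×
2 maps). Per participant: one shared lognormal carotenoid factor
(log-SD 0.08) and independent lognormal jitter on the other peaks
(log-SD 0.05); per spectrum: a global lognormal intensity scale
(log-SD 0.15, removed by SNV) and additive white noise (SD 0.01). The
default depletion effect 0.3 places the class separation at ~4.5
participant-level SDs, a clearly learnable but not degenerate task.
Note the design's asymmetry: with only 10 control participants, each one
is worth 10 percentage points of specificity, so cross-validated
specificity is the quantised, occasionally borderline figure.

**Events (`simEvents`)**: planted CTC rows from a bright-AF488 /
dim-CD45 / bright-DRAQ5 / large-area population, background from the
leukocyte converse, truncated normals, shuffled, truth flags returned.

**Expression (`simExpression`)**: planted DE sets sized to the study's
Venn structure (335 blood-only, 272 tissue-only, 21 shared) with
exactly 18 genes passing all signature gates (16 blood-only + 2 shared
up-regulated); all other DE genes fail at least one gate and null genes
fail the DE definition itself.

What the generators do **not** emulate: GC/mappability coverage bias,
fragment-size structure and duplicate reads in cfDNA; cosmic rays,
detector etaloning, wavenumber miscalibration and real biofluid spectral
diversity in Raman; debris, doublets and spillover in cytometry;
correlated gene-gene structure and dispersion estimation in expression.
A green suite therefore demonstrates the correctness and calibration of
the *computations*, not clinical performance on real cohorts.

# Problem sizes and runtime choices

The test suite and acceptance script use desk-scale sizes chosen as the
package's own defaults: 1e6-read cfDNA depth, 200 null samples for the
false-positive-rate check, the full 30-participant Raman design for the
headline cross-validation (seconds per run), reduced designs (8–16
participants, coarser axes) for property tests such as the 50-fold
permutation null, and 10⁴-event tables. These keep the complete suite in
the low minutes on one CPU while leaving every statistical claim testable
at its stated tolerance.

# Known limitations

- CNI is a burden score; no segmentation (CBS/HMM) or tumour-fraction
  estimate is provided, and none is intended.
- The window Z-test assumes approximately normal log2 ratios; at much
  lower depth the Poisson skew would miscalibrate the tails.
- The LDA is strictly two-class with a midpoint threshold; unequal class
  dispersions shift its operating point away from the Bayes boundary,
  which is visible in the synthetic task as specificity lagging
  sensitivity.
- Gate thresholds for cytometry are fixture-calibrated; real instruments
  require their own calibration before the rule is meaningful.
- The expression module consumes upstream statistics as given; it does
  not recompute p-values, FPKM or fold changes.
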