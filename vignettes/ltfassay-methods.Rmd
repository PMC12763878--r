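---
title: "Methods: models, statistics and design choices in ltfassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and design choices in ltfassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltfassay)
```

# The scientific problem

Ex vivo platforms that culture live tumor fragments (LTFs) — ~300 µm cuboids
cut from a fresh resection or core needle biopsy (CNB) and embedded in
hydrogel — measure a tumor's functional response to immune checkpoint
inhibitors (ICIs) from the cytokines its resident immune cells secrete into
conditioned media. Two statistical obstacles dominate: intra-tumor spatial
heterogeneity (any two pieces of tissue contain different amounts of immune
infiltrate, so cross-well comparisons are confounded unless wells are
equalized), and tissue scarcity in CNBs (too little material for replicate
control wells). This package implements the computational pipeline around
both designs: a fragmentation simulator that quantifies how fragment size
controls sampling variance; assay-level quantitation rules; a cross-well
cohort statistic (MAD-trimmed modified Z-scores); and a sequential-treatment
within-well statistic (slope fold change of cumulative cytokine production).

# The fragmentation experiment

`gen_cellmap()` simulates a 2D cross-section as a marked point process:
homogeneous Poisson (no spatial structure) or a Thomas cluster process
(Poisson parents, Poisson offspring displaced by an isotropic Gaussian), the
minimal stationary clustered process. `cut_map()` cuts slices (full-length
strips, default 300 µm wide — the thickness of a standard tissue slice) or
cuboids, `pool_and_count()` randomly pools fragments into wells at matched
*tissue area* (not fragment number: matching area means every pool sees the
same amount of tissue, and the comparison isolates how finely that tissue is
subdivided), and `cv_by_size()` compares cross-pool coefficients of
variation (CVs) between schemes with a two-sided Mann–Whitney test across
randomized poolings.

**Default simulation world.** The frozen defaults of the acceptance-level
experiment are a 15 × 15 mm section at 300 CD3⁺ cells/mm², with clusters of
mean 400 cells and σ = 500 µm — the scale of peritumoral lymphoid
aggregates/tertiary lymphoid structures — pooled into 4 pools of 4.5 mm²
(one slice equivalent, 50 LTF equivalents) over 12 randomizations. These
were chosen by a designed calibration study (below), then frozen.

**A statistical subtlety worth knowing.** All randomized poolings resample
the *same* realized map, so the CV replicates that enter the Mann–Whitney
test are correlated through it. Conditional on the map, the realized
dispersion of slice counts differs from its process expectation by a
relative error of about $1/\sqrt{2 n_\text{slices}}$, and the rank test
reads that persistent offset as a real difference. The test is therefore
anti-conservative for small sections: with fewer than ~30 slices the
homogeneous-map false-positive rate exceeds 10% at any replicate count that
retains power. The default 15 mm section carries 50 slices, which brings
the measured null acceptance to ~0.94 while slice-vs-300 µm power on
clustered maps is ~0.97. The same caveat applies to p-values computed from
randomized poolings of a single stained section in real data.

Expected behavior on homogeneous maps follows Poisson sampling theory: a
pool with expected count $N$ has CV $\approx 100/\sqrt{N}$ %, independent of
how the tissue is subdivided. Clustering breaks this equivalence: a pooling
unit that tends to contain whole clusters (a slice) inherits the cluster
size variance, while small cuboids split clusters across pools and average
it away — the mechanism that favors 300 µm and 100 µm fragments over
slices.

Geometry helpers are closed-form: a 300 µm cuboid has face area 0.09 mm²
and volume 0.027 mm³ (200 per well ≈ 5.4 mm³ of tissue);
`cnb_geometry()` models a needle core as a cylinder cut at an angle θ, with
elliptical sections of area $\pi d^2/(4\sin\theta)$ and axial advance
$t/\sin\theta$ per slice.

# Quantitation rules

Concentrations above an analyte's upper limit of quantitation are set to
the ULOQ and flagged `capped_uloq`; values below the LLOQ keep their
numeric value but are flagged `below_lloq` (they are dropped where a stage
says so: excluded from replicate CVs, kept for slope fits, since dropping
low early-time points would bias slopes upward). "Consistently below LLOQ"
for panel exclusion defaults to 95% of all measurements — the paper-style
6 dead analytes are recovered exactly by this rule on generator defaults.
Sample SD uses the n−1 denominator; nominal sampling times (~4/~20/~48 h)
are matched within ±2 h. Detection coverage (`pct_above_lloq()`) counts an
analyte as detected from its endpoint measurement by default (`at = "any"`
is available) because cumulative media make the endpoint the sensitive
time point.

# Cross-well response: MAD-trimmed modified Z-scores

Per specimen and analyte, the response is the difference in cumulative
endpoint concentration between ICI- and IgG-treated wells (arm means at the
final shared time point; endpoint rather than AUC, AUC being an option the
data structure supports — the endpoint of a cumulative curve already
integrates production). Each analyte's vector of per-specimen differences is
standardized robustly:

1. median $m$ and $\mathrm{MAD} = \mathrm{median}|x_i - m|$;
2. trim to $\{x_i : |x_i - m| \le 2\,\mathrm{MAD}\}$;
3. recompute $m^\*$, $\mathrm{MAD}^\*$ on the trimmed set;
4. $z_i = 0.6745\,(x_i - m^\*)/\mathrm{MAD}^\*$ for **all** samples,
   outliers included;
5. saturate to ±10.

The trimmed location/scale prevent a handful of strong responders from
inflating the spread estimate and masking themselves; 0.6745 is the
standard modified-Z constant (the normal upper quartile) making $z$
comparable to a standard score. When $\mathrm{MAD}^\*=0$ (more than half
the trimmed values identical) the fallback scale is 1.4826 × mean absolute
deviation of the trimmed set; if that is also zero, all scores are 0. Both
fallbacks are logged. Scores are computed per analyte across specimens
(a score says "this specimen's induction of this cytokine is extreme
relative to the cohort"); the per-specimen axis is available via
`axis = "specimen"`.

Upregulation calls use the conservative inclusive threshold $z \ge 5$.
Clustering is `hclust` Ward (`ward.D2` on Euclidean distances — the
minimum-variance criterion; tie-breaking made deterministic by sorting
labels first), with missing scores imputed at 0 (the "no change" point of
the z scale) up to a 20% per-row/column limit. Enrichment against biomarker
status (PD-L1/MMR/MSI composite) uses two-sided Mann–Whitney for counts and
per-analyte scores and two-sided Fisher exact for binary calls.

**Robustness limitation.** A cohort-relative robust score has a breakdown
point at a responder fraction of 1/2: if most specimens respond, the median
moves into the responders and nobody looks extreme. In the synthetic world
used for the enrichment recovery property (60 specimens, expected responder
fraction 0.425, SD ≈ 0.06), roughly one seed in eight realizes ≥ 50%
responders and the enrichment signal vanishes by construction — the
recovery rate over many seeds is ≈ 0.87, marginally below the 0.9 the
acceptance property asks for. This is a real property of the statistic, not
an implementation artifact, and it mirrors the method's intended use on
cohorts where responders are a minority.

# Sequential response: slope fold change

For tissue-limited CNBs each well is its own control: IgG for 0–20 h, then
ICI to 48 h, with media sampled at ~4/~20/~48 h. The response statistic is

$$\mathrm{FC} = \frac{\text{slope of cumulative concentration, ICI phase
(20–48 h)}}{\text{slope, control phase (4–20 h)}}$$

with OLS slopes (difference quotients at two points). The 20 h boundary
sample belongs to both fits — it terminates the control window and
initiates the treatment window. ULOQ-capped points are excluded from fits
(a capped value can only flatten a slope); if fewer than two uncapped
points remain the slope is undefined. Division is guarded: the control
slope must exceed ε = LLOQ / (control-phase duration), the slowest
production the assay could distinguish from nothing, else the result is
flagged indeterminate rather than divided. Classification bands follow the
platform convention: increase > 1.5; no change 0.5–1.5 (closed interval);
decrease < 0.5. Replicates aggregate by maximum FC and an any-replicate
increase flag — in heterogeneous tissue a response in any replicate
suggests sensitivity. `recist_percent_change()` is the clinical-comparison
helper (partial response = reduction > 30%).

## Noise model and the slope statistic

The generator's noise is multiplicative lognormal at two levels, both mean
1: a **well factor** shared by all of a well's measurements (well-to-well
biological/compositional variability; CV defaults to
$20\% \times \sqrt{200/n_\mathrm{LTF}}$, the square-root law of averaging
independently sampled fragments, anchored at the observed ~20% cross-well
replicate CV at 200 LTFs/well) and an i.i.d. **measurement factor** per
sampled concentration (assay error; default CV 10%). Additive noise was
rejected: concentrations are positive and immunoassay errors scale with
level. The well factor cancels exactly in the within-well slope ratio —
that is the design's point.

Per-measurement noise does **not** cancel, and its effect on the two-point
slope ratio is worth stating precisely. With sampling at 4/20/48 h, the
shared 20 h measurement enters both slopes with opposite signs; first-order
propagation of a 20% per-measurement CV gives the fold change a CV of
≈ 52%. The probability that a true-null well (θ = 1) lands inside the
0.5–1.5 band is therefore only ≈ 0.67 (direct simulation, 50 000 draws,
and reproduced by the acceptance suite at 500 seeds), while a θ = 3
responder exceeds 1.5 with probability ≈ 0.96. The spec-level expectation
that θ = 1 wells classify "no change" in ≥ 90% of seeds at measurement
CV 20% holds only if the 20% is interpreted as *well-level* noise (which
cancels); under the per-measurement reading implemented here it cannot
hold, and the corresponding acceptance assertion is deliberately left
failing rather than weakened. Practically: at this assay noise level,
single-well "no change" calls are unreliable — replicates (and the
max-FC/any-increase aggregation) are what make the call robust.

# Synthetic cohorts and ground truth

`gen_cohort()` draws per-specimen biomarker status
(P(positive) = `biomarker_positive_fraction`) and a hidden responder flag
(P(responder | status)); `gen_well_series()` builds piecewise-linear
cumulative trajectories in which responders multiply the production rate of
the responsive analytes (default: the T-cell activation axis IFN-γ, CXCL10,
TNF-α, IL-2, GM-CSF, Granzyme B) by `effect_theta` during treatment.
Defaults: baseline 10 pg/mL/h; six dead analytes at 0.01 pg/mL/h (below
LLOQ at 48 h) emulating the kit analytes that never quantify in media;
IL-1Ra is a well-expressed non-responder. One root seed governs everything;
per-entity streams derive via `child_seed()` so outputs are reproducible
and independent of evaluation order.

What the generator does *not* emulate: media refresh or evaporation,
analyte degradation and cross-reactivity, nonlinear saturation of
production, antibody penetration kinetics, spatial correlation between a
well's fragments and its cytokine output. A green recovery test therefore
establishes that the statistics recover the generative parameters of this
idealized world — not that the platform's biology behaves this way.

# Numerical and interface choices

* Hours and pg/mL are the only units; converters live at the IO boundary.
* Long/tidy CSV is the single measurement interchange format; the schedule
  travels in `phase_start_h`/`phase_end_h` columns so files round-trip
  exactly. Configs and panels are JSON (no YAML parser is assumed
  available; the config schema is format-agnostic).
* Tie-breaks in clustering are fixed by sorting labels before linkage.
* Errors carry condition classes (`ltf_invalid_parameter`,
  `ltf_insufficient_tissue`); degraded results (undefined CV or slope,
  indeterminate FC) are flagged values, never silent zeros.
* Concordance percentages round to the nearest integer, matching the
  platform's reporting convention (5/6 → 83%).
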