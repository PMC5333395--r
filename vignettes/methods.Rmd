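---
title: "Quantifying cellular target engagement of KDM inhibitors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cellular target engagement of KDM inhibitors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdmscreen)
```

## The assay and its readout

JmjC histone lysine demethylases (KDMs) are Fe(II)/2-oxoglutarate-dependent
oxygenases that remove methyl marks from histone H3 tails. A cell-based
target-engagement assay for KDM inhibitors transiently overexpresses a
FLAG-tagged demethylase in HeLa cells and reads out the enzyme's substrate
mark (for example H3K4me3 for the KDM5 family, H3K9me3 for KDM4) by
quantitative immunofluorescence. In cells overexpressing active wild-type
(WT) enzyme the mark is depleted; a cell-penetrant inhibitor restores it in a
dose-dependent way. A catalytically dead point mutant (MUT, iron-coordination
residues substituted) provides the key control: its staining level
approximates complete inhibition, so the WT curve should plateau at the MUT
baseline when the inhibitor fully engages the enzyme.

`kdmscreen` implements the full analysis path for this assay — nuclear
segmentation, FLAG gating, per-well aggregation, paired WT/MUT dose-response
fitting, cytotoxicity detection, live/dead triple-stain classification, and
2-oxoglutarate competition modelling — together with a synthetic-microscopy
generator whose pharmacological ground truth is fully specified, so that
every stage can be validated against known answers.

## The generator's response model

For a cell overexpressing active WT enzyme at inhibitor concentration $c$,
the expected mark intensity is a Hill restoration curve

$$ m_{WT}(c) = m_{dep} + (m_{base} - m_{dep})\,
   \frac{c^h}{c^h + \mathrm{EC}_{50}^h}, $$

running from the depleted level $m_{dep}$ (untreated, fully active enzyme) to
the nontransfected baseline $m_{base}$ (complete inhibition). MUT-transfected
and nontransfected cells sit at $m_{base}$, plus two optional terms:

* an **endogenous-inhibition** term, the same Hill form against
  `endogenous_ec50` with amplitude `endo_gain` $\times (m_{base}-m_{dep})$ —
  compounds that also inhibit the cell's endogenous demethylases raise the
  mark above baseline in *all* cells at high dose;
* a **toxicity spike**, `spike_gain` $\times\, m_{base}\,(1 -
  \mathrm{surv}(c))$ with $\mathrm{surv}(c) = tc_{50}^s/(c^s + tc_{50}^s)$ —
  cytotoxic compounds produce an abrupt methylation rise that tracks cell
  loss. The spike applies to WT cells as well, since toxic compounds elevate
  the mark in both populations. The survival Hill slope defaults to $s = 8$:
  cytotoxicity in this assay manifests as a steep crash over one or two
  dilution steps, not a gentle decline.

Per-cell intensities get mean-preserving multiplicative log-normal noise with
coefficient of variation `noise_cv` (default 0.15, a typical cell-to-cell CV
for integrated nuclear immunofluorescence).

Default intensity scales were chosen once to resemble a 16-bit acquisition at
moderate exposure: mark baseline 200 a.u., depleted 40 a.u. (a 5× dynamic
range between MUT and WT vehicle wells), DAPI 500 a.u., FLAG modes 50/1000
a.u. with log-scale SD 0.35, giving ≈8.6 SD of separation between
nontransfected and transfected cells — a strongly bimodal distribution, as
transient overexpression produces. `endo_gain` defaults to 1: at saturating
dose the MUT curve rises by the full dynamic range, the pattern observed for
endogenously active compounds.

### Geometry: what the images emulate

Fields are rendered as multichannel rasters (DAPI, mark, FLAG) at
0.65 µm/pixel, the scale of a 20× widefield objective. Nuclei are ellipses
with median radius 6.5 µm (HeLa nuclear area ≈ 130 µm², conveniently just
above the assay's 100 µm² debris filter) with mild eccentricity jitter
(≤ 0.15) — round shapes keep the segmentation oracle exact. Mark and FLAG
stains are painted over the nuclear mask only, matching their nuclear
localization in the assay; overlapping pixels take the maximum of the
contributing cells; Gaussian background (level 5, SD 2 a.u.) is added last.

Cells are placed on a jittered grid with pitch 2.2 nuclear radii and random
phase. This emulates the spatial statistics of an adherent monolayer, in
which nuclei exclude one another: free uniform placement would let nuclei
interpenetrate deeply at realistic densities, contaminating per-nucleus
intensities in a way real cultures never do, while the jittered grid still
produces touching pairs that exercise the watershed. Dead cells are removed
from the rendered field (the survival readout is the count of remaining
nuclei); the `keep_condensed_dead` option instead retains them as condensed
nuclei below the 100 µm² filter, mimicking apoptotic bodies.

The generator does **not** model point-spread-function optics, illumination
gradients, 3D stacks, mitotic figures, or cell-cycle intensity structure.
Passing tests therefore demonstrate correctness of the analysis logic on
idealized-but-noisy images, not robustness to every optical artifact of a
production microscope.

## Segmentation and filtering

The nuclear channel is smoothed (Gaussian, σ = 1 px), thresholded with Otsu's
method, hole-filled, and split by a watershed on the distance transform
(tolerance 1). Any method that passes the count-conservation property
(detected = generated on ≥99% of sparse fields) is acceptable; the method
identifier is recorded in output provenance. Nuclei **smaller than**
100 µm² are excluded — the comparison is strict, so a nucleus of exactly
100 µm² survives — as are nuclei with any pixel on the image boundary.
Areas are always reported in µm² (pixel count × pixel size²), never in
pixels, which makes them invariant to magnification. Coordinates are
0-based, pixel-centred, row-major.

## Gating and per-well aggregation

The mark is quantified "only in cells strongly overexpressing" the tagged
enzyme. The default gate is Otsu's threshold on log FLAG intensity across the
plate's overexpression wells, with a bimodality guard: if the split's mode
separation is below 3.5 pooled SDs (an Otsu split of a single Gaussian
already yields ≈2.65), the plate is declared unimodal and the gate falls
back to reference-well mean + 3 SD when nontransfected reference wells
exist. Gating is strict (`>`), so in the degenerate all-equal case nothing
is "strongly" overexpressing. Cells are pooled across a well's fields before
averaging (robust to uneven field occupancy); SD uses the sample (n−1)
denominator; wells with fewer than 20 gated cells are flagged
low-confidence, and wells with zero gated cells are flagged rather than
silently dropped. Wells with construct `none` (the endogenous assay, run
without FLAG staining over 9–10 fields) pool all cells ungated.

## Dose-response, engagement and the toxicity signature

Well means are fitted with a four-parameter logistic on log10 concentration
(unweighted least squares, the convention of standard dose-response
software), with multi-start initialization over Hill slopes {±0.5, ±1, ±2}
and EC50 starts at the dose-grid quartiles. The vehicle (0 µM) point is
excluded from the log-dose fit and used only for baselines. Two guards keep
failed fits honest: a series whose 4PL does not beat a constant fit (F test,
α = 0.05) is reported `converged = FALSE` with `flat = TRUE` rather than as
noise-fitted parameters, and a fitted EC50 above the tested range is
qualified `greater_than_top_conc`. A flat series with no observed engagement
also reports `greater_than_top_conc` — the assay statement "EC50 > top
concentration" — reserving `not_converged` for genuine numerical failures.
The 95% CI on log10 EC50 is profiled (RSS inversion on a fixed-EC50 grid)
with an asymptotic Wald fallback; it is reported, not asserted, in tests.
The optional `exclude_top_dose` flag drops the highest concentration before
fitting, for series whose top dose is contaminated by toxicity.

Engagement normalizes the WT curve to the MUT vehicle baseline:
`max_inhibition_fraction = (top − WT vehicle)/(MUT baseline − WT vehicle)`,
with 1 meaning the WT plateau reaches the MUT level (full engagement,
declared at ≥ 0.9).

The cytotoxicity signature requires *both* halves at a common concentration:
MUT mark elevation > 3 vehicle SDs **and** nucleus count below 50% of
vehicle. Elevation without count drop is reported as endogenous/off-target
demethylase activity — the pattern of potent, non-toxic compounds — and is
deliberately not called toxicity.

## Death classification

The triple-stain rule is an ordered rule list with apoptotic precedence:
Annexin V-positive → apoptotic (with or without Yo-Pro 3 uptake);
otherwise Yo-Pro 3-positive → necrotic; otherwise healthy. Hoechst serves
only to identify cells. Positivity thresholds default to a two-component
Gaussian mixture on log intensity per channel, cut where the weighted
component densities cross. Otsu's valley is retained as an option but is not
the default: when one class is rare (say 10% Annexin-positive), Otsu places
the cut ~1.6σ above the negative mode while the error-minimizing boundary
sits near 2.3σ, and the resulting false positives leak systematically from
necrotic into apoptotic through the precedence rule. The `reference` method
(healthy-control mean + k SD) operates on the log scale because fluorescence
intensities are approximately log-normal; a linear-scale cut would call the
skewed upper tail positive far more often than the nominal Φ(−k).

At the generator's 4 SD separability the per-channel component overlap alone
costs ≈2.3% error, capping attainable accuracy near 96.5%; the ≥98%
recovery property is therefore exercised at 5 SD, where the ceiling is ≈99%.

## 2-oxoglutarate competition

Nearly all JmjC-KDM inhibitors compete with the 2-OG co-substrate, so their
apparent biochemical IC50 rises linearly with 2-OG
(Cheng–Prusoff): $IC_{50}(S) = K_i(1 + S/K_m)$. `fit_competition()` fits
this line by weighted linear regression with default weights $1/IC_{50}^2$:
IC50 series carry roughly constant relative error, and without the weights
the absolute scatter of the high-2-OG points (µM-scale) swamps the
sub-µM intercept that estimates $K_i$. An optional log-scale nonlinear refit
is available for strongly heteroscedastic series. Non-positive fitted
intercept or slope is rejected as non-competitive behaviour rather than
returned. `physiological_shift()` extrapolates to cytosolic 2-OG
(default 1000 µM) to quantify how much of the biochemical-to-cellular
potency drop-off the competition model explains; because the enzyme-specific
$K_i$/$K_m$ values behind the published shift curves are not tabulated, this
module treats the shift quantitatively only on synthetic round-trips and
qualitatively (monotone increase) otherwise.

## Problem sizes and validation scales

The validation suite runs at reduced, fixed scales chosen to make the
statistics meaningful: engagement plates use an 8-point dilution series
(1:2, plus vehicle) at 4 fields/well, 256×256 px, ~80 cells/field;
endogenous plates use 10 fields/well and a 1:3 series from 300 µM so that a
50 µM EC50 has doses well above it (a 1:2 series from 100 µM would top out
at only twice the EC50, leaving the upper plateau unidentified); EC50
recovery and toxicity false-positive properties use 200 seeded plates at the
per-cell-table level (20 and 4 fields/well respectively); segmentation count
conservation uses 400 rendered sparse fields; the death classifier is
validated on 2000-cell tables. At these scales the pipeline recovers EC50s
with median |log10 error| well under 0.15 and the toxicity flag's
false-positive rate stays below 5%.

## Known limitations

* The mark model treats each channel as a single intensity per cell; no
  texture, focal heterogeneity, or cell-cycle structure.
* Endogenous inhibition uses the same Hill slope as the primary response.
* The competitive-shift module starts from IC50 tables; AlphaScreen signal
  processing is out of scope.
* Watershed splitting assumes roughly convex nuclei; heavily elongated or
  clumped morphologies would need a trained segmenter.
* The toxicity rule keys on the MUT series; a compound toxic only to
  WT-transfected cells (none observed in this assay family) would evade it.
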