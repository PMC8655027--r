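---
title: "Quantifying nucleolar stress and nuclear mHTT distribution: models and methods"
author: "nucleostress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleolar stress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Nucleolar integrity is a candidate histopathological marker in Huntington's
disease models: in stressed neurons and muscle fibers the granular-component
protein NPM1 (nucleophosmin) loses its compact nucleolar localization and
disperses through the nucleoplasm, while NCL (nucleolin) typically does not
change and serves as a specificity control. In parallel, mutant huntingtin
(mHTT, detected by the EM48 antibody) shifts between a diffuse nucleoplasmic
pool and a single bright intranuclear inclusion body.

This package turns confocal images of DAPI-counterstained tissue into four
per-sample readouts:

1. **Fraction of nucleolar-positive nuclei** — the percentage of
   DAPI-positive nuclei in which a marker forms a compact circular
   intranuclear body rather than a delocalized haze.
2. **Nucleolar marker area per DAPI-positive nucleus** (µm²).
3. **mHTT dispersal ratio** — background-subtracted mean mHTT intensity in
   the nucleoplasm divided by the mean in the inclusion body. Values near 1
   mean diffuse mHTT; small values mean the protein is concentrated in the
   inclusion.
4. **Inclusion prevalence and area.**

All four are aggregated per field, then per biological sample, and samples
are compared with nonparametric tests (Mann–Whitney U for two groups,
Kruskal–Wallis with Dunn's post hoc for three or more). Two tabular helpers
round out the analysis layer: relative qPCR expression
(`2^-(dCt - mean dCt[control])`) and the disease-burden score
`(CAG - 35.5) * age` with its screening threshold of 250.

## Why a synthetic generator is first-class

The measured quantities are per-nucleus classifications; their estimators
can only be validated against known truth. `simulateField()` renders
projected 2-D fields — nuclei as hard ellipses, nucleoli as disks or
annuli, inclusions as disks — with per-nucleus ground truth, and
`simulateCohort()`/`analyzeCohort()` build hierarchical group → sample →
field designs with deterministic per-field sub-seeds. Every stage of the
pipeline is tested by parameter recovery on these cohorts.

The generator emulates what the estimators are sensitive to:

* **Geometry.** Brain mode: dense round nuclei (default radius
  3 ± 0.3 µm). Muscle mode: sparser, elongated nuclei (aspect 1.8,
  radius 2.5 ± 0.25 µm) lying along vertical fiber boundaries over a
  faintly striated background — the peripheral-nucleus arrangement of
  skeletal muscle cryosections.
* **Marker states.** Each nucleus is independently "nucleolar" (1–3
  compact bodies at a `contrast` of 3× the nucleoplasmic mean by default)
  or "delocalized" (uniform). NPM1 renders as an annulus with the core at
  40% of rim intensity (the granular component surrounds the fibrillar
  center); NCL renders as a filled disk.
* **Inclusions.** At most one per nucleus; its intensity is set so the
  true background-subtracted nucleoplasm/inclusion ratio equals a draw
  from N(mean, sd) truncated just above zero (floor 0.02, which caps the
  rendered inclusion at 50× the nucleoplasm and keeps 16-bit headroom).
* **Optional coupling.** `nclRatioCorrelation` draws the per-nucleus NCL
  intensity multiplier and the dispersal ratio from a shared bivariate
  normal, so intensity–ratio correlation recovery can be tested.
* **Camera noise.** `Poisson(poissonScale * signal) / poissonScale +
  N(0, gaussianSigma)`, clamped to [0, 65535]. Defaults
  (`poissonScale = 0.1` photons per intensity unit, `gaussianSigma = 20`)
  give roughly 10:1 SNR on the nucleoplasmic marker level of 1000 —
  ordinary confocal conditions. `poissonScale = Inf, gaussianSigma = 0`
  renders noise-free, which several invariant tests rely on.

What it does **not** emulate: a point-spread function (bodies have hard,
unblurred edges), 3-D structure and projection artifacts, autofluorescence
gradients, chromatin texture inside nuclei, mitotic figures, or staining
batch effects. Passing recovery tests therefore demonstrates that the
estimators are correct for well-resolved 2-D data at realistic SNR — not
that they are robust to every pathology of real slides. The acquisition
bit depth and per-channel exposure of the original experiments are not
published; 16-bit output with the intensity scale above is this package's
own convention.

2-D only: although confocal stacks are acquired in 0.5 µm steps, every
reported readout is a per-nucleus quantity on projected views, so the
generator produces the projection directly (default 512 × 512 px at
0.1 µm/px, the 63×/1.3 NA regime).

## Segmentation

`segmentNuclei()` is a deliberately plain, deterministic chain: Gaussian
smooth (σ = 2 px) → Otsu threshold on DAPI → hole fill →
distance-transform watershed to split touching nuclei → area filter
([20, 400] µm² brain, [10, 150] µm² muscle) → border exclusion. Otsu makes
the masks invariant to a global intensity gain. Group and genotype labels
never reach this module (or either scoring module); they are joined to the
measurements only in the statistics layer, which enforces the blinded
design structurally. On default-SNR generator fields the chain detects
nuclei with F1 ≥ 0.95 against truth.

## Nucleolar scoring

A nucleus is **positive** when at least one connected component of marker
signal inside it survives three filters:

* contrast — component pixels (and the component mean) exceed 1.5× the
  nucleus's background-subtracted nucleoplasm estimate (the per-nucleus
  median, robust because nucleoli occupy at most ~30% of the nucleus);
* size — component area between 1% and 30% of the nucleus area;
* shape — circularity `4πA/P² ≥ 0.6`.

Candidate holes are filled before measuring, so an annulus counts with its
full disk area — the confocal reading of a "circular nucleolar signal".
The rim-vs-core **ring score** `(mean_rim − mean_core)/(mean_rim +
mean_core)` (core = pixels deeper than half the maximal boundary distance)
is reported for the largest candidate, positive for annular NPM1 and ~0
for filled disks, but does not enter the positive call: at confocal
resolution the published phenotype is "circular nucleolar signal", not rim
topology.

Whether the original percentage-positive calls used an intensity threshold
or a visual call is not stated; the contrast-ratio rule above is this
package's declared operationalization. For the area readout, every
DAPI-positive nucleus contributes to the denominator — negatives
contribute 0 µm² — because the published normalization is "per
DAPI-positive nucleus"; `over = "positives"` provides the alternative
reading.

The whole-nucleus mean intensity is background-subtracted by the field's
modal intensity (the density mode over the raster, which sits on the
background because background pixels dominate the field).

## Inclusion detection and the dispersal ratio

Inclusion candidates are connected components of mHTT signal above a
contrast threshold times the background-subtracted per-nucleus nucleoplasm
estimate, with area ≥ 0.2 µm². The nucleoplasm mask is the nucleus minus
the inclusion masks dilated by 2 px; the nucleolar territory is *not*
excluded by default (the published ratio definition does not state such an
exclusion), with `excludeNucleoli` available for the alternative reading.
When several inclusions pass, the brightest one defines the ratio (the
typical striatal neuron carries a single EM48 body); an area-weighted
variant is available. Because both means are background-subtracted, the
ratio is invariant to any positive channel gain.

The default contrast threshold is **1.6**. This is the one place where a
seemingly natural stricter choice fails quantitatively: the dispersal
ratio *defines* the inclusion/nucleoplasm contrast as its reciprocal, so
nuclei with a true ratio of 0.40 render their inclusion at exactly 2.5×
the nucleoplasm. A detection threshold at 2.5 would sit on top of the
biologically central value and censor roughly half of a population with
ratios ~ N(0.40, 0.10), biasing the recovered group mean far beyond the
5% accuracy the validation demands. At 1.6, inclusions remain detectable
up to ratios of ~0.62 (+2.2 sd, <2% censoring), while the shot-noise
level at default SNR (a 1.6× excursion of the nucleoplasm mean is a
~5 σ pixel event) plus the 0.2 µm² area floor keeps the false-positive
rate at zero in inclusion-free nuclei.

`lineScan()` provides the STED-style profile readout: bilinear
interpolation along a user segment at ≤ 0.5 px spacing, each channel
normalized to its own maximum along the segment.

## Statistics

Per-sample means are the statistical unit throughout: per-nucleus values
are averaged per field, fields per sample, and only the per-sample values
enter tests. `mwuTest()` computes the exact two-tailed p by full
enumeration of the rank-sum permutation distribution for combined n ≤ 16
(mid-ranks for ties — the common case, since per-sample fractions often
tie), switching to the tie-corrected normal approximation with continuity
correction above that. `kruskalDunn()` takes the tie-corrected H (and
omnibus p) from `kruskal.test` and adds Dunn's pairwise z-tests with
Bonferroni adjustment over all contrasts — the conventional reading of
"Dunn's multiple comparison" when the exact correction is unspecified;
all values identical is handled as H = 0, p = 1 by convention. SEM is
sd/√N over samples. Group effect sizes are reported as
`100 · (1 − mean_B/mean_A)`.

## Numerical choices and degenerate inputs

* Pixels are pure index sets (1-based, row-major); a body contains the
  pixels whose centers fall inside it, with no anti-aliasing. Rounding to
  16-bit happens only at TIFF write time.
* Nuclei smaller than 10 px are skipped with a logged reason; fields with
  zero nuclei yield an empty `NucleusSet`, and a sample whose fields are
  all empty gets `NA` (undefined), never 0.
* An empty nucleoplasm mask after inclusion exclusion flags the
  measurement invalid rather than producing a ratio.
* Placement is rejection sampling with bounded retries (overlap tolerance
  10% of the summed radii); an infeasible density fails with an error
  naming the requested density. In unusually small nuclei the nucleolus
  radius is shrunk to fit rather than failing the render.
* Per-field sub-seeds are a deterministic function of the master seed and
  the (group, sample, field) indices only, so editing one group's
  parameters can never perturb another group's rasters.

## Validation problem sizes

The recovery suite uses cohorts matched to the validated effect sizes:
two groups × 6 fields (~420 and ~630 nuclei) for the positive-fraction
reduction; 7 vs 8 samples at ~200 nuclei/sample for the striatal
fraction; 4 vs 4 samples at ~300 inclusion-bearing nuclei/sample for the
dispersal ratio; muscle cohorts of 4–5 samples/group at 100–210
nuclei/sample for the area and human-cohort readouts; n = 335 pairs for
correlation recovery; 5000 null replicates for the Mann–Whitney size
check (empirical α within [0.03, 0.07] at nominal 0.05). These sizes were
chosen once to mirror the validated designs and are not tuned.

## Known limitations

* The watershed split handles moderate overlap (~15% of a radius);
  heavily clumped tissue would need a trained segmenter, which is out of
  scope by design.
* The ring score needs several pixels of rim and core; at coarse pixel
  sizes (> ~0.2 µm/px with 0.8 µm nucleoli) it degenerates toward `NA`.
* Modal background estimation assumes background-dominated fields; a
  field tiled wall-to-wall with tissue would bias it.
* The positive call treats nucleolar fragmentation (many small bodies)
  the same as 1–3 compact bodies so long as each candidate passes the
  filters; `nNucleoli` is reported for downstream use but no
  fragmentation index is defined.
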