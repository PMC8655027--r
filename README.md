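# nucleostress

Quantification of nucleolar stress phenotypes and nuclear mutant-huntingtin
(mHTT) distribution in multi-channel fluorescence microscopy, for
researchers studying Huntington's disease models (striatal neurons,
skeletal muscle, patient biopsies) or any system where nucleolar marker
delocalization is the readout.

Given confocal fields with a DAPI channel plus nucleolar markers
(NPM1/nucleophosmin, NCL/nucleolin) and an mHTT (EM48) channel, the
package computes, per DAPI-positive nucleus and then per biological
sample:

* the **fraction of nuclei with a compact ("nucleolar") marker signal**
  versus a delocalized one — the central stress readout; NCL serves as the
  specificity control;
* the **nucleolar marker area per DAPI-positive nucleus** (µm²);
* the **mHTT dispersal ratio**
  `R = Ī_nucleoplasm / Ī_inclusion` (background-subtracted means; small R
  = mHTT concentrated in the inclusion body), plus inclusion prevalence
  and area;
* nonparametric group comparisons on per-sample means: two-tailed
  **Mann–Whitney U** (exact by enumeration for combined n ≤ 16, mid-ranks
  for ties) and **Kruskal–Wallis with Dunn's post hoc** (Bonferroni over
  all pairwise contrasts), with group means ± SEM and relative differences
  `100·(1 − mean_B/mean_A)`;
* tabular helpers: ΔΔCt relative expression
  `2^−(ΔCt − mean ΔCt[control])` and the disease-burden score
  `DBS = (CAG − 35.5) × age` with its screening threshold of 250.

A first-class synthetic generator (`simulateField`, `simulateCohort`,
`analyzeCohort`) renders brain- or muscle-like fields with per-nucleus
ground truth (marker states, nucleolus geometry, true dispersal ratios,
Poisson + Gaussian camera noise), so every estimator in the package is
validated by parameter recovery. See the methods vignette
(`vignettes/nucleostress-methods.Rmd`) for the models, operational
definitions and their rationale.

## Worked example

Simulate a two-group cohort (4 samples × 3 fields each, ~30 nuclei per
field) in which the true fraction of NPM1-positive nuclei drops from 0.60
to 0.42, then run the full measurement chain and compare groups:

```r
library(nucleostress)

gs <- list(
  control = fieldSpec("brain", nNuclei = 30,
                      markers = list(NPM1 = list(positiveFraction = 0.60))),
  mutant  = fieldSpec("brain", nNuclei = 30,
                      markers = list(NPM1 = list(positiveFraction = 0.42))))
coh <- analyzeCohort(gs, samplesPerGroup = 4, fieldsPerSample = 3, seed = 7,
                     markers = "NPM1")
ss <- fractionPositive(coh$nucleolar, coh$manifest)
compareGroups(ss, measure = "fractionPositive_NPM1")
```

```
ComparisonResult [MWU] on 'fractionPositive_NPM1'
  control: n=4, mean=0.5382 +/- 0.026 (SEM)
  mutant: n=4, mean=0.4051 +/- 0.0266 (SEM)
  U=15, p = 0.0571
  relative difference: 24.7%
```

Each line of `ss` is one sample's mean over its fields (per-sample means
are the statistical unit); the measured fractions recover the simulated
0.60/0.42 within binomial sampling error at ~85 nuclei per sample, and at
this deliberately small size the exact Mann–Whitney p of 0.057 sits just
above the 0.05 cutoff — detecting a 30% reduction reliably takes the
larger designs used in the validation suite.

`runPipeline(config)` orchestrates the same chain from a YAML
configuration (simulated input or a TIFF directory with a channel map),
writing `nuclei.csv`, `nucleolar.csv`, `inclusions.csv`,
`sample_summary.csv`, `comparisons.csv` and a markdown report;
`inst/scripts/nucstress.R` exposes `run`, `simulate`, `segment`,
`score-nucleolus`, `score-inclusion` and `stats` subcommands for shell
use.

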