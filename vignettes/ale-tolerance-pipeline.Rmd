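---
title: "Methods: the ALE ethanol-tolerance analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ALE ethanol-tolerance analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aletools)
```

`aletools` chains together the quantitative stages that take an adaptive
laboratory evolution (ALE) experiment on solvent tolerance from
population-level mutation calls to confirmed mechanism: prioritizing
two-component systems (TCSs), quantifying promoter-fusion reporters,
processing label-free proteomes, scoring stress assays, quantifying
dilution spot plates, and fitting fermentation kinetics. This vignette
explains each model, the tunable parameters and why their defaults were
chosen, the numerical details, and what the synthetic-data tests do and do
not demonstrate about real data.

## 1. TCS prioritization

### Model

Population-level whole-genome sequencing of `N_p` parallel-evolved
populations (default 16, labelled HT1..HT16) sampled at `N_e` ethanol
levels (default 7) yields mutation records: gene, population, level,
mutation identity, and allele frequency `cp` in `[0, 1]`. For each gene,
per-mutation binary presence matrices (populations x levels) are summed
into the gene's global pattern; the sum of all entries is the gene's
`global_count`, so every distinct mutation in a gene contributes
(`build_mutation_matrices()`).

The scoring chain is:

* per mutation: `fscore_m = cp_m * n_m / N_p`, with `n_m` the number of
  populations carrying the mutation;
* per TCS: `fbar = sum(fscore_m) / N_e` over all mutations in the system's
  sensor and regulator genes;
* `Pscore = fbar * N_MT`, with `N_MT` the number of regulon targets
  annotated with both "membrane" (cellular component) and "transport"
  (biological process), matched case-insensitively as substrings
  (`count_membrane_transporters()`).

### Design choices

Several details are under-determined by the scoring formulas alone; the
package fixes them as follows and exposes each as an argument:

* **cp aggregation.** A mutation observed in several populations (or at
  several levels) has several `cp` values but one `fscore_m`. The default
  aggregates by the mean; `max` and `sum` are available
  (`aggregate` argument of `mutation_fscore()` / `priority_rank()`).
  The mean is the least biased single summary when coverage varies between
  populations and keeps `fscore_m <= 1`.
* **Mean-occurrence denominator.** The gene filter divides `global_count`
  by the number of ethanol levels by default — "one mutation on average per
  sequenced level" — with the number of populations as the alternative
  (`occurrence_denominator`). The per-level reading matches how the global
  pattern accumulates over sequencing time points; when the original
  supplementary mutation tables are supplied, the retained-gene count is
  the calibration anchor for this choice (see `test-acceptance.R`).
* **Tie-breaking.** Ranks order by descending `Pscore`, then descending
  `fbar`, then TCS name, so reports are deterministic.
* **Shared components.** A gene belonging to two systems contributes to
  both; no exclusivity rule is imposed.

`priority_rank()` is verified bit-exactly against a brute-force oracle that
re-enumerates every mutation with plain loops, on dozens of random small
datasets, and obeys three properties: linear scaling in `cp`, monotonicity
under added mutations, and invariance to record order.

## 2. Reporter quantification

Relative fluorescence normalizes background-subtracted fluorescence by
background-subtracted optical density, per time point:
`rF(t) = (F_s - F_b) / (OD_s - OD_b)` (`relative_fluorescence()`). A
non-positive OD difference is an error, never a silent `NaN`: a blank
denser than the sample means a swapped or failed well. No smoothing is
applied across time; the blank is subtracted per time point. Porin promoter
activity is expressed relative to a constitutive *lacZ* fusion in the same
strain (`normalized_expression()`), conventionally at the 10 h endpoint.

Responsiveness of the EnvZ osmosensor to a stressor is the slope test
(`ratio_response_test()`): ordinary least squares of
`log10(FITC_ompC / FITC_ompF)` against numeric dose, with the textbook
two-sided t-test on the slope (n - 2 df) and a 0.05 significance level
(exposed as `alpha`). Dose is numeric, not categorical — a slope is only
defined on a numeric axis. On an exact line the residual standard error is
zero; the p-value is then 1 for a zero slope and 0 otherwise, so noise-free
fixtures behave sensibly. The p-value is tested to 1e-10 against a
closed-form oracle.

## 3. Proteomics pipeline

The stage order is fixed and mirrors standard label-free workflows:

1. `filter_records()` — keep proteins with library q-value < 0.01 and at
   least one proteotypic peptide.
2. `valid_value_filter()` — keep a protein iff at least one group has >= 3
   valid values (`min_valid = 3`). The sentence "fewer than three valid
   values in at least one group" can also be read as *drop if any group is
   incomplete*; that stricter reading is `rule = "all_groups"`. The default
   follows the convention of left-censored imputation workflows, which only
   need one well-observed group to anchor a protein.
3. `impute_missing()` — missing values are drawn per sample from
   `Normal(mean_s - 1.8 * sd_s, 0.3 * sd_s)`, a proxy for the detection
   limit of left-censored data. The width (0.3) and downshift (1.8)
   defaults are the convention of that imputation family; both are
   arguments. The detection limit is proxied per sample, not globally,
   because loading differs between runs. Imputation is seeded and
   reproducible.
4. `differential_test()` — Welch's two-sample t-test per protein on log2
   intensities with Benjamini-Hochberg FDR. A protein is significant iff
   `q < 0.05` **and** `|log2FC| >= 2` (at least 4-fold). Moderated
   linear-model statistics are a natural extension point; the Welch test
   keeps the stage oracle-checkable in closed form, and the gates — not the
   test family — drive which proteins pass. The test suite cross-checks
   strong-effect calls against a moderated-statistics implementation.
   Zero-variance proteins with identical group means get p = 1 by
   convention.

`normalized_lfq()` expresses each protein as its fraction of the sample
total on the linear scale (`2^x / sum(2^x)`); fractions sum to 1 within
1e-12, which the suite checks on a thousand random matrices.

## 4. Stress assays

* `log2_induction()`: the double ratio
  `log2([(FITC/FSC)_t1,c / (FITC/FSC)_t1,nc] / [(FITC/FSC)_t0,c / (FITC/FSC)_t0,nc])`
  of size-normalized reporter fluorescence, challenged vs non-challenged,
  after vs before exposure. Any uniform rescaling of either channel
  cancels. Mean FITC is taken as the arithmetic mean of the summary tables.
* `survival_fraction()`: CFU(t) / CFU(0). Raw zeros are preserved; a
  parallel `fraction_floored` column substitutes a plating detection floor
  (default 0.5 colonies equivalent) so log-scale plots stay finite.
* `npn_uptake()`: NPN fluorescence / OD595 — the outer-membrane
  permeability proxy (NPN fluoresces only once past a permeabilized outer
  membrane).
* `survival_permeability_correlation()`: Spearman correlation between
  strain-mean survival and strain-mean uptake (>= 4 strains). Replicates
  are averaged to strain means before correlating, since the panel-level
  claim concerns strains, not wells. `spearman_test()` uses midranks for
  ties; the two-sided p-value is an exact permutation enumeration for
  n <= 8 without ties and the t-approximation otherwise. Rho is checked
  against a rank-then-Pearson oracle and `stats::cor.test`.

## 5. Spot-assay imaging

Plate photographs are 8-bit grayscale matrices (RGB input is converted by
luminance, `0.299 R + 0.587 G + 0.114 B`). `spot_plate()` tiles the
analysis region into non-overlapping half-open grid cells (one strain row
x one dilution column); `split_grid()` crops them losslessly.

`measure_spot()` reimplements the particle-analysis recipe: binarize,
label 8-connected components (the particle-analyzer convention;
implemented on a pixel-adjacency graph), report the largest component's
area if it reaches `min_area = 100` px², else the cell counts as empty.
The mean intensity is the arithmetic mean over the *whole* sub-image — the
histogram mean, as the original scripts compute it — with a
mask-restricted mean as an option (used when recovering a planted disk's
gray level).

Numerical choices:

* **Binarization** defaults to Otsu's method per sub-image, since the
  original global threshold value is not documented; a fixed threshold can
  be passed. On a two-level image every threshold between the levels is
  equivalent; the midpoint of the optimal plateau is returned.
* **Blank guard**: a sub-image whose gray-level range is below
  `min_contrast = 8` is treated as blank without thresholding — a
  data-driven threshold on pure background noise would otherwise binarize
  noise into spurious particles.

The round-trip property — render planted disks, split, measure — recovers
areas within 5 % and mask intensities within one gray level for radii of
10–40 px, and detection is monotone in radius.

## 6. Kinetics

`growth_parameters()` fits a smoothing spline to log-transformed,
blank-corrected OD; the growth rate is the maximum first derivative, the
lag time the intersection of the maximum-slope tangent with the initial
density level. OD values at or below the floor (default 1e-4) are floored
before the log transform and excluded from the derivative search. If the
spline degenerates (exactly collinear data), a straight-line fit is used.
Noise-free exponentials are recovered to 0.5 % over rates 0.1–1.5 h⁻¹.

`fit_gompertz()` fits the modified Gompertz curve

```
y(t) = y0 + (A - y0) * exp(-exp(mu * e * (lambda - t) / (A - y0) + 1))
```

with explicit asymptote `A`, maximum rate `mu`, lag `lambda`, and baseline
`y0`, by bounded Levenberg–Marquardt least squares with five deterministic
data-driven starts (A = max y; mu = max finite-difference slope; lambda =
time of max slope minus (A - y0)/(mu·e); y0 = min y; plus perturbed
variants), convergence tolerance 1e-10. `mu` is reported as the production
rate, in response units per hour (g/h for cumulative ethanol mass); the
result carries a `rate_unit_note` because such rates are sometimes labelled
h⁻¹ in reports even when the fitted response is a mass. A constant series
is flagged as a fit failure (the 4-parameter model is unidentifiable);
`production_rate()` maps that case to a rate of 0. `rate_contrast()`
compares strains by the ratio of mean rates with a two-sided t-test on
per-replicate rates.

## 7. Synthetic data: what it emulates, and what it does not

Each generator in `simulate_*()` / `render_spot_plate()` emulates one input
class with planted ground truth returned alongside the data, and writes the
same on-disk dialect its consumer stage reads. Every generator draws from
its own RNG stream, derived from the master seed by a fixed offset, so
adding one never perturbs the others; identical configurations give
bit-identical outputs.

Study-design defaults are fixed by the experimental setting they emulate:
16 populations, 7 ethanol levels, mutation frequencies from Beta
distributions (high-frequency shapes for the planted TCS, near-floor shapes
for background); reporter sampling hourly to 10 h with logistic sample
growth and a constant blank; proteome missingness left-censored — a value
is missing iff it falls below its sample's `missing_rate` quantile, which
is the regime the detection-limit imputation assumes; fermentation sampled
every 24 h during the first week plus a 185 h endpoint, matching a
broth-refeed fermentation schedule, with A = 20 g, mu = 0.3 g/h,
lambda = 10 h as a realistic cumulative-ethanol truth. Where a constant was
not dictated by the design (e.g. reporter blank fluorescence 50 a.u.,
background gray level 20), it was chosen once as a plausible instrument
value and left alone.

Passing recovery tests on these generators demonstrates that the
*computational* chain is correct: the statistics recover what was planted,
under the stated noise models. It does **not** demonstrate robustness to
what real data add: plate-reader drift and optical nonlinearity,
non-Gaussian proteome tails and peptide-level artifacts, uneven plate
illumination and off-grid spotting, HPLC calibration error, or biological
replicate structure beyond simple i.i.d. noise. The two counting claims
that tie the prioritization stage to the original population data require
the study's supplementary tables and are checked only when those are
supplied locally (they are not redistributable with the package).

## 8. Known limitations

* The differential test is unmoderated; with very few replicates a
  moderated variance estimator has more power at the same FDR.
* Grid placement for spot plates is supplied, not detected; skewed
  photographs must be rectified upstream.
* The Gompertz fit reports a covariance-free point estimate; replicate
  fits, not per-fit standard errors, carry the inference in
  `rate_contrast()`.
* The exact-permutation Spearman p-value is limited to n <= 8; above that
  the t-approximation is used (adequate for panel sizes in practice).

## 9. Interfaces

All stages are plain R functions over data.frames and matrices; file
exchange uses CSV/TSV (`read_mutation_table()`, `read_tcs_catalog()`,
`read_reporter_series()`, `read_protein_matrix()` and their writers),
8-bit grayscale PNG for plate images, and YAML for simulation
configurations. These functions, this vignette, and
`scripts/acceptance.R` constitute the package's operational surface; no
shell entry point is shipped because every consumer of these stages works
in R.
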