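# aletools

Quantitative analysis of adaptive-laboratory-evolution (ALE) tolerance
studies in bacteria.

When *E. coli* populations are evolved under gradually increasing ethanol,
the mutations they accumulate point at the signaling machinery that confers
tolerance — most prominently two-component systems (TCSs) such as the
EnvZ-OmpR osmosensing pathway that controls the outer-membrane porins OmpC
and OmpF. Confirming and dissecting such a hit takes a chain of downstream
assays: promoter-fusion reporters, whole-proteome quantification, membrane
permeability and survival measurements, dilution spot assays, and
fermentation runs. `aletools` implements that entire quantitative chain as
reusable, tested R functions, together with a seeded synthetic-data module
so every stage can be exercised — and its recovery of planted ground truth
verified — without any external files.

## The core statistic: TCS priority scoring

Given population-level whole-genome sequencing of `N_p` parallel-evolved
populations sampled at `N_e` ethanol levels, each mutation `m` in a TCS
sensor or response-regulator gene receives a frequency score from its allele
frequency `cp_m` and its occurrence `n_m` across populations:

```
fscore_m = cp_m * n_m / N_p
```

Scores of all mutations in one TCS are pooled into a global frequency score

```
fbar = sum_m fscore_m / N_e
```

and weighted by the number `N_MT` of membrane-associated transporter genes
in the TCS regulon (targets annotated with both "membrane" as cellular
component and "transport" as biological process):

```
Pscore = fbar * N_MT
```

Systems are ranked by descending `Pscore`. The package also covers the
surrounding stages:

| stage | functions |
|---|---|
| mutation matrices & occurrence filter | `build_mutation_matrices()`, `filter_by_mean_occurrence()` |
| TCS scoring & ranking | `mutation_fscore()`, `global_fscore()`, `count_membrane_transporters()`, `priority_rank()` |
| reporter quantification | `relative_fluorescence()`, `normalized_expression()`, `ratio_response_test()` |
| proteomics pipeline | `filter_records()`, `valid_value_filter()`, `impute_missing()`, `normalized_lfq()`, `differential_test()` |
| stress assays | `log2_induction()`, `survival_fraction()`, `npn_uptake()`, `survival_permeability_correlation()` |
| spot-assay imaging | `spot_plate()`, `split_grid()`, `measure_spot()`, `summarize_plate()`, `compose_plate_image()` |
| kinetics | `growth_parameters()`, `fit_gompertz()`, `production_rate()`, `rate_contrast()` |
| synthetic data | `simulation_config()`, `simulate_mutation_dataset()`, `simulate_reporter_series()`, `simulate_protein_matrix()`, `render_spot_plate()`, `simulate_fermentation()` |

## Worked example

```r
library(aletools)

# a seeded mutation dataset with one TCS planted as the top target
sim <- simulate_mutation_dataset(simulation_config(seed = 1))
res <- priority_rank(sim$mutations, sim$catalog, n_populations = 16, n_levels = 7)
head(as.data.frame(res), 4)
#>     tcs n_mutations fbar_score n_mt pscore rank
#> 1 TCS01           6    0.58616    6 3.5169    1
#> 2 TCS03           3    0.00795    3 0.0239    2
#> 3 TCS02           1    0.00723    3 0.0217    3
#> 4 TCS08           3    0.00615    3 0.0185    4
```

The planted system (`TCS01`) carries six high-frequency sensor/regulator
mutations spread over most populations and the most membrane-transporter
regulon targets, so its `Pscore` (fbar 0.586 x 6 transporters = 3.52)
dominates the background systems by two orders of magnitude — it is ranked
first, exactly as the generator planted it.

```r
# fermentation kinetics: cumulative ethanol with 0.2 g measurement noise
ferm <- simulate_fermentation(simulation_config(seed = 1), noise_sd = 0.2)
fit  <- fit_gompertz(ferm$series$time, ferm$series$ethanol_g)
fit
#> Gompertz fit: A = 20.08  mu = 0.28612  lambda = 5.2183  y0 = -0.48837  (rss = 0.03301)
```

The fitted maximum production rate `mu` (0.286 g/h, truth 0.3 g/h) is the
quantity contrasted between strains with `rate_contrast()`.

## Documentation

The methods vignette (`vignettes/ale-tolerance-pipeline.Rmd`) describes the
models, parameter choices, numerical details, and the limits of what the
synthetic-data tests demonstrate about real data.
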