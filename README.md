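# floralsync

Seasonal sex allocation, mating opportunity, and siring success in clonal
monoecious plants.

## The problem

In monoecious plants with **synchronous protogyny**, every inflorescence is
functionally unisexual on any given day: all female flowers open (and close)
before the first male flower does. Population-wide, this skews daily floral
sex ratios — female-biased when the season starts, male-biased as it ends —
and with them the availability of mates. The *mating environment hypothesis*
predicts that plants compensate by shifting inflorescence sex allocation
toward the locally rare sex over the season, and that these shifts pay off
in realized siring success. Testing the second half of that prediction
requires connecting three very different data types: daily floral censuses,
clonal identity from codominant markers, and genetic paternity of seeds.

`floralsync` is an R package for that analysis chain, aimed at plant
mating-system researchers:

- **Clone assignment** — ramets are grouped into multilocus genotypes
  (MLGs: identical genotypes with identical missingness) and MLGs are
  clustered into multilocus lineages (MLLs = genets) as connected
  components of the graph joining genotypes at allelic distance ≤ 1
  (`assign_clones()`, `group_mlgs()`, `build_mlls()`).
- **Fractional paternity** — per-seed posteriors over candidate sires from
  an error-tolerant Mendelian likelihood,
  `L = (1 − ε)·T(offspring | mother, father) + ε·P_HW(offspring)` per
  locus (`assign_paternity()`).
- **Mating metrics** — the daily male-flower fraction
  `f_m(j) = N_m(j) / Σ_{l≠j} N_m(l)`, the **pollen-transfer opportunity**
  `K(j, day) = f_m(j) × Σ_{i∉g} N_f(i)` (female flowers on other genets
  only), genet-level daily and season totals, and realized siring success
  `RS(MLL, day) = Σ_seeds π` over seeds assigned to that MLL, excluding
  self-fertilized seeds (`pto_ramet_day()`, `pto_genet()`,
  `siring_success()`).
- **Seasonal models** — binomial penalized-spline mixed model for
  inflorescence sex ratio vs first flowering date (MLL and nested
  inflorescence random intercepts), Gaussian spline for daily PTO (MLL
  intercepts), each with a linear mixed counterpart and AIC comparison,
  and linear mixed models of `log10(RS)` on date and PTO with stepwise
  selection (`fit_sexratio_trend()`, `fit_pto_trend()`,
  `fit_siring_model()`).
- **A synthetic-population simulator** — clonal structure, spatial layout,
  protogynous phenology, microsatellite genotypes with somatic variants
  and typing error, and spatially restricted mating
  (negative-exponential kernel) with known true paternity
  (`population_config()`, `simulate_study()`), so every stage above can be
  tested against ground truth.
- **A file-based pipeline** — `run_pipeline()` / `run_stage()` over plain
  CSVs with validation and provenance JSON, plus a CLI wrapper at
  `inst/cli/floralsync.R`.

## Worked example

```r
library(floralsync)

cfg   <- population_config(rng_seed = 1)   # ~940-ramet clonal stand, days 199-240
study <- simulate_study(cfg)
study
#> Synthetic study: 820 ramets / 169 genets; 4822 inflorescence-day records;
#>   472 genotyped seeds (12% selfed)

clones <- assign_clones(study$genotypes$ramet_genotypes)
pat    <- assign_paternity(study$seeds, study$genotypes$ramet_genotypes, clones)
pat
#> Fractional paternity: 472 seeds assigned, 0 unassignable; 137 candidate
#>   MLLs received mass

sr   <- sex_ratio_table(study$inflorescences, clones)
fit_sexratio_trend(sr)
#> Seasonal trend (sex_ratio): n = 820 (180 MLLs)
#>   intercept 0.688 +/- 0.038 | s(day): edf = 1.00, Chi.sq = 196.55, p = 0
#>   AIC smooth = 3781.8 vs linear = 4468.4 | trend peak at day 207.0

ptod <- pto_genet(pto_ramet_day(study$phenology, clones))
fit_pto_trend(ptod)
#> Seasonal trend (pto): n = 1686 (180 MLLs)
#>   intercept 1.869 +/- 0.220 | s(day): edf = 7.63, F = 81.66, p = 0
#>   AIC smooth = 8623.2 vs linear = 9269.6 | trend peak at day 229.0

rs <- siring_success(pat)
fit_siring_model(rs, ptod)
#> Siring-success mixed models: n = 324 genet-days, 112 sire MLLs
#>   date  AIC = -247.40 | day: F(1, 319.8) = 3.67, p = 0.0563;
#>   pto   AIC = -315.52 | K_day: F(1, 249.6) = 81.6, p = 4.68e-17;
#>   joint AIC = -314.18 | day: F(1, 320.8) = 0.647, p = 0.422;
#>                         K_day: F(1, 245.2) = 77.7, p = 2.25e-16;
#>   selected (lowest AIC): pto
```

Reading the output: the sex-allocation trend is strongly seasonal (the
fitted proportion of male flowers is above 0.5 before peak flowering and
below it after); pollen-transfer opportunity is hump-shaped (edf ≈ 7.6)
and peaks at day 229, essentially at peak flowering; and — because this
synthetic population mates through a 5 m dispersal kernel, still wide
relative to clone spacing — a genet's daily PTO strongly predicts its
realized siring success (F ≈ 82). Re-running the mating with a 1 m kernel
erodes that association without touching the two seasonal trends, which is
the package's working explanation for field studies in which allocation
tracks opportunity but siring does not: spatial restriction alone can
decouple them.

The same chain runs file-to-file:

```r
run_pipeline(run_config(list(dir = "run1",
                             population = list(rng_seed = 1))))
# phenology.csv, ramet_genotypes.csv, seeds.csv, mll_assignments.csv,
# paternity.csv, pto_daily.csv, siring.csv, sex_ratios.csv,
# models_summary.json + per-stage provenance JSON
```

or from a shell: `Rscript inst/cli/floralsync.R run-all --config cfg.yaml`.

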