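---
title: "Seasonal sex allocation, pollen-transfer opportunity and siring success: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal sex allocation, pollen-transfer opportunity and siring success: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floralsync)
```

## The scientific problem

In monoecious plants with synchronous protogyny, every inflorescence passes
through a female phase before any of its male flowers open, so on any given
day an inflorescence is functionally unisexual. At the population scale this
temporal segregation skews daily floral sex ratios: early in the flowering
season most plants are in female phase, late in the season most are in male
phase. The *mating environment hypothesis* predicts that plants should shift
their allocation toward the locally rare sexual function - male-biased
inflorescences early, female-biased late - and that those shifts should pay
off in realized siring success.

`floralsync` implements the full analysis chain needed to test that
prediction in a clonal population scored with codominant (microsatellite)
markers, together with a synthetic-population simulator that provides ground
truth for every stage:

1. **Clone assignment** - group ramets into multilocus genotypes (MLGs) and
   cluster MLGs into multilocus lineages (MLLs = genets).
2. **Fractional paternity** - per-seed posterior probabilities over
   candidate sires from an error-tolerant Mendelian likelihood.
3. **Mating metrics** - inflorescence sex ratios, the daily
   pollen-transfer-opportunity index `K`, and realized siring success `RS`.
4. **Seasonal models** - penalized-spline mixed models for the sex-ratio and
   PTO trends, and linear mixed models for siring success.

## Clone assignment

The allelic distance between two genotypes is, per locus, `2 - |multiset
intersection|` of the two allele pairs, summed over loci scored in both
genotypes. Ramets with identical genotypes *and* identical missing-data
patterns form an MLG (identical missingness prevents chains through
uninformative genotypes). MLLs are the connected components of the graph
joining MLG pairs at distance `<= max_diff` (default 1): a single-allele
mismatch at a single locus - the signature of somatic mutation or one
scoring error - merges two MLGs into one lineage, mismatches at two loci do
not. The transitive closure means a chain of one-step variants collapses
into one genet even if its extremes differ by more; this is deliberate,
because each somatic variant arises from, and is one step away from, a
genotype already in the lineage.

## Fractional paternity

For seed $j$ with known mother, the likelihood of candidate father $i$ is a
product over loci of

$$L_\ell = (1-\varepsilon)\,T(o_\ell \mid m_\ell, f_\ell) +
  \varepsilon\,P_{HW}(o_\ell),$$

where $T$ is the Mendelian transmission probability (the average over the
four equally likely gamete pairs), $P_{HW}$ the Hardy-Weinberg probability
of the offspring genotype, and $\varepsilon$ a per-locus mistyping rate
(default 0.01). The mixture keeps one mistyped locus - including an apparent
mother-offspring mismatch - from vetoing an otherwise compatible candidate;
loci missing in any party contribute likelihood 1. Posteriors
$\pi_{ij}$ are likelihoods times a uniform candidate prior, normalized.
Candidates are MLG representative genotypes; MLG posteriors are summed into
MLL posteriors. An optional `UNSAMPLED` class (off by default: the study
design assumes a closed, isolated population) integrates the paternal allele
over the population allele frequencies. Candidates receiving less than
`min_pi` (default 0.001) are dropped and the rest renormalized, so
assignment tables list only candidates that genuinely compete while
$\sum_i \pi_{ij} = 1$ exactly.

Seeds are treated independently given their known mothers; no sibship
reconstruction is attempted. Per-seed confidence categories of
full-likelihood pedigree software are out of scope.

## Mating metrics

For ramet $j$ on day $k$, the daily male-flower fraction is
$f^m_j = N^m_j / \sum_{l \ne j} N^m_l$ (the focal ramet's share of pollen
relative to all other ramets), and the pollen-transfer opportunity is
$K_{jk} = f^m_j \times \sum_{i \notin g} N^f_i$, the female flowers open
that day on ramets *outside* the focal ramet's genet $g$. Note the
asymmetry, implemented exactly as defined: the pollen denominator excludes
the focal *ramet*, the female sum excludes the focal *genet* (geitonogamous
partners are not mating opportunities). Daily $K$ values are summed over a
genet's ramets into $K_{day}$ and over the season into $K_g$. The index is
an opportunity measure, not a probability, and is not bounded by 1.

Two degenerate-day conventions: a ramet with no open male flowers has
$f = 0$; a sole pollen donor (positive $N^m$, no other male flowers
anywhere) takes $f = 1$ - the monopoly limit, in which $K$ equals all
available female flowers - and is flagged `sole_donor` in the output.
Genet-day PTO records are restricted by default to male-phase genet-days
(`male_phase_only = TRUE`): the index describes siring opportunity, which a
genet without open pollen does not have.

Realized siring success sums per-seed paternity onto sires. By default
(`method = "assigned"`) each seed contributes its probability $\pi$ to the
single MLL assigned as its most probable sire, and a seed whose most
probable sire is its own maternal MLL is excluded as self-fertilized;
`method = "fractional"` instead credits every candidate MLL its full
posterior mass (with the selfed mass dropped). The assigned rule is the
default because summed most-probable-sire probabilities are the standard
output of parentage software in this field; the fractional rule is retained
for sensitivity analyses.

## Seasonal models

*Sex allocation.* The number of male flowers out of the inflorescence total
is modelled with a binomial (logit) penalized-spline mixed model: a
thin-plate regression spline of first flowering date (basis dimension 10,
REML smoothness selection) plus random intercepts for MLL and, nested
within it, inflorescence - an observation-level term that absorbs
extra-binomial heterogeneity. *PTO.* Daily genet-level `K` is modelled with
a Gaussian identity-link spline of date plus an MLL random intercept. Both
fits are accompanied by their linear mixed counterparts (`glmer` / `lmer`)
and both AICs are reported; a significant smooth term together with a lower
smooth-model AIC indicates a genuinely nonlinear season. The AICs come from
different engines (penalized-spline conditional AIC vs ML mixed-model AIC),
so the comparison is a heuristic, reported as such. Models with more than
500 rows are fitted with fast discretized REML (`mgcv::bam`) rather than
`mgcv::gam`; with ~900 observation-level random-effect coefficients the
exact fit takes over a minute while the discretized one takes seconds, at
no material difference in the quantities used here. If the nested
inflorescence term makes the linear model singular it is refitted without
it and flagged (`dropped_inner`).

*Siring.* `log10(RS)` per sire-genet-day is regressed on siring date and on
the genet's same-day PTO - separately and jointly, following a stepwise
protocol - with an MLL random intercept (`lmerTest`); coefficients carry
Satterthwaite degrees of freedom, each term an F test, and the model with
the lowest ML AIC is flagged as selected. Genet-days with zero outcross
siring are excluded by the log transform (sires-only analysis); an offset
alternative `log10(RS + c)` is available via `offset_const` but off by
default. Sire genet-days whose genet has no male-phase PTO record that day
get `K = 0` in the join: genetic paternity can put mass on a genet for a
day on which it was not scored in male phase, and zero opportunity is the
faithful covariate value. Fewer than five sire genets abort the fit. No
multiple-testing correction is applied anywhere, matching standard practice
for these three planned models.

## The synthetic population

`population_config()` defaults describe the kind of dense clonal stand in
which these questions arise, and every parameter is a knob:

| parameter | default | what it encodes |
|---|---|---|
| `n_genets` | 169 | genetic individuals in the stand |
| `ramet_count_law` | hurdle NB (40% singletons, max 35, mean ~5.6) | clone-size distribution; ~940 flowering ramets |
| `arena` | 25 x 60 m | site extent |
| `season` | days 199-240 | Julian-day flowering window |
| `flowering_start_law` | Beta(6, 2.4) | ~1% of inflorescences open in the first 12 days; peak flowering near day 230 |
| `n_male_law` | Poisson-lognormal, median 9, flat | male flowers per inflorescence |
| `n_female_law` | Poisson-lognormal, median 4, `day_effect` 3.5 | female flowers rise over the season |
| `female_phase_days` / `male_stagger_days` | 2 / 5 | near-simultaneous female phase, staggered male phase |
| `n_loci`, `alleles_per_locus` | 7, 15 | microsatellite panel |
| `somatic_mlg_rate` | 0.05 | daughter-ramet somatic variants (one allele, one locus) |
| `genotyping_error` | 0.01 | per-allele mistyping in observed tables |
| `kernel_scale` | 5 m | negative-exponential pollen dispersal (`Inf` = uniform mating) |
| `seed_sample_fraction` | 0.075 | one genotyped seed per sampled fruit; ~400 seeds |

A note on the genet-size law: no zero-truncated negative binomial can hold
40% singletons *and* a mean clone size of ~5.6 with a maximum of 35 (the
heavy-tailed limit of that family caps the singleton share near 34%), so
the law is a hurdle: a genet is a singleton with probability 0.4, otherwise
NB(size 0.8, mu 6.64) conditioned on 2-35 ramets.

Three defaults are calibrated to stated properties of the study system
rather than guessed: the start law reproduces the near-empty first two
weeks of the season; `day_effect = 3.5` makes median female flower
production equal male production at peak flowering, so inflorescence sex
ratios cross 0.5 at the flowering peak (male-biased before, female-biased
after); and the sampling fraction yields a seed set of a few hundred, the
scale at which single-season paternity studies operate.

Structurally, the simulator enforces synchronous protogyny (all female
days strictly precede all male days within an inflorescence; each flower
open exactly one day), which makes within-ramet selfing impossible - only
geitonogamous selfing between ramets of one genet occurs, through the
mating kernel. Mating draws a sire for each sampled female flower with
probability proportional to `N_male * exp(-distance / kernel_scale)`;
female flowers open on days with no pollen anywhere are logged as
unpollinated and produce no seed. Somatic variants arise only in daughter
ramets, so the founding genotype of every genet is observed and each
variant sits at allelic distance 1 from it; with typing error switched off
the MLL rule then recovers the true genet partition exactly, which is the
key identifiability test of the clustering.

Every stage derives its RNG stream from `rng_seed` plus a fixed offset, so
a config is a complete recipe: the same seed gives byte-identical outputs,
and stages can be re-run individually without disturbing one another.

### What the simulator does *not* emulate

Pollinator behaviour (visit sequences, floral-display preferences), flower
size and rewards, size-dependent allocation *within* a season,
overwintering corm dynamics, and inbreeding depression are all outside the
model. Daily flower totals run higher than a typical field census of this
kind because start dates are concentrated to honour the empty early season;
absolute `K` values therefore have no field interpretation - all analyses
here use them comparatively. Passing tests on this generator show the
pipeline recovers structure *of the kind the field system exhibits*; they
cannot show the field estimates themselves are unbiased.

## Numerical choices and edge cases

- Allelic distance skips loci missing in either genotype and errors only
  when two genotypes share no scored locus; MLG/MLL labels are
  canonicalized by smallest member ramet id, so row order never changes a
  partition.
- Paternity likelihoods are products of at most `n_loci` terms bounded
  below by `eps * P_HW`, far from underflow; no log-space machinery is
  needed. Seeds with all-zero candidate likelihoods (possible only with
  `error_rate = 0`) are flagged unassigned and skipped downstream, not
  errors.
- Ties for a seed's most probable sire are broken by MLL id for
  determinism; posterior floors (`min_pi`) renormalize so per-seed masses
  sum to 1 to machine precision.
- Spline basis dimension is capped at the number of distinct days minus
  one; trend curves are population-level predictions excluding the
  random-effect smooths, on a half-day grid.
- The binomial trend model requires at least 20 inflorescences over at
  least 10 distinct days; the siring model at least 5 sire genets.

## Problem sizes used in the test suite

Oracle-equivalence checks run 200 random instances each (PTO tables up to
30 ramets x 10 days; genotype sets up to 50 x 7 loci) against naive-loop
and brute-force-BFS implementations kept deliberately separate from the
package code. Paternity recovery uses 60 candidate sires, 300 seeds, 7
loci x 15 alleles at a 1% typing error. The seasonal pattern checks run 20
seeded replicates of the full default population (~900 ramets), scoring
sex allocation on a 298-inflorescence sample per replicate, and the
siring-vs-PTO contrast runs 20 replicates each under uniform mating and
under a 1 m dispersal kernel. The latter pair is the package's summary of
the scientific story: with spatially uniform mating, the
pollen-transfer-opportunity index predicts realized siring success almost
always; restricting dispersal to a scale far below the stand's extent
erodes that association even though the seasonal sex-allocation and
opportunity trends are unchanged - spatial structure alone can decouple
opportunity from realized success.

## Worked example

```{r example, eval = FALSE}
cfg <- population_config(rng_seed = 1)
study <- simulate_study(cfg)
clones <- assign_clones(study$genotypes$ramet_genotypes)
pat <- assign_paternity(study$seeds, study$genotypes$ramet_genotypes, clones)
ptod <- pto_genet(pto_ramet_day(study$phenology, clones))
rs <- siring_success(pat)
fit_siring_model(rs, ptod)
```

The same chain is available file-to-file through `run_pipeline()` /
`run_stage()` with a YAML config, and from the shell via
`inst/cli/floralsync.R`.

## Known limitations

- The clustering threshold (`max_diff = 1`) is a rule, not an estimator:
  with per-allele typing error > 0 some error variants exceed distance 1
  and split off spurious lineages, exactly as in real SSR surveys.
- Cross-engine AIC comparisons (spline vs linear mixed models) are
  heuristics; decisions about nonlinearity should rest on the smooth-term
  test and the fitted curves.
- Satterthwaite denominator degrees of freedom are approximations; F and
  p values from other mixed-model machinery will differ in detail.
- The PTO index ignores space by construction. That is the point of the
  uniform-vs-steep kernel contrast, but it means absolute effect sizes
  from the siring regression should not be read as dispersal-corrected.
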