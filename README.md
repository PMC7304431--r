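# hetfit — heterozygosity–fitness correlation analysis for microsatellite data

`hetfit` is an R toolkit for asking whether a small, closed wildlife
population is suffering **inbreeding depression**, using the data a field
monitoring program typically has: codominant microsatellite genotypes for a
few hundred individuals and per-individual records of sex, capture year,
age, and reproductive output (here, litter size 0–4). It is aimed at
conservation geneticists running the now-standard heterozygosity–fitness
correlation (HFC) workflow end to end, with every step testable against
simulated data of known truth.

## The statistical chain

Each individual carries a latent inbreeding coefficient *f*; conditional on
*f*, heterozygosity at locus ℓ is Bernoulli(h<sub>ℓ</sub>(1 − f)) and loci
are unlinked. The package implements:

* **Marker screening** — per-locus Na, H<sub>O</sub>, unbiased
  H<sub>E</sub> = (2n/(2n−1))(1 − Σp²), multi-allelic Hardy–Weinberg exact
  tests (complete enumeration ≤ 3 alleles, Monte-Carlo beyond), Brookfield
  null-allele frequencies r = (H<sub>E</sub> − H<sub>O</sub>)/(1 +
  H<sub>E</sub>) per cohort, and Nei F<sub>IS</sub> = 1 − H<sub>O</sub>/H<sub>S</sub>.
* **Multilocus heterozygosity** — internal relatedness
  IR = (2H − Σf)/(2N − Σf), standardized MLH, and heterozygosity-by-loci,
  plus their correlations and calendar-year trends.
* **Identity disequilibrium** — the g₂ statistic
  (estimand Var(f)/(1 − E[f])²) with pairwise-complete handling of missing
  genotypes, bootstrap SEs over individuals, and a permutation test that
  shuffles locus columns independently.
* **HFC models** — binomial logit models of litter size (events out of 4
  trials) and breeding propensity with Gelman-standardized predictors
  (age, IR, year), all-subsets AICc ranking, conditional model averaging
  with adjusted SEs, relative importance, and a global-model R².
* **Local vs general effects** — a locus-by-locus plain-AIC scan (base
  model, one model per locus, multilocus H<sub>O</sub> model) with the
  ΔAIC > 4 / |ΔAIC| < 2 support rules and slope-magnitude comparison that
  decide between single-locus ("local") and genome-wide ("general",
  i.e. inbreeding-depression) interpretations.
* **A synthetic-data generator** — genotypes, metadata and binomial
  fitness with known per-individual *f*, including optional null alleles
  and a planted single-locus-signal scenario.

## Worked example

Simulate a study-scale dataset (168 devils, 32 loci, six sampling years,
inbreeding f ∈ {0, 0.25}) and run the chain:

```r
library(hetfit)

ds <- simulate_dataset(sim_config(seed = 42))
ds
#> synthetic_dataset (seed 42):
#> genotype_table: 168 individuals x 32 loci (5.3% missing calls)
#>   years: 2006, 2007, 2009, 2014, 2015, 2016
#>   87 females, 81 males; litter size known for 87
#>   true E[f] = 0.135, expected g2 = 0.0204

g2_test(ds$table, n_iter = 1000, seed = 42)
#> g2 = 0.0257 (bootstrap SE = 0.0057, permutation p = 0.000999)
#>   168 individuals x 32 loci; 1000 bootstrap, 1000 permutation iterations; seed 42
#>   missing data: pairwise-complete per locus pair
```

The estimate sits within two bootstrap SEs of the generator's closed-form
expectation 0.0204 and the permutation test rejects the no-identity-
disequilibrium null, so heterozygosity here is a usable proxy for
inbreeding. The model-averaged reproductive models then quantify the load:

```r
rec <- mlh(ds$table)
hfc <- run_reproductive_models(ds$table, rec)
hfc$litter_all
#> conditional model average (AICC, litter response, n = 87, global R2 = 0.599 [v])
#>         term estimate adj_se  ci_lo  ci_hi    ri
#>  (Intercept)   -0.785  0.158 -1.094 -0.476    NA
#>          age    0.730  0.309  0.125  1.335 0.860
#>           ir   -0.397  0.307 -1.000  0.205 0.438
#>         year   -3.539  0.393 -4.309 -2.769 1.000
```

Estimates are on the 2-SD-standardized logit scale: the simulated
reproductive decline over years comes through strongly (RI = 1.00), while
the modest simulated load (β<sub>f</sub> = −1 on latent f) appears as a
negative but uncertain IR coefficient — at this effect size and sample
size the sign is recovered far more reliably than significance, which is
exactly what the power analysis in the methods vignette predicts. Finally:

```r
classify_effects(run_local_effects(ds$table))
#> verdict: consistent-with-general-effects
#> multilocus (HO) slope: 4.229
#> ...
```

`run_all(config)` chains every stage and writes `locus_summary.tsv`,
`mlh.tsv`, `g2.json`, `table2_models.tsv`, `table3_local_effects.tsv`,
`fis_by_year.tsv` and a `manifest.json` recording seeds, input hashes and
every method setting in effect; `config` may be a list or a YAML file and
accepts either a genotype CSV (`input:`) or generator settings
(`simulate:`).

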