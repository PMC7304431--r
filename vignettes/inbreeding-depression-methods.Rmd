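---
title: "Methods: heterozygosity–fitness analysis with hetfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterozygosity–fitness analysis with hetfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetfit)
```

# What the package estimates

`hetfit` implements the statistical chain used to diagnose inbreeding
depression in a small, closed wildlife population monitored with
codominant microsatellite markers and individual reproductive records:

1. per-locus diversity and data-quality screening (allele counts, observed
   and unbiased expected heterozygosity, Hardy–Weinberg exact tests,
   per-cohort null-allele frequencies, Nei's $F_{IS}$);
2. per-individual multilocus heterozygosity indices (internal relatedness
   IR, standardized multilocus heterozygosity sMLH, heterozygosity-by-loci
   HL) and their temporal trends;
3. the $g_2$ identity-disequilibrium statistic, which must differ from zero
   before a heterozygosity–fitness correlation can be read as inbreeding
   depression;
4. binomial (logit) models of reproductive success with
   information-theoretic model averaging; and
5. a locus-by-locus AIC scan separating "local" (single-locus) from
   "general" (genome-wide) effects.

A synthetic-data generator with known per-individual inbreeding
coefficients ties the chain together: every stage can be validated against
closed-form expectations or brute-force oracles without any external data.

# Model and assumptions

The underlying model is the classical multiplicative one. Each individual
carries an inbreeding coefficient $f$, the probability that its two alleles
at a locus are identical by descent. Conditional on $f$, heterozygosity at
locus $\ell$ is Bernoulli with probability $h_\ell (1 - f)$, where
$h_\ell$ is the outbred (Hardy–Weinberg) heterozygosity, and loci are
independent (unlinked neutral markers). Variance in $f$ among individuals
induces positive covariance in heterozygosity across loci within
individuals — identity disequilibrium — with

$$g_2 = \frac{\mathrm{Var}(f)}{(1 - E[f])^2},$$

which is what the $g_2$ estimator targets (`expected_g2()` evaluates this
closed form for the generator's $f$ distributions). Fitness operates on
litter size $y \in \{0,\dots,4\}$ as
$y \sim \mathrm{Binomial}(4,\ \mathrm{logit}^{-1}(\beta_0 + \beta_f f +
\beta_{year}(year - 2006) + \beta_{age}\,age))$; because $f$ is latent, the
fitted models use IR as its observable proxy, which attenuates
coefficients (see *Power and attenuation* below).

# Estimators and numerical choices

## Diversity statistics

Unbiased expected heterozygosity is $\frac{2n}{2n-1}(1 - \sum_a p_a^2)$
with $n$ the typed individuals at the locus. The Hardy–Weinberg test is
the conditional exact test: given the allele counts, a genotype table has
probability proportional to $2^H / \prod_g n_g!$ ($H$ heterozygotes), and
the p-value sums configurations no more probable than the observed one.
Tables are enumerated completely for up to three alleles; beyond that the
null is sampled by permuting the $2n$ gene copies (default 10,000 draws,
add-one correction). The original analyses this workflow descends from
used spreadsheet toolkits whose exact-test family is undocumented, so the
method is recorded in the output metadata rather than assumed comparable.

Null-allele frequencies use Brookfield's first estimator
$r = (H_E - H_O)/(1 + H_E)$, the form appropriate when null homozygotes
present as missing data rather than as scored genotypes; negative
estimates are clamped to zero and monomorphic cohorts are reported `NA`.
Per-cohort estimates use per-cohort allele frequencies and
heterozygosities. $F_{IS} = 1 - H_O/H_S$ uses the small-sample-corrected
gene diversity $H_S = \frac{n}{n-1}(1 - \sum \bar p_a^2 - H_O/2n)$, with
monomorphic locus–cohort cells excluded from unweighted cohort means.

## Heterozygosity indices

IR is $(2H - \sum f)/(2N - \sum f)$ over typed polymorphic loci, where
$\sum f$ adds the population frequency of each carried allele copy. Allele
frequencies are pooled over the full sample — both sexes, all years,
focal individual included — to stabilize them against yearly fluctuations;
an option excludes the focal individual but is not the default. sMLH
standardizes an individual's heterozygous-locus count by the mean observed
heterozygosity of the loci it was actually typed at, so missingness does
not bias it; HL weights loci by expected heterozygosity. Temporal trends
are ordinary least squares on raw calendar year (so intercepts are on the
calendar scale); the reproductive models instead recode year to 0 at 2006
before standardizing.

## Identity disequilibrium

`g2_point()` uses the pairwise-complete estimator over ordered locus
pairs: each pair $(i,j)$ is restricted to its own jointly typed
individuals $N_{ij}$, with
$num_{ij} = \frac{1}{N_{ij}}\sum_k h_{ki}h_{kj}$ and
$den_{ij} = \frac{1}{N_{ij}(N_{ij}-1)}\sum_{k \ne l} h_{ki}h_{lj}$, and
$\hat g_2 = \sum num / \sum den - 1$. This is the implementable reading of
the missing-data estimator this statistic is known by; small
constant-order differences from other low-order weightings are possible
and the choice is recorded in output metadata. Pairs with $N_{ij} < 2$
are dropped with a warning. The vectorized implementation is checked
against a literal quadruple-loop oracle to $10^{-12}$ in the test suite.

Precision comes from bootstrap resampling of individuals; significance
from permutations that shuffle every locus column independently, which
destroys between-locus association while preserving each column's
heterozygosity rate and missingness pattern. Permuting whole individuals
would preserve the signal under test and is deliberately not offered. The
permutation p-value carries the add-one correction and is never zero.

## Reproductive-success models and averaging

Litter size enters as binomial events out of 4 trials (the species
maximum); breeding propensity is Bernoulli on litter size $\ge 1$. The
log-likelihood includes the binomial constant so AIC follows mainstream
GLM conventions, and an events/trials fit is coefficient-identical to the
four-Bernoulli-rows encoding (tested to $10^{-8}$). Continuous predictors
(age, IR, year) are Gelman-standardized — centered and divided by two
standard deviations — making their coefficients comparable to binary
predictors.

All $2^3$ predictor subsets are fitted; Akaike weights use AICc by
default for the averaging stage (standard for small samples in this
workflow), with plain AIC available by configuration. Averaging is
*conditional* (natural): each term is averaged over the models containing
it with renormalized weights, and its adjusted SE is
$\sum \tilde w_m \sqrt{SE_m^2 + (\beta_m - \bar\beta)^2}$. Confidence
bounds are fixed at $\pm 1.96 \times$ adjusted SE (not a t quantile).
Relative importance is the full-set weight sum over models containing the
term. Whether a $\Delta$-threshold subset should restrict the averaging
is genuinely open in this workflow; the default averages the full
candidate set and `subset_delta` restricts it when wanted. $R^2$ of the
global model defaults to the variance-function (Pearson-discrepancy
ratio) form, with the deviance-based Kullback–Leibler form as an option —
the variance-function form is unstable when fitted probabilities touch
0/1, which is why both are exposed and the method is recorded. Rows with
any missing predictor are dropped from *all* candidate models of a
response so criterion values are comparable.

## Local-effects scan

The scan deliberately uses *unstandardized* predictors and *plain AIC*:
single-locus 0/1 heterozygosity slopes and the multilocus mean-H$_O$ slope
are then on their natural scales, and model ranking matches the AIC
convention this comparison is reported in. The base model is
`litter/4 ~ year`; each locus model adds that locus's heterozygosity; the
HO model adds the individual mean across loci. Loci monomorphic within
the complete-case subset are excluded with a note rather than silently
fitted as duplicates of the base model. Rows sort by AIC with
alphabetical tie-breaks for deterministic output. The verdict rule:
local effects are indicated only when some single-locus model is both
substantially better supported than the multilocus model
($\Delta AIC < -4$) *and* larger in slope magnitude; support bins at
$|\Delta AIC| < 2$ and opposite-sign slopes are flagged alongside.
Because heterozygosities of individual loci are correlated under
inbreeding, relative effect magnitudes — not significance of individual
loci — carry the interpretation.

# The synthetic generator

`sim_config()` defaults describe the study scale the package is built
around: 168 individuals (~54% female), 32 microsatellite loci with 2–7
alleles each (weighted toward 2–3, as in low-diversity panels), six
sampling years spanning 2006–2016, ages 1–5, 5% missing calls, and
inbreeding $f \in \{0, 0.25\}$ with equal probability — giving identity
disequilibrium $g_2 = 0.0204$, the order observed in such populations.
Fitness defaults ($\beta_0 = 1.1$, $\beta_{year} = -0.36$ per year,
$\beta_f = -1$, $\beta_{age} = 0.1$) produce a declining reproductive
trend with a modest inbreeding load. Genotypes are drawn per locus given
$f$: with probability $f$ one allele is drawn and duplicated (IBD),
otherwise two independent draws. Null alleles can be added (frequency
$r$, invisible; carriers score homozygous, null homozygotes missing) to
exercise the Brookfield estimator.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data:

* **Linkage and pedigree structure.** $f$ is drawn, not propagated
  through matings, and loci are independent given $f$. All statistics in
  scope assume unlinked neutral markers, so this is sufficient for them,
  but linked panels or genuine local effects caused by linked fitness loci
  are only represented through the explicit planted-signal scenario.
* **Clustered missingness.** Missing calls are independent per call. Real
  datasets concentrate failures in a few low-quality samples, which leaves
  far more complete cases than the iid model does at the same marginal
  rate; complete-case subsets of simulated data are therefore smaller than
  a field dataset of the same size and missingness would give.
* **Allele-frequency change over time** and sex-linked or year-structured
  genotyping artifacts.

`simulate_local_effect_dataset()` is the planted-signal companion: all
individuals female and fully genotyped, with the fitness signal attached
to a single biallelic locus at minor-allele frequency 0.1. The planted
locus is deliberately *less* heterozygous than the rest of the panel: the
multilocus mean-H$_O$ slope of a single-locus signal scales as
$b_{het} \cdot L \cdot \mathrm{Var}(h_\ell)/\sum_j \mathrm{Var}(h_j)$,
so a planted locus with below-average heterozygosity variance keeps the
multilocus slope visibly smaller than the single-locus slope, which is
the contrast the classifier keys on. Defaults ($n = 240$, $b_{het} =
3.5$) make the verdict stable across seeds.

# Validation problem sizes

The test suite validates each stage at sizes chosen to make Monte-Carlo
bounds sharp while keeping the default run quick: $g_2$ recovery of the
closed form at $N = 2000, L = 32$; the brute-force equivalence on fifty
$20 \times 6$ matrices with and without missing entries; permutation-test
calibration on 500 null datasets at study scale with 200 permutations
each; IRLS-oracle equivalence on 30-row model fits; load-recovery and
CI-coverage over 200 replicate cohorts of 90 females; and a Wald
power-oracle comparison at a strong load ($\beta_f = -6$), where the
empirical CI-exclusion rate is required to match the analytic power
prediction within ten percentage points.

# Known limitations

* The attenuation of $\beta_f$ through the IR proxy means weak latent
  loads (e.g. a quarter-logit difference between inbreeding classes) are
  detected as a *sign* more often than as a significant coefficient at
  $n \approx 90$; the power-oracle test quantifies this honestly rather
  than overstating sensitivity.
* The HWE Monte-Carlo p-value is itself an estimate; at the default
  10,000 permutations its SE at $p = 0.05$ is about 0.002.
* Exact reproduction of third-party exact-test p-values is not promised:
  test families differ across toolkits, which is why the method metadata
  travels with the output.
* The variance-function $R^2$ should not be used near saturation; switch
  to the deviance-based form there.
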