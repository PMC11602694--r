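---
title: "Methods: common-garden heat-stress analysis with heatgarden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: common-garden heat-stress analysis with heatgarden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`heatgarden` analyses repeated common-garden thermotolerance assays on
temperate octocorals such as *Paramuricea clavata*: tagged colonies from
several source populations are fragmented, reared under a standardized heat
stress (e.g., 25 °C for 28 days) in successive years, and scored daily for
percentage tissue necrosis on a 5 % visual grid. The package turns those
trajectories into an individual fitness proxy, partitions its variance into
environmental (year), genetic (individual, population) and plastic
(population-by-year) components, relates individual thermotolerance to
microsatellite heterozygosity, characterises the summer thermal regime that
the colonies experienced, and quantifies genotype-by-environment sensitivity.
A synthetic-data generator reproduces the statistical structure of the design
so that every stage can be exercised and tested without external downloads.

```{r}
library(heatgarden)
cfg <- pipeline_config(simulate = sim_config(seed = 1), seed = 1)
bundle <- run_pipeline(cfg)
write_report(bundle, "run1")
```

## The phenotype stage

**Descriptors and impact classes.** Daily group summaries per population and
year are the mean extent of injury (± SE over colonies), the percentage of
affected colonies (necrosis above 10 %), and the percentage of dead colonies
(100 % necrosis). Individual values are binned into impact classes at the
conventional boundaries: below 10 % "none", 10–30 % "low", above 30 up to
60 % "moderate", above 60 % "severe"; the boundary values 10 and 30 belong to
"low" and 60 to "moderate".

**PCA fitness proxy.** Cases are colony-by-year trajectories; variables are
the daily necrosis percentages; the PCA operates on the correlation matrix
(all day variables standardized). An exploratory PCA over all days is
reported for reference; the definitive PCA drops days before `trim_before_day`
(default 10), because early days carry little signal before necrosis onset,
and its first component is the fitness proxy. Eigenvector signs are arbitrary
in any eigensolver, so PC1 is oriented to correlate positively with final-day
necrosis: a high score always means strong necrosis development. Cases with
a missing retained day are dropped (complete-case PCA) with a warning.
Constant day columns (for example all-zero early days) cannot be
standardized and are excluded from the PCA with the exclusion recorded.

**Box–Cox normalisation.** PC1 scores contain negatives, so they are shifted
by `1 - min(score)` before transforming (the shift is recorded in the result
for auditability and can be overridden). The exponent is chosen by profile
maximum likelihood under the fixed-effects model
`score ~ population * year`, and Shapiro–Wilk / Levene diagnostics of the
transformed model residuals are reported rather than silently assumed.

**Response models.** Model 1 is the fixed-effects linear model
`population * year`; model 2 adds a per-colony random intercept — the
individual baseline of thermotolerance ("nec-int"), deliberately restricted
to intercepts because a few yearly observations per colony cannot support
random slopes. Both models are fitted by maximum likelihood, not REML, so
log-likelihoods and AICs are comparable across fixed-effect structures.
Fixed factors are tested by likelihood-ratio tests of nested ML fits
(removing a main effect also removes its interaction). Year contrasts are
Tukey-adjusted comparisons of model-based year means using a large-sample z
reference — an approximation, preferred over degrees-of-freedom heuristics
for a model compared across structures. Singular fits (random-intercept
variance collapsing to zero) are flagged, not hidden. Only colonies observed
in at least two gardens enter the models, mirroring the field inclusion rule.

**Variance contributions.** The contribution of each factor (year,
individual, population, population-by-year) is the log-likelihood lost when
the factor is removed from the full mixed model, divided by the change in
parameter count, floored at zero and normalised to percentages summing
to 100. Two caveats are worth stating plainly. First, this per-parameter
likelihood statistic is *not* an ANOVA variance decomposition: in the
small-effect limit the raw contribution of a factor is proportional to its
explained variance divided by its parameter count, so factors with many
levels are discounted relative to a textbook variance share. Second, under a
global null all four normalised shares hover around 25 % each by
construction (they must sum to 100), so normalised shares are only
meaningful when the raw per-parameter gains are non-trivial; both raw and
normalised values are therefore returned.

**Field survey.** The in-situ survey stage is a parametric one-way ANOVA of
percentage necrosis on population with Tukey HSD contrasts and per-population
means ± SD.

## The population-genetics stage

Genotypes are diploid microsatellite calls, read and written in the GENEPOP
text format (2- or 3-digit coding, strict validation with line numbers on
parse errors). Diversity summaries report observed heterozygosity, Nei's
unbiased expected heterozygosity, and allelic richness by hypergeometric
rarefaction to a common number of gene copies.

**Differentiation.** F_ST is the Weir–Cockerham (1984) theta obtained by
summing the among-population, among-individual and within-individual
variance components over alleles and loci, globally and per population pair;
negative estimates are legitimate and not truncated. Significance comes from
permuting individuals among populations; p-values use the
`(1 + exceedances)/(1 + permutations)` estimator and can never be exactly
zero. This permutation test replaces the Markov-chain exact test of the
GENEPOP program: it addresses the same null of no genotypic differentiation
without an external binary, and the substitution is recorded in the result
metadata (`n_permutations`). Bayesian site-specific F_ST estimation is out
of scope.

**Clustering.** The DAPC-style workflow reduces the centred allele-dosage
matrix (missing dosages imputed to column means — standard practice, as the
PCA cannot ingest gaps) to at most 100 principal components, runs k-means
with 20 restarts for each candidate K, scores each K with
`BIC = n log(WSS/n) + K log(n)`, keeps the argmin, and derives per-individual
membership probabilities from a linear discriminant analysis on the retained
components (capped at n/3 components to avoid an overfitted LDA). De-novo
clusters are used rather than population priors. A caveat observed in
testing and inherent to this standard BIC at high dimension: with ~90
individuals and all components retained, k-means can shave enough
within-cluster variance from pure noise that K = 2 occasionally beats K = 1
under panmixia, so the package's tests assert cluster recovery under real
structure rather than a guaranteed K = 1 under none.

**Heterozygosity–fitness.** sMLH is the proportion of an individual's typed
loci that are heterozygous, divided by the mean locus heterozygosity averaged
over exactly the loci typed in that individual; on complete data the mean
sMLH is exactly 1. (Other software standardises slightly differently under
missing data; the definition above is the one implemented and tested.) The
heterosis test regresses nec-int on sMLH and compares the observed OLS slope
with a Monte-Carlo null built by permuting sMLH across individuals (10,000
permutations by default, two-sided p).

## The thermal stage

The climatology follows the standard marine-heatwave construction: for each
day of year, daily means within ±5 days across all baseline years are
pooled; the pool mean is the climatological mean and its 90th percentile the
iT90 threshold; both curves are smoothed with a 31-day circular moving
average, and Feb 29 is interpolated. Events are maximal runs of days
strictly above iT90: runs of at least `min_duration` days (default 5) are
marine heatwaves, shorter runs are heat spikes. The convention "more than 5
days" appears in parts of the literature while the canonical detector uses
"at least 5"; the package uses ≥ 5 and exposes `min_duration`. Gap-joining
of events separated by a few cool days is available (`join_gap`) but off by
default so that short spikes remain distinct events. Severity follows the
anomaly fold `f = (temp - clim_mean)/(iT90 - clim_mean)` at the event peak:
Moderate (1–2), Strong (2–3), Severe (3–4), Extreme (≥ 4); a degenerate
climatology with iT90 equal to the mean on exceedance days is an explicit
error rather than an infinite fold. Summer statistics (June–August) report
mean ± SD, maximum, the T23 count of extreme heat days — daily means at or
above 23 °C, an ecological threshold for *P. clavata*; the series is daily
means, so T23 is computed on daily means — and MHW/MHS counts overlapping
the window.

## The sensitivity stage

Environmental values are yearly mean PC1 scores over the common genotype
set (genotypes scored in every year), so the same set defines every year.
Each genotype's yearly scores are regressed on these values; the slope is
its environmental sensitivity. Over the defining set the mean slope is
exactly 1 — an algebraic identity (the average of the per-genotype
regressions equals the regression of the yearly means on themselves), which
the tests assert to 1e-10 and the acceptance script recomputes.

The randomization null shuffles the pooled scores across all
(genotype, year) cells and refits all slopes against the *observed*
environmental values. A variant that recomputes the environmental values
from each shuffled panel is provided (`recompute_env = TRUE`) but is
degenerate as a null for the mean slope: any panel regressed on its own
yearly means has mean slope exactly 1, by the same identity as above, so
that variant cannot produce the near-zero null mean the method requires;
holding the observed values fixed is therefore the default. Because
three-point regressions make the null heavy-tailed, per-genotype
significance is reported as the fraction of observed slopes exceeding the
null mean, not as p-values.

Genotype categories are qualitative and the thresholds are design choices
recorded in the output: a slope inside the null's central 95 % interval
counts as "flat"; flat genotypes are "resistant" (first-year score below the
first-year median) or "hypersensitive" (above); slopes above the interval are
"sensitive", below it "atypical". Users can re-threshold from the returned
slopes and null interval.

## The synthetic-data generator

The generator is first-class, tested code that defines the study conditions
for every test.

**Necrosis panels.** A latent cumulative propensity
`L = mu + beta_year + pi_pop + u_colony + day_slope (d - 1) + eps` is made
monotone with a running maximum and mapped through `100 * plogis(L)` to the
5 % grid. This guarantees monotone non-decreasing trajectories absorbing at
100 % with a single latent path; it is a modelling stand-in for unknown
day-by-day necrosis dynamics, not a biological claim. Defaults — three
populations of 30 colonies, three gardens, `mu = -5`, `day_slope = 0.12`,
`beta_year = (0, 0.5, 7)`, `sigma_individual = 0.35`,
`sigma_population = 0.05`, `sigma_residual = 0.8`, 15 % single-year
dropout — were calibrated once so the generated panels show the field
pattern this design emulates: moderate necrosis (roughly 30–45 % at day 28)
in two ordinary years, colony death before the assay end in one catastrophic
year, a year factor carrying the overwhelming share of the variance
contribution with the individual factor an order of magnitude smaller, and
~76 genotypes present in all three gardens. Dropout is completely at random
and only ever removes one year per colony, so the two-garden inclusion rule
always holds; the real missingness mechanism is unknown and not modelled.

**Genotypes.** Per-population allele frequencies follow a Balding–Nichols
model: ancestral frequencies Dirichlet(1), population frequencies
`Dirichlet(p (1 - theta)/theta)`, genotypes drawn under within-population
Hardy–Weinberg proportions. Balding–Nichols was chosen because its theta
parameter equals the expected Weir–Cockerham F_ST, giving a closed-form
calibration target; the tests verify the estimator mean against
`theta_target = 0.015` over 200 replicates. The default panel is 14 loci
with 3–8 alleles.

**Temperature.** Daily means are a sinusoid (mean 17.5 °C, semi-amplitude
5 °C, peak in mid-August, typical of ~15 m depth in the north-western
Mediterranean) plus stationary AR(1) noise (phi 0.8, sigma 0.4). Injected
warm anomalies are expressed in folds of the local iT90 width so a `fold`
of 1.5 lands in the Moderate band; the generator converts folds to °C using
the climatology of its own base series and records exact event windows as
ground truth. With the noise switched off entirely, the day-of-year
percentile of an annual cycle still exceeds the pooled mean near the
seasonal peak by a few hundredths of a degree, which can surface as spurious
hair-width exceedances there; tests of exact boundary recovery therefore
inject events away from the seasonal maximum and assert that every injected
window is recovered exactly.

**Survey.** Per-colony survey necrosis is a zero-inflated Beta mixture with
population-specific parameters, giving one mildly impacted population and
two heavy-tailed ones (SD exceeding the mean), then snapped to the 5 % grid.

## Reproducibility and problem sizes

All stochastic stages derive their seeds deterministically from one global
seed; two runs of the same configuration produce byte-identical artifacts,
which the tests assert file by file. The test suite chooses problem sizes
that keep the full run in a few minutes: estimator calibrations use 200
genotype replicates, permutation-uniformity checks 1,000 replicates of 99
permutations, and the year-contribution monotonicity check 200 full-size
panels; the shipped pipeline defaults (1,000 permutations, 10,000
randomizations) are the ones intended for analyses.

## Limitations

Control-temperature fragments are not modelled (an all-zero panel is the
only control-like input, used for QC). Hardy–Weinberg and linkage
disequilibrium testing, Bayesian site-specific F_ST, satellite or multi-depth
temperature ingestion, and reaction-norm models beyond straight-line
three-point fits are out of scope. Passing tests on synthetic data show the
machinery is correct and calibrated under the generator's assumptions —
logistic latent necrosis dynamics, drift-model allele frequencies,
AR(1)-plus-sinusoid temperatures, random dropout — not that real gorgonian
data satisfy those assumptions.
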