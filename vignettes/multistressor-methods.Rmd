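---
title: "Methods: multi-stressor analysis of stream macroinvertebrate communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-stressor analysis of stream macroinvertebrate communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamstress)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely open.

## The problem

Agricultural catchments expose streams to several stressors at once:
pesticide runoff, nutrient enrichment from fertilizer and waste water, and
habitat alteration through fine-sediment deposition and loss of thermal
buffering. Biomonitoring designs for this question sample a set of stream
sites repeatedly over years, identify macroinvertebrates to family level, and
ask (i) how community descriptors and biotic indices respond to each stressor
singly and in combination, and (ii) how much community-composition variance
each stressor set explains, alone and shared. Interactions are judged against
the *additive expectation*: if the combined effect of two stressors falls
short of the sum of their single effects the interaction is antagonistic; if
it exceeds it, synergistic. `streamstress` implements this chain end to end
and validates every stage on synthetic data with known ground truth.

## Pesticide toxicity: toxic units

Measured concentrations are standardized against acute toxicity as
`TU_i = log10(C_i / LC50_i)`, using 48-h *Daphnia magna* LC50 values because
toxicity data for tropical stream taxa are essentially unavailable; a
sample's toxicity is the maximum `TU_i` over detected pesticides
(`tu_max()`). Choices:

- **Log base 10** is the toxic-unit convention; the base is configurable but
  10 is the tested default.
- **Below-LOQ exclusion**: a measurement missing or below its limit of
  quantification never enters the maximum. A sample with no usable
  measurement is flagged `no_detect` (NA toxic unit) rather than erroring,
  because sparse detection tables are the field norm.
- **LC50 coverage is never total**: pesticides without a reference value are
  excluded with a warning naming them, not an error.
- **Aggregation**: per (site, campaign) by default; a `aggregate = "site"`
  option pools campaigns first, since monitoring programs differ in whether
  toxicity is summarized per visit or per site. Per-campaign is the default
  because it preserves the repeated-measures structure the mixed models need.
- The shipped LC50 table (`inst/extdata/lc50_daphnia_synthetic.csv`) is a
  synthetic stand-in with literature-order-of-magnitude values, clearly
  labelled as such; real analyses should supply a curated table.

## Biotic indices

`spear()` implements the SPEAR pesticides index as the log-abundance-weighted
percentage of at-risk taxa,
`100 · Σ log(x_i + 1) y_i / Σ log(x_i + 1)` over taxa present in the sample.
The ratio form bounds the index in [0, 100] and makes it invariant to the
logarithm base (asserted to 1e-12 in the tests). The `log(x + 1)` weight is
the default; a `log(4x + 1)` variant used in parts of the SPEAR literature is
exposed via `weighting = "log4x"`. Taxa with abundance zero do not enter
either sum; an empty sample returns 0 with a warning rather than NaN.

`bmwp()` sums per-family tolerance scores (1 most tolerant … 9 most
sensitive, the Panama-adapted scale) over families *present*; presence is per
sample, and site-level pooling is obtained by aggregating campaigns upstream.
At-risk classifications and score tables are input data: they come from
trait databases, so the package validates user-supplied tables
(binary at-risk flag, scores in 1..9) instead of hard-coding any.

## Candidate mixed models and model averaging

Each response (log total abundance, richness, SPEAR, BMWP) is modeled on the
three stressor gradients with exactly five fixed-effect structures: additive
(`M1`), one pairwise interaction each (`M2` NE×SE, `M3` PT×SE, `M4` PT×NE),
and all pairwise plus the three-way interaction (`M5`). The random structure
mirrors the repeated-measures design: a site random intercept, an AR(1)
correlation over campaigns within site, and per-site residual variances
(`varIdent`). Fitting is by maximum likelihood via `nlme::lme()` (or
`nlme::gls()` when the random intercept is dropped — conventional for the
richness model, exposed per response rather than hard-coded). Choices and
caveats:

- **ML, not REML**, because the candidates differ in fixed effects; a REML
  refit of the final model is available through `method = "REML"`.
- **AR order 1**: higher ARMA orders are rarely identifiable from 20
  campaigns; the within-site correlation parameter `rho` is reported.
- **Predictors are z-standardized** by default so single-effect estimates,
  and therefore additive expectations for interactions, live on a common
  scale; `standardize = FALSE` gives raw-scale fits.
- **Abundance is modeled as log(x + 1)** in the analysis scripts: raw counts
  are heavy-tailed and the Gaussian mixed model is for index-scale
  responses, not counts.
- **Parameter count K** is fixed effects + σ²_site + ρ + (n_sites − 1)
  variance ratios + σ²; for 13 sites this yields K = 19 for the additive
  model and 23 for the full model, the magnitudes typical of published
  selection tables for this design. Other conventions (e.g. not counting the
  variance ratios) change K but not model ranking within a fixed random
  structure.
- **Non-convergence** is captured and reported per candidate; selection and
  averaging proceed over the converged subset and name the dropped models.

AICc is `−2ℓ + 2K + 2K(K+1)/(n−K−1)`; weights are
`w_i = exp(−Δi/2)/Σ exp(−Δj/2)`. The averaging retention rule is `Δi ≤ 2`,
which reproduces the common "two most plausible models" behaviour while
remaining principled when one model dominates; a `top_k` rule is also
available. Averaged estimates use weights renormalized over the retained
models containing the term; the unconditional standard error is the
Burnham–Anderson combination `Σ w_i sqrt(se_i² + (b_i − b̄)²)`, and 95%
intervals are normal-based.

`classify_interaction()` applies the decision sequence: CI contains 0 →
no-effect; CI contains the additive expectation → additive; otherwise
antagonistic if |estimate| < |AE|, else synergistic. The additive expectation
of the three-way term is the sum of the three single effects.

## Ordination and variance partitioning

Site-level communities are campaign means of family counts (`median`
available), Hellinger-transformed: `sqrt(x_ij / Σ_j x_ij)`, which gives every
site unit sum of squares and makes Euclidean projection defensible for count
data. The transformed matrix carries a flag and re-transforming it is an
error — a silent double transform is a classic analysis bug.

`rda_fit()` centers the response, projects it onto the (centered,
z-standardized) predictors via QR, and reports `R² = tr(Ŷ'Ŷ)/tr(Y'Y)` with
canonical axes from the SVD of the fitted matrix. Collinear predictor
columns are dropped with a warning. `adjusted_r2()` is the Ezekiel
correction, which may legitimately be negative. `partial_rda()` residualizes
response and predictors on the conditioning set; its adjusted fraction is
defined by subtraction, `adj(X|Z) = adjR²(X∪Z) − adjR²(Z)`, the construction
under which the Venn fractions of `variance_partition()` add *exactly* (the
tests assert 1e-10) to the full-model adjusted R². Fractions are reported as
computed, never truncated at zero, so the additive-expectation arithmetic
stays exact. The interaction type of a combination is `A` when its combined
adjusted fraction is below its additive expectation and `S` when it
surpasses it; equality (measure-zero in practice) is reported as `A`, i.e.
"not surpassing". The RDA core is implemented in the package (some twenty
lines of linear algebra) so the partitioning and permutation schemes are
exactly as documented; the test suite cross-checks `R²`, adjusted `R²`,
every Venn fraction and the pseudo-F against `vegan` (`rda`, `RsquareAdj`,
`varpart`, `anova.cca`) and against a brute-force per-column regression
oracle.

`permutation_test()` uses the pseudo-F
`(SS_fit/df_model)/(SS_resid/df_resid)` with `p = (1 + #{F* ≥ F_obs})/(1 +
n_perm)`. For partial tests the reduced-model residual scheme (residualize,
then permute rows) is the default, the de-facto standard for conditioned
ordination tests. An exhaustive mode enumerates all n! row orders for small
n and is compared against an independent enumeration oracle in the tests.
Permutation p-values under a true null are verified to be uniform
(Kolmogorov–Smirnov over 200 replicate datasets).

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated. Defaults: 13 sites × 20 campaigns (260 samples); 57 families with
the four dominant families at 33.3 / 26.3 / 18.6 / 4.6 % of individuals and
~166 individuals per sample; stressor gradients uniform across sites within
TU −4.46..0.24, SRP 0.04..0.53 mg/L, sedimentation index 0..20, temperature
13.3..18.2 °C, with campaign noise at 10 % of each range; site random
intercepts (SD 0.3 on the log scale), a shared latent AR(1) process
(ρ = 0.4, SD 0.3) and negative-binomial counts (size 2). Where the emulated
design prints no value (noise fractions, effect sizes, dispersion, variance
components) the defaults are fixed once at values a field ecologist would
call realistic for family-level kick samples — overdispersed counts, modest
site heterogeneity, moderate temporal persistence — and are not tuned
thereafter.

Structural choices:

- Counts are **negative binomial** (Poisson as the `dispersion = Inf`
  limit): overdispersion is the norm in community counts. The downstream
  mixed models are Gaussian on index scales, so the generator is
  deliberately *not* the fitted model — recovery tests for the mixed model
  itself use `simulate_response()`, which draws from exactly the fitted
  structure (Gaussian, site intercept, AR(1)).
- The site intercept and the AR(1) process are **shared across families**:
  they model whole-community productivity shifts, which preserves
  composition shares while giving the index responses genuine temporal
  autocorrelation.
- At-risk families get **more negative toxicity slopes** and
  nutrient-sensitive (high-BMWP) families more negative enrichment slopes,
  so SPEAR and BMWP respond to their target stressors by construction; family
  intercepts carry a lognormal-mean (Jensen) correction so realized dominance
  shares hit their targets in expectation.
- Stressor gradients are **mutually independent by default** (so the
  |r| ≥ 0.70 screen passes); `stressor_cor` couples the site-level means
  through a Gaussian copula to exercise the screen.
- `generate_pesticides()` constructs concentration tables whose `tu_max()`
  is the requested target *exactly*: the carrier pesticide (largest LC50, so
  low targets stay above the LOQ) sits at `LC50 · 10^target`, decoys
  strictly below. The round-trip is asserted at 1e-12 — machine-precision
  exactness of an inversion by construction.
- A `drop_fraction` removes whole (site, campaign) samples to mimic
  unbalanced sampling; all downstream stages tolerate the gaps.

What the generator does **not** emulate: spatial stream-network structure,
taxon-specific temporal dynamics (phenology, drift), trait correlations
beyond the at-risk/score bias, measurement error in stressor variables, and
the heavy inter-family correlation structure of real communities beyond the
shared site/time terms. Passing tests therefore demonstrate the *estimators*
are correct and calibrated under a realistic repeated-measures design — not
that any particular field system behaves like the generator.

## Validation summary

The test suite asserts, among others: exact worked-example arithmetic
(two-taxon SPEAR 33.333, BMWP hand sums, Akaike weights from published
Δ-AICc sets, additive expectations and A/S typing from published adjusted-R²
fractions); OLS reduction of the mixed model when all random terms are
disabled; nested-model likelihood ordering; 95% CI coverage of the known
slopes in 88–99% of 100 replicate simulations (30 sites × 20 campaigns) with
AR(1) bias below 0.05; RDA R² against brute-force regression (1e-8) and
vegan (1e-10); partition fraction identities (1e-10); exhaustive-enumeration
agreement of the permutation test; and null-uniformity of permutation
p-values. Problem sizes in the tests (6–30 sites, 100–200 replicates,
199–999 permutations) were chosen to make these statistical checks decisive
at desk scale.

## Known limitations

- The Gaussian mixed models are fit to index responses; count responses are
  log-transformed rather than modeled with a GLMM.
- Model-averaged CIs are normal-based; no small-sample t adjustment.
- The variance-partition typing rule compares point fractions, not
  uncertainty intervals — as is conventional for adjusted-R² partitioning.
- Empirical estimates from any particular field dataset depend on response
  transformations and predictor scaling that published studies rarely state;
  this package records both in its outputs instead of guessing at any one
  study's choices.
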