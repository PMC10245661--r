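---
title: "Spatiotemporal analysis of root and soil microbiomes with spatiomic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal analysis of root and soil microbiomes with spatiomic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`spatiomic` analyses how plant-associated microbial communities are
structured in space and time under replicated field designs. The package
is organised around a regional survey (five sites, plots nested in
site × nitrogen-addition cells, three soil cores and paired root samples
per subplot) and a single-site growing season (four plots sampled
biweekly for soils, monthly for roots). All stages consume an `otu_table`
(integer read counts, samples × OTUs) and a metadata table carrying the
design columns (`site`, `plot`, `subplot`, `n_treatment`,
`collection_date`) plus UTM coordinates, so geographic distance is plain
Euclidean distance in meters.

Counts are rarefied to a common depth (10,000 reads is the default
convention) by sampling without replacement; samples below depth are
dropped and reported, never silently imputed. Taxa that end up with zero
total reads are kept in the matrix but flagged, which keeps root and soil
matrices alignable. Alpha diversity is richness and inverse Simpson
$1/\sum_i p_i^2$. Environmental covariates can be screened with the
extreme-value rule that flags values outside
$[Q_1 - 3\,\mathrm{IQR},\ Q_3 + 3\,\mathrm{IQR}]$; quartiles use linear
interpolation between order statistics (`quantile` type 7), fixed so the
mask is reproducible.

# Nested PERMANOVA and effect sizes

Community dissimilarity is Bray-Curtis,
$d_{ij} = \sum_t |x_{it}-x_{jt}| / \sum_t (x_{it}+x_{jt})$, computed on
rarefied counts (equivalent to relative abundances at equal depth). The
distance matrix is partitioned by the Gower-centered inner-product
decomposition. Sums of squares are type III (marginal): each term is
adjusted for every other term whose column space does not contain it.
That containment rule, applied with sum-to-zero contrasts, reproduces the
split-plot scheme automatically — Site, N and Site × N are adjusted among
themselves, while the random plot term (indicators of the plot × N cells)
absorbs the remaining between-cell variation. On the regional scaffold
this yields the design degrees of freedom 4 / 1 / 4 / 28 for
Site / N / Site × N / Plot(Site × N).

Each fixed whole-plot term is tested against the mean square of the
nested random plot term; the plot term is tested against the residual.
This is the standard expected-mean-squares logic for a random factor
nested in crossed fixed factors. P-values come from Freedman–Lane
permutation of reduced-model residuals. Exchangeable units respect the
design: whole-plot terms permute intact subplot cells (equal-sized blocks
of cores), the plot term permutes cores within their parent site × N (or
date × N) cell. For one-factor designs with $n \le 8$ an exact
enumeration over all $n!$ relabelings is available and is used to
validate the Monte-Carlo sampler.

Effect size per term is
$\omega^2 = (SS - df\,MS_{denom}) / (SS_{total} + MS_{denom})$, computed
with the term's designated denominator and reported as computed, including
negative values. The formula is validated in the test suite by the
null-expectation zero case ($SS = df\,MS_{denom}$) and the property
$\omega^2 \le R^2$ over randomized designs. Beta dispersion (distance of
each sample to its group spatial median in the corrected principal
coordinate space, with a permutation F-test) is delegated to
`vegan::betadisper`, with size-one groups excluded.

# Ordination concordance

NMDS configurations (via `vegan::metaMDS`, 20 random restarts, $k = 2$)
of two communities are compared by Procrustes superimposition: the second
configuration is translated, uniformly scaled and rotated onto the first,
and the residual sum of squares $m^2$ (target-normalized, so
$m^2 \in [0,1]$ and $t = \sqrt{1-m^2}$) is tested by permuting sample
identities (PROTEST). The fit is deliberately asymmetric — the fungal
configuration is rotated onto the bacterial one in the motivating
analyses — because the per-sample residuals exported for downstream
modelling depend on which community is the target; the $m^2$ statistic
itself does not. The implementation is cross-checked against
`vegan::protest` in the test suite.

# Generalized dissimilarity models

Turnover is modelled as $\hat d = 1 - e^{-\eta}$ with
$\eta = \alpha + \sum_p f_p$, where each $f_p$ is a non-negative
combination of monotone I-splines — per-sample predictors enter through
$|f_p(x_i) - f_p(x_j)|$, while geographic and temporal predictors enter
as splines of the pairwise distance itself. Three quadratic I-spline
basis functions per predictor with knots at the minimum, median and
maximum (the customary default for this model family) are used
throughout. Coefficients are constrained non-negative, so every fitted
transfer function is monotone non-decreasing; fitting minimizes the
binomial-type deviance
$D = \sum 2\,[y \ln(y/\mu) + (1-y)\ln((1-y)/(1-\mu))]$ (with
$0\ln 0 \equiv 0$; observed $d = 1$ is shrunk by $10^{-9}$ for the log
limit) by box-constrained quasi-Newton (L-BFGS-B) from two starts (near
zero, and an intercept matched to the mean dissimilarity). The deviance is
convex in the coefficients for this link, so the multi-start is a
safeguard rather than a necessity. Percent deviance explained is
$100\,(D_{null}-D_{model})/D_{null}$ against the intercept-only fit.

Predictor importance is the percent drop in deviance explained when that
predictor's sample values are permuted (the pairwise-distance column is
permuted directly for `geo`/`days`, which have no sample decomposition);
its p-value is the share of permutations matching or beating the observed
fit. Backward elimination removes the least important non-significant
predictor (ties broken by smaller coefficient mass, then name) and refits
until everything retained is significant at $\alpha = 0.05$. Deviance
partitioning fits the model on every non-empty subset of the predictor
groups and decomposes the full model's deviance explained by
inclusion–exclusion; negative shared components are reported, not
clipped. Spline uncertainty uses sample-level withholding — each of 100
refits drops 30% of the samples and the induced pairs — with 95%
pointwise bands; withholding samples rather than pairs matches how the
motivating analysis describes its bootstrap.

# Lagged root–soil similarity

Each root sample is compared (similarity $= 1 - d_{BC}$) with its
spatially paired soil core on the same date, and with the mean over all
soil samples of the same subplot collected one lag earlier (14 days by
default). Field collections drift, so the soil collection nearest to the
lag target within ±4 days is used — the tolerance is a documented choice,
not stated by the motivating study. Root samples without a qualifying
collection are returned flagged as missing rather than silently paired.

# Core community and the neutral model

Taxa are ranked by the mean of (i) mean per-group occupancy (groups are
sites or collection dates) and (ii) replicate consistency (share of
groups where the taxon is in every sample), with ties broken by mean
relative abundance and then id so the ranking is a total order. The
cumulative Bray-Curtis contribution of each ranking prefix keeps the
full-table denominator, which makes per-taxon contributions additive and
the curve monotone — without that choice the curve need not be monotone.
The core is the prefix ending at the last rank whose inclusion raised
the contribution by at least 5% relative to the previous value; an
absolute-change variant sits behind a flag, and a threshold scan exports
core size, read share and neutral-model fit across thresholds so the
choice can be inspected.

The Sloan neutral model predicts occupancy from mean relative abundance
$\bar p$ as $1 - \mathrm{BetaCDF}(1/N;\ Nm\bar p,\ Nm(1-\bar p))$ at
read depth $N$; the migration rate $m$ is fit by unweighted least
squares (matching the widely used implementation family), and taxa are
classified against 95% Wilson binomial intervals at the realized sample
count. Fits that do not converge or explain no variance ($R^2 \le 0$)
are flagged as failed rather than dropped.

Root-vs-soil family differences are the log2 ratio of median per-sample
family proportions with a two-sided Wilcoxon rank-sum test and
Benjamini–Hochberg correction; a zero median gets a pseudo-proportion of
$1/(2N)$ added to both medians and the row is flagged. Fungal guild
labels are collapsed to grouped categories through a user-supplied
mapping; annotations below "Probable" confidence lose their guild, and
unmapped multi-guild labels are kept verbatim with a warning.

# The synthetic generator

`simulate_design()` emits the two field scaffolds: the regional design
(five sites with 4/4/4/3/4 plots — one site lost a block — two
N-treatment subplots per plot, three cores per subplot, both niches
sharing core points) and the growing season (four plots, 15 biweekly
soil dates with roots on every second date from the fifth, giving six
root dates that coincide with soil collections; this emulation keeps the
published 15/6 date counts and biweekly arithmetic rather than the exact
field calendar). Coordinates are drawn inside 19.5 m plot rectangles
with sites spaced tens of kilometres apart.

`simulate_community()` partitions taxa into core (log-normal pool top,
so occupancy is 1 by construction), neutral (per-sample relative
abundances from the Sloan Beta process at migration rate `m`), and
structured taxa, which receive multiplicative log-scale site offsets
(`site_sigma`), smooth seasonal curves (`date_amplitude`), a spatially
autocorrelated Gaussian field with exponential covariance
(`spatial_range`, in meters) and a weak N-addition shift (`n_effect`) on
a random 10% of structured taxa. Root communities are a convex mixture
(weight 0.7) of the lagged soil expectation of their subplot plus
root-specific abundance, which reproduces the two-week-prior > same-day
similarity contrast by construction. Counts are multinomial at the
configured depth. Log-normal + multinomial was chosen over
Dirichlet-multinomial because the ground truth stays directly
interpretable while giving comparable overdispersion at these scales.

The generator emulates the *statistical* structure the analyses assume —
design nesting, spatial decay, seasonality, a high-occupancy core, a
neutral fraction — and nothing sequence-level: no taxonomy, no chimeras,
no compositional biases of PCR, no phylogenetic correlation among taxa.
Passing tests therefore demonstrate that the estimators recover known
structure of this kind, not that real communities satisfy the model.

# Numerical choices and problem sizes

Defaults follow the emulated study where it states them (rarefaction
depth 10,000; 5% core threshold; 14-day lag; 100 GDM permutations; 30%
bootstrap withholding). Where it is silent the package fixes a value
once and documents it: ±4-day lag tolerance, type-7 quartiles, 3
I-spline basis functions at min/median/max knots, $\alpha = 0.05$
retention in backward selection, taxon pool of 400 and moderate effect
sizes in the generator defaults. The test suite and the acceptance
script exercise the full designs (114 samples per niche regionally; 360
soil and 144 root samples across the season) but with reduced taxon
pools and depths (tens to hundreds of taxa, depths of a few thousand
reads) and hundreds rather than 9,999 permutations; these sizes were
chosen as the smallest at which the statistical checks are stable.

# Known limitations

* Recovery of the Sloan migration rate from read-resampled communities
  is upwardly biased: the closed-form prediction treats detection as a
  hard threshold at abundance $1/N$, while sampling reads detects
  sub-threshold taxa with non-trivial probability. The acceptance suite
  measures this directly — estimates cluster roughly a quarter above the
  generating rate at $N = 10{,}000$ — and the package reports the fit as
  computed rather than correcting it, since the estimator is the field's
  standard form.
* Type III sums of squares decompose the total exactly only on balanced
  designs; with the decommissioned block the regional design is mildly
  unbalanced and the decomposition holds to about a percent.
* The PERMANOVA permutation scheme requires equal-sized exchangeable
  blocks for whole-plot terms; unbalanced core counts within subplots
  are not supported.
* Outlier sample removal is by explicit id list only; no automated
  ordination-space rule is provided, because the motivating study stated
  none.
* UniFrac or other phylogeny-aware distances, covariate imputation, and
  mixed-effects follow-up models on diversity or residuals are out of
  scope; plot-ready tables are exported instead of figures.
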