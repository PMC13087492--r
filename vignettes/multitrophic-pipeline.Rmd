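---
title: "Joint modelling of two-guild lake metacommunities: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of two-guild lake metacommunities: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multitroph)
```

`multitroph` analyses how two trophic guilds — fish and crustacean
zooplankton — co-respond to environmental gradients across a set of lakes,
and how their co-occurrence structure and community trait composition are
expected to change under shifted climate covariates. This vignette states
the statistical models the package implements, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where several defensible options existed.

## Data model

Three tables drive everything:

* a **community table** `Y` (sites × species, binary presence–absence, one
  guild label per species),
* an **environment table** `X` (sites × covariates, each covariate
  classified as climate, morphometry or anthropogenic, with site
  coordinates in decimal degrees and a scenario tag),
* a **trait table** `T` (continuous traits such as body length and
  critical thermal maximum, plus categorical traits such as trophic
  group).

Occurrence data must be strictly binary; abundance tables are admitted
only through an explicit `binarize` flag so that silent coercion can never
happen. Species observed at fewer than two sites are removed before joint
modelling (`filter_rare_species()`): a species seen in a single lake
carries no information about co-occurrence and destabilises the probit
fit.

## Environmental preprocessing

`preprocess_env()` applies, in order: variance-stabilising transforms
(log or square root, per covariate), a pairwise collinearity screen, a
single-pass column-median imputation, and standardisation to mean 0 / sd 1.

* **Collinearity screen.** Of any covariate pair with |Pearson r| above
  the threshold (default 0.9, computed on pairwise-complete observations),
  the *later-listed* member is dropped. The rule is deterministic and
  order-dependent by design — which member of a highly collinear pair is
  retained is scientifically arbitrary, so the package makes the choice
  reproducible rather than pretending it is principled.
* **Imputation.** Missing covariate cells are filled with the observed
  column median (mean available as an option). Multiple imputation is out
  of scope for this pipeline; the simple imputer is deterministic, logged
  in the returned object, and adequate when missingness is sparse.
* **Standardisation parameters are fitted once**, on the baseline table,
  and reused verbatim on every scenario table (`build_scenario_env()`).
  Scenario designs are therefore expressed in baseline standard
  deviations, which is what makes coefficients comparable across
  scenarios. Refitting the scaler on a scenario would silently absorb the
  climate signal being studied.

## Diversity statistics

Per-site **richness** is a row sum, optionally per guild. The **local
contribution to beta diversity** (LCBD) of site *i* is its share of the
total community-composition variance: pairwise Jaccard dissimilarities on
presence–absence data are squared, Gower-centred, and the diagonal of the
centred matrix is normalised to sum to one. Significance is assessed by
independently permuting each species column (999 permutations by default)
with `p = (#\{LCBD* >= LCBD\} + 1) / (n_perm + 1)`, followed by Holm's
step-down correction. The two guilds are tested as separate families,
because the analyses are run and reported per guild. The permutation count
and the within-column scheme are package defaults, documented rather than
asserted to match any particular external implementation.

For richness–LCBD relationships, both linear and quadratic ordinary
least-squares fits are computed. Selection uses **adjusted** R²: the
quadratic nests the linear model, so raw R² would always select the
quadratic; ties favour the linear form. Raw-R² selection is available as
an explicit mode for users who want the literal "highest R²" convention.

## Covariate screening by random forests

One classification forest per species is fitted on the covariates (plus,
optionally, the raw coordinates, which compete as candidates but are
excluded again before the joint model since space enters it as a random
level). Out-of-bag permutation importances are aggregated across species
with misclassification-error weights,

$$I_v = \frac{\sum_s w_s I_{sv}}{\sum_s w_s}, \qquad w_s = \max(0,\; 1 - \mathrm{OOB\ error}_s),$$

so that species the covariates actually predict contribute more to the
ranking. Weighting by error instead of accuracy is available as a switch.
All species share one forest seed, which makes the aggregate exactly
invariant to species order. Plain (unconditional) permutation importance
is used; conditional importance is not implemented. The top-k covariates
(default 10) are retained and the exclusion list is applied afterwards.

## The joint species distribution model

Occurrence is modelled with a probit link and latent liabilities:

$$y_{ij} = \mathbf{1}[z_{ij} > 0], \qquad
z_{ij} = x_i^\top \beta_j + \sum_h \eta^{site}_{ih} \lambda^{site}_{hj}
       + \sum_h \eta^{sp}_{ih} \lambda^{sp}_{hj} + \varepsilon_{ij},
\quad \varepsilon_{ij} \sim N(0, 1).$$

Species coefficients follow a trait-implied hierarchy,
$\beta_j \sim N(\Gamma^\top t_j, V)$, where $t_j$ is the expanded trait
design (intercept, log-standardised continuous traits, treatment-coded
categorical indicators) and $\Gamma$ is the trait-by-covariate effect
matrix — the quantity of scientific interest for trait-mediated
responses. Site-level factors are i.i.d. standard normal; spatial factors
have covariance $\exp(-d/\alpha_h)$ with Euclidean distance on (lon, lat)
in degrees and the decay scale $\alpha_h$ sampled over a fixed grid (101
values from 0 — meaning no spatial structure — to the maximum pairwise
site distance) via its discrete conditional posterior.

Priors: $\mathrm{vec}(\Gamma) \sim N(0, 10 I)$;
$V \sim \mathrm{IW}(K + 1, I)$; factor loadings carry a
multiplicative-gamma shrinkage process (shapes 5 and 5) so that
superfluous factors are damped rather than hand-pruned. These are
documented equivalents of the conventions common in hierarchical
community models, not clones of any specific implementation. The factor
counts are fixed (defaults: 2 site-level, 4 spatial) instead of adapted
during sampling.

The sampler is a Gibbs scheme with truncated-normal data augmentation.
All conditional updates are conjugate: a shared-precision multivariate
normal for all columns of $\beta$ at once, a matrix-normal regression for
$\Gamma$, inverse-Wishart for $V$, and blocked normal updates for factors
and loadings. Two diagnostic modes exist: hyperparameters
($\Gamma$, $V$) can be frozen so the $\beta$ posterior factorises into
one-dimensional probit posteriors that a quadrature grid can evaluate
independently, and a prior-only mode disables the likelihood so that the
sampled $\beta$ can be checked against its prior mean $\Gamma^\top t$.
Both checks run in the test suite.

**MCMC settings.** The long-run configuration is two chains of 1000
retained samples at thinning 5 after a transient of 2500 iterations. For
simulation work at desk scale the package ships
`mcmc_config_reduced()` — two chains × 500 retained, thinning 8,
transient 2000. The thinning here is deliberately heavier than the
minimum that produces 500 samples: at thinning 2 the split-chain PSRF of
the slowest-mixing occurrence coefficients stalls around 1.08–1.12 on
default-size synthetic fits, while thinning 8 brings the maximum PSRF
under 1.1 across seeds at roughly three minutes per fit on one core.

**Posterior summaries.**

* `tjur_r2()`: mean fitted probability at presences minus mean at
  absences, per species.
* `support_filter()`: per element of $\beta$ or $\Gamma$, support is the
  larger of the posterior probabilities of a positive or a negative
  value; heatmap exports mask elements at support > 0.90.
* `residual_associations()`: per sample,
  $\Omega = \Lambda^\top \Lambda$ (summed over factor groups) rescaled to
  a correlation matrix, sign support across samples, masked at > 0.95,
  and summarised by guild pairing. $\Omega$, not $\Lambda$, is the
  reported quantity because it is invariant to factor rotation and
  label switching.
* `variance_partitioning()`: per sample and species, the liability
  variance over sites is attributed to covariate groups — covariances
  between groups are split evenly between the two groups involved, and
  negative covariance-adjusted shares are floored at zero before
  normalisation — plus the sum of squared loadings per random-effect
  group. Fractions are averaged over samples; multiplying by each
  species' Tjur R² re-expresses them on the absolute scale. The
  intercept is constant across sites and therefore carries no share.

A note on calibration: with a truly null trait effect, the sign support
of a $\Gamma$ element behaves like $\Phi(|T|)$ with $T$ approximately
Student-t distributed ($\approx S - Q$ degrees of freedom). The expected
fraction of null cells exceeding 0.90 support is therefore slightly
*above* the 20% Gaussian asymptote at realistic species counts —
about 21% at S = 30. Users should read the 0.90 heatmap threshold as a
display convention, not a 20%-FDR guarantee.

## Scenario projection

`build_scenario_env()` replaces climate-class covariates with scenario
values on the raw scale and pushes them through the baseline
preprocessing. `predict_occurrence()` averages probabilities (never
liabilities) over retained samples. The default mode conditions on the
training-site factor estimates, which is the right choice when
projecting at the fitted lakes themselves; a marginal mode integrates the
factors analytically ($p = \Phi(x^\top\beta / \sqrt{1 + \sum_h
\lambda_{hj}^2})$) for prediction at new sites. Projections inherit the
usual caveats of this model family: dispersal is implicitly unlimited and
the species pool fixed, so homogenization signals are upper bounds.

## Networks

For each scenario's probability matrix, Spearman rank correlations are
computed for every species pair (average ranks under ties) with two-sided
p-values from the t-approximation on n − 2 degrees of freedom; edges are
retained at p < 0.01 with no multiple-testing correction (raw p-values
are the convention for these exploratory graphs, and the null edge rate
is verified empirically in the test suite). Metrics are computed on the
unweighted, sign-agnostic graph over edge-incident nodes: connectance
(edge density), mean shortest-path length over reachable pairs,
edge-betweenness communities cut at maximum modularity, and Newman's Q on
that partition. Correlation signs remain available as edge attributes.
Singleton species never enter the node count; whether to count them is a
genuine convention choice, and the package documents (and tests) the
edge-incident convention.

## Community-weighted means

`cwm()` weights trait values by relative occurrence probability,
per guild: continuous traits give probability-weighted means, categorical
traits give weighted level proportions (summing to one per site and
trait). Trends along raw-scale climate covariates are summarised by OLS
slope, intercept and R² — smoothers are for plots, whereas the slope sign
and magnitude are the comparable quantities across scenarios.
`richness_length_summary()` adds expected richness
($\sum_j p_{ij}$) and a size-class split at a configurable cutoff
(0.5 mm is the conventional split for zooplankton body length).

## The synthetic-data generator

`generate_metacommunity()` draws from exactly the generative model the
sampler fits, so every parameter has a recoverable ground truth. Sites
are placed along a 17-degree latitudinal gradient (matching the spatial
extent of the kind of provincial lake survey this pipeline targets, with
around 150 lakes by default); climate covariates are monotone functions
of latitude plus noise; lake area is lognormal and log-transformed in the
fitted design; traits are lognormal (lengths), normal (thermal maxima)
and multinomial (trophic group); and two guilds of 15 species each are
generated by default.

The default planted structure encodes, on the standardised scale:

* a positive community-wide response to maximum air temperature (0.6)
  and to lake area (0.7) — warmth and habitat size favour occurrence
  across the board,
* a negative length-by-maximum-temperature trait effect (−0.8) — larger
  bodied species respond less positively to warming, which is what makes
  community mean body size fall along the temperature gradient,
* a positive CTmax-by-maximum-temperature effect (0.6) — heat-tolerant
  species do disproportionately well in warm lakes,
* a negative precipitation effect on the top trophic group (−0.6),
* residual niche spread `v_diag = 0.25` around the trait-implied means,
* three planted fish–zooplankton association pairs on one site-level
  latent factor (|loading| 1.2, alternating signs), emulating
  predator–prey coupling that environmental covariates cannot explain.

Species whose drawn coefficients produce fewer than two presences or
absences are redrawn (bounded attempts), since such species would be
excluded by the rare-species filter anyway; this mildly truncates the
tails of the prevalence distribution and is the one place the generator
deviates from the pure model draw.

What the generator does **not** emulate: real geography, spatially
interpolated climate ensembles, observed trait distributions, abundance
dynamics, detection error, or phylogenetic signal. Passing recovery tests
on these data therefore demonstrates that the estimation machinery is
correct and calibrated — not that any particular field dataset satisfies
the model's assumptions.

## Problem sizes used in the checks

The shipped tests run the full pipeline on generated metacommunities of
150 sites × 30 species with the reduced MCMC preset (three seeds for
parameter recovery; ten lighter fits for the null-calibration study), and
verify the small-sample statistics against brute-force oracles on
instances of at most 8 sites or nodes. These sizes were chosen so the
whole suite completes comfortably on a single core while leaving the
recovery problems statistically non-trivial; paper-scale runs (hundreds
of sites, a hundred-plus species, long chains) use the same code paths
with `mcmc_config()` defaults.

## Known limitations

* Only the probit link is implemented; logit is not.
* Factor counts are fixed (with shrinkage), not adapted.
* Conditional importance for forests is not implemented.
* The scenario machinery replaces covariates; it does not model
  colonisation from outside the fitted species pool.
* Phylogenetic correlation among species niches is not modelled.
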