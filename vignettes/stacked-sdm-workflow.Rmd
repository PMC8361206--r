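---
title: "Stacked species distribution models on synthetic landscapes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked species distribution models on synthetic landscapes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stacksdm)
```

`stacksdm` implements a complete stacked species distribution modelling
(S-SDM) workflow — per-species probit BART occurrence models, three
stacking procedures, assemblage evaluation at two spatial scales,
phylogenetic assemblage structure, and Bayesian model comparison —
together with a synthetic-data module that makes every stage testable
against known truth. This vignette is the package's account of the
science: the models, the defaults and why they were chosen, the numerical
decisions, and what the synthetic experiments can and cannot show.

## The occurrence model

Each species' occurrence is modelled with Bayesian additive regression
trees under a probit link. For a binary label $y_i$ at covariates $x_i$,

$$P(y_i = 1) = \Phi\!\left(c + \textstyle\sum_{j=1}^{m} g_j(x_i)\right),$$

where each $g_j$ is a small regression tree and $c = \Phi^{-1}(\bar y)$
offsets the latent mean. Fitting uses the standard latent-variable
construction: $z_i \sim \mathcal N(c + \sum_j g_j(x_i), 1)$ truncated to
the sign dictated by $y_i$, refreshed each sweep, with the noise standard
deviation fixed at 1 as the probit link requires. Trees are updated one at
a time by Metropolis–Hastings moves on their structure — grow (split a
leaf), prune (collapse a pair of sibling leaves) and change (redraw the
rule of a no-grandchild internal node) with probabilities 0.4/0.4/0.2; the
swap move used by some samplers is omitted as a minor refinement — followed
by conjugate Gaussian draws of the leaf values.

Priors are the standard BART regularization: a leaf at depth $d$ splits
with probability $\alpha (1+d)^{-\beta}$ ($\alpha = 0.95$, $\beta = 2$),
split variables and cutpoints are uniform over up to 100 quantile-spaced
candidates, and leaf values are $\mathcal N(0, \sigma_\mu^2)$ with
$\sigma_\mu = 3 / (k\sqrt{m})$, $k = 2$, which shrinks the latent mean of
the ensemble into roughly $[-3, 3]$. Defaults are $m = 200$ trees and
1000 backfitting iterations with 20% burn-in; `bart_test_config()`
(20 trees, 200 iterations) is used throughout the test suite and the
reference pipeline, where fits take about a second and already separate
step-function structure at AUC ≥ 0.95. Leaves must hold at least 5
observations; proposals violating this are rejected.

Predictions evaluate every retained posterior draw of the ensemble, giving
a per-cell posterior mean probability and a 95% credible-interval width
(97.5th − 2.5th percentile) as the uncertainty layer. Variable importance
is the share of splitting rules using each covariate across retained
draws. Backward covariate elimination refits without the least-used
covariate and accepts the drop while stratified 4-fold cross-validated AUC
falls by at most 0.01 (both the tolerance and the fold count are
arguments; the selection internals of the original tooling are not
published, so this rule is this package's interpretation and is flagged as
such).

Model evaluation: AUC is the Mann–Whitney statistic with half credit for
ties; the binarization threshold is the smallest candidate (sorted unique
predicted values) maximizing TSS with the rule `probability >= threshold`.

## Stacking and assemblage evaluation

Given per-species prediction sets (probability layer, binary layer at the
TSS-maximizing threshold, CI-width layer), the three stacks are:

- **bS-SDM**: composition is the per-unit binary vector, richness its sum;
- **pS-SDM**: richness is the per-unit sum of probabilities; composition
  stays probabilistic and is evaluated through *expected* confusion cells
  ($a = \sum_{\text{obs}=1} p$, etc.), the established convention for
  scoring probabilistic community predictions;
- **cS-SDM** (probability ranking rule): the $k$ highest-probability
  species per unit are present, $k$ being that unit's observed richness.
  Ties are broken by fixed alphabetical species order so results are
  reproducible (a seeded random tie-break is available). Because observed
  richness constrains the prediction, SR deviation and SR change are not
  reported for cS-SDM.

Site-level predictions aggregate plot-level ones: species-wise union (max)
for binary/PRR composition, species-wise max for probabilities — the
probability the species occurs in at least its best plot; the independence
rule $1 - \prod(1 - p)$ is available via `prob_rule = "one_minus_prod"`.
Per-unit scores are SR deviation ($|{\rm pred} - {\rm obs}|$ divided by the
survey-wide maximum observed richness), SR change (pred − obs), prediction
success $(a+d)/n$, TSS $a/(a{+}c) + d/(b{+}d) - 1$, and Sørensen
$2a/(2a{+}b{+}c)$. Degenerate denominators yield NA with a warning rather
than an arbitrary value. The stacked uncertainty map is the per-cell sum of
per-species CI widths — a deliberate, documented interpretation, since no
standard definition exists for stacked posterior uncertainty.

## Phylogenetic assemblage structure

MPD is the mean cophenetic distance over unordered pairs of co-occurring
species. SES-MPD compares observed MPD to a taxon-shuffle null that
permutes the tip labels of the distance matrix while holding richness
fixed: $\mathrm{SES} = (\mathrm{MPD}_{\rm obs} - \mu_{\rm null}) /
\sigma_{\rm null}$, with the population SD of the null. When the shuffle
pool has at most 7 tips the null is enumerated exhaustively (a richness-k
community under a tip shuffle is a uniform k-subset, so $\binom{n}{k}$
subsets suffice); otherwise 999 Monte-Carlo shuffles are used by default
and a rank p-value is reported as $(\#\{\rm null \le obs\} + 1)/(n_{\rm
null} + 1)$. The pool defaults to all tree tips; restricting it to the
species present in the community matrix (`pool = "matrix"`) changes SES
and is offered as a switch. The sign convention reported here labels
SES > 0 as clustering and SES < 0 as overdispersion; note this is the
reverse of NRI-style usage (NRI = −SES), a known source of confusion when
comparing studies.

## Bayesian comparison machinery

Two estimators support the assemblage comparisons, both sampled with
seeded adaptive random-walk Metropolis (4 chains × 10,000 iterations, 20%
burn-in by default, matching common practice for these models; step sizes
adapt toward ~23% acceptance during burn-in only, so retained draws come
from a fixed kernel). Split-chain potential-scale-reduction is reported
and asserted < 1.1 on fixture problems.

- **Robust correlation**: bivariate Student-t likelihood with location
  pair, scale pair, correlation $\rho$ and degrees of freedom $\nu$;
  priors are weakly-informative normals on locations, half-normals on
  scales, uniform $\rho$, and $\nu - 1 \sim \mathrm{Exp}(1/29)$ on the
  standardized data scale. The heavy tails make $\rho$ robust to outliers;
  fixing $\nu = \infty$ recovers the plain-normal estimate (verified in
  the tests).
- **Hierarchical ANOVA**: value = intercept + group effect + unit random
  intercept + noise, with the unit intercepts integrated out analytically
  (each unit's observations share a compound-symmetric covariance), which
  keeps the sampler low-dimensional while still correcting for repeated
  measures of the same plots across stacking procedures.

Evidence summaries follow the MAP-p-value/ROPE style: the MAP p-value is
the Gaussian-kernel (Silverman bandwidth) posterior density at zero
divided by the density at the mode, clipped to [0, 1]; the ROPE percentage
is the posterior mass inside ±0.1 response SDs by default — the bounds are
not standardized in the literature, so they are arguments.

## The synthetic study system

The generator emulates the inputs of a remote-sensing S-SDM study:

- **Landscape**: white noise convolved with a Gaussian kernel of scale
  `autocorr_range` (km), standardized per layer — simple, seedable, and
  with directly controllable autocorrelation. Monthly temperature follows
  covariate 1 plus a sinusoidal seasonal cycle (tmax − tmin = 10 °C ± small
  smooth anomalies); monthly precipitation follows covariate 2, so derived
  bioclimatic layers carry real information about the niche axes.
  Coordinates are planar km, cell-centre registered, row 1 = north; points
  on interior cell boundaries belong to the south-east cell (floor rule).
- **Species**: a pure-birth phylogeny scaled to unit depth; per-covariate
  niche optima are Brownian-motion values on the tree blended with i.i.d.
  draws so `phylo_signal` ∈ [0, 1] tunes niche conservatism. Responses are
  logit-quadratic (Gaussian-shaped) around the optima. By default the
  intercept fixes suitability at the optimum to 0.9 and prevalence
  *emerges* from niche breadth and optimum position: presence/background
  designs cannot identify an absolute intercept, so breadth-driven
  prevalence is the only construction under which prevalence recovery is a
  fair test of the models. Calibrating the intercept to an explicit
  prevalence target remains available (`prevalence_range`).
- **Occurrences**: points are drawn with weight proportional to true
  probability times a multiplicative smooth bias field
  (`exp(strength × field)`), emulating uneven collection effort; presence
  grids are Bernoulli draws from the probability surfaces.
- **Survey**: square sites holding point plots; a species present in a
  plot's cell is detected with probability `detection_prob`, with one
  uniform draw per plot-species pair so that raising detectability can
  only add detections (monotone coupling). Site lists are unions of member
  plot lists.

### Reference conditions

The default pipeline configuration defines the package's reference
experiment: a 36 × 36 km landscape (1-km cells, autocorrelation range
8 km) with two broad covariates plus one fine-grained "microhabitat" axis
(smoothing scale 1.5 km); 10 species with `phylo_signal` 0.7; 150 records
per species with bias strength 0.5; 12 sites of 5 × 5 km with 8 plots each
(96 plots — mirroring the plot-heavy, site-light structure of
observatory-network surveys) and detection probability 0.8; reduced-size
BART; SES-MPD with 199 shuffles; and Metropolis runs of 4 × 1500 for the
in-pipeline comparisons. These sizes keep the full experiment around ten
seconds while leaving every estimate stable enough to assert
qualitative properties.

Crucially, the model covariates (`cov1`, `cov2`, `bio1`, `bio4`, `bio12`,
`bio15`) *omit the microhabitat axis* that the truth uses. This built-in
covariate mismatch reproduces a central phenomenon of assemblage
modelling: suitability is not occupancy, so binary stacks overpredict
richness at the plot scale (mean SR change ≈ +1.6 under the reference
conditions), while site-level unions recover composition far better (mean
Sørensen ≈ 0.85 vs ≈ 0.40 at plots) — the scale effect the evaluation
stage is designed to measure.

### What the synthetic system does not emulate

Real survey data differ in ways these tests cannot probe: real covariates
are cross-correlated, measured with sensor noise and gridded at coarse,
heterogeneous resolutions; real occurrence records carry taxonomic and
georeferencing error, not just spatial bias; real detection varies by
species and habitat; real niches are not quadratic on standardized axes;
and real phylogenies have calibration uncertainty. Passing the recovery
tests therefore shows the machinery is correct and well-calibrated under
its stated assumptions — not that any particular real-data analysis will
achieve similar accuracy.

## Numerical and design decisions

- **Raster container and formats.** Layers live in a small in-package
  grid class (matrix + origin + cell size, km); raster I/O uses the ESRI
  ASCII grid text format, keeping every artifact human-readable and
  diff-able. No reprojection is attempted; the synthetic world is planar.
- **Bioclim conventions.** Quarters are all 12 wrap-around 3-month
  windows; ties pick the first window; temperature seasonality is
  100 × sample SD; precipitation seasonality divides by (1 + mean) — the
  guard against zero-precipitation cells used by the common tooling
  dialect — with the plain CV available as a switch. The derivation is
  validated cell-by-cell against an independently coded scalar oracle at
  1e-9. Monthly minimum/maximum temperature inputs are required (and
  synthesized by the generator); products that provide a single surface
  temperature need a pre-processing choice that is out of scope here.
- **LAI composites.** Cumulative = sum of the 12-month climatology,
  minimum = cell-wise minimum, seasonality = 100·sd/mean of the
  climatology. The source conventions for these composites are not
  published precisely; these definitions are this package's documented
  interpretation.
- **Thinning.** The distance schedule between the published anchors (1 km
  below 100 records, 5 km above 10,000) is log-linear in record count — an
  interpretation, since no schedule is published between the anchors.
  Thinning itself is randomized repeated elimination (25 passes by
  default): exact maximum-record retention is NP-hard, so exactness is
  asserted only against brute force on small instances.
- **Pseudoabsences.** "About as many as presences" is implemented as
  exactly equal, at cell resolution (a pseudoabsence never shares a cell
  with a presence record), sampled without replacement.
- **Degenerate inputs.** Constant layers make Spearman comparisons NA with
  a warning; an all-constant null makes SES NA with an `undefined_sd`
  flag; communities below two species are flagged rather than scored;
  single-class labels and zero-variance designs are errors.
- **Determinism.** Every generator and sampler takes a seed and restores
  the caller's RNG state; the pipeline derives per-stage seeds from one
  master seed (all below 2³¹) and records them, with file checksums, in a
  manifest. Identical configurations produce bit-identical artifacts.
- **Package shape.** The BART fitter follows the classic modelling idiom —
  one fitting function returning a classed object with `print`, `summary`,
  `predict`, `plot`, `fitted`, `residuals` methods — because it is the one
  genuine estimator in the workflow; the surrounding stages are plain
  functions orchestrated by `run_pipeline()`, which suits a multi-stage
  pipeline better than forcing it into a single model object. The
  command-line entry points are thin wrappers (`inst/scripts/`,
  `scripts/acceptance.R`) over these functions.

## Known limitations

- The BART sampler is pure R; it is comfortable at the reference sizes
  (hundreds of training points, tens of thousands of cells) but is not a
  replacement for compiled implementations at atlas scale.
- cS-SDM uses per-unit observed richness as its constraint; reading the
  constraint as a survey-wide maximum is possible but not implemented.
- Probabilistic site aggregation by species-wise max is a lower bound on
  union probability; the independence rule is available but neither is
  exact under spatial dependence between plots.
- SES-MPD supports incidence data only (no abundance weighting, no MNTD).
- The Metropolis samplers are adequate for the low-dimensional posteriors
  they target; they are not a general probabilistic-programming substitute.
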