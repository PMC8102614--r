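---
title: "Phylogenetic analysis of yawn duration and brain measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic analysis of yawn duration and brain measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the model

The brain-cooling account of yawning predicts that species with larger,
more neuron-rich brains need longer yawns to achieve a comparable
thermal effect. Testing that prediction across mammals and birds
requires comparing species-typical yawn durations against brain mass
and neuron counts while respecting two facts about comparative data:
durations are positive and right-skewed, and species are not
independent observations — close relatives resemble each other through
shared descent.

`phyloyawn` addresses both with a Bayesian multilevel Gamma regression.
For species $i$ with mean yawn duration $y_i$ (seconds):

$$y_i \sim \mathrm{Gamma}(\mu_i, \alpha), \qquad
  \log \mu_i = \beta_0 + \textstyle\sum_k \beta_k z_{ik} + b_i + u_i$$

where the Gamma is parameterized by mean $\mu$ and shape $\alpha$, the
$z_{ik}$ are z-scored log brain measures (brain mass in grams, total or
cortical/pallial neuron counts, or neuronal density in neurons per gram
of brain), and two species-level intercepts absorb non-independence:

* $b \sim \mathrm{MVN}(0,\ \sigma_{\mathrm{phylo}}^2\, C)$, with $C$
  the phylogenetic correlation matrix (shared root-to-ancestor path
  lengths, scaled to unit tree height), and
* $u_i \sim \mathrm{N}(0,\ \sigma_{\mathrm{species}}^2)$ i.i.d.,
  capturing species idiosyncrasy not explained by phylogeny.

Priors are regularizing throughout: $\mathrm{N}(0,1)$ on $\beta_0$ and
every slope, $\mathrm{Exponential}(3)$ on all random-effect SDs, and
$\mathrm{Gamma}(0.01, 0.01)$ on $\alpha$. The shape prior is the
convention of the Bayesian regression software family this model design
follows; it is configurable through `yawn_model(shape_prior = )`.
Scaling $C$ to unit height puts $\sigma_{\mathrm{phylo}}$ and
$\sigma_{\mathrm{species}}$ on the same (log-link) scale, which is what
makes a common Exponential(3) prior sensible for both.

Posterior sampling uses JAGS with a non-centered parameterization of
the phylogenetic intercepts ($b = \sigma_{\mathrm{phylo}} L z$, $L$ the
Cholesky factor of $C$), which mixes far better than the centered form
when the phylogenetic signal is modest.

## Data preparation rules

`aggregate_species()` encodes the filtering rules of the analysis:

* A species is retained only with at least two yawns from at least two
  distinct individuals; everything dropped is recorded in a drop log,
  never silently.
* An explicit exclusion list handles species whose brain measures or
  tree placement are unreliable (heavily domesticated taxa are the
  usual case).
* Brain mass prefers a direct measurement; endocranial volume is
  otherwise converted by mass (g) = 1.036 x ECV (ml).
* Species trait values are averages (inter-sex means where sexes were
  reported separately, in the upstream tables).
* Neuronal density is total neurons per gram of brain, formed *before*
  the log transform.
* All masses and counts are natural-log transformed, then z-scored
  within clade. Only relative quantities are reported downstream, so
  the log base is internal, but it is fixed and documented as natural.

Whether the species mean duration averages over yawns or over
individual means is genuinely ambiguous when individuals contribute
unequal yawn counts; the default averages over yawns (every observed
yawn is one draw from the species distribution), with
`mean_over = "individuals"` as the alternative.

## Body size: the collinearity gate

Absolute brain measures are the primary predictors: the hypothesis
concerns absolute thermolytic load, so the headline models deliberately
omit body mass. Body-size-adjusted models are fitted alongside to rule
out pure allometric explanations, and their form is gated on
collinearity. With VIF $= 1/(1-R^2)$ computed on the (ordinary,
non-phylogenetic) standardized design:

* VIF > 3: the measure is residualized against log body mass by PGLS
  and the re-standardized residuals become the sole predictor;
* VIF < 3: body mass simply enters as a second covariate.

The PGLS residualization estimates Pagel's lambda by profile maximum
likelihood rather than assuming pure Brownian structure (lambda = 1);
this is the more robust choice when signal is imperfect, and a fixed
lambda can be requested via `pgls_fit(lambda = 1)`. VIFs are computed
non-phylogenetically because the gate is a property of the design
matrix handed to the sampler, not of the evolutionary model; this also
keeps the gate a closed-form function of the observed correlation.

## Random slopes, WAIC, and summaries

Whether the brain-measure slope varies across taxonomic orders is
decided by WAIC on the pointwise posterior log-likelihood. The slopes
model is adopted only when it improves WAIC by at least 2 — the
conventional minimal-evidence threshold — with the paired per-species
SE reported alongside. Self-comparison gives exactly zero. Two
caveats: with one observation per species the pointwise WAIC penalty
is large and its Monte-Carlo noise spans a few units, so decisions
near the threshold are soft; and when the phylogenetic signal of the
residuals is genuinely below 1, order-slope terms can absorb residual
order-level structure the unit-height phylogenetic intercept cannot,
inflating the apparent support for slopes — a model-mismatch effect
rather than evidence of real slope variation.

Posteriors are summarized by the median, the median absolute deviation
(MAD), equal-tailed 90% credible intervals, and $p_+$, the posterior
probability of a positive value (strict inequality; exactly-zero draws
count as not positive). Equal-tailed intervals are used rather than
HPD: the summaries bracket the median symmetrically in probability.
Cohen's *d* for a slope is computed per draw as
$\beta / \sqrt{\sigma_{\mathrm{phylo}}^2 + \sigma_{\mathrm{species}}^2}$
— standardization by the total species-level SD on the link scale —
and then summarized. This is one reasonable standardization among
several; it is flagged as an interpretation, and the raw draws are
always available.

## Cross-clade comparison

Clades are fitted separately (separate trees, separate standardization)
and compared by differencing their posterior draws: the two draw
sequences are independently thinned to a common length and paired
index-wise, requiring at least 1000 pairs. Because the clades also
differ in average size, a constrained joint model re-fits both clades
together with slopes constrained to equivalence, clade-specific
intercepts, random-effect SDs and shapes, and a block-diagonal
phylogenetic correlation. Predictors are standardized on the *pooled*
scale there, so "the same brain size" is well defined across clades;
per-clade standardization is retained for the separate models.
Expected durations marginalize over the Gaussian random intercepts in
closed form, $\mathrm{E}[y] = \exp(\eta + \sigma^2_{\mathrm{tot}}/2)$
(the lognormal mean), which a Monte-Carlo marginalization test verifies
to within 1%.

## Power analysis

`power_analysis()` simulates datasets from a template fit's
posterior-median nuisance parameters with the slope forced to a chosen
value, refits each, and counts replicates whose 90% CI excludes zero.
The CI-exclusion rule (rather than a $p_+$ threshold) was chosen
because at a null effect it has a known calibration target — the
nominal 10% false-positive rate of a 90% interval — which the
acceptance suite verifies on a design with an unstructured predictor.
That qualification matters: when the predictor is itself strongly
phylogenetically structured (as a Brownian-evolved brain measure on a
deep tree is), the data contain few effectively independent contrasts,
plug-in uncertainty in the variance components bites, and the null
rejection rate can run well above nominal (we observe roughly 0.24 at
50 species under the full study conditions). Power estimates from such
designs are therefore best read comparatively, not as calibrated
error rates. Replicates failing the per-replicate convergence gate are
re-run with a fresh seed up to three times, then counted as missing
and reported.

## The simulator and what passing tests mean

`simulate_dataset()` generates data with exactly the structure the
estimator assumes: a unit-height Yule tree; (log body, log brain)
evolving as correlated Brownian motion; neuron counts as a log-linear
allometric map with Gaussian noise; taxonomic orders carved from the
tree at the depth where the lineage count reaches the requested number;
and per-individual yawn durations that are Gamma around a species mean
whose log is linear in the standardized brain measure plus a
phylogenetically correlated intercept (lambda-transformed correlation)
and an i.i.d. species intercept.

The clade presets are the package's study conditions: a mammal-like
clade (55 species, intercept log 3.4 s, slope 0.35 per SD of log brain
mass, lambda 0.80, log brain-body evolutionary correlation 0.95, ~8
individuals per species) and a bird-like clade (46 species, intercept
log 1.46 s, slope 0.20, lambda 0.64, correlation 0.87, ~6 individuals
per species). Random-effect SDs (0.2 phylogenetic, 0.1 species), Gamma
shape 20 and two yawns per individual complete the defaults; they were
fixed once, before any test outcome was inspected, as values a
comparative analysis of this design would find realistic. A Yule tree
(no extinction) is used because the model is insensitive to extinction
history; there is no fossil calibration, no non-ultrametric simulation,
and no measurement-error model for brain masses. Individual-level
Gamma dispersion is a simulator convenience — the estimator models
species means — so the simulator's per-yawn shape and the fitted shape
are related but not identical quantities.

Parameter-recovery suites simulate with lambda fixed at 1 so that the
simulated phylogenetic intercepts have exactly the covariance the
estimator assumes; the lambda-transform path is exercised separately by
the ML lambda recovery tests. Passing these suites shows the estimator
is a faithful inverse of this generative process. It does *not* show
robustness to features real comparative data have and the generator
does not: unbalanced sampling across the tree, non-ultrametric trees,
measurement error in brain masses, or model misspecification of the
duration distribution.

## Numerical choices

* Lambda is searched on [0, 1] only (values above 1 can break positive
  definiteness), by `optimize()` with tolerance 1e-6, explicitly
  comparing both boundaries against the interior optimum.
* All GLS solves go through a Cholesky factorization of the working
  covariance; if factorization fails numerically, a diagonal jitter of
  1e-10 is added once and the event is messaged.
* Star phylogenies (a single root polytomy) are accepted as rooted;
  genuinely unrooted trees are rejected.
* Convergence is gated on rank-normalized split R-hat < 1.01 and bulk
  ESS > 400 over all reported parameters, as an error by default. With
  one species-mean observation per species, the i.i.d. intercept SD and
  the Gamma shape are only weakly separated — the regularizing priors
  are what identifies them — and those two parameters mix the slowest;
  default runs of 4 chains x 2000 iterations will sometimes need to be
  lengthened to clear the gate. Simulation suites (recovery, WAIC
  selection, power) use deliberately short chains — 2 chains x 1200 to
  1500 iterations, half warmup, at 20 to 50 species — with the gate
  relaxed via `check_convergence` and the per-replicate thresholds;
  those sizes were chosen to make the suites' Monte-Carlo error small
  relative to the margins they assert, while keeping a full run on a
  single CPU short.
* All chain seeds derive deterministically from one master seed; fits
  are bit-reproducible given `(seed, chains, iterations)` on a fixed
  platform.

## Known limitations

* The Gamma shape posterior is heavy-tailed and slow-mixing in this
  design; slope inference is robust to this, but shape estimates
  should not be over-interpreted.
* Fits with fewer than 15 species trigger a warning: interval estimates
  at such sizes are wide, and the power analysis shows small effects
  (slopes near 0.1) are essentially undetectable there.
* The cross-clade contrast pairs draws from independent posteriors;
  this matches the definition of a difference between posterior
  distributions but ignores any shared structure a joint model would
  capture — which is exactly what the constrained joint model is for.
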