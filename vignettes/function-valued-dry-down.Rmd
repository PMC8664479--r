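---
title: "Modeling trait responses to a continuous soil-moisture gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling trait responses to a continuous soil-moisture gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fvtdry` treats a plant trait not as a scalar but as a *function of soil
moisture* — a reaction norm. From a dry-down experiment in which pots are
watered at a handful of fixed daily rates and allowed to dry for two weeks,
each plant ends at its own point on a continuous gradient of final gravimetric
soil moisture, and the package estimates per-genotype response curves, then
asks what the curvature of those curves implies for genetic correlations,
plasticity, and evolutionary constraint along the gradient.

This vignette is the package's account of the statistical machinery: the
models, the defaults and why they were chosen, the numerical edge cases, and
what the synthetic-data validation does and does not demonstrate.

## The reaction-norm model and its selection

For one trait in one species the full fixed-effects model is

$$ y = H + G + E + E^2 + s(E)_{df=2} + G{\times}E + G{\times}E^2 + G{\times}s(E) + \varepsilon $$

where $H$ is harvest cohort (a categorical nuisance covariate: cohorts differ
in age by up to several days), $G$ is genotype (a fixed effect — with five
genotypes per species a random-effects formulation has too little replication
to estimate variance components stably), $E$ is final gravimetric soil
moisture on the raw percent scale, and $s(E)$ is a natural cubic spline with
two degrees of freedom. Quadratic and spline terms are deliberately offered
*side by side*: a quadratic imposes symmetric curvature everywhere, a natural
spline can place curvature asymmetrically and extrapolates linearly, and
which shape a trait needs is exactly what is not known in advance.

Because the response shapes are unknown, the model for each trait × species
is chosen by bidirectional stepwise AIC starting from the full model:

* every single-term deletion and addition (scope limited to the eight terms
  above) that respects marginality is refitted from scratch;
* the move with the lowest AIC is applied if it improves strictly on the
  current model; otherwise the search stops;
* marginality means each interaction requires `G` and its own environmental
  term — but `E`, `E2` and `S` are independent main effects (`E2` does not
  require `E`; this matches the formula-term semantics above, where they are
  separate predictors).

AIC is the least-squares form $n\log(\mathrm{RSS}/n) + 2\,\mathrm{rank}$,
dropping the constant that is common to all candidates on the same data.
Using the *rank* rather than the column count as the penalty matters here,
because the full model is intentionally rank-deficient:

* a natural spline with two degrees of freedom, together with the intercept,
  spans all linear functions — so the plain `E` column is exactly collinear
  with `{1, S}`, and `G:E` is likewise aliased when `G:S` is present;
* the fitter (a rank-revealing pivoted QR) flags aliased columns, gives them
  zero coefficients (so prediction is well defined), and reports the rank.

Two further rules make the search deterministic:

* **Ties.** AIC differences are compared with a tolerance of `1e-7`:
  deleting an exactly aliased column reproduces the same AIC only up to
  floating-point noise, and without the tolerance such comparisons would be
  decided by rounding. Ties among candidate moves are broken in favour of
  deletions over additions, then by the fixed term order
  `H, G, E, E2, S, G:E, G:E2, G:S`. A tied move is never applied — the
  criterion must improve strictly. One visible consequence: an aliased `E`
  that rides along with `S` in the full model is never deleted (deletion
  would not change the criterion), it simply carries a zero coefficient.
* **Perfect fits.** When RSS is zero to relative tolerance
  (`1e-13 * sum(y^2)`), AIC is $-\infty$ and candidates are compared by
  rank, so on noise-free data the search descends to the smallest exactly
  fitting term set. This is what makes noise-free recovery tests exact.

Categorical terms use treatment contrasts against the lexicographically
first level; predictions are invariant to that choice. Spline knots are
frozen at fit time — boundary knots at the observed moisture min/max of the
rows entering the fit, one interior knot at their median — and stored in the
fitted model, so later evaluation on the prediction grid uses the training
knots (below the boundary knot the natural spline continues linearly;
quadratic terms extrapolate as fitted).

Both species are always analysed separately, so neither forces its model
shape on the other.

### A known property: stepwise AIC is liberal

AIC-based stepwise selection does not control a false-positive rate. A
spurious term carrying $k$ degrees of freedom survives backward elimination
with probability roughly $P(\chi^2_k > 2k)$ — about 16% for one degree of
freedom — and the full model offers *six* environmental candidates, so on
data with genuinely no environmental effect, the probability that at least
one environmental term survives is large (on the order of one half; the test
suite measures this, and the same behaviour is reproduced by the reference
`MASS::stepAIC` implementation on identical data). The procedure is used
here for what it is good at — choosing a parsimonious *shape* for responses
that do exist — and selected terms should not be read as significance
statements. Power, by contrast, is excellent: with genotype-specific
curvature twice the residual scale, nonlinear and interaction terms are
recovered essentially always (also measured in the suite).

## From fitted curves to gradient-indexed genetics

**Genotype means.** Each selected model is evaluated for every training
genotype at 20 evenly spaced moisture levels from 30% to 100%. The cohort
term is marginalised by averaging predictions over all cohort levels with
equal weight — the data assign cohorts in balanced fashion, the choice is
invariant to the contrast reference level, and it avoids privileging an
arbitrary cohort. (How the original analyses handled the cohort covariate in
prediction is not stated; averaging is the neutral option.)

**Correlation curves.** At each level, the Pearson correlation between two
traits' genotype means is taken across genotypes, per species. Traits whose
selected model has no genotype term are excluded — their genotype "means"
coincide, so a correlation would be 0/0 — and a trait with zero variance
across genotypes at a particular level yields `NA` there, never a fabricated
zero. With no genotype × environment terms anywhere, genotype offsets are
parallel and the curves are exactly flat; curvature in correlation curves is
therefore a direct readout of GxE.

**Multivariate plasticity.** Per species, the genotype × level matrix of
predicted means is z-scored per trait over all pooled rows (divisor $n-1$).
Pooling within species (rather than per level) is what keeps consecutive
levels comparable, which the distance requires; the two species are scaled
separately like every other analysis. Total plasticity of genotype $g$ over
interval $i$ is the Euclidean distance between consecutive scaled
phenotypes,

$$ \Delta T_{g,i} = \sqrt{\textstyle\sum_j (p_{g,i,j} - p_{g,i+1,j})^2 }, $$

giving 19 interval values per genotype on a 20-level grid. Traits without a
genotype term still vary along the gradient and are included by default (the
`traits` argument can restrict them). Species are compared per interval with
Welch's unequal-variance *t*-test at α = 0.05 and no multiplicity
correction — five genotypes per species give the test little power, so the
flags are descriptive. A PCA of the same scaled matrix (sample-covariance
convention; component signs fixed by making each component's
largest-magnitude loading positive) summarises where in trait space the
movement happens.

**Evolutionary constraints.** At each level, per species, the G matrix is
approximated as the covariance (divisor $n-1$) of *mean-standardised*
genotype means: each trait's means are divided by their mean across
genotypes at that level, making variances comparable across units. Division
by a *signed* mean follows the standard definition; for a negative-mean
trait (δ13C) this flips the sign of its standardised deviations and hence of
its covariances — an `abs_mean` option divides by the absolute mean instead,
and the standardisation mean can alternatively be taken across all levels
(`center = "grand"`). Traits whose mean is within `1e-6 · sd` of zero are
dropped with a warning rather than divided by. From the eigenvalues
$\lambda_1 \ge \dots \ge \lambda_n$ (negative values within $10^{-10}
\lambda_1$ clamped to zero):

* $n_D = \sum_i \lambda_i / \lambda_1$ — effective dimensions, from 1 (all
  variation on one axis, high constraint) to $n$ (no covariance);
* $e_{max} = \sqrt{\lambda_1}$ — maximum evolvability, the genetic standard
  deviation along the leading axis;
* $v_T = \sum_i \lambda_i = \mathrm{trace}(G)$ — total genetic variance.

With five genotypes G has rank at most four, so $n_D$ is bounded well below
the trait count regardless of biology; trends along the gradient, not
absolute values, are the interpretable output.

## What the synthetic generator emulates — and what it does not

The generator exists so the whole pipeline can be exercised with a known
truth. It reproduces the *statistical structure* the analysis assumes:

* **A continuous, dry-skewed moisture gradient.** Pots start at field
  capacity and follow a daily water balance with two-stage evaporation:
  energy-limited constant loss (`evaporation_rate`, default 0.085 of
  capacity per day) above a critical moisture fraction (0.5), supply-limited
  linear decline below it, stopping at a residual fraction (0.25). Inputs
  beyond field capacity drain away. These defaults were set once so that
  unwatered pots approach ~30% moisture after 14 days while the highest
  watering rate stays near capacity, and so that the lower watering
  treatments collapse toward the dry end — giving the characteristic excess
  of plants near the driest extreme. Day-to-day loss noise (cv 0.1), per-pot
  capacity variation (cv 0.05) and additive measurement noise on the final
  reading (sd 2 percentage points) turn six discrete treatments into a
  continuum.
* **Genotype-specific nonlinear reaction norms** with optional GxE: each
  trait × genotype has a constant, linear, quadratic or hinge-based
  "spline-like" truth; genotype perturbations of slope or curvature
  coefficients create genuine GxE where the species templates say so.
  Template values (e.g. RWC near 0.96 when wet falling toward 0.82 when
  dry; SLA responding strongly to drying in the annual species and weakly
  in the perennial) were chosen once for physiological plausibility.
* **Design artefacts**: additive harvest-cohort offsets, and the
  destructive two-way harvest split (half the plants carry the biomass and
  composition traits, the other half SLA and RWC), applied by deterministic
  alternation within genotype × treatment so the split never confounds the
  gradient. Composite traits (biomass, root:shoot, C:N) are derived from
  their simulated components, preserving the harvest arithmetic.

It does **not** emulate: real soil heterogeneity or the physics of
evapotranspiration (the two-stage model is a caricature with the right
shape), phenology or germination, image-based green-area extraction
(green area is generated directly as a trait), non-Gaussian or
heteroscedastic residuals, or correlated residuals across traits within a
plant. Passing recovery tests therefore demonstrates that the *estimation
machinery* is correct under the model's own assumptions — not that those
assumptions hold for any particular greenhouse dataset.

All randomness flows from a single seed: the generator derives sub-seeds for
the genotype draws, the moisture dynamics and the residual noise, so the
same seed reproduces a byte-identical experiment and pipeline runs are
byte-reproducible end to end (the output manifest records MD5 checksums).

## Numerical choices, in one place

| choice | value | where |
|---|---|---|
| AIC tie tolerance | `1e-7` | stepwise comparisons |
| zero-RSS (perfect fit) threshold | `1e-13 · sum(y²)` | `fit_least_squares()` |
| rank detection | `lm.fit` pivoted QR, default tolerance | `fit_least_squares()` |
| eigenvalue clamp | `1e-10 · λ₁` | `constraint_stats()` |
| unstable mean-standardisation | `abs(mean) ≤ 1e-6 · sd` drops the trait | `g_matrix()` |
| sd divisor | `n − 1` everywhere | scaling, covariance, PCA |
| PCA sign convention | largest-magnitude loading positive | `trait_space_pca()` |
| stepwise step cap | 50 accepted moves | `stepwise_select()` |
| minimum data | warn below 20 rows per trait fit; ≥ 3 distinct moisture values for knots; ≥ 2 genotypes for `G` | fitting |

Degenerate inputs are flagged, not silently patched: zero genotype variance
gives `NA` correlations, a constant trait stops `scale_traits()` by name
(the pipeline drops it with a warning instead), untestable plasticity
intervals carry `NA`, and a failed constraint level is flagged `ok = FALSE`
while the run continues.

## Validation strategy and problem sizes

The test suite checks every stage against an independent oracle: the spline
term against a truncated-power-basis construction of the same space, least
squares against an SVD pseudo-inverse, AIC differences against
`extractAIC`, the stepwise search against `MASS::stepAIC` on a spline-free
scope, ΔT against per-coordinate loops, Welch tests against the closed form,
eigenvalues against characteristic-polynomial roots, and the full pipeline
against noise-free truths where recovery must be exact to `1e-6` or better.
Simulation-based checks use 100 replicates at 600 plants and 5 genotypes —
the scale of the motivating experiment — and complete in well under a
minute; the gravimetric-formula correction (the printed convention divides
the *total* pot mass by the water capacity and can exceed 100%; the package
defaults to the corrected water-mass numerator and exposes the printed form
behind `as_printed`) is verified by construction.

Two honest gaps remain. First, the liberality of stepwise AIC described
above means false selection of *some* environmental term under a null truth
happens in roughly half the replicates — a property of the procedure, shared
by its reference implementation, and not removable without changing the
method. Second, reproducing the published accession-level numbers requires
the deposited greenhouse dataset, which is not redistributable with the
package; the corresponding check runs only when a local copy is supplied
(option `fvtdry.accession_csv`).
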