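---
title: "Estimating BMI category prevalence trends: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating BMI category prevalence trends: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

National prevalence trends of body-mass-index (BMI) categories must be
estimated from a heterogeneous collection of population surveys: studies
differ in coverage (national, subnational, community), in urban/rural scope,
in the years and age groups they observed, and in sample size; many countries
have few or no studies in some periods. `bmitrend` implements a Bayesian
hierarchical meta-regression that pools this evidence across age, time and a
geographic hierarchy (countries in regions in super-regions in the globe),
together with the post-processing, trajectory clustering and hold-out
validation that turn posterior draws into reportable results.

## The model

An observation is a count $y_{h,i}$ of people in a BMI category out of
$n_{h,i}$ examined in age group $h$ of study $i$ (country $j$, year $t$):

$$y_{h,i} \mid n_{h,i}, p_{h,i} \sim \mathrm{Bin}(n_{h,i}, p_{h,i}),
\qquad \alpha_{h,i} = \Phi^{-1}(p_{h,i}),$$

$$\alpha_{h,i} \sim N\!\big(a_j + b_j t + u_{j,t} + \gamma_i(z_h) +
X_i\beta + e_i,\; \tau^2\big).$$

* **Linear trends.** $a_j$ and $b_j$ are sums of country, region,
  super-region and global components; each non-global component is a
  zero-mean Gaussian with its own variance $\kappa$, so estimates shrink
  toward the parent level where data are weak. The global intercept and slope
  carry flat priors.
* **Nonlinear change.** $u_{j,t}$ is likewise a sum over the four levels.
  Each level's vectors follow a second-order random-walk (RW2) prior with
  precision $\lambda_\ell P$, where $P = D_2^\top D_2$ penalizes second
  differences. $P$ has rank $T-2$: the mean and slope of each $u$ vector are
  unpenalized, and are constrained to zero for identifiability against $a_j$
  and $b_j$. The precisions are ordered a priori,
  $\lambda_c < \lambda_r < \lambda_s < \lambda_g$: a country's trend may bend
  more than its region's, which bends more than the super-region's and the
  globe's. Each $\log\lambda$ is truncated at 20.
* **Age model.** $\gamma_i(z)$ is a cubic spline in the age-group mid-age,
  using the truncated power basis $(z_c, z_c^2, z_c^3, (z-k_1)_+^3,
  (z-k_2)_+^3)$ with knots at 45 and 60 years for adults and 10 and 15 for
  children and adolescents; age is centred (50 / 12 years) to reduce
  coefficient dependence. Each of the five coefficients has hierarchical
  country/region/super-region components; for adults the coefficients also
  carry hierarchical time slopes (age-by-time interaction), which the child
  model omits structurally.
* **Study-level terms.** $X_i\beta$ holds eight time-varying offsets for
  subnational and community coverage and for urban-only / rural-only scope,
  the latter weighted by the country's urbanization share so that, e.g., an
  urban-only study in a fully urban country carries no offset. $e_i$ is a
  study random effect whose variance depends on coverage, ordered
  $v_n < v_s < v_c$: national studies are more trusted. $\tau^2$ absorbs
  residual age-by-study variability.
* **Hyperpriors.** All variance-type parameters have flat priors on the
  standard-deviation scale.

### Prior truncations

Flat-on-SD priors interact badly with reduced data density: when an age grid
has fewer distinct mid-ages than spline basis functions, or when every study
contributes a single year, some random-effect directions are unidentified and
a flat prior on their variance is improper — the joint posterior then has a
degenerate ridge along which the variance and its effects inflate together.
The same device the model already uses for $\lambda$ (hard truncation as a
computational convenience) is therefore applied everywhere, at generous,
epidemiologically motivated bounds on the probit scale: intercept-component
SDs at most 2, slope-component SDs at most 0.1/year, age-term contributions
at most 1 RMS (0.5 for the age-time interaction), study-effect and residual
SDs at most 0.5, a residual SD of at least 0.01 (surveys never agree better
than that), and an RW2 second-difference SD of at most 0.03 per year² (the
model's own premise is that national trends are smooth). Posterior mass in
test runs sits far from every bound except where the data genuinely carry no
information.

## Sampling

The model is fitted by a bespoke Metropolis-within-Gibbs sampler. One sweep
updates, in fixed order: $\alpha$ (adaptive random-walk Metropolis against
the binomial likelihood — the only non-Gaussian conditional), $e$, $\beta$,
the linear components, the RW2 components level by level, the spline
coefficients, and the conjugate variances. A separate Metropolis step handles
the ordered and truncated variance parameters.

Three implementation choices matter:

* **Constrained RW2 draws on the penalty's eigensubspace.** The zero-mean,
  zero-slope constraint set is exactly the span of $P$'s non-null
  eigenvectors, so each $u$ vector is drawn in those coordinates. This is
  algebraically identical to drawing unconstrained and applying the
  conditioning-by-kriging correction for the two constraints, and it covers
  the edge cases uniformly: a unit observed in a single year gets a proper
  draw with the unidentified direction carried by the prior, and a unit with
  no data gets a constrained prior draw.
* **Partially collapsed variance updates.** Variance parameters and their
  random effects form funnels: a one-at-a-time Gibbs update of $v$ given $e$
  (or $\lambda$ given $u$) cannot move between the smooth and the wiggly
  explanation of the same between-study signal, and at reduced data density
  the country-level blocks ($a^c_j$, $b^c_j$, $u^c_j$, spline components,
  $e_i$) can jointly interpolate the data, collapsing $\tau^2$. All
  country-level hyperparameters ($\lambda_c$, the $v$'s, $\kappa_{a,c}$,
  $\kappa_{b,c}$, the country-level spline variances, and $\tau^2$) are
  therefore updated by Metropolis steps against the per-country marginal
  likelihood with *all* country-level random effects integrated out
  analytically (small per-country Gaussian covariances), after which those
  effects are redrawn in conditional sequence — a valid partially collapsed
  Gibbs scheme. The region/super-region/global RW2 precisions are collapsed
  over their own $u$ vectors the same way.
* **Adaptation.** Metropolis proposal scales adapt toward 0.44 acceptance
  during burn-in only and are frozen afterwards, preserving the stationary
  distribution. Variances are held at their starting values for the first
  quarter of burn-in so the mean structure locks onto the data before the
  variance allocation begins.

Starting values come from a pilot phase: short dispersed chains are run, a
multivariate Gaussian is fitted to the pooled posterior of the non-study-
specific parameters with its covariance inflated by 1.5 (about 50%
overdispersion), final-chain starts are sampled from it (resampling until the
ordering constraints hold), and study effects and $\alpha$ are generated
conditionally. Convergence is monitored by split-Rhat on country-year-age
prevalences; the pipeline's gate requires more than 99% of outcomes below
1.05.

## Post-processing

Country-year-age prevalence is $\Phi$ of the composed $a$, $b$, $u$ and
spline terms with $\beta = 0$ and $e = 0$ (study-design terms are not part of
country-level truth). Because categories are fitted independently, per-cell
category prevalences are rescaled to sum to one; adult obesity is the sum of
the three rescaled bands at or above 30 kg/m², child obesity the band above
+2 z-scores. Age standardization takes fixed-weight means over age groups
(a conventional world-standard age table is bundled; the table is an explicit
input because the appropriate revision depends on the application). Velocity
is the signed year-on-year change of age-standardized prevalence in
percentage points, labelled by terminal year, so velocities telescope to the
endpoint difference. Posterior probabilities count draws strictly greater
than zero; intervals are 2.5–97.5 percentile intervals with type-7
interpolation, fixed for implementation stability.

## Synthetic worlds

The generator draws one full parameter set from the model's own generative
structure and simulates studies with coverage/urban labels, design offsets,
study effects, residual noise and binomial sampling. Its defaults are the
package's reduced-scale study conditions: 12 countries in 4 regions in 2
super-regions, 25 years, 3 age groups, 3 studies per country, ~800
participants per age-group row, probit-scale variance components typical of
national obesity series (country intercept SD ≈ 0.22, slopes ≈ 0.01–0.02 per
year, smooth nonlinear excursions of order 0.1, national study effects
≈ 0.03, residual SD 0.05). Each study draws from its own seed substream, so
enlarging a world does not perturb existing studies. What the generator does
*not* emulate: real missingness mechanisms beyond the design labels,
reporting heterogeneity (partial category sets, mean-BMI-only studies), and
measurement error — so passing recovery tests demonstrate correctness of the
inference machinery under the model's own assumptions, not robustness to
misspecification.

## Validation harness

Two hold-out designs mirror external predictive validation: test 1 withholds
all data of a fraction of countries (sampled within data-richness strata);
test 2 withholds, per sampled country, a random third of its studies or all
studies in a recent window. Held-out *observations* carry study effects,
residual noise and binomial noise on top of the country-year-age prevalence,
so they are compared against posterior predictive intervals for a new study
observation; intervals for the latent prevalence alone would be too narrow by
construction. At the package's reduced scale we withhold a third of the
countries' sources rather than a tenth: with 12 countries a tenth yields a
single withheld study, and a coverage proportion over a handful of rows is
uninformative.

## Clustering

Country trajectories (posterior-mean age-standardized prevalence) are
normalized per country (population SD, divisor $n$, fixed for
reproducibility), annually demeaned across countries, reduced to the first
three principal components (covariance PCA — rows are already variance one;
component signs fixed by making the largest-magnitude loading positive), and
clustered by Euclidean k-means with 50 random starts, keeping the allocation
with minimum inertia. k defaults to 6; inertia-elbow and silhouette sweeps
over k = 3..20 are available. Stability is quantified by the mean Jaccard
index between each reference cluster and its most similar counterpart across
1,000 subsample reclusterings (simple random subsampling without replacement,
proportions 0.5–0.9; ties broken by larger intersection, then lower cluster
id). Typology labels ("accelerating increase", "plateau", ...) are assigned
by a documented heuristic on cluster-mean trajectories — they are
annotations, never inputs.

## Problem sizes used by the test suite

The packaged tests exercise everything end to end at sizes chosen so the full
suite runs on a single CPU in well under half an hour: the recovery check
fits 4 chains of 5,000 iterations (half burn-in) to the default reduced-scale
world and requires ≥85% coverage of true country-year prevalences with median
error within ±0.5 percentage points; the conjugate reduction runs 20,000
sweeps against a closed-form Gaussian posterior; simulation-based calibration
runs 150 replicates of a two-block reduction; the validation harness runs
five hold-out replicates with 2 chains of 2,000 iterations each. Full-scale
analyses (200 countries, 45 years, 15 age groups) use the same code paths
with larger configuration values.

## Known limitations

* With three age groups the spline's country-level age pattern is partly
  unidentified; predictions at the observed mid-ages are unaffected, but
  extrapolating the age curve to unobserved ages at reduced scale is not
  meaningful.
* The alpha update is a random-walk Metropolis step, not an exact conditional
  draw; its adaptive scales target 0.44 acceptance and calibration is
  verified by simulation-based calibration rather than by construction.
* The per-study effective-sample-size bridge (n_eff = p(1-p)/var from the
  design-based variance, y = p·n_eff rounded half up) is a documented
  convention: the binomial denominator that reproduces the design-based
  variance of the weighted prevalence.
* Studies reporting only mean BMI or partial category sets are out of scope;
  such records must be converted upstream.
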