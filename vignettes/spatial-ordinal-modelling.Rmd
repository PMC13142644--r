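---
title: "Spatial ordinal modelling of household survey data with spatord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial ordinal modelling of household survey data with spatord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Household surveys such as the DHS and MICS record service conditions —
drinking-water source, sanitation facility, handwashing facility — as ordered
categories, observed at georeferenced cluster locations under a multi-stage
design in which roughly 25–30 households are interviewed per cluster.
`spatord` fits the hierarchical cumulative-logit model that treats these
categories as ordered bins of a latent continuous variable. For household $i$
in cluster $c(i)$ at location $s_{c(i)}$,

$$z_i = x_i^\top \beta + u(s_{c(i)}) + b_{c(i)}, \qquad
  P(y_i \le k) = \mathrm{logit}^{-1}(\theta_k - z_i),$$

with monotone thresholds $\theta_1 < \dots < \theta_{K-1}$ (up to $K = 5$
categories; category 0 is the least-improved reference level),
i.i.d. cluster effects $b_c \sim N(0, \sigma_b^2)$ capturing design-induced
within-cluster correlation, and a Matérn Gaussian random field $u(s)$
capturing residual spatial structure. There is **no fixed intercept**:
location on the latent scale is absorbed by the thresholds, the standard
cumulative-logit identifiability convention, and the package's tests verify
that a constant shift of a covariate moves $\hat\theta$, never $\hat\beta$.

### The spatial field

The field is represented by the SPDE approach: $u$ solves
$(\kappa^2 - \Delta)^{\alpha/2} u = \tau^{-1} \mathcal{W}$ on a triangulated
mesh built from the cluster coordinates. We fix $\alpha = 2$, the standard
default, which gives Matérn smoothness $\nu = 1$ in two dimensions and a
sparse three-term precision for the mesh-node weights $w$:

$$Q = \tau^2 (\kappa^4 C + 2\kappa^2 G + G C^{-1} G),$$

with $C$ the mass-lumped (diagonal) finite-element mass matrix and $G$ the
P1 stiffness matrix. Mass lumping keeps $G C^{-1} G$ sparse. The practical
range — the distance at which correlation drops to
$\sqrt{8}K_1(\sqrt 8) \approx 0.14$ — is $\sqrt{8}/\kappa$, and
$\tau = 1/(\sqrt{4\pi}\,\kappa\,\sigma_u)$ is chosen so the field's marginal
SD is exactly $\sigma_u$; $\sigma_u$ and the range are estimated on the log
scale. Coordinates are treated as planar (degrees as Euclidean distance),
adequate at sub-continental extents; no map projection is applied, which is
a caveat for domains spanning many degrees of latitude.

The default mesh Delaunay-triangulates the cluster coordinates plus a ring
of boundary nodes extending the convex hull by 25% of the domain diameter
(mitigating the inflated boundary variance typical of SPDE models), plus a
filler lattice so no triangle edge greatly exceeds a tenth of the domain
diameter. All households of a cluster share the cluster coordinate, so the
field enters at cluster level through a sparse barycentric projection matrix.

### Estimation

Parameters are estimated by maximising the Laplace-approximated marginal
likelihood. The joint negative log-likelihood is the sum of the ordinal data
term and the Gaussian penalties for $b$ and $w$. For fixed outer parameters
the joint NLL is convex in $(b, w)$ (the cumulative-logit NLL is convex in
$z$, which is linear in the random effects), so the inner Newton solver —
with cluster-level aggregation, sparse Cholesky factorisation of the
$(b, w)$ Hessian and step halving — converges to the unique conditional
mode. The marginal NLL is then
$\mathrm{JNLL}(\hat v) + \tfrac12 \log\det H - \tfrac{n_{re}}{2}\log 2\pi$.
The outer optimiser is box-constrained quasi-Newton (L-BFGS-B) on
$(\beta, \theta_1, \log \Delta\theta, \log\sigma_b, \log\mathrm{range},
\log\sigma_u)$; threshold monotonicity is guaranteed by the log-increment
parameterisation. Outer gradients use finite differences — with at most a
dozen outer parameters this is adequate and dependency-free; forward
differences serve the line searches and central differences the final
gradient and the covariance Hessian. The reported parameter covariance is
the inverse finite-difference Hessian of the marginal NLL; if it is not
positive definite (typically when $\sigma_u$ or the range collapses toward a
boundary in a weakly informative realisation) the package warns and uses an
eigenvalue-clipped pseudo-inverse.

Numerical safeguards, all documented in the code: the ordinal NLL is
computed as a log-difference of sigmoids (stable to $|\theta - z| \approx
35$ and switching to the exact asymptotic slope $\pm 1$ beyond); per-term
second derivatives are floored at $10^{-10}$ to keep the inner Hessian
positive definite in flat regions; the inner tolerance ($10^{-9}$ sup-norm
gradient, relaxed gradually to $10^{-6}$ only when an ill-conditioned inner
problem creeps instead of converging quadratically) is orders tighter than
the outer one so the Laplace objective is smooth to finite-difference
accuracy; inner Newton steps are clamped in norm and Levenberg-damped when
an undamped direction fails to descend numerically; a box of $\pm 6$ on the log
hyperparameters and $\pm 20$ elsewhere keeps trial steps out of regions
where the inner problem is numerically singular, and hopeless probe points
(thresholds beyond $\pm 40$ on a standardized-covariate scale) are rejected
with a smooth penalty before any inner iteration.

### Prediction surfaces and uncertainty

`predict_grid()` evaluates the fitted model on a regular lon/lat grid
(0.05° is the conventional production resolution; the examples here use
coarser grids): $z^* = x^{*\top}\hat\beta + a^{*\top}\hat w$ per cell, the
cluster effect set to its mean 0 — clusters are survey-design artifacts, not
map features. Class probabilities follow the cumulative-logit formula, and
the delta method on the linear predictor gives
$\mathrm{SE}(p_k) = |\partial p_k/\partial z| \cdot \mathrm{sd}(z^*)$ with

$$\mathrm{Var}(z^*) = x^{*\top}\widehat{\mathrm{Cov}}(\hat\beta)\,x^* +
  a^{*\top}\mathrm{Cov}(w \mid y)\,a^*.$$

Both components can be toggled. Two approximations are deliberate: the
$\beta$–$w$ cross-covariance is omitted, and threshold uncertainty is not
propagated (thresholds are held at their estimates). The acceptance suite
bounds the combined effect by comparing the delta-method SE with a
parametric Monte-Carlo SE (500 joint draws of $\beta$ from
$N(\hat\beta, \widehat{\mathrm{Cov}})$ and $w$ from its conditional
Gaussian); agreement within a factor 1.5 is required, assessed on cells with
delta SE above 0.01 because ratios at saturated probabilities are 0/0.
Cells outside the mesh or with non-finite covariates are masked to NaN
rather than silently extrapolated. Surfaces are written as single-band
float32 GeoTIFFs, EPSG:4326, NaN nodata, named
`{component}_prob_{class}.tif` / `{component}_se_{class}.tif` (e.g.
`water_prob_ImpW_Pipe.tif`). The GeoTIFF reader/writer is part of the
package (no R GeoTIFF library is otherwise required) and round-trips values
bit-exactly at float32.

## The synthetic survey generator

`simulate_survey()` draws complete surveys from exactly the model above, so
every downstream stage is testable without restricted-access survey data:
cluster locations uniform over a bounding box, household counts uniform on
25–30, covariates generated at cluster level, $b$, $u$ (sampled from the
exact dense Matérn covariance, or from the SPDE precision beyond a size
cap), and categories drawn from the latent model. All randomness flows
through one seeded stream in a fixed order (locations, counts, covariates,
cluster effects, field, outcomes), making datasets byte-reproducible.

Default conditions, chosen once to mirror a realistic single-country survey
and used by the validation suite throughout: 150 clusters over a 4°×4°
domain, $K = 4$, two smooth continuous covariates plus a log-time covariate
($p = 3$) with $\beta = (0.8, -0.5, 0.3)$, thresholds $(-1, 0.5, 2)$,
$\sigma_b = 0.5$, practical range 1.5°, $\sigma_u = 0.75$. Continuous
covariates are smooth low-order spatial trends plus local noise — smooth so
they resemble the environmental/socioeconomic rasters used in practice, yet
low-order so covariate recovery is not confounded with the Matérn field.
Time enters as $\log(\text{days since 2005-01-01})$, standardized like any
continuous covariate; predictions default to 2024-01-01. Continuous
covariates are standardized to the *training* mean/SD (stored with the
dataset and reused verbatim for prediction grids), categorical factors are
one-hot encoded against their first level.

What the generator deliberately does **not** emulate: DHS coordinate
displacement, survey weights, urban/rural stratified sampling, covariate
measurement error, and non-stationary or anisotropic spatial structure.
Passing recovery and calibration tests on this generator therefore
demonstrates the correctness of the estimation machinery under the model's
own assumptions — not robustness to the ways real survey data violate them.

## Diagnostics

The validation suite mirrors standard practice for hierarchical ordinal
models:

- **Dunn–Smyth residuals** (`residuals()`, `dunn_smyth_residuals()`):
  randomized quantile residuals, exactly standard normal when the
  probabilities are the truth; computed at the fitted probabilities with
  random effects at their conditional mode.
- **Calibration curves** (`calibration_curve()`): 10 equal-width bins by
  default (configurable; no binning convention is canonical), empty bins
  flagged rather than dropped.
- **Posterior predictive checks** (`posterior_predictive_check()`):
  replicate outcome vectors drawn from the fitted model with random effects
  sampled from the Laplace Gaussian $N(\hat v, H^{-1})$ — propagating
  random-effect uncertainty, with a mode-fixed variant via `re_draw =
  FALSE` — compared with observed category frequencies.
- **Classification metrics** (`classification_metrics()`): one-vs-rest AUC
  by the rank (Mann–Whitney) statistic with midrank ties, precision, recall,
  F1 and accuracy under argmax classification (ties to the lower category).
  "Accuracy" is per-class one-vs-rest accuracy; a multi-class convention had
  to be fixed and this is the one used.
- **Shapley attributions** (`shap_linear()`): for a linear predictor under
  feature independence the Shapley decomposition is exact and closed-form,
  $\phi_{ij} = \hat\beta_j (x_{ij} - \bar x_j)$, rows summing to
  $\eta_i - \bar\eta$. Attributions are computed on the fixed-effect
  predictor only — the spatial field and cluster effects are not features —
  and ranked by mean $|\phi|$.

## Problem sizes used by the validation suite

The test and acceptance runs use sizes chosen to give stable Monte-Carlo
estimates while remaining desk-scale: 20 recovery replicates of 150 clusters
× 25 households; a 200-cluster fit for calibration/PPC/SE checks; a
48×48-node lattice (spacing range/9) and 200 field replicates for the
SPDE-vs-Matérn comparison; $10^5$ observations for residual moments and 50
replicates of $n = 5000$ for the KS pass rate; 500 parameter draws for the
Monte-Carlo SE oracle. One fit at the recovery conditions takes on the
order of ten seconds on a single core.

## Known limitations and open choices

- One spatial field per fit; no per-survey or per-country fields, no
  temporal random field (time is a fixed-effect covariate only), no survey
  weights, no full Bayes.
- Whether households sharing a cluster coordinate should share the field
  value is not decidable from the data structure; they do here, which is
  consistent with cluster-level georeferencing.
- Planar-coordinate treatment of lon/lat, convex mesh boundary only.
- The outer covariance is a finite-difference observed-information estimate;
  near variance-component boundaries it degrades to a pseudo-inverse with a
  warning, and log-scale Wald intervals for variance parameters are poor
  when the estimate sits near zero.
- Each outcome component (e.g. water, sanitation, hygiene) is modelled
  independently; no cross-component borrowing.
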