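---
title: "Forecasting aneurysm geometry with node-wise mixed-effects models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting aneurysm geometry with node-wise mixed-effects models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaafc)
```

## The problem

Abdominal aortic aneurysm (AAA) surveillance decisions rest largely on the
maximum diameter, a single scalar that hides where and how fast the sac is
remodeling. Given two or more co-registered, segmented surface meshes of a
patient's lumen and outer wall from serial imaging sessions, `aaafc`
forecasts the full three-dimensional geometry at an arbitrary target time,
so that diameter and volume — and the shape itself — become queryable
functions of time rather than retrospective measurements.

The pipeline has three stages:

1. **Cylindrical parameterization.** Each surface is sliced at K fixed
   axial stations along its smoothed slice-centroid centerline and each
   cross-section is resampled and mapped to polar coordinates about the
   local centerline point, giving a K x N radius matrix on a fixed
   (z_k, theta_i) lattice. All scans of a patient share one lattice, so
   every node corresponds to itself over time and the entire temporal
   change is carried by the radii and the centerline coordinates.
2. **Node-wise linear mixed-effects growth model.** Each response (the
   unwrapped radii, and the centerline x and y coordinates) is modeled as
   a patient-level linear trend plus node-level random intercepts and
   slopes.
3. **Back-projection.** Predicted radii are reshaped to the lattice and
   mapped back to Cartesian space about the predicted centerline, yielding
   a forecast surface directly comparable to an observed scan.

## The model

For node $n$ at time $t$ (days since the patient's first scan) the
response $Y_{tn}$ — one of radius, centerline $x$, centerline $y$, fitted
separately per layer (lumen / outer wall) — follows

$$Y_{tn} = (\alpha + b_{0n}) + (\beta + b_{1n})\,t + \varepsilon_{tn},$$

$$b_{0n} \sim N(0, \sigma_0^2),\quad b_{1n} \sim N(0, \sigma_1^2),\quad
\varepsilon_{tn} \sim N(0, \sigma_\varepsilon^2),$$

with uncorrelated random effects (diagonal $2 \times 2$ covariance).
$\alpha$ (cm) and $\beta$ (cm/day) are the patient-level fixed intercept
and slope; the node-level random effects carry the regional heterogeneity
— growth concentrates near the maximum diameter and fades toward the
proximal and distal ends, and the $b_{1n}$ field expresses exactly that.

**Estimation.** The lattice guarantees a balanced design: every node is
observed at the same $T$ times, so the marginal covariance
$V = \sigma_0^2 \mathbf{1}\mathbf{1}' + \sigma_1^2 t t' +
\sigma_\varepsilon^2 I$ ($T \times T$) is shared by all $G$ nodes. The
fixed effects are profiled out in closed form (GLS) given $V$, and maximum
likelihood searches only over the three log-variances (bounded L-BFGS-B,
three starts: method-of-moments, all-equal, residual-dominated). This is
why a full-lattice six-model fit ($G = 10{,}000$ radius nodes) takes well
under a second. Node effects are recovered as BLUPs
$\hat b_n = D Z' V^{-1}(y_n - X\hat\gamma)$ with
$D = \mathrm{diag}(\sigma_0^2, \sigma_1^2)$, $Z = X = [\mathbf{1}, t]$.

A forecast needs only the target time: $\hat y_n(t^\*) =
(\hat\alpha + \hat b_{0n}) + (\hat\beta + \hat b_{1n})t^\*$, exactly
linear per node, forward or backward. A warning is raised beyond 5 years
outside the training span — the range a clinician would plausibly explore.

### Numerical choices

- **Time scaling.** Internally the optimizer works on span-normalized
  time $t/\max(t)$; the slope and its variance transform back by the span
  afterwards. With raw day-scale covariates the GLS normal equations
  become numerically singular at boundary optima; on the unit scale they
  are well conditioned. This also makes the variance floor meaningful: a
  floored slope variance contributes at most the floor to $V$ at any
  observed time.
- **Variance floor** `1e-12` per component (on the normalized scale),
  keeping $V$ invertible at boundary solutions such as the two-scan case,
  where the model interpolates and $\hat\sigma_\varepsilon^2$ is driven to
  the boundary.
- **Final estimates** use an eigendecomposition whitening of $V$ and QR
  least squares rather than the normal equations, which keeps fixed
  effects and BLUPs accurate to ~1e-7 cm even on exactly collinear
  (zero-noise) data where $\mathrm{cond}(V) \sim 10^{11}$.
- **Convergence handling.** L-BFGS-B occasionally aborts its line search
  at the optimum; the fit is accepted as converged when another start
  reached the same objective, when a Nelder-Mead polish cannot improve it,
  or when the point sits on the variance floor (where the profile
  deviance decreases monotonically into the bound and no interior
  stationary point exists).
- The deviance function returns a large finite penalty (never `Inf`) when
  $V$ is numerically non-invertible, so the bounded optimizer can recover.

### What a formula interface would not buy

The natural input is a balanced $G \times T$ matrix on a lattice, not a
long data frame; `fit_growth_lme()` therefore takes the matrix (or a
`response_matrix()`) directly and exposes the standard S3 surface
(`print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
`simulate`, `plot`). `fit_aaa_patient()` wraps the six per-patient fits
(3 responses x 2 layers) and `predict()` on it produces forecast geometry.

## Geometry processing

- **Slicing** uses constant-z planes at the station levels. Triangle-plane
  intersection is robust to vertices lying exactly on the plane: on-edges
  are emitted once, and segments are chained into loops by snapping
  endpoints at `1e-6` of the bounding-box diagonal. Among multiple loops,
  the one whose area centroid is nearest the station is kept (largest area
  when no station is given).
- **Centerlines** are the area centroids of the cross-section contours,
  smoothed by a truncated Fourier series (mean + `n_harmonics` sine/cosine
  pairs, default 5) in the normalized axial parameter, then resampled at
  the patient-common station levels. Five harmonics preserve aneurysm-
  scale curvature while suppressing slice-centroid jitter; the order is a
  configuration knob. Smoothing applies to x(s) and y(s) only — z is the
  parameter, matching the forecasting model, which predicts only x and y.
- **The common lattice** is built from the z-range shared by all of a
  patient's meshes, shrunk by a 2% interior margin to avoid tangential end
  slices; the baseline and all follow-ups are resampled at those same z
  values, which is the minimal mechanism guaranteeing identical axes
  across sessions.
- **Angular interpolation** onto the fixed theta lattice replicates the
  polar samples at theta +- 2 pi and interpolates linearly. On a single
  slice natural-neighbor interpolation degenerates to exactly this 1-D
  periodic scheme, which is simpler and exactly testable; the seam at
  theta = +-pi is continuous by construction.
- **Star-shape assumption.** Each cross-section must be star-shaped about
  its centerline point so the radius is single-valued in theta. Violations
  (non-monotone theta beyond one full backtrack) raise a warning and are
  resolved by keeping, per angle, the outermost sample — conservative for
  an aneurysm wall.

## Evaluation

Spatial similarity uses HD95 — the 95th percentile (linear interpolation
between order statistics) of the combined bidirectional nearest-neighbor
distances — in three spaces: the centerline stations, the unwrapped
(r, theta, z) node cloud, and the reconstructed Cartesian cloud. The
unwrapped space mixes cm and radians exactly as stored; no unit rescaling
is applied. HD95 discounts isolated outliers while bounding meaningful
disagreement. The nearest-neighbor search prunes candidates by an axial
window that provably contains the minimum, so it equals the brute-force
double loop bit for bit.

Geometric scalars are the hydraulic maximum diameter
$D_h = 4A/P$ per slice (shoelace area, polygon perimeter — consistent for
asymmetric sections, unlike a caliper width) and the slice-integrated
volume (trapezoidal rule over z). Forecast and ground truth are both
measured on constant-z grid contours, so scalar errors isolate the growth
model rather than the parameterization. Cohort summaries are
macro-averages: per-patient means over follow-ups first, then the mean
across patients, so patients with many follow-ups do not dominate; $R^2$
is $1 - SS_{res}/SS_{tot}$ about the ground-truth mean.

## The synthetic generator

No public longitudinal AAA surface data exist, so validation rests on a
generator whose ground truth is known exactly. The wall radius field is

$$r(z, \theta, t) = r_0 + (A_0 + g t)\,
e^{-(z - z_0)^2 / 2w^2}\,(1 + e\cos(\theta - \theta_0))
+ \eta_n + b_n t + \varepsilon_{nt},$$

a Gaussian axial bulge with a cosine azimuthal asymmetry — the minimal
shape family exhibiting growth concentrated at the maximum diameter —
plus node random intercepts $\eta_n$, node random slopes $b_n$, and
per-observation noise. The lumen is the wall field minus a constant
offset, floored at $0.3 r_0$; the centerline drifts as
$x_c(z,t) = \delta \sin(\pi z / L)\, t / t_{max}$. Defaults describe a
surveillance-scale fusiform AAA: trunk radius 1.5 cm, bulge 0.8 cm
(hydraulic maximum diameter about 4.5 cm), growth 5.5e-4 cm/day (about
2 mm/year at the apex), four scans over 1540 days (mean interval about one
year), asymmetry 0.15, drift 0.1 cm, node noise 0.05 cm, observation
noise 0.02 cm. One seeded RNG stream per patient makes every draw
reproducible, and the stored noise draws make oracles exact rather than
statistical.

Fields are swept into watertight triangulated tubes with vertex rings
offset from the analysis stations (so no slicing plane ever passes through
a vertex ring) and with axial and azimuthal refinement keeping the facet
chord error below ~1e-3 cm at the default lattice.

**What the generator does not emulate:** thrombus dynamics and
biomechanics, segmentation artifacts, scan-to-scan registration error,
nonlinear growth, and irregular (unbalanced) acquisition grids. Passing
tests therefore demonstrate correctness of the pipeline and estimator
under the model's own assumptions, not clinical accuracy on real imaging.

## Validation problem sizes

The packaged tests and the acceptance script use scaled problem sizes
chosen to exercise every code path at full fidelity: round-trip fidelity
at the full 100 x 100 lattice; estimator recovery at G = 1000 nodes,
T = 4, over 20 seeds; and an end-to-end held-out experiment with 10
synthetic patients at a 40 x 40 lattice, four scans, exclude-last
fitting. On this experiment the held-out unwrapped HD95 sits at the
observation-noise floor and hydraulic-diameter and volume errors are a
fraction of a percent — comfortably below the few-percent regime expected
for linear growth observed with 0.02 cm noise.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
pat <- generate_patient(synth_config(seed = 7), patient_id = "DEMO")
param <- parameterize_series(pat$series, K = 40, N = 40)
model <- fit_aaa_patient(param, regime = "exclude_last")
model

# forecast one year past the last scan
fc <- predict(model, t_star = 1540 + 365)
cts <- grid_contours(fc$outer_wall$grid, fc$outer_wall$centerline)
hydraulic_dmax(cts)
volume_from_slices(cts)

# honest evaluation at the held-out follow-up
rep <- evaluate_forecast(model, param)
subset(rep, held_out)
```

## Known limitations

- Axial (z) deformation is not modeled: remodeling is assumed to act on
  cross-sectional caliber and shape, and on in-plane centerline drift.
- Node effects are spatially independent; neighboring nodes can disagree
  by noise, and lumen and wall are fitted without a coherence constraint.
- Two-scan patients are fit by what amounts to linear interpolation;
  forecasts from them extrapolate the observed segment and carry no
  information about curvature in time. Three or more sessions are
  required for the exclude-last regime and for any variance estimation
  beyond interpolation.
- Irregularly clustered acquisition times bias the linear trend toward
  the cluster; equally spaced follow-ups are the benign case.
- Cross-sections must be star-shaped about the centerline; strongly
  lobed or branching anatomy (iliac bifurcation and beyond) is out of
  scope.
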