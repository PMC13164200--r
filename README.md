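# aaafc — patient-specific abdominal aortic aneurysm geometry forecasting

Abdominal aortic aneurysm (AAA) surveillance is driven by the maximum
diameter, a single scalar that hides where the sac is remodeling and how
fast. `aaafc` forecasts the full three-dimensional AAA geometry at an
arbitrary time from two or more co-registered, segmented surface meshes
(lumen and outer wall) of a patient's serial imaging sessions.

Each surface is unwrapped onto a centerline-anchored cylindrical lattice:
the smoothed slice-centroid centerline fixes K axial stations z_k, each
constant-z cross-section is resampled and mapped to polar coordinates
about the local centerline point, and the surface becomes a K × N radius
matrix on fixed (z_k, θ_i) axes shared by every scan of the patient —
one-to-one node correspondence over time. Each response (unwrapped radii
r, centerline x and y; per layer) then follows a node-wise linear
mixed-effects growth model

    Y_tn = (α + b0_n) + (β + b1_n) t + ε_tn,
    b0_n ~ N(0, σ0²),  b1_n ~ N(0, σ1²),  ε ~ N(0, σε²),

with uncorrelated random effects: the patient-level fixed intercept α and
slope β carry the global trend, and the node-level random intercepts and
slopes carry the regional heterogeneity. The balanced lattice lets the
fixed effects be profiled in closed form, so maximum likelihood searches
only three log-variances and a full 10,000-node fit takes a fraction of a
second. Predicted radii are back-projected about the predicted centerline
into a Cartesian forecast surface, from which the clinically familiar
scalars — hydraulic maximum diameter D_h = 4A/P and volume — emerge as
by-products.

Evaluation uses HD95 (the 95th percentile of combined bidirectional
nearest-neighbor distances) in three spaces — centerline, unwrapped
(r, θ, z) cloud, reconstructed surface — plus relative errors of the
geometric scalars, with cohort summaries macro-averaged per patient
first. A synthetic longitudinal aneurysm generator (Gaussian bulge ×
cosine asymmetry with node-wise linear growth, drifting centerline and
Gaussian noise) provides exact ground truth for validation; see the
methods vignette (`vignettes/aaa-geometry-forecasting.Rmd`).

## Worked example

```r
library(aaafc)

pat   <- generate_patient(synth_config(seed = 7), patient_id = "DEMO")
param <- parameterize_series(pat$series, K = 40, N = 40)
model <- fit_aaa_patient(param, regime = "exclude_last")
model
#> <aaa_patient_model> patient DEMO (exclude_last): K=40 x N=40, trained on days {0, 513, 1027}
#>   held-out follow-up(s): day 1540
#>   lumen: radius beta = 0.09743 cm/year; centerline drift (0.0242, 0.0108) cm/year
#>   outer_wall: radius beta = 0.09742 cm/year; centerline drift (0.0242, 0.0108) cm/year
#>   six-model fit time: 0.20 s
```

The model trained on the first three scans forecasts the geometry one
year beyond the last (held-out) scan:

```r
fc  <- predict(model, t_star = 1540 + 365)
cts <- grid_contours(fc$outer_wall$grid, fc$outer_wall$centerline)
hydraulic_dmax(cts)        #> 6.566 cm
volume_from_slices(cts)    #> 195.6 cm^3
```

and its honest accuracy at the held-out fourth scan is

```r
subset(evaluate_forecast(model, param), held_out)
#>        layer time_days hd95_unwrapped hd95_reconstruction dmax_err_pct volume_err_pct
#>        lumen      1540         0.0578              0.0585       0.0774          0.119
#>   outer_wall      1540         0.0570              0.0589       0.0243          0.100
```

HD95 in the unwrapped space sits at the configured observation-noise
floor (0.02 cm per node) and the scalar errors are a tenth of a percent:
with linear growth, three scans suffice to pin the trajectory. Individual
fits print their estimates directly:

```r
summary(model$fits$outer_wall$radius)
#> Node-wise linear mixed-effects growth model
#>   G = 1600 nodes, T = 3 times (days 0, 513, 1027)
#>   alpha = 1.88395 cm, beta = 0.000266721 cm/day = 0.09742 cm/year
#>   sigma0^2 = 0.07393 cm^2, sigma1^2 = 3.521e-08 (cm/day)^2, sigma_eps^2 = 0.0002339 cm^2
#>   BLUP spread: sd(b0) = 0.2716 cm, sd(b1) = 0.0001865 cm/day
#>   logLik = 4259.15 (converged: TRUE)
```

A command-line driver wraps the same pipeline
(`inst/exec/aaafc simulate | parameterize | fit | forecast | evaluate |
cohort-report`), writing STL meshes, CSV grids, JSON models and a cohort
CSV shaped layer × regime × representation.

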