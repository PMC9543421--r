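# corneatilt

Corneal densitometry — backscatter measured by Scheimpflug tomography in
standardised greyscale units (GSU, 0 = fully transparent, 100 = fully
opaque) — correlates with corneal tilt. But age drives both tilt and
densitometry, so is the tilt–densitometry correlation a real optical
effect or a confound? `corneatilt` provides everything needed to study
this question quantitatively on synthetic data with known ground truth.
It is aimed at researchers in ophthalmic biometry and at statisticians
who want a worked, reproducible example of mediation analysis on a
realistic biometric triangle.

The package implements:

* **Corneal tilt (angle alpha) estimation.** The visual axis is taken as
  the instrument axis; the optical axis is found by rotating the cornea,
  in a Levenberg–Marquardt loop, until the central ray refracted through
  both surfaces by the vector form of Snell's law,
  `t = (n1/n2) d + ((n1/n2) cos(theta_i) - cos(theta_t)) n`,
  exits undeviated (equivalently: with diverging focal length). Angle
  alpha is the 3D angle between the two axes:
  `alpha = arccos(cos(alpha_x) cos(alpha_y))` for a tilt of
  `(alpha_x, alpha_y)`. Elevation maps are smoothed with degree-8
  polynomials over the central 8-mm disc (the span of Zernike terms to
  radial order 8).
* **Regional densitometry.** Exact volume-weighted GSU means over the
  standard concentric zones (0–2, 2–6, 6–10, 10–12 mm diameter) and depth
  layers (anterior 120 µm, central, posterior 60 µm), plus overall.
* **A synthetic-data generator.** Tilted biconic corneas sampled to
  elevation grids with Gaussian measurement noise, and cohorts from the
  linear-Gaussian chain `age -> tilt -> densitometry` calibrated so the
  population moments and correlations equal specified targets (defaults:
  age 42.8 ± 20.0 y, tilt 5.8 ± 1.8°, overall 17 ± 7 GSU,
  r(age,tilt) = 0.50, r(age,dens) = 0.91, r(tilt,dens) = 0.45), with a
  support-aware correction so the bounded GSU scale does not deflate the
  calibrated moments.
* **Simple mediation analysis.** OLS paths `a`, `b`, `c`, `c'` with the
  identity `c = c' + a*b`, percent direct/mediated `100 c'/c` and
  `100 ab/c`, and a percentile-bootstrap CI for the indirect effect `a*b`.

## Worked example

```r
library(corneatilt)

# 1. a synthetic eye with known tilt, and its recovery
eye <- make_cornea(cornea_spec(tilt_x = 3, tilt_y = 4, noise_sd_um = 2, seed = 1))
res <- estimate_optical_axis(eye$anterior, eye$posterior)
res
#> <tilt_result> angle alpha 4.9784 deg, axis (0.06935, -0.05217, 0.99623)
#>   residual 1.22e-17, 4 iterations, converged: TRUE
```

The true angle alpha for a (3°, 4°) tilt is `arccos(cos 3 cos 4)` = 4.9985°;
the estimate above recovers it to 0.02° despite 2 µm of elevation noise
(noise-free recovery is accurate to better than 0.001°).

```r
# 2. the full synthetic study: cohort, correlations, both mediation cases
report <- run_study(study_config(cohort = list(n = 86, seed = 11),
                                 mediation = list(n_boot = 300, seed = 12)))
report
#> corneatilt study report (version 1.0.0)
#> ...
#> r(age, tilt)         = 0.570 (p = 1.03e-08)
#> r(age, densitometry) = 0.912 (p = 2.73e-34)
#> ...
#> mediation case1: tilt -> densitometry through age
#>   a = 5.5477, b = 0.3356, c = 1.9557, c' = 0.0939, indirect = 1.8618
#>   4.8% direct, 95.2% mediated; 95% CI for indirect [1.2208, 2.4567] (significant)
#>
#> mediation case2: age -> densitometry through tilt
#>   a = 0.0585, b = 0.0939, c = 0.3411, c' = 0.3356, indirect = 0.0055
#>   98.4% direct, 1.6% mediated; 95% CI for indirect [-0.0214, 0.0301]
```

Reading the output: at n = 86 most of the tilt–densitometry correlation is
carried by age (the indirect path `a*b` dominates `c` in case 1 and its
bootstrap CI excludes 0), while the age–densitometry correlation is almost
entirely direct (case 2). At n = 100 000 the mediated share of case 1 and
the direct share of case 2 both exceed 90%.

A command-line wrapper over the same functions ships in
`inst/cli/corneatilt.R` (commands `simulate-cornea`, `estimate-tilt`,
`simulate-cohort`, `mediate`, `run-study`).

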