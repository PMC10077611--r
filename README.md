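# hipmorph

Three-dimensional hip morphometry across pelvic tilt.

How well do the two workhorse radiographic measures of acetabular coverage —
the lateral center-edge angle of Wiberg (LCEA) and Lequesne's anterior
center-edge angle (ACEA) — reflect the *actual* 3D coverage of the femoral
head, and how much do they move when the pelvis tilts? `hipmorph` implements
the full 3D measurement pipeline needed to ask that question of CT-derived
hip models, for orthopaedic researchers and morphometrists working on hip
dysplasia, femoroacetabular impingement, and pelvic-tilt correction:

- **APP frame** — an anterior-pelvic-plane (APP) anchored coordinate system
  built from five landmarks: X along the line between the femoral head
  centers, Z perpendicular to X and contained in the APP (superior), Y
  completing the right-handed triad (anterior).
- **Tilt sweep** — rigid rotation of the pelvis about the inter-head axis
  from −30° to +30° in 5° steps (positive = anterior tilt), with the femur
  held in the default posture.
- **Measurements at each pose**
  - *LCEA*: in the cut plane parallel to the neutral-orientation APP through
    the most lateral rim point, the signed angle between the vertical and
    the head-center→edge line — `LCEA = atan2(s·wₓ, w_z)` for the
    center-edge vector `w` with laterality sign `s`. For an axisymmetric cup
    of rim colatitude θ at tilt φ this reduces to the closed form
    `arctan(tan θ / cos φ)`.
  - *ACEA*: the same construction in the 65°-rotated (false-profile) plane
    through the most anterolateral rim point:
    `ACEA = atan2(w·u, w_z)` with `u = s·cos 65°·x + sin 65°·y`.
  - *Coverage*: fraction of the superior-hemisphere silhouette (area πr²)
    covered by the rim-bounded spherical region, integrated on a
    deterministic horizontal grid. Closed form `sin²θ` at neutral for
    axisymmetric cups.
- **Femoral head sphere fit** — algebraic least squares plus Gauss–Newton
  refinement of Σ(|p−c|−r)².
- **Synthetic cohort generator** — parametric hips (head sphere + single
  harmonic rim-colatitude modulation) with closed-form ground truth,
  emulating a bilateral cohort of 142 hips (38 men / 33 women, both sides)
  with a configurable male–female coverage effect.
- **Cohort statistics** — per-angle sex comparisons (pooled or Welch
  two-sample t), CEA-vs-coverage Pearson correlations with conventional
  strength labels, ICC(2,1) reliability, and range/peak arithmetic over a
  tilt window, including on a packaged published-cohort summary table.

## Worked example

```r
library(hipmorph)

hip <- generate_hip(synthetic_hip_params(rim_colatitude_deg = 38, seed = 42),
                    hip_id = "demo")
hip
#> <hip_model> demo: unknown right hip, 360 rim points, tilt +0 deg
#> <head_sphere> center (90.000, -10.000, -60.000) mm, radius 24.000 mm

sw <- tilt_sweep(hip, measurement_config(tilt_grid = seq(-30, 30, 10)))
as.data.frame(sw[, c("app_tilt_deg", "lcea_deg", "acea_deg", "coverage")])
#>   app_tilt_deg lcea_deg acea_deg coverage
#> 1          -30    46.69    3.549   0.2980
#> 2          -20    43.28   12.350   0.3366
#> 3          -10    41.04   21.149   0.3651
#> 4            0    39.79   29.945   0.3825
#> 5           10    39.43   38.811   0.3881
#> 6           20    39.93   47.799   0.3821
#> 7           30    41.33   56.941   0.3645
```

The demo hip's rim is modulated with its deepest coverage posterior (the
generator default, mimicking the anterior-wall deficiency of real
acetabula), so coverage peaks at an anterior tilt of about +10° while ACEA
climbs steeply — roughly 4.5° per 5° of anterior tilt — across the whole
grid. `autoplot(sw)` draws the three curves.

Range/peak arithmetic over the physiologic tilt window (−10° to +5°) on the
packaged summary of a published CT cohort (142 normal hips, 76 men / 66
women):

```r
range_stats(table1_summary(), -10, 5, "overall")
#>   measure range argmax_deg   max   min n_angles
#> 1     acea 11.77          5 37.46 25.69        4
#> 2 coverage  0.05          0  0.84  0.79        4
#> 3     lcea  1.84          5 34.95 33.11        4
```

ACEA moves by 11.77° across the physiologic window while LCEA moves by only
1.84° — the quantitative core of the advice that pelvic tilt must always be
considered when interpreting ACEA, but hardly matters for LCEA within the
physiologic range.

A shell pipeline is available as `inst/cli/hipmorph`
(`simulate`, `measure`, `cohort-stats` subcommands).

## Package layout

| file | contents |
| --- | --- |
| `R/app_frame.R` | landmarks, APP frame, tilt poses, measurement config |
| `R/hip_model.R` | head sphere + fit, rim curves, hip container |
| `R/io.R` | landmark/rim/mesh readers and writers |
| `R/morphometry.R` | LCEA, ACEA, coverage, tilt sweep |
| `R/synthetic.R` | parametric hip and cohort generators |
| `R/cohort_stats.R` | t-tests, correlations, ICC, range/peak stats |
| `R/cli.R`, `inst/cli/hipmorph` | pipeline commands and shell wrapper |
| `vignettes/hip-morphometry.Rmd` | methods and design notes |
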