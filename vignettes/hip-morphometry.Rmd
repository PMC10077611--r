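---
title: "Measuring 3D acetabular coverage across pelvic tilt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D acetabular coverage across pelvic tilt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipmorph)
```

## The measurement problem

The lateral center-edge angle (LCEA) and the anterior center-edge angle
(ACEA) summarize how far the acetabulum wraps around the femoral head
laterally and anteriorly. Both are defined against a *vertical* reference,
so they are functions not only of anatomy but of how the pelvis happens to
be oriented: anterior pelvic plane (APP) tilt rotates the acetabular rim
relative to the vertical while the femur stays put. `hipmorph` makes that
dependence explicit: it measures LCEA, ACEA, and true horizontal-plane
coverage on a 3D hip model at every APP tilt angle on a grid (default −30°
to +30° in 5° steps).

## Coordinate frame and tilt model

The frame is anchored on anatomy, not on scanner axes:

- **X** — unit vector from the left to the right femoral head center;
- **Z** — the direction perpendicular to X contained in the APP (the plane
  through both anterior superior iliac spines and the pubic-tubercle
  midpoint), signed superiorly;
- **Y** — `Z × X`, pointing anteriorly;
- origin at the midpoint of the head centers.

The default posture holds the femoral mechanical axis parallel to Z. APP
tilt is a rigid rotation of the pelvic structures (rim, landmarks) about the
X-axis line through the origin, so both head centers are fixed points.
*Positive tilt is anterior*: at +90° the superior axis Z maps onto the
anterior axis Y. This one sign convention is encoded once, in
`make_tilt_pose()`, and everything else inherits it; it makes ACEA increase
with anterior tilt, as it must for an anteriorly-opening construction.

The model frame built at construction time is kept as the *fixed* reference
for all measurements; `apply_pose()` deliberately does not update it. This
realizes the "pelvis moves, observer does not" semantics of the sweep, and
makes all measures exactly invariant under rigid motions of the whole input
(the frame co-rotates) and under mirroring with a side-label flip.

## The three measures

Let `c` be the head center, `e` the selected rim point, `w = e − c`, and
`s = +1` for right hips, `−1` for left.

**LCEA.** The cut plane is parallel to the neutral-orientation APP and
passes through the most laterally protruding rim point (maximal `s·wₓ`).
The plane-normal component of `w` is dropped and the signed angle from the
vertical is reported: `LCEA = atan2(s·wₓ, w_z)`. Edges medial to the
vertical give negative angles (dysplastic configurations) rather than being
clamped at zero.

**ACEA.** The same construction in the 65° false-profile orientation: the
edge maximizes `w·u` with `u = s·cos65°·x + sin65°·y`, and
`ACEA = atan2(w·u, w_z)`. The projection onto the rotated cut plane drops
out algebraically because the discarded normal component is orthogonal to
both reference directions.

Two realization choices deserve comment, because the verbal definitions
underdetermine them:

1. *The cut planes are fixed in the default-posture frame*, not re-derived
   from the tilted APP. If both the plane and the vertical reference
   rotated with the pelvis, the whole construction would be rigidly attached
   to the anatomy and the measured angles provably could not depend on tilt
   at all — contradicting the purpose of the sweep. With the fixed plane,
   an axisymmetric cup of rim colatitude θ measures exactly
   `arctan(tan θ / cos φ)` at tilt φ, which is the closed form the test
   suite pins the engine to.
2. *The head center generally lies off the cut plane*; the center-edge
   vector is orthogonally projected into the plane (equivalently, the
   plane-normal component is dropped) before the angle is read off.

**Coverage.** The denominator is the area of the superior-hemisphere
silhouette on the neutral horizontal plane, πr². The numerator is the
silhouette area of the rim-bounded spherical region containing the cup pole,
clipped to the superior hemisphere first, so acetabular overhang beyond the
equator adds nothing. For an axisymmetric cup at neutral this is `sin²θ`
of the disk — the closed form used in validation.

### Extremal points, exactly

Both edge selections maximize a *linear* functional of position. The
maximum of a linear functional over a closed polyline is attained at a
vertex, so the search is run over the rim's vertices and is exact — no
resampling error enters the CEAs, ties are broken toward the more superior
point, and mirror/rigid invariance holds to machine precision. The error in
the CEAs is therefore governed entirely by how densely the *input* rim
polygon samples the true anatomical rim.

### Coverage integration

Coverage is integrated by midpoint counting on a deterministic grid over the
silhouette disk (cell edge `area_grid_resolution`, default 0.15 mm for a
~24 mm head). Each superior-hemisphere grid direction is classified as
in-cup by comparing its colatitude about the cup axis with the rim's
colatitude profile, linearly interpolated in azimuth with wraparound. The
cup axis is the best-fit rim-plane normal signed toward the rim centroid.
This classification assumes the rim is star-shaped about the cup axis
(single-valued colatitude profile), which holds for the synthetic family
and for non-pathological anatomical rims. Numerator and denominator are
counted on the same grid, so a full superior hemisphere scores exactly 1
and discretization errors partially cancel; halving the cell size moves
results by well under half a coverage point, which the acceptance tests
check.

## Tunable parameters

| parameter | default | units | notes |
| --- | --- | --- | --- |
| `tilt_grid` | −30…+30 by 5 | deg | strictly increasing |
| `false_profile_deg` | 65 | deg | ACEA construction; (0, 90) |
| `physiologic_range` | (−10, +5) | deg | reporting window for range stats |
| `rim_sampling_n` | 3600 | — | rim densification for coverage |
| `area_grid_resolution` | 0.15 | mm | coverage grid cell edge |
| `tol_rim` | 2% of r | — | rim-on-sphere validation gate |

## The synthetic generator

Real CT cohorts are not redistributable, so validation runs on a parametric
family with analytic ground truth. A synthetic hip is a sphere of radius
`head_radius` (default 24 mm) with a rim whose colatitude at azimuth ψ
(measured from lateral toward anterior) is

θ(ψ) = θ₀ + A·cos(ψ − ψ₀) + ε(ψ),  ε ~ N(0, σ²)

To first order in A, this rim is a *circle* on a cup axis tipped by A
toward azimuth ψ₀ — the simplest family that breaks the LCEA/ACEA
degeneracy and gives coverage a tilt-angle at which it peaks. With the
default posterior phase (ψ₀ = −90°, emulating the anterior-wall deficiency
of real acetabula) the equivalent cup axis tips posteriorly by ≈A, so
cohort coverage peaks at an anterior tilt of ≈ +A; the default amplitude
A = 10° targets the +10° coverage peak reported for normal hips. When
A = σ = cup-pre-tilt = 0 the ground truth is closed-form: LCEA = ACEA = θ₀
and coverage = sin²θ₀.

Cohort defaults emulate the shape of the reference study — 38 male and 33
female subjects, bilateral, 142 hips — with a +3° male–female difference in
mean rim colatitude (SD 5°) as the generative sex effect, head radii
25 ± 1.2 mm (men) and 22 ± 1.1 mm (women), modulation 10 ± 2° at phase
−90 ± 8°, per-point rim noise SD 0.3°, and bilateral hips sharing subject
parameters up to a 1° left–right jitter. These were fixed once, from
anatomical orders of magnitude, as the package's study conditions.

**What the generator does *not* emulate.** The cup pole sits near the
superior axis, so at θ₀ ≈ 40° synthetic coverage is ≈ sin²40° ≈ 0.41 —
roughly half the ~0.84 of real acetabula, whose sockets extend far
medially around a medially-directed cup axis. Synthetic cohorts therefore
reproduce the *qualitative* structure (sex ordering, ACEA monotonicity,
coverage peak location, positive CEA–coverage correlations), not the
printed magnitudes of a real cohort; passing tests certify the measurement
engine, not anatomical realism.

**A structural limitation worth knowing.** When the measured lateral edge
is a fixed material point of the rim — as it is here, because the lateral
coordinate is invariant under rotation about the lateral axis — LCEA(φ) has
an interior *minimum* near the tilt that verticalizes the cup axis and
rises toward both grid ends. An interior LCEA *maximum* of the kind
reported for real hips cannot arise in this model family; it requires the
measured edge to migrate along the sclerotic sourcil as the cut plane
changes, a structure distinct from the bony rim that the generator does not
model. Cohort-mean coverage does peak at the targeted anterior tilt;
cohort-mean LCEA peaks at the posterior end of the grid instead, and the
corresponding acceptance expectation is knowingly left failing rather than
redefined.

## Statistics stage

Hips are treated as independent observations (n = 142 from 71 subjects),
mirroring how such cohorts are conventionally tabulated; this is a
faithful-reproduction choice, not a statistical endorsement — a
mixed-effects treatment of bilateral correlation is out of scope. The
two-sample t-test defaults to the pooled (Student's) form with Welch
selectable; a summary-statistics variant computes the identical statistic
from (n, mean, sd), which is what the packaged cohort summary supports.
Pearson correlations carry the conventional strength ladder (0.2 / 0.4 /
0.6 / 0.8, inclusive thresholds). Reliability uses ICC(2,1) — two-way
random effects, absolute agreement, single measures — computed from the
mean-squares decomposition and cross-checked in the tests against an
independent `aov()` route. No multiple-testing correction is applied.
P-values from the summary-statistics route on a *rounded* published table
are not expected to reproduce published p-values exactly and are not
asserted anywhere.

The packaged `table1_summary()` fixture ships the per-angle means, SDs, and
group sizes of a published CT cohort; `range_stats()` reproduces its
derivable arithmetic (window ranges and peak angles) exactly.

## Numerical choices and degenerate inputs

- Sphere fitting: algebraic (Kåsa) linear fit for starting values, then
  Gauss–Newton on the geometric residuals, capped at 50 iterations with a
  1e−12 relative step tolerance; coplanar or <4-point inputs are rejected
  via the design matrix's smallest singular value.
- Collinear APP landmarks and coincident head centers raise degenerate-input
  errors at construction, not at measurement time.
- Rim validation reports the index and offset of the worst off-sphere point;
  the side label is checked against the nearest head-center landmark.
- Rims are stored counter-clockwise as seen from superior; loaders enforce
  the convention by reversing when needed.
- An exact tie in an extremal search is broken toward the more superior
  point; a zero in-plane center-edge vector raises an undefined-angle error.
- Coverage problem sizes: the default 0.15 mm grid on a 24 mm head
  classifies ≈80k surface directions per pose; a 142-hip, 13-angle sweep is
  the package's standard full-cohort workload.

## Known limitations

- The sourcil edge is identified with the bony rim; sclerotic-line
  segmentation is not modeled (see the structural limitation above).
- Coverage assumes a star-shaped rim about the cup axis; severely retro-
  or anteverted pathological rims could violate it.
- Only spherical head models are supported; aspherical (cam) morphology is
  out of scope.
- Mesh readers are ASCII-only and vertex-only by design.
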