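---
title: "Measuring joint ROM from 2D keypoints: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring joint ROM from 2D keypoints: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poserom)
```

## The measurement problem

Clinical range-of-motion (ROM) assessment traditionally uses a handheld
goniometer. A markerless alternative detects body keypoints in webcam video
and computes joint angles from their pixel coordinates. `poserom`
implements that angle computation, the manual reference-picture method it
is validated against, and the psychometric analysis (reliability and
validity) that decides whether the method is clinically usable. The
pose-estimation backend itself is out of scope: any detector that emits
shoulder/hip/knee/ankle pixel coordinates can feed the pipeline.

## Angle geometry

All coordinates are image pixels, origin top-left, y increasing downward.

**Sagittal movements** (lateral view). The measured joint is the vertex of
a triangle of keypoints: knee–**hip**–shoulder for hip flexion/extension,
hip–**knee**–ankle for knee flexion. The interior angle $\alpha$ at the
vertex comes from the law of cosines, and the reported ROM is
$\beta = 180^\circ - \alpha$: a perfectly straight segment chain
($\alpha = 180^\circ$) reads $0^\circ$ of movement. $\beta$ is invariant to
translating, rotating and uniformly scaling the image, so camera roll does
not bias sagittal angles.

**Hip rotations** (frontal view). Axial femoral rotation is observed as
lateral ankle displacement: the knee, the ankle and the vertical pixel line
through the knee form a right triangle, and
$\theta = \arctan(|x_{ankle}-x_{knee}| / (y_{ankle}-y_{knee}))$. This angle
is referenced to the *image* vertical, deliberately: the protocol levels
the camera, and the application has no calibration frame. $\theta$ is
therefore not rotation-invariant (a test asserts that asymmetry), and a
tilted camera biases rotation readings — a documented limitation of the
method itself, not of this implementation.

The app path rounds to whole degrees; the manual reference path rounds to
1°. Both use *ties away from zero*, matching how a clinician reads a
goniometer scale; the choice only matters at exact half-degree values.

Direction labels for rotation (the protocol reports magnitudes only) are a
package convention: for the left leg seen from the front, ankle toward
image right of the knee = inner, toward image left = outer; mirrored for
the right leg; an exactly vertical shank is "neutral".

**Degenerate inputs.** Coincident keypoints, or an ankle at/above the knee
in a rotation frame, indicate tracking failure and raise typed errors
rather than being clamped. The arccosine argument is clamped to $[-1, 1]$
only within $10^{-12}$ to absorb floating-point excursion; anything larger
errors. Note one numerical fact: exactly at collinearity
($\cos\alpha = -1$) the arccosine's derivative is unbounded, so machine
rounding of the cosine can perturb the raw angle by $\sim 10^{-5}$ degrees.
Whole-degree output is unaffected; tests of the collinear case use a
commensurate tolerance while non-degenerate configurations are held to
$10^{-9}$ degrees against an independent `atan2(cross, dot)` oracle.

## Reference landmarks

The reference method marks the bony landmarks a goniometrist would palpate
(greater trochanter, lateral femoral epicondyle, humeral head midpoint,
lateral malleolus, patella midpoint, talocrural-space centre) on the saved
frame and runs the *same* geometry on them. The two methods share every
line of angle code; they differ only in where the points come from. Real
bony landmarks are systematically offset from learned joint centres; the
study generator exposes `landmark_offset_px` to probe the bias this
induces (default 0, since no per-landmark offset is quantified for the
protocol).

## Reliability and validity statistics

With $n$ participants measured in $k = 2$ sessions, the two-way
random-effects ANOVA mean squares (rows = subjects $MS_R$, columns =
sessions $MS_C$, residual $MS_E$) give the single-measure
absolute-agreement ICC:

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}$$

Absolute agreement (not consistency) is the right form here because the
downstream SEM is an absolute-reliability quantity: a method that drifts
5° between sessions should be penalised even if it ranks participants
identically. The consistency variant ICC(C,1) is available via
`type = "consistency"` for sensitivity checks. The 95% CI uses the
F-distribution method of McGraw & Wong for ICC(A,1), the procedure behind
the intervals mainstream statistics packages print for this design.

$\mathrm{SEM} = S\sqrt{1-\mathrm{ICC}}$ with $S$ read as the sample SD of
the pooled $2n$ session scores (denominator $2n-1$). "SD of first and
second measurement scores" admits a second reading — the mean of the two
per-session SDs — which is available as `pooling = "session_mean"`; the
pooled form is the default because it is the conventional one and the two
differ negligibly unless sessions differ strongly in spread.
$\mathrm{MDC} = \mathrm{SEM}\cdot\sqrt{2}\cdot 1.96 = 2.771859\,\mathrm{SEM}$.

Validity: Pearson $r$ on session-1 app vs reference values, and
Bland–Altman analysis of $d_i = \mathrm{app}_i - \mathrm{ref}_i$ (so a
method reading low shows a negative bias), limits of agreement
$\bar d \pm 1.96\,\mathrm{SD}(d)$ with the $n-1$ SD, outliers counted
strictly outside the limits. Classification bands (ICC: Landis–Koch;
$r$: very strong ≥ 0.90 … very weak < 0.30) are lower-bound inclusive on
the magnitude.

## The synthetic study generator

Because the validation cohort's raw data is not publicly available, the
generator reproduces the *design*: 30 participants, five movements in the
protocol order (hip flexion, knee flexion, hip extension, inner rotation,
outer rotation), two sessions 24 h apart, an app and a reference reading.

The latent model is a standard two-level variance-components model:
participant true angle $\theta_i \sim N(\mu_m, \sigma_b^2)$, session value
$\theta_{is} = \theta_i + N(0, \sigma_w^2)$, truncated to the anatomical
range by re-sampling (counted; > 1% triggers a warning). The app reading
is the whole-degree measurement of the skeleton posed at $\theta_{is}$,
projected through a pinhole camera at the standardized geometry (lens
55 cm above the floor, 2.05 m from the participant, 1280×720) with
i.i.d. Gaussian keypoint noise $\sigma_{px}$; the reference reading applies
the landmark geometry to the same session-1 frame with its own placement
noise. The theoretical reliability
$\sigma_b^2 / (\sigma_b^2 + \sigma_w^2 + \sigma_{meas}^2)$ is reported in
the ground truth, with $\sigma_{meas}$ — the angle-domain noise induced by
$\sigma_{px}$ — estimated by the module itself via Monte Carlo (2000
draws at the movement's mean angle).

Choices worth recording:

* **Fronto-parallel posing.** The skeleton is posed in a plane parallel to
  the image plane (lateral view for sagittal movements, frontal for
  rotations), so projection is a similarity transform and the pixel-space
  angle equals the requested angle *exactly* — which is what makes the
  exhaustive project-then-measure round-trip test meaningful. At 2.05 m
  the out-of-plane perspective error a real limb would add is a small
  fraction of a degree; it is a feature real data has that the generator
  does not emulate.
* **Field of view.** At 2.05 m a 720p frame needs roughly a 62° vertical
  FOV to contain a standing 177.5 cm adult's shoulder with the lens at
  55 cm; the default camera therefore uses a 78° *horizontal* FOV (a
  typical wide-angle webcam). Narrower lenses raise a framing error with
  a suggestion rather than silently clipping.
* **Rotation proxy.** Hip rotation is simulated as frontal-plane ankle
  displacement of the full shank with drop $\ell\cos\theta$ — a 2D proxy
  for 3D axial rotation that matches exactly what the right-triangle
  measurement observes. No claim is made about the 3D kinematics behind it.
* **Default movement parameters** ($\mu$, $\sigma_b$; flexion 105 ± 10,
  knee 125 ± 10, extension 18 ± 6, rotations 35 ± 8 / 33 ± 8 degrees,
  $\sigma_w = 3$, $\sigma_{px} = 2$) are anatomically plausible values for
  healthy young adults, documented as simulation defaults — they are not
  cohort estimates.
* **Noise model.** Keypoint error is i.i.d. Gaussian per coordinate. Real
  detector error is heavier-tailed and temporally correlated, and clothing
  or occlusion produce structured failures; passing tests on synthetic
  data therefore validates the *pipeline arithmetic and statistics*, not
  detector robustness.
* **Anthropometry.** Segment lengths as fixed stature fractions (trunk
  0.30, thigh 0.245, shank 0.246), stature default 177.5 cm.

Determinism: every random quantity flows from the single `seed` in
`study_gen_config()`; identical config and seed give byte-identical study
tables, and report files embed the config hash and seed for provenance.

## Workflow guards

The blinded protocol keeps app readings unseen until the reference angle is
computed. `rom_validity()` enforces the observable consequence — reference
timestamps must postdate the app measurements — and can be overridden with
`blind_check = FALSE` for data that lacks trustworthy timestamps. Movement
order is enforced in simulated output and only warned about in user data.

## Problem sizes used in the checks

The shipped checks run at sizes chosen to make sampling error negligible
relative to their tolerances while remaining desk-scale: $10^4$ random
configurations for the geometry-oracle bound, the full 5°-grid of every
movement's range for the round-trip, 200 replicate 30-participant cohorts
for ICC recovery (mean within ±0.03 of the 0.90 truth; CI coverage
95% ± 3%), and $10^5$ differences for Bland–Altman coverage (95% ± 1%).

## Known limitations

* 2D projection only: out-of-plane limb motion biases sagittal angles in
  real footage; no camera calibration or undistortion is modelled.
* Rotation angles assume a level camera and upright posture; no
  participant-specific neutral calibration is applied.
* Single-person frames; no temporal smoothing (each frame is measured
  independently, as the save-button workflow implies).
* The ICC CI method is the standard F-based approximation; very small
  cohorts (n < 10) give wide, asymmetric intervals that the simulation
  checks do not exercise below n = 30.
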