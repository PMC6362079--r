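---
title: "Methods: simulating and analyzing camera effects on conjunctival redness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing camera effects on conjunctival redness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redcam)
```

## The problem

Objective quantification of bulbar conjunctival hyperaemia ("ocular
redness") from slit-lamp photographs is attractive for teleophthalmology,
but the pixel values a smartphone camera records are device-dependent:
sensor channel mixing, illuminant color casts, the slit lamp's inhomogeneous
light field and magnification-dependent optical color distortion all change
the recorded RGB of the same eye. Clinicians grading the same photographs
are largely immune to these factors — human color constancy keeps perceived
surface color stable under changing illumination — so objective and
subjective assessments can disagree for purely photometric reasons.

`redcam` rebuilds this comparison as a fully synthetic, ground-truthed
study: simulated eyes with a *known* vessel-coverage fraction are imaged
through parametric camera models under a factorial design (camera x
lighting x magnification x calibration arm), scored with four objective
redness metrics, graded by simulated clinicians, and analyzed with the
repeatability, agreement, correlation and repeated-measures ANOVA machinery
that a real study of this kind uses. Because the generator's parameters are
the ground truth, every processing stage can be tested against exact
expectations — something no real photographic dataset allows.

## The camera forward model

All synthesis and scoring happens in linear-light RGB in $[0,1]$; gamma is
an encoding applied at the camera boundary and inverted on load. A
`camera_profile` maps scene reflectance $s(x,y)$ to observed values

$$ o(x,y) = \mathrm{clip}\!\left( \big[ V(x,y)\, \ell \, G M \,
   s'(x,y) + \varepsilon \big]^{1/\gamma},\ 0,\ c \right) $$

where $s'$ is the reflectance after central crop-and-resample by the
relative magnification and a radial hue rotation, $M$ is an invertible
$3\times3$ channel-mixing matrix, $G = \mathrm{diag}(g_R, g_G, g_B)$ the
illuminant gains, $\ell$ the scalar lighting intensity, $V(x,y) = 1 -
v\,r(x,y)^2$ a radial vignette normalized to 1 at the image center
($r$ = radius normalized to 1 at the corners), $\varepsilon \sim
N(0, \sigma^2)$ additive sensor noise, and $c$ the clipping ceiling.

Choices worth stating:

* **Magnification** is a relative zoom $z \ge 1$: crop the central $1/z$
  of the field, then nearest-neighbour resample back to the original size.
  The rendered scene is defined as the field of view at the *lower*
  slit-lamp magnification, so the study's 6x/10x settings map to relative
  zooms $\{1, 10/6\}$. Nearest-neighbour resampling keeps $z = 1$ an exact
  no-op (the identity contract the tests assert) and introduces no new
  colors.
* **Peripheral color distortion** is a rotation of each pixel's color about
  the neutral axis by an angle proportional to $r$. The rotation preserves
  $R+G+B$; at higher magnification the same conjunctival features land at
  larger $r$, hence suffer more rotation — the mechanism by which
  magnification changes color, beyond the pure area effect.
* **Noise** is additive Gaussian per channel, truncated by the clip. No
  shot-noise term: the calibration-recovery tests only need a simple,
  seedable perturbation.
* The default profiles give the three cameras *common-signed* positive
  off-diagonal cross-talk in $M$, differing in amount per camera. This is
  the physically expected situation — spectral overlap of color filter
  arrays desaturates every device — and it is what gives the calibration
  factor a main effect: every uncalibrated camera is biased in the same
  direction relative to ground truth. Gains and scales are chosen so no
  channel of the default scenes clips. Sensor noise and vignetting are off
  by default; the low lighting level halves intensity and adds a warm cast.

## The synthetic scenes

An eye scene is a whitish sclera (default reflectance (0.92, 0.90, 0.86))
with a vessel network drawn as seeded random-walk polylines in a vessel red
(default (0.62, 0.15, 0.15)), until the drawn pixels cover the requested
fraction of the region of interest to within one pixel. The ROI mask
excludes an iris disc and eyelid bands by construction, standing in for the
manual cropping of clinical photographs. Tests never assert the absolute
sclera or vessel colors, only relations between metric values.

Per-subject redness is drawn once per subject — uniform on $[0.05, 0.6]$ by
default — and held fixed across all acquisition conditions, because the
factor structure of the analysis requires the same eye under every
condition. The range is a modelling choice: it spans visibly white to
moderately red eyes, wider than a healthy-only cohort would show, so that
correlations with grading are identifiable. Diseased-eye severity
distributions can be supplied via `study_design(redness_range = ...)`.

Simulated clinicians score $4t + b + e$ on the Efron scale (0 normal to 4
severe, 0.1 steps; grades are clamped and rounded), where $t$ is the true
vessel fraction, $b$ a rater bias and $e$ Gaussian grading noise. Grades
depend *only* on $t$ — never on camera, lighting, magnification or
calibration — which is the color-constancy emulation: the subjective arm of
the study is null by construction, up to grading noise. Default rater noise
standard deviations are 0.11, 0.22 and 0.27 (with biases 0, +0.1, -0.1),
chosen so the simulated within-subject repeatability matches values
reported for clinical graders of anterior-eye signs; the pipeline's
repeatability table recovers them.

## Calibration

Calibration follows the standard two-step chart procedure, once per
(camera, lighting) condition. From a photographed 24-patch chart:

1. **Patch measurement** averages each patch's interior (a 20% border
   margin discarded per side), excluding saturated pixels; a patch more
   than half saturated is flagged and excluded from fitting.
2. **White balance** scales channels by $g_c = \text{ref}_c /
   \text{meas}_c$ of the designated neutral patch.
3. **Color-correction matrix**: unweighted least squares for
   $\text{ref} = C\,(g \circ \text{meas})$ over unflagged patches (a
   $3\times4$ affine fit is available behind `affine_ccm`). The fit
   requires at least 4 (affine: 5) usable patches and a full-rank design.

For a noiseless linear camera the composition is an exact inverse: the
fitted $C$ equals $(GM)^{-1}$ up to the white-balance diagonal, and images
round-trip to machine precision. Vignetting is deliberately *not*
corrected — a single matrix cannot represent a spatially varying gain — and
this is what leaves residual post-calibration differences when the light
field varies.

One algebraic subtlety the test suite documents: if all cameras share the
same vignette and hue-distortion fields, least squares re-parameterizes
$C(GM)$ to the *same* optimum for every camera, so calibrated images are
identical across cameras and the between-camera residual is exactly zero.
Nonzero residuals require the light field to differ per device — which is
realistic, since each phone seats differently on the eyepiece — and the
imperfection test therefore uses per-camera vignette strengths. Under
strong vignetting the post-calibration spread of relative redness can even
exceed the pre-calibration spread (relative redness is intensity-invariant,
so vignetting barely perturbs the uncalibrated arm while biasing the fitted
matrix); and the red-hue fraction, being a count of band membership, can
absorb residuals smaller than its quantization step. The test asserts
reduction for all four metrics and nonzero residuals for the three
continuous ones.

## The four redness metrics

Over the $N$ included ROI pixels (mask AND all channels strictly below the
saturation threshold, default 0.99 linear $\approx$ 253/255):

| metric | definition | behavior |
|---|---|---|
| relative redness | $\sum R/(R+G+B)$ | a **sum**: proportional to ROI area |
| red–green difference | $\frac1N \sum (R-G)$ | scales with intensity |
| red–blue difference | $\frac1N \sum (R-B)$ | scales with intensity |
| red hue | fraction of pixels with defined HSL hue in $[330°,360)\cup[0°,30°]$ | bounded, intensity-invariant |

Relative redness is a sum rather than a mean so that it is directly
proportional to the conjunctival area considered — the documented reason
magnification alone increases it. The red-hue metric is operationalized as
a band fraction with a chroma floor (default 0.01) so gray pixels never
count as red; the band and floor are configuration options, since the
underlying literature does not pin the statistic down to one form.
Intensity invariance of relative redness and red hue holds as long as no
pixel's chroma crosses the floor; the property tests use images with
chroma comfortably above it.

## The statistics

* **Repeatability**: within-subject standard deviation
  $S_w = \sqrt{\sum_j\sum_k (x_{jk}-\bar x_j)^2 / \sum_j (k_j-1)}$, applied
  per rater over duplicate photographs of the same condition.
* **Agreement**: Bland–Altman limits $\bar d \pm 1.96\,s_d$ with t-based
  95% CIs $\mathrm{LoA} \pm t_{0.975,n-1}\, s_d \sqrt{3/n}$.
* **Correlation**: Pearson r (via `stats::cor.test`) between each metric
  and the first rater's grades, overall and grouped by arm x camera.
* **Repeated-measures ANOVA** (`rm_anova`): classical univariate
  decomposition for a fully balanced subjects x factors grid, one
  observation per cell (replicates averaged first — the analysis has four
  factors; replicate is not one of them). Every effect $E$ is tested
  against its own $E\times$subject stratum. Sums of squares come from
  marginal means via repeated centering (inclusion–exclusion), which is
  exact for balanced data: effect, error and subject SS add to the total
  SS to 1e-8, and the decomposition matches both `stats::aov` with `Error`
  strata and a brute-force cell-mean oracle in the tests. No sphericity
  correction is applied by default (`sphericity = "greenhouse-geisser"`
  adds epsilon-adjusted p-values). Degenerate strata get sentinels: zero
  effect SS gives F = 0, p = 1; a positive effect over a zero error
  stratum gives F = Inf, p = 0 (relative tolerance 1e-12 of the total SS).
* **Bonferroni pairwise**: paired t-tests on subject-level means, p
  multiplied by the number of pairs *within* the factor.
* **Clinician ANOVA**: the single-factor special case with image as the
  blocking unit.

With 4 subjects the error strata have very few degrees of freedom (3 for a
main effect of a 2-level factor), so main-effect significance is genuinely
marginal — the default run's calibration and lighting p-values land in the
0.002–0.04 range, and under other random subject draws they can cross 0.05.
This mirrors the power regime of a real 4-subject design and is reported
as-is rather than smoothed away.

## Problem sizes and determinism

Everything is a pure function of (parameters, seed); a master seed fans out
to per-stage, per-record seeds, so stages can be re-run in isolation and
whole runs are byte-deterministic. The default study uses 128 px scenes,
4 subjects x 24 cells x 2 arms = 192 records, and runs in a few seconds.
The test suite exercises coverage control over 50 seeded draws, loop-oracle
equivalence on 20 random 16 x 16 images, ANOVA oracle agreement on 25
seeded datasets, Type-I calibration on 500 pure-noise simulations, and the
full default run end-to-end.

## What passing tests do and do not show

The generator produces piecewise-constant scenes with exactly two tissue
colors, additive Gaussian noise and a quadratic vignette. Real conjunctival
photographs have specular highlights, depth-of-field blur, demosaicing
artifacts, JPEG compression and autofocus-driven tone mapping, none of
which are modelled; a calibration that is exact here is only approximate
there. The simulated graders implement perfect color constancy by
construction, so the null subjective result validates the *analysis
pathway*, not the perceptual claim itself. Results on synthetic data
characterize the correctness and statistical calibration of the pipeline —
not the clinical performance of any particular camera.
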