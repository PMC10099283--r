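---
title: "Models and methods behind tactoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tactoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactoscope)
```

This vignette is the package's own account of the science it
implements: the physical model of the tactile-imaging probe, the
numerical choices inside each module, the parameters that matter, and
what the synthetic data can and cannot show about the real instrument.

## The sensing principle

The probe is a four-layer elastic optical waveguide: three transparent
silicone (PDMS) layers of decreasing refractive index over a
borosilicate glass plate, surrounded by air, flooded edge-on by LED
light. Because every layer index exceeds that of air, light launched
inside the acceptance cone undergoes total internal reflection (TIR) at
both air faces and propagates losslessly. Pressing the probe against
tissue containing a stiff inclusion indents the top surface; the local
surface normal tilts, the incidence angle at the deformed patch drops
below the critical angle, and light escapes exactly there. A grayscale
camera below the glass records the escaped light: brighter and wider
patches mean stiffer, shallower, larger inclusions. The package models
this chain at three levels — wave optics for wavelength-scale stacks,
geometric optics for design angles, and ray tracing for the
millimetre-scale device — and then implements the image-side pipeline
that turns tactile frames into stiffness estimates and detection calls.

## Wave optics: the four-layer TE mode problem

For a stack with indices $n_1 > n_2 > n_3 > n_4 > n_0 = n_5 = 1$,
cumulative boundaries $a_1 < a_2 < a_3 < a_4$ and vacuum wave vector
$k_0 = 2\pi/\lambda$, a guided TE mode
$\mathbf{E}(x,z,t) = e(x)\,\hat{\jmath}\,e^{i(\omega t - \beta z)}$
satisfies $e'' + (k_0^2 n^2 - \beta^2)\,e = 0$ in every region. The
implemented ansatz is oscillatory in all four layers and evanescent
outside:

$$e(x) = e_0 e^{g_0 x}\ (x<0), \qquad e(x) = e_i \cos(k_i x + \varphi_i)
\ (a_{i-1} < x < a_i), \qquad e(x) = e_5 e^{g_5 (a_4 - x)}\ (x>a_4),$$

with $k_i^2 = k_0^2 n_i^2 - \beta^2$ and
$g_{0,5}^2 = \beta^2 - k_0^2 n_{0,5}^2$. This restricts the admissible
propagation constants to $k_0 n_0 < \beta < k_0 n_4$; modes that are
evanescent in an inner layer exist physically (up to $\beta < k_0 n_1$)
but are outside the model — a documented limitation, not an error
(`dispersionResidual()` refuses $\beta$ outside the window by naming
the violated bound).

The longitudinal magnetic amplitude is proportional to $e'(x)$, so
matching the impedance $h/e$ at the five boundaries chains the phases,

$$\varphi_1 = -\arctan(g_0/k_1), \qquad
\varphi_{i+1} = \arctan\!\big[(k_i/k_{i+1})\tan(k_i a_i + \varphi_i)\big]
- k_{i+1} a_i,$$

and leaves one scalar condition at the top surface,
$k_4 \tan(k_4 a_4 + \varphi_4) = g_5$. `dispersionResidual()` returns
the mismatch $k_4\tan(k_4 a_4 + \varphi_4) - g_5$; its zeros are the
guided modes. Amplitudes follow from continuity of $e$ with $e_0 = 1$:
$e_1 = e_0/\cos\varphi_1$ and
$e_{i+1} = e_i \cos(k_i a_i + \varphi_i)/\cos(k_{i+1} a_i + \varphi_{i+1})$.

### Numerical choices

* **Branch handling.** The residual is invariant under
  $\varphi \mapsto \varphi + m\pi$, so the principal arctan branch is
  fine for *evaluating* it — but root *searching* on the raw residual is
  treacherous: the outer tangent has poles, and near the oscillatory
  cutoff a root can hide between a pole and the interval edge.
  `findModes()` therefore works with the phase mismatch
  $\Phi(\beta) = (k_4 a_4 + \varphi_4) - \arctan(g_5/k_4)$, whose only
  discontinuities are exact $\pm\pi$ branch jumps. Unwrapping those on a
  grid makes $\Phi$ continuous and pole-free; guided modes are exactly
  its crossings of integer multiples of $\pi$.
* **Grid.** 2000 uniform points by default (the unwrap needs the true
  phase change per cell below $\pi/2$, roughly `gridPoints` $> k_0 a_4$,
  so 2000 covers stacks hundreds of wavelengths thick), plus a
  geometric refinement towards $\beta \to k_0 n_4$ where
  $\arctan(g_5/k_4)$ varies with divergent slope and a uniform grid can
  gain or lose a near-cutoff mode.
* **Refinement.** Bisection to an absolute $\beta$ tolerance of
  $10^{-10} k_0$ — immune to the steep derivatives near cutoff where
  Newton steps are unreliable.
* **Degenerate limits.** At $\beta = k_0 n_4$ exactly, $k_4 \to 0$ but
  the tangent argument passes $\pm\pi/2$, so
  $k_4\tan(\cdot)$ tends to a finite $O(1/h_4)$ value rather than 0;
  the residual stays bounded away from zero and no mode sits on the
  boundary. With symmetric air cladding the fundamental mode has no
  thickness cutoff, so a valid stack always guides at least one mode.
* **Conventions.** Time dependence harmonised to
  $e^{i(\omega t - \beta z)}$; lossless media (extinction $k = 0$); TE
  only — the instrument's analysis never uses TM.

The solver is validated against an independent transfer-matrix solver
(propagating $(e, e')$ through the layers) on dozens of random
wavelength-scale stacks to $10^{-6}$ relative in $\beta$, and against
the closed-form symmetric-slab dispersion relation in the degenerate
limit where all four inner indices coincide.

## Geometric optics: acceptance angles and the LED cone

For the millimetre-thick device, rays replace modes. Along a Snell
chain $n_i \sin\theta_i = \text{const}$, TIR at the air faces holds iff
the invariant exceeds 1; the acceptance angle of a layer of index $n$
is $\theta = \arcsin\sqrt{n^2 - 1}$ (measured from the end-face
normal), and the widest safe LED radiation cone is twice the smallest
per-layer acceptance angle. Angles are computed in full precision; the
device report's printed values truncate at two decimals (e.g.
$71.9897^\circ \to 71.98$) and double *after* truncating
($2 \times 71.98 = 143.96$), so `printedAngle()` reproduces that
display convention exactly while `ledCone()` stays full-precision. At
exactly the critical angle the ray is treated as refracted — a strict
inequality tie-break, applied consistently in `tirDecision()` and the
ray tracer. Angles are always measured from the interface normal; the
complement $\gamma = 90^\circ - \theta$ is reported alongside in
`snellChain()`.

## Ray tracing the deformed guide

`traceRay()` advances a ray through a 2D side view: $z$ along the
100 mm guide, $x$ depth below the undeformed surface, layers at
cumulative boundaries 6/15/30/33 mm (the physical 6/9/15 mm PDMS
stack over a 3 mm glass plate). At internal boundaries Snell refraction
is applied (rays that would become evanescent reflect specularly — the
TIR logic continued); at the air faces the binary TIR rule decides
between a specular bounce and escape with the ray's full unit power (no
Fresnel partial reflections, matching the instrument's sensing
description). The indentation is a raised-cosine bump
$\delta(z) = d\,(\tfrac12 + \tfrac12\cos(2\pi(z - c)/w))$ on
$|z - c| \le w/2$ — the simplest profile with continuous normals; the
surface intersection is found by sampling the signed distance along the
segment and polishing with `uniroot`. Launches are a deterministic
uniform fan (reproducibility without seeds; a seeded random fan sits
behind the `random` flag), from the left edge at mid-depth by default.
The bounce limit is 10 000, with truncated power tallied, and the power
budget closes exactly: launched = end-exits + top-scatter +
bottom-scatter + truncated.

Two structural facts the tests lean on: with zero indentation and an
in-cone fan the scattered power is *exactly* zero, and any effective
indentation scatters power localized within one bump width of its
centre. Note the binary model's threshold behaviour: a bump scatters
only once its maximum slope can push some ray's incidence below
critical, so very shallow bumps (slope a few degrees) deflect rays
without surface escape — consistent with the model, and the reason the
monotonicity claim is "never decreases", not "strictly increases".

## The synthetic phantom generator

No deposited images exist, so the generator *is* the study-conditions
module. It emulates the reference phantom series: gelatin blocks 40 mm
thick, background stiffness 50 kPa, inclusion 5 mm deep and 12 mm wide
by default, with the three experimental series varying elasticity
(110/80/50 kPa), depth (3/5/7 mm) and size (8/12 mm). A frame is

$$I(x,y) = B + A\,e^{-r^2/2\sigma^2} + \varepsilon, \qquad
A = g\,(E - E_{bg})\,e^{-d/d_0}\,(s/s_0), \qquad
\sigma = s/2 + 0.6\,d\ \text{[mm]},$$

the bell shape brightest at the centre of the deformation area.
Defaults: background gray $B = 30$, gain $g = 6$ gray/kPa, depth decay
$d_0 = 4$ mm, size reference $s_0 = 12$ mm, Gaussian read noise of 2
gray levels, camera 656×492 at 8 bits, and 10 px/mm optical
magnification (a single config key — the instrument's true
magnification is unpublished). This is the simplest forward model that
satisfies every ordering the experiments report: centre intensity
strictly increasing in elasticity, strictly decreasing in depth, and
integrated signal strictly increasing in size. The size factor $s/s_0$
in the amplitude is a deliberate design choice: the measured peak
stiffness roughly doubles from the 8 mm to the 12 mm inclusion, and a
size-independent amplitude cannot reproduce that (the top-fraction mean
of a pure Gaussian blob is scale-invariant in $\sigma$), so larger
contact area is modelled as proportionally stronger scattering. The
gain is set so the 110 kPa reference phantom spans most of the 8-bit
range at 5 mm depth without clipping.

What the generator does *not* emulate: gelatin contact mechanics,
speckle and vignetting, surface-coupling variability between
self-tests, and the device's physical gray-to-kPa calibration. Passing
tests therefore demonstrate the pipeline's correctness and the
orderings' reproducibility, not field performance on real tissue.

## Image analysis

* **Calibration.** An affine gray→kPa map anchored on two noise-free
  generator fixtures: nodule-free background ↔ 50 kPa, and the 110 kPa
  reference phantom's centre ↔ 110 kPa. The instrument's device-bound
  calibration is unavailable; this stands in for it transparently.
* **Elasticity surface.** Gaussian smoothing ($\sigma = 2$ px),
  pixel-wise calibration, then the peak statistic: the mean of the top
  1 % of pixels inside the largest 8-connected above-background region
  (background = calibrated median, margin 2 kPa). "Peak = top-1 % mean"
  operationalises the report's "highest average", which never states an
  averaging window; 1 % balances noise suppression against bias, and
  the choice is pinned by a closed-form test (disk mean of a Gaussian
  cap). An image with nothing above background reports the calibrated
  background, flagged.
* **Fuzzy binarization.** The named thresholding approach is
  implemented as fuzzy-entropy minimisation: for each candidate
  threshold the two class means $m_0, m_1$ are computed, each pixel's
  membership is $1/(1 + |x - m|/C)$ with $C$ the gray range, and the
  summed binary Shannon entropy is minimised by exhaustive search over
  the observed levels — deterministic and brute-force verifiable. The
  reported threshold is the midpoint between the two adjacent levels,
  so no pixel ever sits on the class boundary; constant images are
  rejected by name.
* **Segmentation.** Ordered stages: binarize → morphological opening
  then closing (disk radius 3 px; the report names the operations but
  not the sizes) → hole filling → removal of border-touching components
  → minimum-area filter (25 px) → contour tracing. Components are
  labelled 8-connected (a diagonal-merge pass on top of the 4-connected
  labeller), contours are closed pixel loops, and coordinates are
  1-based row/column with origin top-left, the R convention. The
  pipeline is idempotent on its own mask for smooth blobs.
* **Detection.** Score = peak statistic restricted to the surviving
  regions; background when nothing survives; positive iff score
  *strictly* exceeds the threshold. The default threshold of 55 kPa
  sits midway between the 50 kPa normal-tissue background and the
  weakest inclusion response the generator produces (~60 kPa for an
  80 kPa inclusion at 7 mm depth and 8 mm size), derived from the
  forward model, not fitted.

## Evaluation

`scoreCohort()` tabulates the confusion matrix at an operating point
with exact integer arithmetic; undefined rates in single-class cohorts
are reported as NA, never 0. `rocSweep()` sweeps the threshold over the
observed score range, always includes the (0,0) and (1,1) endpoints,
and reports both the trapezoid AUC and the exact Mann–Whitney
concordance AUC (ties counted one half); the two agree to within the
sweep discretization. The cohort evaluation emulates the study's 80
self-tests as 40 positives (elasticity, depth and size drawn uniformly
from the experimental ranges 80–110 kPa, 3–7 mm, 8–12 mm) and 40
nodule-free negatives — the study never states its composition, so an
even split is assumed. The instrument's published 95 % sensitivity /
97 % specificity came from real self-tests that are not available; the
synthetic cohort verifies that the pipeline reaches that operating
point under the emulated conditions, which on this forward model it
does with full separation. The study's compound definition of a "true
position" (pairs of depth/elasticity/size being "correct") is ambiguous
as printed; detection here is plain presence/absence, and that
divergence is deliberate and documented.

## Problem sizes and runtimes

The suite solves ~60 wavelength-scale stacks against the
transfer-matrix oracle (heights 0.5–4 µm, indices 1.2–1.5, tens of
modes each), traces fans of up to 721 rays on the 100 mm guide, and
evaluates one 80-frame cohort at the full 656×492 camera resolution —
about two minutes end to end on one core. These sizes were chosen as
the smallest that exercise every claim; all of them scale up linearly
if heavier validation is wanted.

## Known limitations

TM polarisation, lossy media, Fresnel partial reflections, diffraction
at the indentation, 3D ray tracing, and malignant-vs-benign grading are
out of scope. Mode solving covers only the all-oscillatory window
$\beta < k_0 n_4$. The mode spectrum depends on the chosen design
wavelength (default 0.55 µm, the centre of the visible band — the
LED's spectrum is broadband and unpublished), so quantitative spectra
are validated only against the internal oracle. Whether the printed
per-layer angles are in-layer confinement angles or in-air launch
angles is not stated in the device report; the implementation
reproduces the printed arithmetic exactly and leaves the
interpretation open.
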