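# tactoscope

Computational core of a total-internal-reflection (TIR) tactile-sensation
imaging system for stiffness-based screening of thyroid nodules.

## The problem and the instrument

Malignant tissue is typically stiffer than the normal tissue around it.
The instrument this package models turns that contrast into an image
without radiation or an expert operator: a four-layer elastic optical
waveguide — three transparent silicone (PDMS) layers of decreasing
refractive index over a borosilicate glass plate — is flooded edge-on
with LED light. While the surface is undeformed, every in-cone ray is
totally internally reflected and no light leaves the guide. Pressing the
probe against tissue containing a stiff inclusion indents the surface,
tilts the local surface normal past the critical angle and lets light
escape exactly where the deformation is. A grayscale camera under the
glass records the escaped light as a *tactile image*: a bell-shaped
bright patch whose amplitude and extent encode the inclusion's stiffness,
depth and size.

The package implements, end to end:

* **Waveguide physics.** Guided TE modes of the four-layer slab. With
  layer indices n1 > n2 > n3 > n4 > n0 = n5 = 1, transverse wave vectors
  k_i = sqrt(k0²n_i² − β²) inside and decay constants
  g = sqrt(β² − k0²) outside, the field ansatz
  e(x) = e_i·cos(k_i·x + φ_i) per layer (exponential tails outside) and
  impedance continuity of h(x)/e(x) ∝ e′(x)/e(x) at the five boundaries
  chain the phases φ_1..φ_4 and leave one scalar dispersion condition
  k4·tan(k4·a4 + φ4) = g5 whose roots β are the guided modes
  (`dispersionResidual()`, `findModes()`, `fieldProfile()`).
* **Geometric optics.** Snell chains, per-layer acceptance angles
  θ_i = asin(√(n_i² − 1)), the TIR decision rule, and the widest LED
  injection cone 2·min_i θ_i (`acceptanceAngle()`, `ledCone()`,
  `snellChain()`, `tirDecision()`).
* **Ray tracing.** A 2D side-view tracer of the millimetre-scale guide:
  specular bouncing under the binary TIR rule, a smooth cosine surface
  indentation, and the scattered-light exit profile along the surface
  (`traceRay()`, `surfaceScatterProfile()`).
* **Synthetic phantoms.** A camera-model generator of tactile images of
  gelatin tissue phantoms, I(r) = B + A·exp(−r²/2σ²) + noise, with
  amplitude increasing in inclusion stiffness and size and decreasing in
  depth (`generateImage()`, `generateCohort()`).
* **Image analysis.** Fuzzy-entropy binarization, morphological nodule
  extraction with contour tracing, calibrated 3D elasticity surfaces
  with peak-stiffness (top-1 % mean) estimation, and presence/absence
  detection (`fuzzyBinarize()`, `extractNodules()`,
  `elasticitySurface()`, `detectNodule()`).
* **Evaluation.** Confusion matrices, sensitivity/specificity and ROC
  curves with both trapezoid and exact concordance AUC on labelled
  cohorts (`scoreCohort()`, `rocSweep()`).

## Worked example

```r
library(tactoscope)

## acceptance angles of the device stack (printed_deg uses the device
## report's truncating two-decimal convention)
stack <- layerStack(1.41, 1.40, 1.39, 1.38, heights = rep(2, 4))
acceptanceTable(stack)
#>  layer    n acceptance_deg printed_deg
#>      1 1.41       83.73731       83.73
#>      2 1.40       78.46304       78.46
#>      3 1.39       74.89574       74.89
#>      4 1.38       71.98943       71.98
attr(acceptanceTable(stack), "ledConePrinted")
#> [1] 143.96     # an LED cone narrower than this stays confined in every layer

## guided modes of the wavelength-scale stack at 550 nm
length(findModes(stack, waveParams(0.55)))
#> [1] 24

## ray-traced scattering: a 0.5 mm indentation on the mm-scale guide
geom <- waveguideGeometry()          # 6/9/15 mm PDMS + 3 mm glass
prof <- surfaceScatterProfile(geom, indentation(25, 0.5, 3),
                              nRays = 361, fan = c(-40, 40))
attr(prof, "power")
#>  launched  exit_end  scattered_top  scattered_bottom  truncated
#>       361       350              9                 2          0
## with depth 0 every one of the 361 rays reaches the far end: the
## undeformed guide scatters exactly nothing

## synthetic phantom -> detection
img <- generateImage(phantomSpec(110, depth = 5, size = 12),
                     cameraModel(), seed = 7)
detectNodule(img, defaultCalibration())
#> DetectionOutcome: POSITIVE (score 109.5 kPa, threshold 55 kPa)
```

The detection score is the mean of the top 1 % of calibrated pixels
inside the segmented nodule region — here 109.5 kPa for a 110 kPa
inclusion; a nodule-free phantom scores at the 50 kPa background and is
called negative.

A command-line wrapper over the same functions ships at
`inst/scripts/tactoscope.R` (subcommands `modes`, `angles`, `trace`,
`phantom`, `cohort`, `analyze`, `evaluate`).

## Scope notes

Only the TE polarisation of the mode problem is implemented, media are
lossless, and reflection in the ray tracer is binary (no Fresnel
partial reflections) — matching the instrument's sensing description.
The synthetic cohort emulates the study design (40 positive / 40
negative self-tests); the physical device's measured rates are not
reproducible without its raw data. See `vignettes/tactile-imaging.Rmd`
for the full model account, parameter defaults and limitations.
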