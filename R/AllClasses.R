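#' @import methods
#' @importFrom stats rnorm runif setNames uniroot
NULL

## ---------------------------------------------------------------------------
## Waveguide physics containers
## ---------------------------------------------------------------------------

#' Four-layer slab waveguide stack
#'
#' Describes the layered elastic optical waveguide: three silicone (PDMS)
#' layers and one glass plate, surrounded by air. Layer 1 is the contact
#' surface layer; indices must decrease monotonically towards the glass so
#' that every layer supports total internal reflection against air.
#'
#' @slot n numeric(6), refractive indices \code{n0..n5}; \code{n0} and
#'   \code{n5} are the surrounding medium (air, 1 by default).
#' @slot h numeric(4), layer heights (any consistent length unit).
#' @slot a numeric(4), cumulative boundary positions \code{a_i = sum(h_1..h_i)}.
#' @exportClass LayerStack
setClass("LayerStack",
  representation(n = "numeric", h = "numeric", a = "numeric"))

setValidity("LayerStack", function(object) {
  msg <- character()
  if (length(object@n) != 6L) msg <- c(msg, "n must hold n0..n5 (length 6)")
  if (length(object@h) != 4L) msg <- c(msg, "h must hold h1..h4 (length 4)")
  if (length(object@a) != 4L) msg <- c(msg, "a must hold a1..a4 (length 4)")
  if (!length(msg)) {
    n <- object@n
    if (any(object@h <= 0)) msg <- c(msg, "all layer heights must be > 0")
    if (any(diff(object@a) <= 0)) msg <- c(msg, "boundaries a1..a4 must increase")
    if (max(abs(object@a - cumsum(object@h))) > 1e-9 * max(object@a))
      msg <- c(msg, "a must equal cumsum(h)")
    if (!(n[2] > n[3] && n[3] > n[4] && n[4] > n[5]))
      msg <- c(msg, "inner indices must satisfy n1 > n2 > n3 > n4")
    if (!(n[5] > n[1]) || !(n[5] > n[6]))
      msg <- c(msg, "n4 must exceed the surrounding indices n0 and n5")
    if (abs(n[1] - n[6]) > 1e-12)
      msg <- c(msg, "surrounding indices n0 and n5 must be equal")
  }
  if (length(msg)) msg else TRUE
})

#' Monochromatic wave parameters
#'
#' @slot wavelength vacuum wavelength (same length unit as the stack).
#' @slot k0 vacuum wave vector, \code{2*pi/wavelength}.
#' @slot omega angular frequency \code{k0*c} (SI, rad/s, assuming wavelength
#'   in micrometres unless stated otherwise by the caller; only the ratio
#'   \code{omega/k0} ever enters the field formulas).
#' @exportClass WaveParams
setClass("WaveParams",
  representation(wavelength = "numeric", k0 = "numeric", omega = "numeric"))

setValidity("WaveParams", function(object) {
  if (object@wavelength <= 0) return("wavelength must be > 0")
  if (abs(object@k0 - 2 * pi / object@wavelength) > 1e-9 * object@k0)
    return("k0 must equal 2*pi/wavelength")
  TRUE
})

#' One guided TE mode of a layer stack
#'
#' @slot beta propagation constant (1/length unit of the stack).
#' @slot kLayer numeric(6): the outer decay constants (regions 0 and 5) and
#'   the transverse wave vectors \code{k1..k4} of the oscillatory layers.
#' @slot phi numeric(4), phases of the cosine ansatz in layers 1..4 (rad).
#' @slot amp numeric(6), field amplitudes \code{e0..e5}, \code{e0 = 1}.
#' @slot residual absolute dispersion residual at \code{beta}.
#' @exportClass ModeSolution
setClass("ModeSolution",
  representation(beta = "numeric", kLayer = "numeric", phi = "numeric",
                 amp = "numeric", residual = "numeric"))

## ---------------------------------------------------------------------------
## Ray tracing containers
## ---------------------------------------------------------------------------

#' Millimetre-scale waveguide geometry for ray tracing
#'
#' Side view: z runs along the guide (0..length), x is depth below the
#' undeformed top surface (0 at the contact surface, a4 at the glass
#' bottom). Layers 1..4 occupy (0,a1), (a1,a2), (a2,a3), (a3,a4).
#'
#' @slot length guide length along z (mm).
#' @slot boundaries numeric(4), cumulative layer boundaries a1..a4 (mm).
#' @slot indices numeric(6), refractive indices n0..n5.
#' @exportClass WaveguideGeometry
setClass("WaveguideGeometry",
  representation(length = "numeric", boundaries = "numeric", indices = "numeric"))

setValidity("WaveguideGeometry", function(object) {
  msg <- character()
  if (object@length <= 0) msg <- c(msg, "guide length must be > 0")
  if (length(object@boundaries) != 4L || any(diff(object@boundaries) <= 0) ||
      object@boundaries[1] <= 0)
    msg <- c(msg, "boundaries must be 4 strictly increasing positive values")
  if (length(object@indices) != 6L || any(object@indices < 1))
    msg <- c(msg, "indices must hold n0..n5, all >= 1")
  if (length(msg)) msg else TRUE
})

#' Surface indentation (contact deformation)
#'
#' A smooth cosine bump pressed into the top surface: displacement
#' \code{depth * (0.5 + 0.5*cos(2*pi*(z - centerZ)/width))} for
#' \code{|z - centerZ| <= width/2}, zero elsewhere. \code{depth = 0} is the
#' undeformed surface.
#'
#' @slot centerZ bump centre along the guide (mm).
#' @slot depth maximum surface displacement (mm), >= 0.
#' @slot width lateral extent (mm), > 0.
#' @slot profile shape identifier (only \code{"cosine"} implemented).
#' @exportClass Indentation
setClass("Indentation",
  representation(centerZ = "numeric", depth = "numeric", width = "numeric",
                 profile = "character"))

setValidity("Indentation", function(object) {
  msg <- character()
  if (object@depth < 0) msg <- c(msg, "depth must be >= 0")
  if (object@width <= 0) msg <- c(msg, "width must be > 0")
  if (!identical(object@profile, "cosine"))
    msg <- c(msg, "only the 'cosine' profile is implemented")
  if (length(msg)) msg else TRUE
})

#' One traced ray
#'
#' @slot launchAngle launch angle from the guide axis (degrees).
#' @slot segments numeric matrix with columns z0, x0, z1, x1 (mm), one row
#'   per straight segment, contiguous.
#' @slot terminatedBy one of \code{"exit_end"}, \code{"scattered"},
#'   \code{"absorbed_bounce_limit"}.
#' @slot scatterPoint z position where the ray escaped through a guide
#'   surface (mm), \code{NA} unless \code{terminatedBy == "scattered"}.
#' @slot scatterIntensity escaped fraction of the ray's unit power (0 or 1
#'   in the binary TIR model).
#' @slot scatterBoundary \code{"top"}, \code{"bottom"} or \code{NA}.
#' @exportClass RayPath
setClass("RayPath",
  representation(launchAngle = "numeric", segments = "matrix",
                 terminatedBy = "character", scatterPoint = "numeric",
                 scatterIntensity = "numeric", scatterBoundary = "character"))

setValidity("RayPath", function(object) {
  msg <- character()
  if (!object@terminatedBy %in% c("exit_end", "scattered", "absorbed_bounce_limit"))
    msg <- c(msg, "unknown terminatedBy value")
  if (object@terminatedBy == "scattered" && is.na(object@scatterPoint))
    msg <- c(msg, "scattered ray must carry a scatterPoint")
  if (object@terminatedBy != "scattered" && !is.na(object@scatterPoint))
    msg <- c(msg, "scatterPoint present only for scattered rays")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Phantom / imaging containers
## ---------------------------------------------------------------------------

#' Tissue-phantom specification
#'
#' @slot elasticity inclusion stiffness (kPa).
#' @slot depth inclusion depth below the phantom top surface (mm).
#' @slot size inclusion diameter (mm).
#' @slot phantomThickness phantom thickness (mm).
#' @slot backgroundElasticity surrounding (normal tissue) stiffness (kPa).
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(elasticity = "numeric", depth = "numeric", size = "numeric",
                 phantomThickness = "numeric", backgroundElasticity = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@elasticity <= 0) msg <- c(msg, "elasticity must be > 0 kPa")
  if (object@size <= 0) msg <- c(msg, "size must be > 0 mm")
  if (object@depth <= 0 || object@depth >= object@phantomThickness)
    msg <- c(msg, "depth must lie strictly inside (0, phantomThickness)")
  if (object@backgroundElasticity <= 0)
    msg <- c(msg, "backgroundElasticity must be > 0 kPa")
  if (length(msg)) msg else TRUE
})

#' Camera model for synthetic frames
#'
#' @slot width,height sensor size in pixels.
#' @slot pixelPitch sensor pixel pitch (micrometres).
#' @slot bitDepth 8 or 16.
#' @slot noiseSigma additive Gaussian read-noise standard deviation
#'   (gray levels).
#' @slot pxPerMm optical magnification at the waveguide surface
#'   (pixels per mm); the single place where mm convert to pixels.
#' @exportClass CameraModel
setClass("CameraModel",
  representation(width = "integer", height = "integer", pixelPitch = "numeric",
                 bitDepth = "integer", noiseSigma = "numeric",
                 pxPerMm = "numeric"))

setValidity("CameraModel", function(object) {
  msg <- character()
  if (object@width <= 0L || object@height <= 0L)
    msg <- c(msg, "width and height must be positive")
  if (!object@bitDepth %in% c(8L, 16L)) msg <- c(msg, "bitDepth must be 8 or 16")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@pxPerMm <= 0) msg <- c(msg, "pxPerMm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Grayscale tactile frame
#'
#' Pixels are stored as a numeric matrix with \code{nrow = height} (rows are
#' image rows, origin top-left, 1-based indices as usual in R).
#'
#' @slot pixels numeric matrix of integer gray levels.
#' @slot pitch physical size of one pixel at the object plane (micrometres).
#' @slot meta list of generation parameters (including the seed) or empty
#'   for images read from disk.
#' @exportClass TactileImage
setClass("TactileImage",
  representation(pixels = "matrix", pitch = "numeric", meta = "list"))

setValidity("TactileImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels)) msg <- c(msg, "pixels must be numeric")
  if (any(!is.finite(object@pixels))) msg <- c(msg, "pixels must be finite")
  bd <- object@meta$bitDepth
  if (!is.null(bd) && (min(object@pixels) < 0 || max(object@pixels) > 2^bd - 1))
    msg <- c(msg, "pixel values outside bit-depth range")
  if (length(msg)) msg else TRUE
})

#' Affine gray-level to stiffness calibration
#'
#' @slot slope kPa per gray level (> 0).
#' @slot intercept kPa at gray level zero.
#' @exportClass Calibration
setClass("Calibration",
  representation(slope = "numeric", intercept = "numeric"))

setValidity("Calibration", function(object)
  if (object@slope <= 0) "calibration slope must be > 0" else TRUE)

#' Calibrated elasticity surface
#'
#' @slot surface matrix of estimated stiffness (kPa), same shape as the
#'   source image.
#' @slot calibration the \linkS4class{Calibration} used.
#' @slot peakKpa peak statistic: mean of the top 1\% of pixels inside the
#'   largest connected above-background region.
#' @slot emptyRegion TRUE when no pixel rose above background and
#'   \code{peakKpa} fell back to the calibrated background.
#' @exportClass ElasticityMap
setClass("ElasticityMap",
  representation(surface = "matrix", calibration = "Calibration",
                 peakKpa = "numeric", emptyRegion = "logical"))

#' Nodule segmentation result
#'
#' @slot mask binary (0/1) matrix, same shape as the input image.
#' @slot regions data.frame: label, area (px), centroidRow, centroidCol,
#'   bboxRowMin/RowMax/ColMin/ColMax, aspectRatio (height/width of the
#'   bounding box).
#' @slot contours list of closed contour matrices (columns row, col),
#'   one per region, in region label order.
#' @slot thresholdUsed gray level selected by fuzzy binarization.
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(mask = "matrix", regions = "data.frame", contours = "list",
                 thresholdUsed = "numeric"))

#' Presence / absence detection outcome
#'
#' @slot isPositive TRUE when the score exceeds the decision threshold
#'   (strict inequality; a tie scores negative).
#' @slot score continuous detection statistic (peak stiffness, kPa).
#' @slot threshold the decision threshold used (kPa).
#' @exportClass DetectionOutcome
setClass("DetectionOutcome",
  representation(isPositive = "logical", score = "numeric",
                 threshold = "numeric"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "LayerStack", function(object) {
  cat("LayerStack: 4 layers + surrounding medium\n")
  cat(sprintf("  n0=%.4g | n1=%.4g n2=%.4g n3=%.4g n4=%.4g | n5=%.4g\n",
              object@n[1], object@n[2], object@n[3], object@n[4],
              object@n[5], object@n[6]))
  cat(sprintf("  heights: %s (boundaries at %s)\n",
              paste(signif(object@h, 4), collapse = ", "),
              paste(signif(object@a, 4), collapse = ", ")))
})

setMethod("show", "ModeSolution", function(object) {
  cat(sprintf("ModeSolution: beta=%.8g  residual=%.3g\n",
              object@beta, object@residual))
  cat(sprintf("  k: [%s]\n", paste(signif(object@kLayer, 6), collapse = ", ")))
  cat(sprintf("  phi: [%s]  e: [%s]\n",
              paste(signif(object@phi, 6), collapse = ", "),
              paste(signif(object@amp, 4), collapse = ", ")))
})

setMethod("show", "TactileImage", function(object) {
  p <- object@pixels
  cat(sprintf("TactileImage: %d x %d px, pitch %.3g um, gray [%d, %d]\n",
              nrow(p), ncol(p), object@pitch, min(p), max(p)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: inclusion %.4g kPa, depth %.4g mm, size %.4g mm (background %.4g kPa, thickness %.4g mm)\n",
    object@elasticity, object@depth, object@size,
    object@backgroundElasticity, object@phantomThickness))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d region(s), threshold %.4g\n",
              nrow(object@regions), object@thresholdUsed))
  if (nrow(object@regions)) print(object@regions)
})

setMethod("show", "ElasticityMap", function(object) {
  cat(sprintf("ElasticityMap: %d x %d, peak %.4g kPa%s\n",
              nrow(object@surface), ncol(object@surface), object@peakKpa,
              if (object@emptyRegion) " (no above-background region)" else ""))
})

setMethod("show", "DetectionOutcome", function(object) {
  cat(sprintf("DetectionOutcome: %s (score %.4g kPa, threshold %.4g kPa)\n",
              if (object@isPositive) "POSITIVE" else "negative",
              object@score, object@threshold))
})
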