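## Accessor generics and methods. Slot access from user code should go
## through these, never through @.

#' Refractive indices of a stack or geometry
#'
#' @param x a \linkS4class{LayerStack} or \linkS4class{WaveguideGeometry}.
#' @return numeric(6), indices n0..n5 (named).
#' @export
setGeneric("refractiveIndices", function(x) standardGeneric("refractiveIndices"))

#' @rdname refractiveIndices
#' @export
setMethod("refractiveIndices", "LayerStack", function(x)
  setNames(x@n, c("n0", "n1", "n2", "n3", "n4", "n5")))

#' @rdname refractiveIndices
#' @export
setMethod("refractiveIndices", "WaveguideGeometry", function(x)
  setNames(x@indices, c("n0", "n1", "n2", "n3", "n4", "n5")))

#' Layer boundary positions
#'
#' @param x a \linkS4class{LayerStack} or \linkS4class{WaveguideGeometry}.
#' @return numeric(4), cumulative boundaries a1..a4.
#' @export
setGeneric("layerBoundaries", function(x) standardGeneric("layerBoundaries"))

#' @rdname layerBoundaries
#' @export
setMethod("layerBoundaries", "LayerStack", function(x)
  setNames(x@a, c("a1", "a2", "a3", "a4")))

#' @rdname layerBoundaries
#' @export
setMethod("layerBoundaries", "WaveguideGeometry", function(x)
  setNames(x@boundaries, c("a1", "a2", "a3", "a4")))

#' Layer heights of a stack
#' @param x a \linkS4class{LayerStack}.
#' @return numeric(4), heights h1..h4.
#' @export
layerHeights <- function(x) {
  stopifnot(is(x, "LayerStack"))
  setNames(x@h, c("h1", "h2", "h3", "h4"))
}

#' Propagation constant of a mode
#' @param x a \linkS4class{ModeSolution}.
#' @return numeric scalar beta.
#' @export
propagationConstant <- function(x) {
  stopifnot(is(x, "ModeSolution"))
  x@beta
}

#' Pixel matrix of a tactile image
#' @param x a \linkS4class{TactileImage}.
#' @return numeric matrix of gray levels (rows = image rows).
#' @export
imagePixels <- function(x) {
  stopifnot(is(x, "TactileImage"))
  x@pixels
}

#' Physical pixel pitch of a tactile image
#' @param x a \linkS4class{TactileImage}.
#' @return micrometres per pixel at the object plane.
#' @export
imagePitch <- function(x) {
  stopifnot(is(x, "TactileImage"))
  x@pitch
}

#' Generation metadata of a tactile image
#' @param x a \linkS4class{TactileImage}.
#' @return list of generation parameters (possibly empty).
#' @export
imageMeta <- function(x) {
  stopifnot(is(x, "TactileImage"))
  x@meta
}

#' Peak stiffness of an elasticity map
#' @param x an \linkS4class{ElasticityMap}.
#' @return peak statistic in kPa.
#' @export
peakKpa <- function(x) {
  stopifnot(is(x, "ElasticityMap"))
  x@peakKpa
}

#' Calibrated stiffness surface
#' @param x an \linkS4class{ElasticityMap}.
#' @return matrix of kPa values.
#' @export
elasticityValues <- function(x) {
  stopifnot(is(x, "ElasticityMap"))
  x@surface
}

#' Segmentation mask
#' @param x a \linkS4class{SegmentationResult}.
#' @return binary 0/1 matrix.
#' @export
segmentationMask <- function(x) {
  stopifnot(is(x, "SegmentationResult"))
  x@mask
}

#' Segmented region feature table
#' @param x a \linkS4class{SegmentationResult}.
#' @return data.frame of per-region features.
#' @export
segmentedRegions <- function(x) {
  stopifnot(is(x, "SegmentationResult"))
  x@regions
}

#' Region contours
#' @param x a \linkS4class{SegmentationResult}.
#' @return list of closed contour matrices (columns row, col).
#' @export
regionContours <- function(x) {
  stopifnot(is(x, "SegmentationResult"))
  x@contours
}

#' Detection score
#' @param x a \linkS4class{DetectionOutcome}.
#' @return detection statistic in kPa.
#' @export
detectionScore <- function(x) {
  stopifnot(is(x, "DetectionOutcome"))
  x@score
}

#' Detection decision
#' @param x a \linkS4class{DetectionOutcome}.
#' @return TRUE for a positive call.
#' @export
isPositive <- function(x) {
  stopifnot(is(x, "DetectionOutcome"))
  x@isPositive
}
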