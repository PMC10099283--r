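## Synthetic tissue-phantom tactile-image generator.
##
## The camera sees a bell-shaped patch of scattered light over the
## inclusion: brightest at the centre of the deformation area, falling
## off with distance. The forward model renders
##
##   I(r) = B + A * exp(-r^2 / (2 sigma^2)) + noise
##
## with amplitude A = gain * (E - E_bg) * exp(-depth/d0) * (size/s0)
## (stiffer, shallower and larger inclusions scatter more light) and
## width sigma = size/2 + 0.6 * depth in mm (deeper and larger inclusions
## spread the light over a wider area). mm convert to pixels through the
## camera's pxPerMm. A nodule-free phantom (elasticity equal to the
## background) renders background plus noise only.

#' Construct a phantom specification
#'
#' Defaults reproduce the reference study conditions: 40 mm thick
#' phantom, normal-tissue background of 50 kPa, inclusion 5 mm deep.
#'
#' @param elasticity inclusion stiffness (kPa).
#' @param depth inclusion depth below the top surface (mm).
#' @param size inclusion diameter (mm).
#' @param phantomThickness phantom thickness (mm, default 40).
#' @param backgroundElasticity normal-tissue stiffness (kPa, default 50).
#' @return a \linkS4class{PhantomSpec}.
#' @examples
#' phantomSpec(110, depth = 5, size = 12)
#' @export
phantomSpec <- function(elasticity, depth = 5, size = 12,
                        phantomThickness = 40, backgroundElasticity = 50) {
  new("PhantomSpec", elasticity = elasticity, depth = depth, size = size,
      phantomThickness = phantomThickness,
      backgroundElasticity = backgroundElasticity)
}

#' Construct a camera model
#'
#' Defaults follow the device camera: 656 x 492 pixels of 7.4 um pitch,
#' 8-bit output. \code{pxPerMm} is the optical magnification at the
#' waveguide surface and the single mm-to-pixel conversion key.
#'
#' @param width,height sensor size (pixels).
#' @param pixelPitch sensor pixel pitch (micrometres).
#' @param bitDepth 8 or 16.
#' @param noiseSigma additive Gaussian noise sd (gray levels, default 2).
#' @param pxPerMm pixels per mm at the object plane (default 10).
#' @return a \linkS4class{CameraModel}.
#' @export
cameraModel <- function(width = 656, height = 492, pixelPitch = 7.4,
                        bitDepth = 8, noiseSigma = 2, pxPerMm = 10) {
  new("CameraModel", width = as.integer(width), height = as.integer(height),
      pixelPitch = pixelPitch, bitDepth = as.integer(bitDepth),
      noiseSigma = noiseSigma, pxPerMm = pxPerMm)
}

## forward-model amplitude (gray levels) and width (pixels)
.phantomAmplitude <- function(spec, gain = 6, d0 = 4, s0 = 12) {
  gain * (spec@elasticity - spec@backgroundElasticity) *
    exp(-spec@depth / d0) * (spec@size / s0)
}

.phantomSigmaPx <- function(spec, cam) {
  (spec@size / 2 + 0.6 * spec@depth) * cam@pxPerMm
}

#' Render a synthetic tactile image of a phantom
#'
#' Deterministic for a fixed seed: identical arguments give bit-identical
#' images. Gray levels are rounded and clamped to the camera bit depth.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param cam a \linkS4class{CameraModel}.
#' @param seed integer seed for the additive noise.
#' @param backgroundGray background gray level B (default 30).
#' @param gain amplitude gain (gray levels per kPa of stiffness contrast
#'   at zero depth and reference size; default 6).
#' @param depthScale exponential depth-attenuation constant d0 (mm,
#'   default 4).
#' @param sizeRef reference inclusion diameter s0 (mm, default 12).
#' @return a \linkS4class{TactileImage}; \code{imageMeta} records every
#'   generation parameter.
#' @examples
#' img <- generateImage(phantomSpec(110), cameraModel(), seed = 7)
#' @export
generateImage <- function(spec, cam, seed = 1L, backgroundGray = 30,
                          gain = 6, depthScale = 4, sizeRef = 12) {
  validObject(spec); validObject(cam)
  A <- .phantomAmplitude(spec, gain, depthScale, sizeRef)
  sigma <- .phantomSigmaPx(spec, cam)
  h <- cam@height; w <- cam@width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, `+`)
  img <- backgroundGray + A * exp(-r2 / (2 * sigma^2))
  if (cam@noiseSigma > 0)
    img <- img + withSeed(seed, matrix(rnorm(h * w, 0, cam@noiseSigma), h, w))
  img <- round(.clamp(img, 0, 2^cam@bitDepth - 1))
  new("TactileImage", pixels = img, pitch = 1000 / cam@pxPerMm,
      meta = list(elasticity = spec@elasticity, depth = spec@depth,
                  size = spec@size,
                  backgroundElasticity = spec@backgroundElasticity,
                  backgroundGray = backgroundGray, gain = gain,
                  depthScale = depthScale, sizeRef = sizeRef,
                  amplitude = A, sigmaPx = sigma, seed = seed,
                  noiseSigma = cam@noiseSigma, bitDepth = cam@bitDepth))
}

#' Generate a labelled synthetic cohort
#'
#' Positives carry an inclusion with parameters drawn uniformly from
#' \code{specRanges}; negatives are nodule-free phantoms (inclusion
#' elasticity equal to the background). Per-image noise seeds derive
#' deterministically from \code{seed}, so the whole cohort is
#' reproducible.
#'
#' @param nPositive,nNegative image counts (>= 0).
#' @param cam a \linkS4class{CameraModel}.
#' @param seed integer master seed.
#' @param specRanges list with two-element ranges \code{elasticity},
#'   \code{depth}, \code{size} (defaults 80-110 kPa, 3-7 mm, 8-12 mm,
#'   the reference phantom conditions).
#' @param outdir optional directory: writes one PNG per image plus a
#'   \code{manifest.csv} (filename, label, elasticity, depth, size, seed).
#' @return list with \code{images} (list of \linkS4class{TactileImage}),
#'   \code{labels} (0/1 integer vector) and \code{manifest} (data.frame).
#' @export
generateCohort <- function(nPositive, nNegative, cam = cameraModel(),
                           seed = 1L,
                           specRanges = list(elasticity = c(80, 110),
                                             depth = c(3, 7),
                                             size = c(8, 12)),
                           outdir = NULL) {
  if (nPositive < 0 || nNegative < 0) stop("counts must be >= 0")
  nTot <- nPositive + nNegative
  pars <- withSeed(seed, data.frame(
    label = rep(c(1L, 0L), c(nPositive, nNegative)),
    elasticity = c(runif(nPositive, specRanges$elasticity[1],
                         specRanges$elasticity[2]), rep(50, nNegative)),
    depth = c(runif(nPositive, specRanges$depth[1], specRanges$depth[2]),
              rep(5, nNegative)),
    size = c(runif(nPositive, specRanges$size[1], specRanges$size[2]),
             rep(12, nNegative)),
    seed = sample.int(.Machine$integer.max - 1L, max(nTot, 1L))[seq_len(nTot)]))
  pars$elasticity[pars$label == 0L] <- 50
  images <- lapply(seq_len(nTot), function(i) {
    sp <- phantomSpec(pars$elasticity[i], pars$depth[i], pars$size[i])
    generateImage(sp, cam, seed = pars$seed[i])
  })
  manifest <- cbind(filename = sprintf("phantom_%03d.png", seq_len(nTot)),
                    pars)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nTot))
      writeTactileImage(images[[i]], file.path(outdir, manifest$filename[i]))
    utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(images = images, labels = pars$label, manifest = manifest)
}

#' Write a tactile image to PNG or TIFF
#'
#' @param img a \linkS4class{TactileImage}.
#' @param path output path (.png or .tif/.tiff).
#' @return invisibly, \code{path}.
#' @export
writeTactileImage <- function(img, path) {
  bd <- if (is.null(img@meta$bitDepth)) 8L else img@meta$bitDepth
  EBImage::writeImage(EBImage::Image(t(img@pixels) / (2^bd - 1)), path,
                      bits.per.sample = bd)
  invisible(path)
}

#' Read a grayscale tactile image from PNG or TIFF
#'
#' Values are rescaled to integer gray levels at the stated bit depth.
#'
#' @param path image path (8- or 16-bit grayscale PNG/TIFF).
#' @param pitch physical pixel pitch to attach (micrometres; default 100,
#'   i.e. 10 px per mm).
#' @param bitDepth bit depth to restore gray levels at (default 8).
#' @return a \linkS4class{TactileImage}.
#' @export
readTactileImage <- function(path, pitch = 100, bitDepth = 8) {
  im <- EBImage::readImage(path)
  px <- EBImage::imageData(im)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  new("TactileImage", pixels = round(t(px) * (2^bitDepth - 1)),
      pitch = pitch, meta = list(bitDepth = as.integer(bitDepth)))
}
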