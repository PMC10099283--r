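## Tactile-image analysis: display colormap, calibrated elasticity
## surface with peak-stiffness estimation, fuzzy-entropy binarization and
## the morphological nodule-extraction pipeline.

## ---- internal: matrix <-> EBImage (EBImage stores x = columns first) ----
.asEB <- function(m) EBImage::Image(t(m))
.fromEB <- function(im) t(EBImage::imageData(im))

## 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
## touch only diagonally are merged afterwards with a small union-find.
.label8 <- function(mask) {
  lab <- .fromEB(EBImage::bwlabel(.asEB(mask)))
  nl <- max(lab)
  if (nl < 2) return(lab)
  parent <- seq_len(nl)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (s in list(c(1L, 1L), c(1L, -1L))) {
    r1 <- seq_len(nr - 1L); c1 <- if (s[2] > 0) seq_len(nc - 1L) else 2:nc
    A <- lab[r1, c1, drop = FALSE]
    B <- lab[r1 + 1L, c1 + s[2], drop = FALSE]
    hit <- which(A > 0 & B > 0 & A != B)
    for (h in hit) {
      ra <- findRoot(A[h]); rb <- findRoot(B[h])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nl), findRoot, integer(1))
  lab[lab > 0] <- match(roots, sort(unique(roots)))[lab[lab > 0]]
  lab
}

## ---------------------------------------------------------------------------

#' 2D colormap render of a tactile image
#'
#' Pure presentation: subtracts the background (the image minimum),
#' scales to [0, 1] and maps through a blue-to-red palette so that
#' stiffer (brighter) centres render redder. The render is invariant to
#' adding a constant offset to the whole image.
#'
#' @param img a \linkS4class{TactileImage}.
#' @param palette colour vector for \code{\link[grDevices]{colorRamp}};
#'   default blue-cyan-yellow-red.
#' @return list with \code{display} (matrix in [0,1]) and \code{rgb}
#'   (height x width x 3 array in [0,1]).
#' @export
colormap2d <- function(img,
                       palette = c("blue", "cyan", "yellow", "red")) {
  px <- imagePixels(img)
  rng <- range(px)
  disp <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1])
          else matrix(0, nrow(px), ncol(px))
  ramp <- grDevices::colorRamp(palette)
  cols <- ramp(as.vector(disp)) / 255
  rgb <- array(cols, dim = c(nrow(px), ncol(px), 3L))
  list(display = disp, rgb = rgb)
}

#' Fit an affine gray-to-stiffness calibration from two anchors
#'
#' @param grayBg,kpaBg background anchor: gray level and its stiffness.
#' @param grayNodule,kpaNodule nodule anchor (must have
#'   \code{grayNodule > grayBg} and \code{kpaNodule > kpaBg}).
#' @return a \linkS4class{Calibration}.
#' @export
fitCalibration <- function(grayBg, kpaBg, grayNodule, kpaNodule) {
  if (grayNodule <= grayBg) stop("nodule anchor must be brighter than background")
  slope <- (kpaNodule - kpaBg) / (grayNodule - grayBg)
  new("Calibration", slope = slope, intercept = kpaBg - slope * grayBg)
}

#' Default calibration from two noise-free generator fixtures
#'
#' Renders a nodule-free phantom (background anchor, 50 kPa) and the
#' strong reference phantom (110 kPa, 5 mm deep, 12 mm) without noise and
#' anchors the affine map at their centre gray levels. This replaces the
#' device-bound physical calibration.
#'
#' @param cam a \linkS4class{CameraModel} (noise setting ignored).
#' @param ... forward-model parameters passed to
#'   \code{\link{generateImage}}.
#' @return a \linkS4class{Calibration}.
#' @export
defaultCalibration <- function(cam = cameraModel(), ...) {
  cam0 <- cameraModel(width = cam@width, height = cam@height,
                      pixelPitch = cam@pixelPitch, bitDepth = cam@bitDepth,
                      noiseSigma = 0, pxPerMm = cam@pxPerMm)
  ctr <- function(im) {
    p <- imagePixels(im)
    p[round(nrow(p) / 2), round(ncol(p) / 2)]
  }
  bg <- generateImage(phantomSpec(50), cam0, seed = 0L, ...)
  nod <- generateImage(phantomSpec(110, depth = 5, size = 12), cam0,
                       seed = 0L, ...)
  fitCalibration(ctr(bg), 50, ctr(nod), 110)
}

#' Apply a calibration to gray levels
#' @param calibration a \linkS4class{Calibration}.
#' @param gray gray level(s).
#' @return stiffness in kPa.
#' @export
applyCalibration <- function(calibration, gray)
  calibration@intercept + calibration@slope * gray

## Gaussian smoothing that tolerates images smaller than the kernel.
.smooth <- function(px, sigma) {
  if (sigma <= 0) return(px)
  half <- min(ceiling(3 * sigma), floor((min(dim(px)) - 1) / 2))
  if (half < 1) return(px)
  br <- EBImage::makeBrush(2 * half + 1, shape = "Gaussian", sigma = sigma)
  .fromEB(EBImage::filter2(.asEB(px), br))
}

#' Calibrated 3D elasticity surface and peak stiffness
#'
#' Smooths the image with a small Gaussian, applies the affine gray-to-kPa
#' calibration pixel-wise, and summarises the peak as the mean of the top
#' 1 percent of pixels inside the largest 8-connected region lying above
#' background (background = calibrated image median, plus a margin). When
#' nothing rises above background the peak falls back to the calibrated
#' background and the map is flagged.
#'
#' @param img a \linkS4class{TactileImage}.
#' @param calibration a \linkS4class{Calibration} (slope > 0).
#' @param smoothSigma Gaussian sd in pixels (default 2).
#' @param bgMarginKpa margin above calibrated background that counts as
#'   signal (default 2 kPa).
#' @param topFraction fraction of region pixels averaged for the peak
#'   (default 0.01).
#' @return an \linkS4class{ElasticityMap}.
#' @export
elasticitySurface <- function(img, calibration, smoothSigma = 2,
                              bgMarginKpa = 2, topFraction = 0.01) {
  validObject(calibration)
  px <- .smooth(imagePixels(img), smoothSigma)
  surf <- applyCalibration(calibration, px)
  bgKpa <- stats::median(surf)
  above <- surf > bgKpa + bgMarginKpa
  if (!any(above))
    return(new("ElasticityMap", surface = surf, calibration = calibration,
               peakKpa = bgKpa, emptyRegion = TRUE))
  lab <- .label8(above * 1)
  big <- which.max(tabulate(lab[lab > 0]))
  vals <- surf[lab == big]
  nTop <- max(1L, ceiling(topFraction * length(vals)))
  peak <- mean(sort(vals, decreasing = TRUE)[seq_len(nTop)])
  new("ElasticityMap", surface = surf, calibration = calibration,
      peakKpa = peak, emptyRegion = FALSE)
}

#' Fuzzy-entropy threshold selection
#'
#' Selects the gray threshold minimising the Shannon fuzzy entropy of the
#' two-class membership: for a candidate threshold the two class means
#' are computed, each pixel's membership to its class is
#' \code{1 / (1 + |x - m_class| / C)} (C = gray range), and the fuzziness
#' is the summed binary entropy of the memberships. All candidate levels
#' are examined (exhaustive search over the observed gray levels).
#'
#' @param img a \linkS4class{TactileImage} or a numeric matrix of gray
#'   levels with at least two distinct values.
#' @return list with \code{threshold} (gray level; pixels strictly above
#'   it are foreground), \code{mask} (0/1 matrix) and \code{fuzziness}
#'   (data.frame of candidate thresholds and their entropy).
#' @export
fuzzyBinarize <- function(img) {
  px <- if (is(img, "TactileImage")) imagePixels(img) else img
  lv <- sort(unique(as.vector(px)))
  if (length(lv) < 2)
    stop("constant image: fuzzy binarization needs >= 2 distinct gray levels")
  cnt <- as.vector(table(factor(as.vector(px), levels = lv)))
  C <- lv[length(lv)] - lv[1]
  csum <- cumsum(cnt); wsum <- cumsum(cnt * lv)
  N <- csum[length(csum)]; W <- wsum[length(wsum)]
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  ent <- vapply(seq_len(length(lv) - 1L), function(j) {
    m0 <- wsum[j] / csum[j]
    m1 <- (W - wsum[j]) / (N - csum[j])
    mu <- c(1 / (1 + abs(lv[seq_len(j)] - m0) / C),
            1 / (1 + abs(lv[(j + 1):length(lv)] - m1) / C))
    -sum(cnt * (xlx(mu) + xlx(1 - mu))) / (N * log(2))
  }, numeric(1))
  j <- which.min(ent)
  ## report the class boundary as the midpoint between the last low-class
  ## level and the first high-class level (strictly between the classes)
  thr <- (lv[j] + lv[j + 1]) / 2
  list(threshold = thr, mask = (px > thr) * 1,
       fuzziness = data.frame(threshold = (lv[-length(lv)] + lv[-1]) / 2,
                              entropy = ent))
}

## region features from an 8-connected label matrix
.regionFeatures <- function(lab) {
  labs <- sort(unique(lab[lab > 0]))
  rows <- row(lab); cols <- col(lab)
  feats <- lapply(labs, function(l) {
    sel <- lab == l
    r <- rows[sel]; c <- cols[sel]
    h <- diff(range(r)) + 1L; w <- diff(range(c)) + 1L
    data.frame(label = l, area = sum(sel),
               centroidRow = mean(r), centroidCol = mean(c),
               bboxRowMin = min(r), bboxRowMax = max(r),
               bboxColMin = min(c), bboxColMax = max(c),
               aspectRatio = h / w)
  })
  do.call(rbind, feats)
}

#' Extract candidate nodule regions from a tactile image
#'
#' Ordered pipeline: (1) fuzzy-entropy binarization; (2) morphological
#' opening then closing with a disk structuring element; (3) hole
#' filling; (4) removal of components touching the image border;
#' (5) removal of components below a minimum area; (6) contour tracing of
#' each survivor. Regions are labelled 8-connected.
#'
#' @param img a \linkS4class{TactileImage} (or gray-level matrix).
#' @param diskRadius structuring-element radius in pixels (default 3).
#' @param minArea minimum surviving region area in pixels (default 25).
#' @return a \linkS4class{SegmentationResult} (possibly with zero
#'   regions).
#' @export
extractNodules <- function(img, diskRadius = 3, minArea = 25) {
  px <- if (is(img, "TactileImage")) imagePixels(img) else img
  if (length(unique(as.vector(px))) < 2) {
    ## a featureless frame has nothing to segment; empty result, never
    ## an error (the raw binarizer alone does reject constant input)
    return(new("SegmentationResult", mask = px * 0,
               regions = data.frame(label = integer(), area = integer(),
                 centroidRow = numeric(), centroidCol = numeric(),
                 bboxRowMin = integer(), bboxRowMax = integer(),
                 bboxColMin = integer(), bboxColMax = integer(),
                 aspectRatio = numeric()),
               contours = list(), thresholdUsed = NA_real_))
  }
  fb <- fuzzyBinarize(img)
  mask <- fb$mask
  if (any(mask > 0) && diskRadius > 0) {
    brush <- EBImage::makeBrush(2 * diskRadius + 1, shape = "disc")
    em <- .asEB(mask)
    em <- EBImage::closing(EBImage::opening(em, brush), brush)
    em <- EBImage::fillHull(em)
    mask <- .fromEB(em)
  }
  lab <- .label8(mask)
  if (max(lab) > 0) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    lab[lab %in% border[border > 0]] <- 0L
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < minArea)
    if (length(small)) lab[lab %in% small] <- 0L
  }
  if (max(lab) > 0) {
    keep <- sort(unique(lab[lab > 0]))
    lab[lab > 0] <- match(lab[lab > 0], keep)
    regions <- .regionFeatures(lab)
    oc <- EBImage::ocontour(EBImage::Image(t(lab)))
    contours <- lapply(oc, function(m) {
      out <- cbind(row = m[, 2] + 1, col = m[, 1] + 1)
      rbind(out, out[1, , drop = FALSE])  # close the loop
    })
  } else {
    regions <- data.frame(label = integer(), area = integer(),
                          centroidRow = numeric(), centroidCol = numeric(),
                          bboxRowMin = integer(), bboxRowMax = integer(),
                          bboxColMin = integer(), bboxColMax = integer(),
                          aspectRatio = numeric())
    contours <- list()
  }
  new("SegmentationResult", mask = (lab > 0) * 1, regions = regions,
      contours = contours, thresholdUsed = fb$threshold)
}

#' Presence / absence nodule detection
#'
#' Score = peak stiffness (top-1-percent mean of the calibrated, smoothed
#' surface) restricted to the regions surviving
#' \code{\link{extractNodules}}; when no region survives the score is the
#' calibrated background. The call is positive iff the score strictly
#' exceeds the decision threshold.
#'
#' @param img a \linkS4class{TactileImage}.
#' @param calibration a \linkS4class{Calibration}.
#' @param decisionThreshold decision threshold in kPa (default 55,
#'   midway between the 50 kPa normal-tissue background and the weakest
#'   inclusion response the generator produces).
#' @param smoothSigma,topFraction as in \code{\link{elasticitySurface}}.
#' @param ... forwarded to \code{\link{extractNodules}}.
#' @return a \linkS4class{DetectionOutcome}.
#' @export
detectNodule <- function(img, calibration, decisionThreshold = 55,
                         smoothSigma = 2, topFraction = 0.01, ...) {
  seg <- extractNodules(img, ...)
  surf <- applyCalibration(calibration,
                           .smooth(imagePixels(img), smoothSigma))
  score <- if (nrow(seg@regions) == 0) stats::median(surf) else {
    vals <- surf[seg@mask > 0]
    nTop <- max(1L, ceiling(topFraction * length(vals)))
    mean(sort(vals, decreasing = TRUE)[seq_len(nTop)])
  }
  new("DetectionOutcome", isPositive = score > decisionThreshold,
      score = score, threshold = decisionThreshold)
}
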