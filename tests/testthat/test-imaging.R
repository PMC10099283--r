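test_that("colormap render is affine-invariant pure presentation", {
  img <- blobImage()
  cm <- colormap2d(img)
  expect_equal(dim(cm$display), dim(imagePixels(img)))
  expect_true(all(cm$display >= 0 & cm$display <= 1))
  ## constant image: single colour
  flat <- new("TactileImage", pixels = matrix(42, 20, 20), pitch = 100,
              meta = list(bitDepth = 8L))
  cmF <- colormap2d(flat)
  expect_equal(diff(range(cmF$display)), 0)
  ## offset invariance
  shifted <- new("TactileImage", pixels = imagePixels(img) + 17,
                 pitch = 100, meta = list())
  expect_equal(colormap2d(shifted)$display, cm$display)
  ## stiffer (brighter centre) renders a larger display value at centre
  weak <- blobImage(A = 40)
  expect_gt(cm$display[60, 80] - min(cm$display),
            colormap2d(weak)$display[60, 80] - min(colormap2d(weak)$display) - 1)
  expect_equal(cm$display[60, 80], max(cm$display))
})

test_that("elasticity surface applies the calibration and finds the peak", {
  ## identity calibration on a constant image: surface = value, flagged
  flat <- new("TactileImage", pixels = matrix(77, 30, 30), pitch = 100,
              meta = list(bitDepth = 8L))
  em <- elasticitySurface(flat, identityCalibration(), smoothSigma = 0)
  expect_true(em@emptyRegion)
  expect_equal(peakKpa(em), 77)
  expect_equal(unique(as.vector(elasticityValues(em))), 77)
})

test_that("peak statistic matches the closed-form Gaussian top-fraction mean", {
  A <- 120; sigma <- 12; bg <- 30; margin <- 2
  img <- blobImage(A = A, sigma = sigma, bg = bg)
  em <- elasticitySurface(img, identityCalibration(), smoothSigma = 0,
                          bgMarginKpa = margin)
  ## continuous-blob oracle: region r < rmax with A exp(-r^2/2s^2) >
  ## margin; top 1% = disk r1 with r1^2 = 0.01 rmax^2; disk mean of the
  ## Gaussian in closed form
  rmax2 <- 2 * sigma^2 * log(A / margin)
  r12 <- 0.01 * rmax2
  oracle <- bg + A * (2 * sigma^2 / r12) * (1 - exp(-r12 / (2 * sigma^2)))
  expect_equal(peakKpa(em), oracle, tolerance = 0.02)
})

test_that("peak ordering across the three inclusion-elasticity phantoms", {
  cam <- cameraModel(noiseSigma = 0)
  cal <- defaultCalibration(cam)
  pk <- sapply(c(110, 80, 50), function(E)
    peakKpa(elasticitySurface(generateImage(phantomSpec(E, 5, 12), cam), cal)))
  expect_true(all(diff(pk) < 0))
})

test_that("fuzzy binarization separates two-level images and matches brute force", {
  ## separable two-level image
  px <- matrix(10, 20, 20); px[8:12, 8:12] <- 200
  fb <- fuzzyBinarize(px)
  expect_gt(fb$threshold, 10); expect_lt(fb$threshold, 200)
  expect_identical(fb$mask, (px == 200) * 1)
  ## 16-level toy image vs exhaustive per-pixel minimization
  set.seed(21)
  toy <- matrix(sample(seq(0, 150, by = 10), 400, replace = TRUE,
                       prob = c(rep(3, 8), rep(1, 8))), 20, 20)
  fb2 <- fuzzyBinarize(toy)
  expect_equal(fb2$threshold, bruteFuzzyThreshold(toy))
  expect_equal(nrow(fb2$fuzziness), length(unique(as.vector(toy))) - 1L)
  ## inversion symmetry: inverting the image inverts the mask (midpoint
  ## thresholds put no pixel on the class boundary)
  fbI <- fuzzyBinarize(max(toy) - toy)
  expect_identical(fbI$mask, 1 - fb2$mask)
  expect_equal(fbI$threshold, max(toy) - fb2$threshold)
  ## degenerate input
  expect_error(fuzzyBinarize(matrix(5, 4, 4)), "constant")
})

test_that("8-connected labelling merges diagonal touches", {
  m <- matrix(0, 9, 9)
  m[2, 2] <- 1; m[3, 3] <- 1              # diagonal pair: one component
  m[7, 7] <- 1                            # far pixel: its own component
  lab <- tactoscope:::.label8(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_false(lab[7, 7] == lab[2, 2])
})

test_that("nodule extraction finds a clean blob and honours its stage contracts", {
  img <- blobImage(A = 120, sigma = 10)
  seg <- extractNodules(img)
  reg <- segmentedRegions(seg)
  expect_equal(nrow(reg), 1)
  expect_lt(abs(reg$centroidRow - 60.5), 1)
  expect_lt(abs(reg$centroidCol - 80.5), 1)
  ## closed contour present
  ct <- regionContours(seg)[[1]]
  expect_identical(ct[1, ], ct[nrow(ct), ])
  ## border-touching blob is removed
  border <- blobImage(centerRow = 3, centerCol = 80)
  expect_equal(nrow(segmentedRegions(extractNodules(border))), 0)
  ## isolated speckles are cleaned up by opening / min-area
  noisy <- imagePixels(blobImage(A = 120, sigma = 10))
  noisy[10, 10] <- 200; noisy[15, 140] <- 200; noisy[100, 20] <- 200
  segN <- extractNodules(new("TactileImage", pixels = noisy, pitch = 100,
                             meta = list(bitDepth = 8L)))
  expect_equal(nrow(segmentedRegions(segN)), 1)
})

test_that("segmentation is idempotent on its own mask", {
  seg <- extractNodules(blobImage(A = 120, sigma = 10))
  maskImg <- new("TactileImage", pixels = segmentationMask(seg) * 255,
                 pitch = 100, meta = list(bitDepth = 8L))
  seg2 <- extractNodules(maskImg)
  expect_identical(segmentationMask(seg2), segmentationMask(seg))
  expect_equal(segmentedRegions(seg2)$area, segmentedRegions(seg)$area)
})

test_that("region features match closed-form values on a constructed mask", {
  px <- matrix(0, 40, 40)
  px[11:20, 6:25] <- 200                  # 10 x 20 rectangle
  seg <- extractNodules(new("TactileImage", pixels = px, pitch = 100,
                            meta = list(bitDepth = 8L)),
                        diskRadius = 0, minArea = 10)
  reg <- segmentedRegions(seg)
  expect_equal(reg$area, 200L)
  expect_equal(reg$centroidRow, 15.5)
  expect_equal(reg$centroidCol, 15.5)
  expect_equal(reg$aspectRatio, 0.5)
})

test_that("detection scores track inclusion elasticity monotonically", {
  cam <- cameraModel(noiseSigma = 0)
  cal <- defaultCalibration(cam)
  ## nodule-free image with threshold above background: negative
  neg <- detectNodule(generateImage(phantomSpec(50), cam), cal,
                      decisionThreshold = 55)
  expect_false(isPositive(neg))
  expect_equal(detectionScore(neg), 50, tolerance = 0.05)
  ## strong nodule at the default threshold: positive
  pos <- detectNodule(generateImage(phantomSpec(110, 5, 12), cam), cal)
  expect_true(isPositive(pos))
  ## monotone score over an elasticity sweep
  sc <- sapply(c(60, 75, 90, 105), function(E)
    detectionScore(detectNodule(generateImage(phantomSpec(E, 5, 12), cam),
                                cal)))
  expect_true(all(diff(sc) >= 0))
})
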