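## Small in-code fixtures.

## the device stack scaled to wavelength dimensions (thin, for the wave
## solver)
thinDeviceStack <- function(h = rep(2, 4))
  layerStack(1.41, 1.40, 1.39, 1.38, heights = h)

## small camera for fast imaging tests
tinyCam <- function(noiseSigma = 0)
  cameraModel(width = 160, height = 120, noiseSigma = noiseSigma,
              pxPerMm = 10)

## synthetic Gaussian-blob tactile image built directly (independent of
## generateImage)
blobImage <- function(h = 120, w = 160, A = 120, sigma = 10, bg = 30,
                      centerRow = (h + 1) / 2, centerCol = (w + 1) / 2) {
  r2 <- outer((seq_len(h) - centerRow)^2, (seq_len(w) - centerCol)^2, `+`)
  px <- round(bg + A * exp(-r2 / (2 * sigma^2)))
  new("TactileImage", pixels = px, pitch = 100,
      meta = list(bitDepth = 8L, sigmaPx = sigma, amplitude = A,
                  backgroundGray = bg))
}

identityCalibration <- function()
  new("Calibration", slope = 1, intercept = 0)
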