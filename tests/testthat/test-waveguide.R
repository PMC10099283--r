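test_that("degenerate stack reproduces single-slab TE modes", {
  ## collapse the four inner layers to (numerically) one index; the
  ## validity ordering needs strict inequalities, so use 1e-12 steps
  eps <- 1e-12
  st <- layerStack(1.40 + 3 * eps, 1.40 + 2 * eps, 1.40 + eps, 1.40,
                   heights = rep(2, 4))
  wv <- waveParams(0.6328)
  betas <- vapply(findModes(st, wv), propagationConstant, numeric(1))
  ref <- slabModes(1.40, 8, wv@k0)
  expect_equal(length(betas), length(ref))
  expect_lt(max(abs(betas - ref) / ref), 1e-9)
})

test_that("dispersion residual matches the transfer-matrix mode structure", {
  st <- thinDeviceStack()
  wv <- waveParams(0.6328)
  k0 <- wv@k0
  ## at the oscillatory cutoff beta -> k0*n4 the residual stays finite
  ## and bounded away from zero (k4*tan(...) tends to a finite O(1/h4)
  ## term while -g5 dominates): no guided mode sits on the boundary
  bHi <- k0 * 1.38 * (1 - 1e-12)
  g5 <- sqrt(bHi^2 - k0^2)
  rHi <- dispersionResidual(st, wv, bHi)
  expect_true(is.finite(rHi))
  expect_lt(rHi, 0)
  expect_lt(abs(rHi + g5), 1)   # g5-dominated
  ## domain errors name the violated bound
  expect_error(dispersionResidual(st, wv, k0 * 0.5), "k0\\*n0")
  expect_error(dispersionResidual(st, wv, k0 * 1.4), "k0\\*n4")
  ## residual roots = oracle modes (count compared away from tan poles
  ## via the mode list itself)
  modes <- findModes(st, wv)
  oracle <- tmmModes(c(1, 1.41, 1.40, 1.39, 1.38, 1), rep(2, 4), k0)
  expect_equal(length(modes), length(oracle))
  for (m in modes)
    expect_lt(abs(dispersionResidual(st, wv, propagationConstant(m))), 1e-4)
})

test_that("guided modes match the transfer-matrix oracle on the device stack", {
  st <- thinDeviceStack()
  wv <- waveParams(0.6328)
  betas <- vapply(findModes(st, wv), propagationConstant, numeric(1))
  ref <- tmmModes(c(1, 1.41, 1.40, 1.39, 1.38, 1), rep(2, 4), wv@k0)
  expect_equal(length(betas), length(ref))
  expect_lt(max(abs(betas - ref) / ref), 1e-6)
  expect_true(all(diff(betas) < 0))  # sorted by decreasing beta
})

test_that("random thin stacks agree with the oracle", {
  set.seed(7)
  for (i in 1:8) {
    rs <- randomStack()
    betas <- vapply(findModes(rs$stack, rs$wave), propagationConstant,
                    numeric(1))
    ref <- tmmModes(rs$n, rs$h, rs$wave@k0)
    expect_equal(length(betas), length(ref), info = paste("stack", i))
    if (length(ref))
      expect_lt(max(abs(betas - ref) / ref), 1e-6)
  }
})

test_that("every mode satisfies impedance continuity at all boundaries", {
  st <- thinDeviceStack()
  wv <- waveParams(0.55)
  for (m in findModes(st, wv))
    expect_lt(max(impedanceMismatch(m, st)), 1e-6)
})

test_that("field profile is continuous, evanescent outside, and solves the wave ODE", {
  st <- thinDeviceStack()
  wv <- waveParams(0.6328)
  modes <- findModes(st, wv)
  m <- modes[[3]]
  a <- layerBoundaries(st)
  ## continuity of e (and h) across every boundary as eps -> 0
  for (b in c(0, a)) {
    eps <- 1e-9
    lr <- fieldProfile(m, st, wv, c(b - eps, b + eps))
    expect_equal(lr$e[1], lr$e[2], tolerance = 1e-6)
    expect_equal(lr$h[1], lr$h[2], tolerance = 1e-6)
  }
  ## evanescent decay far below the stack
  expect_lt(abs(fieldProfile(m, st, wv, -30)$e), 1e-10)
  ## e'' + (k0^2 n2^2 - beta^2) e = 0 inside region 2, by central
  ## differences on a fine grid
  xs <- seq(a[1] + 0.2, a[2] - 0.2, length.out = 401)
  hstep <- xs[2] - xs[1]
  e <- fieldProfile(m, st, wv, xs)$e
  d2 <- (e[-c(1, 2)] - 2 * e[-c(1, length(e))] + e[-c(length(e) - 1, length(e))]) /
    hstep^2
  coef <- (wv@k0 * 1.40)^2 - propagationConstant(m)^2
  resid <- d2 + coef * e[-c(1, length(e))]
  expect_lt(max(abs(resid)) / max(abs(coef * e)), 1e-4)
})

test_that("adding thickness to an inner layer never removes a guided mode", {
  set.seed(11)
  for (i in 1:3) {
    rs <- randomStack()
    base <- length(findModes(rs$stack, rs$wave))
    for (layer in 1:4) {
      h2 <- rs$h
      h2[layer] <- h2[layer] + runif(1, 0.5, 2)
      n <- refractiveIndices(rs$stack)
      st2 <- layerStack(n[2], n[3], n[4], n[5], heights = h2)
      expect_gte(length(findModes(st2, rs$wave)), base)
    }
  }
})

test_that("stack configs round-trip through YAML", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("n1: 1.41", "n2: 1.40", "n3: 1.39", "n4: 1.38",
               "heights_um: [2, 2, 2, 2]", "wavelength_um: 0.6328"), cfg)
  got <- readStackConfig(cfg)
  expect_s4_class(got$stack, "LayerStack")
  expect_equal(unname(refractiveIndices(got$stack)[2]), 1.41)
  expect_equal(got$wave@wavelength, 0.6328)
  expect_error(readStackConfig({
    bad <- tempfile(fileext = ".yaml"); writeLines("n1: 1.41", bad); bad
  }), "heights_um")
})

test_that("invalid stacks are rejected", {
  expect_error(layerStack(1.38, 1.39, 1.40, 1.41, heights = rep(2, 4)),
               "n1 > n2")
  expect_error(layerStack(1.41, 1.40, 1.39, 1.38, heights = c(2, -1, 2, 2)),
               "> 0")
})
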