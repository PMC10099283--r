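## Guided TE modes of the four-layer elastic slab waveguide.
##
## Regions (x transverse to the layers): 0 (x < 0, air), 1..4 (the three
## PDMS layers and the glass plate), 5 (x > a4, air). The TE ansatz is
##   e(x) = e0 exp(g0 x)              x < 0
##   e(x) = ei cos(ki x + phi_i)      a_{i-1} < x < a_i, i = 1..4
##   e(x) = e5 exp(g5 (a4 - x))       x > a4
## with g0^2 = beta^2 - k0^2 n0^2, ki^2 = k0^2 ni^2 - beta^2,
## g5^2 = beta^2 - k0^2 n5^2. Matching the impedance h(x)/e(x) (h is the
## longitudinal magnetic-field amplitude, proportional to e'(x)) at the
## five boundaries chains the phases and yields one scalar dispersion
## condition in beta; its zeros are the guided modes.

#' Construct a four-layer waveguide stack
#'
#' @param n1,n2,n3,n4 layer refractive indices, must satisfy
#'   \code{n1 > n2 > n3 > n4 > n0}.
#' @param heights numeric(4), layer heights (any consistent length unit;
#'   micrometres pair naturally with \code{\link{waveParams}} defaults).
#' @param n0,n5 surrounding-medium indices (air, default 1).
#' @return a \linkS4class{LayerStack}.
#' @examples
#' layerStack(1.41, 1.40, 1.39, 1.38, heights = rep(2, 4))
#' @export
layerStack <- function(n1, n2, n3, n4, heights, n0 = 1, n5 = 1) {
  heights <- as.numeric(heights)
  new("LayerStack", n = c(n0, n1, n2, n3, n4, n5), h = heights,
      a = cumsum(heights))
}

#' Read a stack configuration from YAML or JSON
#'
#' Expected keys: \code{n0..n5} (n0/n5 optional, default 1),
#' \code{heights_um} (4 values) and optionally \code{wavelength_um}.
#'
#' @param path file path; format chosen by extension (.yaml/.yml/.json).
#' @return list with elements \code{stack} (\linkS4class{LayerStack}) and
#'   \code{wave} (\linkS4class{WaveParams} or NULL).
#' @export
readStackConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  need <- c("n1", "n2", "n3", "n4", "heights_um")
  if (!all(need %in% names(cfg)))
    stop("stack config must provide keys: ", paste(need, collapse = ", "))
  stack <- layerStack(cfg$n1, cfg$n2, cfg$n3, cfg$n4, cfg$heights_um,
                      n0 = if (is.null(cfg$n0)) 1 else cfg$n0,
                      n5 = if (is.null(cfg$n5)) 1 else cfg$n5)
  wave <- if (!is.null(cfg$wavelength_um)) waveParams(cfg$wavelength_um)
  list(stack = stack, wave = wave)
}

#' Wave parameters from a vacuum wavelength
#'
#' The device uses a broadband white LED; a single design wavelength in the
#' centre of the visible spectrum (0.55 um) is the default for modal
#' analysis.
#'
#' @param wavelength vacuum wavelength, same length unit as the stack.
#' @return a \linkS4class{WaveParams}.
#' @export
waveParams <- function(wavelength = 0.55) {
  k0 <- 2 * pi / wavelength
  ## omega = k0 * c; c in m/s, wavelength unit cancels wherever omega/k0
  ## enters, so the absolute scale is irrelevant to the solver.
  new("WaveParams", wavelength = wavelength, k0 = k0, omega = k0 * 299792458)
}

## Transverse wave vectors at beta. Returns list(g0, k(4), g5).
## Admissible interval: k0*n0 < beta < k0*n4 keeps all four inner layers
## oscillatory (real k_i) and both outer tails evanescent.
.transverseK <- function(stack, wave, beta) {
  n <- stack@n
  k0 <- wave@k0
  list(g0 = sqrt(beta^2 - (k0 * n[1])^2),
       k  = sqrt(pmax((k0 * n[2:5])^2 - beta^2, 0)),
       g5 = sqrt(beta^2 - (k0 * n[6])^2))
}

## Chain the phases phi1..phi4 through the inner boundaries:
##   phi1     = -atan(g0/k1)
##   phi_{i+1} = atan[(k_i/k_{i+1}) tan(k_i a_i + phi_i)] - k_{i+1} a_i
## (principal atan branch; the residual is invariant under phi -> phi + m*pi
## because tan is pi-periodic, so no branch bookkeeping is needed there).
.phaseChain <- function(kt, a) {
  k <- kt$k
  phi <- numeric(4)
  phi[1] <- -atan(kt$g0 / k[1])
  for (i in 1:3)
    phi[i + 1] <- atan((k[i] / k[i + 1]) * tan(k[i] * a[i] + phi[i])) -
      k[i + 1] * a[i]
  phi
}

#' Dispersion residual of the four-layer TE boundary-value problem
#'
#' Chains the phases through the inner boundaries and returns the mismatch
#' of the top-surface impedance condition,
#' \code{k4*tan(k4*a4 + phi4) - g5}; a zero of this function in beta is a
#' guided mode. (The top-boundary condition follows from matching
#' \code{h/e} with the evanescent tail \code{exp(g5*(a4-x))}, whose
#' logarithmic derivative is \code{-g5}.)
#'
#' @param stack a \linkS4class{LayerStack}.
#' @param wave a \linkS4class{WaveParams}.
#' @param beta propagation constant(s); vectorized. Must satisfy
#'   \code{k0*n0 < beta < k0*n4} (all inner layers oscillatory).
#' @return numeric vector of residuals, same length as \code{beta}.
#' @export
dispersionResidual <- function(stack, wave, beta) {
  k0 <- wave@k0
  lo <- k0 * stack@n[1]
  hi <- k0 * stack@n[5]
  if (any(beta <= lo))
    stop("beta must exceed k0*n0 = ", lo, " (evanescent outer tails)")
  if (any(beta >= hi))
    stop("beta must be below k0*n4 = ", hi, " (oscillatory inner layers)")
  a <- stack@a
  vapply(beta, function(b) {
    kt <- .transverseK(stack, wave, b)
    phi <- .phaseChain(kt, a)
    kt$k[4] * tan(kt$k[4] * a[4] + phi[4]) - kt$g5
  }, numeric(1))
}

## Amplitudes e0..e5 chained by continuity of e(x) at each boundary,
## e0 = 1:  e1 = e0/cos(phi1), e_{i+1} = e_i cos(k_i a_i + phi_i) /
## cos(k_{i+1} a_i + phi_{i+1}), e5 = e4 cos(k4 a4 + phi4).
.amplitudeChain <- function(kt, phi, a) {
  k <- kt$k
  e <- numeric(6)
  e[1] <- 1
  e[2] <- e[1] / cos(phi[1])
  for (i in 1:3)
    e[i + 2] <- e[i + 1] * cos(k[i] * a[i] + phi[i]) /
      cos(k[i + 1] * a[i] + phi[i + 1])
  e[6] <- e[5] * cos(k[4] * a[4] + phi[4])
  e
}

## Principal-branch phase mismatch of the top-surface condition:
##   Phi(beta) = (k4*a4 + phi4) - atan(g5/k4).
## The dispersion condition k4 tan(k4 a4 + phi4) = g5 holds iff
## Phi = m*pi for an integer m. Phi is continuous in beta except for
## exact +-pi jumps where an inner tan crosses a pole (the principal
## atan branch switches); those jumps do not move the mod-pi class, so
## after unwrapping on a grid Phi is a smooth, pole-free function whose
## pi-level crossings are exactly the guided modes.
.phaseMismatch <- function(stack, wave, beta) {
  a <- stack@a
  vapply(beta, function(b) {
    kt <- .transverseK(stack, wave, b)
    phi <- .phaseChain(kt, a)
    (kt$k[4] * a[4] + phi[4]) - atan(kt$g5 / kt$k[4])
  }, numeric(1))
}

#' Find all guided modes of a stack
#'
#' Evaluates the top-surface phase mismatch on a uniform beta grid over
#' the admissible interval \code{(k0*n0, k0*n4)}, unwraps the arctan
#' branch jumps so the phase is continuous in beta (the branch-aware
#' evaluation), brackets every crossing of an integer multiple of pi and
#' refines it by bisection. This formulation has no tan poles, so no
#' root can hide between a pole and a nearby zero of the raw residual.
#' Returns \linkS4class{ModeSolution}s sorted by decreasing beta.
#'
#' @param stack a \linkS4class{LayerStack}.
#' @param wave a \linkS4class{WaveParams}.
#' @param gridPoints number of grid points (>= 100; default 2000). The
#'   unwrap needs the true phase change per grid cell to stay below
#'   pi/2, i.e. roughly \code{gridPoints > k0 * a4}; 2000 covers stacks
#'   hundreds of wavelengths thick.
#' @param tol absolute bisection tolerance on beta, default \code{1e-10*k0}.
#' @return list of \linkS4class{ModeSolution} (possibly empty).
#' @export
findModes <- function(stack, wave, gridPoints = 2000, tol = 1e-10 * wave@k0) {
  if (gridPoints < 100) stop("gridPoints must be >= 100")
  k0 <- wave@k0
  lo <- k0 * stack@n[1]
  hi <- k0 * stack@n[5]
  eps <- (hi - lo) * 1e-9
  ## uniform grid, plus geometric refinement towards the upper edge where
  ## k4 -> 0 makes atan(g5/k4) vary with divergent slope (a uniform grid
  ## aliases the branch unwrap there and can gain or lose a near-cutoff
  ## mode)
  edge <- hi - (hi - lo) * 10^seq(-9, -2, length.out = 60)
  grid <- sort(unique(c(seq(lo + eps, hi - eps, length.out = gridPoints),
                        edge)))
  gridPoints <- length(grid)
  raw <- .phaseMismatch(stack, wave, grid)

  ## non-finite phase at a grid point: subdivide locally
  bad <- which(!is.finite(raw))
  for (j in bad) {
    b <- grid[j] + (grid[min(j + 1, gridPoints)] - grid[j]) * 1e-3
    raw[j] <- .phaseMismatch(stack, wave, b)
    grid[j] <- b
    message("subdivided non-finite phase near beta = ", signif(b, 10))
  }

  ## remove the exact +-pi branch jumps
  jumps <- round(diff(raw) / pi)
  phiC <- raw - pi * c(0, cumsum(jumps))
  modes <- list()
  for (j in seq_len(gridPoints - 1L)) {
    for (m in seq(ceiling(min(phiC[j], phiC[j + 1]) / pi),
                  floor(max(phiC[j], phiC[j + 1]) / pi))) {
      target <- m * pi
      if ((phiC[j] - target) * (phiC[j + 1] - target) > 0) next
      a <- grid[j]; b <- grid[j + 1]
      fa <- phiC[j] - target; fb <- phiC[j + 1] - target
      if (fa == 0) next  # counted in the previous cell
      while (b - a > tol) {
        mid <- (a + b) / 2
        ref <- fa + target           # unwrapped value at bracket start
        p <- .phaseMismatch(stack, wave, mid)
        fm <- p - pi * round((p - ref) / pi) - target
        if (fa * fm <= 0) { b <- mid; fb <- fm } else { a <- mid; fa <- fm }
      }
      root <- (a + b) / 2
      kt <- .transverseK(stack, wave, root)
      phi <- .phaseChain(kt, stack@a)
      amp <- .amplitudeChain(kt, phi, stack@a)
      fr <- abs(kt$k[4] * tan(kt$k[4] * stack@a[4] + phi[4]) - kt$g5)
      modes[[length(modes) + 1]] <- new("ModeSolution", beta = root,
        kLayer = c(kt$g0, kt$k, kt$g5), phi = phi, amp = amp, residual = fr)
    }
  }
  modes[order(vapply(modes, function(m) m@beta, numeric(1)),
              decreasing = TRUE)]
}

#' Evaluate the transverse field profile of a mode
#'
#' Piecewise evaluation of the electric-field amplitude e(x) (exponential
#' tails outside, cosines inside) and the associated magnetic-field
#' amplitude, reported as \code{h(x) = e'(x)/k0} (the longitudinal H
#' component up to the constant factor i*c/omega; dividing by k0 keeps it
#' in the units of e).
#'
#' @param mode a \linkS4class{ModeSolution} from \code{\link{findModes}}.
#' @param stack the \linkS4class{LayerStack} it was solved on.
#' @param wave the \linkS4class{WaveParams} it was solved with.
#' @param x transverse positions (vectorized; any real value).
#' @return data.frame with columns \code{x}, \code{e}, \code{h}.
#' @export
fieldProfile <- function(mode, stack, wave, x) {
  a <- stack@a
  k0 <- wave@k0
  g0 <- mode@kLayer[1]; k <- mode@kLayer[2:5]; g5 <- mode@kLayer[6]
  phi <- mode@phi; e <- mode@amp
  region <- findInterval(x, c(0, a)) + 1L  # 1..6 for regions 0..5
  ev <- hv <- numeric(length(x))
  for (i in seq_along(x)) {
    r <- region[i]; xi <- x[i]
    if (r == 1L) {
      ev[i] <- e[1] * exp(g0 * xi)
      hv[i] <- (g0 / k0) * e[1] * exp(g0 * xi)
    } else if (r == 6L) {
      ev[i] <- e[6] * exp(g5 * (a[4] - xi))
      hv[i] <- -(g5 / k0) * e[6] * exp(g5 * (a[4] - xi))
    } else {
      j <- r - 1L
      ev[i] <- e[j + 1] * cos(k[j] * xi + phi[j])
      hv[i] <- -(k[j] / k0) * e[j + 1] * sin(k[j] * xi + phi[j])
    }
  }
  data.frame(x = x, e = ev, h = hv)
}

#' Boundary impedance-continuity check for a mode
#'
#' Evaluates the logarithmic derivative e'(x)/e(x) one-sidedly on both
#' sides of each of the five region boundaries and returns the maximum
#' relative mismatch. For a genuine guided mode this is at solver-tolerance
#' level at every boundary, independently of how the mode was found.
#'
#' @param mode a \linkS4class{ModeSolution}.
#' @param stack its \linkS4class{LayerStack}.
#' @return numeric(5): relative impedance mismatch at x = 0, a1..a4.
#' @export
impedanceMismatch <- function(mode, stack) {
  a <- c(0, stack@a)
  g0 <- mode@kLayer[1]; k <- mode@kLayer[2:5]; g5 <- mode@kLayer[6]
  phi <- mode@phi
  ## boundary j sits at a[j] and separates region j-1 (lower side) from
  ## region j (upper side); e'/e is g0 in region 0, -k_i tan(k_i x + phi_i)
  ## in layer i, -g5 in region 5
  lower <- c(g0, -k[1:4] * tan(k[1:4] * a[2:5] + phi[1:4]))
  upper <- c(-k[1:4] * tan(k[1:4] * a[1:4] + phi[1:4]), -g5)
  scale <- pmax(abs(lower), abs(upper), mode@kLayer[1])
  abs(lower - upper) / scale
}
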