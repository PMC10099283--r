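## Geometric-optics approximation: Snell refraction chain, per-layer
## acceptance angles, the TIR decision rule and the LED injection cone.
## All angles are measured FROM THE INTERFACE NORMAL, in degrees; the
## complement gamma = 90 - theta is reported alongside where useful.

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

#' Snell refraction chain through a sequence of media
#'
#' Applies \code{n_i sin(theta_i) = n_{i-1} sin(theta_{i-1})} through the
#' index list, starting from \code{thetaEntry} in the first medium. If the
#' sine would exceed 1 at an interface (entering a lower-index medium too
#' obliquely) that interface and all following ones are flagged as total
#' internal reflection and the angle is reported as NA from there on.
#'
#' @param nList refractive indices of the media in traversal order (all
#'   >= 1).
#' @param thetaEntry angle from the normal in the first medium (degrees,
#'   0..90).
#' @return data.frame with columns \code{n}, \code{theta} (degrees),
#'   \code{gamma} (= 90 - theta) and \code{tir} (logical).
#' @examples
#' snellChain(c(1, 1.41, 1.40, 1.39, 1.38, 1), 90)
#' @export
snellChain <- function(nList, thetaEntry) {
  if (any(nList < 1)) stop("all refractive indices must be >= 1")
  if (thetaEntry < 0 || thetaEntry > 90)
    stop("thetaEntry must lie in [0, 90] degrees")
  m <- length(nList)
  theta <- rep(NA_real_, m)
  tir <- rep(FALSE, m)
  theta[1] <- thetaEntry
  inv <- nList[1] * sin(.deg2rad(thetaEntry))  # the Snell invariant
  for (i in seq_len(m)[-1]) {
    s <- inv / nList[i]
    if (s > 1 + 1e-12) {
      tir[i:m] <- TRUE
      break
    }
    theta[i] <- .rad2deg(asin(min(s, 1)))
  }
  data.frame(n = nList, theta = theta, gamma = 90 - theta, tir = tir)
}

#' Acceptance angle of a waveguide layer
#'
#' Largest launch angle (from the normal of the guide's end face) for
#' which light in a layer of index n stays confined by TIR against air:
#' \code{asin(sqrt(n^2 - 1))}, in degrees. For n above sqrt(2) every
#' launch angle is confined and the full 90-degree cone is returned with
#' a note.
#'
#' @param n refractive index (vectorized), must be >= 1.
#' @return acceptance angle(s) in degrees, full precision (round only for
#'   display).
#' @examples
#' round(acceptanceAngle(c(1.41, 1.40, 1.39, 1.38)), 2)
#' @export
acceptanceAngle <- function(n) {
  if (any(n < 1)) stop("refractive index must be >= 1")
  out <- numeric(length(n))
  over <- n > sqrt(2)
  if (any(over)) {
    message("index above sqrt(2): acceptance cone saturates at 90 degrees")
    out[over] <- 90
  }
  out[!over] <- .rad2deg(asin(pmin(sqrt(n[!over]^2 - 1), 1)))
  out
}

#' Truncate an angle to the printed two-decimal convention
#'
#' The device report quotes angles truncated (not rounded) at two
#' decimals, and quotes the LED cone as twice the truncated minimum
#' acceptance angle; this helper reproduces that display convention
#' (e.g. 71.9897 degrees prints as 71.98). Internal computation is
#' always full precision.
#'
#' @param x angle(s) in degrees.
#' @param digits decimals kept (default 2).
#' @return truncated value(s).
#' @export
printedAngle <- function(x, digits = 2) trunc(x * 10^digits) / 10^digits

#' Widest LED radiation cone confined in every layer
#'
#' Twice the smallest per-layer acceptance angle: an LED whose spatial
#' radiation pattern is narrower than this full-cone angle launches only
#' rays that stay confined by TIR in all four layers.
#'
#' @param stack a \linkS4class{LayerStack}, or a numeric vector of inner
#'   layer indices.
#' @return full-cone angle in degrees.
#' @examples
#' ledCone(c(1.41, 1.40, 1.39, 1.38))
#' @export
ledCone <- function(stack) {
  n <- if (is(stack, "LayerStack")) refractiveIndices(stack)[2:5]
       else as.numeric(stack)
  2 * min(acceptanceAngle(n))
}

#' Binary total-internal-reflection decision
#'
#' TRUE iff light travelling in the denser medium meets the interface
#' beyond the critical angle \code{asin(nTo/nFrom)}. Incidence exactly at
#' the critical angle is treated as refracted (strict inequality).
#'
#' @param nFrom,nTo refractive indices on the incidence and transmission
#'   sides (>= 1).
#' @param incidence angle from the interface normal, degrees, 0..90.
#' @return logical.
#' @export
tirDecision <- function(nFrom, nTo, incidence) {
  if (any(c(nFrom, nTo) < 1)) stop("refractive indices must be >= 1")
  if (any(incidence < 0 | incidence > 90))
    stop("incidence must lie in [0, 90] degrees")
  nFrom > nTo & incidence > .rad2deg(asin(pmin(nTo / nFrom, 1)))
}

#' Per-layer acceptance-angle table for a stack
#'
#' @param stack a \linkS4class{LayerStack}.
#' @return data.frame with layer, index, full-precision acceptance angle
#'   and its printed (truncated, 2 d.p.) form; attributes
#'   \code{"ledCone"} (full precision) and \code{"ledConePrinted"}
#'   (twice the truncated minimum, the report convention).
#' @export
acceptanceTable <- function(stack) {
  n <- refractiveIndices(stack)[2:5]
  acc <- acceptanceAngle(as.numeric(n))
  tab <- data.frame(layer = 1:4, n = as.numeric(n), acceptance_deg = acc,
                    printed_deg = printedAngle(acc))
  attr(tab, "ledCone") <- ledCone(stack)
  attr(tab, "ledConePrinted") <- 2 * min(printedAngle(acc))
  tab
}
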