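## 2D side-view ray tracer for the millimetre-scale waveguide.
##
## Coordinates: z runs along the guide (0..length, light injected at the
## left edge, z = 0), x is depth below the undeformed top surface (0 at
## the contact surface, a4 at the outer glass face). A contact indentation
## presses the top surface down to x = delta(z) >= 0. Reflection is
## binary: a ray either reflects totally (specular) or leaves the guide
## with its full unit power (no Fresnel partial reflections).

#' Construct a ray-tracing waveguide geometry
#'
#' Defaults follow the physical device: PDMS layers of 6, 9 and 15 mm over
#' a 3 mm glass plate (cumulative boundaries 6, 15, 30, 33 mm) with
#' indices 1.41/1.40/1.39/1.38 in air.
#'
#' @param length guide length along z (mm).
#' @param boundaries cumulative layer boundaries a1..a4 (mm).
#' @param indices refractive indices n0..n5.
#' @return a \linkS4class{WaveguideGeometry}.
#' @export
waveguideGeometry <- function(length = 100,
                              boundaries = c(6, 15, 30, 33),
                              indices = c(1, 1.41, 1.40, 1.39, 1.38, 1)) {
  if (length <= 0) stop("degenerate geometry: guide length must be > 0")
  new("WaveguideGeometry", length = length,
      boundaries = as.numeric(boundaries), indices = as.numeric(indices))
}

#' Construct a surface indentation
#'
#' @param centerZ bump centre along the guide (mm).
#' @param depth maximum displacement (mm); 0 = undeformed surface.
#' @param width lateral extent (mm).
#' @param profile shape identifier; only \code{"cosine"} (a smooth raised
#'   cosine with continuous slope) is implemented.
#' @return an \linkS4class{Indentation}.
#' @export
indentation <- function(centerZ, depth, width, profile = "cosine") {
  new("Indentation", centerZ = centerZ, depth = depth, width = width,
      profile = profile)
}

#' Indentation surface displacement and slope
#'
#' @param indent an \linkS4class{Indentation}.
#' @param z positions along the guide (mm), vectorized.
#' @return list with \code{delta} (displacement, mm) and \code{slope}
#'   (d delta / d z).
#' @export
indentSurface <- function(indent, z) {
  u <- z - indent@centerZ
  inside <- abs(u) <= indent@width / 2 & indent@depth > 0
  delta <- slope <- numeric(length(z))
  if (any(inside)) {
    w <- indent@width
    delta[inside] <- indent@depth * (0.5 + 0.5 * cos(2 * pi * u[inside] / w))
    slope[inside] <- -indent@depth * pi / w * sin(2 * pi * u[inside] / w)
  }
  list(delta = delta, slope = slope)
}

## first intersection of the segment p + t*d, t in (0, tMax], with the
## deformed top surface x = delta(z); returns t or NA. g(t) = x(t) -
## delta(z(t)) is positive inside the material.
.surfaceHit <- function(indent, z, x, d, tMax) {
  if (!is.finite(tMax) || tMax <= 0) return(NA_real_)
  flat <- indent@depth == 0
  footprint <- c(indent@centerZ - indent@width / 2,
                 indent@centerZ + indent@width / 2)
  zr <- sort(c(z, z + tMax * d[1]))
  touchesBump <- !flat && zr[2] >= footprint[1] && zr[1] <= footprint[2] &&
    min(x, x + tMax * d[2]) <= indent@depth
  if (!touchesBump) {
    ## flat surface x = 0; only an upward ray can reach it
    if (d[2] < 0) {
      t0 <- -x / d[2]
      if (t0 > 0 && t0 <= tMax) return(t0)
    }
    return(NA_real_)
  }
  g <- function(t) x + t * d[2] - indentSurface(indent, z + t * d[1])$delta
  ts <- seq(0, tMax, length.out = 257L)
  gs <- g(ts)
  sc <- which(gs[-length(gs)] > 0 & gs[-1] <= 0)
  if (!length(sc)) return(NA_real_)
  j <- sc[1]
  if (gs[j + 1] == 0) return(ts[j + 1])
  uniroot(g, c(ts[j], ts[j + 1]), tol = 1e-12)$root
}

#' Trace a single ray through the (possibly deformed) waveguide
#'
#' The ray starts at the left edge (z = 0) and advances segment by
#' segment. At internal layer boundaries Snell refraction is applied
#' (rays that would become evanescent reflect specularly). At the top
#' surface the local normal comes from the indentation profile and the
#' TIR rule decides between a specular bounce and escape; the glass-air
#' bottom face is treated the same way. The trace ends at a guide end, at
#' the first escape, or at the bounce limit.
#'
#' @param geom a \linkS4class{WaveguideGeometry}.
#' @param indent an \linkS4class{Indentation} (depth 0 for the undeformed
#'   guide).
#' @param launchAngle angle from the guide axis in degrees, |angle| < 90;
#'   positive angles point towards the glass (increasing depth x).
#' @param maxBounces reflection/refraction event limit (>= 1, default
#'   10000); exceeding it truncates the ray.
#' @param launchHeight starting depth x at z = 0 (mm); defaults to
#'   mid-depth of the stack.
#' @return a \linkS4class{RayPath}.
#' @export
traceRay <- function(geom, indent, launchAngle, maxBounces = 10000,
                     launchHeight = geom@boundaries[4] / 2) {
  if (abs(launchAngle) >= 90) stop("|launchAngle| must be < 90 degrees")
  if (maxBounces < 1) stop("maxBounces must be >= 1")
  a <- geom@boundaries
  n <- geom@indices        # n0..n5
  L <- geom@length
  th <- launchAngle * pi / 180
  d <- c(cos(th), sin(th))
  z <- 0; x <- launchHeight
  if (x <= indentSurface(indent, 0)$delta || x >= a[4])
    stop("launchHeight must lie strictly inside the guide")
  eps <- 1e-9 * max(L, a[4])
  segs <- list()
  bounces <- 0L
  terminated <- NULL; scatterZ <- NA_real_; scatterB <- NA_character_
  repeat {
    layer <- findInterval(x, a) + 1L          # 1..4
    layer <- min(max(layer, 1L), 4L)
    tEnd <- if (d[1] > 0) (L - z) / d[1] else if (d[1] < 0) -z / d[1] else Inf
    ## next horizontal plane in the travel direction (NA for the top
    ## surface, which is handled separately)
    tPlane <- Inf; plane <- NA_integer_
    if (d[2] > 0) {
      tPlane <- (a[layer] - x) / d[2]; plane <- layer
    } else if (d[2] < 0 && layer > 1L) {
      tPlane <- (a[layer - 1L] - x) / d[2]; plane <- layer - 1L
    }
    tSurf <- if (layer == 1L)
      .surfaceHit(indent, z, x, d, min(tEnd, tPlane)) else NA_real_
    tHit <- min(tEnd, tPlane, tSurf, na.rm = TRUE)
    zNew <- z + tHit * d[1]; xNew <- x + tHit * d[2]
    segs[[length(segs) + 1L]] <- c(z, x, zNew, xNew)
    if (!is.na(tSurf) && tSurf <= min(tEnd, tPlane)) {
      ## top-surface event
      sl <- indentSurface(indent, zNew)$slope
      m <- c(-sl, 1) / sqrt(sl^2 + 1)         # normal, into the material
      cosInc <- min(1, abs(sum(d * m)))
      inc <- acos(cosInc) * 180 / pi
      if (tirDecision(n[2], n[1], inc)) {
        d <- d - 2 * sum(d * m) * m
        bounces <- bounces + 1L
        z <- zNew + eps * d[1]; x <- xNew + eps * d[2]
      } else {
        terminated <- "scattered"; scatterZ <- zNew; scatterB <- "top"
        z <- zNew; x <- xNew
      }
    } else if (tEnd <= min(tPlane, tSurf, na.rm = TRUE)) {
      terminated <- "exit_end"
      z <- zNew; x <- xNew
    } else {
      ## horizontal plane event at a[plane]
      sinIn <- abs(d[1]); cosIn <- abs(d[2])
      if (plane == 4L && d[2] > 0) {
        ## glass-air bottom face
        inc <- acos(min(1, cosIn)) * 180 / pi
        if (tirDecision(n[5], n[6], inc)) {
          d[2] <- -d[2]; bounces <- bounces + 1L
        } else {
          terminated <- "scattered"; scatterZ <- zNew; scatterB <- "bottom"
        }
      } else {
        nFrom <- n[1 + layer]
        nTo <- n[1 + layer + sign(d[2])]
        sinOut <- nFrom * sinIn / nTo
        if (sinOut > 1) {
          d[2] <- -d[2]; bounces <- bounces + 1L  # evanescent: reflect
        } else {
          d <- c(sign(d[1]) * sinOut, sign(d[2]) * sqrt(1 - sinOut^2))
          bounces <- bounces + 1L
        }
      }
      z <- zNew + eps * d[1]; x <- xNew + eps * d[2]
    }
    if (!is.null(terminated)) break
    if (bounces >= maxBounces) { terminated <- "absorbed_bounce_limit"; break }
  }
  segm <- do.call(rbind, segs)
  colnames(segm) <- c("z0", "x0", "z1", "x1")
  new("RayPath", launchAngle = launchAngle, segments = segm,
      terminatedBy = terminated, scatterPoint = scatterZ,
      scatterIntensity = if (identical(terminated, "scattered")) 1 else 0,
      scatterBoundary = scatterB)
}

#' Largest launch angle confined by TIR
#'
#' A ray launched at depth \code{launchHeight} keeps the Snell invariant
#' \code{n_layer * sin(theta_from_normal)}; it stays totally reflected at
#' both air faces iff that invariant exceeds 1. The bound on the launch
#' angle measured from the guide axis is \code{90 - asin(1/n_launch)}
#' degrees.
#'
#' @param geom a \linkS4class{WaveguideGeometry}.
#' @param launchHeight starting depth (mm).
#' @return maximum confined |launch angle| from the axis, degrees.
#' @export
maxConfinedLaunchAngle <- function(geom,
                                   launchHeight = geom@boundaries[4] / 2) {
  layer <- min(max(findInterval(launchHeight, geom@boundaries) + 1L, 1L), 4L)
  nl <- geom@indices[1 + layer]
  90 - asin(geom@indices[1] / nl) * 180 / pi
}

#' Scattered-light surface profile from a deterministic ray fan
#'
#' Launches \code{nRays} rays with angles uniformly spaced over
#' \code{fan} from the left edge, traces each, and accumulates the power
#' escaping through the TOP surface into uniform bins along z. Power
#' escaping through the bottom face, through the guide ends, or truncated
#' at the bounce limit is tallied separately so that the budget closes
#' exactly.
#'
#' @param geom a \linkS4class{WaveguideGeometry}.
#' @param indent an \linkS4class{Indentation}.
#' @param nRays number of rays (>= 1).
#' @param fan numeric(2), launch-angle range in degrees (from the axis).
#' @param nBins number of surface bins (default 200).
#' @param launchHeight starting depth (mm).
#' @param maxBounces per-ray bounce limit.
#' @param random launch a seeded random fan instead of the uniform one.
#' @param seed RNG seed used when \code{random = TRUE}.
#' @return data.frame with columns \code{z} (bin centres, mm) and
#'   \code{intensity} (summed escaped power); attributes \code{power}
#'   (named totals: launched, exit_end, scattered_top, scattered_bottom,
#'   truncated) and \code{rays} (list of \linkS4class{RayPath}).
#' @export
surfaceScatterProfile <- function(geom, indent, nRays, fan = c(-40, 40),
                                  nBins = 200,
                                  launchHeight = geom@boundaries[4] / 2,
                                  maxBounces = 10000, random = FALSE,
                                  seed = 1L) {
  if (nRays < 1) stop("nRays must be >= 1")
  angles <- if (random)
    withSeed(seed, runif(nRays, fan[1], fan[2]))
  else if (nRays == 1) mean(fan)
  else seq(fan[1], fan[2], length.out = nRays)
  rays <- lapply(angles, function(ang)
    traceRay(geom, indent, ang, maxBounces = maxBounces,
             launchHeight = launchHeight))
  term <- vapply(rays, function(r) r@terminatedBy, character(1))
  bnd <- vapply(rays, function(r) r@scatterBoundary, character(1))
  power <- c(launched = length(rays),
             exit_end = sum(term == "exit_end"),
             scattered_top = sum(term == "scattered" & bnd == "top"),
             scattered_bottom = sum(term == "scattered" & bnd == "bottom"),
             truncated = sum(term == "absorbed_bounce_limit"))
  breaks <- seq(0, geom@length, length.out = nBins + 1)
  intensity <- numeric(nBins)
  for (r in rays) {
    if (r@terminatedBy == "scattered" && r@scatterBoundary == "top") {
      b <- min(max(findInterval(r@scatterPoint, breaks,
                                rightmost.closed = TRUE), 1L), nBins)
      intensity[b] <- intensity[b] + r@scatterIntensity
    }
  }
  out <- data.frame(z = (breaks[-1] + breaks[-(nBins + 1)]) / 2,
                    intensity = intensity)
  attr(out, "power") <- power
  attr(out, "rays") <- rays
  out
}
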