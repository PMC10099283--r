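## Independent oracles used across the suite. These deliberately avoid
## the package's phase-chaining formulation.

## Transfer-matrix TE residual: propagate (e, e') through the four layers
## starting from the lower evanescent tail and impose the upper decay.
tmmResidual <- function(n, h, k0, beta) {
  g0 <- sqrt(beta^2 - (k0 * n[1])^2)
  g5 <- sqrt(beta^2 - (k0 * n[6])^2)
  v <- c(1, g0)
  for (i in 1:4) {
    kap2 <- (k0 * n[i + 1])^2 - beta^2
    if (kap2 > 0) {
      k <- sqrt(kap2)
      M <- matrix(c(cos(k * h[i]), -k * sin(k * h[i]),
                    sin(k * h[i]) / k, cos(k * h[i])), 2, 2)
    } else {
      g <- sqrt(-kap2)
      M <- matrix(c(cosh(g * h[i]), g * sinh(g * h[i]),
                    sinh(g * h[i]) / g, cosh(g * h[i])), 2, 2)
    }
    v <- M %*% v
  }
  v[2] + g5 * v[1]
}

## Brute-force guided-mode search on a dense grid + uniroot polish,
## restricted (like the package) to k0*n0 < beta < k0*n4.
tmmModes <- function(n, h, k0, npts = 40001) {
  lo <- k0 * n[1]; hi <- k0 * n[5]
  bs <- seq(lo + (hi - lo) * 1e-9, hi - (hi - lo) * 1e-9, length.out = npts)
  rs <- vapply(bs, function(b) tmmResidual(n, h, k0, b), numeric(1))
  idx <- which(rs[-npts] * rs[-1] < 0)
  roots <- c()
  for (j in idx) {
    r <- uniroot(function(b) tmmResidual(n, h, k0, b),
                 c(bs[j], bs[j + 1]), tol = 1e-14)$root
    if (abs(tmmResidual(n, h, k0, r)) < min(abs(rs[j]), abs(rs[j + 1])))
      roots <- c(roots, r)
  }
  sort(roots, decreasing = TRUE)
}

## Closed-form symmetric single-slab TE modes (core index nco, total
## thickness d, cladding 1): k*d = 2*atan(g/k) + m*pi.
slabModes <- function(nco, d, k0) {
  roots <- c()
  for (m in 0:200) {
    f <- function(b) {
      k <- sqrt((k0 * nco)^2 - b^2); g <- sqrt(b^2 - k0^2)
      k * d - 2 * atan(g / k) - m * pi
    }
    lo <- k0 * (1 + 1e-10); hi <- k0 * nco * (1 - 1e-10)
    if (f(lo) * f(hi) < 0)
      roots <- c(roots, uniroot(f, c(lo, hi), tol = 1e-14)$root)
    else break
  }
  sort(roots, decreasing = TRUE)
}

## random admissible thin stack + wavelength, as used by the oracle
## equivalence checks
randomStack <- function() {
  n4 <- runif(1, 1.2, 1.45)
  gaps <- sort(runif(3, 0.005, 0.05))
  ns <- n4 + c(sum(gaps), sum(gaps[1:2]), gaps[1], 0)
  hs <- runif(4, 0.5, 4)
  list(stack = layerStack(ns[1], ns[2], ns[3], ns[4], heights = hs),
       n = c(1, ns, 1), h = hs, wave = waveParams(runif(1, 0.4, 0.7)))
}

## Direct per-pixel brute-force fuzzy-entropy threshold (no histogram
## shortcuts): for every candidate level, class means, Huang-Wang
## memberships and summed binary Shannon entropy.
bruteFuzzyThreshold <- function(px) {
  x <- as.vector(px)
  lv <- sort(unique(x))
  C <- max(x) - min(x)
  xlx <- function(v) ifelse(v > 0, v * log(v), 0)
  ents <- sapply(lv[-length(lv)], function(t) {
    lowMean <- mean(x[x <= t]); highMean <- mean(x[x > t])
    mu <- ifelse(x <= t, 1 / (1 + abs(x - lowMean) / C),
                 1 / (1 + abs(x - highMean) / C))
    -sum(xlx(mu) + xlx(1 - mu)) / (length(x) * log(2))
  })
  j <- which.min(ents)
  (lv[j] + lv[j + 1]) / 2   # class boundary between the two levels
}

## Exact O(n^2) pairwise concordance
pairwiseAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
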