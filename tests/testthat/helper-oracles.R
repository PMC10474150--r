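## Independent oracles used across the suite. These deliberately share no
## code with the implementation: the phantom oracle re-rasterizes the
## ellipse sums pointwise with scalar loops, the strip-area oracles use
## Sutherland-Hodgman polygon clipping and subcell-center counting, and
## the residual oracle evaluates ||A x - P||^2 directly.

# pointwise ellipse-sum rasterization (scalar loops, base trig)
oracleSheppLogan <- function(n, variant = "modified") {
  tab <- sheppLoganTable(variant)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      x <- -1 + (2 * j - 1) / n
      y <- 1 - (2 * i - 1) / n
      v <- 0
      for (e in seq_len(nrow(tab))) {
        phi <- tab[e, "phi"] * pi / 180
        dx <- x - tab[e, "x0"]; dy <- y - tab[e, "y0"]
        xr <- dx * cos(phi) + dy * sin(phi)
        yr <- -dx * sin(phi) + dy * cos(phi)
        if ((xr / tab[e, "a"])^2 + (yr / tab[e, "b"])^2 <= 1)
          v <- v + tab[e, "intensity"]
      }
      out[i, j] <- min(max(v, 0), 1)
    }
  }
  out
}

# clip a convex polygon (rows = vertices) against a*x + b*y <= c
clipHalfplane <- function(poly, a, b, c) {
  if (is.null(poly) || nrow(poly) == 0) return(poly)
  n <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(n)) {
    p <- poly[k, ]; q <- poly[k %% n + 1, ]
    fp <- a * p[1] + b * p[2] - c
    fq <- a * q[1] + b * q[2] - c
    if (fp <= 0) out <- rbind(out, p)
    if ((fp < 0) != (fq < 0)) {
      t <- fp / (fp - fq)
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

polygonArea <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

pixelCorners <- function(i, j, n) {
  x0 <- j - 1 - n / 2; y0 <- n / 2 - i
  rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1))
}

# exact pixel/strip overlap by polygon clipping; lo/hi may be +-Inf
# (extended end bins)
oracleStripAreaClip <- function(i, j, n, thetaDeg, lo, hi) {
  ct <- cos(thetaDeg * pi / 180); st <- sin(thetaDeg * pi / 180)
  poly <- pixelCorners(i, j, n)
  if (is.finite(hi)) poly <- clipHalfplane(poly, ct, st, hi)
  if (is.finite(lo)) poly <- clipHalfplane(poly, -ct, -st, -lo)
  polygonArea(poly)
}

# subdivide the pixel into k x k subcells and count centers in the strip
oracleStripAreaSupersample <- function(i, j, n, thetaDeg, lo, hi, k = 512) {
  ct <- cos(thetaDeg * pi / 180); st <- sin(thetaDeg * pi / 180)
  x0 <- j - 1 - n / 2; y0 <- n / 2 - i
  cs <- (seq_len(k) - 0.5) / k
  x <- x0 + rep(cs, times = k)
  y <- y0 + rep(cs, each = k)
  t <- x * ct + y * st
  sum(t >= lo & t < hi) / k^2
}

# strip bounds of bin s under the package's convention
binBounds <- function(s, n, numBins = n) {
  c(if (s == 1) -Inf else s - 1 - n / 2,
    if (s == numBins) Inf else s - n / 2)
}

# squared sinogram residual of a flat row-major pixel vector
oracleResidual <- function(sm, sino, pixels) {
  A <- coefficientMatrix(sm)
  P <- as.vector(t(sinogramValues(sino)))
  sum((as.numeric(A %*% pixels) - P)^2)
}

# random consistent instance: integer image + its sinogram
randomInstance <- function(n, m, numProjections) {
  vals <- matrix(sample(0:(2^(m + 1) - 1), n * n, replace = TRUE), n, n)
  img <- ImageGrid(vals, bitDepth = m + 1L)
  sm <- systemMatrix(makeGeometry(n, numProjections))
  list(img = img, sm = sm, sino = project(img, sm))
}

randomBits <- function(k) sample(0:1, k, replace = TRUE)

# the worked-example model: 2x2 sample, two angles, two bits per pixel
toyQubo <- function() {
  sm <- systemMatrix(makeGeometry(2, 2))
  buildQubo(sm, project(toySample2x2(), sm), m = 1)
}
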