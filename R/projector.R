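## Parallel-beam geometry, exact overlap-area system matrix, forward
## projection.
##
## Conventions: pixel (i, j) is row i from the top, column j, a unit square
## on an image centered at the origin (pixel (i, j) spans x in
## [j - 1 - n/2, j - n/2], y in [n/2 - i, n/2 - i + 1]). The detector
## coordinate at angle theta (degrees, counterclockwise) is
## t = x cos(theta) + y sin(theta); bin s collects t in
## [s - 1 - n/2, s - n/2], so at theta = 0 bin s is exactly column s and at
## theta = 90 bin s is row n + 1 - s. The two end bins are extended to
## half-infinite strips so the detector spans the image at every angle,
## which keeps per-pixel area conservation exact at oblique angles.

#' Construct an equally spaced projection geometry
#'
#' The sweep covers \code{[0, 180)} end-exclusively: with
#' \code{dtheta = 180 / numProjections} the angles are
#' \code{0, dtheta, ..., 180 - dtheta}. One detector bin per image column
#' (\code{numBins = n}, unit bin width).
#'
#' @param n image side in pixels.
#' @param numProjections number of equally spaced projection angles.
#' @return a [ProjectionGeometry-class].
#' @examples
#' projectionAngles(makeGeometry(2, 2))    # 0 90
#' projectionAngles(makeGeometry(30, 30))  # 0, 6, ..., 174
#' @export
makeGeometry <- function(n, numProjections) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer")
  if (!is.numeric(numProjections) || length(numProjections) != 1L ||
      numProjections < 1 || numProjections != round(numProjections))
    stop("'numProjections' must be a positive integer")
  dtheta <- 180 / numProjections
  new("ProjectionGeometry", n = as.integer(n),
      angles = dtheta * (seq_len(numProjections) - 1),
      numBins = as.integer(n), binWidth = 1)
}

#' Arbitrary-angle geometry
#'
#' @param n image side in pixels.
#' @param angles strictly increasing projection angles in \code{[0, 180)}.
#' @return a [ProjectionGeometry-class].
#' @export
geometryFromAngles <- function(n, angles) {
  new("ProjectionGeometry", n = as.integer(n), angles = as.numeric(angles),
      numBins = as.integer(n), binWidth = 1)
}

# Fraction of a unit pixel square with detector coordinate t <= tc + u,
# where the square's t-extent is tc +/- (|cos| + |sin|)/2. The projection of
# a uniform point in the square onto t is the sum of two independent
# uniforms of widths |cos(theta)| and |sin(theta)|, so the cumulative area
# is the trapezoidal CDF below -- identical to the polygon-clipping area but
# vectorizable.
.areaBelow <- function(u, a, b) {
  mx <- max(a, b); mn <- min(a, b)
  out <- numeric(length(u))
  if (mn < 1e-14) {            # axis-aligned: uniform of width mx (= 1)
    out <- pmin(pmax(u / mx + 0.5, 0), 1)
  } else {
    h <- (mx + mn) / 2; f <- (mx - mn) / 2; ab2 <- 2 * mx * mn
    out[u >= h] <- 1
    k <- u > -h & u < -f
    out[k] <- (u[k] + h)^2 / ab2
    k <- u >= -f & u <= f
    out[k] <- mn / (2 * mx) + (u[k] + f) / mx
    k <- u > f & u < h
    out[k] <- 1 - (h - u[k])^2 / ab2
  }
  out[u == Inf] <- 1
  out[u == -Inf] <- 0
  out
}

#' Compute the sparse overlap-area system matrix
#'
#' For every angle, detector bins are unit-width strips perpendicular to
#' the rays; the coefficient of pixel \code{(i, j)} for bin \code{s} is the
#' exact area of intersection between the unit pixel square and the strip.
#' Coefficients below \code{prune} are dropped. For every pixel and angle
#' the coefficients over that angle's bins sum to the pixel area, 1.
#'
#' @param geom a [ProjectionGeometry-class].
#' @param prune sparsity threshold on coefficients (default \code{1e-12}).
#' @return a [SystemMatrix-class].
#' @export
systemMatrix <- function(geom, prune = 1e-12) {
  stopifnot(is(geom, "ProjectionGeometry"))
  n <- geom@n
  nb <- geom@numBins
  npx <- n * n
  # row-major pixel centers
  j <- rep(seq_len(n), times = n)        # column
  i <- rep(seq_len(n), each = n)         # row
  xc <- j - (n + 1) / 2
  yc <- (n + 1) / 2 - i
  ri <- list(); ci <- list(); xs <- list()
  for (ai in seq_along(geom@angles)) {
    th <- geom@angles[ai]
    cth <- cospi(th / 180); sth <- sinpi(th / 180)
    a <- abs(cth); b <- abs(sth)
    tc <- xc * cth + yc * sth
    h <- (a + b) / 2
    sFirst <- pmax(1L, pmin(nb, as.integer(floor(tc - h + n / 2 - 1e-12)) + 1L))
    sLast  <- pmin(nb, pmax(1L, as.integer(ceiling(tc + h + n / 2 + 1e-12))))
    maxSpan <- max(sLast - sFirst)
    for (d in 0:maxSpan) {
      s <- sFirst + d
      keep <- s <= sLast
      if (!any(keep)) next
      sk <- s[keep]; tck <- tc[keep]
      lo <- ifelse(sk == 1L, -Inf, sk - 1 - n / 2)
      hi <- ifelse(sk == nb, Inf, sk - n / 2)
      area <- .areaBelow(hi - tck, a, b) - .areaBelow(lo - tck, a, b)
      pos <- area > prune
      if (!any(pos)) next
      ri[[length(ri) + 1L]] <- (ai - 1L) * nb + sk[pos]
      ci[[length(ci) + 1L]] <- which(keep)[pos]
      xs[[length(xs) + 1L]] <- area[pos]
    }
  }
  A <- Matrix::sparseMatrix(i = unlist(ri), j = unlist(ci), x = unlist(xs),
                            dims = c(length(geom@angles) * nb, npx))
  new("SystemMatrix", geometry = geom, A = as(A, "CsparseMatrix"))
}

#' @describeIn project Project an ImageGrid through a SystemMatrix.
#' @export
setMethod("project", signature("ImageGrid", "SystemMatrix"), function(img, sm) {
  g <- sm@geometry
  if (imageSide(img) != g@n)
    stop(sprintf("image side %d does not match geometry side %d",
                 imageSide(img), g@n))
  v <- as.vector(t(imageValues(img)))          # row-major pixel order
  p <- as.numeric(sm@A %*% v)
  new("Sinogram", geometry = g,
      values = matrix(p, nrow = length(g@angles), ncol = g@numBins,
                      byrow = TRUE))
})

#' @describeIn project Plain-matrix convenience method.
#' @export
setMethod("project", signature("matrix", "SystemMatrix"), function(img, sm) {
  grid <- if (all(img == round(img)) && all(img >= 0))
    ImageGrid(img, bitDepth = bitsNeeded(max(img))) else ImageGrid(img)
  project(grid, sm)
})

#' Construct a Sinogram from raw values
#'
#' @param values numeric matrix, one row per angle, one column per bin.
#' @param geom the matching [ProjectionGeometry-class].
#' @return a [Sinogram-class].
#' @export
Sinogram <- function(values, geom) {
  new("Sinogram", geometry = geom, values = as.matrix(values))
}
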