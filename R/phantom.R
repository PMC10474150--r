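## Shepp-Logan phantom generation and pixel-value quantization.

# Canonical ten-ellipse parameter table. Columns: additive intensity A,
# semi-axes a (x) and b (y), center (x0, y0), rotation phi in degrees
# (counterclockwise). Coordinates live on [-1, 1]^2.
.SHEPP_LOGAN_TABLES <- list(
  original = matrix(c(
     2.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.98, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.02, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.02, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.01, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.01, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.01, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.01, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.01, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.01, 0.0230, 0.0460,  0.06, -0.6050,   0), ncol = 6, byrow = TRUE),
  modified = matrix(c(
     1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.80, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.20, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.20, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.10, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.10, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.10, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.10, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.10, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.10, 0.0230, 0.0460,  0.06, -0.6050,   0), ncol = 6, byrow = TRUE))

#' Shepp-Logan ellipse parameter table
#'
#' @param variant `"modified"` (high-contrast, the default) or `"original"`.
#' @return a 10 x 6 matrix with columns intensity, a, b, x0, y0, phi (deg).
#' @export
sheppLoganTable <- function(variant = c("modified", "original")) {
  tab <- .SHEPP_LOGAN_TABLES[[match.arg(variant)]]
  colnames(tab) <- c("intensity", "a", "b", "x0", "y0", "phi")
  tab
}

#' Render the Shepp-Logan head phantom
#'
#' Rasterizes the standard multi-ellipse head phantom at \code{n x n}
#' pixels: each pixel takes the sum of ellipse intensities evaluated at its
#' center on the square \code{[-1, 1]^2}, clamped to \code{[0, 1]}.
#' Deterministic for fixed \code{n} and \code{variant}.
#'
#' @param n image side, at least 2.
#' @param variant which ellipse table to use, see [sheppLoganTable()].
#' @return a float [ImageGrid-class] with values in \code{[0, 1]}.
#' @examples
#' ph <- sheppLogan(30)
#' imageValues(binarize(ph))[15, 15]
#' @export
sheppLogan <- function(n, variant = c("modified", "original")) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 || n != round(n))
    stop("'n' must be a single integer >= 2")
  n <- as.integer(n)
  tab <- sheppLoganTable(match.arg(variant))
  # pixel centers: row i from top -> y decreasing, column j -> x increasing
  xs <- -1 + (2 * seq_len(n) - 1) / n
  ys <- 1 - (2 * seq_len(n) - 1) / n
  x <- matrix(xs, n, n, byrow = TRUE)
  y <- matrix(ys, n, n)
  img <- matrix(0, n, n)
  for (e in seq_len(nrow(tab))) {
    A <- tab[e, 1]; a <- tab[e, 2]; b <- tab[e, 3]
    x0 <- tab[e, 4]; y0 <- tab[e, 5]; phi <- tab[e, 6]
    cp <- cospi(phi / 180); sp <- sinpi(phi / 180)
    xr <- (x - x0) * cp + (y - y0) * sp
    yr <- -(x - x0) * sp + (y - y0) * cp
    img <- img + A * ((xr / a)^2 + (yr / b)^2 <= 1)
  }
  ImageGrid(pmin(pmax(img, 0), 1))
}

#' Binarize a float image
#'
#' Pixels strictly above \code{threshold} become 1, all others 0. With the
#' default threshold 0 this is the "binary Shepp-Logan phantom": every
#' strictly positive pixel maps to 1. Idempotent on its own output.
#'
#' @param img float [ImageGrid-class] (an integer grid is accepted and
#'   thresholded the same way).
#' @param threshold nonnegative cut, default 0.
#' @return integer [ImageGrid-class] with \code{bitDepth = 1}.
#' @export
binarize <- function(img, threshold = 0) {
  stopifnot(is(img, "ImageGrid"), threshold >= 0)
  ImageGrid((imageValues(img) > threshold) * 1, bitDepth = 1L)
}

#' Quantize a float image to integers
#'
#' Maps each value \code{v} in \code{[0, 1]} to
#' \code{round(v * (2^bits - 1))} with half-up rounding, so 1.0 maps to
#' \code{2^bits - 1} (1023 for \code{bits = 10}). Monotone in the input.
#'
#' @param img float [ImageGrid-class] with values in \code{[0, 1]}.
#' @param bits bits per pixel, at least 1.
#' @return integer [ImageGrid-class] with \code{bitDepth = bits}.
#' @export
quantize <- function(img, bits) {
  stopifnot(is(img, "ImageGrid"), bits >= 1, bits == round(bits))
  v <- imageValues(img)
  if (any(v < 0 | v > 1)) stop("values must lie in [0, 1] before quantization")
  ImageGrid(floor(v * (2^bits - 1) + 0.5), bitDepth = as.integer(bits))
}

#' The 2x2 worked-example image
#'
#' The two-bit sample \code{[[0, 1], [2, 3]]} (row 1: 0, 1; row 2: 2, 3)
#' whose two-angle (0 and 90 degree) sinogram has values \{2, 4, 5, 1\} and
#' analytic QUBO minimum energy \code{-(2^2 + 4^2 + 5^2 + 1^2) = -46}.
#'
#' @return integer [ImageGrid-class], \code{bitDepth = 2}.
#' @export
toySample2x2 <- function() {
  ImageGrid(matrix(c(0, 1, 2, 3), 2, 2, byrow = TRUE), bitDepth = 2L)
}
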