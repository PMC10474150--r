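## End-to-end reconstruction pipeline: sinogram -> QUBO -> solver ->
## decoded image -> quality report.

#' Decode a bit assignment to an image
#'
#' Inverts the binary pixel expansion \code{I_ij = sum_k 2^k q_k^ij} under
#' the fixed variable order (row-major pixels, ascending bit).
#'
#' @param assignment bit vector of length \code{n^2 (m + 1)}.
#' @param n image side.
#' @param m highest bit exponent.
#' @return integer [ImageGrid-class] with \code{bitDepth = m + 1}.
#' @examples
#' imageValues(decodeImage(c(0, 0, 1, 0, 0, 1, 1, 1), n = 2, m = 1))
#' @export
decodeImage <- function(assignment, n, m) {
  nbits <- m + 1
  if (length(assignment) != n * n * nbits)
    stop(sprintf("assignment length %d; expected n^2 (m+1) = %d",
                 length(assignment), n * n * nbits))
  if (!all(assignment %in% c(0, 1))) stop("assignment entries must be bits")
  B <- matrix(as.numeric(assignment), nrow = nbits)   # bits x pixels
  pix <- as.numeric(2^(0:m) %*% B)
  ImageGrid(matrix(pix, n, n, byrow = TRUE), bitDepth = as.integer(nbits))
}

#' Encode an integer image to a bit vector
#'
#' Inverse of [decodeImage()]: bitwise binary expansion of each pixel in
#' the fixed variable order.
#'
#' @param img integer [ImageGrid-class].
#' @param m highest bit exponent; defaults to the grid's
#'   \code{bitDepth - 1}.
#' @return integer bit vector of length \code{n^2 (m + 1)}.
#' @export
encodeImage <- function(img, m = bitDepth(img) - 1L) {
  stopifnot(is(img, "ImageGrid"), isIntegerGrid(img))
  v <- as.vector(t(imageValues(img)))                 # row-major pixels
  if (any(v > 2^(m + 1) - 1)) stop("pixel values exceed the bit budget")
  as.integer(sapply(v, function(p) (p %/% 2^(0:m)) %% 2))
}

#' Calibrate a raw X-ray image against its empty region
#'
#' Subtracts the mean over the masked empty-space region from every pixel
#' (so empty space averages zero) and clamps negatives to 0. Quantization
#' to integers is a separate explicit step ([quantize()]).
#'
#' @param raw numeric matrix of nonnegative raw values (or a float
#'   [ImageGrid-class]).
#' @param emptyMask logical matrix marking the empty (air) region; must
#'   select at least one pixel.
#' @return numeric matrix of calibrated float values.
#' @export
calibrateXray <- function(raw, emptyMask) {
  if (is(raw, "ImageGrid")) raw <- imageValues(raw)
  stopifnot(is.matrix(raw), is.logical(emptyMask),
            all(dim(raw) == dim(emptyMask)))
  if (!any(emptyMask)) stop("empty mask selects no pixels")
  pmax(raw - mean(raw[emptyMask]), 0)
}

#' Compare two images exactly
#'
#' @param a,b [ImageGrid-class] objects (or matrices) of equal size.
#' @return list with \code{mismatchedPixels} (count of exact integer
#'   inequalities), \code{relativeError} (count / n^2), and
#'   \code{diffImage} (signed \code{a - b}).
#' @export
compareImages <- function(a, b) {
  va <- if (is(a, "ImageGrid")) imageValues(a) else a
  vb <- if (is(b, "ImageGrid")) imageValues(b) else b
  if (!all(dim(va) == dim(vb))) stop("images differ in size")
  mm <- sum(va != vb)
  list(mismatchedPixels = as.integer(mm),
       relativeError = mm / length(va),
       diffImage = va - vb)
}

#' Reconstruct an image from a sinogram
#'
#' The full pipeline: build the system matrix for the sinogram's geometry,
#' assemble the QUBO of the squared residual with \code{m + 1} bits per
#' pixel, minimize it with the requested solver, decode the bits, and
#' report the achieved energy against the analytic minimum
#' \code{-sum P^2}. A zero energy gap certifies that the decoded image
#' reproduces the input sinogram exactly. When \code{reference} is given,
#' exact pixel mismatches and the signed difference map are reported.
#'
#' @param sino a [Sinogram-class].
#' @param m highest bit exponent (bits per pixel \code{= m + 1}).
#' @param solver solver name or function, see [getSolver()].
#' @param reference optional ground-truth [ImageGrid-class].
#' @param sm optional precomputed [SystemMatrix-class] for the geometry.
#' @param ... fixed arguments for the named solver (e.g. \code{seed}).
#' @return a [ReconstructionReport-class].
#' @examples
#' geom <- makeGeometry(2, 2)
#' sm <- systemMatrix(geom)
#' sino <- project(toySample2x2(), sm)
#' rep <- reconstruct(sino, m = 1, solver = "exhaustive",
#'                    reference = toySample2x2())
#' @export
reconstruct <- function(sino, m, solver = "sa", reference = NULL, sm = NULL,
                        ...) {
  stopifnot(is(sino, "Sinogram"))
  g <- sino@geometry
  if (is.null(sm)) sm <- systemMatrix(g)
  qm <- buildQubo(sm, sino, m = m)
  res <- getSolver(solver, ...)(qm)
  img <- decodeImage(res@assignment, n = g@n, m = m)
  expected <- expectedMinEnergy(sino)
  gap <- res@energy - expected
  if (!is.null(reference)) {
    if (imageSide(reference) != g@n) stop("reference size does not match")
    cmp <- compareImages(img, reference)
    mm <- cmp$mismatchedPixels
    rel <- cmp$relativeError
    diff <- cmp$diffImage
  } else {
    mm <- NA_integer_; rel <- NA_real_
    diff <- matrix(NA_real_, 0, 0)
  }
  new("ReconstructionReport", image = img, achievedEnergy = res@energy,
      expectedEnergy = expected, energyGap = gap,
      mismatchedPixels = mm, relativeError = rel, diffImage = diff,
      result = res)
}

#' Render a signed difference map for display
#'
#' Maps signed differences symmetrically about mid-gray: pixels where the
#' reconstruction exceeds the reference darken, pixels where it falls
#' short brighten.
#'
#' @param diffImage signed difference matrix (reference minus
#'   reconstruction, or vice versa).
#' @return numeric matrix in \code{[0, 1]} suitable for raster export.
#' @export
renderDiffImage <- function(diffImage) {
  if (!length(diffImage)) return(diffImage)
  s <- max(abs(diffImage), 1e-12)
  0.5 - diffImage / (2 * s)
}
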