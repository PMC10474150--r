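#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' Square attenuation image
#'
#' An \code{ImageGrid} holds an \code{n x n} map of X-ray mass attenuation
#' values, either as floats in \code{[0, 1]} (pre-quantization) or as
#' nonnegative integers representable in \code{bitDepth} bits. Integer grids
#' are the reconstruction unknowns: each pixel is expanded into
#' \code{bitDepth} binary variables.
#'
#' @slot values numeric matrix, \code{n x n}.
#' @slot bitDepth integer number of bits per pixel (\code{m + 1}), or
#'   \code{NA} for float grids.
#' @export
setClass("ImageGrid",
  representation(values = "matrix", bitDepth = "integer"),
  prototype(values = matrix(0, 2, 2), bitDepth = NA_integer_))

setValidity("ImageGrid", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (nrow(v) != ncol(v)) return("image must be square")
  if (nrow(v) < 1) return("image side must be >= 1")
  if (length(object@bitDepth) != 1L) return("bitDepth must be length 1")
  if (is.na(object@bitDepth)) {
    if (any(v < 0 | v > 1)) return("float grid values must lie in [0, 1]")
  } else {
    if (object@bitDepth < 1L) return("bitDepth must be >= 1")
    if (any(v != round(v))) return("integer grid has non-integer values")
    if (any(v < 0) || any(v > 2^object@bitDepth - 1))
      return(sprintf("integer grid values must lie in [0, %d]",
                     2^object@bitDepth - 1))
  }
  TRUE
})

#' Parallel-beam projection geometry
#'
#' Angles are in degrees, strictly increasing in \code{[0, 180)}; the
#' detector has \code{numBins} unit-width bins per angle. The usual sweep
#' constructor is [makeGeometry()], which takes equally spaced angles
#' \code{0, d, ..., 180 - d}.
#'
#' @slot n image side in pixels.
#' @slot angles numeric vector of projection angles (degrees).
#' @slot numBins detector bins per angle (equal to \code{n}).
#' @slot binWidth detector bin width in pixel units (1).
#' @export
setClass("ProjectionGeometry",
  representation(n = "integer", angles = "numeric", numBins = "integer",
                 binWidth = "numeric"),
  prototype(n = 2L, angles = c(0, 90), numBins = 2L, binWidth = 1))

setValidity("ProjectionGeometry", function(object) {
  if (object@n < 1L) return("n must be positive")
  a <- object@angles
  if (length(a) < 1L) return("at least one angle required")
  if (any(a < 0 | a >= 180)) return("angles must lie in [0, 180)")
  if (length(a) > 1L && any(diff(a) <= 0))
    return("angles must be strictly increasing")
  if (object@numBins < 1L) return("numBins must be positive")
  if (object@binWidth <= 0) return("binWidth must be positive")
  TRUE
})

#' Sparse overlap-area system matrix
#'
#' Row \code{r = (angleIndex - 1) * numBins + s} corresponds to the ray
#' (detector strip) at that angle and bin; column \code{p = (i - 1) * n + j}
#' to pixel \code{(i, j)} in row-major order. Entries are exact pixel/strip
#' overlap areas, so each row of the forward model is
#' \code{IP(theta, s) = sum_ij c_ij I_ij}.
#'
#' @slot geometry a [ProjectionGeometry-class].
#' @slot A \code{dgCMatrix} of overlap coefficients, rays by pixels.
#' @export
setClass("SystemMatrix",
  representation(geometry = "ProjectionGeometry", A = "dgCMatrix"))

setValidity("SystemMatrix", function(object) {
  g <- object@geometry
  if (nrow(object@A) != length(g@angles) * g@numBins)
    return("row count must equal #angles * numBins")
  if (ncol(object@A) != g@n^2)
    return("column count must equal n^2")
  if (any(object@A@x < 0)) return("overlap coefficients must be >= 0")
  if (any(object@A@x > 1 + 1e-9)) return("overlap areas cannot exceed pixel area 1")
  TRUE
})

#' Sinogram of projection values
#'
#' Values \code{P(theta, s)} arranged one row per angle (in sweep order) and
#' one column per detector bin.
#'
#' @slot geometry a [ProjectionGeometry-class].
#' @slot values numeric matrix, angles by bins.
#' @export
setClass("Sinogram",
  representation(geometry = "ProjectionGeometry", values = "matrix"))

setValidity("Sinogram", function(object) {
  g <- object@geometry
  if (!is.numeric(object@values)) return("values must be numeric")
  if (nrow(object@values) != length(g@angles))
    return("one sinogram row per angle required")
  if (ncol(object@values) != g@numBins)
    return("one sinogram column per detector bin required")
  TRUE
})

#' Quadratic unconstrained binary optimization model
#'
#' Energy of a bit vector \code{q} is
#' \code{sum_i linear_i q_i + sum_{i<j} Q_ij q_i q_j}; the constant term
#' \code{offset = sum P(theta,s)^2} of the squared sinogram residual is
#' excluded from the model and tracked separately, so the achievable minimum
#' is \code{-offset} exactly when an integer image consistent with the
#' sinogram exists.
#'
#' Bit variables follow the fixed row-major order: variable
#' \code{((i-1) n + (j-1)) (m+1) + k + 1} is bit \code{k} (value \code{2^k})
#' of pixel \code{(i, j)}.
#'
#' @slot numVars number of binary variables, \code{n^2 (m+1)}.
#' @slot linear numeric vector of diagonal (linear) coefficients.
#' @slot quadratic strictly upper-triangular \code{dgCMatrix} of couplings.
#' @slot offset excluded constant term.
#' @slot n image side; \code{0} when the model was not built from an image.
#' @slot m highest bit exponent (bits per pixel \code{= m + 1}).
#' @export
setClass("QuboModel",
  representation(numVars = "integer", linear = "numeric",
                 quadratic = "dgCMatrix", offset = "numeric",
                 n = "integer", m = "integer"))

.validQuadratic <- function(numVars, linear, quadratic) {
  if (length(linear) != numVars) return("linear length must equal numVars")
  if (any(dim(quadratic) != numVars)) return("quadratic must be numVars x numVars")
  nz <- Matrix::which(quadratic != 0, arr.ind = TRUE)
  if (nrow(nz) && any(nz[, 1] >= nz[, 2]))
    return("quadratic must be strictly upper triangular")
  TRUE
}

setValidity("QuboModel", function(object) {
  .validQuadratic(object@numVars, object@linear, object@quadratic)
})

#' Ising spin model
#'
#' Energy of a spin vector \code{s} in \code{{-1, +1}^numVars} is
#' \code{sum h_i s_i + sum_{i<j} J_ij s_i s_j}. For a model obtained by
#' [quboToIsing()], QUBO energy and Ising energy are related by
#' \code{E_qubo(q) = E_ising(2q - 1) + offset} for every assignment.
#'
#' @slot numVars number of spins.
#' @slot h numeric vector of field coefficients.
#' @slot J strictly upper-triangular \code{dgCMatrix} of couplings.
#' @slot offset constant absorbed by the substitution \code{q = (s + 1)/2}.
#' @slot n,m image-side / bit-exponent bookkeeping carried from the QUBO.
#' @export
setClass("IsingModel",
  representation(numVars = "integer", h = "numeric", J = "dgCMatrix",
                 offset = "numeric", n = "integer", m = "integer"))

setValidity("IsingModel", function(object) {
  .validQuadratic(object@numVars, object@h, object@J)
})

#' Result of a model solve
#'
#' @slot assignment integer vector; bits in \code{{0,1}} for QUBO models,
#'   spins in \code{{-1,+1}} for Ising models.
#' @slot energy model energy of \code{assignment} (offset excluded),
#'   re-verified by direct evaluation.
#' @slot numReads number of independent restarts/reads performed.
#' @slot occurrencesBest reads that attained the best energy.
#' @slot solverName character.
#' @slot seed integer seed, or \code{NA}.
#' @slot wallTime elapsed seconds (informational).
#' @export
setClass("SolveResult",
  representation(assignment = "integer", energy = "numeric",
                 numReads = "integer", occurrencesBest = "integer",
                 solverName = "character", seed = "integer",
                 wallTime = "numeric"))

setValidity("SolveResult", function(object) {
  if (object@occurrencesBest > object@numReads)
    return("occurrencesBest cannot exceed numReads")
  TRUE
})

#' Reconstruction report
#'
#' Output of [reconstruct()]: the decoded image, the achieved and analytic
#' (\code{-sum P^2}) energies, their gap (a reconstruction certificate: gap
#' zero means the decoded image reproduces the sinogram exactly), and, when
#' a reference image was supplied, the exact-mismatch pixel count, the
#' relative error (mismatch fraction), and the signed difference map.
#'
#' @export
setClass("ReconstructionReport",
  representation(image = "ImageGrid", achievedEnergy = "numeric",
                 expectedEnergy = "numeric", energyGap = "numeric",
                 mismatchedPixels = "integer", relativeError = "numeric",
                 diffImage = "matrix", result = "SolveResult"))

## ---- constructors & accessors -------------------------------------------

#' Create an ImageGrid
#'
#' @param values square numeric matrix.
#' @param bitDepth bits per pixel for integer grids; \code{NA} (default
#'   when values fit in \code{[0,1]} and are not flagged integer) for float
#'   grids.
#' @return an [ImageGrid-class].
#' @export
ImageGrid <- function(values, bitDepth = NA) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ImageGrid", values = values, bitDepth = as.integer(bitDepth))
}

#' @rdname ImageGrid
#' @param x an ImageGrid.
#' @export
imageValues <- function(x) x@values

#' @rdname ImageGrid
#' @export
imageSide <- function(x) nrow(x@values)

#' @rdname ImageGrid
#' @export
bitDepth <- function(x) x@bitDepth

#' @rdname ImageGrid
#' @export
isIntegerGrid <- function(x) !is.na(x@bitDepth)

#' Geometry accessor
#' @param x an object carrying a [ProjectionGeometry-class].
#' @export
geometry <- function(x) {
  if (is(x, "ProjectionGeometry")) x else x@geometry
}

#' @rdname geometry
#' @export
projectionAngles <- function(x) geometry(x)@angles

#' Sinogram values accessor
#' @param x a [Sinogram-class].
#' @return numeric matrix, one row per angle, one column per bin.
#' @export
sinogramValues <- function(x) x@values

#' Overlap-coefficient matrix accessor
#' @param x a [SystemMatrix-class].
#' @return sparse \code{dgCMatrix}, rays by pixels.
#' @export
coefficientMatrix <- function(x) x@A

#' @rdname SolveResult-class
#' @param x a SolveResult.
#' @export
assignment <- function(x) x@assignment

## ---- show methods --------------------------------------------------------

setMethod("show", "ImageGrid", function(object) {
  kind <- if (isIntegerGrid(object))
    sprintf("integer, %d bit(s)", object@bitDepth) else "float in [0,1]"
  cat(sprintf("ImageGrid %dx%d (%s), range [%g, %g]\n",
              imageSide(object), imageSide(object), kind,
              min(object@values), max(object@values)))
})

setMethod("show", "ProjectionGeometry", function(object) {
  cat(sprintf("ProjectionGeometry: n=%d, %d angle(s) in [%g, %g] deg, %d bins\n",
              object@n, length(object@angles), min(object@angles),
              max(object@angles), object@numBins))
})

setMethod("show", "SystemMatrix", function(object) {
  cat(sprintf("SystemMatrix: %d rays x %d pixels, %d nonzero overlap areas\n",
              nrow(object@A), ncol(object@A), length(object@A@x)))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d angle(s) x %d bins, total mass %g\n",
              nrow(object@values), ncol(object@values), sum(object@values)))
})

setMethod("show", "QuboModel", function(object) {
  cat(sprintf("QuboModel: %d variables, %d couplings, offset %g (min energy >= %g)\n",
              object@numVars, length(object@quadratic@x), object@offset,
              -object@offset))
})

setMethod("show", "IsingModel", function(object) {
  cat(sprintf("IsingModel: %d spins, %d couplings, offset %g\n",
              object@numVars, length(object@J@x), object@offset))
})

setMethod("show", "SolveResult", function(object) {
  cat(sprintf("SolveResult [%s]: energy %g (%d/%d reads at best)\n",
              object@solverName, object@energy, object@occurrencesBest,
              object@numReads))
})

setMethod("show", "ReconstructionReport", function(object) {
  cat(sprintf("ReconstructionReport: achieved %g, analytic minimum %g, gap %g\n",
              object@achievedEnergy, object@expectedEnergy, object@energyGap))
  if (!is.na(object@mismatchedPixels))
    cat(sprintf("  vs reference: %d mismatched pixel(s), relative error %g\n",
                object@mismatchedPixels, object@relativeError))
})
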