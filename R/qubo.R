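## QUBO assembly from the squared sinogram residual, Ising conversion,
## energy evaluation, analytic minimum.
##
## Each integer pixel is expanded in binary, I_ij = sum_k 2^k q_k^ij with
## k = 0..m, and the model minimizes
##   F = sum_{theta, s} (IP(theta, s) - P(theta, s))^2
## over the bits. Expanding the square and using q^2 = q turns F into a
## quadratic form over bits; the constant term sum P^2 is excluded from the
## model (tracked as `offset`), so F >= 0 implies every model energy is
## >= -offset, with equality exactly when the decoded image reproduces the
## sinogram.

#' Number of bits needed to represent a maximum pixel value
#'
#' The smallest \code{m + 1} with \code{maxValue < 2^(m+1)}, at least 1:
#' 1023 needs 10 bits, a binary image needs 1.
#'
#' @param maxValue nonnegative integer.
#' @return integer bit count \code{m + 1}.
#' @export
bitsNeeded <- function(maxValue) {
  stopifnot(length(maxValue) == 1L, maxValue >= 0)
  max(1L, as.integer(ceiling(log2(floor(maxValue) + 1))))
}

#' Construct a QuboModel from raw coefficients
#'
#' @param linear numeric vector of linear (diagonal) coefficients.
#' @param quadratic strictly upper-triangular coupling matrix (any Matrix
#'   coercible to \code{dgCMatrix}); defaults to all-zero.
#' @param offset excluded constant term (default 0).
#' @param n,m image-side / bit-exponent bookkeeping (0 when the model is
#'   not tied to an image).
#' @return a [QuboModel-class].
#' @export
QuboModel <- function(linear, quadratic = NULL, offset = 0, n = 0L, m = 0L) {
  nv <- length(linear)
  if (is.null(quadratic))
    quadratic <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                      x = numeric(0), dims = c(nv, nv))
  new("QuboModel", numVars = as.integer(nv), linear = as.numeric(linear),
      quadratic = as(as(quadratic, "generalMatrix"), "CsparseMatrix"),
      offset = as.numeric(offset), n = as.integer(n), m = as.integer(m))
}

#' Construct an IsingModel from raw coefficients
#'
#' @param h numeric vector of fields.
#' @param J strictly upper-triangular coupling matrix; defaults to
#'   all-zero.
#' @param offset constant absorbed by a QUBO-to-Ising substitution.
#' @param n,m bookkeeping as for [QuboModel()].
#' @return an [IsingModel-class].
#' @export
IsingModel <- function(h, J = NULL, offset = 0, n = 0L, m = 0L) {
  nv <- length(h)
  if (is.null(J))
    J <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                              x = numeric(0), dims = c(nv, nv))
  new("IsingModel", numVars = as.integer(nv), h = as.numeric(h),
      J = as(as(J, "generalMatrix"), "CsparseMatrix"),
      offset = as.numeric(offset), n = as.integer(n), m = as.integer(m))
}

# flat variable index of bit k (0-based) of pixel (i, j):
# ((i-1) n + (j-1)) (m+1) + k + 1
.bitIndex <- function(i, j, k, n, m) ((i - 1) * n + (j - 1)) * (m + 1) + k + 1

#' Assemble the QUBO of the squared sinogram residual
#'
#' Builds the quadratic model whose energy at a bit assignment \code{q}
#' equals \code{||A decode(q) - P||^2 - sum(P^2)}: the linear coefficient
#' of bit \code{k} of pixel \code{(i,j)} accumulates
#' \code{2^(2k) c^2 - 2 P 2^k c} over the rays containing the pixel, and
#' every pair of bits sharing a ray couples with
#' \code{2^(k+k'+1) c c'} (same-pixel pairs use \code{c^2}). Variables are
#' ordered row-major by pixel, ascending bit.
#'
#' @param sm a [SystemMatrix-class].
#' @param sino a [Sinogram-class] on the same geometry.
#' @param m highest bit exponent; each pixel uses \code{m + 1} bits.
#' @param prune drop accumulated coefficients below this magnitude.
#' @return a [QuboModel-class].
#' @export
buildQubo <- function(sm, sino, m, prune = 1e-12) {
  stopifnot(is(sm, "SystemMatrix"), is(sino, "Sinogram"),
            m >= 0, m == round(m))
  g <- sm@geometry
  gs <- sino@geometry
  if (g@n != gs@n || length(g@angles) != length(gs@angles) ||
      any(g@angles != gs@angles) || g@numBins != gs@numBins)
    stop("sinogram geometry does not match the system matrix geometry")
  m <- as.integer(m)
  n <- g@n
  nbits <- m + 1L
  nvars <- n * n * nbits
  P <- as.vector(t(sino@values))               # ray order: angle-major
  At <- Matrix::t(sm@A)                        # columns = rays (CSC access)
  ptr <- At@p
  w <- 2^(0:m)
  linear <- numeric(nvars)
  qi <- vector("list", nrow(sm@A)); qj <- qi; qx <- qi
  for (r in seq_len(nrow(sm@A))) {
    idx <- seq.int(ptr[r] + 1L, length.out = ptr[r + 1L] - ptr[r])
    if (!length(idx)) next
    px <- At@i[idx] + 1L                       # pixel indices on this ray
    cr <- At@x[idx]
    # bit-level expansion: variable indices and weights d_v = c_p * 2^k
    v <- rep((px - 1L) * nbits, each = nbits) + rep(seq_len(nbits), length(px))
    d <- rep(cr, each = nbits) * rep(w, length(px))
    linear[v] <- linear[v] + d * d - 2 * P[r] * d
    L <- length(v)
    if (L >= 2L) {
      a <- rep.int(seq_len(L - 1L), rev(seq_len(L - 1L)))
      b <- sequence(rev(seq_len(L - 1L)), from = 2:L)
      qi[[r]] <- v[a]; qj[[r]] <- v[b]
      qx[[r]] <- 2 * d[a] * d[b]
    }
  }
  Q <- Matrix::sparseMatrix(i = unlist(qi), j = unlist(qj), x = unlist(qx),
                            dims = c(nvars, nvars))
  Q <- Matrix::drop0(Q, tol = prune)
  linear[abs(linear) < prune] <- 0
  new("QuboModel", numVars = as.integer(nvars), linear = linear,
      quadratic = as(Q, "CsparseMatrix"), offset = sum(P^2),
      n = n, m = m)
}

#' Analytic lower bound / expected minimum energy of a sinogram's QUBO
#'
#' Returns \code{-sum P(theta, s)^2}, the negated excluded constant of the
#' residual expansion. It is the exact achievable QUBO minimum whenever an
#' integer image exactly consistent with the sinogram exists (e.g. when the
#' sinogram was produced by projecting an integer image).
#'
#' @param sino a [Sinogram-class].
#' @return numeric scalar.
#' @export
expectedMinEnergy <- function(sino) {
  stopifnot(is(sino, "Sinogram"))
  -sum(sino@values^2)
}

#' Convert a QUBO to the equivalent Ising model
#'
#' Substitutes \code{q_i = (sigma_i + 1)/2}: fields are
#' \code{h_i = linear_i / 2 + sum_j quadratic_ij / 4} (sum over couplings
#' incident to \code{i}), couplings \code{J_ij = quadratic_ij / 4}, and the
#' absorbed constant \code{offset = sum linear / 2 + sum quadratic / 4}, so
#' that \code{E_qubo(q) = E_ising(2q - 1) + offset} for every assignment.
#'
#' @param qm a [QuboModel-class].
#' @return an [IsingModel-class].
#' @export
quboToIsing <- function(qm) {
  stopifnot(is(qm, "QuboModel"))
  Q <- qm@quadratic
  incident <- as.numeric(Matrix::rowSums(Q) + Matrix::colSums(Q))
  h <- qm@linear / 2 + incident / 4
  new("IsingModel", numVars = qm@numVars, h = h, J = Q / 4,
      offset = sum(qm@linear) / 2 + sum(Q@x) / 4, n = qm@n, m = qm@m)
}

.checkAssignment <- function(x, nvars, alphabet) {
  if (length(x) != nvars)
    stop(sprintf("assignment length %d, model has %d variables",
                 length(x), nvars))
  if (!all(x %in% alphabet))
    stop(sprintf("assignment entries must be in {%s}",
                 paste(alphabet, collapse = ", ")))
  as.numeric(x)
}

#' @describeIn energy QUBO energy of a bit vector.
#' @export
setMethod("energy", signature("QuboModel", "numeric"), function(model, x) {
  x <- .checkAssignment(x, model@numVars, c(0, 1))
  sum(model@linear * x) + sum(as.numeric(model@quadratic %*% x) * x)
})

#' @describeIn energy Ising energy of a spin vector.
#' @export
setMethod("energy", signature("IsingModel", "numeric"), function(model, x) {
  x <- .checkAssignment(x, model@numVars, c(-1, 1))
  sum(model@h * x) + sum(as.numeric(model@J %*% x) * x)
})

# columnwise energies of an nvars x B matrix of assignments (internal,
# used by the exhaustive solver)
.energiesMatrix <- function(linear, Q, X) {
  colSums(linear * X) + colSums(X * as.matrix(Q %*% X))
}
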