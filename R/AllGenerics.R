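#' Evaluate the energy of an assignment
#'
#' Computes \code{sum linear * x + sum quadratic * x * x} for a
#' [QuboModel-class] (bits in \code{{0,1}}) or [IsingModel-class] (spins in
#' \code{{-1,+1}}). The model's constant offset is never added; it is
#' reported separately on the model object.
#'
#' @param model a QuboModel or IsingModel.
#' @param x assignment vector of length \code{numVars} in the model's
#'   alphabet.
#' @return numeric scalar energy.
#' @examples
#' qm <- buildQubo(systemMatrix(makeGeometry(2, 2)),
#'                 project(toySample2x2(), systemMatrix(makeGeometry(2, 2))),
#'                 m = 1)
#' energy(qm, c(0, 0, 1, 0, 0, 1, 1, 1))   # -46
#' @export
setGeneric("energy", function(model, x) standardGeneric("energy"))

#' Forward-project an image to a sinogram
#'
#' Applies the sparse overlap-area operator: each sinogram value is the
#' coefficient-weighted sum of the pixels its detector strip overlaps,
#' \code{IP(theta, s) = sum_ij c_ij I_ij}. Linear in the image; for every
#' angle the bin sums conserve the total image mass.
#'
#' @param img an [ImageGrid-class] (or plain square matrix).
#' @param sm a [SystemMatrix-class] with matching image side.
#' @return a [Sinogram-class].
#' @export
setGeneric("project", function(img, sm) standardGeneric("project"))
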