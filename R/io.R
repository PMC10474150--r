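## Plain-text interchange formats: CSV grids with JSON sidecars for images
## and sinograms, coordinate-list text for QUBO/Ising models, JSON for
## solver results. Integer data round-trip losslessly.

.FORMAT_VERSION <- 1L

.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

.writeSidecar <- function(path, fields) {
  jsonlite::write_json(c(fields, list(format_version = .FORMAT_VERSION)),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
}

.readSidecar <- function(path) {
  sc <- .sidecarPath(path)
  if (!file.exists(sc)) return(NULL)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Read and write images as CSV grids
#'
#' The grid is written row-major as a headerless CSV; a JSON sidecar
#' (same path with extension \code{.json}) records the side length, the
#' bit depth (or float kind) and a format version. Integer grids
#' round-trip losslessly.
#'
#' @param img an [ImageGrid-class].
#' @param path CSV path; the sidecar is derived from it.
#' @return \code{readImage} returns an [ImageGrid-class];
#'   \code{writeImage} returns \code{path} invisibly.
#' @export
writeImage <- function(img, path) {
  stopifnot(is(img, "ImageGrid"))
  utils::write.table(imageValues(img), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  .writeSidecar(path, list(kind = "image", n = imageSide(img),
                           bit_depth = if (isIntegerGrid(img)) bitDepth(img)
                                       else NA))
  invisible(path)
}

#' @rdname writeImage
#' @export
readImage <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  v <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(v) <- NULL
  side <- .readSidecar(path)
  bd <- NA_integer_
  if (!is.null(side)) {
    if (!identical(side$kind, "image"))
      stop(sprintf("sidecar '%s': kind is '%s', expected 'image'",
                   .sidecarPath(path), side$kind))
    if (nrow(v) != side$n)
      stop(sprintf("sidecar '%s': declared n=%d but grid has %d rows",
                   .sidecarPath(path), side$n, nrow(v)))
    if (!is.null(side$bit_depth) && !is.na(side$bit_depth))
      bd <- as.integer(side$bit_depth)
  } else if (all(v == round(v)) && any(v > 1)) {
    bd <- bitsNeeded(max(v))
  }
  ImageGrid(v, bitDepth = bd)
}

#' Read and write sinograms as CSV
#'
#' Rows are angles in sweep order, columns detector bins; the JSON sidecar
#' records the image side, the angle list and the bin width.
#'
#' @param sino a [Sinogram-class].
#' @param path CSV path.
#' @return \code{readSinogram} returns a [Sinogram-class].
#' @export
writeSinogram <- function(sino, path) {
  stopifnot(is(sino, "Sinogram"))
  g <- sino@geometry
  utils::write.table(sino@values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  .writeSidecar(path, list(kind = "sinogram", n = g@n, angles = g@angles,
                           num_bins = g@numBins, bin_width = g@binWidth))
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  if (!file.exists(path)) stop("no such sinogram file: ", path)
  v <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(v) <- NULL
  side <- .readSidecar(path)
  if (is.null(side))
    stop(sprintf("sinogram '%s' requires its JSON sidecar '%s' (geometry)",
                 path, .sidecarPath(path)))
  if (!identical(side$kind, "sinogram"))
    stop(sprintf("sidecar '%s': kind is '%s', expected 'sinogram'",
                 .sidecarPath(path), side$kind))
  geom <- new("ProjectionGeometry", n = as.integer(side$n),
              angles = as.numeric(side$angles),
              numBins = as.integer(side$num_bins),
              binWidth = as.numeric(side$bin_width))
  if (nrow(v) != length(geom@angles) || ncol(v) != geom@numBins)
    stop(sprintf("sinogram '%s': %dx%d values do not match %d angles x %d bins",
                 path, nrow(v), ncol(v), length(geom@angles), geom@numBins))
  Sinogram(v, geom)
}

#' Read and write quadratic models as coordinate lists
#'
#' One \code{"i j value"} line per coefficient; diagonal entries
#' (\code{i == j}) hold the linear (field) terms, off-diagonal entries the
#' upper-triangular couplings. The JSON sidecar records the variable
#' count, offset, model type, image side, bit exponent and the indexing
#' convention. Duplicate coordinates are rejected on read.
#'
#' @param model a [QuboModel-class] or [IsingModel-class].
#' @param path coordinate-list path.
#' @return \code{readModel} returns the model object.
#' @export
writeModel <- function(model, path) {
  parts <- .modelParts(model)
  tr <- .tripletsOf(parts$Q)
  dg <- which(parts$linear != 0)
  df <- data.frame(i = c(dg, tr$i), j = c(dg, tr$j),
                   value = c(parts$linear[dg], tr$x))
  df <- df[order(df$i, df$j), ]
  lines <- sprintf("%d %d %.17g", df$i, df$j, df$value)
  writeLines(lines, path)
  .writeSidecar(path, list(kind = "model",
                           type = if (parts$spin) "ising" else "qubo",
                           num_vars = length(parts$linear),
                           offset = model@offset, n = model@n, m = model@m,
                           indexing = "row-major pixels, ascending bit"))
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  side <- .readSidecar(path)
  if (is.null(side) || !identical(side$kind, "model"))
    stop(sprintf("model '%s' requires a JSON sidecar of kind 'model'", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  nv <- as.integer(side$num_vars)
  linear <- numeric(nv)
  qi <- integer(0); qj <- integer(0); qx <- numeric(0)
  seen <- character(0)
  for (ln in seq_along(lines)) {
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(parts) != 3L)
      stop(sprintf("model '%s' line %d: expected 'i j value', got '%s'",
                   path, ln, lines[ln]))
    i <- suppressWarnings(as.integer(parts[1]))
    j <- suppressWarnings(as.integer(parts[2]))
    x <- suppressWarnings(as.numeric(parts[3]))
    if (is.na(i) || is.na(j) || is.na(x))
      stop(sprintf("model '%s' line %d: unparseable entry '%s'",
                   path, ln, lines[ln]))
    if (i < 1 || j < 1 || i > nv || j > nv)
      stop(sprintf("model '%s' line %d: index out of range 1..%d",
                   path, ln, nv))
    if (i > j)
      stop(sprintf("model '%s' line %d: lower-triangular entry (%d, %d)",
                   path, ln, i, j))
    key <- paste(i, j)
    if (key %in% seen)
      stop(sprintf("model '%s' line %d: duplicate coordinate (%d, %d)",
                   path, ln, i, j))
    seen <- c(seen, key)
    if (i == j) linear[i] <- x
    else { qi <- c(qi, i); qj <- c(qj, j); qx <- c(qx, x) }
  }
  Q <- Matrix::sparseMatrix(i = qi, j = qj, x = qx, dims = c(nv, nv))
  Q <- as(Q, "CsparseMatrix")
  nimg <- as.integer(side$n); mexp <- as.integer(side$m)
  if (identical(side$type, "ising"))
    new("IsingModel", numVars = nv, h = linear, J = Q,
        offset = as.numeric(side$offset), n = nimg, m = mexp)
  else
    new("QuboModel", numVars = nv, linear = linear, quadratic = Q,
        offset = as.numeric(side$offset), n = nimg, m = mexp)
}

#' Read and write solver results as JSON
#'
#' The assignment is stored as a compact 0/1 string (spins are stored as
#' bits via \code{(sigma + 1)/2} with a \code{"spin"} flag).
#'
#' @param res a [SolveResult-class].
#' @param path JSON path.
#' @return \code{readResult} returns a [SolveResult-class].
#' @export
writeResult <- function(res, path) {
  stopifnot(is(res, "SolveResult"))
  spin <- any(res@assignment < 0)
  bits <- if (spin) (res@assignment + 1L) %/% 2L else res@assignment
  jsonlite::write_json(
    list(kind = "result", assignment = paste(bits, collapse = ""),
         spin = spin, energy = res@energy, num_reads = res@numReads,
         occurrences_best = res@occurrencesBest, solver = res@solverName,
         seed = if (is.na(res@seed)) NULL else res@seed,
         wall_time = res@wallTime, format_version = .FORMAT_VERSION),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeResult
#' @export
readResult <- function(path) {
  if (!file.exists(path)) stop("no such result file: ", path)
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(out$kind, "result"))
    stop(sprintf("result '%s': kind is '%s', expected 'result'",
                 path, out$kind))
  bits <- as.integer(strsplit(out$assignment, "")[[1]])
  a <- if (isTRUE(out$spin)) 2L * bits - 1L else bits
  .solveResult(a, out$energy, out$num_reads, out$occurrences_best,
               out$solver, out$seed, out$wall_time)
}

#' Export an image as 8- or 16-bit grayscale PNG or TIFF
#'
#' Integer grids are scaled by their declared bit depth (value
#' \code{2^bitDepth - 1} maps to white); float grids map \code{[0, 1]}
#' directly. A JSON sidecar records the scaling. Requires the \pkg{png}
#' or \pkg{tiff} package.
#'
#' @param img an [ImageGrid-class].
#' @param path output path ending in \code{.png} or \code{.tif}/\code{.tiff}.
#' @return \code{path}, invisibly.
#' @export
writeImageRaster <- function(img, path) {
  stopifnot(is(img, "ImageGrid"))
  scale <- if (isIntegerGrid(img)) 2^bitDepth(img) - 1 else 1
  v <- imageValues(img) / scale
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("PNG export requires the 'png' package")
    png::writePNG(v, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("TIFF export requires the 'tiff' package")
    tiff::writeTIFF(v, path, bits.per.sample = 16L)
  } else stop("unsupported raster extension: ", ext)
  .writeSidecar(path, list(kind = "raster", n = imageSide(img),
                           bit_depth = if (isIntegerGrid(img)) bitDepth(img)
                                       else NA,
                           white_value = scale))
  invisible(path)
}
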