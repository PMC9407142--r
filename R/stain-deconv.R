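#' Construct an RGBField
#'
#' @param pixels H x W x 3 numeric array with channel intensities in
#'   [0, 255].
#' @param mpp microns per pixel (> 0).
#' @param fieldId identifier string.
#' @return an [RGBField].
#' @examples
#' f <- rgbField(array(255, c(4, 4, 3)), mpp = 0.5)
#' mpp(f)
#' @export
rgbField <- function(pixels, mpp, fieldId = "field") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("pixels must be an H x W x 3 array")
  new("RGBField", pixels = pixels, mpp = as.numeric(mpp),
      fieldId = as.character(fieldId))
}

#' Build and validate a stain matrix
#'
#' A stain matrix has one row per stain (hematoxylin, DAB, residual), each a
#' unit vector in optical-density space. A 2 x 3 input (hematoxylin and DAB
#' only) is completed with the normalized cross product as the residual
#' channel. Rows are renormalized to unit Euclidean norm.
#'
#' @param m numeric 2 x 3 or 3 x 3 matrix, row-major stain OD vectors.
#' @return a validated 3 x 3 matrix with rownames
#'   `c("hematoxylin", "dab", "residual")`.
#' @seealso [defaultHDABMatrix()]
#' @export
stainMatrix <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 3L || !nrow(m) %in% 2:3)
    stop("stain matrix must be 2 x 3 or 3 x 3")
  if (anyNA(m) || any(!is.finite(m)))
    stop("stain matrix must be finite")
  if (nrow(m) == 2L) {
    r <- c(m[1, 2] * m[2, 3] - m[1, 3] * m[2, 2],
           m[1, 3] * m[2, 1] - m[1, 1] * m[2, 3],
           m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
    if (sqrt(sum(r^2)) < 1e-12)
      stop("degenerate stain matrix: stain vectors are collinear")
    m <- rbind(m, r)
  }
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm < 1e-12))
    stop("degenerate stain matrix: zero-norm stain vector")
  m <- m / nrm
  if (abs(det(m)) < 1e-8)
    stop("degenerate stain matrix: rows are linearly dependent")
  dimnames(m) <- list(c("hematoxylin", "dab", "residual"), c("R", "G", "B"))
  m
}

#' Default H-DAB stain matrix
#'
#' The standard published optical-density vectors for hematoxylin
#' (0.65, 0.70, 0.29) and DAB (0.27, 0.57, 0.78), row-normalized, with the
#' residual channel as their normalized cross product (orthogonal to both).
#'
#' @return a 3 x 3 stain matrix (see [stainMatrix()]).
#' @examples
#' m <- defaultHDABMatrix()
#' rowSums(m^2)  # unit rows
#' @export
defaultHDABMatrix <- function() {
  stainMatrix(rbind(c(0.65, 0.70, 0.29),
                    c(0.27, 0.57, 0.78)))
}

#' Convert RGB intensities to optical densities
#'
#' Applies the Beer-Lambert transform per channel:
#' `OD = -log10((I + 1) / (i0 + 1))`, clipped below at 0. The +1 offset
#' avoids log(0) at pixel value 0; `i0` is the blank (background) intensity.
#'
#' @param field an [RGBField], or an H x W x 3 intensity array in [0, 255].
#' @param i0 background intensity in [1, 255].
#' @return H x W x 3 array of optical densities (>= 0).
#' @examples
#' od <- rgbToOD(array(25, c(1, 1, 3)))  # ~0.993 per channel
#' @export
rgbToOD <- function(field, i0 = 255L) {
  if (is(field, "RGBField")) field <- field@pixels
  if (!is.array(field) || length(dim(field)) != 3L || dim(field)[3] != 3L)
    stop("field must be an RGBField or an H x W x 3 array")
  if (anyNA(field) || min(field) < 0 || max(field) > 255)
    stop("channel intensities must lie in [0, 255]")
  i0 <- as.numeric(i0)
  if (length(i0) != 1L || is.na(i0) || i0 < 1 || i0 > 255)
    stop("i0 must lie in [1, 255]")
  od <- -log10((field + 1) / (i0 + 1))
  od[od < 0] <- 0
  od
}

#' Unmix optical densities into per-stain concentration maps
#'
#' Solves `od = concentrations %*% m` per pixel by the pseudo-inverse of the
#' stain matrix; with a full-rank 3 x 3 matrix this is an exact linear
#' solve. Negative concentrations (noise outside the stain simplex) are
#' clipped to 0.
#'
#' @param od H x W x 3 optical-density array (from [rgbToOD()]).
#' @param m stain matrix (default [defaultHDABMatrix()]).
#' @param mpp microns per pixel carried into the result.
#' @return an [ODImage] with hematoxylin, DAB and residual maps.
#' @export
deconvolve <- function(od, m = defaultHDABMatrix(), mpp = 1) {
  m <- stainMatrix(m)
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L)
    stop("od must be an H x W x 3 array")
  d <- dim(od)
  odm <- matrix(od, nrow = d[1] * d[2], ncol = 3L)
  conc <- odm %*% solve(m)
  conc[conc < 0] <- 0
  new("ODImage",
      hema = matrix(conc[, 1], d[1], d[2]),
      dab = matrix(conc[, 2], d[1], d[2]),
      residual = matrix(conc[, 3], d[1], d[2]),
      mpp = as.numeric(mpp))
}

#' Render concentration maps back to RGB pixels
#'
#' Inverse of the deconvolution path, used by the synthetic field renderer:
#' per-pixel `OD = concentrations %*% m`, then
#' `I = round((i0 + 1) * 10^(-OD) - 1)` clipped to [0, 255].
#'
#' @param hemaMap,dabMap non-negative H x W concentration matrices.
#' @param m stain matrix.
#' @param i0 background intensity in [1, 255].
#' @param residualMap optional non-negative residual concentration map
#'   (default zero).
#' @return H x W x 3 integer-valued pixel array.
#' @export
composeOD <- function(hemaMap, dabMap, m = defaultHDABMatrix(), i0 = 255L,
                      residualMap = NULL) {
  m <- stainMatrix(m)
  hemaMap <- as.matrix(hemaMap); dabMap <- as.matrix(dabMap)
  if (!identical(dim(hemaMap), dim(dabMap)))
    stop("hemaMap and dabMap must share their shape")
  if (is.null(residualMap)) residualMap <- matrix(0, nrow(hemaMap), ncol(hemaMap))
  residualMap <- as.matrix(residualMap)
  if (!identical(dim(residualMap), dim(hemaMap)))
    stop("residualMap must share the concentration maps' shape")
  if (anyNA(hemaMap) || anyNA(dabMap) || anyNA(residualMap) ||
      min(hemaMap) < 0 || min(dabMap) < 0 || min(residualMap) < 0)
    stop("concentration maps must be non-negative")
  i0 <- as.numeric(i0)
  if (length(i0) != 1L || is.na(i0) || i0 < 1 || i0 > 255)
    stop("i0 must lie in [1, 255]")
  d <- dim(hemaMap)
  conc <- cbind(as.vector(hemaMap), as.vector(dabMap), as.vector(residualMap))
  od <- conc %*% m
  I <- round((i0 + 1) * 10^(-od) - 1)
  I[I < 0] <- 0
  I[I > 255] <- 255
  array(I, c(d[1], d[2], 3L))
}

#' Deconvolve a field in one step
#'
#' Convenience wrapper: [rgbToOD()] followed by [deconvolve()], carrying the
#' field's spatial calibration.
#'
#' @inheritParams rgbToOD
#' @inheritParams deconvolve
#' @return an [ODImage].
#' @export
fieldToOD <- function(field, m = defaultHDABMatrix(), i0 = 255L) {
  stopifnot(is(field, "RGBField"))
  deconvolve(rgbToOD(field, i0 = i0), m = m, mpp = field@mpp)
}
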