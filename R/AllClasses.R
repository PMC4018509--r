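#' @useDynLib swtreg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Image2D: a 2D grayscale image with physical pixel spacing
#'
#' The central data container of the package: a matrix of gray values
#' (float, arbitrary units) together with the physical pixel size in mm
#' and a physical origin. Rows map to the y axis, columns to the x axis;
#' indices are 1-based in R but all geometry (rotation centers, sampling
#' positions) is computed on the 0-based pixel lattice with pixel centers
#' at integer coordinates.
#'
#' @slot pixels numeric matrix of gray values (no NaN/Inf).
#' @slot spacing numeric(2), (row_mm, col_mm) physical pixel size, > 0.
#' @slot origin numeric(2), physical position (mm) of pixel (1,1).
#' @export
setClass("Image2D",
  representation(pixels = "matrix", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1), origin = c(0, 0))
)

setValidity("Image2D", function(object) {
  px <- object@pixels
  if (!is.numeric(px)) return("pixels must be a numeric matrix")
  if (nrow(px) < 2L || ncol(px) < 2L)
    return("pixels must have at least 2 rows and 2 columns")
  if (anyNA(px) || any(!is.finite(px)))
    return("pixels must be finite (no NA/NaN/Inf)")
  if (length(object@spacing) != 2L || any(object@spacing <= 0))
    return("spacing must be two strictly positive numbers (row_mm, col_mm)")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    return("origin must be two finite numbers")
  TRUE
})

#' Construct an Image2D
#'
#' @param pixels numeric matrix of gray values.
#' @param spacing numeric(2) physical pixel size in mm (row, col).
#' @param origin numeric(2) physical position of the first pixel, in mm.
#' @return an \linkS4class{Image2D} object.
#' @examples
#' img <- Image2D(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
Image2D <- function(pixels, spacing = c(1, 1), origin = c(0, 0)) {
  if (is(pixels, "Image2D")) return(pixels)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  new("Image2D", pixels = pixels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' FilterBank: analysis/synthesis filter taps of an orthonormal wavelet
#'
#' Holds the low-pass analysis taps h0, the high-pass analysis taps g0
#' (quadrature mirror of h0), and the synthesis taps h1, g1 (time-reversed
#' analysis taps for an orthonormal bank). Taps are normalized so that
#' sum(h0) = sqrt(2) and sum(h0^2) = 1, which makes the undecimated
#' analysis/synthesis pair satisfy perfect reconstruction.
#'
#' @slot h0 numeric, low-pass analysis taps.
#' @slot g0 numeric, high-pass analysis taps.
#' @slot h1 numeric, low-pass synthesis taps.
#' @slot g1 numeric, high-pass synthesis taps.
#' @slot name character, wavelet family label (e.g. "haar", "db4").
#' @export
setClass("FilterBank",
  representation(h0 = "numeric", g0 = "numeric", h1 = "numeric",
                 g1 = "numeric", name = "character")
)

setValidity("FilterBank", function(object) {
  L <- length(object@h0)
  if (L < 2L) return("h0 must have at least 2 taps")
  if (length(object@g0) != L || length(object@h1) != L ||
      length(object@g1) != L)
    return("all four filters must have equal length")
  if (abs(sum(object@h0) - sqrt(2)) > 1e-10)
    return("h0 must sum to sqrt(2) (orthonormal scaling filter)")
  if (abs(sum(object@h0^2) - 1) > 1e-10)
    return("h0 must have unit energy")
  TRUE
})

#' WaveletPyramid: bands of an undecimated wavelet decomposition
#'
#' Stores the approximation band A_j and the three detail bands (LH, HL,
#' HH) for each level j = 1..levels of a stationary wavelet transform.
#' Every band has the shape of the input image (no downsampling). When the
#' decomposition used the symmetric boundary, bands are stored internally
#' on the reflect-extended (2M x 2N) domain so that reconstruction is an
#' exact inverse; the accessors \code{\link{approxBand}} and
#' \code{\link{detailBand}} always return bands cropped to the base shape.
#'
#' @slot levels integer, decomposition depth J >= 1.
#' @slot approx list of approximation bands A_j, j = 1..J.
#' @slot detailLH list of row-lowpass/column-highpass detail bands D1_j.
#' @slot detailHL list of row-highpass/column-lowpass detail bands D2_j.
#' @slot detailHH list of diagonal detail bands D3_j.
#' @slot baseShape integer(2), (M, N) of the decomposed image.
#' @slot boundary character, "symmetric" or "periodic".
#' @slot filterName character, wavelet family used.
#' @slot spacing numeric(2), carried over from the input image.
#' @export
setClass("WaveletPyramid",
  representation(levels = "integer", approx = "list", detailLH = "list",
                 detailHL = "list", detailHH = "list", baseShape = "integer",
                 boundary = "character", filterName = "character",
                 spacing = "numeric")
)

setValidity("WaveletPyramid", function(object) {
  J <- object@levels
  if (J < 1L) return("levels must be >= 1")
  bands <- list(object@approx, object@detailLH, object@detailHL,
                object@detailHH)
  if (any(vapply(bands, length, 1L) != J))
    return("each band list must hold exactly 'levels' arrays")
  sh <- dim(object@approx[[1L]])
  for (b in bands) for (j in seq_len(J)) {
    if (!identical(dim(b[[j]]), sh))
      return("all stored bands must share one shape")
  }
  if (!object@boundary %in% c("symmetric", "periodic"))
    return("boundary must be 'symmetric' or 'periodic'")
  exp_sh <- if (object@boundary == "symmetric") 2L * object@baseShape
            else object@baseShape
  if (!identical(as.integer(sh), exp_sh))
    return("stored band shape inconsistent with baseShape/boundary")
  TRUE
})

#' RigidTransform: 2D translation plus in-plane rotation
#'
#' The three setup-correction parameters optimized by the registration:
#' a translation (dx, dy) and a rotation theta about a center point.
#' x corresponds to columns, y to rows. theta is stored in degrees;
#' positive theta rotates from the +x axis toward the +y axis (i.e.
#' clockwise on screen when rows are drawn downward). Translations are in
#' pixels (\code{units = "px"}) or millimetres (\code{units = "mm"},
#' converted via the image spacing when applied).
#'
#' @slot dx numeric, translation along x (columns).
#' @slot dy numeric, translation along y (rows).
#' @slot theta numeric, rotation angle in degrees.
#' @slot units character, "px" or "mm".
#' @slot center numeric(2) or NA: rotation center as 0-based (row, col)
#'   pixel coordinates; NA means "image center", resolved when applied.
#' @export
setClass("RigidTransform",
  representation(dx = "numeric", dy = "numeric", theta = "numeric",
                 units = "character", center = "numeric"),
  prototype(units = "px", center = NA_real_)
)

setValidity("RigidTransform", function(object) {
  if (!all(is.finite(c(object@dx, object@dy, object@theta))))
    return("dx, dy, theta must be finite")
  if (!object@units %in% c("px", "mm"))
    return("units must be 'px' or 'mm'")
  TRUE
})

#' Construct a RigidTransform
#'
#' @param dx,dy translations along x (columns) and y (rows).
#' @param theta rotation angle in degrees.
#' @param units "px" (default) or "mm".
#' @param center rotation center as 0-based (row, col) coordinates, or NA
#'   for the image center (the default used throughout the registration).
#' @return a \linkS4class{RigidTransform}.
#' @examples
#' rigidTransform(10, 15, -3)
#' @export
rigidTransform <- function(dx = 0, dy = 0, theta = 0, units = "px",
                           center = NA_real_) {
  new("RigidTransform", dx = as.numeric(dx), dy = as.numeric(dy),
      theta = as.numeric(theta), units = units,
      center = as.numeric(center))
}

#' RegistrationResult: output of a registration run
#'
#' @slot transform the recovered \linkS4class{RigidTransform} (pixel units)
#'   that maps the floating image onto the reference grid.
#' @slot combined final value of the weighted similarity measure.
#' @slot nmiI normalized mutual information of the intensity images at the
#'   optimum.
#' @slot nmiG normalized mutual information of the gradient images at the
#'   optimum (NA in \code{mi_only} mode).
#' @slot mse root-mean-square gray difference between the registered
#'   floating image and the reference.
#' @slot trace numeric, objective value (negated measure) after each Powell
#'   sweep; non-increasing.
#' @slot evaluations integer, number of objective evaluations.
#' @slot preShift numeric(2), the manual narrowing shift (mm) applied to
#'   the floating image before optimization.
#' @slot mode character, "proposed" or "mi_only".
#' @export
setClass("RegistrationResult",
  representation(transform = "RigidTransform", combined = "numeric",
                 nmiI = "numeric", nmiG = "numeric", mse = "numeric",
                 trace = "numeric", evaluations = "integer",
                 preShift = "numeric", mode = "character")
)
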