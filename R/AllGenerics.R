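#' @rdname Image2D-class
#' @param x an Image2D.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname Image2D-class
#' @export
setMethod("pixels", "Image2D", function(x) x@pixels)

#' @rdname Image2D-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname Image2D-class
#' @export
setMethod("spacing", "Image2D", function(x) x@spacing)

#' @rdname Image2D-class
#' @export
setMethod("dim", "Image2D", function(x) dim(x@pixels))

setMethod("show", "Image2D", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Image2D: %d x %d, spacing (%.4g, %.4g) mm, gray [%.4g, %.4g]\n",
              d[1], d[2], object@spacing[1], object@spacing[2],
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "FilterBank", function(object) {
  cat(sprintf("FilterBank '%s': %d taps, sum(h0)=%.6f\n",
              object@name, length(object@h0), sum(object@h0)))
})

setMethod("show", "WaveletPyramid", function(object) {
  cat(sprintf(
    "WaveletPyramid: %d level(s), base %d x %d, wavelet '%s', %s boundary\n",
    object@levels, object@baseShape[1], object@baseShape[2],
    object@filterName, object@boundary))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: dx=%.4g dy=%.4g %s, theta=%.4g deg\n",
              object@dx, object@dy, object@units, object@theta))
})

setMethod("show", "RegistrationResult", function(object) {
  t <- object@transform
  cat(sprintf("RegistrationResult (%s mode)\n", object@mode))
  cat(sprintf("  recovered: dx=%.3f dy=%.3f px, theta=%.3f deg\n",
              t@dx, t@dy, t@theta))
  cat(sprintf("  combined measure %.5f (NMI_i %.5f, NMI_g %s)\n",
              object@combined, object@nmiI,
              if (is.na(object@nmiG)) "-" else sprintf("%.5f", object@nmiG)))
  cat(sprintf("  MSE %.4f after %d evaluations, %d sweep(s)\n",
              object@mse, object@evaluations, length(object@trace)))
})

#' Transform parameters as a named numeric vector
#'
#' @param x a RigidTransform or RegistrationResult.
#' @return named numeric (dx, dy, theta).
#' @export
setGeneric("transformParams", function(x) standardGeneric("transformParams"))

#' @rdname transformParams
#' @export
setMethod("transformParams", "RigidTransform", function(x)
  c(dx = x@dx, dy = x@dy, theta = x@theta))

#' @rdname transformParams
#' @export
setMethod("transformParams", "RegistrationResult", function(x)
  transformParams(x@transform))
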