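# Stationary (undecimated, a-trous) wavelet transform.
#
# Analysis at level j is stride-1 correlation with the filter dilated by
# 2^(j-1) (zero-insertion between taps), applied separably to rows and
# columns under a circular index wrap. Synthesis applies the adjoint of
# each analysis operator and halves per dimension; for an orthonormal
# quadrature-mirror pair this inverts the analysis exactly, because
# |H(w)|^2 + |G(w)|^2 = 2 at every frequency. The "symmetric" boundary is
# realized by whole-image reflect extension to (2M, 2N) followed by the
# periodic transform, which keeps the inverse exact while preventing
# wrap-around ghost edges between opposite image borders.

# Correlation of x with dilated taps along rows (margin 1) or columns
# (margin 2); adjoint = TRUE applies the transpose operator (scatter).
.pfilt <- function(x, taps, step, margin, adjoint = FALSE) {
  n <- if (margin == 1L) nrow(x) else ncol(x)
  off <- step * (seq_along(taps) - 1L)
  if (adjoint) off <- -off
  y <- 0
  base <- seq_len(n) - 1L
  for (k in seq_along(taps)) {
    idx <- ((base + off[k]) %% n) + 1L
    y <- y + taps[k] *
      (if (margin == 1L) x[idx, , drop = FALSE] else x[, idx, drop = FALSE])
  }
  y
}

.reflect_extend <- function(x) {
  x <- rbind(x, x[rev(seq_len(nrow(x))), , drop = FALSE])
  cbind(x, x[, rev(seq_len(ncol(x))), drop = FALSE])
}

.crop_base <- function(x, shape) x[seq_len(shape[1]), seq_len(shape[2]),
                                   drop = FALSE]

.as_pixel_matrix <- function(img) {
  if (is(img, "Image2D")) img@pixels else {
    m <- as.matrix(img); storage.mode(m) <- "double"; m
  }
}

#' Stationary wavelet decomposition of an image
#'
#' Decomposes a 2D image into approximation (LL) and detail (LH, HL, HH)
#' bands at each of \code{levels} scales using the undecimated a-trous
#' algorithm: every band retains the input shape, which makes the transform
#' equivariant under circular shifts (translation invariance).
#'
#' @param img an \linkS4class{Image2D} or numeric matrix.
#' @param levels decomposition depth J >= 1 (default 3).
#' @param filters a \linkS4class{FilterBank} or wavelet name (default
#'   "haar").
#' @param boundary "symmetric" (default; reflect extension, no wrap-around
#'   ghost edges) or "periodic" (circular; exactly shift-equivariant).
#' @return a \linkS4class{WaveletPyramid}.
#' @examples
#' img <- makePhantom(phantomSpec(shape = c(64, 64), seed = 1))
#' pyr <- swtDecompose(img, levels = 3)
#' pyr
#' @seealso \code{\link{swtReconstruct}}, \code{\link{synthesizeGradientImage}}
#' @export
swtDecompose <- function(img, levels = 3L, filters = waveletFilters("haar"),
                         boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  if (is.character(filters)) filters <- waveletFilters(filters)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  px <- .as_pixel_matrix(img)
  sp <- if (is(img, "Image2D")) img@spacing else c(1, 1)
  shape <- dim(px)
  L <- length(filters@h0)
  support <- (L - 1L) * 2L^(levels - 1L) + 1L
  if (support > min(shape))
    stop(sprintf(
      "image %d x %d too small for %d levels of '%s' (needs >= %d px)",
      shape[1], shape[2], levels, filters@name, support))
  a <- if (boundary == "symmetric") .reflect_extend(px) else px
  h0 <- filters@h0; g0 <- filters@g0
  approx <- detLH <- detHL <- detHH <- vector("list", levels)
  for (j in seq_len(levels)) {
    s <- 2L^(j - 1L)
    lr <- .pfilt(a, h0, s, 1L)
    hr <- .pfilt(a, g0, s, 1L)
    approx[[j]] <- .pfilt(lr, h0, s, 2L)
    detLH[[j]]  <- .pfilt(lr, g0, s, 2L)
    detHL[[j]]  <- .pfilt(hr, h0, s, 2L)
    detHH[[j]]  <- .pfilt(hr, g0, s, 2L)
    a <- approx[[j]]
  }
  new("WaveletPyramid", levels = levels, approx = approx, detailLH = detLH,
      detailHL = detHL, detailHH = detHH, baseShape = as.integer(shape),
      boundary = boundary, filterName = filters@name, spacing = sp)
}

#' Inverse stationary wavelet transform
#'
#' Reconstructs the image from a \linkS4class{WaveletPyramid} by applying,
#' at each level from coarsest to finest, the adjoint synthesis of the four
#' bands with a 1/4 normalization (the average over the redundant phases of
#' the undecimated transform). For an unmodified pyramid this inverts
#' \code{\link{swtDecompose}} to within numerical round-off, and the map is
#' linear in the coefficients.
#'
#' @param pyr a \linkS4class{WaveletPyramid}.
#' @param filters filter bank to use; defaults to the family recorded in
#'   the pyramid.
#' @return an \linkS4class{Image2D}.
#' @export
swtReconstruct <- function(pyr, filters = NULL) {
  stopifnot(is(pyr, "WaveletPyramid"))
  validObject(pyr)
  if (is.null(filters)) filters <- waveletFilters(pyr@filterName)
  if (is.character(filters)) filters <- waveletFilters(filters)
  h0 <- filters@h0; g0 <- filters@g0
  a <- pyr@approx[[pyr@levels]]
  for (j in rev(seq_len(pyr@levels))) {
    s <- 2L^(j - 1L)
    lo <- .pfilt(a, h0, s, 2L, adjoint = TRUE) +
          .pfilt(pyr@detailLH[[j]], g0, s, 2L, adjoint = TRUE)
    hi <- .pfilt(pyr@detailHL[[j]], h0, s, 2L, adjoint = TRUE) +
          .pfilt(pyr@detailHH[[j]], g0, s, 2L, adjoint = TRUE)
    a <- (.pfilt(lo, h0, s, 1L, adjoint = TRUE) +
          .pfilt(hi, g0, s, 1L, adjoint = TRUE)) / 4
  }
  if (pyr@boundary == "symmetric") a <- .crop_base(a, pyr@baseShape)
  Image2D(a, spacing = pyr@spacing)
}

#' Zero the approximation bands of a pyramid
#'
#' Sets the low-frequency (LL) band of every level to zero, leaving only
#' detail content; reconstructing the result yields the gradient image.
#'
#' @param pyr a \linkS4class{WaveletPyramid}.
#' @return the pyramid with all approximation bands set to 0.
#' @export
zeroApprox <- function(pyr) {
  stopifnot(is(pyr, "WaveletPyramid"))
  z <- pyr@approx[[1L]] * 0
  pyr@approx <- rep(list(z), pyr@levels)
  pyr
}

#' Extract a band from a wavelet pyramid
#'
#' Bands are always returned at the base image shape (for the symmetric
#' boundary the internally stored reflect-extended arrays are cropped).
#'
#' @param pyr a \linkS4class{WaveletPyramid}.
#' @param level band level, 1 (finest) .. \code{levels}.
#' @param orientation for \code{detailBand}: "LH" (low along rows, high
#'   along columns), "HL", or "HH".
#' @return a numeric matrix of the base image shape.
#' @export
approxBand <- function(pyr, level = pyr@levels) {
  stopifnot(is(pyr, "WaveletPyramid"), level >= 1L, level <= pyr@levels)
  b <- pyr@approx[[level]]
  if (pyr@boundary == "symmetric") .crop_base(b, pyr@baseShape) else b
}

#' @rdname approxBand
#' @export
detailBand <- function(pyr, level, orientation = c("LH", "HL", "HH")) {
  stopifnot(is(pyr, "WaveletPyramid"), level >= 1L, level <= pyr@levels)
  orientation <- match.arg(orientation)
  b <- switch(orientation, LH = pyr@detailLH, HL = pyr@detailHL,
              HH = pyr@detailHH)[[level]]
  if (pyr@boundary == "symmetric") .crop_base(b, pyr@baseShape) else b
}

# Element-wise arithmetic on pyramids (used e.g. to check linearity of the
# inverse transform). Operates on the stored bands; metadata must agree.
setMethod("Arith", signature("WaveletPyramid", "WaveletPyramid"),
  function(e1, e2) {
    if (!identical(e1@baseShape, e2@baseShape) ||
        !identical(e1@levels, e2@levels) ||
        !identical(e1@boundary, e2@boundary))
      stop("pyramids are not conformable")
    op <- .Generic
    f <- function(a, b) mapply(function(x, y) do.call(op, list(x, y)),
                               a, b, SIMPLIFY = FALSE)
    e1@approx   <- f(e1@approx, e2@approx)
    e1@detailLH <- f(e1@detailLH, e2@detailLH)
    e1@detailHL <- f(e1@detailHL, e2@detailHL)
    e1@detailHH <- f(e1@detailHH, e2@detailHH)
    e1
  })

#' Synthesize an edge-dominant gradient image
#'
#' Decomposes the image with the stationary wavelet transform, zeroes the
#' approximation (low-frequency) bands produced at every level, and
#' inverse-transforms the remaining detail bands. The result is a
#' zero-mean, edge-dominant companion of the input in which tissue
#' transitions carry the signal; it supplies the spatial information that a
#' pure intensity histogram ignores.
#'
#' @inheritParams swtDecompose
#' @return an \linkS4class{Image2D} of the same shape; values are signed
#'   and centered near zero.
#' @examples
#' img <- makePhantom(phantomSpec(shape = c(64, 64), seed = 1))
#' g <- synthesizeGradientImage(img)
#' range(pixels(g))
#' @export
synthesizeGradientImage <- function(img, levels = 3L,
                                    filters = waveletFilters("haar"),
                                    boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  if (is.character(filters)) filters <- waveletFilters(filters)
  pyr <- swtDecompose(img, levels = levels, filters = filters,
                      boundary = boundary)
  swtReconstruct(zeroApprox(pyr), filters = filters)
}
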