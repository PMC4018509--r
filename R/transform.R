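# Rigid 2D transforms. The forward map acts on 0-based pixel coordinates
# (x = column, y = row): q = Rot(theta) (p - center) + center + (dx, dy).
# Floating images are pulled back onto the reference grid through the
# inverse map, so each objective evaluation costs one interpolation pass.

.default_center <- function(shape) c((shape[1] - 1) / 2, (shape[2] - 1) / 2)

.t_as_px <- function(t, img) {
  if (t@units == "mm") {
    sp <- if (is(img, "Image2D")) img@spacing else c(1, 1)
    rigidTransform(t@dx / sp[2], t@dy / sp[1], t@theta, units = "px",
                   center = t@center)
  } else t
}

# 3x3 homogeneous matrix of the forward map (pixel units, explicit center)
.t_matrix <- function(t, center) {
  th <- t@theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  # center is (row, col) = (cy, cx); matrix acts on (x, y)
  cvec <- c(center[2], center[1])
  shift <- cvec + c(t@dx, t@dy) - R %*% cvec
  rbind(cbind(R, shift), c(0, 0, 1))
}

.t_from_matrix <- function(A, center) {
  th <- atan2(A[2, 1], A[1, 1]) * 180 / pi
  R <- A[1:2, 1:2]
  cvec <- c(center[2], center[1])
  d <- A[1:2, 3] - cvec + R %*% cvec
  rigidTransform(d[1], d[2], th, units = "px", center = center)
}

#' Resample an image under a rigid transform
#'
#' Applies the forward rigid map to the image content: the output grid
#' equals the input grid and each output pixel is filled by pull-back
#' sampling of the input at the inverse-mapped position, using nearest or
#' bilinear interpolation. Positions falling outside the input are set to
#' \code{pad_value} (the image minimum by default, mimicking the air
#' background of CT; \code{NA} marks them invalid for histogramming).
#'
#' @param img an \linkS4class{Image2D} or matrix.
#' @param t a \linkS4class{RigidTransform}; mm translations are converted
#'   to pixels via the image spacing.
#' @param interpolation "bilinear" (default) or "nearest".
#' @param pad_value fill for out-of-bounds samples; default
#'   \code{min(pixels(img))}; may be \code{NA}.
#' @return an \linkS4class{Image2D} on the same grid, or a bare numeric
#'   matrix (with NAs marking invalid samples) when \code{pad_value} is NA.
#' @examples
#' img <- makePhantom(phantomSpec(shape = c(64, 64), seed = 1))
#' shifted <- applyRigid(img, rigidTransform(3, -2, 0), "nearest")
#' @export
applyRigid <- function(img, t, interpolation = c("bilinear", "nearest"),
                       pad_value = NULL) {
  interpolation <- match.arg(interpolation)
  px <- .as_pixel_matrix(img)
  sp <- if (is(img, "Image2D")) img@spacing else c(1, 1)
  tp <- .t_as_px(t, img)
  center <- if (anyNA(tp@center)) .default_center(dim(px)) else tp@center
  if (is.null(pad_value)) pad_value <- min(px)
  out <- .cpp_rigid_resample(px, tp@dx, tp@dy, tp@theta * pi / 180,
                             center[2], center[1],
                             interpolation == "nearest",
                             if (is.na(pad_value)) 0 else pad_value,
                             is.na(pad_value))
  if (is.na(pad_value)) {
    # NA markers flag invalid samples; return a bare matrix since Image2D
    # requires finite pixels
    return(out)
  }
  Image2D(out, spacing = sp,
          origin = if (is(img, "Image2D")) img@origin else c(0, 0))
}

#' Invert a rigid transform
#'
#' Returns the transform whose forward map is the inverse of \code{t}'s:
#' theta' = -theta and translation -Rot(-theta) (dx, dy), about the same
#' center. Composing a transform with its inverse gives identity
#' parameters to within round-off.
#'
#' @param t a \linkS4class{RigidTransform} (pixel units).
#' @return the inverse \linkS4class{RigidTransform}.
#' @examples
#' invertTransform(rigidTransform(10, 15, 0))
#' @export
invertTransform <- function(t) {
  stopifnot(is(t, "RigidTransform"))
  th <- -t@theta * pi / 180
  d <- -c(cos(th) * t@dx - sin(th) * t@dy,
          sin(th) * t@dx + cos(th) * t@dy)
  rigidTransform(d[1], d[2], -t@theta, units = t@units, center = t@center)
}

#' Compose two rigid transforms
#'
#' \code{composeTransforms(t2, t1)} is the transform that applies
#' \code{t1} first, then \code{t2} (both about the same center).
#'
#' @param t2,t1 \linkS4class{RigidTransform}s in pixel units.
#' @param center rotation center used to resolve parameters; defaults to
#'   the transforms' center (must agree) or (0, 0).
#' @return a \linkS4class{RigidTransform}.
#' @export
composeTransforms <- function(t2, t1, center = NULL) {
  if (is.null(center)) {
    center <- if (!anyNA(t2@center)) t2@center
              else if (!anyNA(t1@center)) t1@center else c(0, 0)
  }
  A <- .t_matrix(t2, center) %*% .t_matrix(t1, center)
  .t_from_matrix(A, center)
}

#' Serialize / restore a rigid transform as JSON
#'
#' @param t a \linkS4class{RigidTransform}.
#' @param path file to write to / read from.
#' @return \code{readTransform} returns a \linkS4class{RigidTransform}.
#' @export
writeTransform <- function(t, path) {
  jsonlite::write_json(list(dx = t@dx, dy = t@dy, theta_deg = t@theta,
                            units = t@units),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(x$dx, x$dy, x$theta_deg, units = x$units)
}
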