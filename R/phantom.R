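# Synthetic anatomical phantom. Emulates an axial CT slice: an elliptical
# body outline on an air background, filled with piecewise-constant
# "organ" structures bounded by ellipses and rectangles (curved and
# straight edges so the wavelet gradient image is non-trivial), optional
# partial-volume blur, then CBCT-style degradation (contrast offset and
# additive Gaussian noise) on top.

#' Specification of a synthetic phantom
#'
#' @param shape integer(2), (rows, cols) of the phantom (default 256x256).
#' @param n_regions number of distinct-intensity regions including the
#'   background (>= 1, default 6).
#' @param noise_sigma standard deviation of additive Gaussian noise in
#'   gray units (default 0), added last.
#' @param contrast_offset global intensity shift (default 0), applied
#'   before the noise.
#' @param blur_sigma Gaussian blur (pixels) applied to the clean phantom
#'   to emulate the scanner point-spread/partial-volume effect; default
#'   0.7. Set 0 for strictly piecewise-constant output.
#' @param spacing physical pixel size in mm (default c(1, 1)).
#' @param seed RNG seed; identical seeds give bitwise-identical phantoms.
#' @return a list of class \code{phantomSpec}.
#' @export
phantomSpec <- function(shape = c(256, 256), n_regions = 6,
                        noise_sigma = 0, contrast_offset = 0,
                        blur_sigma = 0.7, spacing = c(1, 1), seed = 1) {
  stopifnot(length(shape) == 2L, all(shape >= 8L), n_regions >= 1,
            noise_sigma >= 0, blur_sigma >= 0, all(spacing > 0))
  structure(list(shape = as.integer(shape), n_regions = n_regions,
                 noise_sigma = noise_sigma,
                 contrast_offset = contrast_offset,
                 blur_sigma = blur_sigma, spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "phantomSpec")
}

# run code under a local RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.gauss_blur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  # separable blur with reflect extension (periodic on the mirrored image)
  ext <- .reflect_extend(px)
  conv1 <- function(x, margin) {
    n <- if (margin == 1L) nrow(x) else ncol(x)
    base <- seq_len(n) - 1L
    y <- 0
    for (i in seq_along(k)) {
      idx <- ((base + (i - 1L - r)) %% n) + 1L
      y <- y + k[i] *
        (if (margin == 1L) x[idx, , drop = FALSE] else x[, idx, drop = FALSE])
    }
    y
  }
  .crop_base(conv1(conv1(ext, 1L), 2L), dim(px))
}

#' Generate a synthetic anatomical phantom
#'
#' Deterministic given the seed. Region 1 is the air background
#' (gray 0); region 2 is an elliptical body outline; further regions are
#' randomly placed ellipses and axis-aligned rectangles inside the body,
#' each with its own gray level drawn from 100..1000. The clean phantom is
#' optionally blurred (partial volume), shifted by \code{contrast_offset},
#' and Gaussian noise of sd \code{noise_sigma} is added last.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return an \linkS4class{Image2D}.
#' @examples
#' img <- makePhantom(phantomSpec(shape = c(64, 64), n_regions = 4, seed = 7))
#' img
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  M <- spec$shape[1]; N <- spec$shape[2]
  .with_seed(spec$seed, {
    px <- matrix(0, M, N)
    rr <- matrix(seq_len(M) - 1, M, N)
    cc <- matrix(seq_len(N) - 1, M, N, byrow = TRUE)
    cy <- (M - 1) / 2; cx <- (N - 1) / 2
    grays <- round(stats::runif(max(spec$n_regions - 1L, 0L), 100, 1000))
    if (spec$n_regions >= 2L) {
      # body: ellipse covering ~ 70% of the frame
      body <- ((rr - cy) / (0.42 * M))^2 + ((cc - cx) / (0.38 * N))^2 <= 1
      px[body] <- grays[1]
      for (i in seq_len(spec$n_regions - 2L)) {
        # alternate curved (ellipse) and straight (rectangle) boundaries
        pr <- cy + stats::runif(1, -0.22, 0.22) * M
        pc <- cx + stats::runif(1, -0.2, 0.2) * N
        if (i %% 2L == 1L) {
          ar <- stats::runif(1, 0.05, 0.14) * M
          ac <- stats::runif(1, 0.05, 0.14) * N
          th <- stats::runif(1, 0, pi)
          dr <- rr - pr; dc <- cc - pc
          u <- cos(th) * dc + sin(th) * dr
          v <- -sin(th) * dc + cos(th) * dr
          mask <- (u / ac)^2 + (v / ar)^2 <= 1
        } else {
          hr <- stats::runif(1, 0.04, 0.12) * M
          hc <- stats::runif(1, 0.04, 0.12) * N
          mask <- abs(rr - pr) <= hr & abs(cc - pc) <= hc
        }
        px[mask & body] <- grays[i + 1L]
      }
    }
    px <- .gauss_blur(px, spec$blur_sigma)
    px <- px + spec$contrast_offset
    if (spec$noise_sigma > 0)
      px <- px + matrix(stats::rnorm(M * N, 0, spec$noise_sigma), M, N)
    Image2D(px, spacing = spec$spacing)
  })
}

#' Derive a CBCT-like floating image from a CT-like image
#'
#' Emulates the setup CBCT counterpart of a planning CT slice: the scene
#' is resampled onto a coarser grid (smaller matrix, larger pixels), a
#' global contrast offset is applied, and Gaussian noise is added. Useful
#' for exercising the cross-grid registration path.
#'
#' @param img the CT-like \linkS4class{Image2D}.
#' @param target_spacing CBCT pixel size in mm (default c(1.27, 1.27)).
#' @param target_shape CBCT matrix size; default scales the input shape by
#'   the spacing ratio (keeps the field of view).
#' @param noise_sigma additive Gaussian noise sd in gray units.
#' @param contrast_offset global intensity shift.
#' @param seed RNG seed for the noise.
#' @return an \linkS4class{Image2D} on the CBCT grid.
#' @export
makeCbctLike <- function(img, target_spacing = c(1.27, 1.27),
                         target_shape = NULL, noise_sigma = 0,
                         contrast_offset = 0, seed = 1) {
  stopifnot(is(img, "Image2D"))
  if (is.null(target_shape))
    target_shape <- round(dim(img) * img@spacing / target_spacing)
  out <- resampleToGrid(img, target_spacing, target_shape)
  px <- out@pixels + contrast_offset
  if (noise_sigma > 0) {
    px <- px + .with_seed(seed,
      matrix(stats::rnorm(length(px), 0, noise_sigma), nrow(px), ncol(px)))
  }
  Image2D(px, spacing = out@spacing, origin = out@origin)
}
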