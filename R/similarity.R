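# Histogram-based similarity: marginal/joint entropy, mutual information,
# normalized mutual information, and the logistic-weighted fusion of the
# intensity and gradient NMIs. All entropies are in bits (log base 2).

#' Configuration of the similarity measure
#'
#' @param bins number of histogram bins per image (default 64).
#' @param T temperature of the logistic weighting function (default 0.04);
#'   smaller values make the weight switch harder.
#' @param interpolation interpolation used when sampling the moving image:
#'   "linear" (default) or "nearest".
#' @param nmi_rescale logical (default TRUE): use NMI - 1 (range 0..1)
#'   inside the weighting argument v so the logistic, centered at 0.5,
#'   operates on its design domain; the combination itself always mixes
#'   the raw NMI values. FALSE feeds raw NMI (range 1..2) into v, which
#'   saturates the weight at ~1 and reduces the measure to the intensity
#'   NMI.
#' @return a list of class \code{measureConfig}.
#' @export
measureConfig <- function(bins = 64L, T = 0.04,
                          interpolation = c("linear", "nearest"),
                          nmi_rescale = TRUE) {
  interpolation <- match.arg(interpolation)
  if (bins < 2L) stop("bins must be >= 2")
  if (!is.finite(T) || T <= 0) stop("T must be > 0")
  structure(list(bins = as.integer(bins), T = T,
                 interpolation = interpolation, log_base = 2,
                 nmi_rescale = isTRUE(nmi_rescale)),
            class = "measureConfig")
}

#' Joint gray-value histogram of two aligned images
#'
#' Bins both images on equal-width grids spanning each image's own
#' (or a supplied, frozen) gray range and normalizes the pair counts to a
#' joint probability table. Pixels where either image is NA (out-of-bounds
#' samples of a transformed floating image) are excluded, so the histogram
#' covers only the overlap region.
#'
#' @param ref,flt \linkS4class{Image2D}s or matrices of the same shape;
#'   \code{flt} may contain NAs marking invalid samples.
#' @param cfg a \code{\link{measureConfig}}.
#' @param range_ref,range_flt optional fixed (lo, hi) gray ranges; default
#'   each image's finite range.
#' @return a list with \code{joint} (bins x bins probability matrix),
#'   \code{marginal_a}, \code{marginal_b}, \code{bins}, \code{n} (pixel
#'   pairs used), \code{range_a}, \code{range_b}.
#' @export
jointHistogram <- function(ref, flt, cfg = measureConfig(),
                           range_ref = NULL, range_flt = NULL) {
  a <- .as_pixel_matrix(ref); b <- .as_pixel_matrix(flt)
  if (!identical(dim(a), dim(b)))
    stop("images must have the same shape (resample first)")
  if (is.null(range_ref)) range_ref <- range(a, na.rm = TRUE)
  if (is.null(range_flt)) range_flt <- range(b, na.rm = TRUE)
  h <- .cpp_joint_hist(a, b, cfg$bins, range_ref[1], range_ref[2],
                       range_flt[1], range_flt[2])
  if (h$n == 0) stop("degenerate overlap: no valid pixel pairs")
  joint <- h$counts / h$n
  list(joint = joint, marginal_a = rowSums(joint),
       marginal_b = colSums(joint), bins = cfg$bins, n = h$n,
       range_a = range_ref, range_b = range_flt)
}

#' Shannon entropy of a probability vector, in bits
#'
#' Uses the convention 0 * log 0 = 0.
#'
#' @param p nonnegative probabilities summing to 1 (a marginal of
#'   \code{\link{jointHistogram}}).
#' @return entropy in bits, between 0 and log2(length(p)).
#' @examples
#' entropyBits(c(0.5, 0.5))  # 1 bit
#' @export
entropyBits <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("probabilities must be nonnegative")
  s <- sum(p)
  if (abs(s - 1) > 1e-8) stop("probabilities must sum to 1")
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

#' Joint entropy, mutual information and normalized mutual information
#'
#' \code{jointEntropy} evaluates the entropy of the joint table;
#' \code{mutualInformation} returns H(A) + H(B) - H(A,B);
#' \code{normalizedMI} returns (H(A) + H(B)) / H(A,B), which lies in
#' [1, 2] and is insensitive to the size of the image overlap.
#'
#' @param hist a histogram model from \code{\link{jointHistogram}}.
#' @return a scalar (bits for the entropies and MI; dimensionless NMI).
#' @export
jointEntropy <- function(hist) entropyBits(as.numeric(hist$joint))

#' @rdname jointEntropy
#' @export
mutualInformation <- function(hist) {
  entropyBits(hist$marginal_a) + entropyBits(hist$marginal_b) -
    jointEntropy(hist)
}

#' @rdname jointEntropy
#' @export
normalizedMI <- function(hist) {
  hab <- jointEntropy(hist)
  if (hab <= 0)
    stop("degenerate entropy: both images are constant on the overlap")
  (entropyBits(hist$marginal_a) + entropyBits(hist$marginal_b)) / hab
}

#' Logistic weighting function
#'
#' f(v) = 1 / (1 + exp(-(v - 0.5) / T)): a sigmoid centered at 0.5 whose
#' steepness is controlled by the temperature T. Satisfies f(0.5) = 0.5
#' and f(v) + f(1 - v) = 1.
#'
#' @param v weighting argument (the mean of the two rescaled NMIs).
#' @param T temperature > 0 (default 0.04).
#' @return weight in (0, 1).
#' @export
logisticWeight <- function(v, T = 0.04) {
  if (!is.numeric(T) || T <= 0) stop("T must be > 0")
  1 / (1 + exp(-(v - 0.5) / T))
}

#' Weighted combination of intensity and gradient NMI
#'
#' Fuses the normalized mutual information of the intensity images
#' (\code{nmi_i}) and of the wavelet gradient images (\code{nmi_g}) into a
#' single similarity measure: a convex combination
#' f(v) * nmi_i + (1 - f(v)) * nmi_g with the logistic weight f evaluated
#' at v = (x + y) / 2. With \code{nmi_rescale} on (the default),
#' x = nmi_i - 1 and y = nmi_g - 1, mapping the NMI range [1, 2] onto the
#' logistic's [0, 1] design domain: near alignment (both NMIs high) the
#' weight moves toward the intensity term, far from alignment toward the
#' gradient term.
#'
#' @param nmi_i,nmi_g the two NMI values (finite).
#' @param cfg a \code{\link{measureConfig}} supplying T and
#'   \code{nmi_rescale}.
#' @return the combined measure, bounded by min and max of the inputs.
#' @examples
#' combinedMeasure(1.8, 1.4)
#' @export
combinedMeasure <- function(nmi_i, nmi_g, cfg = measureConfig()) {
  stopifnot(is.finite(nmi_i), is.finite(nmi_g))
  if (cfg$T <= 0) stop("T must be > 0")
  x <- if (cfg$nmi_rescale) nmi_i - 1 else nmi_i
  y <- if (cfg$nmi_rescale) nmi_g - 1 else nmi_g
  f <- logisticWeight((x + y) / 2, cfg$T)
  f * nmi_i + (1 - f) * nmi_g
}
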