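# Derivative-free optimization: Brent's 1D minimizer on a bracketing
# triple (golden-section with parabolic interpolation) and Powell's
# direction-set method with the standard direction-replacement heuristic.
# Both are deterministic. The registration driver MAXIMIZES the similarity
# measure by minimizing its negation.

#' Optimizer configuration
#'
#' @param xtol absolute parameter tolerance of the line search (scaled
#'   units; default 1e-3, i.e. well below one pixel / one degree).
#' @param ftol relative objective decrease below which a Powell sweep
#'   terminates (default 1e-5).
#' @param max_iter maximum number of Powell sweeps (default 50).
#' @param max_line_evals cap on function evaluations per line search,
#'   including bracketing (default 100).
#' @param bracket_step initial bracketing step in scaled units
#'   (default 1).
#' @param param_scales per-parameter scaling; a unit step in scaled space
#'   equals one scale unit of the parameter (default c(1, 1, 1): 1 px,
#'   1 px, 1 degree).
#' @return a list of class \code{optimizerConfig}.
#' @export
optimizerConfig <- function(xtol = 1e-3, ftol = 1e-5, max_iter = 50L,
                            max_line_evals = 100L, bracket_step = 1,
                            param_scales = c(1, 1, 1)) {
  stopifnot(xtol > 0, ftol > 0, max_iter >= 1, max_line_evals >= 10,
            bracket_step > 0, all(param_scales > 0))
  structure(list(xtol = xtol, ftol = ftol, max_iter = as.integer(max_iter),
                 max_line_evals = as.integer(max_line_evals),
                 bracket_step = bracket_step, param_scales = param_scales),
            class = "optimizerConfig")
}

.GOLD <- (1 + sqrt(5)) / 2

# Expand from (a, b) until a triple with a low middle point is found.
# Returns list(a, b, c, fa, fb, fc, evals) with a < b < c, fb < fa, fb < fc.
.bracket_minimum <- function(f, x0, step, max_evals) {
  a <- x0; b <- x0 + step
  fa <- f(a); fb <- f(b); evals <- 2L
  if (fb > fa) { tmp <- a; a <- b; b <- tmp; tmp <- fa; fa <- fb; fb <- tmp }
  cc <- b + .GOLD * (b - a); fc <- f(cc); evals <- evals + 1L
  while (fc <= fb) {
    if (evals >= max_evals)
      stop("bracketing failure: no minimum found within max_line_evals ",
           "(objective may be monotone on the search interval)")
    a <- b; fa <- fb; b <- cc; fb <- fc
    cc <- b + .GOLD * (b - a); fc <- f(cc); evals <- evals + 1L
  }
  if (a > cc) { tmp <- a; a <- cc; cc <- tmp; tmp <- fa; fa <- fc; fc <- tmp }
  list(a = a, b = b, c = cc, fa = fa, fb = fb, fc = fc, evals = evals)
}

#' Brent line minimization
#'
#' Minimizes a scalar function of one variable on a bracketing triple
#' (a, b, c) with f(b) < f(a) and f(b) < f(c), combining golden-section
#' steps with parabolic interpolation. If \code{bracket} is a pair or a
#' single start value, a bracket is first grown by golden-ratio expansion
#' from \code{step}; a monotone objective then raises a bracketing error.
#'
#' @param f scalar function of one variable.
#' @param bracket numeric of length 1 (start), 2 (a, b) or 3 (a, b, c).
#' @param cfg an \code{\link{optimizerConfig}} (xtol, max_line_evals).
#' @param step initial bracketing step (default \code{cfg$bracket_step}).
#' @return list(xmin, fmin, evals).
#' @examples
#' brentMinimize(function(x) (x - 2)^2, bracket = 0)$xmin
#' @export
brentMinimize <- function(f, bracket = 0, cfg = optimizerConfig(),
                          step = cfg$bracket_step) {
  evals <- 0L
  fc_ <- function(x) { evals <<- evals + 1L; f(x) }
  if (length(bracket) == 3L) {
    a <- bracket[1]; b <- bracket[2]; cc <- bracket[3]
    fb <- fc_(b)
    if (fc_(a) <= fb || fc_(cc) <= fb || !(a < b && b < cc))
      stop("invalid bracket: need a < b < c with f(b) < f(a), f(b) < f(c)")
    x <- b; fx <- fb
  } else {
    x0 <- if (length(bracket) == 2L) bracket[1] else bracket[1]
    st <- if (length(bracket) == 2L) bracket[2] - bracket[1] else step
    br <- .bracket_minimum(fc_, x0, st, cfg$max_line_evals)
    a <- br$a; cc <- br$c; x <- br$b; fx <- br$fb
  }
  # Brent's method proper (golden section + parabolic steps)
  cgold <- (3 - sqrt(5)) / 2
  w <- v <- x; fw <- fv <- fx
  d <- e <- 0
  for (iter in seq_len(cfg$max_line_evals)) {
    xm <- (a + cc) / 2
    tol1 <- cfg$xtol * abs(x) + 1e-12
    tol2 <- 2 * tol1
    if (abs(x - xm) <= tol2 - (cc - a) / 2) break
    use_golden <- TRUE
    if (abs(e) > tol1) {
      r <- (x - w) * (fx - fv)
      q <- (x - v) * (fx - fw)
      p <- (x - v) * q - (x - w) * r
      q <- 2 * (q - r)
      if (q > 0) p <- -p
      q <- abs(q)
      etemp <- e; e <- d
      if (abs(p) < abs(q * etemp / 2) && p > q * (a - x) &&
          p < q * (cc - x)) {
        d <- p / q
        u <- x + d
        if (u - a < tol2 || cc - u < tol2) d <- sign(xm - x) * tol1
        use_golden <- FALSE
      }
    }
    if (use_golden) {
      e <- if (x >= xm) a - x else cc - x
      d <- cgold * e
    }
    u <- if (abs(d) >= tol1) x + d else x + sign(d) * tol1
    fu <- fc_(u)
    if (fu <= fx) {
      if (u >= x) a <- x else cc <- x
      v <- w; fv <- fw; w <- x; fw <- fx; x <- u; fx <- fu
    } else {
      if (u < x) a <- u else cc <- u
      if (fu <= fw || w == x) { v <- w; fv <- fw; w <- u; fw <- fu }
      else if (fu <= fv || v == x || v == w) { v <- u; fv <- fu }
    }
    if (evals >= cfg$max_line_evals) break
  }
  list(xmin = x, fmin = fx, evals = evals)
}

#' Powell direction-set minimization
#'
#' Minimizes a function of n parameters without derivatives by cycling
#' Brent line searches along a set of directions (initially the scaled
#' coordinate axes) and applying the standard direction-replacement rule:
#' after each sweep, the direction of largest single decrease is replaced
#' by the net sweep displacement when the replacement test passes.
#' Terminates when a sweep reduces the objective by less than
#' \code{ftol} relatively, or after \code{max_iter} sweeps.
#'
#' @param f objective function of a numeric vector; must be finite at
#'   \code{x0}.
#' @param x0 numeric start vector.
#' @param cfg an \code{\link{optimizerConfig}}.
#' @return list(x, f, trace, evals, sweeps): \code{trace} holds the
#'   objective after each sweep and is non-increasing.
#' @examples
#' powellMinimize(function(p) sum((p - c(1, 2, 3))^2), c(0, 0, 0))$x
#' @export
powellMinimize <- function(f, x0, cfg = optimizerConfig()) {
  n <- length(x0)
  scales <- rep_len(cfg$param_scales, n)
  evals <- 0L
  fn <- function(x) {
    val <- f(x); evals <<- evals + 1L
    if (!is.finite(val))
      stop("objective returned a non-finite value at (",
           paste(signif(x, 6), collapse = ", "), ")")
    val
  }
  dirs <- diag(scales, n, n)
  x <- as.numeric(x0)
  fx <- fn(x)
  trace <- numeric(0)
  for (sweep in seq_len(cfg$max_iter)) {
    f0 <- fx
    x_start <- x
    biggest <- 0; ibig <- 1L
    for (i in seq_len(n)) {
      u <- dirs[, i]
      fprev <- fx
      ls <- tryCatch(
        brentMinimize(function(t) fn(x + t * u), bracket = 0, cfg = cfg,
                      step = cfg$bracket_step),
        error = function(e) NULL)  # monotone direction: skip
      if (!is.null(ls) && ls$fmin < fx) {
        x <- x + ls$xmin * u
        fx <- ls$fmin
      }
      if (fprev - fx > biggest) { biggest <- fprev - fx; ibig <- i }
    }
    trace <- c(trace, fx)
    if (2 * (f0 - fx) <= cfg$ftol * (abs(f0) + abs(fx)) + 1e-25) break
    # extrapolated point and direction replacement (Powell/Acton test)
    xe <- 2 * x - x_start
    fe <- fn(xe)
    if (fe < f0) {
      t <- 2 * (f0 - 2 * fx + fe) * (f0 - fx - biggest)^2 -
           biggest * (f0 - fe)^2
      if (t < 0) {
        unew <- x - x_start
        if (sqrt(sum(unew^2)) > 1e-14) {
          ls <- tryCatch(
            brentMinimize(function(t) fn(x + t * unew), bracket = 0,
                          cfg = cfg, step = 1),
            error = function(e) NULL)
          if (!is.null(ls) && ls$fmin < fx) {
            x <- x + ls$xmin * unew
            fx <- ls$fmin
          }
          dirs[, ibig] <- dirs[, n]
          dirs[, n] <- unew
        }
      }
    }
  }
  list(x = x, f = fx, trace = trace, evals = evals,
       sweeps = length(trace))
}
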