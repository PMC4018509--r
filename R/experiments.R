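# Experiment harnesses: preset-transform recovery and shift-linearity
# protocols, mirroring the two standard ways of validating a rigid
# registration when ground truth is known by construction.

#' Preset-transform recovery experiment
#'
#' For each preset rigid transform, a floating image is generated by
#' applying the preset to the reference; both registration modes then
#' recover it. Because the preset is known, parameter errors and the
#' residual gray-level error are exact. The estimated preset is the
#' inverse of the recovered correction transform.
#'
#' @param ref reference \linkS4class{Image2D} (e.g. from
#'   \code{\link{makePhantom}}).
#' @param presets list of \linkS4class{RigidTransform}s (pixel units).
#' @param cfg a \code{\link{registrationConfig}}; its \code{mode} is
#'   overridden per run.
#' @param modes registration modes to run (default both).
#' @return a data.frame with one row per preset: preset parameters,
#'   estimated parameters and errors per mode, pre-registration MSE, and
#'   post-registration MSE per mode (\code{mse_proposed},
#'   \code{mse_mi_only}).
#' @export
runRecoveryExperiment <- function(ref, presets,
                                  cfg = registrationConfig(),
                                  modes = c("proposed", "mi_only")) {
  stopifnot(length(presets) >= 1L)
  ref <- Image2D(ref)
  rows <- lapply(seq_along(presets), function(i) {
    t <- presets[[i]]
    flt <- applyRigid(ref, t, cfg$interpolation)
    row <- data.frame(image = i, dx = t@dx, dy = t@dy, theta = t@theta,
                      mse_pre = mseError(ref, flt))
    for (mode in modes) {
      cfg_m <- cfg; cfg_m$mode <- mode
      res <- registerImages(ref, flt, cfg_m)
      est <- transformParams(invertTransform(res@transform))
      tag <- if (mode == "proposed") "prop" else "mi"
      row[[paste0("dx_", tag)]] <- est[["dx"]]
      row[[paste0("dy_", tag)]] <- est[["dy"]]
      row[[paste0("theta_", tag)]] <- est[["theta"]]
      row[[paste0("err_dx_", tag)]] <- est[["dx"]] - t@dx
      row[[paste0("err_dy_", tag)]] <- est[["dy"]] - t@dy
      row[[paste0("err_theta_", tag)]] <- est[["theta"]] - t@theta
      row[[paste0("mse_", mode)]] <- res@mse
    }
    row
  })
  do.call(rbind, rows)
}

#' Shift-linearity experiment
#'
#' Applies an arithmetic progression of translations along one axis to
#' the floating image, registers each shifted copy to the reference, and
#' fits the recovered translation against the preset shift by least
#' squares. Perfect registration gives slope -1 (the recovered correction
#' negates the preset, minus the fixed narrowing pre-shift) with R^2 = 1
#' and recovered rotations near 0.
#'
#' @param ref reference \linkS4class{Image2D}.
#' @param flt floating \linkS4class{Image2D} (any grid; resampled by the
#'   driver).
#' @param shift_grid numeric vector of preset shifts in mm (arithmetic
#'   progression, e.g. \code{seq(80, 100, 5)}).
#' @param axis "x" or "y": the shifted direction.
#' @param cfg a \code{\link{registrationConfig}}; \code{initial_shift}
#'   acts as the manual narrowing applied before each optimization.
#' @param base_shift numeric(2), fixed (dx, dy) shift in mm applied on the
#'   non-varied axis (default c(0, 0)); the varied axis takes the grid
#'   values.
#' @return a list with \code{table} (per-shift recovered parameters in px
#'   and mm), \code{slope}, \code{intercept}, \code{r2} of the
#'   recovered-vs-preset least-squares fit (mm scale), and
#'   \code{max_abs_theta}.
#' @export
runLinearityExperiment <- function(ref, flt, shift_grid,
                                   axis = c("y", "x"),
                                   cfg = registrationConfig(),
                                   base_shift = c(0, 0)) {
  axis <- match.arg(axis)
  stopifnot(length(shift_grid) >= 2L)
  ref <- Image2D(ref); flt <- Image2D(flt)
  sp <- ref@spacing
  rows <- lapply(shift_grid, function(s) {
    t <- if (axis == "x") rigidTransform(s, base_shift[2], 0, units = "mm")
         else rigidTransform(base_shift[1], s, 0, units = "mm")
    flt_s <- applyRigid(flt, t, cfg$interpolation)
    res <- registerImages(ref, flt_s, cfg)
    p <- transformParams(res)
    data.frame(preset_mm = s,
               dx_px = p[["dx"]], dy_px = p[["dy"]],
               dx_mm = p[["dx"]] * sp[2], dy_mm = p[["dy"]] * sp[1],
               theta = p[["theta"]], mse = res@mse)
  })
  tab <- do.call(rbind, rows)
  rec <- if (axis == "x") tab$dx_mm else tab$dy_mm
  fit <- stats::lm(rec ~ tab$preset_mm)
  list(table = tab,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = summary(fit)$r.squared,
       max_abs_theta = max(abs(tab$theta)))
}

#' The ten preset transforms of the recovery protocol
#'
#' Translations in pixels along x and y plus a rotation in degrees; used
#' by the recovery experiment as a standard battery spanning +-30 px and
#' -5..2 degrees.
#'
#' @return a list of \linkS4class{RigidTransform}s.
#' @export
recoveryPresets <- function() {
  p <- list(c(10, 15, -3), c(10, 10, -3), c(20, 15, -3), c(20, -10, -5),
            c(18, -8, -3.45), c(30, 20, -3), c(10, 25, -3),
            c(10, -16, -3), c(5, 8, 2), c(10, 12, 2))
  lapply(p, function(v) rigidTransform(v[1], v[2], v[3]))
}

#' Paired robustness comparison of the two registration modes
#'
#' Repeats one fixed misalignment over several noise realizations of the
#' floating image and registers each realization in both modes. The
#' translation error is the Euclidean distance between the estimated and
#' the true preset translation; pairing the modes on identical noise
#' fields makes the comparison a matched-samples one.
#'
#' @param ref clean reference \linkS4class{Image2D}.
#' @param preset the applied \linkS4class{RigidTransform} (pixel units).
#' @param n_rep number of noise realizations (default 20).
#' @param noise_sigma sd of the Gaussian noise added to the floating
#'   image, gray units.
#' @param cfg a \code{\link{registrationConfig}}.
#' @param seed_base realization i uses seed \code{seed_base + i}.
#' @return a list with \code{table} (per-realization errors),
#'   \code{mean_err_proposed}, \code{mean_err_mi_only}.
#' @export
runRobustnessComparison <- function(ref, preset, n_rep = 20L,
                                    noise_sigma, cfg = registrationConfig(),
                                    seed_base = 1000L) {
  ref <- Image2D(ref)
  clean_flt <- applyRigid(ref, preset, cfg$interpolation)
  true_t <- transformParams(preset)
  rows <- lapply(seq_len(n_rep), function(i) {
    noisy <- .with_seed(seed_base + i, {
      px <- pixels(clean_flt) +
        matrix(stats::rnorm(prod(dim(clean_flt)), 0, noise_sigma),
               nrow(pixels(clean_flt)))
      Image2D(px, spacing = spacing(clean_flt))
    })
    err_of <- function(mode) {
      cfg_m <- cfg; cfg_m$mode <- mode
      est <- transformParams(
        invertTransform(registerImages(ref, noisy, cfg_m)@transform))
      sqrt((est[["dx"]] - true_t[["dx"]])^2 +
           (est[["dy"]] - true_t[["dy"]])^2)
    }
    data.frame(rep = i, err_proposed = err_of("proposed"),
               err_mi_only = err_of("mi_only"))
  })
  tab <- do.call(rbind, rows)
  list(table = tab, mean_err_proposed = mean(tab$err_proposed),
       mean_err_mi_only = mean(tab$err_mi_only))
}
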