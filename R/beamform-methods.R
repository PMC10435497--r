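#' @export
print.lifu_beamform <- function(x, ...) {
  cat(sprintf("<lifu_beamform> method = %s, M = %d elements, P = %g\n",
              x$method, length(x$w), x$P))
  cat(sprintf("  activated off-target cells at ratio %.2f: %d (%.3g mm^2)\n",
              x$ratio, x$hard_count, x$hard_count * x$cell_area_mm2))
  if (!is.null(x$iterations) && x$iterations > 0)
    cat(sprintf("  iterations: %d, converged: %s\n", x$iterations, x$converged))
  if (isTRUE(x$infeasible))
    cat("  NOTE: cap constraints reported infeasible; best drive returned\n")
  invisible(x)
}

#' @export
summary.lifu_beamform <- function(object, ...) {
  s <- list(method = object$method, M = length(object$w), P = object$P,
            ratio = object$ratio,
            otaa_mm2 = object$hard_count * object$cell_area_mm2,
            hard_count = object$hard_count,
            n_control = object$n_control,
            target_intensity_unit_power = object$target_intensity,
            iterations = object$iterations, converged = object$converged,
            infeasible = object$infeasible,
            amplitudes = Mod(object$w), phases = Arg(object$w))
  class(s) <- "summary.lifu_beamform"
  s
}

#' @export
print.summary.lifu_beamform <- function(x, ...) {
  cat(sprintf("Beamforming fit: %s (M = %d, P = %g, I_l/I_h = %.2f)\n",
              x$method, x$M, x$P, x$ratio))
  cat(sprintf("  off-target activation: %d of %d control cells (%.3g mm^2)\n",
              x$hard_count, x$n_control, x$otaa_mm2))
  cat(sprintf("  target intensity at unit-power drive: %.4g W/cm^2\n",
              x$target_intensity_unit_power))
  if (x$iterations > 0)
    cat(sprintf("  optimizer: %d iterations, converged = %s\n", x$iterations, x$converged))
  cat("  element amplitudes:\n")
  print(signif(x$amplitudes, 4))
  invisible(x)
}

#' @export
coef.lifu_beamform <- function(object, ...) object$w

#' Drive rescaled to a prescribed target intensity
#'
#' Returns the fitted drive scaled so that the intensity at the target cell
#' equals `I_target` (pressures at all other points scale proportionally).
#'
#' @param object a fitted `lifu_beamform`.
#' @param I_target desired target intensity in W/cm^2.
#' @export
scale_to_target <- function(object, I_target) {
  if (object$target_intensity <= 0) stop("degenerate fit: zero target intensity")
  object$w * sqrt(I_target / object$target_intensity)
}

#' @export
fitted.lifu_beamform <- function(object, ...) intensity_map(object$w, object$field)

#' Predicted intensity map at a stimulation intensity
#'
#' @param object a fitted `lifu_beamform`.
#' @param I_target target intensity the drive is rescaled to; default the
#'   intensity achieved by the unit-power fit.
#' @param ... unused.
#' @export
predict.lifu_beamform <- function(object, I_target = NULL, ...) {
  w <- if (is.null(I_target)) object$w else scale_to_target(object, I_target)
  intensity_map(w, object$field)
}

#' @export
plot.lifu_beamform <- function(x, log = TRUE, ...) {
  I <- fitted(x)
  In <- I / max(I[x$target_cell[1], x$target_cell[2]], .Machine$double.xmin)
  co <- grid_coords(x$field$grid)
  z <- if (log) log10(pmax(In, 1e-6)) else In
  graphics::image(co$x, co$y, z, asp = 1, col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("%s beam (%s intensity / target)",
                                 x$method, if (log) "log10" else "relative"), ...)
  txy <- c(co$x[x$target_cell[1]], co$y[x$target_cell[2]])
  graphics::points(txy[1], txy[2], pch = 1, col = "white", cex = 1.5)
  invisible(x)
}
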