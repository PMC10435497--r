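#' Off-target activation area (OTAA)
#'
#' The resolution metric S(w): the number of off-target brain cells whose
#' intensity reaches the conservative threshold I_l, converted to mm^2 via
#' the cell area, subject to the target cell itself reaching the excitation
#' threshold I_h.  The step indicator counts I(G) - I_l >= 0 as activated
#' (closed half-line, chi(0) = 1).  Exposure of supportive tissue (skin,
#' skull) above I_l is reported as a separate diagnostic, not as part of
#' the OTAA.
#'
#' @param I an [intensity_map()] (or matrix, W/cm^2) on the masks' grid.
#' @param masks [region_masks()].
#' @param model a [neuron_response_model()] supplying I_l and I_h.
#' @param exclusion_radius_mm radius around the target excluded from the
#'   count (default 0: only the target cell itself is excluded).
#' @return object of class `otaa_result` with `area_mm2`, `n_points`,
#'   `target_excited`, `supportive_exposure_mm2`.
#' @export
otaa <- function(I, masks, model, exclusion_radius_mm = 0) {
  if (!all(dim(I) == dim(masks$brain_mask))) stop("intensity and mask shapes differ")
  grid <- masks$grid
  tc <- masks$target_cell
  excl <- matrix(FALSE, grid$nx, grid$ny)
  excl[tc[1], tc[2]] <- TRUE
  if (exclusion_radius_mm > 0) {
    co <- grid_coords(grid)
    txy <- c(co$x[tc[1]], co$y[tc[2]])
    excl <- excl | (sqrt((co$X - txy[1])^2 + (co$Y - txy[2])^2) <= exclusion_radius_mm)
  }
  off <- masks$brain_mask & !excl
  n_points <- sum(I[off] >= model$I_l)
  supp <- sum(I[masks$supportive_mask] >= model$I_l)
  structure(list(area_mm2 = n_points * cell_area(grid),
                 n_points = as.integer(n_points),
                 target_excited = I[tc[1], tc[2]] >= model$I_h,
                 supportive_exposure_mm2 = supp * cell_area(grid),
                 I_l = model$I_l, I_h = model$I_h),
            class = "otaa_result")
}

#' @export
print.otaa_result <- function(x, ...) {
  cat(sprintf("<otaa_result> %.3g mm^2 (%d cells), target %s, supportive exposure %.3g mm^2\n",
              x$area_mm2, x$n_points,
              if (x$target_excited) "excited" else "NOT excited",
              x$supportive_exposure_mm2))
  invisible(x)
}

#' OTAA sweep over stimulation parameters
#'
#' Sweeps the OTAA over target intensity, duration or duty cycle for a
#' fixed transfer field and drive direction.  For the intensity sweep the
#' drive is rescaled so that the target intensity equals each swept value
#' (the field pattern is fixed up to scale); for duration and duty-cycle
#' sweeps the field is fixed and the response model's thresholds are
#' re-derived for each protocol.
#'
#' @param field a `transfer_field`.
#' @param w complex drive vector.
#' @param masks [region_masks()].
#' @param protocol baseline [stimulus_protocol()].
#' @param sweep one of `"intensity"`, `"duration"`, `"duty_cycle"`.
#' @param values positive sorted sweep values (W/cm^2, ms, or fraction).
#' @param ratio I_l / I_h.
#' @param ... further arguments to [neuron_response_model()].
#' @return data.frame with the swept value, `area_mm2`, `n_points`,
#'   `target_excited` and `supportive_exposure_mm2` per row.
#' @export
otaa_sweep <- function(field, w, masks, protocol,
                       sweep = c("intensity", "duration", "duty_cycle"),
                       values, ratio = 0.6, ...) {
  sweep <- match.arg(sweep)
  if (length(values) == 0) stop("sweep values must be non-empty")
  if (any(values <= 0) || is.unsorted(values)) stop("sweep values must be positive and sorted")
  I0 <- intensity_map(w, field)
  tc <- masks$target_cell
  I_t <- I0[tc[1], tc[2]]
  if (I_t <= 0) stop("zero target intensity; cannot sweep")
  rows <- lapply(values, function(v) {
    if (sweep == "intensity") {
      I <- I0 * (v / I_t)          # w scaled so that I(G*) = v; thresholds fixed
      mdl <- neuron_response_model(protocol, ratio = ratio, ...)
    } else {
      pr <- if (sweep == "duration") {
        stimulus_protocol(protocol$waveform, duration_ms = v,
                          prf_hz = protocol$prf_hz,
                          duty_cycle = if (protocol$waveform == "pulsed") protocol$duty_cycle else NULL)
      } else {
        if (protocol$waveform != "pulsed") stop("duty-cycle sweep needs a pulsed protocol")
        stimulus_protocol("pulsed", duration_ms = protocol$duration_ms,
                          prf_hz = protocol$prf_hz, duty_cycle = v)
      }
      I <- I0
      mdl <- neuron_response_model(pr, ratio = ratio, ...)
    }
    res <- otaa(I, masks, mdl)
    data.frame(value = v, area_mm2 = res$area_mm2, n_points = res$n_points,
               target_excited = res$target_excited,
               supportive_exposure_mm2 = res$supportive_exposure_mm2)
  })
  out <- do.call(rbind, rows)
  attr(out, "sweep") <- sweep
  out
}
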