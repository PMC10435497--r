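#' Phased-array transducer placement on a phantom
#'
#' Places an M-element arc array on one of the phantom's surfaces:
#' `transcranial` (on the outer skin boundary), `intracranial_single`
#' (on the inner skull surface, i.e. on the dura) or `intracranial_double`
#' (two arcs on the inner skull surface driven synchronously at the same
#' frequency, one combined drive vector of length M_total).
#'
#' Elements are spaced by `pitch_mm` along the arc; `centre_angle_deg` gives
#' the angular position of each arc's center (length 2 for the double
#' placement).  For homogeneous media without layer geometry the placement
#' radius must be supplied via `radius_mm`.
#'
#' @param medium a `lifu_medium`.
#' @param masks the phantom's [region_masks()].
#' @param placement one of `"transcranial"`, `"intracranial_single"`,
#'   `"intracranial_double"`.
#' @param n_elements total element count (split evenly across two arcs for
#'   the double placement, or a length-2 vector).
#' @param pitch_mm inter-element arc spacing in mm.
#' @param frequency operating frequency in Hz.
#' @param centre_angle_deg arc center angle(s), degrees, measured from +x.
#' @param radius_mm placement radius override (required for homogeneous
#'   media that carry no layer geometry).
#' @param power_budget total drive power constraint P (dimensionless).
#' @return an object of class `transducer_array`.
#' @export
place_array <- function(medium, masks, placement = c("transcranial",
                                                     "intracranial_single",
                                                     "intracranial_double"),
                        n_elements, pitch_mm, frequency = 5e5,
                        centre_angle_deg = 90, radius_mm = NULL,
                        power_budget = 1) {
  placement <- match.arg(placement)
  if (frequency <= 0) stop("frequency must be positive")
  geom <- attr(medium, "geometry")
  if (is.null(radius_mm)) {
    if (is.null(geom)) stop("geometry error: homogeneous medium needs radius_mm")
    radius_mm <- switch(placement,
                        transcranial = geom$r_skin_out,
                        geom$r_skull_in)
  }
  ctr <- if (!is.null(geom)) geom$center else grid_center(medium$grid)

  n_arcs <- if (placement == "intracranial_double") 2L else 1L
  if (length(centre_angle_deg) != n_arcs)
    stop("centre_angle_deg must have length ", n_arcs, " for placement ", placement)
  n_per <- if (length(n_elements) == n_arcs) as.integer(n_elements)
           else rep(as.integer(n_elements) %/% n_arcs, n_arcs)
  if (any(n_per < 1L)) stop("each arc needs at least one element")

  pos <- NULL; nrm <- NULL
  for (a in seq_len(n_arcs)) {
    dtheta <- pitch_mm / radius_mm           # arc-length pitch -> angular step
    span <- dtheta * (n_per[a] - 1)
    if (span >= 2 * pi)
      stop("geometry error: arc does not fit ", n_per[a], " elements at pitch ", pitch_mm)
    th0 <- centre_angle_deg[a] * pi / 180
    th <- th0 + (seq_len(n_per[a]) - (n_per[a] + 1) / 2) * dtheta
    p <- cbind(ctr[1] + radius_mm * cos(th), ctr[2] + radius_mm * sin(th))
    pos <- rbind(pos, p)
    nrm <- rbind(nrm, cbind(-cos(th), -sin(th)))  # inward-pointing normals
  }
  half_x <- (medium$grid$nx - 1) / 2 * medium$grid$dx
  half_y <- (medium$grid$ny - 1) / 2 * medium$grid$dx
  if (any(abs(pos[, 1] - ctr[1]) > half_x) || any(abs(pos[, 2] - ctr[2]) > half_y))
    stop("geometry error: array elements fall outside the grid")

  structure(list(element_positions = pos, element_normals = nrm,
                 frequency = frequency, power_budget = power_budget,
                 placement_tag = placement, radius_mm = radius_mm,
                 pitch_mm = pitch_mm, center = ctr),
            class = "transducer_array")
}

#' @export
print.transducer_array <- function(x, ...) {
  cat(sprintf("<transducer_array> %d elements, %s, f = %g kHz, pitch = %g mm, r = %g mm\n",
              nrow(x$element_positions), x$placement_tag, x$frequency / 1e3,
              x$pitch_mm, x$radius_mm))
  invisible(x)
}
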