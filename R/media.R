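#' Registered acoustic tissue properties
#'
#' Default acoustic property tuples per tissue tag: density rho (kg/m^3),
#' sound speed c (m/s), attenuation coefficient alpha0 (dB/(MHz^y cm)) and
#' attenuation power-law exponent y.  The skull is a single homogeneous
#' layer (one-layer assumption); cerebrospinal fluid is water-like.  Values
#' follow standard tissue-property compilations and every tuple can be
#' overridden.
#'
#' @param overrides optional named list; each entry a list/vector with fields
#'   `density`, `sound_speed`, `atten_coeff`, `atten_power` replacing or
#'   adding a tissue tag.
#' @return data.frame with one row per tissue tag.
#' @export
tissue_table <- function(overrides = NULL) {
  tab <- data.frame(
    tissue        = c("water", "csf", "skin", "skull", "grey", "white", "brain_generic"),
    density       = c(1007,   1007,  1109,   1900,    1046,   1041,    1046),
    sound_speed   = c(1504,   1504,  1624,   2800,    1546,   1562,    1546),
    atten_coeff   = c(0.05,   0.05,  0.4,    8.0,     0.6,    0.8,     0.6),
    atten_power   = c(1.1,    1.1,   1.1,    1.1,     1.2,    1.2,     1.2),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      ov <- as.list(overrides[[nm]])
      row <- which(tab$tissue == nm)
      if (length(row) == 0L) {
        tab <- rbind(tab, data.frame(tissue = nm,
                                     density = ov$density, sound_speed = ov$sound_speed,
                                     atten_coeff = ov$atten_coeff, atten_power = ov$atten_power))
      } else {
        for (f in intersect(names(ov), names(tab))) tab[row, f] <- ov[[f]]
      }
    }
  }
  tab
}

tissue_tuple <- function(material, properties = tissue_table()) {
  row <- which(properties$tissue == material)
  if (length(row) != 1L) stop("unknown material tag: ", material)
  properties[row, , drop = FALSE]
}

new_medium <- function(grid, density, sound_speed, atten_coeff, atten_power, labels) {
  stopifnot(all(density > 0), all(sound_speed > 0), all(atten_coeff >= 0))
  structure(list(grid = grid, density = density, sound_speed = sound_speed,
                 atten_coeff = atten_coeff, atten_power = atten_power,
                 labels = labels),
            class = "lifu_medium")
}

#' @export
print.lifu_medium <- function(x, ...) {
  tabs <- table(x$labels)
  cat(sprintf("<lifu_medium> %d x %d cells, dx = %g mm\n", x$grid$nx, x$grid$ny, x$grid$dx))
  cat("  tissues:", paste(sprintf("%s (%d)", names(tabs), as.integer(tabs)), collapse = ", "), "\n")
  invisible(x)
}

is_homogeneous <- function(medium) length(unique(as.vector(medium$labels))) == 1L

#' Homogeneous 2-D acoustic medium
#'
#' @param material registered tissue tag (see [tissue_table()]).
#' @param grid a [grid2d()] object.
#' @param properties property table, default [tissue_table()].
#' @return a `lifu_medium` with uniform property maps.
#' @export
make_homogeneous_medium <- function(material, grid, properties = tissue_table()) {
  tp <- tissue_tuple(material, properties)
  fill <- function(v) matrix(v, grid$nx, grid$ny)
  new_medium(grid,
             density = fill(tp$density), sound_speed = fill(tp$sound_speed),
             atten_coeff = fill(tp$atten_coeff), atten_power = tp$atten_power,
             labels = matrix(material, grid$nx, grid$ny))
}

#' Region masks for OTAA evaluation
#'
#' The brain mask holds the cells eligible for off-target activation
#' counting; the supportive mask (skin and skull) is reported separately as
#' an exposure diagnostic.  The two masks must be disjoint and the target
#' must lie inside the brain mask.
#'
#' @param brain_mask,supportive_mask logical nx x ny matrices.
#' @param target_cell integer c(i, j) cell index of the stimulation target.
#' @param grid the associated [grid2d()].
#' @export
region_masks <- function(brain_mask, supportive_mask, target_cell, grid) {
  target_cell <- as.integer(target_cell)
  if (any(brain_mask & supportive_mask))
    stop("brain and supportive masks must be disjoint")
  if (!brain_mask[target_cell[1], target_cell[2]])
    stop("target cell must lie inside the brain mask")
  structure(list(brain_mask = brain_mask, supportive_mask = supportive_mask,
                 target_cell = target_cell, grid = grid),
            class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  cat(sprintf("<region_masks> brain %d cells, supportive %d cells, target (%d,%d)\n",
              sum(x$brain_mask), sum(x$supportive_mask),
              x$target_cell[1], x$target_cell[2]))
  invisible(x)
}

#' Layered circular head phantom
#'
#' Concentric annuli (skin > skull > CSF > brain) around the grid center,
#' emulating a 2-D head cross-section with a homogeneous one-layer skull.
#' The background outside the skin is water.  A seed perturbs the layer
#' boundaries with a small smooth angular jitter; generation is
#' bit-reproducible given identical arguments.
#'
#' @param grid a [grid2d()].
#' @param skull_outer_radius_mm outer radius of the skull annulus.
#' @param skull_thickness_mm,skin_thickness_mm,csf_thickness_mm layer
#'   thicknesses in mm (0 drops the layer).
#' @param seed integer seed for the boundary jitter (NULL: no jitter).
#' @param boundary_jitter_mm amplitude of the smooth boundary perturbation.
#' @param target_mm physical target coordinate (mm); default grid center.
#' @param properties tissue property table.
#' @return list with elements `medium` and `masks`.
#' @export
make_head_phantom <- function(grid, skull_outer_radius_mm,
                              skull_thickness_mm = 6, skin_thickness_mm = 4,
                              csf_thickness_mm = 2, seed = NULL,
                              boundary_jitter_mm = 0.15,
                              target_mm = NULL, properties = tissue_table()) {
  r_skull_out <- skull_outer_radius_mm
  r_skin_out  <- r_skull_out + skin_thickness_mm
  r_skull_in  <- r_skull_out - skull_thickness_mm
  r_brain     <- r_skull_in - csf_thickness_mm
  if (any(c(r_skull_out, skull_thickness_mm, skin_thickness_mm, csf_thickness_mm) < 0))
    stop("radii and thicknesses must be non-negative")
  if (r_brain <= 0) stop("geometry error: layers leave no brain interior")
  half_extent <- min(grid$nx, grid$ny) / 2 * grid$dx
  if (r_skin_out >= half_extent)
    stop("geometry error: phantom annuli exceed the grid extent")

  co <- grid_coords(grid)
  ctr <- grid_center(grid)
  RX <- co$X - ctr[1]; RY <- co$Y - ctr[2]
  r <- sqrt(RX^2 + RY^2)
  theta <- atan2(RY, RX)

  jitter <- matrix(0, grid$nx, grid$ny)
  if (!is.null(seed) && boundary_jitter_mm > 0) {
    set.seed(as.integer(seed))
    ph <- stats::runif(3, 0, 2 * pi)
    amp <- boundary_jitter_mm * stats::runif(3, 0.3, 1)
    for (m in 1:3) jitter <- jitter + amp[m] * cos((m + 1) * theta + ph[m])
  }
  rj <- r - jitter  # jittered radial coordinate, shared by all boundaries

  labels <- matrix("water", grid$nx, grid$ny)
  labels[rj < r_skin_out]  <- "skin"
  labels[rj < r_skull_out] <- "skull"
  labels[rj < r_skull_in]  <- "csf"
  labels[rj < r_brain]     <- "brain_generic"
  if (skull_thickness_mm == 0) labels[labels == "skull"] <- "skin"

  maps <- lapply(c("density", "sound_speed", "atten_coeff"), function(f) {
    m <- matrix(NA_real_, grid$nx, grid$ny)
    for (tis in unique(as.vector(labels)))
      m[labels == tis] <- tissue_tuple(tis, properties)[[f]]
    m
  })
  # power-law exponent is a scalar; use the brain value as the global exponent
  y <- tissue_tuple("brain_generic", properties)$atten_power
  medium <- new_medium(grid, maps[[1]], maps[[2]], maps[[3]], y, labels)
  attr(medium, "geometry") <- list(center = ctr, r_skin_out = r_skin_out,
                                   r_skull_out = r_skull_out,
                                   r_skull_in = r_skull_in, r_brain = r_brain)

  if (is.null(target_mm)) target_mm <- ctr
  tc <- nearest_cell(grid, target_mm)
  masks <- region_masks(brain_mask = labels == "brain_generic",
                        supportive_mask = labels %in% c("skin", "skull"),
                        target_cell = tc, grid = grid)
  list(medium = medium, masks = masks)
}

#' Disc-shaped region masks for homogeneous phantoms
#'
#' Convenience masks for homogeneous media: the brain region is a disc of
#' the given radius around the grid center (no supportive tissue).
#'
#' @param grid a [grid2d()].
#' @param radius_mm disc radius in mm.
#' @param target_mm physical target coordinate; default grid center.
#' @export
disc_masks <- function(grid, radius_mm, target_mm = NULL) {
  co <- grid_coords(grid); ctr <- grid_center(grid)
  r <- sqrt((co$X - ctr[1])^2 + (co$Y - ctr[2])^2)
  if (is.null(target_mm)) target_mm <- ctr
  region_masks(brain_mask = r < radius_mm,
               supportive_mask = matrix(FALSE, grid$nx, grid$ny),
               target_cell = nearest_cell(grid, target_mm), grid = grid)
}
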