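# 2-D map -> NIfTI on disk (stored as nx x ny x 1 with the grid spacing)
map_to_nifti <- function(m, grid, path) {
  arr <- array(as.numeric(m), dim = c(grid$nx, grid$ny, 1))
  img <- RNifti::asNifti(arr, pixdim = c(grid$dx, grid$dx, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a medium to disk
#'
#' Property maps (density, sound speed, attenuation) as NIfTI volumes,
#' labels as an integer-coded NIfTI with a JSON legend carrying the grid
#' and the attenuation exponent.
#'
#' @param medium a `lifu_medium`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @export
write_medium <- function(medium, dir, prefix = "medium") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- medium$grid
  map_to_nifti(medium$density, g, file.path(dir, paste0(prefix, "_density.nii.gz")))
  map_to_nifti(medium$sound_speed, g, file.path(dir, paste0(prefix, "_sound_speed.nii.gz")))
  map_to_nifti(medium$atten_coeff, g, file.path(dir, paste0(prefix, "_atten_coeff.nii.gz")))
  tissues <- sort(unique(as.vector(medium$labels)))
  codes <- matrix(match(medium$labels, tissues), g$nx, g$ny)
  map_to_nifti(codes, g, file.path(dir, paste0(prefix, "_labels.nii.gz")))
  meta <- list(nx = g$nx, ny = g$ny, dx = g$dx, origin = g$origin,
               atten_power = medium$atten_power, tissues = tissues)
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a medium written by [write_medium()]
#' @param dir directory holding the files.
#' @param prefix file name prefix used at write time.
#' @export
read_medium <- function(dir, prefix = "medium") {
  meta <- jsonlite::fromJSON(file.path(dir, paste0(prefix, "_meta.json")))
  g <- grid2d(meta$nx, meta$ny, meta$dx, meta$origin)
  rd <- function(nm) matrix(as.numeric(RNifti::readNifti(
    file.path(dir, paste0(prefix, "_", nm, ".nii.gz")))), g$nx, g$ny)
  codes <- rd("labels")
  labels <- matrix(meta$tissues[codes], g$nx, g$ny)
  new_medium(g, rd("density"), rd("sound_speed"), rd("atten_coeff"),
             meta$atten_power, labels)
}

#' Persist a transfer field
#'
#' Real and imaginary parts of the M x N transfer matrix as two NIfTI
#' stacks (nx x ny x M), the impedance map as one more, and a JSON
#' metadata sidecar.
#'
#' @param field a `transfer_field`.
#' @param dir output directory.
#' @export
write_transfer_field <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- field$grid
  M <- nrow(field$H)
  dimv <- c(g$nx, g$ny, M)
  wr <- function(a, nm) RNifti::writeNifti(
    RNifti::asNifti(array(a, dimv), pixdim = c(g$dx, g$dx, 1)),
    file.path(dir, nm))
  wr(Re(t(field$H)), "transfer_re.nii.gz")
  wr(Im(t(field$H)), "transfer_im.nii.gz")
  map_to_nifti(field$rhoc, g, file.path(dir, "rhoc.nii.gz"))
  jsonlite::write_json(list(frequency = field$frequency, solver = field$solver,
                            nx = g$nx, ny = g$ny, dx = g$dx, origin = g$origin,
                            n_elements = M),
                       file.path(dir, "transfer_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a transfer field written by [write_transfer_field()]
#' @param dir directory holding the files.
#' @export
read_transfer_field <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "transfer_meta.json"))
  g <- grid2d(meta$nx, meta$ny, meta$dx, meta$origin)
  N <- g$nx * g$ny; M <- meta$n_elements
  re <- as.numeric(RNifti::readNifti(file.path(dir, "transfer_re.nii.gz")))
  im <- as.numeric(RNifti::readNifti(file.path(dir, "transfer_im.nii.gz")))
  H <- t(matrix(complex(real = re, imaginary = im), N, M))
  rhoc <- matrix(as.numeric(RNifti::readNifti(file.path(dir, "rhoc.nii.gz"))), g$nx, g$ny)
  new_transfer_field(H, meta$frequency, g, rhoc, meta$solver)
}

#' Write an experiment report's artifacts
#'
#' Per method: intensity and spike maps (CSV and NIfTI) plus a JSON
#' summary with the OTAA values, protocol echo and provenance.
#'
#' @param report an `experiment_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(report$methods)) {
    I <- report$methods[[m]]$intensity
    sm <- report$methods[[m]]$spikes
    g <- attr(I, "grid")
    utils::write.csv(unclass(I), file.path(dir, paste0("intensity_", m, ".csv")),
                     row.names = FALSE)
    utils::write.csv(unclass(sm), file.path(dir, paste0("spikes_", m, ".csv")),
                     row.names = FALSE)
    map_to_nifti(unclass(I), g, file.path(dir, paste0("intensity_", m, ".nii.gz")))
  }
  summ <- list(otaa_mm2 = as.list(report$otaa_mm2),
               target_excited = as.list(report$target_excited),
               supportive_exposure_mm2 = as.list(report$supportive_exposure_mm2),
               pulse_ms = report$pulse_ms,
               protocol = unclass(report$protocol),
               I_l = report$model$I_l, I_h = report$model$I_h,
               provenance = report$provenance)
  jsonlite::write_json(summ, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
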