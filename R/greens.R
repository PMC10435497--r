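# Outgoing 2-D line-source Hankel function H0(z) = J0(z) + i Y0(z)
hankel1 <- function(z) besselJ(z, 0) + 1i * besselY(z, 0)

# power-law attenuation alpha0 dB/(MHz^y cm) at frequency f -> Np/mm
atten_np_per_mm <- function(alpha0, y, frequency) {
  alpha_db_cm <- alpha0 * (frequency / 1e6)^y
  alpha_db_cm * log(10) / 20 / 10
}

# wavenumber in rad/mm for sound speed c (m/s) at frequency f (Hz)
wavenumber_mm <- function(sound_speed, frequency) 2 * pi * frequency / (sound_speed * 1e3)

# source calibration: unit drive -> unit pressure amplitude (1 Pa) at 1 mm
# in the lossless medium; overall absolute level is a configurable scalar.
source_amplitude <- function(k, calibration = 1) calibration / Mod(hankel1(k * 1))

new_transfer_field <- function(H, frequency, grid, rhoc, solver) {
  structure(list(H = H, frequency = frequency, grid = grid, rhoc = rhoc,
                 solver = solver),
            class = "transfer_field")
}

#' @export
print.transfer_field <- function(x, ...) {
  cat(sprintf("<transfer_field> %d elements x %d grid cells, f = %g kHz (%s)\n",
              nrow(x$H), ncol(x$H), x$frequency / 1e3, x$solver))
  invisible(x)
}

#' Analytic per-element transfer field in a homogeneous medium
#'
#' Steady-state complex pressure transfer h_m(G) from every array element m
#' to every grid cell G, using the outgoing 2-D line-source Green's function
#' `H0(k r) exp(-alpha(f) r)` with power-law attenuation.  The source scale
#' is calibrated so a unit-amplitude drive produces 1 Pa at 1 mm range in
#' the lossless medium.  Cells coinciding with an element position are
#' regularized to the value one cell away.
#'
#' @param medium a homogeneous `lifu_medium`.
#' @param array a [place_array()] object (or any `transducer_array`).
#' @param calibration absolute source pressure scale (Pa at 1 mm per unit
#'   drive).
#' @return a `transfer_field` with the M x N complex transfer matrix `H`.
#' @export
greens_transfer <- function(medium, array, calibration = 1) {
  if (!is_homogeneous(medium))
    stop("greens_transfer requires a homogeneous medium; use helmholtz_transfer")
  grid <- medium$grid
  c0 <- medium$sound_speed[1, 1]
  k <- wavenumber_mm(c0, array$frequency)
  alpha <- atten_np_per_mm(medium$atten_coeff[1, 1], medium$atten_power, array$frequency)
  A <- source_amplitude(k, calibration)

  co <- grid_coords(grid)
  M <- nrow(array$element_positions)
  H <- matrix(0i, M, n_cells(grid))
  px <- as.vector(co$X); py <- as.vector(co$Y)
  for (m in seq_len(M)) {
    r <- sqrt((px - array$element_positions[m, 1])^2 +
              (py - array$element_positions[m, 2])^2)
    r <- pmax(r, grid$dx)  # regularize the source cell singularity
    H[m, ] <- A * hankel1(k * r) * exp(-alpha * r)
  }
  rhoc <- medium$density * medium$sound_speed  # Rayl, SI
  new_transfer_field(H, array$frequency, grid, rhoc, solver = "greens")
}
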