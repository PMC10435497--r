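# PML stretch profiles: complex sx(i) = 1 + i*sigma~(i) with a cubic ramp
# inside the absorbing layer.  sigma~ is dimensionless (sigma/omega).
pml_stretch <- function(n, pml_cells, sigma_max) {
  prof <- function(pos) {            # pos: cell coordinate, may be half-integer
    d_lo <- pml_cells + 1 - pos      # depth into the low-side layer
    d_hi <- pos - (n - pml_cells)    # depth into the high-side layer
    d <- pmax(pmax(d_lo, d_hi), 0) / pml_cells
    1 + 1i * sigma_max * d^3
  }
  list(center = prof(seq_len(n)), lo = prof(seq_len(n) - 0.5), hi = prof(seq_len(n) + 0.5))
}

#' Heterogeneous Helmholtz transfer field (FDFD with PML)
#'
#' Per-element steady-state phasor fields in an arbitrary 2-D medium,
#' obtained by solving the heterogeneous Helmholtz equation with a
#' second-order 5-point finite-difference stencil, complex coordinate
#' stretching (perfectly matched layers) along the outer `pml_cells`
#' cells, and a direct sparse LU solve shared across all element sources.
#' Skull reflections and refraction are captured through the spatially
#' varying wavenumber; power-law attenuation enters as the imaginary part
#' of the wavenumber.  Source normalization matches [greens_transfer()]
#' (unit drive gives 1 Pa at 1 mm in the element's local medium).
#'
#' @param medium a `lifu_medium` (may be heterogeneous).
#' @param array a `transducer_array`.
#' @param pml_cells width of the absorbing layer in cells (default 12).
#' @param tol relative residual bound; the solve fails if the direct
#'   solution's residual exceeds it.
#' @param calibration absolute source pressure scale.
#' @return a `transfer_field`; interior accuracy requires >= 6 grid cells
#'   per wavelength (a warning is issued below 10).
#' @export
helmholtz_transfer <- function(medium, array, pml_cells = 12, tol = 1e-8,
                               calibration = 1) {
  grid <- medium$grid
  nx <- grid$nx; ny <- grid$ny; dx <- grid$dx
  N <- nx * ny
  f <- array$frequency
  lambda_min <- min(medium$sound_speed) / f * 1e3   # mm
  ppw <- lambda_min / dx
  if (ppw < 6) stop(sprintf("grid resolves only %.1f cells per wavelength (need >= 6)", ppw))
  if (ppw < 10) warning(sprintf("only %.1f cells per wavelength; expect dispersion error", ppw))

  k_re <- wavenumber_mm(medium$sound_speed, f)
  alpha <- atten_np_per_mm(medium$atten_coeff, medium$atten_power, f)
  k2 <- (k_re + 1i * alpha)^2

  # absorb to ~exp(-8) one-way for the least-attenuated (fastest) tissue
  k_min <- wavenumber_mm(max(medium$sound_speed), f)
  sigma_max <- 32 / (k_min * pml_cells * dx)
  sx <- pml_stretch(nx, pml_cells, sigma_max)
  sy <- pml_stretch(ny, pml_cells, sigma_max)

  ii <- rep(seq_len(nx), ny)
  jj <- rep(seq_len(ny), each = nx)
  idx <- seq_len(N)
  inv_dx2 <- 1 / dx^2

  cxe <- inv_dx2 / (sx$center[ii] * sx$hi[ii])   # coupling to (i+1, j)
  cxw <- inv_dx2 / (sx$center[ii] * sx$lo[ii])   # coupling to (i-1, j)
  cyn <- inv_dx2 / (sy$center[jj] * sy$hi[jj])   # coupling to (i, j+1)
  cys <- inv_dx2 / (sy$center[jj] * sy$lo[jj])   # coupling to (i, j-1)
  diag_v <- -(cxe + cxw + cyn + cys) + as.vector(k2)

  has_e <- ii < nx; has_w <- ii > 1; has_n <- jj < ny; has_s <- jj > 1
  tri_i <- c(idx, idx[has_e], idx[has_w], idx[has_n], idx[has_s])
  tri_j <- c(idx, idx[has_e] + 1, idx[has_w] - 1, idx[has_n] + nx, idx[has_s] - nx)
  tri_v <- c(diag_v, cxe[has_e], cxw[has_w], cyn[has_n], cys[has_s])

  # real 2N x 2N equivalent of the complex system
  vr <- Re(tri_v); vi <- Im(tri_v)
  A <- Matrix::sparseMatrix(
    i = c(tri_i,     tri_i,     tri_i + N, tri_i + N),
    j = c(tri_j,     tri_j + N, tri_j,     tri_j + N),
    x = c(vr,        -vi,       vi,        vr),
    dims = c(2 * N, 2 * N))

  M <- nrow(array$element_positions)
  B <- matrix(0, 2 * N, M)
  src_idx <- integer(M)
  for (m in seq_len(M)) {
    # bilinear spreading of the point source over the 4 surrounding cells
    # keeps sub-cell element positions to first order
    pxy <- array$element_positions[m, ]
    fi <- (pxy[1] - grid$origin[1]) / dx + 1
    fj <- (pxy[2] - grid$origin[2]) / dx + 1
    i0 <- min(max(floor(fi), 1), nx - 1); j0 <- min(max(floor(fj), 1), ny - 1)
    tx <- min(max(fi - i0, 0), 1); ty <- min(max(fj - j0, 0), 1)
    wts <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
    cells <- rbind(c(i0, j0), c(i0 + 1, j0), c(i0, j0 + 1), c(i0 + 1, j0 + 1))
    cij <- nearest_cell(grid, pxy)
    if (cij[1] <= pml_cells || cij[1] > nx - pml_cells ||
        cij[2] <= pml_cells || cij[2] > ny - pml_cells)
      warning("array element ", m, " lies inside the PML region")
    src_idx[m] <- cell_index(grid, cij[1], cij[2])
    c_src <- medium$sound_speed[cij[1], cij[2]]
    Acal <- source_amplitude(wavenumber_mm(c_src, f), calibration)
    s <- 4i * Acal * inv_dx2           # b = -(-4iA) * delta / dx^2
    for (q in 1:4) {
      li <- cell_index(grid, cells[q, 1], cells[q, 2])
      B[li, m] <- B[li, m] + Re(s) * wts[q]
      B[li + N, m] <- B[li + N, m] + Im(s) * wts[q]
    }
  }

  X <- as.matrix(Matrix::solve(A, B))
  H <- t(matrix(complex(real = X[idx, ], imaginary = X[idx + N, ]), N, M))

  # residual check of the direct solve
  res <- as.matrix(A %*% X - B)
  rel <- sqrt(sum(res^2)) / sqrt(sum(B^2))
  if (!is.finite(rel) || rel > tol)
    stop(sprintf("Helmholtz solve failed: relative residual %.3e > tol %.1e", rel, tol))

  fld <- new_transfer_field(H, f, grid, medium$density * medium$sound_speed,
                            solver = "helmholtz")
  fld$pml_cells <- pml_cells
  fld$source_cells <- src_idx
  fld
}
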