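# Shared fixture builders.  All fixtures are generated in code; sizes are
# kept small so the whole suite runs in minutes.

# lossless water override for analytic-field tests
lossless_water <- function() tissue_table(list(water = list(
  density = 1007, sound_speed = 1504, atten_coeff = 0, atten_power = 1.1)))

# homogeneous disc phantom with an arc array and analytic transfer field
homog_setup <- function(nx = 64, dx = 0.5, material = "csf", n_elem = 8,
                        radius_mm = NULL, brain_radius_mm = NULL, f = 5e5,
                        pitch_mm = 1.5, placement = "intracranial_single",
                        centre_angle_deg = 90) {
  if (is.null(radius_mm)) radius_mm <- 0.44 * nx * dx
  if (is.null(brain_radius_mm)) brain_radius_mm <- 0.37 * nx * dx
  grid <- grid2d(nx, nx, dx)
  med <- make_homogeneous_medium(material, grid)
  masks <- disc_masks(grid, brain_radius_mm)
  arr <- place_array(med, masks, placement, n_elem, pitch_mm, frequency = f,
                     radius_mm = radius_mm, centre_angle_deg = centre_angle_deg)
  fld <- greens_transfer(med, arr)
  list(grid = grid, med = med, masks = masks, arr = arr, fld = fld)
}

# random synthetic transfer instance for optimizer tests (not tied to a grid)
random_qstar <- function(M, n_ctrl, seed, ratio = 0.6, rhoc = 1.5e6) {
  set.seed(seed)
  h <- matrix(complex(real = rnorm(M * n_ctrl), imaginary = rnorm(M * n_ctrl)),
              M, n_ctrl)
  h_t <- complex(real = rnorm(M), imaginary = rnorm(M))
  scale <- rep(1 / (2 * rhoc) / 1e4, n_ctrl)
  corbeam:::qstar_field(list(h = h, scale = scale), h_t, scale[1], ratio)
}

random_drive <- function(M) complex(real = rnorm(M), imaginary = rnorm(M))

# exhaustive M = 2 search over amplitude split (step 0.005) and phase
# difference (step 0.005 rad) for the hard activated-cell count
exhaustive_min_count <- function(qs) {
  stopifnot(nrow(qs$h) == 2)
  a <- seq(0, 1, by = 0.005)
  phi <- seq(0, 2 * pi, by = 0.005); phi <- phi[phi < 2 * pi]
  W1 <- sqrt(a); W2 <- sqrt(1 - a)
  n_ctrl <- ncol(qs$h)
  best <- Inf
  for (p in phi) {
    w2 <- W2 * exp(1i * p)
    at <- Conj(qs$h_t[1]) * W1 + Conj(qs$h_t[2]) * w2
    thr <- qs$ratio * qs$scale_t * Mod(at)^2
    cnt <- numeric(length(a))
    for (g in seq_len(n_ctrl)) {
      ag <- Conj(qs$h[1, g]) * W1 + Conj(qs$h[2, g]) * w2
      cnt <- cnt + (qs$scale[g] * Mod(ag)^2 - thr >= 0)
    }
    best <- min(best, min(cnt))
  }
  best
}

# helper shared with the acceptance suite: relative L2 error between the
# FDFD solution and the analytic Green's function on interior cells
helmholtz_green_errors <- function(nx = 64, dx = 0.1, n_elem = 4, f = 5e5) {
  g <- grid2d(nx, nx, dx)
  med <- make_homogeneous_medium("water", g)
  masks <- disc_masks(g, nx * dx * 0.2)
  arr <- place_array(med, masks, "intracranial_single", n_elem, 3 * dx,
                     frequency = f, radius_mm = nx * dx * 0.25)
  fh <- helmholtz_transfer(med, arr)
  fg <- greens_transfer(med, arr)
  pml <- fh$pml_cells
  co <- grid_coords(g)
  interior <- matrix(FALSE, g$nx, g$ny)
  interior[(pml + 6):(g$nx - pml - 5), (pml + 6):(g$ny - pml - 5)] <- TRUE
  pos <- arr$element_positions
  dmin <- Reduce(pmin, lapply(seq_len(n_elem), function(m)
    sqrt((co$X - pos[m, 1])^2 + (co$Y - pos[m, 2])^2)))
  sel <- which(as.vector(interior & dmin >= 5 * dx))
  vapply(seq_len(n_elem), function(m)
    sqrt(sum(Mod(fh$H[m, sel] - fg$H[m, sel])^2) / sum(Mod(fg$H[m, sel])^2)),
    numeric(1))
}

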