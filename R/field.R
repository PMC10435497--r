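# pressure amplitude (Pa) + characteristic impedance (Rayl) -> W/cm^2
pressure_to_intensity <- function(p, rhoc) Mod(p)^2 / (2 * rhoc) / 1e4

#' Complex steady-state amplitude of a sampled pressure trace
#'
#' Extracts the single-frequency phasor of a (possibly offset) sinusoidal
#' pressure time series via the FFT-based analytic signal, demodulated at
#' the drive frequency and averaged over an integer number of cycles.  Used
#' to validate frequency-domain solvers against time-domain references.
#'
#' @param p numeric vector of pressure samples.
#' @param fs sampling rate in Hz.
#' @param f drive frequency in Hz.
#' @return a single complex amplitude; `Mod()` of it is the sine amplitude.
#' @export
steady_state_phasor <- function(p, fs, f) {
  n_cycles <- length(p) / fs * f
  if (n_cycles < 2) stop("insufficient data: time series must cover >= 2 cycles")
  # trim to an integer number of cycles so the single-frequency component
  # is periodic in the analysis window
  n <- round(floor(n_cycles) * fs / f)
  p <- p[seq_len(n)]
  p <- p - mean(p)
  if (all(p == 0)) return(0 + 0i)
  # analytic signal: zero the negative-frequency half of the spectrum
  P <- stats::fft(p)
  h <- numeric(n); h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 } else h[2:((n + 1) / 2)] <- 2
  z <- stats::fft(P * h, inverse = TRUE) / n
  t <- (seq_len(n) - 1) / fs
  mean(z * exp(-2i * pi * f * t))
}

#' Time-averaged intensity map for a drive vector
#'
#' I(G) = |h(G)^H w|^2 / (2 rho(G) c(G)) in W/cm^2, identical to the
#' quadratic form w^H Q(G) w.
#'
#' @param w complex drive vector of length M.
#' @param field a `transfer_field`.
#' @return nx x ny intensity matrix of class `intensity_map` (W/cm^2).
#' @export
intensity_map <- function(w, field) {
  if (length(w) != nrow(field$H)) stop("drive vector length does not match element count")
  p <- as.vector(crossprod(Conj(field$H), w))   # h(G)^H w per cell
  I <- matrix(pressure_to_intensity(p, as.vector(field$rhoc)),
              field$grid$nx, field$grid$ny)
  structure(I, class = c("intensity_map", "matrix"), grid = field$grid)
}

#' Per-point intensity quadratic forms Q(G), factored
#'
#' Q(G) = h(G) h(G)^H / (2 rho(G) c(G)) is Hermitian, positive
#' semi-definite and rank <= 1 for every G; it is stored in factored form
#' (transfer columns plus per-point scalars) and never materialized unless
#' requested via [q_matrix()].  Units are chosen so that
#' `w^H Q(G) w` is W/cm^2.
#'
#' @param field a `transfer_field`.
#' @param points integer vector of linear cell indices (default: all cells).
#' @return object of class `q_field` with elements `h` (M x length(points))
#'   and `scale` (= 1 / (2 rho c) per point, W/cm^2 per Pa^2).
#' @export
build_q <- function(field, points = NULL) {
  N <- ncol(field$H)
  if (is.null(points)) points <- seq_len(N)
  if (any(points < 1 | points > N)) stop("points outside the grid")
  structure(list(h = field$H[, points, drop = FALSE],
                 scale = 1 / (2 * as.vector(field$rhoc)[points]) / 1e4,
                 points = points),
            class = "q_field")
}

#' Materialize one Q(G) matrix
#' @param q a [build_q()] object.
#' @param i index into the stored point set.
#' @export
q_matrix <- function(q, i) {
  h <- q$h[, i]
  q$scale[i] * (h %*% t(Conj(h)))
}

# quadratic forms w^H Q(G) w for all stored points, vectorized
q_forms <- function(q, w) {
  a <- as.vector(crossprod(Conj(q$h), w))
  q$scale * Mod(a)^2
}
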