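# Off-target suppression benchmark.
#
# Phase-anchored surrogate of the classical "maximize target power while
# limiting power to all off-target brain regions" beamformer: maximize
# Re(h_t^H w) subject to ||w||^2 <= P and, for every capped control point
# i, I_i(w) <= cap * t where t is the achieved target intensity.  Cells
# inside a focal neighborhood (one wavelength by default, set in
# `beamform()`) are not capped: diffraction forces them to carry
# near-target intensity, so capping them leaves no feasible drive.
#
# Because the caps couple to t, the convex subproblem at fixed t (projected
# gradient with quadratic-penalty continuation on the normalized cap
# violations) is wrapped in a damped fixed-point iteration on t.  A cap the
# geometry cannot satisfy makes the fixed point collapse instead of
# settling; this is reported through the `infeasible` flag (best iterate
# returned) rather than as an error.
suppress_fit <- function(qs, P, cap, cap_set = NULL,
                         outer_iter = 30, inner_iter = 150,
                         lambda_stages = c(1, 10, 100, 1000)) {
  w_conj <- conjugate_beamformer(qs$h_t, P)
  if (!is.finite(cap)) {
    return(list(w = w_conj, trace = NULL, iterations = 0L,
                converged = TRUE, infeasible = FALSE))
  }
  if (cap <= 0) stop("cap must be positive")
  if (is.null(cap_set)) cap_set <- seq_len(ncol(qs$h))
  hc <- qs$h[, cap_set, drop = FALSE]
  sc <- qs$scale[cap_set]
  target_I <- function(w) qs$scale_t * Mod(sum(Conj(qs$h_t) * w))^2
  cap_I <- function(w) sc * Mod(as.vector(crossprod(Conj(hc), w)))^2
  ball <- function(w) { n <- sqrt(sum(Mod(w)^2)); if (n > sqrt(P)) w * sqrt(P) / n else w }
  ht_norm <- sqrt(sum(Mod(qs$h_t)^2))

  t_conj <- target_I(w_conj)
  w <- w_conj
  t <- t_conj
  total_iter <- 0L
  outer_converged <- FALSE
  best <- list(w = w_conj, viol = Inf, t = t_conj)
  for (out in seq_len(outer_iter)) {
    t_cap <- cap * t
    phi <- function(w, lambda) {
      v <- pmax(cap_I(w) / t_cap - 1, 0)
      -Re(sum(Conj(qs$h_t) * w)) / (ht_norm * sqrt(P)) + lambda * sum(v^2)
    }
    for (lambda in lambda_stages) {
      obj <- phi(w, lambda)
      gamma <- 0.1 * sqrt(P) / ht_norm
      for (it in seq_len(inner_iter)) {
        a <- as.vector(crossprod(Conj(hc), w))
        v <- pmax(sc * Mod(a)^2 / t_cap - 1, 0)
        g <- -qs$h_t / (ht_norm * sqrt(P)) +
          lambda * 4 * as.vector(hc %*% (v * sc * a)) / t_cap
        accepted <- FALSE
        for (bt in 0:40) {
          w_new <- ball(w - gamma * g)
          obj_new <- phi(w_new, lambda)
          if (obj_new <= obj + 1e-14) { accepted <- TRUE; break }
          gamma <- gamma / 2
        }
        if (!accepted) break
        step <- sqrt(sum(Mod(w_new - w)^2))
        w <- w_new; obj <- obj_new
        total_iter <- total_iter + 1L
        if (bt == 0) gamma <- gamma * 1.5
        if (step < 1e-9 * sqrt(P)) break
      }
    }
    t_new <- target_I(w)
    viol <- if (t_new > 0) max(cap_I(w) / (cap * t_new) - 1, 0) else Inf
    if (viol < best$viol - 1e-9 || (viol <= best$viol + 1e-9 && t_new > best$t))
      best <- list(w = w, viol = viol, t = t_new)
    if (abs(t_new - t) <= 1e-4 * max(t, .Machine$double.eps)) {
      t <- t_new; outer_converged <- TRUE; break
    }
    if (t_new < 1e-3 * t_conj) { t <- t_new; break }  # collapsing: infeasible caps
    t <- 0.5 * t + 0.5 * t_new
  }
  infeasible <- t < 1e-3 * t_conj || best$viol > 0.05
  list(w = best$w, trace = NULL, iterations = total_iter,
       converged = outer_converged, infeasible = infeasible)
}
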