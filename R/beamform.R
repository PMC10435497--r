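#' Conjugate (time-reversal) drive vector
#'
#' w = sqrt(P) h(G*) / ||h(G*)||: the principal eigenvector of the rank-1
#' target quadratic form, hence the exact maximizer of the target intensity
#' w^H Q(G*) w on the power sphere ||w||^2 = P.
#'
#' @param h_target complex transfer column at the target cell.
#' @param P total drive power.
#' @export
conjugate_beamformer <- function(h_target, P = 1) {
  nrm <- sqrt(sum(Mod(h_target)^2))
  if (nrm == 0) stop("degenerate target: zero transfer column")
  sqrt(P) * h_target / nrm
}

#' Projection onto the power sphere
#'
#' Normalizes a drive vector to the transducer power constraint:
#' returns sqrt(P) w / ||w||_2.
#'
#' @param w nonzero complex vector.
#' @param P total power.
#' @export
project_power <- function(w, P = 1) {
  nrm <- sqrt(sum(Mod(w)^2))
  if (nrm == 0) stop("projection error: zero vector")
  sqrt(P) * w / nrm
}

# internal container for the off-target quadratic forms
# w^H Q*(G) w = scale_G |h_G^H w|^2 - ratio * scale_t |h_t^H w|^2
qstar_field <- function(q_control, h_target, scale_target, ratio) {
  structure(list(h = q_control$h, scale = q_control$scale,
                 h_t = h_target, scale_t = scale_target, ratio = ratio),
            class = "qstar_field")
}

# vectorized w^H Q*(G) w over all control points
qstar_forms <- function(w, qs) {
  a <- as.vector(crossprod(Conj(qs$h), w))
  at <- sum(Conj(qs$h_t) * w)
  qs$scale * Mod(a)^2 - qs$ratio * qs$scale_t * Mod(at)^2
}

# hard step-function count of activated control points (chi(0) = 1)
hard_count <- function(w, qs) sum(qstar_forms(w, qs) >= 0)

# connected component of a logical mask containing `start`, 4-neighborhood,
# optionally dilated by `dilate` cells
flood_fill <- function(mask, start, dilate = 0L) {
  nx <- nrow(mask); ny <- ncol(mask)
  comp <- matrix(FALSE, nx, ny)
  if (!mask[start[1], start[2]]) { comp[start[1], start[2]] <- TRUE; return(comp) }
  comp[start[1], start[2]] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nx, ]
    grown[-nx, ] <- grown[-nx, ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -ny]
    grown[, -ny] <- grown[, -ny] | comp[, -1]
    grown <- grown & mask
    grown <- grown | comp
    if (identical(grown, comp)) break
    comp <- grown
  }
  for (d in seq_len(dilate)) {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nx, ]
    grown[-nx, ] <- grown[-nx, ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -ny]
    grown[, -ny] <- grown[, -ny] | comp[, -1]
    comp <- grown
  }
  comp
}

#' Fit a beam focusing drive vector
#'
#' The central fitting function: computes a complex drive vector w for the
#' given transfer field, target and off-target control region using one of
#' three methods.  `"conjugate"` maximizes target intensity
#' (time-reversal).  `"suppress"` maximizes target intensity while capping
#' every off-target intensity at `cap` times the achieved target intensity
#' (a phase-anchored convex surrogate of the classical off-target power
#' suppression benchmark).  `"corb"` minimizes the count of off-target
#' cells whose intensity reaches `ratio` times the target intensity, on
#' the fixed-power sphere, via logistic smoothing with continuation and
#' gradient projection, initialized at the conjugate drive.
#'
#' @param field a `transfer_field`.
#' @param masks [region_masks()]; the control set is every brain cell
#'   except the target (optionally subsampled by `control_stride`).
#' @param method `"conjugate"`, `"suppress"` or `"corb"`.
#' @param ratio I_l / I_h in (0, 1], the intensity ratio defining an
#'   activated off-target cell.
#' @param power total drive power P (the fit lives on ||w||^2 = P).
#' @param cap off-target intensity cap for the suppression benchmark,
#'   relative to the achieved target intensity (default `ratio`).
#' @param control a [corb_control()] list of optimizer settings.
#' @param control_stride subsampling stride of the control set (1 = all
#'   off-target brain cells).
#' @param suppress_exclude_mm radius of the focal neighborhood left
#'   uncapped by the suppression benchmark.  By default (NULL) the
#'   uncapped region is instead the conjugate beam's connected focal lobe
#'   above `cap` times its target intensity: diffraction forces that lobe
#'   to carry near-target intensity, so capping it leaves no feasible
#'   drive and the caps act on sidelobes.
#' @return an object of class `lifu_beamform`.
#' @export
beamform <- function(field, masks, method = c("conjugate", "suppress", "corb"),
                     ratio = 0.6, power = 1, cap = ratio,
                     control = corb_control(), control_stride = 1L,
                     suppress_exclude_mm = NULL) {
  method <- match.arg(method)
  if (ratio <= 0 || ratio > 1) stop("ratio must be in (0, 1]")
  grid <- field$grid
  tidx <- cell_index(grid, masks$target_cell[1], masks$target_cell[2])
  ctrl_idx <- setdiff(which(masks$brain_mask), tidx)
  if (control_stride > 1L)
    ctrl_idx <- ctrl_idx[seq(1L, length(ctrl_idx), by = as.integer(control_stride))]
  if (length(ctrl_idx) == 0) stop("empty control set")
  qc <- build_q(field, ctrl_idx)
  h_t <- field$H[, tidx]
  scale_t <- 1 / (2 * as.vector(field$rhoc)[tidx]) / 1e4
  qs <- qstar_field(qc, h_t, scale_t, ratio)

  cap_set <- NULL
  if (method == "suppress") {
    if (is.null(suppress_exclude_mm)) {
      # exclude the conjugate beam's connected focal lobe: diffraction forces
      # it to carry near-target intensity, so capping it leaves no feasible
      # drive; the caps then act on sidelobes (classical constrained
      # pattern synthesis)
      w_c <- conjugate_beamformer(h_t, power)
      I_c <- intensity_map(w_c, field)
      I_t <- I_c[masks$target_cell[1], masks$target_cell[2]]
      lobe <- flood_fill(unclass(I_c) >= cap * I_t, masks$target_cell, dilate = 1L)
      cap_set <- which(!lobe[ctrl_idx])
    } else {
      co <- grid_coords(grid)
      txy <- c(co$x[masks$target_cell[1]], co$y[masks$target_cell[2]])
      px <- as.vector(co$X)[ctrl_idx]; py <- as.vector(co$Y)[ctrl_idx]
      cap_set <- which(sqrt((px - txy[1])^2 + (py - txy[2])^2) > suppress_exclude_mm)
    }
    if (length(cap_set) == 0) stop("suppression exclusion covers every control point")
  }

  fit <- switch(method,
    conjugate = list(w = conjugate_beamformer(h_t, power), trace = NULL,
                     iterations = 0L, converged = TRUE, infeasible = FALSE),
    suppress  = suppress_fit(qs, power, cap, cap_set = cap_set),
    corb      = corb_fit(qs, power, control))

  at <- sum(Conj(h_t) * fit$w)
  out <- structure(list(
    w = fit$w, method = method, P = power, ratio = ratio,
    target_cell = masks$target_cell, target_index = tidx,
    target_intensity = scale_t * Mod(at)^2,
    n_control = length(ctrl_idx), control_index = ctrl_idx,
    hard_count = hard_count(fit$w, qs),
    objective_trace = fit$trace, objective_stage = fit$trace_stage,
    iterations = fit$iterations,
    converged = fit$converged, infeasible = fit$infeasible,
    cell_area_mm2 = cell_area(grid), field = field, masks = masks),
    class = "lifu_beamform")
  out
}

#' CORB optimizer settings
#'
#' @param mu0 initial logistic sharpness; default scales so the largest
#'   |mu * w^H Q* w| at the conjugate initialization is about 1.
#' @param mu_stages,mu_factor continuation schedule: `mu_stages` values
#'   multiplying mu0 by `mu_factor` each stage.
#' @param gamma initial step size (default chosen from the first gradient).
#' @param backtrack halve the step until the smoothed objective does not
#'   increase (keeps the per-stage trace monotone).
#' @param beta stop when the iterate displacement norm falls below beta.
#' @param max_iter iteration cap per continuation stage.
#' @export
corb_control <- function(mu0 = NULL, mu_stages = 4, mu_factor = 10,
                         gamma = NULL, backtrack = TRUE,
                         beta = 1e-6, max_iter = 2000) {
  stopifnot(mu_stages >= 1, mu_factor > 1, beta > 0, max_iter >= 1)
  list(mu0 = mu0, mu_stages = mu_stages, mu_factor = mu_factor,
       gamma = gamma, backtrack = backtrack, beta = beta, max_iter = max_iter)
}

#' Smoothed off-target activation objective
#'
#' The logistic relaxation of the activated-cell count:
#' sum over control points of (1 + exp(-mu w^H Q*(G) w))^{-1}, evaluated
#' through the factored rank <= 2 forms (no M x M matrices).
#'
#' @param w complex drive vector.
#' @param qs a `qstar_field` (internal; see [beamform()]).
#' @param mu logistic sharpness (> 0).
#' @export
logistic_objective <- function(w, qs, mu) {
  if (mu <= 0) stop("mu must be positive")
  sum(stats::plogis(mu * qstar_forms(w, qs)))
}

#' Gradient of the smoothed objective
#'
#' Returns mu * D_mu * w where D_mu is the logistic-weighted sum of the
#' Q*(G) matrices; computed in factored form.  The directional derivative
#' of [logistic_objective()] along a perturbation d equals
#' 2 Re(d^H g) for the returned g.
#'
#' @inheritParams logistic_objective
#' @export
corb_gradient <- function(w, qs, mu) {
  f <- qstar_forms(w, qs)
  sig <- stats::plogis(mu * f)
  s <- sig * (1 - sig)                      # logistic derivative, overflow-safe
  a <- as.vector(crossprod(Conj(qs$h), w))
  at <- sum(Conj(qs$h_t) * w)
  Dw <- as.vector(qs$h %*% (s * qs$scale * a)) -
    qs$ratio * qs$scale_t * at * sum(s) * qs$h_t
  mu * Dw
}

corb_fit <- function(qs, P, control = corb_control()) {
  w <- conjugate_beamformer(qs$h_t, P)
  f0 <- qstar_forms(w, qs)
  mu <- control$mu0
  if (is.null(mu)) mu <- 1 / max(max(abs(f0)), .Machine$double.eps)
  trace <- numeric(0)
  trace_stage <- integer(0)
  total_iter <- 0L
  converged <- TRUE
  for (stage in seq_len(control$mu_stages)) {
    J <- logistic_objective(w, qs, mu)
    g <- corb_gradient(w, qs, mu)
    gamma <- control$gamma
    if (is.null(gamma))
      gamma <- 0.1 * sqrt(P) / max(sqrt(sum(Mod(g)^2)), .Machine$double.eps)
    stage_converged <- FALSE
    for (it in seq_len(control$max_iter)) {
      g <- corb_gradient(w, qs, mu)
      gnorm <- sqrt(sum(Mod(g)^2))
      if (gnorm < .Machine$double.eps) { stage_converged <- TRUE; break }
      accepted <- FALSE
      for (bt in 0:40) {
        w_new <- project_power(w - gamma * g, P)
        J_new <- logistic_objective(w_new, qs, mu)
        if (!control$backtrack || J_new <= J + 1e-12) { accepted <- TRUE; break }
        gamma <- gamma / 2
      }
      if (!accepted) { stage_converged <- TRUE; break }  # numerically stationary
      step <- sqrt(sum(Mod(w_new - w)^2))
      w <- w_new; J <- J_new
      trace <- c(trace, J)
      trace_stage <- c(trace_stage, stage)
      total_iter <- total_iter + 1L
      if (bt == 0) gamma <- gamma * 1.5
      if (step < control$beta) { stage_converged <- TRUE; break }
    }
    if (!stage_converged) converged <- FALSE
    mu <- mu * control$mu_factor
  }
  list(w = w, trace = trace, trace_stage = trace_stage,
       iterations = total_iter, converged = converged, infeasible = FALSE)
}
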