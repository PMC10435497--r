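test_that("conjugate beamforming is phase conjugation and maximizes target intensity", {
  # M = 1: the whole power budget on the single element
  w1 <- conjugate_beamformer(2 - 3i, P = 4)
  expect_equal(Mod(w1), 2, tolerance = 1e-12)
  # equal-magnitude transfer: drive phases equal the transfer phases
  th <- c(0.3, -1.2, 2.5)
  h <- exp(1i * th)
  wc <- conjugate_beamformer(h, P = 1)
  expect_equal(Arg(wc), th, tolerance = 1e-12)
  # Monte-Carlo optimality and the principal-eigenvalue identity
  set.seed(31)
  for (rep in 1:5) {
    M <- sample(2:6, 1)
    h_t <- random_drive(M)
    scale_t <- 1 / (2 * 1.5e6) / 1e4
    wc <- conjugate_beamformer(h_t, P = 1)
    I_conj <- scale_t * Mod(sum(Conj(h_t) * wc))^2
    expect_equal(I_conj, scale_t * sum(Mod(h_t)^2), tolerance = 1e-10)
    W <- matrix(complex(real = rnorm(M * 2e4), imaginary = rnorm(M * 2e4)), M)
    W <- sweep(W, 2, sqrt(colSums(Mod(W)^2)), "/")
    I_rand <- scale_t * Mod(crossprod(Conj(h_t), W))^2
    expect_true(all(I_rand <= I_conj + 1e-18))
  }
  expect_error(conjugate_beamformer(c(0i, 0i)), "degenerate")
})

test_that("power projection is exact, idempotent and direction-preserving", {
  set.seed(32)
  w <- random_drive(6)
  pw <- project_power(w, P = 2.5)
  expect_equal(sum(Mod(pw)^2), 2.5, tolerance = 1e-12)
  expect_equal(project_power(pw, P = 2.5), pw, tolerance = 1e-12)
  expect_equal(Arg(pw), Arg(w), tolerance = 1e-12)
  expect_error(project_power(rep(0i, 3)), "zero")
})

test_that("logistic objective matches its dense-matrix definition", {
  set.seed(33)
  for (rep in 1:5) {
    qs <- random_qstar(M = 4, n_ctrl = 7, seed = 330 + rep)
    w <- random_drive(4) * 3e5
    mu <- 10^runif(1, -2, 2) / max(abs(corbeam:::qstar_forms(w, qs)))
    # dense oracle: materialize every Q*(G) and sum the logistic terms
    Qt <- qs$scale_t * (qs$h_t %*% t(Conj(qs$h_t)))
    dense <- sum(vapply(seq_len(7), function(g) {
      Qg <- qs$scale[g] * (qs$h[, g] %*% t(Conj(qs$h[, g]))) - qs$ratio * Qt
      x <- Re(t(Conj(w)) %*% Qg %*% w)[1, 1]
      1 / (1 + exp(-mu * x))
    }, numeric(1)))
    expect_equal(logistic_objective(w, qs, mu), dense, tolerance = 1e-10)
  }
  qs <- random_qstar(M = 3, n_ctrl = 10, seed = 3)
  expect_equal(logistic_objective(rep(0i, 3), qs, mu = 1), 5, tolerance = 1e-12)
  # step-function limit: strictly negative forms vanish as mu grows
  w <- conjugate_beamformer(qs$h_t)
  f <- corbeam:::qstar_forms(w, qs)
  qs_neg <- qs; qs_neg$ratio <- qs$ratio * 1e6   # push every form negative
  stopifnot(all(corbeam:::qstar_forms(w, qs_neg) < 0))
  expect_lt(logistic_objective(w, qs_neg, mu = 1e12 / max(abs(f))), 1e-8)
  expect_error(logistic_objective(w, qs, mu = -1), "positive")
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(34)
  for (rep in 1:10) {
    M <- sample(2:5, 1); n_ctrl <- sample(3:8, 1)
    qs <- random_qstar(M, n_ctrl, seed = 340 + rep)
    w <- random_drive(M) * 3e5
    mu <- 1 / max(abs(corbeam:::qstar_forms(w, qs)))
    g <- corb_gradient(w, qs, mu)
    # w^H (mu D w) must be real (Hermitian D)
    expect_lt(abs(Im(sum(Conj(w) * g))) / max(abs(g)), 1e-10)
    for (d_rep in 1:3) {
      d <- random_drive(M); d <- d / sqrt(sum(Mod(d)^2))
      eps <- 1e-4 * sqrt(sum(Mod(w)^2))
      fd <- (logistic_objective(w + eps * d, qs, mu) -
             logistic_objective(w - eps * d, qs, mu)) / (2 * eps)
      an <- 2 * Re(sum(Conj(d) * g))
      expect_lt(abs(fd - an) / max(abs(fd), 1e-12), 1e-5)
    }
  }
})

test_that("CORB keeps the power constraint and a monotone objective trace", {
  s <- homog_setup(nx = 48, n_elem = 6)
  fit <- beamform(s$fld, s$masks, "corb", power = 2)
  expect_equal(sum(Mod(fit$w)^2), 2, tolerance = 1e-10)
  # within each continuation stage the smoothed objective never increases
  # (backtracking line search); mu jumps between stages reset the scale
  for (st in unique(fit$objective_stage)) {
    tr <- fit$objective_trace[fit$objective_stage == st]
    if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-9))
  }
})

test_that("CORB with a single element returns the initialization up to phase", {
  s <- homog_setup(nx = 48, n_elem = 1)
  fit <- beamform(s$fld, s$masks, "corb")
  expect_equal(Mod(fit$w), 1, tolerance = 1e-10)
  tidx <- fit$target_index
  wc <- conjugate_beamformer(s$fld$H[, tidx])
  expect_equal(Mod(sum(Conj(wc) * fit$w)), 1, tolerance = 1e-10)
})

test_that("CORB leaves an already-clean conjugate beam at zero activation", {
  # a strong target column and negligible off-target transfer
  set.seed(36)
  h_t <- random_drive(4)
  h <- matrix(random_drive(4 * 5), 4, 5) * 1e-3
  scale <- rep(1 / (2 * 1.5e6) / 1e4, 5)
  qs <- corbeam:::qstar_field(list(h = h, scale = scale), h_t, scale[1], 0.6)
  w0 <- conjugate_beamformer(h_t)
  expect_equal(corbeam:::hard_count(w0, qs), 0L)
  fit <- corbeam:::corb_fit(qs, 1, corb_control())
  expect_equal(corbeam:::hard_count(fit$w, qs), 0L)
})

test_that("CORB finds the exhaustive global optimum on small instances", {
  matches <- 0; max_gap <- 0
  for (inst in 1:10) {
    n_ctrl <- sample(2:6, 1)
    qs <- random_qstar(2, n_ctrl, seed = 3700 + inst)
    fit <- corbeam:::corb_fit(qs, 1, corb_control())
    gap <- corbeam:::hard_count(fit$w, qs) - exhaustive_min_count(qs)
    if (gap <= 0) matches <- matches + 1
    max_gap <- max(max_gap, gap)
  }
  expect_gte(matches, 9)
  expect_lte(max_gap, 1)
})

test_that("suppression recovers the conjugate drive when caps are infinite", {
  qs <- random_qstar(5, 8, seed = 38)
  fit <- corbeam:::suppress_fit(qs, P = 1, cap = Inf)
  wc <- conjugate_beamformer(qs$h_t, 1)
  expect_lt(max(Mod(fit$w - wc)), 1e-6)
  expect_false(fit$infeasible)
})

test_that("suppression flags a self-contradictory colocated cap as infeasible", {
  set.seed(39)
  h_t <- random_drive(4)
  qs <- corbeam:::qstar_field(list(h = matrix(h_t, 4, 1),
                                   scale = 1 / (2 * 1.5e6) / 1e4),
                              h_t, 1 / (2 * 1.5e6) / 1e4, 0.6)
  fit <- corbeam:::suppress_fit(qs, P = 1, cap = 0.5)
  expect_true(fit$infeasible)
})

test_that("suppression approaches the exhaustive optimum on a small instance", {
  set.seed(40)
  M <- 3; cap <- 0.4
  h <- matrix(random_drive(M * 2), M, 2)
  h_t <- random_drive(M)
  scale <- rep(1 / (2 * 1.5e6) / 1e4, 2)
  qs <- corbeam:::qstar_field(list(h = h, scale = scale), h_t, scale[1], 0.6)
  fit <- corbeam:::suppress_fit(qs, P = 1, cap = cap)
  t_fit <- qs$scale_t * Mod(sum(Conj(h_t) * fit$w))^2
  # brute force over amplitude angles and phases on the power sphere
  th1 <- seq(0, pi / 2, length.out = 40)
  th2 <- seq(0, pi / 2, length.out = 40)
  ph <- seq(0, 2 * pi, length.out = 60 + 1)[-(60 + 1)]
  grid <- expand.grid(t1 = th1, t2 = th2, p2 = ph, p3 = ph)
  W <- rbind(cos(grid$t1),
             sin(grid$t1) * cos(grid$t2) * exp(1i * grid$p2),
             sin(grid$t1) * sin(grid$t2) * exp(1i * grid$p3))
  It <- qs$scale_t * Mod(crossprod(Conj(h_t), W))[1, ]^2
  I1 <- qs$scale[1] * Mod(crossprod(Conj(h[, 1]), W))[1, ]^2
  I2 <- qs$scale[2] * Mod(crossprod(Conj(h[, 2]), W))[1, ]^2
  feas <- I1 <= cap * It & I2 <= cap * It
  t_best <- max(It[feas])
  expect_gt(t_fit, 0.9 * t_best)
  expect_false(fit$infeasible)
})

test_that("rescaling to the excitation threshold preserves the activated set", {
  # scaling equivalence between the quadratic-form counts and direct
  # threshold counting at I(G*) = I_h
  s <- homog_setup(nx = 48)
  for (method in c("conjugate", "suppress", "corb")) {
    fit <- beamform(s$fld, s$masks, method, ratio = 0.6)
    qs <- corbeam:::qstar_field(build_q(s$fld, fit$control_index),
                                s$fld$H[, fit$target_index],
                                1 / (2 * as.vector(s$fld$rhoc)[fit$target_index]) / 1e4,
                                0.6)
    act_forms <- corbeam:::qstar_forms(fit$w, qs) >= 0
    I_h <- 0.05
    w_scaled <- scale_to_target(fit, I_h)
    I <- intensity_map(w_scaled, s$fld)
    act_direct <- as.vector(unclass(I))[fit$control_index] >= 0.6 * I_h
    expect_identical(act_forms, act_direct)
  }
})

test_that("CORB never exceeds the conjugate activation on suite phantoms", {
  for (seed_angle in c(90, 200)) {
    s <- homog_setup(nx = 48, n_elem = 8, centre_angle_deg = seed_angle)
    fc <- beamform(s$fld, s$masks, "conjugate")
    fo <- beamform(s$fld, s$masks, "corb")
    expect_lte(fo$hard_count, fc$hard_count)
  }
})
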