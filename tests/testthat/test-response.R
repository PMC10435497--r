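test_that("spike counts are zero below the excitation thresholds", {
  cw <- stimulus_protocol("continuous", duration_ms = 100)
  pw <- stimulus_protocol("pulsed", duration_ms = 100, prf_hz = 1000,
                          duty_cycle = 0.36)
  m_cw <- neuron_response_model(cw, kind = "spike_curve")
  m_pw <- neuron_response_model(pw, kind = "spike_curve")
  # default thresholds sit near the intramembrane-cavitation simulation values
  expect_equal(m_cw$I_h, 0.05, tolerance = 1e-12)
  expect_lt(abs(m_pw$I_h - 0.45), 0.01)
  expect_equal(spike_count(0.01, cw, m_cw), 0L)
  expect_equal(spike_count(0.2, pw, m_pw), 0L)
  expect_equal(spike_count(0, cw, m_cw), 0L)
  expect_equal(spike_count(0, pw, m_pw), 0L)
  expect_gt(spike_count(0.06, cw, m_cw), 0L)
  expect_error(spike_count(-1, cw, m_cw), "non-negative")
})

test_that("continuous-wave counts are non-decreasing in intensity and duration", {
  Is <- seq(0, 2, by = 0.01)
  for (dur in c(50, 100, 200)) {
    pr <- stimulus_protocol("continuous", duration_ms = dur)
    mdl <- neuron_response_model(pr, kind = "spike_curve")
    counts <- spike_count(Is, pr, mdl)
    expect_true(all(diff(counts) >= 0))
  }
  pr1 <- stimulus_protocol("continuous", 50)
  pr2 <- stimulus_protocol("continuous", 200)
  m1 <- neuron_response_model(pr1, kind = "spike_curve")
  m2 <- neuron_response_model(pr2, kind = "spike_curve")
  # longer stimulation: lower threshold and at least as many spikes
  expect_lt(m2$I_h, m1$I_h)
  expect_true(all(spike_count(Is, pr2, m2) >= spike_count(Is, pr1, m1)))
})

test_that("pulsed counts grow more slowly and can dip non-monotonically", {
  pw <- stimulus_protocol("pulsed", duration_ms = 100, prf_hz = 1000,
                          duty_cycle = 0.36)
  cw <- stimulus_protocol("continuous", duration_ms = 100)
  m_pw <- neuron_response_model(pw, kind = "spike_curve", dip_amplitude = 2)
  m_cw <- neuron_response_model(cw, kind = "spike_curve")
  # compare counts at matched multiples of each threshold
  mult <- seq(1, 8, by = 0.05)
  c_pw <- spike_count(mult * m_pw$I_h, pw, m_pw)
  c_cw <- spike_count(mult * m_cw$I_h, cw, m_cw)
  expect_true(all(c_pw <= c_cw))
  expect_true(any(diff(c_pw) < 0))          # configurable dip
  expect_true(all(c_pw[mult >= 1] >= 1))    # never extinguishes above threshold
  m_flat <- neuron_response_model(pw, kind = "spike_curve", dip_amplitude = 0)
  expect_true(all(diff(spike_count(mult * m_flat$I_h, pw, m_flat)) >= 0))
})

test_that("pulse duration derives as duty over PRF", {
  expect_identical(derive_pulse_duration(1000, 0.36), 0.36)
  expect_identical(derive_pulse_duration(500, 0.5), 1.0)
  expect_equal(derive_pulse_duration(250, 1), 1 / 250 * 1e3)
  expect_error(derive_pulse_duration(-1, 0.5), "prf")
  expect_error(derive_pulse_duration(1000, 1.5), "duty")
  pr <- stimulus_protocol("pulsed", 100, prf_hz = 1000, duty_cycle = 0.36)
  expect_identical(pr$pulse_ms, 0.36)
})

test_that("spike maps match pointwise evaluation and respect the brain mask", {
  g <- grid2d(24, 24, 0.5)
  bm <- matrix(FALSE, 24, 24); bm[6:18, 6:18] <- TRUE
  masks <- region_masks(bm, matrix(FALSE, 24, 24), c(12, 12), g)
  pr <- stimulus_protocol("continuous", 100)
  mdl <- neuron_response_model(pr, kind = "spike_curve")
  set.seed(21)
  I <- matrix(runif(24 * 24, 0, 0.3), 24, 24)
  sm <- spike_map(I, masks, pr, mdl)
  oracle <- matrix(0L, 24, 24)
  for (i in 1:24) for (j in 1:24)
    if (bm[i, j]) oracle[i, j] <- spike_count(I[i, j], pr, mdl)
  expect_equal(unclass(sm), oracle, ignore_attr = TRUE)
  expect_true(all(sm[!bm] == 0))
  expect_true(all(spike_map(matrix(0, 24, 24), masks, pr, mdl) == 0))
  I2 <- matrix(0, 24, 24); I2[12, 12] <- 1
  sm2 <- spike_map(I2, masks, pr, mdl)
  expect_true(sm2[12, 12] > 0 && sum(sm2 > 0) == 1)
})

test_that("the OTAA counts off-target cells above I_l with chi(0) = 1", {
  g <- grid2d(8, 8, 0.5)
  bm <- matrix(TRUE, 8, 8)
  masks <- region_masks(bm, matrix(FALSE, 8, 8), c(4, 4), g)
  pr <- stimulus_protocol("continuous", 100)
  mdl <- neuron_response_model(pr, I_h = 0.05, I_l = 0.03)
  I <- matrix(0, 8, 8)
  I[4, 4] <- 0.06                       # target excited
  I[c(1, 10, 20)] <- c(0.03, 0.031, 10) # 3 off-target cells, one exactly at I_l
  res <- otaa(I, masks, mdl)
  expect_equal(res$n_points, 3L)
  expect_equal(res$area_mm2, 3 * 0.25)
  expect_true(res$target_excited)
  # target below I_h: flagged regardless of the off-target field
  I[4, 4] <- 0.049
  expect_false(otaa(I, masks, mdl)$target_excited)
  # clean beam: area 0 with the target excited
  I0 <- matrix(0, 8, 8); I0[4, 4] <- 1
  r0 <- otaa(I0, masks, mdl)
  expect_equal(r0$n_points, 0L)
  expect_true(r0$target_excited)
})

test_that("OTAA reports supportive exposure separately and honors exclusion radius", {
  g <- grid2d(16, 16, 0.5)
  bm <- matrix(FALSE, 16, 16); bm[5:12, 5:12] <- TRUE
  sm <- matrix(FALSE, 16, 16); sm[1:2, ] <- TRUE
  masks <- region_masks(bm, sm, c(8, 8), g)
  mdl <- neuron_response_model(stimulus_protocol("continuous", 100),
                               I_h = 0.05, I_l = 0.03)
  I <- matrix(0, 16, 16); I[8, 8] <- 1; I[1, 1:4] <- 1; I[8, 9] <- 0.04
  res <- otaa(I, masks, mdl)
  expect_equal(res$supportive_exposure_mm2, 4 * 0.25)
  expect_equal(res$n_points, 1L)        # supportive cells are not OTAA
  res2 <- otaa(I, masks, mdl, exclusion_radius_mm = 0.6)
  expect_equal(res2$n_points, 0L)       # neighbor inside the exclusion disc
})

test_that("OTAA is invariant to global drive phase and monotone in the field", {
  s <- homog_setup(nx = 48)
  set.seed(22)
  w <- random_drive(nrow(s$fld$H))
  mdl <- neuron_response_model(stimulus_protocol("continuous", 100),
                               I_h = 1e-10, I_l = 6e-11)
  I1 <- intensity_map(w, s$fld)
  I2 <- intensity_map(exp(1.2i) * w, s$fld)
  expect_equal(as.vector(I1), as.vector(I2), tolerance = 1e-12)
  expect_equal(otaa(I1, s$masks, mdl)$n_points, otaa(I2, s$masks, mdl)$n_points)
  # pointwise-larger field cannot shrink the OTAA
  expect_gte(otaa(I1 * 1.7, s$masks, mdl)$n_points, otaa(I1, s$masks, mdl)$n_points)
})

test_that("OTAA sweeps are consistent with direct evaluation and monotone", {
  s <- homog_setup(nx = 48)
  tc <- s$masks$target_cell
  ti <- corbeam:::cell_index(s$grid, tc[1], tc[2])
  w <- conjugate_beamformer(s$fld$H[, ti])
  pr <- stimulus_protocol("continuous", 100)
  sw <- otaa_sweep(s$fld, w, s$masks, pr, "intensity",
                   values = c(0.05, 0.078, 0.12, 0.3))
  expect_true(all(diff(sw$area_mm2) >= 0))
  # singleton sweep equals a direct otaa call at the same scaling
  one <- otaa_sweep(s$fld, w, s$masks, pr, "intensity", values = 0.078)
  mdl <- neuron_response_model(pr, ratio = 0.6)
  I <- intensity_map(w, s$fld)
  I <- I * (0.078 / I[tc[1], tc[2]])
  expect_equal(one$area_mm2, otaa(I, s$masks, mdl)$area_mm2)
  expect_error(otaa_sweep(s$fld, w, s$masks, pr, "intensity", values = numeric(0)),
               "non-empty")
  expect_error(otaa_sweep(s$fld, w, s$masks, pr, "intensity", values = c(2, 1)),
               "sorted")
})
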