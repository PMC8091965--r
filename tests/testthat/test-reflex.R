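p <- default_p
geom <- default_geom

test_that("delay line interpolates linearly and handles cold starts", {
  dl <- delay_line(4)
  expect_identical(read_delay(dl, 0.5), 0) # empty
  for (i in 0:9) push_delay(dl, i * 0.01, i / 10)
  expect_identical(read_delay(dl, -0.01), 0) # before first sample
  expect_equal(read_delay(dl, 0.035), 0.35) # midpoint interpolation
  expect_equal(read_delay(dl, 0.05), 0.5)
  expect_equal(read_delay(dl, 1), 0.9) # past the end: last value
  expect_error(push_delay(dl, 0.05, 1), "increase")
})

test_that("stimulation: gain, clamp and exact delay of a force step", {
  rp <- reflex_params(gain = 1.2, delay = 0.010, prestim = 0.01)
  dl <- delay_line()
  # force history: 0 until t0 = 0.1 s, then 0.5
  for (i in 0:299) push_delay(dl, i * 1e-3, if (i * 1e-3 < 0.1) 0 else 0.5)
  expect_equal(stimulation(dl, 0.109, rp), 0.01) # just before t0 + delay
  expect_equal(stimulation(dl, 0.110, rp), 0.61) # exactly at t0 + delay
  expect_equal(stimulation(dl, 0.2, rp), 0.61)

  # zero gain ignores any history
  rp0 <- reflex_params(gain = 0, prestim = 0.02)
  expect_equal(stimulation(dl, 0.2, rp0), 0.02)

  # upper clamp
  rph <- reflex_params(gain = 2.0, prestim = 0.01)
  dl2 <- delay_line()
  for (i in 0:99) push_delay(dl2, i * 1e-3, 1)
  expect_identical(stimulation(dl2, 0.09, rph), 1)

  # cold start returns prestim
  expect_equal(stimulation(delay_line(), 0, rp), rp$prestim)
})

test_that("exo_torque: arithmetic, psi-linearity and swing slack", {
  rp <- reflex_params(psi = 0.5)
  expect_equal(exo_torque(1000, 0, rp, geom, "stance"), 25)
  expect_identical(exo_torque(1000, 0, reflex_params(psi = 0), geom, "stance"), 0)
  expect_identical(exo_torque(5000, 0.2, rp, geom, "swing"), 0)
  # halving psi halves torque exactly, at every force and angle
  f <- seq(0, 6000, length.out = 50)
  th <- seq(-0.3, 0.3, length.out = 50)
  t_full <- exo_torque(f, th, reflex_params(psi = 0.5), geom, "stance")
  t_half <- exo_torque(f, th, reflex_params(psi = 0.25), geom, "stance")
  expect_identical(t_half, t_full / 2)
})

test_that("controller reset: determinism, equilibrium hold, extreme angles", {
  rp <- reflex_params(gain = 1.2, delay = 0.01)
  # two resets produce bit-identical trajectories
  run1 <- run_playback(fixture_trial, rp)
  run2 <- run_playback(fixture_trial, rp)
  expect_identical(run1$f_mtu, run2$f_mtu)
  expect_identical(run1$torque, run2$torque)

  # zero-input hold from reset: stationary passive state
  ctrl <- controller_reset(rp, p, geom, theta0 = 0)
  tq <- numeric(300)
  for (i in 1:300) {
    tq[i] <- controller_step(ctrl, 0, "swing", 1e-3, rp, p, geom)$torque
  }
  expect_identical(tq, rep(0, 300)) # swing commands zero torque
  # and the internal state barely moves (equilibrium + prestim hold)
  expect_lt(abs(ctrl$l_ce - controller_reset(rp, p, geom, 0)$l_ce), 1e-6)

  # extreme dorsiflexion still yields a finite positive CE length
  ctrl_df <- controller_reset(rp, p, geom, theta0 = -0.5)
  expect_true(is.finite(ctrl_df$l_ce) && ctrl_df$l_ce > 0)
})

test_that("reflex delay is exact on the sample grid, including fractional delays", {
  rp <- reflex_params(gain = 1.5, delay = 0.017, prestim = 0.01)
  trial <- synth_gait(gait_spec(stance_fraction = 0.79), n_strides = 4)
  log <- run_playback(trial, rp)
  fn <- log$f_mtu / p$f_max
  s_impl <- (log$stim - rp$prestim) / rp$gain
  d <- rp$delay / 1e-3 # 17 samples
  idx <- which(log$phase == "stance")
  idx <- idx[idx > d + 1]
  expect_equal(s_impl[idx], fn[idx - d], tolerance = 1e-12)

  # fractional delay uses linear interpolation between samples
  rpf <- reflex_params(gain = 1.5, delay = 0.0175, prestim = 0.01)
  logf <- run_playback(trial, rpf)
  fnf <- logf$f_mtu / p$f_max
  sf <- (logf$stim - rpf$prestim) / rpf$gain
  expect_equal(sf[idx], 0.5 * fnf[idx - 17] + 0.5 * fnf[idx - 18],
               tolerance = 1e-12)
})

test_that("open reflex loop (gain 0, prestim 0) leaves only passive force", {
  rp <- reflex_params(gain = 0, prestim = 0, psi = 0.5)
  log <- run_playback(fixture_trial, rp)
  expect_identical(max(log$a), 0)
  expect_identical(max(log$stim), 0)
  # torque is the passive force through the moment arm during stance
  st <- log$phase == "stance"
  expect_equal(log$torque[st],
               log$f_mtu[st] * moment_arm(log$theta[st], geom) * rp$psi)
})

test_that("self-excitation grows during stance but stays bounded over 100 strides", {
  trial <- synth_gait(gait_spec(), n_strides = 100)
  rp <- reflex_params(gain = 2.0, delay = 0.01)
  log <- run_playback(trial, rp)
  expect_true(all(is.finite(log$f_mtu)))
  expect_lte(max(log$stim), 1)
  expect_lt(max(log$f_mtu), 2 * p$f_max)
  # reflex amplifies force well above the open-loop passive level
  log0 <- run_playback(fixture_trial, reflex_params(gain = 0, prestim = 0))
  expect_gt(max(log$f_mtu), 1.5 * max(log0$f_mtu))
  # stride-periodic steady state: late strides repeat to within 1%
  ev <- attr(log, "heel_strike")
  m50 <- stride_metrics(log, n_strides = 1, discard = 49)
  m99 <- stride_metrics(log, n_strides = 1, discard = 98)
  expect_equal(m50$avg_torque, m99$avg_torque, tolerance = 0.01)
})

test_that("step-wise controller agrees with the vectorized engine", {
  rp <- reflex_params(gain = 1.2, delay = 0.01)
  log <- run_playback(fixture_trial, rp)
  ph <- gait_phase(fixture_trial)
  ctrl <- controller_reset(rp, p, geom, theta0 = fixture_trial$angle[1])
  n <- 2000
  tq <- numeric(n)
  for (i in 1:n) {
    out <- controller_step(ctrl, fixture_trial$angle[i], ph[i], 1e-3, rp, p,
                           geom, theta_next = fixture_trial$angle[i + 1])
    tq[i] <- out$torque
  }
  expect_equal(tq, log$torque[1:n], tolerance = 1e-8)
})
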