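p <- default_p
geom <- default_geom

test_that("musculoskeletal geometry: length map, moment arm and their consistency", {
  expect_equal(mtu_length(geom$theta_ref, geom), geom$l_mtu_ref)
  # dorsiflexion (negative angle) lengthens the MTU
  expect_equal(mtu_length(geom$theta_ref - 0.1, geom),
               geom$l_mtu_ref + 0.05 * sin(0.1))
  expect_gt(mtu_length(-0.2, geom), mtu_length(0.2, geom))

  expect_equal(moment_arm(geom$theta_ref, geom), geom$r0)
  expect_equal(moment_arm(geom$theta_ref + pi / 3, geom), geom$r0 / 2)
  expect_equal(moment_arm(geom$theta_ref - pi / 3, geom), geom$r0 / 2)

  # moment arm equals the negative angular derivative of MTU length
  h <- 1e-6
  for (th in c(-0.4, -0.1, 0, 0.15, 0.5)) {
    fd <- -(mtu_length(th + h, geom) - mtu_length(th - h, geom)) / (2 * h)
    expect_equal(fd, moment_arm(th, geom), tolerance = 1e-6)
  }
  expect_error(mtu_length(NaN, geom), "finite")
  expect_error(moment_arm(Inf, geom), "finite")

  # constant-arm option freezes the torque arm but not the length map
  gc <- ankle_geometry(constant_arm = TRUE, p = p)
  expect_equal(moment_arm(0.3, gc), gc$r0)
  expect_equal(mtu_length(0.3, gc), mtu_length(0.3, geom))
})

test_that("SEE force: slack, toe/linear junction continuity and monotonicity", {
  ls <- p$l_slack
  expect_identical(see_force(ls, p), 0)
  expect_identical(see_force(ls - 0.01, p), 0) # compressed: never negative

  # closed-form force at the end of the toe region
  expect_equal(see_force(ls * (1 + p$eps_ref), p),
               p$k_see * p$eps_ref * ls / 2)

  # C1 junction: slopes from both sides agree
  h <- 1e-8
  lj <- ls * (1 + p$eps_ref)
  slope_lo <- (see_force(lj, p) - see_force(lj - h, p)) / h
  slope_hi <- (see_force(lj + h, p) - see_force(lj, p)) / h
  expect_equal(slope_lo, slope_hi, tolerance = 1e-5)

  # tangent stiffness in the linear region is the configured k_SEE
  l2 <- ls * (1 + 2 * p$eps_ref)
  tangent <- (see_force(l2 + 1e-7, p) - see_force(l2 - 1e-7, p)) / 2e-7
  expect_equal(tangent / 1000, 315.4, tolerance = 1e-6) # N/mm

  grid <- seq(ls - 0.01, ls * 1.12, length.out = 400)
  f <- see_force(grid, p)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0))
})

test_that("force-length curve is bell-shaped, symmetric, 1 at optimum", {
  expect_equal(force_length(p$l_opt, p), 1)
  # curve-width calibration: exp(c_fl) at l_opt * (1 +/- w)
  expect_equal(force_length(p$l_opt * (1 + p$w), p), exp(p$c_fl))
  expect_equal(force_length(p$l_opt * (1 - p$w), p), exp(p$c_fl))
  for (x in c(0.1, 0.25, 0.5)) {
    expect_equal(force_length(p$l_opt * (1 + x), p),
                 force_length(p$l_opt * (1 - x), p))
  }
  grid <- seq(0.3, 1.7, by = 0.01) * p$l_opt
  fl <- force_length(grid, p)
  expect_true(all(fl >= 0 & fl <= 1))
  expect_equal(grid[which.max(fl)], p$l_opt, tolerance = 0.011)
})

test_that("force-velocity: Hill hyperbola, clipping and eccentric plateau", {
  expect_equal(force_velocity(0, p), 1)
  expect_identical(force_velocity(p$v_max, p), 0)
  expect_identical(force_velocity(2 * p$v_max, p), 0)
  # closed form at half the maximal shortening velocity (k_fv = 5)
  expect_equal(force_velocity(p$v_max / 2, p), 0.5 / 3.5)
  # strictly decreasing across both branches
  grid <- seq(-3 * p$v_max, p$v_max, length.out = 500)
  fv <- force_velocity(grid, p)
  expect_true(all(diff(fv) < 0))
  # eccentric values approach but never reach the plateau
  expect_true(all(fv <= p$n_fv))
  expect_gt(force_velocity(-10 * p$v_max, p), 0.98 * p$n_fv)
})

test_that("ce_velocity inverts the force balance exactly when unclamped", {
  # isometric balance
  l <- p$l_opt * 1.02
  a <- 0.6
  f_iso <- p$f_max * (a * force_length(l, p) + passive_force(l, p))
  expect_equal(ce_velocity(f_iso, l, a, p), 0)
  # demand at the passive-only level: full unloaded shortening
  f_pass <- p$f_max * passive_force(p$l_opt * 1.1, p)
  expect_equal(ce_velocity(f_pass, p$l_opt * 1.1, 0.5, p), p$v_max)
  # algebraic round trip on random unclamped triples
  set.seed(42)
  fv_cap <- p$n_fv - (p$n_fv - 1) / (1 + 7.56 * p$k_fv)
  for (i in 1:200) {
    l <- stats::runif(1, 0.8, 1.2) * p$l_opt
    a <- stats::runif(1, 0.2, 1)
    fv_target <- stats::runif(1, 0.05, fv_cap - 0.05)
    f <- p$f_max * (a * force_length(l, p) * fv_target + passive_force(l, p))
    v <- ce_velocity(f, l, a, p)
    expect_lt(abs(force_velocity(v, p) - fv_target), 1e-9)
  }
  expect_error(ce_velocity(-1, p$l_opt, 0.5, p), ">= 0")
  expect_error(ce_velocity(100, p$l_opt, 1.5, p), "\\[0, 1\\]")
})

test_that("activation dynamics follow the closed-form exponential", {
  expect_equal(activation_step(0.3, 0.3, 1e-3, p), 0.3)
  # stepwise integration reproduces 1 - exp(-T / tau)
  a <- 0
  for (i in 1:500) a <- activation_step(a, 1, 1e-3, p)
  expect_equal(a, 1 - exp(-0.5 / p$tau_act), tolerance = 1e-6)
  # monotone decay toward 0
  a <- 1
  trace <- numeric(50)
  for (i in 1:50) {
    a <- activation_step(a, 0, 1e-3, p)
    trace[i] <- a
  }
  expect_true(all(diff(trace) < 0))
  expect_error(activation_step(0.5, 0.5, 0, p), "dt")
  expect_error(activation_step(1.5, 0.5, 1e-3, p), "\\[0, 1\\]")
})

test_that("mtu_step: passive equilibrium, isometric force ceiling, length constraint", {
  # constant angle, no stimulation: settles to static equilibrium
  out <- run_mtu_trace(rep(0, 1500), stim = 0, dt = 1e-3,
                       l_ce0 = p$l_opt * 0.98)
  s <- out$state
  expect_lt(abs(s$v_ce), 1e-9)
  expect_equal(s$l_see, s$l_mtu - s$l_ce) # exact length constraint
  expect_gte(s$f_mtu, 0)

  # isometric ceiling: stim = 1 with geometry placing the CE at l_opt
  # when the SEE carries f_max
  gi <- isometric_geom(p)
  out <- run_mtu_trace(rep(0, 2000), stim = 1, dt = 1e-3, geom = gi,
                       l_ce0 = p$l_opt * 1.05, a0 = 0)
  expect_equal(out$state$f_mtu, p$f_max, tolerance = 1e-3)
  expect_equal(out$state$l_ce, p$l_opt, tolerance = 1e-3)
})

test_that("mtu_step converges under time-step refinement", {
  mk_theta <- function(dt, dur = 0.5) 0.1 * sin(2 * pi * (0:round(dur / dt)) * dt)
  ref <- run_mtu_trace(mk_theta(5e-5), 0.3, 5e-5)$force
  err_at <- function(dt) {
    # compare at the coarse sample times common to both grids
    n <- round(0.5 / dt)
    f <- run_mtu_trace(mk_theta(dt), 0.3, dt)$force[1:n]
    k <- round(dt / 5e-5)
    sub <- ref[seq(k, by = k, length.out = n)]
    max(abs(f - sub)) / max(abs(sub))
  }
  e2 <- err_at(2e-3)
  e1 <- err_at(1e-3)
  expect_lt(e1, 1e-3)
  # better-than-first-order convergence
  expect_gt(e2 / e1, 2.5)
})
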