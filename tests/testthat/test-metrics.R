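test_that("stride_average: constant, ramp and zero-mean closed forms", {
  dt <- 0.01
  t <- seq(0, 2, by = dt)
  ev <- c(1, 101, 201)
  # constant c over a stride -> c / mass
  out <- stride_average(rep(3, length(t)), t, ev, mass = 70)
  expect_equal(out$mean, 3 / 70)
  expect_length(out$per_stride, 2)
  # linear ramp 0 -> b over one stride -> b / (2 mass), trapezoid-exact
  ramp <- c(seq(0, 5, length.out = 101), seq(0, 5, length.out = 101)[-1])
  out <- stride_average(ramp, t, ev, mass = 2)
  expect_equal(out$per_stride[1], 5 / 4)
  # full-period sine -> 0 within trapezoid error
  s <- sin(2 * pi * t)
  expect_lt(abs(stride_average(s, t, c(1, 101), mass = 1)$mean), 1e-6)
  expect_error(stride_average(s, t, events = 1, mass = 1), "2 heel-strike")
})

test_that("stride_average is linear and stable under sampling-rate doubling", {
  set.seed(1)
  f <- function(tt) sin(2 * pi * tt) + 0.3 * cos(6 * pi * tt) + 0.5
  t1 <- seq(0, 1, by = 1e-3)
  t2 <- seq(0, 1, by = 5e-4)
  a1 <- stride_average(f(t1), t1, c(1, length(t1)), mass = 1)$mean
  a2 <- stride_average(f(t2), t2, c(1, length(t2)), mass = 1)$mean
  expect_equal(a1, a2, tolerance = 1e-6) # O(dt^2) trapezoid error
  # linearity in the signal
  x <- f(t1); y <- cos(2 * pi * t1)
  ax <- stride_average(x, t1, c(1, length(t1)), mass = 1)$mean
  ay <- stride_average(y, t1, c(1, length(t1)), mass = 1)$mean
  axy <- stride_average(2 * x + 3 * y, t1, c(1, length(t1)), mass = 1)$mean
  expect_equal(axy, 2 * ax + 3 * ay)
})

test_that("net_power: in-phase product, quadrature orthogonality, antisymmetry", {
  t <- seq(0, 1, by = 1e-4)
  ev <- c(1, length(t))
  A <- 30; B <- 2; mass <- 70
  tau <- A * sin(2 * pi * t)
  om_in <- B * sin(2 * pi * t)
  om_q <- B * cos(2 * pi * t)
  expect_equal(net_power(tau, om_in, t, ev, mass)$mean, A * B / (2 * mass),
               tolerance = 1e-6)
  expect_lt(abs(net_power(tau, om_q, t, ev, mass)$mean), 1e-8)
  expect_identical(net_power(rep(0, length(t)), om_in, t, ev, mass)$mean, 0)
  # antisymmetry in torque
  expect_equal(net_power(tau, om_in, t, ev, mass)$mean,
               -net_power(-tau, om_in, t, ev, mass)$mean)
  expect_error(net_power(tau, om_in[-1], t, ev, mass), "length")
})

test_that("EMG envelope: DC rejection, rectified-sine level, homogeneity", {
  fs <- 960
  t <- seq(0, 10, by = 1 / fs)
  # pure DC is killed by the high-pass
  env_dc <- emg_envelope(rep(2, length(t)), fs)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  expect_lt(max(abs(env_dc[mid])), 1e-3 * 2)
  # 50 Hz sine of amplitude A -> steady-state envelope 2A/pi within 2%
  A <- 1.7
  env <- emg_envelope(A * sin(2 * pi * 50 * t), fs)
  expect_equal(mean(env[mid]), 2 * A / pi, tolerance = 0.02)
  # degree-1 homogeneity
  set.seed(4)
  x <- rnorm(2000)
  expect_equal(emg_envelope(3 * x, fs), 3 * emg_envelope(x, fs),
               tolerance = 1e-12)
  expect_error(emg_envelope(x, fs = 35), "cutoff")
})

test_that("EMG normalization: self-reference peaks, linearity, summing", {
  # synthetic envelopes on a shared grid: two conditions, four muscles
  t <- seq(0, 4, by = 1e-3)
  ev <- c(1, 1001, 2001, 3001, 4001)
  base <- 0.5 + 0.4 * sin(2 * pi * t)^2
  mk <- function(cond, muscles, scale) {
    do.call(rbind, lapply(seq_along(muscles), function(i) {
      data.frame(condition = cond, muscle = muscles[i], time = t,
                 value = scale[i] * base)
    }))
  }
  muscles <- c("SOL", "MG", "LG", "TA")
  env <- rbind(mk("NoPwr", muscles, rep(1, 4)),
               mk("Pwr", muscles, rep(2, 4)))
  out <- normalize_and_sum_emg(env, ev, reference = "NoPwr")
  # reference condition: peak of stride-averaged envelope normalizes to 1
  expect_equal(unname(out$reference_peaks), rep(max(base), 4),
               tolerance = 1e-6)
  ref_avg <- out$per_muscle$avg_norm_emg[out$per_muscle$condition == "NoPwr"]
  # doubling the raw channel doubles the normalized average
  pwr_avg <- out$per_muscle$avg_norm_emg[out$per_muscle$condition == "Pwr"]
  expect_equal(pwr_avg, 2 * ref_avg)
  # four identical muscles: summed = 4 x single
  expect_equal(out$summed$summed_avg_emg[out$summed$condition == "NoPwr"],
               4 * ref_avg[1])
  # muscle-volume weighting
  outw <- normalize_and_sum_emg(env, ev, weights = c(SOL = 2, MG = 1,
                                                     LG = 1, TA = 0))
  expect_equal(outw$summed$summed_avg_emg[outw$summed$condition == "NoPwr"],
               4 * ref_avg[1])
  # zero reference peak is rejected
  env0 <- env
  env0$value[env0$condition == "NoPwr" & env0$muscle == "TA"] <- 0
  expect_error(normalize_and_sum_emg(env0, ev), "peak")
})

test_that("Brockway conversion is linear with the canonical coefficients", {
  expect_identical(brockway_rate(0, 0, time = 0, mass = 70, window = 0), 0)
  expect_equal(brockway_rate(1, 0, time = 0, mass = 1, window = 0), 16.58)
  expect_equal(brockway_rate(0, 1, time = 0, mass = 1, window = 0), 4.51)
  # constant series: the 2-min window mean recovers the value exactly
  t <- seq(0, 420, by = 3)
  r <- brockway_rate(rep(10, length(t)), rep(8, length(t)), t, mass = 70)
  expect_equal(r, (16.58 * 10 + 4.51 * 8) / 70)
  # linearity in both flows
  r2 <- brockway_rate(rep(20, length(t)), rep(16, length(t)), t, mass = 70)
  expect_equal(r2, 2 * r)
  expect_error(brockway_rate(c(-1, 1), c(0, 0), c(0, 1), 70), "negative")
  expect_error(brockway_rate(1:5, 1:5, seq(0, 60, 15), 70, window = 120),
               "window")
})

test_that("noiseless synthetic gas exchange round-trips through Brockway", {
  g <- synth_gas_exchange(duration = 600, breath_noise_sd = 0, tau_on = 20)
  r <- brockway_rate(g$vo2, g$vco2, g$time, mass = 71.3)
  expect_equal(r, (16.58 * 17.5 + 4.51 * 14.9) / 71.3, tolerance = 1e-4)
})

test_that("biological moment is the exoskeleton-subtracted total", {
  tot <- c(10, 20, 30)
  exo <- c(1, 2, 3)
  expect_identical(bio_moment(tot, exo), c(9, 18, 27))
  expect_error(bio_moment(tot, exo[-1]), "mismatch")
})
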