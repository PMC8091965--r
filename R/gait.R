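#' @title Synthetic treadmill-gait fixtures
#' @description
#' Generators for periodic ankle-angle trajectories emulating steady
#' treadmill walking (~1.25 m/s: stance about 60% of the stride, with
#' progressive stance dorsiflexion followed by a rapid plantarflexion
#' push-off), plus synthetic surface-EMG and breath-wise gas-exchange
#' channels, so the whole analysis chain can be exercised without any
#' recorded data. All generators are deterministic under a fixed seed.
#' @name gait_synthesis
NULL

.default_keyframes <- function() {
  # plantarflexion positive (degrees): small plantarflexion after heel
  # strike, progressive stance dorsiflexion to about -10 deg, rapid
  # push-off plantarflexion to about +15 deg just after the 60% stance-
  # swing transition, back to neutral in swing
  data.frame(
    pct = c(0, 8, 50, 62, 75),
    angle_deg = c(0, 5, -10, 15, 0)
  )
}

#' Specification of a synthetic gait trial
#'
#' @param stride_time Stride duration (s); default 1.1 s, typical of
#'   walking at 1.25 m/s.
#' @param stance_fraction Fraction of the stride in stance, in (0.3, 0.8).
#' @param sample_rate Sampling rate (Hz).
#' @param angle_keyframes Data frame with columns `pct` (stride percent in
#'   \[0, 100)) and `angle_deg` (plantarflexion positive) defining the
#'   within-stride shape; interpolated periodically.
#' @param harmonics Number of Fourier harmonics kept when smoothing the
#'   keyframe interpolation into a C1-periodic trajectory.
#' @param noise_sd Additive Gaussian angle noise (deg); 0 for a noiseless
#'   trial.
#' @param body_mass Body mass (kg) attached to the trial; default 71.3 kg,
#'   the study-population mean.
#' @param seed Integer seed for the noise generator.
#' @return An object of class `gait_spec`.
#' @export
gait_spec <- function(stride_time = 1.1,
                      stance_fraction = 0.60,
                      sample_rate = 1000,
                      angle_keyframes = .default_keyframes(),
                      harmonics = 8,
                      noise_sd = 0,
                      body_mass = 71.3,
                      seed = 1L) {
  stopifnot(
    stride_time > 0,
    stance_fraction > 0.3, stance_fraction < 0.8,
    sample_rate > 0, harmonics >= 1, noise_sd >= 0, body_mass > 0
  )
  kf <- as.data.frame(angle_keyframes)
  if (!all(c("pct", "angle_deg") %in% names(kf))) {
    stop("angle_keyframes needs columns pct and angle_deg")
  }
  if (any(kf$pct < 0) || any(kf$pct >= 100) || is.unsorted(kf$pct, strictly = TRUE)) {
    stop("keyframe pct values must be strictly increasing within [0, 100)")
  }
  structure(
    list(
      stride_time = stride_time, stance_fraction = stance_fraction,
      sample_rate = sample_rate, angle_keyframes = kf,
      harmonics = harmonics, noise_sd = noise_sd,
      body_mass = body_mass, seed = as.integer(seed)
    ),
    class = "gait_spec"
  )
}

# Fourier-smooth one stride of keyframe-interpolated angle (radians).
# Returns list(angle, omega, trunc_error) sampled at m points.
.smooth_stride <- function(spec) {
  m <- round(spec$stride_time * spec$sample_rate)
  kf <- spec$angle_keyframes
  # periodic linear interpolation of keyframes on the sample grid
  pct <- (seq_len(m) - 1) / m * 100
  xs <- c(kf$pct, kf$pct[1] + 100)
  ys <- c(kf$angle_deg, kf$angle_deg[1]) * pi / 180
  raw <- stats::approx(xs, ys, xout = ifelse(pct < xs[1], pct + 100, pct))$y
  # truncate the spectrum to the requested number of harmonics
  co <- stats::fft(raw) / m
  keep <- rep(0, m)
  keep[1] <- 1
  h <- min(spec$harmonics, floor((m - 1) / 2))
  keep[2:(h + 1)] <- 1
  keep[(m - h + 1):m] <- 1
  co <- co * keep
  angle <- Re(stats::fft(co, inverse = TRUE))
  # analytic derivative from the Fourier coefficients
  k <- c(0:(floor(m / 2)), -((ceiling(m / 2) - 1):1))
  dco <- co * 1i * 2 * pi * k / spec$stride_time
  if (m %% 2 == 0) dco[m / 2 + 1] <- 0
  omega <- Re(stats::fft(dco, inverse = TRUE))
  list(angle = angle, omega = omega, trunc_error = max(abs(angle - raw)))
}

#' Synthesize a periodic ankle-angle gait trial
#'
#' Builds `n_strides` strides of a C1-periodic ankle-angle trajectory
#' through the keyframes of `spec`, Fourier-smoothed, with heel-strike
#' events at every stride boundary (so `n_strides + 1` events bracket
#' exactly `n_strides` strides). The angular-velocity channel is the
#' analytic derivative of the smoothed trajectory (centred finite
#' differences of the noisy angle when `noise_sd > 0`).
#'
#' @param spec A [gait_spec()].
#' @param n_strides Number of strides, >= 1.
#' @return A tibble of class `gait_trial` with columns `time` (s),
#'   `angle` (rad, plantarflexion positive) and `omega` (rad/s), and
#'   attributes `heel_strike` (sample indices), `body_mass`,
#'   `sample_rate`, `stance_fraction`, `fourier_trunc_error` and `spec`.
#' @examples
#' trial <- synth_gait(gait_spec(), n_strides = 3)
#' attr(trial, "heel_strike")
#' @export
synth_gait <- function(spec = gait_spec(), n_strides = 10) {
  stopifnot(inherits(spec, "gait_spec"), n_strides >= 1)
  s <- .smooth_stride(spec)
  m <- length(s$angle)
  n <- n_strides * m + 1
  angle <- c(rep(s$angle, n_strides), s$angle[1])
  omega <- c(rep(s$omega, n_strides), s$omega[1])
  dt <- 1 / spec$sample_rate
  time <- (seq_len(n) - 1) * dt
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    angle <- angle + stats::rnorm(n, sd = spec$noise_sd * pi / 180)
    omega <- numeric(n)
    omega[2:(n - 1)] <- (angle[3:n] - angle[1:(n - 2)]) / (2 * dt)
    omega[1] <- (angle[2] - angle[1]) / dt
    omega[n] <- (angle[n] - angle[n - 1]) / dt
  }
  trial <- tibble::tibble(time = time, angle = angle, omega = omega)
  attr(trial, "heel_strike") <- as.integer(seq(1L, n, by = m))
  attr(trial, "body_mass") <- spec$body_mass
  attr(trial, "sample_rate") <- spec$sample_rate
  attr(trial, "stance_fraction") <- spec$stance_fraction
  attr(trial, "fourier_trunc_error") <- s$trunc_error
  attr(trial, "spec") <- spec
  class(trial) <- c("gait_trial", class(trial))
  trial
}

#' Heel-strike annotations of a trial
#' @param trial A `gait_trial` (or any simulation log carrying events).
#' @return Integer vector of heel-strike sample indices.
#' @export
heel_strikes <- function(trial) attr(trial, "heel_strike")

# per-sample stance mask: stance covers the first stance_fraction of each
# stride (heel strike to heel strike); samples outside any stride (after
# the final event) count as stance onset of the next stride
.stance_mask <- function(n, events, stance_fraction) {
  stance <- rep(FALSE, n)
  for (k in seq_len(length(events) - 1)) {
    hs <- events[k]
    to <- events[k] + floor(stance_fraction * (events[k + 1] - events[k]))
    stance[hs:min(to, n)] <- TRUE
  }
  if (events[length(events)] <= n) stance[events[length(events)]:n] <- TRUE
  stance
}

#' Per-sample gait-phase labels for a trial
#'
#' @param trial A `gait_trial`.
#' @return Character vector (`"stance"`/`"swing"`), one entry per sample:
#'   stance spans the configured fraction of each stride from heel strike.
#' @export
gait_phase <- function(trial) {
  m <- .stance_mask(nrow(trial), heel_strikes(trial),
                    attr(trial, "stance_fraction"))
  ifelse(m, "stance", "swing")
}

#' Synthesize raw surface-EMG channels for a trial
#'
#' Amplitude-modulated, band-limited (20-450 Hz) Gaussian noise with
#' per-stride activity bursts: within each burst window the modulation
#' envelope is a raised cosine peaking mid-window at the given amplitude.
#' Only the envelope pipeline downstream consumes these channels, so no
#' motor-unit structure is modelled.
#'
#' @param trial A `gait_trial` providing the stride timing.
#' @param bursts Named list (one entry per muscle) of data frames with
#'   columns `onset`, `offset` (stride %, in \[0, 100)) and `amp`;
#'   windows with `offset < onset` wrap around the stride boundary.
#'   Defaults emulate plantarflexor push-off bursts (SOL, MG, LG) and
#'   tibialis anterior activity around heel strike.
#' @param fs EMG sampling rate (Hz); default 960 Hz.
#' @param seed Integer seed.
#' @return A tibble with a `time` column and one column per muscle, with
#'   attributes `fs` and `heel_strike_times` (s).
#' @export
synth_emg <- function(trial,
                      bursts = list(
                        SOL = data.frame(onset = 30, offset = 60, amp = 1.0),
                        MG  = data.frame(onset = 32, offset = 60, amp = 0.9),
                        LG  = data.frame(onset = 32, offset = 58, amp = 0.8),
                        TA  = data.frame(onset = 90, offset = 15, amp = 0.6)
                      ),
                      fs = 960, seed = 1L) {
  stopifnot(fs > 2 * 450)
  for (b in bursts) {
    if (any(b$onset < 0 | b$onset >= 100 | b$offset < 0 | b$offset >= 100)) {
      stop("burst windows must lie within [0, 100)% of the stride")
    }
  }
  duration <- trial$time[nrow(trial)]
  n <- floor(duration * fs) + 1
  time <- (seq_len(n) - 1) / fs
  hs_t <- trial$time[heel_strikes(trial)]
  # stride percent for every EMG sample
  stride_of <- findInterval(time, hs_t, rightmost.closed = TRUE)
  stride_of <- pmin(pmax(stride_of, 1L), length(hs_t) - 1L)
  t0 <- hs_t[stride_of]
  t1 <- hs_t[stride_of + 1L]
  pct <- (time - t0) / (t1 - t0) * 100
  set.seed(as.integer(seed))
  bp <- signal::butter(2, c(20, 450) / (fs / 2), type = "pass")
  out <- tibble::tibble(time = time)
  for (mname in names(bursts)) {
    env <- rep(0, n)
    b <- bursts[[mname]]
    for (j in seq_len(nrow(b))) {
      on <- b$onset[j]; off <- b$offset[j]; amp <- b$amp[j]
      if (off >= on) {
        inside <- pct >= on & pct <= off
        width <- off - on
        phase <- (pct - on) / width
      } else { # wraps the stride boundary
        inside <- pct >= on | pct <= off
        width <- 100 - on + off
        phase <- ifelse(pct >= on, pct - on, pct + 100 - on) / width
      }
      if (width <= 0) next
      env[inside] <- pmax(env[inside],
                          amp * 0.5 * (1 - cos(2 * pi * phase[inside])))
    }
    noise <- signal::filtfilt(bp, stats::rnorm(n))
    out[[mname]] <- env * noise
  }
  attr(out, "fs") <- fs
  attr(out, "heel_strike_times") <- hs_t
  out
}

#' Synthesize breath-wise gas-exchange channels
#'
#' First-order exponential rise of oxygen uptake and carbon-dioxide
#' output to their steady-state values, with independent breath-to-breath
#' Gaussian noise, sampled one value per breath.
#'
#' @param duration Trial duration (s); default 420 s (a 7-min condition).
#' @param vo2_ss,vco2_ss Steady-state flow rates (ml/s). Defaults give a
#'   net metabolic rate of about 5 W/kg at 71.3 kg with a respiratory
#'   exchange ratio of 0.85.
#' @param tau_on Onset time constant (s).
#' @param breath_noise_sd Breath-to-breath noise s.d. (ml/s).
#' @param breath_period Mean breath interval (s); ~0.33 Hz breathing.
#' @param seed Integer seed.
#' @return A tibble with columns `time` (s, breath timestamps), `vo2` and
#'   `vco2` (ml/s).
#' @export
synth_gas_exchange <- function(duration = 420,
                               vo2_ss = 17.5, vco2_ss = 14.9,
                               tau_on = 30, breath_noise_sd = 0.5,
                               breath_period = 3, seed = 1L) {
  stopifnot(duration > 0, vo2_ss >= 0, vco2_ss >= 0, tau_on > 0,
            breath_noise_sd >= 0, breath_period > 0)
  time <- seq(0, duration, by = breath_period)
  rise <- 1 - exp(-time / tau_on)
  set.seed(as.integer(seed))
  vo2 <- vo2_ss * rise + stats::rnorm(length(time), sd = breath_noise_sd)
  vco2 <- vco2_ss * rise + stats::rnorm(length(time), sd = breath_noise_sd)
  tibble::tibble(time = time, vo2 = pmax(vo2, 0), vco2 = pmax(vco2, 0))
}
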