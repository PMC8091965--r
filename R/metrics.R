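#' @title Stride-averaged outcome metrics
#' @description
#' The outcome computations applied to each condition: stride-averaged
#' torque/moment (time integral over the gait cycle divided by stride
#' time, body-mass normalized), net mechanical power (the same average of
#' the instantaneous torque-velocity product), the surface-EMG envelope
#' pipeline (20 Hz high-pass, full-wave rectification, 6 Hz low-pass,
#' normalization to the zero-torque condition), and metabolic rate from
#' gas exchange via the Brockway equation averaged over the final two
#' minutes of a trial.
#' @name analysis_metrics
NULL

# indices of the strides summarized: drop the first `discard`, then the
# last up-to-`n_strides` complete strides
.select_strides <- function(events, n_strides, discard) {
  total <- length(events) - 1
  usable <- seq_len(total)
  if (discard > 0) usable <- usable[usable > discard]
  if (length(usable) == 0) stop("no strides left after transient discard")
  utils::tail(usable, n_strides)
}

#' Stride-averaged value of a sampled signal
#'
#' For each stride (heel strike to heel strike) the trapezoidal integral
#' of the signal over the stride divided by the stride duration, divided
#' by body mass; then the mean across the selected strides (by default
#' the last up to ~10 representative strides, after discarding none).
#'
#' @param x Sampled signal (e.g. torque in Nm).
#' @param time Sample times (s), same length as `x`, uniformly spaced.
#' @param events Heel-strike sample indices (>= 2).
#' @param mass Body mass (kg) used as normalizer; use 1 for an
#'   unnormalized (or dimensionless) average.
#' @param n_strides Number of representative strides averaged (taken from
#'   the end of the trial).
#' @param discard Initial strides dropped as transient.
#' @return A list with `per_stride` (one value per selected stride),
#'   `mean`, and `strides` (the stride indices used).
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' stride_average(rep(2, length(t)), t, events = c(1, 101, 201), mass = 1)$mean
#' @export
stride_average <- function(x, time, events, mass = 1,
                           n_strides = 10, discard = 0) {
  if (length(events) < 2) stop("need at least 2 heel-strike events")
  stopifnot(length(x) == length(time), mass > 0)
  strides <- .select_strides(events, n_strides, discard)
  per <- vapply(strides, function(k) {
    i0 <- events[k]; i1 <- events[k + 1]
    idx <- i0:i1
    pracma::trapz(time[idx], x[idx]) / (time[i1] - time[i0]) / mass
  }, numeric(1))
  list(per_stride = per, mean = mean(per), strides = strides)
}

#' Net mechanical power delivered over the stride
#'
#' Pointwise product of torque and angular velocity, stride-averaged as
#' in [stride_average()]. Positive values indicate net energy transfer to
#' the user.
#'
#' @param torque Torque series (Nm).
#' @param omega Angular velocity series (rad/s), aligned with `torque`.
#' @inheritParams stride_average
#' @return A list as in [stride_average()], in W/kg.
#' @export
net_power <- function(torque, omega, time, events, mass = 1,
                      n_strides = 10, discard = 0) {
  if (length(torque) != length(omega)) {
    stop("torque and omega must have the same length")
  }
  stride_average(torque * omega, time, events, mass,
                 n_strides = n_strides, discard = discard)
}

#' Summarize a simulation log into stride metrics
#'
#' Body-mass-normalized average exoskeleton torque (Nm/kg) and net
#' exoskeleton power (W/kg) over the representative strides of a
#' controller log.
#'
#' @param log An `nmm_log` from [run_playback()] or [run_adaptive()].
#' @param mass Body mass (kg); defaults to the mass carried by the log.
#' @param n_strides Representative strides averaged (last complete ones).
#' @param discard Initial transient strides dropped (delay-line and
#'   activation warm-up).
#' @return A one-row tibble: `avg_torque` (Nm/kg), `net_power` (W/kg),
#'   `n_strides_used`.
#' @export
stride_metrics <- function(log, mass = attr(log, "body_mass"),
                           n_strides = 10, discard = 2) {
  events <- attr(log, "heel_strike")
  at <- stride_average(log$torque, log$t, events, mass,
                       n_strides = n_strides, discard = discard)
  np <- net_power(log$torque, log$omega, log$t, events, mass,
                  n_strides = n_strides, discard = discard)
  tibble::tibble(
    avg_torque = at$mean,
    net_power = np$mean,
    n_strides_used = length(at$strides)
  )
}

#' EMG linear envelope
#'
#' Zero-phase (forward-backward) 2nd-order Butterworth high-pass at
#' 20 Hz, full-wave rectification, then zero-phase 2nd-order Butterworth
#' low-pass at 6 Hz. Design cutoffs are corrected for the double pass
#' (Winter's factor `(sqrt(2) - 1)^(1/4) ~ 0.802`) so the stated cutoff
#' is the -3 dB point of the *combined* forward-backward filter — the
#' standard gait-lab convention. The raw filter output is returned
#' without clamping the small negative undershoot of the zero-phase
#' low-pass, preserving linearity of the pipeline.
#'
#' @param x Raw EMG series.
#' @param fs Sampling rate (Hz), > 40 (twice the high-pass cutoff).
#' @param hp,lp Effective high-/low-pass cutoffs (Hz).
#' @return Envelope series, same length as `x`.
#' @export
emg_envelope <- function(x, fs, hp = 20, lp = 6) {
  if (fs <= 2 * hp) stop("fs must exceed twice the high-pass cutoff")
  corr <- (sqrt(2) - 1)^0.25 # double-pass cutoff correction
  bh <- signal::butter(2, hp * corr / (fs / 2), type = "high")
  bl <- signal::butter(2, lp / corr / (fs / 2), type = "low")
  signal::filtfilt(bl, abs(signal::filtfilt(bh, x)))
}

# mean within-stride profile on a common 0-100% grid (101 points)
.stride_profile <- function(x, time, events, strides, npts = 101) {
  prof <- matrix(NA_real_, nrow = length(strides), ncol = npts)
  for (j in seq_along(strides)) {
    k <- strides[j]
    idx <- events[k]:events[k + 1]
    pct <- (time[idx] - time[idx[1]]) / (time[idx[length(idx)]] - time[idx[1]])
    prof[j, ] <- stats::approx(pct, x[idx], xout = seq(0, 1, length.out = npts))$y
  }
  colMeans(prof)
}

#' Normalize EMG envelopes to the zero-torque condition and sum muscles
#'
#' Each muscle's envelope is divided by the peak of its stride-averaged
#' envelope in the reference (zero-torque, NoPwr) condition; the summed
#' channel adds the normalized muscles (optionally weighted, e.g. by
#' relative muscle volume); averages are gait-cycle integrals divided by
#' stride time (dimensionless, no mass normalization).
#'
#' @param env Long tibble/data frame with columns `condition`, `muscle`,
#'   `time` (s) and `value` (envelope), on a common uniform time base per
#'   condition.
#' @param events Heel-strike sample indices: either a vector shared by all
#'   conditions or a named list with one vector per condition.
#' @param reference Name of the normalization condition (default
#'   `"NoPwr"`).
#' @param weights Optional named numeric vector of per-muscle weights for
#'   the summed channel (default: all 1).
#' @param n_strides,discard Stride selection, as in [stride_average()].
#' @return A list with `per_muscle` (tibble: condition, muscle,
#'   `avg_norm_emg`), `summed` (tibble: condition, `summed_avg_emg`) and
#'   `reference_peaks` (named vector of the NoPwr peaks used).
#' @export
normalize_and_sum_emg <- function(env, events, reference = "NoPwr",
                                  weights = NULL, n_strides = 10,
                                  discard = 0) {
  req <- c("condition", "muscle", "time", "value")
  if (!all(req %in% names(env))) {
    stop("env must have columns: ", paste(req, collapse = ", "))
  }
  if (!reference %in% env$condition) {
    stop("reference condition '", reference, "' not present")
  }
  conds <- unique(env$condition)
  muscles <- unique(env$muscle)
  ev_of <- function(cond) {
    if (is.list(events)) events[[cond]] else events
  }
  # reference peaks: max of the stride-mean profile in the NoPwr condition
  peaks <- vapply(muscles, function(mu) {
    d <- env[env$condition == reference & env$muscle == mu, ]
    ev <- ev_of(reference)
    strides <- .select_strides(ev, n_strides, discard)
    max(.stride_profile(d$value, d$time, ev, strides))
  }, numeric(1))
  names(peaks) <- muscles
  if (any(peaks <= 0)) {
    stop("zero (or negative) reference envelope peak; cannot normalize")
  }
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(muscles)), muscles)

  per <- list(); summed <- list()
  for (cond in conds) {
    ev <- ev_of(cond)
    sum_series <- NULL
    tt <- NULL
    for (mu in muscles) {
      d <- env[env$condition == cond & env$muscle == mu, ]
      norm <- d$value / peaks[[mu]]
      avg <- stride_average(norm, d$time, ev, mass = 1,
                            n_strides = n_strides, discard = discard)$mean
      per[[length(per) + 1]] <- tibble::tibble(
        condition = cond, muscle = mu, avg_norm_emg = avg
      )
      wnorm <- weights[[mu]] * norm
      sum_series <- if (is.null(sum_series)) wnorm else sum_series + wnorm
      tt <- d$time
    }
    savg <- stride_average(sum_series, tt, ev, mass = 1,
                           n_strides = n_strides, discard = discard)$mean
    summed[[length(summed) + 1]] <- tibble::tibble(
      condition = cond, summed_avg_emg = savg
    )
  }
  list(
    per_muscle = dplyr::bind_rows(per),
    summed = dplyr::bind_rows(summed),
    reference_peaks = peaks
  )
}

#' Metabolic rate from gas exchange (Brockway equation)
#'
#' `P(t) = 16.58 * vo2 + 4.51 * vco2` (W, with flows in ml/s; the
#' canonical indirect-calorimetry coefficients), time-averaged over the
#' final `window` seconds of the trial and divided by body mass.
#'
#' @param vo2,vco2 Oxygen uptake / carbon-dioxide output series (ml/s),
#'   >= 0, sampled (possibly breath-wise, non-uniformly) at `time`.
#' @param time Sample times (s).
#' @param mass Body mass (kg).
#' @param window Averaging window (s) taken from the end of the series;
#'   default 120 s (the last 2 min of a 7-min trial).
#' @return Steady-state metabolic rate (W/kg).
#' @examples
#' brockway_rate(1, 0, time = 0, mass = 1, window = 0) # 16.58 W/kg
#' @export
brockway_rate <- function(vo2, vco2, time, mass, window = 120) {
  if (any(vo2 < 0) || any(vco2 < 0)) stop("negative flow values")
  stopifnot(mass > 0, length(vo2) == length(vco2),
            length(vo2) == length(time))
  p <- 16.58 * vo2 + 4.51 * vco2
  if (length(time) == 1) return(p / mass)
  t_end <- time[length(time)]
  if (t_end - time[1] < window) stop("series shorter than averaging window")
  keep <- time >= t_end - window
  tw <- time[keep]; pw <- p[keep]
  pracma::trapz(tw, pw) / (tw[length(tw)] - tw[1]) / mass
}

#' Biological moment by exoskeleton subtraction
#'
#' The biological contribution to a total joint moment: total minus the
#' measured exoskeleton torque, elementwise.
#'
#' @param total Total joint moment series (Nm).
#' @param exo Exoskeleton torque series (Nm), same length.
#' @return Biological moment series (Nm).
#' @export
bio_moment <- function(total, exo) {
  if (length(total) != length(exo)) stop("length mismatch")
  total - exo
}
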