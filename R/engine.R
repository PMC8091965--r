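#' @title Simulation engine
#' @description
#' Runs the reflex controller over recorded or synthetic ankle kinematics
#' in open-loop playback, optionally inside a quasi-static
#' kinematic-admittance plant emulating the user's postural response to
#' assistive torque, and executes the full Gain/Delay condition sweep.
#' @name simulation_engine
NULL

# CE-velocity kernel of the inner loop (same algebra as .ce_velocity1,
# with the parameter fields unpacked to scalars for speed)
.vel <- function(f, l_ce, a, f_max, l_opt, w, c_fl, kp, k_fv, n_fv,
                 v_max, fv_cap) {
  fp <- if (l_ce <= l_opt) 0 else {
    e <- (l_ce / l_opt - 1) / w
    kp * e * e
  }
  f_net <- f / f_max - fp
  if (f_net <= 0) return(v_max)
  afl <- a * exp(c_fl * abs((l_ce / l_opt - 1) / w)^3)
  if (afl < 1e-3) afl <- 1e-3 # activation floor, as in .ce_velocity1
  fv <- f_net / afl
  if (fv >= fv_cap) -v_max
  else if (fv <= 1) v_max * (1 - fv) / (1 + k_fv * fv)
  else v_max * (1 - fv) / (7.56 * k_fv * (n_fv - fv))
}

# Inner simulation loop. Mirrors controller_step() sample by sample (one
# shared set of scalar model helpers) but keeps the delay-line history as
# a plain vector on the uniform dt grid for speed.
.sim_core <- function(theta, stance, dt, rp, p, geom,
                      l_ce0 = NULL, a0 = NULL) {
  n <- length(theta)
  stopifnot(length(stance) == n, dt > 0)
  if (is.null(l_ce0)) l_ce0 <- .equilibrium_lce(theta[1], rp$prestim, p, geom)
  if (is.null(a0)) a0 <- rp$prestim

  f_max <- p$f_max; l_slack <- p$l_slack; k_see <- p$k_see
  toe <- p$eps_ref * p$l_slack
  l_opt <- p$l_opt; w <- p$w; c_fl <- p$c_fl
  k_fv <- p$k_fv; n_fv <- p$n_fv; v_max <- p$v_max
  kp <- p$k_pass / p$f_max
  expf <- exp(-dt / p$tau_act)
  fv_cap <- .fv_ecc_cap(p)
  gain <- rp$gain; prestim <- rp$prestim; psi <- rp$psi
  nba <- rp$norm_by_activation
  r0 <- geom$r0; th_ref <- geom$theta_ref; l_ref <- geom$l_mtu_ref
  const_arm <- geom$constant_arm
  dsteps <- rp$delay / dt

  fhist <- numeric(n)
  l_ce_v <- numeric(n); l_see_v <- numeric(n); a_v <- numeric(n)
  stim_v <- numeric(n); f_v <- numeric(n); v_v <- numeric(n)
  tau_v <- numeric(n)

  l_ce <- l_ce0; a <- a0
  for (i in seq_len(n)) {
    th <- theta[i] - th_ref
    l_mtu <- l_ref - r0 * sin(th)
    l_see <- l_mtu - l_ce
    ext <- l_see - l_slack
    f <- if (ext <= 0) 0
         else if (ext <= toe) k_see * ext * ext / (2 * toe)
         else k_see * (ext - toe / 2)
    fhist[i] <- if (nba) f / (max(a, 1e-3) * f_max) else f / f_max

    if (stance[i]) {
      idx <- i - dsteps
      d <- if (idx < 1) 0 else {
        i0 <- floor(idx)
        fr <- idx - i0
        if (fr == 0) fhist[i0] else (1 - fr) * fhist[i0] + fr * fhist[i0 + 1]
      }
      s <- prestim + gain * d
      s <- if (s > 1) 1 else if (s < 0) 0 else s
    } else {
      s <- prestim
    }

    v <- .vel(f, l_ce, a, f_max, l_opt, w, c_fl, kp, k_fv, n_fv, v_max, fv_cap)

    r <- if (const_arm) r0 else r0 * cos(th)
    tau_v[i] <- if (stance[i]) f * r * psi else 0
    l_ce_v[i] <- l_ce; l_see_v[i] <- l_see; a_v[i] <- a
    stim_v[i] <- s; f_v[i] <- f; v_v[i] <- v

    # Heun advance: stage 2 at end-of-step angle and activation
    a_next <- s + (a - s) * expf
    a_next <- if (a_next > 1) 1 else if (a_next < 0) 0 else a_next
    th_next <- (if (i < n) theta[i + 1] else theta[n]) - th_ref
    l_mtu_next <- l_ref - r0 * sin(th_next)
    l_pred <- l_ce - v * dt
    if (l_pred > 0) {
      ext2 <- l_mtu_next - l_pred - l_slack
      f2 <- if (ext2 <= 0) 0
            else if (ext2 <= toe) k_see * ext2 * ext2 / (2 * toe)
            else k_see * (ext2 - toe / 2)
      v2 <- .vel(f2, l_pred, a_next, f_max, l_opt, w, c_fl, kp, k_fv, n_fv,
                 v_max, fv_cap)
      l_ce <- l_ce - 0.5 * dt * (v + v2)
    } else {
      l_ce <- l_pred
    }
    if (!is.finite(l_ce) || l_ce <= 0) {
      stop(sprintf("simulation diverged: l_ce = %g at sample %d", l_ce, i))
    }
    a <- a_next
  }

  tibble::tibble(
    t = (seq_len(n) - 1) * dt,
    theta = theta,
    phase = ifelse(stance, "stance", "swing"),
    l_ce = l_ce_v, l_see = l_see_v, a = a_v, stim = stim_v,
    f_mtu = f_v, v_ce = v_v, torque = tau_v
  )
}

# Resample a trial's angle/omega channels onto a uniform dt grid,
# remapping heel-strike indices. No-op when the rates already agree.
.align_trial <- function(trial, dt) {
  si <- trial$time[2] - trial$time[1]
  if (abs(si - dt) < 1e-9) {
    return(list(time = trial$time, angle = trial$angle, omega = trial$omega,
                events = heel_strikes(trial)))
  }
  warning(sprintf(
    "trial sample interval %g s differs from dt = %g s; resampling", si, dt
  ))
  time <- seq(trial$time[1], trial$time[nrow(trial)], by = dt)
  angle <- stats::approx(trial$time, trial$angle, xout = time)$y
  omega <- stats::approx(trial$time, trial$omega, xout = time)$y
  hs_t <- trial$time[heel_strikes(trial)]
  events <- vapply(hs_t, function(tt) which.min(abs(time - tt)), integer(1))
  list(time = time, angle = angle, omega = omega, events = events)
}

#' Run the controller in open-loop playback over a gait trial
#'
#' Applies the reflex controller sample-by-sample along the recorded (or
#' synthetic) ankle-angle trajectory. Fully deterministic: identical
#' inputs give identical logs.
#'
#' @param trial A `gait_trial` covering at least 3 strides (early strides
#'   are treated as controller transient by the metrics stage).
#' @param rp A [reflex_params()].
#' @param p An [mtu_params()].
#' @param geom An [ankle_geometry()].
#' @param dt Controller time step (s); the trial is resampled (with a
#'   warning) if its sampling interval differs.
#' @return A tibble of class `nmm_log` with per-sample columns `t`,
#'   `theta`, `phase`, `l_ce`, `l_see`, `a`, `stim`, `f_mtu`, `v_ce`,
#'   `torque` and an `omega` column carried over from the trial, plus
#'   attributes `heel_strike`, `body_mass` and `dt`.
#' @examples
#' trial <- synth_gait(gait_spec(), n_strides = 4)
#' log <- run_playback(trial, reflex_params(gain = 1.2, delay = 0.01))
#' @export
run_playback <- function(trial, rp, p = mtu_params(),
                         geom = ankle_geometry(p = p), dt = 1e-3) {
  if (length(heel_strikes(trial)) < 4) {
    stop("trial must cover at least 3 strides")
  }
  al <- .align_trial(trial, dt)
  stance <- .stance_mask(length(al$angle), al$events,
                         attr(trial, "stance_fraction"))
  log <- .sim_core(al$angle, stance, dt, rp, p, geom)
  log$omega <- al$omega
  attr(log, "heel_strike") <- al$events
  attr(log, "body_mass") <- attr(trial, "body_mass")
  attr(log, "stance_fraction") <- attr(trial, "stance_fraction")
  attr(log, "dt") <- dt
  attr(log, "reflex_params") <- rp
  class(log) <- c("nmm_log", class(log))
  log
}

#' Quasi-static kinematic admittance plant
#'
#' A minimal stand-in for the user's postural adaptation: low-pass
#' filtered exoskeleton torque is mapped through a compliance `alpha` to a
#' plantarflexion angle offset, and the coupled human-controller system is
#' solved by fixed-point iteration over whole trials. This emulates the
#' negative feedback loop in which early assistive torque plantarflexes
#' the ankle, shortening the virtual muscle and reducing its force; it is
#' not a forward-dynamic model of the human.
#'
#' @param alpha Compliance (rad/Nm), >= 0; 0 disables adaptation.
#' @param lpf_cutoff Torque low-pass cutoff (Hz) applied before the
#'   compliance map.
#' @param max_iters Maximum fixed-point iterations.
#' @param tol Convergence tolerance on the max angle change (rad).
#' @return An object of class `admittance_model`.
#' @export
admittance_model <- function(alpha = 0.001, lpf_cutoff = 5,
                             max_iters = 30, tol = 1e-6) {
  stopifnot(alpha >= 0, lpf_cutoff > 0, max_iters >= 1, tol > 0)
  structure(list(alpha = alpha, lpf_cutoff = lpf_cutoff,
                 max_iters = max_iters, tol = tol),
            class = "admittance_model")
}

#' Run the controller inside the kinematic-admittance plant
#'
#' Iterates `theta[k+1](t) = theta_nom(t) + alpha * LPF(torque[k])(t)` to
#' a fixed point: each iteration replays the controller over the adapted
#' angle trajectory. With `alpha = 0` the fixed point is the nominal
#' trajectory and the result is bit-identical to [run_playback()].
#'
#' @inheritParams run_playback
#' @param plant An [admittance_model()].
#' @return An `nmm_log` as in [run_playback()] for the converged
#'   trajectory, with extra attributes `iterations`, `residuals` (max
#'   angle change per iteration, rad) and `converged`.
#' @export
run_adaptive <- function(trial, rp, p = mtu_params(),
                         geom = ankle_geometry(p = p),
                         plant = admittance_model(), dt = 1e-3) {
  log <- run_playback(trial, rp, p, geom, dt)
  if (plant$alpha == 0) {
    attr(log, "iterations") <- 1L
    attr(log, "residuals") <- 0
    attr(log, "converged") <- TRUE
    return(log)
  }
  theta_nom <- log$theta
  stance <- log$phase == "stance"
  events <- attr(log, "heel_strike")
  fs <- 1 / dt
  lp <- signal::butter(2, plant$lpf_cutoff / (fs / 2), type = "low")
  residuals <- numeric(0)
  theta <- theta_nom
  for (k in seq_len(plant$max_iters)) {
    offset <- plant$alpha * signal::filtfilt(lp, log$torque)
    theta_new <- theta_nom + offset
    res <- max(abs(theta_new - theta))
    residuals <- c(residuals, res)
    theta <- theta_new
    log <- .sim_core(theta, stance, dt, rp, p, geom)
    if (res < plant$tol) break
    if (k >= 3 && residuals[k] > residuals[k - 1] &&
        residuals[k - 1] > residuals[k - 2]) {
      stop(sprintf(
        paste0("admittance iteration is diverging (alpha too large?); ",
               "residual history: %s"),
        paste(signif(residuals, 4), collapse = ", ")
      ))
    }
  }
  converged <- residuals[length(residuals)] < plant$tol
  if (!converged) {
    warning(sprintf(
      "admittance iteration did not converge in %d iterations (residual %g)",
      plant$max_iters, residuals[length(residuals)]
    ))
  }
  log$omega <- c(diff(theta) / dt, (theta[length(theta)] -
                                      theta[length(theta) - 1]) / dt)
  attr(log, "heel_strike") <- events
  attr(log, "body_mass") <- attr(trial, "body_mass")
  attr(log, "stance_fraction") <- attr(trial, "stance_fraction")
  attr(log, "dt") <- dt
  attr(log, "reflex_params") <- rp
  attr(log, "iterations") <- length(residuals)
  attr(log, "residuals") <- residuals
  attr(log, "converged") <- converged
  class(log) <- c("nmm_log", class(log))
  log
}

#' The study's ten-condition Gain/Delay grid
#'
#' The default sweep: a zero-torque reference (NoPwr, psi = 0), four Gain
#' conditions (0.8, 1.2, 1.6, 2.0) at 10 ms Delay, four Delay conditions
#' (10, 20, 30, 40 ms) at Gain 1.2 (D10 shares the G1.2 parameter set),
#' and the high-Gain/high-Delay combination G2.0D40.
#'
#' @param psi Torque fraction for the powered conditions.
#' @param prestim Baseline stimulation used in every condition.
#' @return A tibble with columns `condition`, `gain`, `delay` (s), `psi`.
#' @export
study_conditions <- function(psi = 0.5, prestim = 0.01) {
  tibble::tibble(
    condition = c("NoPwr", "G0.8", "G1.2", "G1.6", "G2.0",
                  "D10", "D20", "D30", "D40", "G2.0D40"),
    gain = c(1.2, 0.8, 1.2, 1.6, 2.0, 1.2, 1.2, 1.2, 1.2, 2.0),
    delay = c(0.010, 0.010, 0.010, 0.010, 0.010,
              0.010, 0.020, 0.030, 0.040, 0.040),
    psi = c(0, rep(psi, 9)),
    prestim = prestim
  )
}

#' Run the condition sweep
#'
#' Runs every condition of the grid on the same kinematic input and
#' summarizes each run with the stride-averaged outcome metrics.
#'
#' @inheritParams run_playback
#' @param conditions A condition grid as returned by [study_conditions()]
#'   (columns `condition`, `gain`, `delay`, `psi` and optionally
#'   `prestim`).
#' @param mode `"playback"` (open loop) or `"adaptive"` (admittance
#'   plant).
#' @param plant An [admittance_model()]; used when `mode = "adaptive"`.
#' @param n_strides,discard Strides used / discarded when summarizing,
#'   passed to [stride_metrics()].
#' @return An object of class `nmm_sweep`: a list with `metrics` (tibble,
#'   one row per condition: `avg_torque` Nm/kg, `net_power` W/kg,
#'   `n_strides_used`) and `logs` (named list of `nmm_log`s).
#' @examples
#' trial <- synth_gait(gait_spec(), n_strides = 4)
#' sw <- run_sweep(trial, conditions = study_conditions()[1:2, ])
#' sw$metrics
#' @export
run_sweep <- function(trial, conditions = study_conditions(),
                      p = mtu_params(), geom = ankle_geometry(p = p),
                      mode = c("playback", "adaptive"),
                      plant = admittance_model(), dt = 1e-3,
                      n_strides = 10, discard = 2) {
  mode <- match.arg(mode)
  req <- c("condition", "gain", "delay", "psi")
  if (!all(req %in% names(conditions))) {
    stop("conditions must have columns: ", paste(req, collapse = ", "))
  }
  logs <- list()
  rows <- list()
  for (i in seq_len(nrow(conditions))) {
    cd <- conditions[i, ]
    rp <- reflex_params(
      gain = cd$gain, delay = cd$delay, psi = cd$psi,
      prestim = if ("prestim" %in% names(cd)) cd$prestim else 0.01
    )
    log <- if (mode == "playback") {
      run_playback(trial, rp, p, geom, dt)
    } else {
      run_adaptive(trial, rp, p, geom, plant, dt)
    }
    logs[[cd$condition]] <- log
    m <- stride_metrics(log, n_strides = n_strides, discard = discard)
    rows[[i]] <- dplyr::bind_cols(tibble::tibble(condition = cd$condition), m)
  }
  structure(
    list(metrics = dplyr::bind_rows(rows), logs = logs,
         meta = list(mode = mode, dt = dt, conditions = conditions)),
    class = "nmm_sweep"
  )
}

#' @export
print.nmm_sweep <- function(x, ...) {
  cat(sprintf("<nmm_sweep>  %d conditions, mode = %s, dt = %g s\n",
              nrow(x$metrics), x$meta$mode, x$meta$dt))
  print(x$metrics)
  invisible(x)
}

#' @rdname run_sweep
#' @param x An `nmm_sweep`.
#' @param ... Unused.
#' @export
tidy.nmm_sweep <- function(x, ...) x$metrics
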