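#' @title Positive force-feedback reflex pathway
#' @description
#' The reflex loop that stimulates the virtual muscle: MTU force is
#' normalized by the maximal isometric force, multiplied by the reflex
#' Gain, delayed by the reflex Delay, offset by a small pre-stimulation
#' and clamped to \[0, 1\]. During stance the resulting MTU force, acting
#' through the virtual moment arm and scaled by the torque fraction psi,
#' becomes the commanded exoskeleton torque; during swing the cable is
#' slack and the commanded torque is zero.
#' @name reflex_controller
NULL

# ---- delay line --------------------------------------------------------

#' Create a delay line for the reflex pathway
#'
#' A growable buffer of (time, normalized force) samples with linear
#' interpolation between samples. Reads before the first stored sample
#' (cold start) return 0.
#'
#' @param capacity Initial buffer capacity (samples); grows as needed.
#' @return An environment of class `delay_line`.
#' @export
delay_line <- function(capacity = 1024) {
  e <- new.env(parent = emptyenv())
  e$t <- numeric(capacity)
  e$f <- numeric(capacity)
  e$n <- 0L
  class(e) <- "delay_line"
  e
}

#' Push a sample into a delay line
#'
#' @param dl A [delay_line()].
#' @param t Timestamp (s); must exceed the previous timestamp.
#' @param f Normalized force sample.
#' @return The delay line, invisibly.
#' @export
push_delay <- function(dl, t, f) {
  n <- dl$n
  if (n > 0L && t <= dl$t[n]) stop("delay line timestamps must increase")
  if (n == length(dl$t)) {
    dl$t <- c(dl$t, numeric(length(dl$t)))
    dl$f <- c(dl$f, numeric(length(dl$f)))
  }
  dl$n <- n + 1L
  dl$t[dl$n] <- t
  dl$f[dl$n] <- f
  invisible(dl)
}

#' Read a delay line at an arbitrary time
#'
#' Linear interpolation between stored samples; times before the first
#' sample return 0 (cold start), times at or after the last sample return
#' the last sample.
#'
#' @param dl A [delay_line()].
#' @param t Query time (s).
#' @return Interpolated normalized force.
#' @export
read_delay <- function(dl, t) {
  n <- dl$n
  if (n == 0L || t < dl$t[1]) return(0)
  if (t >= dl$t[n]) return(dl$f[n])
  i <- findInterval(t, dl$t[seq_len(n)])
  t0 <- dl$t[i]; t1 <- dl$t[i + 1L]
  w <- (t - t0) / (t1 - t0)
  (1 - w) * dl$f[i] + w * dl$f[i + 1L]
}

# ---- stimulation and torque -------------------------------------------

#' Reflex stimulation from delayed force feedback
#'
#' `S(t) = clamp(prestim + gain * F_norm(t - delay), 0, 1)` where
#' `F_norm` is the normalized-force history held in the delay line. An
#' empty delay line (cold start) yields `prestim`.
#'
#' @param dl A [delay_line()] holding the normalized-force history.
#' @param t Current time (s), >= 0.
#' @param rp A [reflex_params()].
#' @return Stimulation in \[0, 1\].
#' @export
stimulation <- function(dl, t, rp) {
  if (t < 0) stop("t must be >= 0")
  s <- rp$prestim + rp$gain * read_delay(dl, t - rp$delay)
  min(max(s, 0), 1)
}

#' Exoskeleton torque command
#'
#' During stance the virtual ankle moment `F_MTU * r(theta)` is scaled by
#' the torque fraction `psi`; during swing the slack-adjustment behaviour
#' is modelled as zero commanded torque.
#'
#' @param f_mtu MTU force (N), >= 0; may be a vector.
#' @param theta Ankle angle (rad), recycled against `f_mtu`.
#' @param rp A [reflex_params()].
#' @param geom An [ankle_geometry()].
#' @param phase `"stance"` or `"swing"` (recycled).
#' @return Commanded exoskeleton torque (Nm), >= 0.
#' @examples
#' exo_torque(1000, 0, reflex_params(psi = 0.5), ankle_geometry(), "stance")
#' @export
exo_torque <- function(f_mtu, theta, rp, geom, phase = "stance") {
  if (any(f_mtu < 0)) stop("f_mtu must be >= 0")
  phase <- match.arg(phase, c("stance", "swing"), several.ok = TRUE)
  n <- max(length(f_mtu), length(theta), length(phase))
  f_mtu <- rep_len(f_mtu, n); theta <- rep_len(theta, n)
  phase <- rep_len(phase, n)
  tau <- f_mtu * moment_arm(theta, geom) * rp$psi
  tau[phase == "swing"] <- 0
  tau
}

# ---- controller state --------------------------------------------------

# static CE equilibrium: see_force(l_mtu - l) == f_max * (a0 * fl(l) + fp(l))
.equilibrium_lce <- function(theta0, a0, p, geom) {
  l_mtu <- mtu_length(theta0, geom)
  g <- function(l) {
    .see_force1(l_mtu - l, p) -
      p$f_max * (a0 * .force_length1(l, p) + .passive_force1(l, p))
  }
  lower <- 0.3 * p$l_opt
  upper <- max(l_mtu - p$l_slack, p$l_opt)
  res <- tryCatch(
    stats::uniroot(g, lower = lower, upper = upper, tol = 1e-12)$root,
    error = function(e) NA_real_
  )
  if (!is.finite(res)) {
    warning("equilibrium solve failed; falling back to l_ce = l_opt")
    res <- p$l_opt
  }
  res
}

#' Reset the reflex controller to a fresh state
#'
#' Returns a controller state with an empty (zero-filled) delay line,
#' activation at `prestim`, and the CE length at the static equilibrium
#' for the initial ankle angle (solved numerically; falls back to `l_opt`
#' with a warning if the solve fails).
#'
#' @param rp A [reflex_params()].
#' @param p An [mtu_params()].
#' @param geom An [ankle_geometry()].
#' @param theta0 Initial ankle angle (rad).
#' @return An environment of class `reflex_controller` holding the MTU
#'   state and delay line.
#' @export
controller_reset <- function(rp, p, geom, theta0 = 0) {
  ctrl <- new.env(parent = emptyenv())
  ctrl$t <- 0
  ctrl$l_ce <- .equilibrium_lce(theta0, rp$prestim, p, geom)
  ctrl$a <- rp$prestim
  ctrl$dl <- delay_line()
  class(ctrl) <- "reflex_controller"
  ctrl
}

#' Advance the controller one time-step
#'
#' One step of the closed reflex loop at the current sample: evaluate the
#' MTU force at the current CE length and ankle angle, push its normalized
#' value into the delay line, read the delayed value to form the
#' stimulation (stance) or hold `prestim` (swing; the virtual muscle keeps
#' integrating), emit the commanded torque, and advance CE length and
#' activation by `dt`.
#'
#' @param ctrl A [controller_reset()] state (mutated in place).
#' @param theta Ankle angle (rad) at the current sample.
#' @param phase `"stance"` or `"swing"`.
#' @param dt Time step (s), > 0.
#' @param rp,p,geom Controller configuration, see [controller_reset()].
#' @param theta_next Ankle angle at the end of the step (defaults to
#'   `theta`); used by the second stage of the Heun CE advance.
#' @return A list with elements `state` (an [mtu_state()] snapshot at the
#'   current sample), `torque` (Nm) and `stim`.
#' @export
controller_step <- function(ctrl, theta, phase, dt, rp, p, geom,
                            theta_next = theta) {
  if (dt <= 0) stop("dt must be > 0")
  phase <- match.arg(phase, c("stance", "swing"))
  l_mtu <- mtu_length(theta, geom)
  l_see <- l_mtu - ctrl$l_ce
  f_mtu <- .see_force1(l_see, p)
  f_norm <- if (rp$norm_by_activation) {
    f_mtu / (max(ctrl$a, 1e-3) * p$f_max)
  } else {
    f_mtu / p$f_max
  }
  push_delay(ctrl$dl, ctrl$t, f_norm)
  s <- if (phase == "stance") stimulation(ctrl$dl, ctrl$t, rp) else rp$prestim
  v_ce <- .ce_velocity1(f_mtu, ctrl$l_ce, ctrl$a, p)
  r <- if (geom$constant_arm) geom$r0 else geom$r0 * cos(theta - geom$theta_ref)
  tau <- if (phase == "stance") f_mtu * r * rp$psi else 0
  snap <- mtu_state(
    t = ctrl$t, l_ce = ctrl$l_ce, a = ctrl$a,
    l_mtu = l_mtu, l_see = l_see, f_mtu = f_mtu, v_ce = v_ce
  )
  a_next <- .activation_step1(ctrl$a, s, dt, p)
  adv <- .ce_advance1(ctrl$l_ce, ctrl$a, a_next, l_mtu,
                      mtu_length(theta_next, geom), dt, p)
  ctrl$l_ce <- adv$l_ce
  ctrl$a <- a_next
  ctrl$t <- ctrl$t + dt
  if (!is.finite(ctrl$l_ce) || ctrl$l_ce <= 0) {
    stop(sprintf("controller_step: CE length left the valid range at t = %g",
                 ctrl$t))
  }
  list(state = snap, torque = tau, stim = s)
}
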