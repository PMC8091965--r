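#' @title Hill-type muscle-tendon unit primitives
#' @description
#' The building blocks of the virtual plantarflexor: musculoskeletal
#' geometry, the nonlinear series elastic element (SEE), the contractile
#' element (CE) force-length / force-velocity / passive curves, the CE
#' velocity obtained by inverting the force balance, and first-order
#' activation dynamics. All exported functions are vectorized over their
#' first argument; internal scalar versions are shared with the simulation
#' loop so that a single definition of the model is exercised everywhere.
#' @name hill_mtu
NULL

# ---- geometry ----------------------------------------------------------

#' MTU length from ankle angle
#'
#' `L_MTU(theta) = l_mtu_ref - r0 * sin(theta - theta_ref)`: plantarflexion
#' (positive angle) shortens the MTU, dorsiflexion lengthens it. The
#' negative angular derivative of this map is the moment arm, see
#' [moment_arm()].
#'
#' @param theta Ankle angle (rad), plantarflexion positive. Must lie within
#'   pi/2 of `geom$theta_ref`.
#' @param geom An [ankle_geometry()].
#' @return MTU length (m).
#' @examples
#' g <- ankle_geometry()
#' mtu_length(0, g)
#' mtu_length(-0.1, g) # dorsiflexed: longer
#' @export
mtu_length <- function(theta, geom) {
  if (any(!is.finite(theta))) stop("theta must be finite")
  if (any(abs(theta - geom$theta_ref) > pi / 2)) {
    stop("theta outside +/- pi/2 of theta_ref")
  }
  geom$l_mtu_ref - geom$r0 * sin(theta - geom$theta_ref)
}

#' Ankle moment arm
#'
#' `r(theta) = r0 * cos(theta - theta_ref)`, the negative angular
#' derivative of [mtu_length()]. If the geometry was built with
#' `constant_arm = TRUE` this returns `r0` regardless of angle (torque map
#' only; the length map always uses the angle-dependent form).
#'
#' @inheritParams mtu_length
#' @return Moment arm (m), positive over the physiological range.
#' @export
moment_arm <- function(theta, geom) {
  if (any(!is.finite(theta))) stop("theta must be finite")
  if (any(abs(theta - geom$theta_ref) > pi / 2)) {
    stop("theta outside +/- pi/2 of theta_ref")
  }
  if (geom$constant_arm) rep_len(geom$r0, length(theta))
  else geom$r0 * cos(theta - geom$theta_ref)
}

# ---- series elastic element -------------------------------------------

# scalar SEE force; shared by the exported wrapper and the sim loop
.see_force1 <- function(l_see, p) {
  ext <- l_see - p$l_slack
  if (ext <= 0) return(0)
  toe <- p$eps_ref * p$l_slack
  if (ext <= toe) {
    # quadratic toe, slope-continuous with the linear region at ext = toe
    p$k_see * ext * ext / (2 * toe)
  } else {
    p$k_see * (ext - toe / 2)
  }
}

#' Series elastic element force
#'
#' Nonlinear tendon force-extension curve: zero when slack, a quadratic
#' toe region up to strain `eps_ref`, then linear with stiffness `k_see`.
#' Force and tangent stiffness are both continuous at the toe/linear
#' junction, and the curve is monotone nondecreasing.
#'
#' @param l_see SEE length (m); may be a vector.
#' @param p An [mtu_params()].
#' @return SEE force (N), >= 0.
#' @examples
#' p <- mtu_params()
#' see_force(p$l_slack, p)                  # slack: 0 N
#' see_force(p$l_slack * (1 + p$eps_ref), p) # end of toe region
#' @export
see_force <- function(l_see, p) {
  if (any(!is.finite(l_see))) stop("l_see must be finite")
  vapply(l_see, .see_force1, numeric(1), p = p)
}

# ---- contractile element curves ---------------------------------------

.force_length1 <- function(l_ce, p) {
  exp(p$c_fl * abs((l_ce / p$l_opt - 1) / p$w)^3)
}

#' Active force-length relationship
#'
#' Bell-shaped curve `exp(c_fl * |(L/l_opt - 1)/w|^3)`, equal to 1 at the
#' optimal length and to `exp(c_fl)` (0.05 with defaults) at
#' `L = l_opt * (1 +/- w)`; symmetric about `l_opt`.
#'
#' @param l_ce CE length (m), > 0; may be a vector.
#' @inheritParams see_force
#' @return Dimensionless force scale in (0, 1].
#' @export
force_length <- function(l_ce, p) {
  stopifnot(all(l_ce > 0))
  .force_length1(l_ce, p)
}

.force_velocity1 <- function(v_ce, p) {
  if (v_ce >= p$v_max) {
    0
  } else if (v_ce >= 0) {
    (p$v_max - v_ce) / (p$v_max + p$k_fv * v_ce)
  } else {
    # lengthening: saturating rise toward the eccentric plateau n_fv
    p$n_fv - (p$n_fv - 1) * p$v_max / (p$v_max - 7.56 * p$k_fv * v_ce)
  }
}

#' Force-velocity relationship
#'
#' Concentric side: Hill hyperbola `(v_max - v)/(v_max + k_fv * v)`,
#' clipped at 0 for `v >= v_max`. Eccentric side (lengthening, `v < 0`):
#' monotone rise saturating at the plateau `n_fv`. `fv(0) = 1` and the
#' curve is strictly decreasing in shortening velocity below `v_max`.
#'
#' @param v_ce CE velocity (m/s), shortening positive; may be a vector.
#' @inheritParams see_force
#' @return Dimensionless force scale in \[0, n_fv).
#' @examples
#' p <- mtu_params()
#' force_velocity(0, p)        # 1
#' force_velocity(p$v_max, p)  # 0
#' @export
force_velocity <- function(v_ce, p) {
  if (any(!is.finite(v_ce))) stop("v_ce must be finite")
  vapply(v_ce, .force_velocity1, numeric(1), p = p)
}

.passive_force1 <- function(l_ce, p) {
  if (l_ce <= p$l_opt) return(0)
  e <- (l_ce / p$l_opt - 1) / p$w
  p$k_pass / p$f_max * e * e
}

#' Passive force-length relationship
#'
#' Dimensionless passive CE force: zero at or below the optimal length,
#' quadratic in normalized strain above it, reaching `k_pass / f_max`
#' (1 with defaults) at `L = (1 + w) * l_opt`.
#'
#' @inheritParams force_length
#' @return Dimensionless passive force, >= 0 (multiply by `f_max` for N).
#' @export
passive_force <- function(l_ce, p) {
  stopifnot(all(l_ce > 0))
  vapply(l_ce, .passive_force1, numeric(1), p = p)
}

# ---- CE velocity by inversion of the force balance --------------------

# largest fv reachable on the eccentric branch before the lengthening
# clamp at v = -v_max
.fv_ecc_cap <- function(p) {
  p$n_fv - (p$n_fv - 1) / (1 + 7.56 * p$k_fv)
}

.ce_velocity1 <- function(f_mtu, l_ce, a, p) {
  afl <- a * .force_length1(l_ce, p)
  f_net <- f_mtu / p$f_max - .passive_force1(l_ce, p)
  # activation floor: with vanishing active capacity the force balance
  # degenerates to a relay; the floor keeps the inversion continuous in
  # the net force so passive states settle instead of chattering
  if (afl < 1e-3) afl <- 1e-3
  if (f_net <= 0) return(p$v_max) # demand at/below passive: full shortening
  fv <- f_net / afl
  if (fv >= .fv_ecc_cap(p)) {
    -p$v_max
  } else if (fv <= 1) {
    # concentric inversion of the Hill hyperbola
    p$v_max * (1 - fv) / (1 + p$k_fv * fv)
  } else {
    # eccentric inversion
    p$v_max * (1 - fv) / (7.56 * p$k_fv * (p$n_fv - fv))
  }
}

#' CE velocity from the force balance
#'
#' Inverts `F_MTU = f_max * (a * fl(L_CE) * fv(v) + fp(L_CE))` for the CE
#' velocity `v` (shortening positive). When the required force-velocity
#' value exceeds what the eccentric branch can deliver before the
#' lengthening clamp, or active capacity `a * fl` vanishes under load, the
#' velocity is clamped to `-v_max`; when the demand is at or below the
#' passive level it is clamped to `+v_max` (unloaded shortening). The
#' active capacity is floored at 1e-3 so the inversion stays continuous in
#' the net force as activation vanishes (passive states then settle to a
#' static equilibrium instead of chattering). On unclamped inputs the
#' inversion is algebraically exact: substituting the result back through
#' [force_velocity()] recovers the required value to machine precision.
#'
#' @param f_mtu MTU force (N), >= 0.
#' @param l_ce CE length (m), > 0.
#' @param a Activation in \[0, 1\].
#' @inheritParams see_force
#' @return CE velocity (m/s) in `[-v_max, v_max]`, shortening positive.
#' @export
ce_velocity <- function(f_mtu, l_ce, a, p) {
  if (any(f_mtu < 0)) stop("f_mtu must be >= 0")
  if (any(a < 0 | a > 1)) stop("activation must be in [0, 1]")
  stopifnot(all(l_ce > 0))
  n <- max(length(f_mtu), length(l_ce), length(a))
  f_mtu <- rep_len(f_mtu, n); l_ce <- rep_len(l_ce, n); a <- rep_len(a, n)
  vapply(seq_len(n), function(i) .ce_velocity1(f_mtu[i], l_ce[i], a[i], p),
         numeric(1))
}

# ---- activation dynamics ----------------------------------------------

.activation_step1 <- function(a, stim, dt, p) {
  # exact one-step solution of da/dt = (stim - a) / tau_act
  a2 <- stim + (a - stim) * exp(-dt / p$tau_act)
  min(max(a2, 0), 1)
}

#' One step of first-order activation dynamics
#'
#' Advances activation by `dt` under the lag `da/dt = (stim - a)/tau_act`,
#' using the exact exponential update (so constant stimulation yields the
#' closed-form solution at any step size), clamped to \[0, 1\]. `a = stim`
#' is an exact fixed point.
#'
#' @param a Current activation in \[0, 1\]; may be a vector.
#' @param stim Stimulation in \[0, 1\].
#' @param dt Time step (s), > 0.
#' @inheritParams see_force
#' @return New activation in \[0, 1\].
#' @export
activation_step <- function(a, stim, dt, p) {
  if (any(dt <= 0)) stop("dt must be > 0")
  if (any(a < 0 | a > 1) || any(stim < 0 | stim > 1)) {
    stop("a and stim must be in [0, 1]")
  }
  n <- max(length(a), length(stim))
  a <- rep_len(a, n); stim <- rep_len(stim, n)
  vapply(seq_len(n), function(i) .activation_step1(a[i], stim[i], dt, p),
         numeric(1))
}

# ---- composed state update --------------------------------------------

#' Instantaneous MTU state
#'
#' @param t Time (s).
#' @param l_ce CE length (m).
#' @param a Activation in \[0, 1\].
#' @param l_mtu,l_see,f_mtu,v_ce Derived quantities (filled by
#'   [mtu_step()]); `l_see = l_mtu - l_ce` always holds exactly.
#' @return A `mtu_state` list.
#' @export
mtu_state <- function(t = 0, l_ce, a = 0, l_mtu = NA_real_,
                      l_see = NA_real_, f_mtu = NA_real_, v_ce = 0) {
  stopifnot(l_ce > 0, a >= 0, a <= 1)
  structure(
    list(t = t, l_ce = l_ce, a = a, l_mtu = l_mtu, l_see = l_see,
         f_mtu = f_mtu, v_ce = v_ce),
    class = "mtu_state"
  )
}

# Heun (explicit trapezoid) advance of the CE length over one step:
# stage 1 at the current angle/activation, stage 2 at the end-of-step
# angle and activation. Returns list(l_ce, v1).
.ce_advance1 <- function(l_ce, a, a_next, l_mtu, l_mtu_next, dt, p) {
  f1 <- .see_force1(l_mtu - l_ce, p)
  v1 <- .ce_velocity1(f1, l_ce, a, p)
  l_pred <- l_ce - v1 * dt
  if (l_pred <= 0) return(list(l_ce = l_pred, v1 = v1))
  f2 <- .see_force1(l_mtu_next - l_pred, p)
  v2 <- .ce_velocity1(f2, l_pred, a_next, p)
  list(l_ce = l_ce - 0.5 * dt * (v1 + v2), v1 = v1)
}

#' Advance the MTU one control time-step
#'
#' Composes the model equations for one step of length `dt`: MTU length
#' from the ankle angle, SEE length as the difference of MTU and CE
#' lengths, MTU force from the SEE curve, CE velocity by inverting the
#' force balance, and the exact exponential activation update. The CE
#' length is advanced with Heun's method (explicit trapezoid: a second
#' velocity evaluation at the predicted CE length, end-of-step activation
#' and end-of-step angle), which keeps the fixed 1 ms control step while
#' giving second-order accuracy under time-step refinement.
#'
#' @param state An [mtu_state()].
#' @param theta Ankle angle (rad) at the current sample.
#' @param stim Stimulation in \[0, 1\].
#' @param dt Time step (s), > 0.
#' @param p An [mtu_params()].
#' @param geom An [ankle_geometry()].
#' @param theta_next Ankle angle at the end of the step (defaults to
#'   `theta`, i.e. a held input).
#' @return The advanced `mtu_state`: `l_ce`, `a`, `t` advanced; `l_mtu`,
#'   `l_see`, `f_mtu` re-evaluated at the advanced CE length (so
#'   `l_see = l_mtu - l_ce` holds exactly); `v_ce` is the stage-1
#'   velocity used for the advance.
#' @examples
#' p <- mtu_params(); g <- ankle_geometry(p = p)
#' s <- mtu_state(l_ce = p$l_opt)
#' s <- mtu_step(s, theta = 0, stim = 0, dt = 1e-3, p = p, geom = g)
#' @export
mtu_step <- function(state, theta, stim, dt, p, geom, theta_next = theta) {
  if (dt <= 0) stop("dt must be > 0")
  l_mtu <- mtu_length(theta, geom)
  l_mtu_next <- mtu_length(theta_next, geom)
  a_new <- .activation_step1(state$a, stim, dt, p)
  adv <- .ce_advance1(state$l_ce, state$a, a_new, l_mtu, l_mtu_next, dt, p)
  l_ce_new <- adv$l_ce
  if (!is.finite(l_ce_new) || l_ce_new <= 0) {
    stop(sprintf(
      "mtu_step: CE length left the valid range (l_ce = %g at t = %g)",
      l_ce_new, state$t + dt
    ))
  }
  # derived quantities evaluated at the advanced CE length so the
  # returned state satisfies l_see = l_mtu - l_ce exactly
  l_see_new <- l_mtu_next - l_ce_new
  mtu_state(
    t = state$t + dt, l_ce = l_ce_new, a = a_new,
    l_mtu = l_mtu_next, l_see = l_see_new,
    f_mtu = .see_force1(l_see_new, p), v_ce = adv$v1
  )
}
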