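#' Muscle-tendon parameters for the lumped virtual plantarflexor
#'
#' Constructs the parameter set of the Hill-type virtual muscle-tendon unit
#' (MTU): a contractile element (CE) with active force-length (F-L),
#' force-velocity (F-V) and passive properties, in series with a nonlinear
#' series elastic element (SEE) modelling the tendon.
#'
#' Defaults follow the study parameter set for the lumped plantarflexors
#' (`f_max` = 6000 N, `l_opt` = 0.04 m, `v_max` = 0.326 m/s, `k_see` =
#' 315.4 N/mm). Curve-shape constants (`w`, `c_fl`, `k_fv`, `n_fv`) are the
#' standard reflex-walking-model values; they are exposed here so that any
#' alternative calibration can be supplied.
#'
#' @param f_max Maximal isometric CE force (N).
#' @param l_opt Optimal CE length (m).
#' @param v_max Maximal CE shortening velocity (m/s); shortening is positive.
#' @param k_see SEE linear-region stiffness in N/mm (converted to N/m
#'   internally; see `$k_see` in the returned object).
#' @param l_slack SEE slack length (m).
#' @param eps_ref SEE toe-region reference strain (dimensionless); the
#'   force-extension curve is quadratic up to this strain, then linear with
#'   slope `k_see`, slope-continuous at the junction.
#' @param w Width of the force-length relationship (dimensionless fraction
#'   of `l_opt`).
#' @param c_fl Shape exponent coefficient of the force-length curve;
#'   `fl = exp(c_fl * |(L/l_opt - 1)/w|^3)` so `exp(c_fl)` is the value at
#'   the curve width. Must be negative.
#' @param k_fv Curvature constant of the concentric Hill hyperbola.
#' @param n_fv Eccentric (lengthening) force plateau, > 1.
#' @param k_pass Passive-force scale (N); passive CE force reaches `k_pass`
#'   at `L = (1 + w) * l_opt`.
#' @param tau_act Activation time constant (s) of the first-order
#'   stimulation-to-activation lag.
#'
#' @return An object of class `mtu_params` (a named list with `k_see` in
#'   N/m and `k_see_nmm` retaining the N/mm input).
#' @examples
#' p <- mtu_params()
#' p$f_max
#' @export
mtu_params <- function(f_max = 6000,
                       l_opt = 0.04,
                       v_max = 0.326,
                       k_see = 315.4,
                       l_slack = 0.26,
                       eps_ref = 0.04,
                       w = 0.56,
                       c_fl = log(0.05),
                       k_fv = 5,
                       n_fv = 1.5,
                       k_pass = f_max,
                       tau_act = 0.01) {
  stopifnot(
    is.numeric(f_max), f_max > 0,
    l_opt > 0, v_max > 0, k_see > 0, l_slack > 0,
    eps_ref > 0, eps_ref < 0.10,
    w > 0, w < 1,
    c_fl < 0,
    k_fv > 0, n_fv > 1,
    k_pass > 0, tau_act > 0
  )
  structure(
    list(
      f_max = f_max, l_opt = l_opt, v_max = v_max,
      k_see = k_see * 1000, # N/m internally
      k_see_nmm = k_see,
      l_slack = l_slack, eps_ref = eps_ref,
      w = w, c_fl = c_fl, k_fv = k_fv, n_fv = n_fv,
      k_pass = k_pass, tau_act = tau_act
    ),
    class = "mtu_params"
  )
}

#' Virtual ankle-joint geometry
#'
#' Maps ankle angle to MTU length and moment arm. The moment arm is
#' `r0 * cos(theta - theta_ref)` and MTU length is
#' `l_mtu_ref - r0 * sin(theta - theta_ref)`, so plantarflexion (positive
#' angle) shortens the MTU and dorsiflexion lengthens it, and the moment
#' arm equals minus the angular derivative of MTU length. Setting
#' `constant_arm = TRUE` freezes the moment arm used for torque output at
#' `r0` (the MTU length map is unchanged).
#'
#' @param r0 Peak moment arm (m).
#' @param theta_ref Ankle angle (rad) at which the moment arm peaks;
#'   0 = neutral ankle.
#' @param l_mtu_ref MTU length (m) at `theta_ref`. Default places the CE at
#'   its optimal length with the tendon just taut.
#' @param constant_arm Use a constant moment arm `r0` in the torque map.
#' @param p Optional [mtu_params()] used for the default `l_mtu_ref` and a
#'   consistency check `l_mtu_ref >= l_slack + l_opt * (1 - w)`.
#' @return An object of class `ankle_geometry`.
#' @examples
#' g <- ankle_geometry()
#' moment_arm(0, g)
#' @export
ankle_geometry <- function(r0 = 0.05,
                           theta_ref = 0,
                           l_mtu_ref = NULL,
                           constant_arm = FALSE,
                           p = mtu_params()) {
  if (is.null(l_mtu_ref)) l_mtu_ref <- p$l_slack + p$l_opt
  stopifnot(r0 > 0, is.finite(theta_ref), l_mtu_ref > 0)
  if (l_mtu_ref < p$l_slack + p$l_opt * (1 - p$w)) {
    stop("l_mtu_ref too short: CE would sit below its force-length range")
  }
  structure(
    list(
      r0 = r0, theta_ref = theta_ref, l_mtu_ref = l_mtu_ref,
      constant_arm = isTRUE(constant_arm)
    ),
    class = "ankle_geometry"
  )
}

#' Reflex-pathway parameters defining one controller condition
#'
#' One experimental condition of the positive force-feedback reflex
#' controller: the normalized MTU force is multiplied by `gain`, delayed by
#' `delay` seconds, added to a baseline `prestim`, clamped to \[0, 1\] and
#' fed back as muscle stimulation. `psi` scales the virtual ankle moment to
#' the commanded exoskeleton torque fraction (0.5 in the study; 0 gives the
#' zero-torque condition).
#'
#' @param gain Reflex loop gain (dimensionless, >= 0). Study grid 0.8-2.0.
#' @param delay Reflex loop delay (s, >= 0). Study grid 0.010-0.040.
#' @param prestim Baseline (pre-)stimulation seeding the positive feedback
#'   loop, in \[0, 0.1\].
#' @param psi Torque fraction scaling virtual ankle moment to exoskeleton
#'   torque, in \[0, 1\].
#' @param norm_by_activation If `TRUE`, normalize the fed-back force by
#'   `a * f_max` instead of `f_max` (alternative reading of the pathway;
#'   guarded against division by activations below 1e-3).
#' @return An object of class `reflex_params`.
#' @examples
#' reflex_params(gain = 1.2, delay = 0.010)
#' @export
reflex_params <- function(gain = 1.2,
                          delay = 0.010,
                          prestim = 0.01,
                          psi = 0.5,
                          norm_by_activation = FALSE) {
  stopifnot(
    gain >= 0, delay >= 0,
    prestim >= 0, prestim <= 0.1,
    psi >= 0, psi <= 1
  )
  structure(
    list(
      gain = gain, delay = delay, prestim = prestim, psi = psi,
      norm_by_activation = isTRUE(norm_by_activation)
    ),
    class = "reflex_params"
  )
}

#' @export
print.mtu_params <- function(x, ...) {
  cat("<mtu_params>  Hill-type virtual muscle-tendon unit\n")
  cat(sprintf("  F_max %g N | L_opt %g m | V_max %g m/s | k_SEE %g N/mm\n",
              x$f_max, x$l_opt, x$v_max, x$k_see_nmm))
  cat(sprintf("  L_slack %g m | eps_ref %g | w %g | tau_act %g s\n",
              x$l_slack, x$eps_ref, x$w, x$tau_act))
  invisible(x)
}

#' @export
print.reflex_params <- function(x, ...) {
  cat(sprintf(
    "<reflex_params>  Gain %g | Delay %g ms | prestim %g | psi %g\n",
    x$gain, 1000 * x$delay, x$prestim, x$psi
  ))
  invisible(x)
}

#' @export
print.ankle_geometry <- function(x, ...) {
  cat(sprintf(
    "<ankle_geometry>  r0 %g m | theta_ref %g rad | L_MTU_ref %g m%s\n",
    x$r0, x$theta_ref, x$l_mtu_ref,
    if (x$constant_arm) " | constant moment arm" else ""
  ))
  invisible(x)
}
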