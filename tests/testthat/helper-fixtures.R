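# shared fixtures: study-default parameter set and a small noiseless trial
default_p <- mtu_params()
default_geom <- ankle_geometry(p = default_p)

# noiseless 6-stride trial used across engine/metrics tests
fixture_trial <- synth_gait(gait_spec(), n_strides = 6)

# geometry whose isometric operating point puts the CE at its optimal
# length exactly when the SEE carries f_max (MTU length = slack +
# extension-at-f_max + l_opt)
isometric_geom <- function(p = default_p) {
  ext_fmax <- p$f_max / p$k_see + p$eps_ref * p$l_slack / 2
  ankle_geometry(l_mtu_ref = p$l_slack + ext_fmax + p$l_opt, p = p)
}

# run mtu_step over a prescribed angle sequence, returning the force trace
run_mtu_trace <- function(theta, stim, dt, p = default_p, geom = default_geom,
                          l_ce0 = p$l_opt, a0 = 0) {
  s <- mtu_state(l_ce = l_ce0, a = a0)
  n <- length(theta)
  f <- numeric(n)
  for (i in seq_len(n)) {
    th_next <- if (i < n) theta[i + 1] else theta[n]
    s <- mtu_step(s, theta[i], stim, dt, p, geom, theta_next = th_next)
    f[i] <- s$f_mtu
  }
  list(force = f, state = s)
}
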