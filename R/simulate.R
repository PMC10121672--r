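#' Protocol of one simulated dynamometry trial
#'
#' @param omega Target angular velocity in deg/s (0 to 200).  `omega = 0`
#'   denotes the fixed-end reference condition simulated at `sample_angle`.
#' @param theta_start,theta_end Rotation range in degrees (defaults -15 to
#'   +15: 15 deg dorsiflexion to 15 deg plantar flexion).
#' @param preload Preload fraction: 0 (non-preloaded: the muscle rests until
#'   rotation onset, when it is maximally excited), 0.5 (fixed-end preload to
#'   50% of the fully excited steady force), or 1 (fixed-end preload to the
#'   fully excited steady state).
#' @param sample_angle Angle at which the torque-angular-velocity profile is
#'   sampled, degrees (default 0).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(omega, theta_start = -15, theta_end = 15,
                          preload = 0, sample_angle = 0) {
  stopifnot(omega >= 0, omega <= 200, theta_start < theta_end,
            preload %in% c(0, 0.5, 1))
  structure(list(omega = omega, theta_start = theta_start,
                 theta_end = theta_end, preload = preload,
                 sample_angle = sample_angle),
            class = "protocol_spec")
}

#' Fiber velocity from the damped force balance
#'
#' Solves the along-tendon force balance
#' `f_T(e) [+ beta_T v_T / f_o] = (a f_L f_V(v) + f_PE + beta v) cos(alpha)`
#' for the normalized fiber velocity at an instantaneous state.  The
#' concentric branch reduces to a quadratic through the Hill hyperbola; the
#' eccentric branch is solved by safeguarded Newton iteration.
#'
#' @param a Activation in `[0, 1]`.
#' @param l_CE Fiber length in m.
#' @param theta Ankle angle in degrees.
#' @param omega Ankle angular velocity in deg/s (plantar flexion positive).
#' @param arch A [muscle_architecture()] with an elastic tendon.
#' @param path A calibrated [joint_path()].
#' @return A list with `v_CE` (fiber velocity, m/s), `v_CE_AT` (along-tendon
#'   CE velocity, m/s), `vtil` (normalized), and `resid` (force-balance
#'   residual in units of `f_o_CE`).
#' @export
fiber_velocity <- function(a, l_CE, theta, omega, arch, path) {
  stopifnot(inherits(arch, "muscle_architecture"))
  if (arch$tendon == "rigid") {
    stop("the rigid tendon fixes the fiber kinematically; no solve is needed")
  }
  lP <- path_length(theta, path)
  vP <- -path$r * .deg2rad(omega)
  sol <- cpp_solve_vtil(a, l_CE, lP, vP, .params(arch, path))
  v_CE <- sol$vtil * arch$l_o_CE * arch$v_max
  ca <- cos(pennation_angle(l_CE, arch))
  list(v_CE = v_CE, v_CE_AT = v_CE / ca, vtil = sol$vtil, resid = sol$resid)
}

#' Simulate one trial of the isokinetic protocol
#'
#' Integrates the two-state model (activation, fiber length) through the
#' protocol with an embedded Runge-Kutta 5(4) method (relative tolerance
#' 1e-8, absolute 1e-10) and emits a dense 1 kHz trace.  Preloaded protocols
#' begin with a fixed-end phase at `theta_start` from rest to the steady
#' excited state before rotation; non-preloaded protocols start at the
#' passive equilibrium and are maximally excited at rotation onset.  For
#' `omega = 0` the trial is a fixed-end contraction at `sample_angle`.
#' Derived channels (pennation, tendon strain, velocities, force, torque,
#' cumulative CE work) are recomputed from the state at every emitted
#' sample, so the force-balance residual column reflects the trace itself.
#'
#' @param protocol A [protocol_spec()].
#' @param arch A [muscle_architecture()].
#' @param path A calibrated [joint_path()].
#' @param dt Output sampling interval in s (default 1e-3).
#' @param t_preload Duration of the fixed-end preload phase in s.
#' @param t_settle Duration of fixed-end (`omega = 0`) trials in s.
#' @param rtol,atol Integrator tolerances.
#' @return A data.frame of class `mtu_trace` with one row per sample and
#'   columns `time_s, theta_deg, omega_deg_s, excitation, activation,
#'   l_CE_m, l_CE_norm, alpha_deg, l_T_m, strain, v_CE_m_s, v_CE_AT_m_s,
#'   v_T_m_s, F_T_N, torque_Nm, W_CE_J, resid_norm`.  Attributes carry the
#'   protocol, architecture, path, the rotation-onset time `t_rot`, and the
#'   count of force-velocity clamp events.
#' @export
simulate_trial <- function(protocol, arch, path, dt = 1e-3,
                           t_preload = 0.8, t_settle = 1.2,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(arch, "muscle_architecture"),
            inherits(path, "joint_path"))
  if (is.na(path$l_P_ref)) stop("path must be calibrated (l_P_ref is NA)")
  p <- .params(arch, path)

  if (protocol$omega == 0) {
    # fixed-end reference contraction at the sample angle
    th0 <- .deg2rad(protocol$sample_angle)
    segments <- matrix(c(0, th0, 0, 0), nrow = 1)
    t_u <- 0; u_before <- 1; u_after <- 1
    t_rot <- 0
    t_total <- t_settle
  } else {
    th0 <- .deg2rad(protocol$theta_start)
    om <- .deg2rad(protocol$omega)
    t_rot <- if (protocol$preload > 0) t_preload else 0
    t_stop <- t_rot + (.deg2rad(protocol$theta_end) - th0) / om
    segments <- rbind(c(0, th0, 0, 0),
                      c(t_rot, th0, om, 0),
                      c(t_stop, .deg2rad(protocol$theta_end), 0, 0))
    if (t_rot == 0) segments <- segments[-1, , drop = FALSE]
    t_u <- t_rot
    u_before <- if (protocol$preload > 0) {
      preload_excitation(protocol$preload, protocol$theta_start, arch, path)
    } else 0
    u_after <- 1
    t_total <- t_stop + 2 * dt
  }

  lP0 <- path$l_P_ref - path$r * segments[1, 2]
  lce0 <- if (arch$tendon == "rigid") {
    x <- lP0 - arch$l_s_T
    sqrt(x^2 + (arch$l_o_CE * sin(arch$alpha_o))^2)
  } else {
    cpp_static_fiber_length(0, lP0, p)
  }

  times <- sort(unique(c(seq(0, t_total, by = dt), t_rot, t_total)))
  sim <- cpp_simulate(p, times, segments, t_u, u_before, u_after,
                      0, lce0, path$l_P_ref, rtol, atol)
  tr <- as.data.frame(sim$trace)

  out <- data.frame(
    time_s = tr$time_s,
    theta_deg = .rad2deg(tr$theta_rad),
    omega_deg_s = .rad2deg(tr$omega_rad_s),
    excitation = tr$excitation,
    activation = tr$activation,
    l_CE_m = tr$l_CE_m,
    l_CE_norm = tr$l_CE_m / arch$l_o_CE,
    alpha_deg = .rad2deg(tr$alpha_rad),
    l_T_m = tr$l_T_m,
    strain = tr$strain,
    v_CE_m_s = tr$v_CE_m_s,
    v_CE_AT_m_s = tr$v_CE_AT_m_s,
    v_T_m_s = tr$v_T_m_s,
    F_T_N = tr$F_T_N,
    torque_Nm = tr$torque_Nm,
    W_CE_J = tr$W_CE_J,
    resid_norm = tr$resid_norm)

  structure(out, class = c("mtu_trace", "data.frame"),
            protocol = protocol, arch = arch, path = path,
            t_rot = t_rot, n_clamped = sim$n_clamped)
}

#' @export
print.mtu_trace <- function(x, ...) {
  pr <- attr(x, "protocol")
  cat(sprintf(
    "MTU trial trace: omega = %g deg/s, preload = %g, tendon = %s\n",
    pr$omega, pr$preload, attr(x, "arch")$tendon))
  cat(sprintf("  %d samples over %.3f s; peak torque %.2f N m\n",
              nrow(x), max(x$time_s), max(x$torque_Nm)))
  invisible(x)
}
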