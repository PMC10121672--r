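#' First-order activation dynamics
#'
#' `da/dt = (u - a) / tau` with `tau = 0.015` s when the excitation exceeds
#' the activation (activation) and `0.050` s otherwise (deactivation).
#'
#' @param a Activation in `[0, 1]`.
#' @param u Excitation in `[0, 1]`.
#' @return Activation rate in 1/s.
#' @export
activation_rate <- function(a, u) {
  stopifnot(all(a >= 0 & a <= 1), all(u >= 0 & u <= 1))
  tau <- ifelse(u > a, 0.015, 0.050)
  (u - a) / tau
}

#' Static (fixed-end) equilibrium fiber length
#'
#' Solves the zero-velocity force balance along the tendon,
#' `f_T(e) = (a * f_L + f_PE) * cos(alpha)`, for the fiber length at a given
#' activation and ankle angle.  With zero activation this returns the
#' passive equilibrium; if no tension is possible anywhere the tendon is
#' placed exactly at its slack length.
#'
#' @param a Activation in `[0, 1]`.
#' @param theta Ankle angle in degrees (plantar flexion positive).
#' @param arch A [muscle_architecture()].
#' @param path A calibrated [joint_path()].
#' @return Fiber length in m.
#' @export
static_fiber_length <- function(a, theta, arch, path) {
  stopifnot(a >= 0, a <= 1)
  lP <- path_length(theta, path)
  p <- .params(arch, path)
  if (arch$tendon == "rigid") {
    x <- lP - arch$l_s_T
    if (x <= 0) stop("infeasible geometry: path shorter than the rigid tendon")
    h <- arch$l_o_CE * sin(arch$alpha_o)
    return(sqrt(x^2 + h^2))
  }
  cpp_static_fiber_length(a, lP, p)
}

#' Static fixed-end tendon force and torque
#'
#' Tendon force (N) and plantar-flexion torque (N m) developed at static
#' equilibrium for a given activation and ankle angle.
#'
#' @inheritParams static_fiber_length
#' @return `static_force()`: force in N; `static_torque()`: torque in N m.
#' @export
static_force <- function(a, theta, arch, path) {
  stopifnot(a >= 0, a <= 1)
  lP <- path_length(theta, path)
  cpp_static_force(a, lP, .params(arch, path))
}

#' @rdname static_force
#' @export
static_torque <- function(a, theta, arch, path) {
  static_force(a, theta, arch, path) * path$r
}

#' Calibrate the path offset so peak isometric torque falls at a target angle
#'
#' Places the origin of the MTU (the path length at the neutral angle,
#' `l_P_ref`) such that the *active* fixed-end torque-angle curve (fully
#' activated minus passive torque, the quantity a dynamometry experiment
#' reports) peaks at `theta_peak` (default 17 deg of dorsiflexion, i.e.
#' -17 deg in the plantar-flexion-positive convention).  Because the moment
#' arm is constant, static torque depends on the ankle angle only through
#' the path length, so the calibration reduces to locating the path length
#' `L*` that maximizes active static force and setting
#' `l_P_ref = L* + r * theta_peak`.
#'
#' @param arch A [muscle_architecture()].
#' @param path A [joint_path()] (its `l_P_ref` is ignored and replaced).
#' @param theta_peak Target angle of peak active isometric torque, degrees
#'   (negative = dorsiflexion).
#' @return The calibrated `joint_path`.
#' @export
calibrate_path_offset <- function(arch, path = joint_path(),
                                  theta_peak = -17) {
  stopifnot(inherits(arch, "muscle_architecture"), inherits(path, "joint_path"))
  p <- .params(arch, path)
  # static force as a function of path length; bracket generously around
  # slack length + stretched tendon + CE near optimum
  L_lo <- arch$l_s_T + 0.2 * arch$l_o_CE
  L_hi <- arch$l_s_T + 0.12 * arch$l_s_T + 2.2 * arch$l_o_CE
  obj <- function(L) cpp_static_force(1, L, p) - cpp_static_force(0, L, p)
  opt <- optimize(obj, c(L_lo, L_hi), maximum = TRUE, tol = 1e-10)
  L_star <- opt$maximum
  if (L_star - L_lo < 1e-6 || L_hi - L_star < 1e-6) {
    stop("calibration error: no interior maximum of static torque found")
  }
  joint_path(r = path$r, l_P_ref = L_star + path$r * .deg2rad(theta_peak))
}

#' Angle of peak active fixed-end torque
#'
#' Sweeps the active static torque (fully activated minus passive) over an
#' ankle-angle grid and returns the argmax, for verifying
#' [calibrate_path_offset()].
#'
#' @inheritParams static_fiber_length
#' @param theta_grid Angle grid in degrees (default -30 to 0 in 0.1 deg
#'   steps).
#' @return Angle of maximum static torque, degrees.
#' @export
peak_torque_angle <- function(arch, path,
                              theta_grid = seq(-30, 0, by = 0.1)) {
  lP <- path$l_P_ref - path$r * .deg2rad(theta_grid)
  p <- .params(arch, path)
  f <- cpp_static_force_sweep(1, lP, p) - cpp_static_force_sweep(0, lP, p)
  theta_grid[which.max(f)]
}

#' Excitation level producing a given fraction of full preload force
#'
#' Finds the constant excitation `u` whose steady fixed-end tendon force at
#' the start angle equals `fraction` of the fully excited steady force.
#' Used for partially preloaded protocols, where "50% preload" is a force
#' criterion, not an activation criterion.
#'
#' @inheritParams static_fiber_length
#' @param fraction Target force fraction in (0, 1].
#' @param theta Ankle angle of the preload phase, degrees.
#' @return Excitation level in (0, 1].
#' @export
preload_excitation <- function(fraction, theta, arch, path) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(1)
  f_full <- static_force(1, theta, arch, path)
  g <- function(u) static_force(u, theta, arch, path) - fraction * f_full
  uniroot(g, c(1e-6, 1), tol = 1e-10)$root
}
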