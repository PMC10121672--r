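#' Muscle architecture of the modelled gastrocnemius medialis
#'
#' Bundles the contractile-element (CE) and tendon parameters of the
#' Hill-type model.  The default values are the GM parameter set used
#' throughout the simulation study: optimal CE length 3.78 cm, pennation
#' 32.5 deg at the optimal length, maximum isometric force 894.7 N, tendon
#' slack length 40.1 cm (Achilles tendon plus aponeurosis), and a maximum
#' shortening velocity of ten optimal CE lengths per second.
#'
#' @param l_o_CE Optimal CE length in m.
#' @param alpha_o Pennation angle at the optimal CE length, degrees.
#' @param f_o_CE Maximum isometric CE force in N.
#' @param l_s_T Tendon slack length in m.
#' @param v_max Maximum shortening velocity in optimal CE lengths per second.
#' @param tendon Tendon variant: `"rigid"`, `"typical"` (maximum strain 4.9%
#'   at `f_o_CE`) or `"compliant"` (9.2%).
#' @param e_o_T Tendon strain at which the tendon carries `f_o_CE`.  Defaults
#'   to the value implied by `tendon`; supply a number to override (used when
#'   fitting tendon compliance).
#' @param fiber_damping Dimensionless CE damping coefficient (force in units
#'   of `f_o_CE` per unit normalized fiber velocity).  Regularizes the
#'   classic elastic-equilibrium formulation, which is singular at zero
#'   activation.
#' @param tendon_damping Logical; when `TRUE` the tendon transmits an extra
#'   damping force `beta_T * d(l_T)/dt` with `beta_T = 0.05 * K_T(l_T)`,
#'   where `K_T` is the instantaneous tendon stiffness.
#' @return An object of class `muscle_architecture`.
#' @examples
#' arch <- muscle_architecture()                 # GM, typical tendon
#' muscle_architecture(tendon = "compliant")
#' @export
muscle_architecture <- function(l_o_CE = 0.0378, alpha_o = 32.5,
                                f_o_CE = 894.7, l_s_T = 0.401, v_max = 10,
                                tendon = c("typical", "compliant", "rigid"),
                                e_o_T = NULL, fiber_damping = 0.1,
                                tendon_damping = FALSE) {
  tendon <- match.arg(tendon)
  stopifnot(l_o_CE > 0, f_o_CE > 0, l_s_T > 0, v_max > 0,
            alpha_o >= 0, alpha_o < 90, fiber_damping >= 0)
  if (is.null(e_o_T)) {
    e_o_T <- switch(tendon, typical = 0.049, compliant = 0.092, rigid = NA_real_)
  } else {
    if (tendon == "rigid") stop("a rigid tendon has no maximum strain 'e_o_T'")
    stopifnot(is.numeric(e_o_T), length(e_o_T) == 1L, e_o_T > 0, e_o_T < 0.2)
  }
  structure(list(
    l_o_CE = l_o_CE, alpha_o = alpha_o * pi / 180, f_o_CE = f_o_CE,
    l_s_T = l_s_T, v_max = v_max, tendon = tendon, e_o_T = e_o_T,
    fiber_damping = fiber_damping, tendon_damping = isTRUE(tendon_damping)),
    class = "muscle_architecture")
}

#' Alternative GM architecture used for the robustness re-run
#'
#' The cadaver-based parameter set (optimal CE length 5.1 cm, pennation
#' 9.9 deg, maximum isometric force 1308 N) that differs substantially from
#' the in vivo default; the study conditions are re-run with it to check
#' that the preload/compliance orderings are architecture-robust.
#'
#' @inheritParams muscle_architecture
#' @param ... Further arguments passed to [muscle_architecture()].
#' @return A `muscle_architecture` object.
#' @export
muscle_architecture_alt <- function(tendon = "typical", ...) {
  muscle_architecture(l_o_CE = 0.051, alpha_o = 9.9, f_o_CE = 1308,
                      tendon = tendon, ...)
}

#' @export
print.muscle_architecture <- function(x, ...) {
  cat("Muscle architecture (Hill-type MTU)\n")
  cat(sprintf("  l_o_CE  %.4f m   alpha_o %.1f deg   f_o_CE %.1f N\n",
              x$l_o_CE, x$alpha_o * 180 / pi, x$f_o_CE))
  cat(sprintf("  l_s_T   %.4f m   v_max   %g l_o/s\n", x$l_s_T, x$v_max))
  cat(sprintf("  tendon  %s%s   fiber damping %g   tendon damping %s\n",
              x$tendon,
              if (x$tendon == "rigid") "" else sprintf(" (e_o_T = %.3f)", x$e_o_T),
              x$fiber_damping, if (x$tendon_damping) "on" else "off"))
  invisible(x)
}

#' Set the tendon variant of an architecture
#'
#' @param arch A [muscle_architecture()] object.
#' @param tendon Tendon variant name.
#' @param e_o_T Optional explicit maximum strain (elastic variants only).
#' @return The modified `muscle_architecture`.
#' @export
set_tendon <- function(arch, tendon, e_o_T = NULL) {
  stopifnot(inherits(arch, "muscle_architecture"))
  muscle_architecture(l_o_CE = arch$l_o_CE, alpha_o = arch$alpha_o * 180 / pi,
                      f_o_CE = arch$f_o_CE, l_s_T = arch$l_s_T,
                      v_max = arch$v_max, tendon = tendon, e_o_T = e_o_T,
                      fiber_damping = arch$fiber_damping,
                      tendon_damping = arch$tendon_damping)
}

#' Joint path model of the GM spanning the ankle
#'
#' The MTU spans a path `l_P(theta) = l_P_ref - r * theta` between the CE
#' origin and the calcaneus; `theta` is the ankle angle in radians with
#' plantar flexion positive, so the path shortens during plantar flexion and
#' the path velocity is `v_P = -r * omega`.
#'
#' @param r Achilles tendon moment arm in m (constant over the range of
#'   motion; default 0.056 m, the scaled group mean).
#' @param l_P_ref Path length at the neutral ankle angle (0 deg), m.  Usually
#'   left `NA` and set by [calibrate_path_offset()].
#' @return An object of class `joint_path`.
#' @export
joint_path <- function(r = 0.056, l_P_ref = NA_real_) {
  stopifnot(r > 0)
  structure(list(r = r, l_P_ref = l_P_ref), class = "joint_path")
}

#' @export
print.joint_path <- function(x, ...) {
  cat(sprintf("Joint path: r = %.4f m, l_P_ref = %s\n", x$r,
              if (is.na(x$l_P_ref)) "<uncalibrated>"
              else sprintf("%.4f m", x$l_P_ref)))
  invisible(x)
}

#' MTU path length at an ankle angle
#'
#' @param theta Ankle angle in degrees (plantar flexion positive).
#' @param path A calibrated [joint_path()].
#' @return Path length in m.
#' @export
path_length <- function(theta, path) {
  stopifnot(inherits(path, "joint_path"), !is.na(path$l_P_ref))
  path$l_P_ref - path$r * theta * pi / 180
}

#' Pennation angle from fiber length (constant-thickness model)
#'
#' The CE acts at angle `alpha` to the tendon with `l_CE * sin(alpha)`
#' constant, so `sin(alpha) = l_o_CE * sin(alpha_o) / l_CE`.
#'
#' @param l_CE Fiber (CE) length in m.
#' @param arch A [muscle_architecture()].
#' @return Pennation angle in radians.
#' @export
pennation_angle <- function(l_CE, arch) {
  stopifnot(inherits(arch, "muscle_architecture"))
  h <- arch$l_o_CE * sin(arch$alpha_o)
  if (any(l_CE < h)) {
    stop("fiber length below the pennation-model limit l_o_CE * sin(alpha_o)")
  }
  asin(h / l_CE)
}

# Named parameter vector handed to the compiled core.
.params <- function(arch, path) {
  c(lo = arch$l_o_CE, alpha_o = arch$alpha_o, fo = arch$f_o_CE,
    ls = arch$l_s_T, vmax = arch$v_max,
    eo = if (arch$tendon == "rigid") -1 else arch$e_o_T,
    beta = arch$fiber_damping,
    beta_t = if (arch$tendon_damping) 0.05 else 0,
    r = path$r)
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi
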