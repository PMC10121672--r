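#' Normalized characteristic curves of the Hill-type model
#'
#' The four dimensionless curves of the muscle model, each continuously
#' differentiable:
#'
#' * `eval_fl(l)` - active force-length: a unimodal bell with compact
#'   support on (0.4441, 1.8123) normalized CE lengths, value 1 at the
#'   optimal length, built from cubic Hermite segments with a steep
#'   ascending limb up to a shoulder at 0.73 and a shallow ascending
#'   segment (slope 0.8616) into the optimum.
#' * `eval_fv(v)` - force-velocity: Hill hyperbola with curvature
#'   `a/f_o = 0.25` on the concentric branch (`f(-1) = 0`, `f(0) = 1`) and a
#'   saturating exponential eccentric branch approaching 1.4.  Velocities
#'   are normalized by `l_o_CE * v_max`; shortening is negative.  Inputs
#'   below -1 clamp to 0 with a warning.
#' * `eval_fpe(l)` - passive force-length: zero at or below the optimal
#'   length, cubic growth reaching 1 at a CE strain of 0.7 beyond optimal.
#' * `eval_ft(e, e_o)` - tendon force-strain: zero for non-positive strain,
#'   a quadratic toe ending at `2/3 * e_o` (normalized force 0.5 there),
#'   then linear with slope `1.5 / e_o`, so the curve carries the maximum
#'   isometric force exactly at strain `e_o`.
#'
#' @param l Normalized CE length `l_CE / l_o_CE` (must be positive).
#' @param v Normalized CE velocity `v_CE / (l_o_CE * v_max)`, shortening
#'   negative.
#' @param f Force multiplier in `[0, 1.4)` for the inverse force-velocity
#'   curve.
#' @param e Tendon strain `(l_T - l_s_T) / l_s_T`.
#' @param e_o Tendon strain at the maximum isometric force (0.049 typical,
#'   0.092 compliant), or a `muscle_architecture` whose variant supplies it.
#' @return Numeric vector of curve values.
#' @examples
#' eval_fl(1)            # 1 at the optimal length
#' eval_fv(c(-1, 0))     # 0 at maximum shortening velocity, 1 isometric
#' eval_ft(0.049, 0.049) # 1 at the typical tendon's maximum strain
#' @name curves
NULL

.eo_of <- function(e_o) {
  if (inherits(e_o, "muscle_architecture")) {
    if (e_o$tendon == "rigid") {
      stop("the rigid tendon variant has no force-strain curve")
    }
    e_o <- e_o$e_o_T
  }
  stopifnot(is.numeric(e_o), length(e_o) == 1L, e_o > 0)
  e_o
}

#' @rdname curves
#' @export
eval_fl <- function(l) {
  if (any(!is.finite(l)) || any(l <= 0)) {
    stop("normalized CE length must be positive and finite")
  }
  cpp_fl(as.numeric(l))
}

#' @rdname curves
#' @export
eval_fv <- function(v) {
  stopifnot(all(is.finite(v)))
  n_clamp <- sum(v < -1)
  if (n_clamp > 0) {
    warning(sprintf(
      "%d velocity value(s) below -1 (faster than v_max) clamped to zero force",
      n_clamp))
  }
  cpp_fv(as.numeric(v))
}

#' @rdname curves
#' @export
inv_fv <- function(f) {
  if (any(!is.finite(f)) || any(f < 0) || any(f >= 1.4)) {
    stop("force multiplier must lie in [0, 1.4) to invert the f-v curve")
  }
  cpp_fv_inv(as.numeric(f))
}

#' @rdname curves
#' @export
eval_fpe <- function(l) {
  if (any(!is.finite(l)) || any(l <= 0)) {
    stop("normalized CE length must be positive and finite")
  }
  cpp_fpe(as.numeric(l))
}

#' @rdname curves
#' @export
eval_ft <- function(e, e_o) {
  cpp_ft(as.numeric(e), .eo_of(e_o))
}

#' Derivatives of the characteristic curves
#'
#' Analytic first derivatives of [eval_fl()], [eval_fv()], [eval_fpe()] and
#' [eval_ft()], used by the stiffness/damping laws and checkable against
#' central differences.
#'
#' @inheritParams curves
#' @return Numeric vector of derivative values.
#' @name curve_derivatives
NULL

#' @rdname curve_derivatives
#' @export
deriv_fl <- function(l) cpp_dfl(as.numeric(l))

#' @rdname curve_derivatives
#' @export
deriv_fv <- function(v) cpp_dfv(as.numeric(v))

#' @rdname curve_derivatives
#' @export
deriv_fpe <- function(l) cpp_dfpe(as.numeric(l))

#' @rdname curve_derivatives
#' @export
deriv_ft <- function(e, e_o) cpp_dft(as.numeric(e), .eo_of(e_o))

#' Tendon stiffness and damping laws
#'
#' `tendon_stiffness()` returns the instantaneous tendon stiffness
#' `K_T = (f_o_CE / l_s_T) * d f_T / d e` in N/m at tendon length `l_T`;
#' `tendon_damping_beta()` returns the damping coefficient
#' `beta_T = 0.05 * K_T(l_T)` in N s/m (the damping force is
#' `beta_T * d(l_T)/dt`).
#'
#' @param l_T Tendon length in m.
#' @param arch A [muscle_architecture()] with an elastic tendon variant.
#' @return Stiffness in N/m, or damping coefficient in N s/m.
#' @export
tendon_stiffness <- function(l_T, arch) {
  stopifnot(inherits(arch, "muscle_architecture"))
  if (arch$tendon == "rigid") {
    stop("tendon stiffness is undefined for the rigid tendon variant")
  }
  e <- (l_T - arch$l_s_T) / arch$l_s_T
  (arch$f_o_CE / arch$l_s_T) * cpp_dft(as.numeric(e), arch$e_o_T)
}

#' @rdname tendon_stiffness
#' @export
tendon_damping_beta <- function(l_T, arch) {
  0.05 * tendon_stiffness(l_T, arch)
}

#' Tendon strain energy
#'
#' Elastic energy stored in the tendon at strain `e`, in joules:
#' `f_o_CE * l_s_T * integral of f_T from 0 to e`.
#'
#' @inheritParams curves
#' @param arch A [muscle_architecture()] with an elastic tendon.
#' @return Energy in J.
#' @export
tendon_energy <- function(e, arch) {
  stopifnot(inherits(arch, "muscle_architecture"))
  if (arch$tendon == "rigid") return(rep(0, length(e)))
  arch$f_o_CE * arch$l_s_T * cpp_ft_energy(as.numeric(e), arch$e_o_T)
}

#' Tabulate the characteristic curves
#'
#' Evaluates all four curves on a common abscissa, for plotting or for
#' pinning regression fixtures.  The active/passive curves are evaluated at
#' normalized length `x`, the force-velocity curve at normalized velocity
#' `x - 1` (so the table spans the concentric branch), and the tendon curve
#' at strain `x * e_o / 2`.
#'
#' @param x Abscissa grid (default 0 to 2 in steps of 0.01).
#' @param e_o Maximum tendon strain for the tendon column.
#' @return A data.frame with columns `x, fl, fv, fpe, ft`.
#' @export
curve_table <- function(x = seq(0.01, 2, by = 0.01), e_o = 0.049) {
  data.frame(x = x,
             fl = cpp_fl(x),
             fv = cpp_fv(x - 1),
             fpe = cpp_fpe(x),
             ft = cpp_ft(x * e_o / 2, e_o))
}

#' Curve-family constants
#'
#' @return Named list: `fv_eccentric_plateau` (asymptotic eccentric force
#'   multiplier), `e_o_PE` (CE strain beyond optimal where the passive curve
#'   reaches 1), `fl_support` (active force-length support bounds), and
#'   `tendon_toe_fraction` (fraction of `e_o` where the tendon toe ends).
#' @export
curve_constants <- function() {
  list(fv_eccentric_plateau = 1.4, e_o_PE = 0.7,
       fl_support = c(0.4441, 1.8123), tendon_toe_fraction = 2 / 3)
}
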