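#' Sample a simulated trial at an ankle angle
#'
#' Returns the trial state at the first crossing of `angle` (linear
#' interpolation in the angle between the two bracketing samples).  For
#' fixed-end (`omega = 0`) trials the steady terminal state is returned.
#'
#' @param trace An `mtu_trace` from [simulate_trial()].
#' @param angle Ankle angle to sample, degrees.
#' @return A one-row data.frame with the interpolated channels.
#' @export
sample_at_angle <- function(trace, angle = 0) {
  pr <- attr(trace, "protocol")
  num <- vapply(trace, is.numeric, logical(1))
  if (!is.null(pr) && pr$omega == 0) {
    return(as.data.frame(trace[nrow(trace), num, drop = FALSE],
                         row.names = NULL))
  }
  th <- trace$theta_deg
  idx <- which(th[-1] >= angle & th[-length(th)] <= angle)
  if (length(idx) == 0) {
    if (any(abs(th - angle) < 1e-9)) {
      i <- which(abs(th - angle) < 1e-9)[1]
      return(as.data.frame(trace[i, num, drop = FALSE], row.names = NULL))
    }
    stop(sprintf("protocol error: the trial never reaches %g deg", angle))
  }
  i <- idx[1]
  w <- (angle - th[i]) / (th[i + 1] - th[i])
  row <- as.data.frame(lapply(trace[num], function(col) {
    (1 - w) * col[i] + w * col[i + 1]
  }))
  row
}

#' Contractile-element work of a simulated trial
#'
#' Integrates the CE power along the tendon, `F_T * (-v_CE_AT)`, from
#' excitation onset to the first crossing of `until_angle` (trapezoidal rule
#' on the dense trace, with the final partial interval interpolated).  For
#' fixed-end trials the integral runs to the end of the trace (steady
#' state).  Preloaded trials include the tendon-stretching work done during
#' the preload phase, because their excitation onset is the start of that
#' phase.
#'
#' @param trace An `mtu_trace`.
#' @param until_angle Stop angle in degrees (default 0).
#' @return Work in J.
#' @seealso [ce_work_quasistatic()] for the 0 deg/s (quasi-static) limit of
#'   a moving contraction.
#' @export
ce_work <- function(trace, until_angle = 0) {
  pr <- attr(trace, "protocol")
  if (!is.null(pr) && pr$omega == 0) {
    return(trace$W_CE_J[nrow(trace)])
  }
  s <- sample_at_angle(trace, until_angle)
  s$W_CE_J
}

#' Quasi-static contractile-element work of the 0 deg/s condition
#'
#' The limit of the CE work of a shortening trial as the angular velocity
#' approaches zero: the muscle fully activates at the start angle and then
#' rotates the ankle quasi-statically to `until_angle`, so
#' `W = [E_T(until, a = 1) - E_T(start, rest)] + integral of tau(theta)` with
#' the static fully activated torque-angle curve `tau`.  In this limit the
#' preloaded and non-preloaded protocols coincide (the state depends only on
#' the angle), so no preload argument exists.
#'
#' @param arch A [muscle_architecture()].
#' @param path A calibrated [joint_path()].
#' @param theta_start Start angle, degrees (default -15).
#' @param until_angle Target angle, degrees (default 0).
#' @param n Number of grid points for the torque-angle integral.
#' @return Work in J.
#' @export
ce_work_quasistatic <- function(arch, path, theta_start = -15,
                                until_angle = 0, n = 601) {
  p <- .params(arch, path)
  th <- seq(theta_start, until_angle, length.out = n)
  lP <- path$l_P_ref - path$r * .deg2rad(th)
  tau <- cpp_static_force_sweep(1, lP, p) * path$r
  w_out <- sum(0.5 * (tau[-1] + tau[-n]) * diff(.deg2rad(th)))
  if (arch$tendon == "rigid") return(w_out)
  strain_at <- function(a, theta) {
    lP1 <- path_length(theta, path)
    lce <- cpp_static_fiber_length(a, lP1, p)
    ca <- sqrt(lce^2 - (arch$l_o_CE * sin(arch$alpha_o))^2) / lce
    (lP1 - lce * ca - arch$l_s_T) / arch$l_s_T
  }
  dE <- tendon_energy(strain_at(1, until_angle), arch) -
    tendon_energy(strain_at(0, theta_start), arch)
  dE + w_out
}

#' Energy bookkeeping of a simulated trial
#'
#' Decomposes the CE work of a trace into elastic tendon storage and joint
#' output work: `W_CE = dE_T + W_out` for an elastic tendon without tendon
#' damping (with tendon damping the difference `W_CE - dE_T - W_out` is the
#' energy dissipated in the tendon and must be non-negative).  `dE_T` is
#' evaluated from the analytic tendon strain-energy function at the first
#' and last sample; `W_out = integral of F_T * (-v_P)` is integrated
#' phase-wise (the path velocity is discontinuous at rotation onset and
#' stop, so the trapezoids never straddle a corner).
#'
#' @param trace An `mtu_trace` from [simulate_trial()].
#' @return A list with `W_CE`, `dE_T`, `W_out`, and `residual`
#'   (`W_CE - dE_T - W_out`, in J).
#' @export
energy_closure <- function(trace) {
  arch <- attr(trace, "arch")
  path <- attr(trace, "path")
  W_CE <- trace$W_CE_J[nrow(trace)]
  dE_T <- if (arch$tendon == "rigid") 0 else {
    tendon_energy(trace$strain[nrow(trace)], arch) -
      tendon_energy(trace$strain[1], arch)
  }
  pr <- attr(trace, "protocol")
  t_rot <- attr(trace, "t_rot")
  if (pr$omega == 0) {
    W_out <- 0
  } else {
    t_stop <- t_rot + (pr$theta_end - pr$theta_start) / pr$omega
    om <- .deg2rad(pr$omega)
    dtv <- diff(trace$time_s)
    mid <- trace$time_s[-nrow(trace)] + dtv / 2
    in_rot <- mid > t_rot & mid < t_stop
    f_mid <- 0.5 * (trace$F_T_N[-1] + trace$F_T_N[-nrow(trace)])
    W_out <- sum((f_mid * path$r * om * dtv)[in_rot])
  }
  list(W_CE = W_CE, dE_T = dE_T, W_out = W_out,
       residual = W_CE - dE_T - W_out)
}

#' The two-factor condition grid
#'
#' Builds the list of (preload, tendon) conditions of the block study.
#' `"fig3"` is the default 2 x 3 design (0% and 100% preload for the rigid,
#' typical and compliant tendons); `"fig4"` adds the 50% preload condition
#' for the elastic tendons.
#'
#' @param design `"fig3"` or `"fig4"`.
#' @return A data.frame with columns `preload` and `tendon`.
#' @export
block_design <- function(design = c("fig3", "fig4")) {
  design <- match.arg(design)
  d <- expand.grid(preload = c(0, 1),
                   tendon = c("rigid", "typical", "compliant"),
                   stringsAsFactors = FALSE)
  if (design == "fig4") {
    d <- rbind(d, data.frame(preload = 0.5,
                             tendon = c("typical", "compliant")))
  }
  d
}

#' Run the block simulation study
#'
#' Simulates every condition of the design over the angular-velocity grid
#' and assembles one torque-angular-velocity (T-omega-r) profile per
#' condition, sampled at `sample_angle`.  Each profile is normalized by the
#' static fully activated fixed-end torque of its own tendon variant at the
#' sample angle, and carries the CE work to the sample angle per velocity
#' (quasi-static limit at 0 deg/s).  The path offset is calibrated per
#' tendon variant so that peak isometric torque falls at 17 deg of
#' dorsiflexion.
#'
#' @param arch A [muscle_architecture()] supplying the CE parameters (its
#'   tendon variant is overridden per condition).
#' @param design A design data.frame from [block_design()], or a design name.
#' @param omegas Angular-velocity grid in deg/s (default 0 to 200 by 10).
#' @param path A [joint_path()] carrying the moment arm; `l_P_ref` is
#'   recalibrated per tendon variant.
#' @param sample_angle Sampling angle in degrees.
#' @param ... Passed on to [simulate_trial()].
#' @return An object of class `towr_block`: a list of data.frames (one per
#'   condition, named `preload<pct>_<tendon>`) with columns `omega,
#'   torque_norm, v_CE_AT_m_s, v_T_m_s, l_CE_norm, W_CE_J`.
#' @export
run_block <- function(arch = muscle_architecture(), design = "fig3",
                      omegas = seq(0, 200, by = 10), path = joint_path(),
                      sample_angle = 0, ...) {
  if (is.character(design)) design <- block_design(design)
  variants <- unique(design$tendon)
  ctx <- lapply(setNames(variants, variants), function(v) {
    a <- set_tendon(arch, v)
    cp <- calibrate_path_offset(a, path)
    list(arch = a, path = cp,
         tau_ref = static_torque(1, sample_angle, a, cp))
  })
  out <- list()
  for (i in seq_len(nrow(design))) {
    cond <- design[i, ]
    cx <- ctx[[cond$tendon]]
    rows <- lapply(omegas, function(om) {
      pr <- protocol_spec(om, preload = cond$preload,
                          sample_angle = sample_angle)
      trace <- simulate_trial(pr, cx$arch, cx$path, ...)
      s <- sample_at_angle(trace, sample_angle)
      w <- if (om == 0) {
        ce_work_quasistatic(cx$arch, cx$path, until_angle = sample_angle)
      } else {
        s$W_CE_J
      }
      data.frame(omega = om, torque_norm = s$torque_Nm / cx$tau_ref,
                 v_CE_AT_m_s = s$v_CE_AT_m_s, v_T_m_s = s$v_T_m_s,
                 l_CE_norm = s$l_CE_norm, W_CE_J = w)
    })
    nm <- sprintf("preload%03d_%s", round(100 * cond$preload), cond$tendon)
    out[[nm]] <- do.call(rbind, rows)
  }
  structure(out, class = "towr_block",
            arch = arch, design = design, sample_angle = sample_angle)
}

#' @export
print.towr_block <- function(x, ...) {
  cat(sprintf("T-omega-r block: %d conditions x %d velocities\n",
              length(x), nrow(x[[1]])))
  for (nm in names(x)) {
    cat(sprintf("  %-22s torque_norm @200: %.3f\n", nm,
                x[[nm]]$torque_norm[nrow(x[[nm]])]))
  }
  invisible(x)
}

#' Simulate one condition's T-omega-r profile
#'
#' Convenience wrapper used by the tendon-compliance fit: the normalized
#' torque profile of one (preload, tendon-strain) condition over a velocity
#' grid.
#'
#' @inheritParams run_block
#' @param e_o Maximum tendon strain of the (elastic) tendon.
#' @param preload Preload fraction.
#' @return A data.frame with columns `omega` and `torque_norm`.
#' @export
towr_profile <- function(e_o, preload, omegas, arch = muscle_architecture(),
                         path = joint_path(), ...) {
  a <- set_tendon(arch, "typical", e_o_T = e_o)
  cp <- calibrate_path_offset(a, path)
  tau_ref <- static_torque(1, 0, a, cp)
  tn <- vapply(omegas, function(om) {
    pr <- protocol_spec(om, preload = preload)
    s <- sample_at_angle(simulate_trial(pr, a, cp, ...), 0)
    s$torque_Nm / tau_ref
  }, numeric(1))
  data.frame(omega = omegas, torque_norm = tn)
}

#' Precompute T-omega-r profiles over a tendon-strain grid
#'
#' Builds the simulated response surface `torque_norm(omega, e_o)` used by
#' [fit_tendon_strain()] when many fits against the same model are needed
#' (e.g. Monte-Carlo noise studies).  The surface is interpolated with
#' cubic splines in `e_o`, which is smooth on this scale.
#'
#' @inheritParams towr_profile
#' @param e_grid Tendon-strain grid.
#' @return An object of class `towr_cache`.
#' @export
build_towr_cache <- function(omegas, preload, e_grid = seq(0.02, 0.12, by = 0.0025),
                             arch = muscle_architecture(), path = joint_path(),
                             ...) {
  profs <- vapply(e_grid, function(e) {
    towr_profile(e, preload, omegas, arch, path, ...)$torque_norm
  }, numeric(length(omegas)))
  # profs: omegas x e_grid
  structure(list(omegas = omegas, e_grid = e_grid, preload = preload,
                 torque_norm = matrix(profs, nrow = length(omegas))),
            class = "towr_cache")
}

#' Fit tendon compliance to an observed T-omega-r profile
#'
#' Estimates the maximum tendon strain `e_o` by minimizing the sum of
#' squared errors between the observed normalized torques and the simulated
#' profile of the same protocol, over `e_o` in `bounds` (scalar bounded
#' minimization, tolerance 1e-4 strain).
#'
#' @param observed A data.frame with columns `omega` (deg/s) and
#'   `torque_norm`.
#' @param preload Preload fraction of the observed protocol.
#' @param arch,path Model context (see [towr_profile()]).
#' @param bounds Search interval for `e_o`.
#' @param cache Optional [build_towr_cache()] result matching `observed$omega`
#'   and `preload`; when supplied, profiles are spline-interpolated from the
#'   cache instead of re-simulated, making repeated fits cheap.
#' @param ... Passed to [simulate_trial()] when simulating directly.
#' @return A list with `e_o` (the estimate), `sse` (objective at the
#'   estimate), and `boundary` (TRUE when the estimate sits on a bound,
#'   reported with a warning for flat, rigid-like objectives).
#' @export
fit_tendon_strain <- function(observed, preload = 1,
                              arch = muscle_architecture(),
                              path = joint_path(),
                              bounds = c(0.02, 0.12), cache = NULL, ...) {
  stopifnot(all(c("omega", "torque_norm") %in% names(observed)))
  if (!is.null(cache)) {
    stopifnot(inherits(cache, "towr_cache"),
              isTRUE(all.equal(cache$omegas, observed$omega)),
              cache$preload == preload)
    sim_at <- function(e) {
      vapply(seq_along(cache$omegas), function(i) {
        spline(cache$e_grid, cache$torque_norm[i, ], xout = e,
               method = "natural")$y
      }, numeric(1))
    }
  } else {
    sim_at <- function(e) {
      towr_profile(e, preload, observed$omega, arch, path, ...)$torque_norm
    }
  }
  obj <- function(e) sum((sim_at(e) - observed$torque_norm)^2)
  opt <- optimize(obj, bounds, tol = 1e-4)
  e_hat <- opt$minimum
  boundary <- (e_hat - bounds[1] < 2e-4) || (bounds[2] - e_hat < 2e-4)
  if (boundary) {
    warning(sprintf(
      "tendon-strain estimate at the search boundary (%.4f); the observed profile may be rigid-like or uninformative",
      e_hat))
  }
  list(e_o = e_hat, sse = opt$objective, boundary = boundary)
}
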