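#' Configuration of the synthetic in vivo trial generator
#'
#' Bundles the subject model (architecture + path), the dynamometer
#' kinematics, the gravity/passive torque polynomial, and per-channel noise
#' levels used to emit in-vivo-like trials with known ground truth.
#'
#' @param arch A [muscle_architecture()].
#' @param path A [joint_path()]; calibrated automatically when `l_P_ref` is
#'   missing.
#' @param gravity_coef Ascending polynomial coefficients (N m per deg^k) of
#'   the gravitational torque of the foot/footplate against the ankle angle
#'   in degrees.
#' @param noise Named list of channel noise SDs: `torque` (N m), `angle`
#'   (deg), `emg` (mV), `fascicle` (cm), `excursion` (m).
#' @param accel Dynamometer crank acceleration, deg/s^2 (default 400).
#' @param trigger_fraction Rotation trigger: fraction of the steady
#'   fixed-end torque at the start angle (default 0.95).
#' @param gm_fraction GM share of the plantar-flexion torque used to scale
#'   the simulated GM torque up to a net ankle torque channel.
#' @param fascicle_mode `"simulated"` (fascicle channel = simulated CE
#'   length) or `"linear"` (idealized linear-in-time fascicle shortening at
#'   a rate proportional to the trial's angular velocity at 0 deg; a
#'   validation mode for the processing chain).
#' @param seed Integer seed; a fixed seed makes generated trials
#'   byte-identical.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(arch = muscle_architecture(),
                             path = joint_path(),
                             gravity_coef = c(-4, -0.12, 0.0015),
                             noise = list(torque = 0.5, angle = 0.05,
                                          emg = 0.02, fascicle = 0.05,
                                          excursion = 2e-4),
                             accel = 400, trigger_fraction = 0.95,
                             gm_fraction = 0.159,
                             fascicle_mode = c("simulated", "linear"),
                             seed = 1L) {
  stopifnot(accel > 0, trigger_fraction > 0, trigger_fraction < 1,
            all(unlist(noise) >= 0))
  fascicle_mode <- match.arg(fascicle_mode)
  if (is.na(path$l_P_ref)) path <- calibrate_path_offset(arch, path)
  structure(list(arch = arch, path = path, gravity_coef = gravity_coef,
                 noise = noise, accel = accel,
                 trigger_fraction = trigger_fraction,
                 gm_fraction = gm_fraction, fascicle_mode = fascicle_mode,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.gravity_torque <- function(coef, angle_deg) {
  drop(outer(angle_deg, seq_along(coef) - 1, `^`) %*% coef)
}

#' Isokinetic dynamometer ramp kinematics
#'
#' Trapezoidal velocity profile: accelerate at `accel` from `theta_start`,
#' cruise at the target velocity, and decelerate to stop at `theta_end`.
#' When the target cannot be reached within the range under the stop
#' constraint, the profile is triangular with peak `sqrt(accel * range)`
#' and a warning is issued (e.g. a 200 deg/s setting over 30 deg at
#' 400 deg/s^2 never reaches 200 deg/s).
#'
#' @param omega_target Velocity setting, deg/s.
#' @param accel Crank acceleration, deg/s^2.
#' @param theta_start,theta_end Range of motion, degrees.
#' @param fs Sampling rate of the returned series, Hz.
#' @return A data.frame `time_s, theta_deg, omega_deg_s` covering the
#'   rotation, with attribute `segments` (piecewise constant-acceleration
#'   description) and `t_end`.
#' @export
ramp_kinematics <- function(omega_target, accel = 400, theta_start = -15,
                            theta_end = 15, fs = 1000) {
  stopifnot(omega_target >= 0, theta_end > theta_start)
  rng <- theta_end - theta_start
  v_feas <- sqrt(accel * rng)
  v_c <- min(omega_target, v_feas)
  if (omega_target > v_feas) {
    warning(sprintf(
      "setting %g deg/s unattainable over %g deg at %g deg/s^2; peak %.1f deg/s",
      omega_target, rng, accel, v_feas))
  }
  t_acc <- v_c / accel
  d_acc <- v_c^2 / (2 * accel)
  t_cru <- max((rng - 2 * d_acc) / v_c, 0)
  segments <- rbind(
    c(0, theta_start, 0, accel),
    c(t_acc, theta_start + d_acc, v_c, 0),
    c(t_acc + t_cru, theta_end - d_acc, v_c, -accel))
  if (t_cru == 0) segments <- segments[-2, , drop = FALSE]
  t_end <- 2 * t_acc + t_cru
  tt <- seq(0, t_end, by = 1 / fs)
  eval_seg <- function(t) {
    i <- findInterval(t, segments[, 1])
    dt <- t - segments[i, 1]
    c(theta = segments[i, 2] + segments[i, 3] * dt + 0.5 * segments[i, 4] * dt^2,
      omega = segments[i, 3] + segments[i, 4] * dt)
  }
  m <- t(vapply(tt, eval_seg, numeric(2)))
  structure(data.frame(time_s = tt, theta_deg = pmin(m[, 1], theta_end),
                       omega_deg_s = m[, 2]),
            segments = segments, t_end = t_end)
}

# Simulate the muscle through an arbitrary prescribed kinematic profile.
.simulate_prescribed <- function(config, segments_deg, t_total, u = 1,
                                 dt = 1e-3) {
  arch <- config$arch; path <- config$path
  p <- .params(arch, path)
  seg <- segments_deg
  seg[, 2] <- .deg2rad(seg[, 2]); seg[, 3] <- .deg2rad(seg[, 3])
  seg[, 4] <- .deg2rad(seg[, 4])
  lP0 <- path$l_P_ref - path$r * seg[1, 2]
  lce0 <- if (arch$tendon == "rigid") {
    sqrt((lP0 - arch$l_s_T)^2 + (arch$l_o_CE * sin(arch$alpha_o))^2)
  } else {
    cpp_static_fiber_length(0, lP0, p)
  }
  times <- seq(0, t_total, by = dt)
  sim <- cpp_simulate(p, times, seg, 0, u, u, 0, lce0, path$l_P_ref,
                      1e-8, 1e-10)
  as.data.frame(sim$trace)
}

# Band-limited EMG-like noise, amplitude modulated by activation.
.emg_channel <- function(n, fs, activation, amp = 0.5, floor_sd = 0.02) {
  bf <- signal::butter(2, c(20, 450) / (fs / 2), type = "pass")
  carrier <- as.numeric(signal::filtfilt(bf, rnorm(n)))
  carrier <- carrier / sd(carrier)
  amp * carrier * (0.05 + 0.95 * activation) + rnorm(n, sd = floor_sd)
}

#' Generate one synthetic in vivo trial
#'
#' Runs the muscle simulation through the recorded protocol and emits the
#' multichannel trial an experimenter would record: net ankle torque
#' (simulated GM torque scaled by the GM fraction, plus the gravitational
#' polynomial and the passive muscle torque, plus noise), ankle angle
#' (generated at 200 Hz and resampled to the 1 kHz torque clock), three EMG
#' channels (band-limited noise modulated by activation), and a sparse
#' 61.5 Hz fascicle-length channel.  Shortening trials preload at the start
#' angle and trigger the rotation when the simulated torque exceeds
#' `trigger_fraction` of the steady fixed-end maximum there.  Ground truth
#' (trigger time, angular velocity and normalized torque at 0 deg, CE
#' lengths) is stored in the metadata.
#'
#' @param config A [synthetic_config()].
#' @param omega_setting Velocity setting in deg/s (ignored for fixed-end
#'   trials).
#' @param kind `"shortening"`, `"fixed_end"`, or `"passive"` (slow passive
#'   rotation for the gravity/passive fit).
#' @param theta_start,theta_end Range of motion, degrees.
#' @return An `invivo_trial`: list with `data` (the channel data.frame) and
#'   `meta` (rates, protocol, ground truth).
#' @export
generate_invivo_trial <- function(config, omega_setting = 100,
                                  kind = c("shortening", "fixed_end",
                                           "passive"),
                                  theta_start = -15, theta_end = 15) {
  stopifnot(inherits(config, "synthetic_config"))
  kind <- match.arg(kind)
  arch <- config$arch; path <- config$path
  fs <- 1000
  set.seed(config$seed + 7L * switch(kind, shortening = round(omega_setting),
                                     fixed_end = 1L, passive = 2L))

  gm <- config$gm_fraction
  passive0 <- static_force(0, 0, arch, path) * path$r / gm

  if (kind == "passive") {
    # slow (5 deg/s) relaxed rotation for the gravity/passive model
    t_end <- (theta_end + 5 - (theta_start - 5)) / 5
    seg <- rbind(c(0, theta_start - 5, 5, 0))
    tr <- .simulate_prescribed(config, seg, t_end, u = 0)
    th <- .rad2deg(tr$theta_rad)
    torque <- .gravity_torque(config$gravity_coef, th) +
      tr$F_T_N * path$r / gm +
      rnorm(nrow(tr), sd = config$noise$torque)
    d <- data.frame(time_s = tr$time_s,
                    angle_deg = th + rnorm(nrow(tr), sd = config$noise$angle),
                    torque_Nm = torque,
                    emg_sol_mV = .emg_channel(nrow(tr), fs, 0),
                    emg_gl_mV = .emg_channel(nrow(tr), fs, 0),
                    emg_ta_mV = .emg_channel(nrow(tr), fs, 0),
                    fascicle_cm = NA_real_)
    return(structure(list(data = d,
                          meta = list(fs = fs, fascicle_fs = 61.5,
                                      omega_setting = 5, kind = kind)),
                     class = "invivo_trial"))
  }

  if (kind == "fixed_end") {
    seg <- rbind(c(0, 0, 0, 0))
    t_total <- 3
    tr <- .simulate_prescribed(config, seg, t_total)
    truth <- list(net_torque_ss = static_force(1, 0, arch, path) * path$r / gm,
                  t_trigger = NA_real_)
  } else {
    tau_ss <- static_force(1, theta_start, arch, path) * path$r
    pre <- .simulate_prescribed(config,
                                rbind(c(0, theta_start, 0, 0)), 2)
    idx <- which(pre$torque_Nm >= config$trigger_fraction * tau_ss)
    if (length(idx) == 0) {
      stop("simulation never reached the trigger torque at the start angle")
    }
    t_trig <- pre$time_s[idx[1]]
    ramp <- ramp_kinematics(omega_setting, config$accel, theta_start,
                            theta_end, fs)
    seg <- attr(ramp, "segments")
    seg[, 1] <- seg[, 1] + t_trig
    seg <- rbind(c(0, theta_start, 0, 0), seg,
                 c(t_trig + attr(ramp, "t_end"), theta_end, 0, 0))
    t_total <- t_trig + attr(ramp, "t_end") + 0.3
    tr <- .simulate_prescribed(config, seg, t_total)
    truth <- list(t_trigger = t_trig)
  }

  n <- nrow(tr)
  th_true <- .rad2deg(tr$theta_rad)
  net_true <- tr$F_T_N * path$r / gm
  torque <- net_true + .gravity_torque(config$gravity_coef, th_true) +
    rnorm(n, sd = config$noise$torque)

  # angle recorded at 200 Hz, then resampled onto the 1 kHz torque clock
  i200 <- seq(1, n, by = 5)
  ang200 <- th_true[i200] + rnorm(length(i200), sd = config$noise$angle)
  angle <- approx(tr$time_s[i200], ang200, xout = tr$time_s, rule = 2)$y

  # sparse fascicle channel at 61.5 Hz
  t_f <- seq(0, tr$time_s[n], by = 1 / 61.5)
  fasc <- rep(NA_real_, n)
  fi <- findInterval(t_f, tr$time_s)
  if (kind == "shortening" && config$fascicle_mode == "linear") {
    cross <- which(th_true[-1] >= 0 & th_true[-n] <= 0)[1]
    om0 <- .rad2deg(tr$omega_rad_s[cross])
    t_rot <- truth$t_trigger
    t_stop <- seg[nrow(seg), 1]
    l0 <- tr$l_CE_m[fi[1]] * 100
    lf <- l0 - 0.05 * om0 * (pmin(pmax(t_f, t_rot), t_stop) - t_rot)
    fasc[fi] <- lf + rnorm(length(fi), sd = config$noise$fascicle)
  } else {
    fasc[fi] <- tr$l_CE_m[fi] * 100 +
      rnorm(length(fi), sd = config$noise$fascicle)
  }

  d <- data.frame(time_s = tr$time_s, angle_deg = angle, torque_Nm = torque,
                  emg_sol_mV = .emg_channel(n, fs, tr$activation),
                  emg_gl_mV = .emg_channel(n, fs, tr$activation),
                  emg_ta_mV = .emg_channel(n, fs, 0),
                  fascicle_cm = fasc)

  if (kind == "shortening") {
    cross <- which(th_true[-1] >= 0 & th_true[-n] <= 0)[1]
    w <- (0 - th_true[cross]) / (th_true[cross + 1] - th_true[cross])
    lint <- function(x) (1 - w) * x[cross] + w * x[cross + 1]
    ref <- static_force(1, 0, arch, path) * path$r / gm
    truth <- c(truth, list(
      omega_at0 = .rad2deg(lint(tr$omega_rad_s)),
      net_torque_at0 = lint(net_true),
      torque_norm_at0 = lint(net_true) / ref,
      l_CE_at0_cm = lint(tr$l_CE_m) * 100))
  }

  structure(list(data = d,
                 meta = list(fs = fs, fascicle_fs = 61.5,
                             omega_setting = omega_setting, kind = kind,
                             truth = truth)),
            class = "invivo_trial")
}

#' @export
print.invivo_trial <- function(x, ...) {
  cat(sprintf("Synthetic in vivo trial: kind = %s, setting = %g deg/s, %d samples\n",
              x$meta$kind, x$meta$omega_setting, nrow(x$data)))
  invisible(x)
}

#' Generate a passive tendon-excursion trial
#'
#' Emits tendon length against ankle angle during a slow passive rotation,
#' `length = const - r * theta + noise`, with the true moment arm recorded
#' in the metadata, for validating [estimate_moment_arm()].
#'
#' @param config A [synthetic_config()].
#' @param theta_range Rotation range, degrees.
#' @param n Number of samples.
#' @return A list with `data` (`angle_rad`, `length_m`) and `meta`
#'   (`r_true` in m).
#' @export
generate_passive_rotation <- function(config, theta_range = c(-15, 15),
                                      n = 300) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 11L)
  r_true <- config$path$r / 1.22     # raw (resting) moment arm
  th <- .deg2rad(seq(theta_range[1], theta_range[2], length.out = n))
  len <- config$arch$l_s_T - r_true * th +
    rnorm(n, sd = config$noise$excursion)
  list(data = data.frame(angle_rad = th, length_m = len),
       meta = list(r_true = r_true))
}

#' Generate the full synthetic trial battery
#'
#' The set of trials the in vivo protocol records: one shortening trial per
#' velocity setting, a fixed-end MVIC reference at 0 deg, a passive rotation
#' for the gravity/passive fit, and a tendon-excursion trial.
#'
#' @param config A [synthetic_config()].
#' @param settings Velocity settings in deg/s.
#' @return A list with elements `shortening` (list of trials), `mvic`,
#'   `passive`, and `excursion`.
#' @export
generate_battery <- function(config, settings = seq(20, 200, by = 20)) {
  list(shortening = lapply(settings, function(om) {
         generate_invivo_trial(config, om, "shortening")
       }),
       mvic = generate_invivo_trial(config, 0, "fixed_end"),
       passive = generate_invivo_trial(config, 0, "passive"),
       excursion = generate_passive_rotation(config))
}
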