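#' Low-pass filter the dynamometer torque channel
#'
#' 4th-order Butterworth low-pass (default 10 Hz) applied forward and
#' backward (dual pass, zero phase, DC gain 1).
#'
#' @param x Torque series in N m, uniformly sampled.
#' @param fs Sampling rate in Hz (default 1000).
#' @param cutoff Cutoff frequency in Hz.
#' @param time Optional time vector; when supplied, sampling uniformity is
#'   checked.
#' @return Filtered series.
#' @export
filter_torque <- function(x, fs = 1000, cutoff = 10, time = NULL) {
  .check_uniform(time, fs)
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  .filtfilt_padded(bf, x)
}

# Zero-phase filtering with odd-reflection end padding, which suppresses
# the start/end transients of plain forward-backward filtering.  The pad
# is generous because the slowest pole of a 10 Hz/1 kHz Butterworth decays
# with a time constant of tens of samples.
.filtfilt_padded <- function(bf, x, npad = min(length(x) - 1L, 1500L)) {
  n <- length(x)
  if (npad < 1L) return(as.numeric(signal::filtfilt(bf, x)))
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(npad + 1):(npad + n)]
}

.check_uniform <- function(time, fs) {
  if (!is.null(time)) {
    dtv <- diff(time)
    if (any(abs(dtv - 1 / fs) > 1e-6 / fs)) {
      stop("input error: non-uniform sampling (expected ", fs, " Hz)")
    }
  }
  invisible(TRUE)
}

#' Fit the angle-specific gravitational and passive torque model
#'
#' Least-squares polynomial (degree <= 4) of torque against ankle angle,
#' fitted to passive trials, used to correct active trials for gravity and
#' passive structures.
#'
#' @param angle_deg Ankle angle samples, degrees.
#' @param torque_Nm Passive torque samples, N m.
#' @param degree Polynomial degree (<= 4).
#' @return An object of class `gravity_passive_fit` with the coefficients,
#'   the fitted angle range, and the residual SD.
#' @export
fit_gravity_passive <- function(angle_deg, torque_Nm, degree = 4) {
  stopifnot(degree >= 1, degree <= 4, length(angle_deg) == length(torque_Nm))
  ok <- is.finite(angle_deg) & is.finite(torque_Nm)
  fit <- lm(torque_Nm[ok] ~ poly(angle_deg[ok], degree, raw = TRUE))
  structure(list(coef = unname(coef(fit)), degree = degree,
                 range = range(angle_deg[ok]),
                 resid_sd = sd(fit$residuals)),
            class = "gravity_passive_fit")
}

#' @rdname fit_gravity_passive
#' @param object A `gravity_passive_fit`.
#' @param newdata Angles (degrees) at which to evaluate the model.
#' @param ... Unused.
#' @export
predict.gravity_passive_fit <- function(object, newdata, ...) {
  drop(outer(newdata, 0:object$degree, `^`) %*% object$coef)
}

#' Correct torque for gravitational and passive components
#'
#' Subtracts the fitted angle-specific gravity/passive torque from a
#' filtered torque series; warns when angles extrapolate beyond the range
#' the model was fitted on.
#'
#' @param torque_Nm Filtered torque series, N m.
#' @param angle_deg Ankle angle series aligned with the torque samples.
#' @param gp_fit A [fit_gravity_passive()] model.
#' @return Net active torque series, N m.
#' @export
correct_torque <- function(torque_Nm, angle_deg, gp_fit) {
  stopifnot(inherits(gp_fit, "gravity_passive_fit"),
            length(torque_Nm) == length(angle_deg))
  pad <- 0.02 * diff(gp_fit$range)
  if (any(angle_deg < gp_fit$range[1] - pad | angle_deg > gp_fit$range[2] + pad,
          na.rm = TRUE)) {
    warning("angles extrapolate beyond the fitted gravity/passive range")
  }
  torque_Nm - predict(gp_fit, angle_deg)
}

#' Estimate the Achilles tendon moment arm by the tendon excursion method
#'
#' Least-squares slope of tendon length against ankle angle during a
#' passive rotation; the moment arm is the negated slope, scaled by 1.22 to
#' account for moment-arm changes during maximum contractions.
#'
#' @param length_m Tendon length series, m.
#' @param angle_rad Ankle angle series, radians.
#' @param scale Contraction scale factor (default 1.22).
#' @return A list of class `moment_arm_estimate` with `ma_raw`, `ma_scaled`
#'   (both m), and `slope_se` (standard error of the slope, m/rad).
#' @export
estimate_moment_arm <- function(length_m, angle_rad, scale = 1.22) {
  stopifnot(length(length_m) == length(angle_rad))
  if (diff(range(angle_rad)) < 10 * pi / 180) {
    stop("input error: passive rotation must span at least 10 degrees")
  }
  fit <- lm(length_m ~ angle_rad)
  slope <- unname(coef(fit)[2])
  n <- length(angle_rad)
  sxx <- sum((angle_rad - mean(angle_rad))^2)
  se <- sqrt(sum(fit$residuals^2) / (n - 2) / sxx)
  if (se > 0.1 * abs(slope)) {
    warning("low-quality moment-arm fit: slope SE exceeds 10% of the slope")
  }
  structure(list(ma_raw = -slope, ma_scaled = -slope * scale,
                 slope_se = se, scale = scale),
            class = "moment_arm_estimate")
}

#' @export
print.moment_arm_estimate <- function(x, ...) {
  cat(sprintf("Moment arm: raw %.4f m, scaled (x%.2f) %.4f m (slope SE %.2g)\n",
              x$ma_raw, x$scale, x$ma_scaled, x$slope_se))
  invisible(x)
}

#' GM Achilles tendon force from net ankle torque
#'
#' Divides the net plantar-flexion torque by the moment arm and weights by
#' the GM's anatomical proportion of the plantar flexors (15.9% by
#' physiological cross-sectional area).
#'
#' @param torque_Nm Net active torque, N m.
#' @param ma Achilles tendon moment arm, m.
#' @param gm_fraction GM fraction of the plantar flexors.
#' @return GM tendon force in N.
#' @export
gm_tendon_force <- function(torque_Nm, ma, gm_fraction = 0.159) {
  stopifnot(ma > 0)
  torque_Nm * gm_fraction / ma
}

#' EMG envelope: band-pass, rectify, smooth
#'
#' Offset correction (mean subtraction), 4th-order Butterworth band-pass,
#' full-wave rectification, and a centered moving average (default 75 ms).
#' The upper band edge defaults to 450 Hz (0.45 of the 1 kHz sampling rate),
#' the highest realizable corner below the Nyquist frequency.
#'
#' @param x Raw EMG series, mV.
#' @param fs Sampling rate, Hz.
#' @param band Band-pass corners in Hz.
#' @param smooth_ms Moving-average window in ms.
#' @return Envelope series (same length; edge windows use partial means).
#' @export
emg_envelope <- function(x, fs = 1000, band = c(10, 450), smooth_ms = 75) {
  stopifnot(band[1] > 0, band[2] < fs / 2, band[1] < band[2])
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- abs(.filtfilt_padded(bf, x - mean(x)))
  n <- max(1L, round(smooth_ms / 1000 * fs))
  half <- n %/% 2
  cs <- cumsum(c(0, y))
  i <- seq_along(y)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, length(y))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Normalize an EMG envelope by the MVIC peak
#'
#' @param envelope Envelope series from [emg_envelope()].
#' @param mvic_peak Peak envelope value over all fixed-end MVICs at 0 deg.
#' @return Envelope as a fraction of the MVIC peak.
#' @export
normalize_emg <- function(envelope, mvic_peak) {
  if (!is.finite(mvic_peak) || mvic_peak <= 0) {
    stop("input error: MVIC peak must be positive")
  }
  envelope / mvic_peak
}

#' Mean fascicle shortening velocity
#'
#' Least-squares slope of fascicle length over time within the shortening
#' phase (negative = shortening).
#'
#' @param length_cm Fascicle length samples, cm (NA allowed).
#' @param time_s Sample times, s.
#' @return Mean velocity in cm/s.
#' @export
mean_fascicle_velocity <- function(length_cm, time_s) {
  ok <- is.finite(length_cm) & is.finite(time_s)
  if (sum(ok) < 3) stop("input error: need at least 3 fascicle samples")
  unname(coef(lm(length_cm[ok] ~ time_s[ok]))[2])
}

#' Normalize fascicle length by the optimal fascicle length
#'
#' @param length_cm Fascicle length, cm.
#' @param l_opt Optimal fascicle length, cm (default 4.2).
#' @return Dimensionless normalized length.
#' @export
normalize_fascicle_length <- function(length_cm, l_opt = 4.2) {
  length_cm / l_opt
}

# Net active torque of a trial interpolated at an angle (steady maximum for
# fixed-end trials).
.trial_torque_at <- function(trial, gp_fit, angle = 0) {
  d <- trial$data
  tq <- filter_torque(d$torque_Nm, fs = trial$meta$fs)
  net <- if (is.null(gp_fit)) tq else correct_torque(tq, d$angle_deg, gp_fit)
  if (identical(trial$meta$kind, "fixed_end")) return(max(net))
  th <- d$angle_deg
  idx <- which(th[-1] >= angle & th[-length(th)] <= angle)
  if (length(idx) == 0) stop("trial never crosses ", angle, " deg")
  i <- idx[1]
  w <- (angle - th[i]) / (th[i + 1] - th[i])
  (1 - w) * net[i] + w * net[i + 1]
}

#' Select the better of two recorded trials
#'
#' Returns the trial with the higher net torque at 0 deg (interpolated at
#' the crossing for shortening trials, steady maximum for fixed-end
#' trials); ties return the first.
#'
#' @param trial_a,trial_b Trials from [read_trial_csv()] or
#'   [generate_invivo_trial()].
#' @param gp_fit Optional gravity/passive model used to net the torques.
#' @return The selected trial.
#' @export
select_better_trial <- function(trial_a, trial_b, gp_fit = NULL) {
  ta <- .trial_torque_at(trial_a, gp_fit)
  tb <- .trial_torque_at(trial_b, gp_fit)
  if (tb > ta) trial_b else trial_a
}

#' Measured angular velocity at the 0 deg crossing
#'
#' Smooths the angle channel (4th-order zero-lag low-pass, 6 Hz),
#' differentiates by central differences, and interpolates at the first
#' 0 deg crossing.
#'
#' @param trial An in vivo trial.
#' @return Angular velocity in deg/s.
#' @export
omega_at_zero <- function(trial) {
  d <- trial$data
  fs <- trial$meta$fs
  bf <- signal::butter(4, 6 / (fs / 2), type = "low")
  th <- .filtfilt_padded(bf, d$angle_deg)
  n <- length(th)
  om <- c(NA, (th[-(1:2)] - th[-((n - 1):n)]) * fs / 2, NA)
  idx <- which(th[-1] >= 0 & th[-n] <= 0)
  if (length(idx) == 0) stop("trial never crosses 0 deg")
  i <- max(idx[1], 2)
  w <- (0 - th[i]) / (th[i + 1] - th[i])
  (1 - w) * om[i] + w * om[i + 1]
}

#' Assemble the in vivo T-omega-r table from processed trials
#'
#' For each shortening trial: filters and gravity-corrects the torque,
#' interpolates the net torque at the 0 deg crossing, measures the angular
#' velocity at 0 deg from the smoothed angle derivative, and computes the
#' mean fascicle velocity over the rotation window.  Torques are normalized
#' by the fixed-end MVIC reference processed the same way.
#'
#' @param trials List of shortening trials (one per velocity setting).
#' @param mvic_trial Fixed-end MVIC reference trial at 0 deg.
#' @param gp_fit Gravity/passive model from [fit_gravity_passive()].
#' @return A data.frame with columns `omega_setting, omega_at0, torque_norm,
#'   fascicle_velocity_cm_s`.
#' @export
build_invivo_towr <- function(trials, mvic_trial, gp_fit) {
  ref <- .trial_torque_at(mvic_trial, gp_fit)
  if (!is.finite(ref) || ref <= 0) stop("input error: invalid MVIC reference")
  rows <- lapply(trials, function(tr) {
    d <- tr$data
    tq0 <- .trial_torque_at(tr, gp_fit)
    om0 <- omega_at_zero(tr)
    # fascicle slope over the rotation window (angle moving, ends excluded)
    th_lo <- min(d$angle_deg) + 1
    th_hi <- max(d$angle_deg) - 1
    win <- d$angle_deg > th_lo & d$angle_deg < th_hi & is.finite(d$fascicle_cm)
    vf <- if (sum(win) >= 3) {
      mean_fascicle_velocity(d$fascicle_cm[win], d$time_s[win])
    } else NA_real_
    data.frame(omega_setting = tr$meta$omega_setting, omega_at0 = om0,
               torque_norm = tq0 / ref, fascicle_velocity_cm_s = vf)
  })
  out <- do.call(rbind, rows)
  out[order(out$omega_setting), , drop = FALSE]
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient.
#' @export
pearson_r <- function(x, y) cor(x, y)
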