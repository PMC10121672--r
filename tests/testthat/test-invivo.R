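test_that("torque filter has unit DC gain, strong stopband, zero phase", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  expect_equal(filter_torque(rep(5, length(t)), fs), rep(5, length(t)),
               tolerance = 1e-9)
  # 50 Hz (5x cutoff) attenuated by > 99% after the dual pass
  x50 <- sin(2 * pi * 50 * t)
  y <- filter_torque(x50, fs)
  mid <- y[500:2500]
  expect_lt(max(abs(mid)), 0.01)
  # a smooth pulse keeps its peak position (zero phase)
  pulse <- exp(-((t - 1.5) / 0.3)^2)
  expect_lt(abs(which.max(filter_torque(pulse, fs)) - which.max(pulse)), 2)
  expect_error(filter_torque(pulse, fs, time = t^1.01), "non-uniform")
})

test_that("gravity/passive correction removes the fitted model", {
  th <- seq(-20, 20, by = 0.25)
  truth <- -4 - 0.12 * th + 0.0015 * th^2
  set.seed(7)
  gp <- fit_gravity_passive(th, truth + rnorm(length(th), sd = 0.2))
  # passive trial through the model: near-zero mean residual
  resid <- correct_torque(truth, th, gp)
  expect_lt(abs(mean(resid)), 2 * gp$resid_sd)
  # zero-torque channel returns the negated model exactly
  expect_equal(correct_torque(rep(0, length(th)), th, gp),
               -predict(gp, th), tolerance = 1e-12)
  # known signal + gravity curve is recovered within the fit residual
  sig <- 100 * exp(-((th) / 8)^2)
  rec <- correct_torque(sig + truth, th, gp)
  expect_equal(rec, sig, tolerance = 0.05)
  expect_warning(correct_torque(c(0, 0), c(-30, 0), gp), "extrapolate")
})

test_that("tendon-excursion moment arm estimation recovers known slopes", {
  th <- seq(-0.3, 0.3, length.out = 200)
  len <- 0.4 - 0.0459 * th
  ma <- estimate_moment_arm(len, th)
  expect_equal(ma$ma_raw, 0.0459, tolerance = 1e-9)
  expect_equal(ma$ma_scaled, 0.0459 * 1.22, tolerance = 1e-9)
  expect_equal(ma$ma_scaled / ma$ma_raw, 1.22)
  expect_equal(ma$ma_scaled, 0.0560, tolerance = 1e-3)
  # seeded noise keeps recovery within 2%
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    m <- estimate_moment_arm(len + rnorm(200, sd = 2e-4), th)
    abs(m$ma_raw / 0.0459 - 1)
  }, numeric(1))
  expect_lt(max(errs), 0.02)
  expect_error(estimate_moment_arm(len[1:5], th[1:5] / 10), "10 degrees")
})

test_that("GM tendon force weighting and proportionality", {
  expect_equal(gm_tendon_force(218, 0.055), 218 * 0.159 / 0.055)
  expect_equal(gm_tendon_force(218, 0.055), 630.2, tolerance = 1e-3)
  expect_equal(gm_tendon_force(0, 0.055), 0)
  expect_equal(gm_tendon_force(100, 0.11), gm_tendon_force(100, 0.055) / 2)
})

test_that("EMG envelope pipeline: DC rejection, sinusoid mean, self-normalization", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  expect_lt(max(emg_envelope(rep(3, length(t)), fs)), 1e-9)
  # 100 Hz sinusoid of amplitude A: envelope ~ 2A/pi
  A <- 0.8
  env <- emg_envelope(A * sin(2 * pi * 100 * t), fs)
  expect_equal(median(env[200:1800]), 2 * A / pi, tolerance = 0.05)
  env_n <- normalize_emg(env, max(env))
  expect_equal(max(env_n), 1)
  expect_error(normalize_emg(env, 0), "positive")
})

test_that("fascicle velocity and length normalization", {
  t <- seq(0, 0.5, length.out = 32)
  len <- 4.2 + (3.6 - 4.2) * t / 0.5
  expect_equal(mean_fascicle_velocity(len, t), -1.2, tolerance = 1e-9)
  expect_equal(mean_fascicle_velocity(len + 2, t), -1.2, tolerance = 1e-9)
  expect_equal(normalize_fascicle_length(4.2), 1)
  expect_error(mean_fascicle_velocity(c(4, NA, NA), t[1:3]), "3 fascicle")
})

test_that("trial selection takes the higher torque at 0 deg, ties to the first", {
  cfg <- synthetic_config(seed = 3,
                          noise = list(torque = 0, angle = 0, emg = 0.01,
                                       fascicle = 0, excursion = 0))
  tr_hi <- generate_invivo_trial(cfg, 40, "shortening")
  tr_lo <- suppressWarnings(generate_invivo_trial(cfg, 160, "shortening"))
  expect_identical(select_better_trial(tr_hi, tr_lo), tr_hi)
  expect_identical(select_better_trial(tr_lo, tr_hi), tr_hi)
  expect_identical(select_better_trial(tr_hi, tr_hi), tr_hi)
})

test_that("pearson_r matches the product-moment definition", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
})
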