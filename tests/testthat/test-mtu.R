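test_that("pennation geometry follows the constant-thickness model", {
  arch <- muscle_architecture()
  expect_equal(pennation_angle(arch$l_o_CE, arch), 32.5 * pi / 180,
               tolerance = 1e-12)
  # arcsin(0.5) case: fiber at twice the constant-thickness height
  h <- arch$l_o_CE * sin(arch$alpha_o)
  expect_equal(pennation_angle(2 * h, arch), asin(0.5), tolerance = 1e-12)
  l <- seq(0.8, 1.6, by = 0.1) * arch$l_o_CE
  expect_true(all(diff(pennation_angle(l, arch)) < 0))
  expect_error(pennation_angle(0.5 * h, arch), "limit")
})

test_that("path model is linear with the documented moment arm", {
  path <- joint_path(l_P_ref = 0.45)
  expect_equal(path_length(0, path), 0.45)
  expect_equal(path_length(15, path) - path_length(0, path),
               -0.056 * 15 * pi / 180, tolerance = 1e-12)
  expect_equal(path_length(15, path) - path_length(0, path), -0.01466,
               tolerance = 1e-3)
  # path velocity at 200 deg/s
  expect_equal(-0.056 * 200 * pi / 180, -0.1955, tolerance = 1e-3)
})

test_that("activation dynamics match the first-order closed forms", {
  expect_equal(activation_rate(0.5, 0.5), 0)
  # step response checks via exact exponentials
  a_step <- function(t) 1 - exp(-t / 0.015)
  expect_equal(a_step(0.015), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(activation_rate(0, 1), 1 / 0.015)
  expect_equal(activation_rate(1, 0), -1 / 0.050)
  ctx <- model_ctx("typical")
  tr <- simulate_trial(protocol_spec(200, preload = 0), ctx$arch, ctx$path)
  a75 <- approx(tr$time_s, tr$activation, xout = 0.075)$y
  expect_equal(a75, 1 - exp(-5), tolerance = 1e-4)
})

test_that("static equilibrium satisfies its contract", {
  ctx <- model_ctx("typical")
  arch <- ctx$arch; path <- ctx$path
  for (a in c(1, 0.5)) {
    lce <- static_fiber_length(a, -15, arch, path)
    ca <- cos(pennation_angle(lce, arch))
    e <- (path_length(-15, path) - lce * ca - arch$l_s_T) / arch$l_s_T
    resid <- eval_ft(e, arch) -
      (a * eval_fl(lce / arch$l_o_CE) + eval_fpe(lce / arch$l_o_CE)) * ca
    expect_lt(abs(resid), 1e-9)
  }
  # active contraction stretches the tendon and shortens the CE
  expect_lt(static_fiber_length(1, -15, arch, path),
            static_fiber_length(0, -15, arch, path))
  # rigid variant: fiber length is kinematically forced
  ctr <- model_ctx("rigid")
  lce <- static_fiber_length(1, 0, ctr$arch, ctr$path)
  ca <- cos(pennation_angle(lce, ctr$arch))
  expect_equal(lce * ca, path_length(0, ctr$path) - ctr$arch$l_s_T,
               tolerance = 1e-12)
})

test_that("path-offset calibration puts peak active torque at 17 deg dorsiflexion", {
  for (tendon in c("typical", "compliant", "rigid")) {
    ctx <- model_ctx(tendon)
    ang <- peak_torque_angle(ctx$arch, ctx$path)
    expect_gte(ang, -17.25)
    expect_lte(ang, -16.75)
  }
  # idempotence
  ctx <- model_ctx("typical")
  again <- calibrate_path_offset(ctx$arch, joint_path())
  expect_equal(again$l_P_ref, ctx$path$l_P_ref, tolerance = 1e-6)
  # pinned direction: lengthening the neutral path moves the peak toward
  # plantar flexion (the optimal path length is reached at a larger angle)
  shifted <- joint_path(l_P_ref = ctx$path$l_P_ref + 0.01)
  expect_gt(peak_torque_angle(ctx$arch, shifted, seq(-40, 10, 0.1)), -17)
})

test_that("partial preload uses a force criterion", {
  ctx <- model_ctx("compliant")
  u50 <- preload_excitation(0.5, -15, ctx$arch, ctx$path)
  f <- static_force(u50, -15, ctx$arch, ctx$path)
  f_full <- static_force(1, -15, ctx$arch, ctx$path)
  expect_equal(f / f_full, 0.5, tolerance = 1e-7)
  expect_gt(u50, 0)
  expect_lt(u50, 0.5)  # activation nonlinearity: force 50% needs less than u=0.5
})

test_that("fiber velocity solve is static-consistent and residual-free", {
  ctx <- model_ctx("typical")
  lce <- static_fiber_length(1, -15, ctx$arch, ctx$path)
  sol <- fiber_velocity(1, lce, -15, 0, ctx$arch, ctx$path)
  expect_lt(abs(sol$v_CE), 1e-9)
  expect_lt(abs(sol$resid), 1e-9)
  # moving states across activation levels and velocities
  for (om in c(-100, 50, 200)) for (a in c(0.1, 0.9)) {
    sol <- fiber_velocity(a, lce * 0.95, -5, om, ctx$arch, ctx$path)
    expect_lt(abs(sol$resid), 1e-9)
  }
  expect_error(fiber_velocity(1, lce, 0, 0, model_ctx("rigid")$arch,
                              model_ctx("rigid")$path), "rigid")
})

test_that("rigid-tendon simulation matches the closed-form algebraic oracle", {
  ctx <- model_ctx("rigid")
  arch <- ctx$arch; path <- ctx$path
  tr <- simulate_trial(protocol_spec(150, preload = 1), arch, path)
  h <- arch$l_o_CE * sin(arch$alpha_o)
  lP <- path$l_P_ref - path$r * tr$theta_deg * pi / 180
  x <- lP - arch$l_s_T
  lce <- sqrt(x^2 + h^2)
  ca <- x / lce
  vP <- -path$r * tr$omega_deg_s * pi / 180
  vtil <- vP * ca / (arch$l_o_CE * arch$v_max)
  oracle <- path$r * arch$f_o_CE *
    (tr$activation * eval_fl(lce / arch$l_o_CE) * suppressWarnings(eval_fv(vtil)) +
       eval_fpe(lce / arch$l_o_CE) + arch$fiber_damping * vtil) * ca
  expect_equal(tr$torque_Nm, oracle, tolerance = 1e-6)
})

test_that("trial traces satisfy the state invariants at every sample", {
  for (tendon in c("typical", "compliant")) {
    ctx <- model_ctx(tendon)
    for (spec in list(protocol_spec(200, preload = 0),
                      protocol_spec(100, preload = 1))) {
      tr <- simulate_trial(spec, ctx$arch, ctx$path)
      # kinematic closure v_P = v_CE_AT + v_T
      vP <- -ctx$path$r * tr$omega_deg_s * pi / 180
      expect_lt(max(abs(vP - tr$v_CE_AT_m_s - tr$v_T_m_s)), 1e-9)
      # force-balance residual below 1e-6 * fo (resid_norm is in units of fo)
      expect_lt(max(abs(tr$resid_norm)), 1e-6)
      expect_true(all(tr$activation >= 0 & tr$activation <= 1))
      h <- ctx$arch$l_o_CE * sin(ctx$arch$alpha_o)
      expect_true(all(tr$l_CE_m >= h))
      # cumulative CE work non-decreasing while the CE shortens
      shortening <- tr$v_CE_AT_m_s[-1] < 0
      expect_true(all(diff(tr$W_CE_J)[shortening] >= -1e-12))
    }
  }
})

test_that("preloaded elastic trials recoil the tendon at the sample angle", {
  ctx <- model_ctx("typical")
  for (om in c(50, 120, 200)) {
    s <- sample_at_angle(simulate_trial(protocol_spec(om, preload = 1),
                                        ctx$arch, ctx$path), 0)
    expect_lt(s$v_T_m_s, 0)
  }
})

test_that("non-preloaded rotation reaches 0 deg in 75 ms at 200 deg/s", {
  ctx <- model_ctx("typical")
  tr <- simulate_trial(protocol_spec(200, preload = 0), ctx$arch, ctx$path)
  i0 <- which(tr$theta_deg[-1] >= 0 & tr$theta_deg[-nrow(tr)] <= 0)[1]
  w <- -tr$theta_deg[i0] / (tr$theta_deg[i0 + 1] - tr$theta_deg[i0])
  t_cross <- (1 - w) * tr$time_s[i0] + w * tr$time_s[i0 + 1]
  expect_equal(t_cross, 0.075, tolerance = 1e-6)
})

test_that("halving integrator tolerances leaves the sampled torque unchanged", {
  ctx <- model_ctx("compliant")
  s1 <- sample_at_angle(simulate_trial(protocol_spec(150, preload = 1),
                                       ctx$arch, ctx$path), 0)
  s2 <- sample_at_angle(simulate_trial(protocol_spec(150, preload = 1),
                                       ctx$arch, ctx$path,
                                       rtol = 5e-9, atol = 5e-11), 0)
  expect_lt(abs(s1$torque_Nm - s2$torque_Nm) / s1$torque_Nm, 1e-4)
})
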