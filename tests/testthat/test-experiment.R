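test_that("sampling at an angle interpolates the crossing accurately", {
  ctx <- model_ctx("typical")
  spec <- protocol_spec(120, preload = 1)
  s1 <- sample_at_angle(simulate_trial(spec, ctx$arch, ctx$path), 0)
  s10 <- sample_at_angle(simulate_trial(spec, ctx$arch, ctx$path, dt = 1e-4), 0)
  expect_lt(abs(s1$torque_Nm - s10$torque_Nm) / s10$torque_Nm, 1e-4)
  # fixed-end trial: steady value, self-normalizing to the static reference
  tr0 <- simulate_trial(protocol_spec(0), ctx$arch, ctx$path)
  s0 <- sample_at_angle(tr0, 0)
  expect_equal(s0$torque_Nm, static_torque(1, 0, ctx$arch, ctx$path),
               tolerance = 1e-6)
  expect_error(sample_at_angle(simulate_trial(protocol_spec(100, preload = 1,
                                                           theta_end = -5),
                                              ctx$arch, ctx$path), 0),
               "never reaches")
})

test_that("quasi-static CE work is the slow-rotation limit", {
  ctx <- model_ctx("typical")
  w_qs <- ce_work_quasistatic(ctx$arch, ctx$path)
  # grid refinement changes the integral negligibly
  expect_equal(w_qs, ce_work_quasistatic(ctx$arch, ctx$path, n = 2401),
               tolerance = 1e-6)
  # slow preloaded and non-preloaded trials both approach the quasi-static
  # work from below (finite shortening velocity costs force), and the
  # slower trial is closer
  w10 <- ce_work(simulate_trial(protocol_spec(10, preload = 1),
                                ctx$arch, ctx$path))
  w10_np <- ce_work(simulate_trial(protocol_spec(10, preload = 0),
                                   ctx$arch, ctx$path))
  w40 <- ce_work(simulate_trial(protocol_spec(40, preload = 1),
                                ctx$arch, ctx$path))
  expect_equal(w10, w_qs, tolerance = 0.1)
  expect_equal(w10_np, w_qs, tolerance = 0.1)
  expect_lt(w10, w_qs)
  expect_lt(abs(w10 - w_qs), abs(w40 - w_qs))
})

test_that("rigid fixed-end contraction does no CE work", {
  ctx <- model_ctx("rigid")
  tr <- simulate_trial(protocol_spec(0), ctx$arch, ctx$path)
  expect_equal(ce_work(tr), 0, tolerance = 1e-12)
})

test_that("energy closes: CE work = tendon storage + joint output", {
  for (tendon in c("typical", "compliant")) {
    ctx <- model_ctx(tendon)
    for (spec in list(protocol_spec(200, preload = 0),
                      protocol_spec(60, preload = 1),
                      protocol_spec(200, preload = 1))) {
      ec <- energy_closure(simulate_trial(spec, ctx$arch, ctx$path))
      expect_lt(abs(ec$residual), 0.001 * max(1, ec$W_CE))
    }
  }
  # with tendon damping the balance residual is dissipation: non-negative
  archd <- muscle_architecture(tendon = "compliant", tendon_damping = TRUE)
  pathd <- calibrate_path_offset(archd)
  ec <- energy_closure(simulate_trial(protocol_spec(150, preload = 1),
                                      archd, pathd))
  expect_gte(ec$residual, 0)
})

test_that("the block study covers the design grid deterministically", {
  blk <- block_ctx("fig4")
  expect_length(blk, 8)
  expect_true(all(vapply(blk, nrow, 0L) == 21))
  for (d in blk) {
    expect_true(all(diff(d$omega) == 10))
    expect_equal(d$torque_norm[1], 1, tolerance = 1e-6)
    expect_true(all(d$torque_norm >= 0))
  }
  # determinism: an independent re-run of one condition reproduces the block
  again <- run_block(design = data.frame(preload = 1, tendon = "typical"),
                     omegas = c(0, 100, 200))
  expect_equal(again[[1]]$torque_norm,
               blk$preload100_typical$torque_norm[c(1, 11, 21)],
               tolerance = 1e-12)
})

test_that("tendon-strain fitting recovers itself and is locally optimal", {
  omegas <- c(0, 50, 100, 150, 200)
  obs <- towr_profile(0.092, 1, omegas)
  fit <- fit_tendon_strain(obs, preload = 1)
  expect_equal(fit$e_o, 0.092, tolerance = 0.002)
  expect_false(fit$boundary)
  # objective at the truth below neighbours
  sse <- function(e) sum((towr_profile(e, 1, omegas)$torque_norm -
                            obs$torque_norm)^2)
  expect_lte(sse(0.092), sse(0.072))
  expect_lte(sse(0.092), sse(0.112))
})

test_that("a rigid-like flat profile is reported at the boundary", {
  obs <- data.frame(omega = c(0, 100, 200), torque_norm = c(1, 1, 1))
  expect_warning(fit <- fit_tendon_strain(obs, preload = 1,
                                          cache = NULL,
                                          bounds = c(0.02, 0.04)),
                 "boundary")
  expect_true(fit$boundary)
})
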