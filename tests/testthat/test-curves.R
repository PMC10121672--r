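test_that("curve anchors hold exactly", {
  expect_equal(eval_fl(1), 1, tolerance = 1e-9)
  expect_equal(eval_fl(0.3), 0)          # outside active support
  expect_equal(eval_fl(1.95), 0)
  expect_equal(eval_fv(0), 1, tolerance = 1e-9)
  expect_equal(eval_fv(-1), 0, tolerance = 1e-9)
  expect_equal(eval_fpe(0.9), 0)
  expect_equal(eval_fpe(1 + curve_constants()$e_o_PE), 1, tolerance = 1e-9)
  expect_equal(eval_ft(0, 0.049), 0)
  expect_equal(eval_ft(0.049, 0.049), 1, tolerance = 1e-9)
  expect_equal(eval_ft(0.092, 0.092), 1, tolerance = 1e-9)
})

test_that("pinned regression fixtures of the default curves", {
  expect_equal(eval_fl(1.25), 0.7741407629, tolerance = 1e-9)
  expect_equal(eval_fl(0.73), 0.767368, tolerance = 1e-9)
  expect_equal(eval_fv(-0.5), 0.2368421053, tolerance = 1e-9)
  expect_gt(eval_fv(-0.5), 0)
  expect_lt(eval_fv(-0.5), 0.5)
  expect_equal(eval_fpe(1.2), 0.02332361516035, tolerance = 1e-9)
})

test_that("force-velocity inverse round-trips over the full force range", {
  f <- seq(0, 1.4 - 1e-6, length.out = 1000)
  v <- inv_fv(f)
  expect_equal(eval_fv(v), f, tolerance = 1e-9)
  expect_equal(inv_fv(1), 0, tolerance = 1e-12)
  expect_equal(inv_fv(0), -1, tolerance = 1e-12)
  expect_equal(inv_fv(eval_fv(-0.37)), -0.37, tolerance = 1e-9)
})

test_that("force-velocity curve shape and clamping", {
  v <- seq(-1, 2, by = 0.01)
  fv <- eval_fv(v)
  expect_true(all(diff(fv) > 0))                     # strictly increasing
  expect_true(all(fv <= curve_constants()$fv_eccentric_plateau))
  expect_warning(res <- eval_fv(c(-1.5, 0)), "clamped")
  expect_equal(res[1], 0)
})

test_that("active force-length is unimodal with compact support inside (0,2)", {
  sup <- curve_constants()$fl_support
  expect_gt(sup[1], 0)
  expect_lt(sup[2], 2)
  l <- seq(0.05, 1.99, by = 0.005)
  fl <- eval_fl(l)
  expect_true(all(fl >= 0 & fl <= 1))
  i_max <- which.max(fl)
  expect_true(all(diff(fl[seq_len(i_max)]) >= 0))
  expect_true(all(diff(fl[i_max:length(fl)]) <= 0))
  expect_error(eval_fl(-0.5), "positive")
  expect_error(eval_fl(0), "positive")
})

test_that("analytic curve derivatives match central differences", {
  h <- 1e-6
  num <- function(f, x) (f(x + h) - f(x - h)) / (2 * h)
  l <- c(0.5, 0.6, 0.8, 0.95, 1.1, 1.4, 1.7)      # away from segment joints
  expect_equal(deriv_fl(l), num(eval_fl, l), tolerance = 1e-5)
  v <- c(-0.9, -0.5, -0.2, 0.3, 1)
  expect_equal(deriv_fv(v), num(eval_fv, v), tolerance = 1e-5)
  lp <- c(1.1, 1.3, 1.6)
  expect_equal(deriv_fpe(lp), num(eval_fpe, lp), tolerance = 1e-5)
  e <- c(0.01, 0.02, 0.04, 0.06)
  expect_equal(deriv_ft(e, 0.049),
               num(function(x) eval_ft(x, 0.049), e), tolerance = 1e-5)
})

test_that("tendon force-strain is strictly increasing and C1 at the toe", {
  e <- seq(1e-4, 1.5 * 0.049, length.out = 400)
  ft <- eval_ft(e, 0.049)
  expect_true(all(diff(ft) > 0))
  # slope continuity across the toe end (2/3 e_o)
  et <- 2 * 0.049 / 3
  expect_equal(deriv_ft(et - 1e-9, 0.049), deriv_ft(et + 1e-9, 0.049),
               tolerance = 1e-6)
})

test_that("tendon stiffness and damping laws", {
  arch <- muscle_architecture()
  ls <- arch$l_s_T
  expect_equal(tendon_stiffness(ls, arch), 0)
  # linear-region stiffness = fo/ls * 1.5/e_o
  expect_equal(tendon_stiffness(ls * 1.049, arch),
               arch$f_o_CE / ls * 1.5 / 0.049, tolerance = 1e-9)
  expect_lte(tendon_stiffness(ls * 1.02, arch),
             tendon_stiffness(ls * 1.049, arch))
  # damping scales with stiffness by exactly 0.05
  lT <- ls * c(1.01, 1.03, 1.049)
  expect_equal(tendon_damping_beta(lT, arch) / tendon_stiffness(lT, arch),
               rep(0.05, 3))
  rigid <- muscle_architecture(tendon = "rigid")
  expect_error(tendon_stiffness(ls, rigid), "rigid")
  expect_error(eval_ft(0.02, rigid), "rigid")
})

test_that("curve table spans all four curves", {
  tab <- curve_table()
  expect_named(tab, c("x", "fl", "fv", "fpe", "ft"))
  expect_true(all(is.finite(as.matrix(tab))))
})
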