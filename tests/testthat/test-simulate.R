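test_that("pure relaxation integrates to the closed-form exponential", {
  spec <- model_spec("sigmoidal", 1,
                     active_params = c("tau_1", "theta_1", "W_1_1"))
  pv <- pack_params(sigmoidal_params(1, matrix(0, 1, 1), 0), spec)
  tr <- integrate_model(spec, pv, 1, NULL, c(0, 0.5, 1, 2))
  expect_equal(tr$status, "ok")
  expect_equal(tr$states[, 1], exp(-c(0, 0.5, 1, 2)), tolerance = 1e-6)
})

test_that("an S-system at production-degradation balance stays constant", {
  spec <- model_spec("s_system", 1,
                     active_params = c("alpha_1", "beta_1", "h_1_1", "g_1_1"))
  pv <- pack_params(ssystem_params(2, 2, matrix(1.3, 1, 1), matrix(1.3, 1, 1)),
                    spec)
  tr <- integrate_model(spec, pv, 1.7, NULL, seq(0, 3, 0.5))
  expect_equal(tr$states[, 1], rep(1.7, 7), tolerance = 1e-8)
})

test_that("finite-time blow-up is flagged, not raised", {
  # dx/dt = x^2 diverges at t = 1/x0
  spec <- model_spec("s_system", 1,
                     active_params = c("alpha_1", "beta_1", "h_1_1", "g_1_1"))
  pv <- pack_params(ssystem_params(1, 0, matrix(2, 1, 1), matrix(0, 1, 1)),
                    spec)
  tr <- integrate_model(spec, pv, 1, NULL, c(0, 0.9, 1.5))
  expect_equal(tr$status, "blow_up")
  expect_true(all(is.na(tr$states[3, ])))
})

test_that("S-system trajectories that cross zero report positivity violation", {
  # dx/dt = -1 (alpha 0, beta 1, h = 0): hits zero at t = x0
  spec <- model_spec("s_system", 1,
                     active_params = c("alpha_1", "beta_1", "h_1_1"))
  pv <- pack_params(ssystem_params(0, 1, matrix(0, 1, 1), matrix(0, 1, 1)),
                    spec)
  tr <- integrate_model(spec, pv, 0.5, NULL, c(0, 2))
  expect_equal(tr$status, "positivity_violation")
})

test_that("gravity rhs matches hand evaluation and balances circular orbits", {
  expect_equal(gravity_rhs(1, 0, ell = 0, mu = 1), c(0, -1))
  # circular orbit: r = ell^2/mu
  expect_equal(gravity_rhs(4, 0, ell = 2, mu = 1), c(0, 0))
  expect_error(gravity_rhs(-1, 0, 1, 1), "domain")
})

test_that("gravity trajectories conserve energy", {
  for (ell in c(0.8, 1.5)) {
    tr <- integrate_gravity(1.2, 0, ell = ell, mu = 1, times = seq(0, 8, 0.25))
    r <- tr$states[, 1]; v <- tr$states[, 2]
    E <- v^2 / 2 + ell^2 / (2 * r^2) - 1 / r
    expect_lt(max(abs(E - E[1])), 1e-5)
  }
})

test_that("halving tolerances changes terminal states by less than the coarser tolerance", {
  spec <- model_spec("sigmoidal", 1,
                     active_params = c("tau_1", "theta_1", "W_1_1"))
  pv <- pack_params(sigmoidal_params(0.7, matrix(2, 1, 1), 0.3), spec)
  coarse <- integrate_model(spec, pv, 1, NULL, c(0, 5),
                            default_control(rtol = 1e-6, atol = 1e-8))
  fine <- integrate_model(spec, pv, 1, NULL, c(0, 5),
                          default_control(rtol = 5e-7, atol = 5e-9))
  expect_lt(abs(coarse$states[2, 1] - fine$states[2, 1]),
            1e-6 * max(1, abs(coarse$states[2, 1])))
})

test_that("the integrator agrees with an independent stiff solver", {
  skip_if_not_installed("deSolve")
  m <- build_glycolysis_model()
  x0 <- m$x0_cycle
  tt <- seq(0, 3, 0.1)
  mine <- integrate_glycolysis(m, x0, tt,
                               default_control(rtol = 1e-9, atol = 1e-11))
  ref <- deSolve::lsoda(y = x0, times = tt,
                        func = function(t, y, p) list(m$rhs(y)),
                        rtol = 1e-9, atol = 1e-11)
  expect_equal(unname(mine$states), unname(as.matrix(ref[, -1])),
               tolerance = 1e-5)
})

test_that("model-evaluation counters increase with every integration", {
  reset_eval_counter()
  spec <- model_spec("sigmoidal", 1,
                     active_params = c("tau_1", "theta_1", "W_1_1"))
  pv <- pack_params(sigmoidal_params(1, matrix(0, 1, 1), 0), spec)
  c0 <- eval_counter()
  integrate_model(spec, pv, 1, NULL, c(0, 1))
  c1 <- eval_counter()
  expect_equal(c1[["model_evaluations"]], c0[["model_evaluations"]] + 1)
  expect_gt(c1[["rhs_evaluations"]], c0[["rhs_evaluations"]])
  integrate_model(spec, pv, 1, NULL, c(0, 1))
  expect_equal(eval_counter()[["model_evaluations"]],
               c0[["model_evaluations"]] + 2)
})

test_that("piecewise-constant inputs are applied segment by segment", {
  # relaxation toward W * xi(theta_in - I): saturate the input sigmoid so the
  # drive switches between 1 and 0 across the breakpoint
  spec <- model_spec("sigmoidal", 1, n_inputs = 1,
                     active_params = c("tau_1", "theta_1", "W_1_1",
                                       "Win_1_1", "thetain_1"))
  pv <- dynadapt:::new_param_vector(
    c(tau_1 = 1, theta_1 = 0, W_1_1 = 0, Win_1_1 = 1, thetain_1 = 0),
    spec)
  sig <- pw_input(c(0, 2), matrix(c(1000, -1000), 2, 1))
  tr <- integrate_model(spec, pv, 0, sig, c(0, 1, 2, 3, 4))
  # segment 1: dx = -x + 1 -> 1 - e^{-t}; segment 2: dx = -x
  expect_equal(tr$states[2, 1], 1 - exp(-1), tolerance = 1e-5)
  x2 <- 1 - exp(-2)
  expect_equal(tr$states[4, 1], x2 * exp(-1), tolerance = 1e-5)
  expect_equal(tr$states[5, 1], x2 * exp(-2), tolerance = 1e-5)
})

test_that("trajectories tidy into long tibbles", {
  spec <- model_spec("sigmoidal", 1,
                     active_params = c("tau_1", "theta_1", "W_1_1"))
  pv <- pack_params(sigmoidal_params(1, matrix(0, 1, 1), 0), spec)
  tr <- integrate_model(spec, pv, 1, NULL, c(0, 1, 2))
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("time", "variable", "value"))
  expect_equal(nrow(td), 3)
})
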