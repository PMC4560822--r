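test_that("chi-squared is zero on noiseless in-model data and sums squared residuals", {
  spec <- model_spec("sigmoidal", 1,
                     active_params = c("tau_1", "theta_1", "W_1_1"))
  pv <- pack_params(sigmoidal_params(2, matrix(0, 1, 1), 0), spec)
  tt <- c(0.5, 1, 3)
  tr <- integrate_model(spec, pv, 1, NULL, c(0, tt))
  recs <- tibble::tibble(condition = "c1", time = tt, variable = "x",
                         value = tr$states[-1, 1], sigma = 1)
  data <- timeseries_set(recs, list(c1 = list(x0 = c(x = 1))), "x")
  expect_lt(chi_squared(spec, pv, data), 1e-8)
  # single record: prediction 2, value 1, sigma 1 -> 1
  spec0 <- model_spec("sigmoidal", 1,
                      active_params = c("tau_1", "theta_1", "W_1_1"))
  pv0 <- pack_params(sigmoidal_params(1e8, matrix(0, 1, 1), 0), spec0)
  one <- timeseries_set(
    tibble::tibble(condition = "c1", time = 1, variable = "x",
                   value = 1, sigma = 1),
    list(c1 = list(x0 = c(x = 2))), "x")
  expect_equal(chi_squared(spec0, pv0, one), 1, tolerance = 1e-6)
})

test_that("chi-squared at true parameters is distributed like chi-squared on N records", {
  spec <- model_spec("sigmoidal", 1,
                     active_params = c("tau_1", "theta_1", "W_1_1"))
  pv <- pack_params(sigmoidal_params(2, matrix(0, 1, 1), 0), spec)
  tt <- seq(0.2, 5, length.out = 10)
  tr <- integrate_model(spec, pv, 1, NULL, c(0, tt))
  truth <- tr$states[-1, 1]
  sig <- pmax(0.05 * truth, 0.01)
  set.seed(202)
  vals <- replicate(200, {
    recs <- tibble::tibble(condition = "c1", time = tt, variable = "x",
                           value = truth + rnorm(10, 0, sig), sigma = sig)
    data <- timeseries_set(recs, list(c1 = list(x0 = c(x = 1))), "x")
    chi_squared(spec, pv, data)
  })
  # mean ~ N = 10, Monte-Carlo s.e. = sqrt(2N/200) ~ 0.32
  expect_equal(mean(vals), 10, tolerance = 0.15)
})

test_that("failed integrations give an infinite chi-squared sentinel", {
  spec <- model_spec("s_system", 1,
                     active_params = c("alpha_1", "beta_1", "h_1_1"))
  pv <- pack_params(ssystem_params(0, 1, matrix(0, 1, 1), matrix(0, 1, 1)),
                    spec)
  data <- timeseries_set(
    tibble::tibble(condition = "c1", time = 3, variable = "x",
                   value = 1, sigma = 1),
    list(c1 = list(x0 = c(x = 0.5))), "x")
  expect_equal(chi_squared(spec, pv, data), Inf)
})

test_that("log prior matches a closed-form density oracle and peaks at the mean", {
  spec <- model_spec("sigmoidal", 1, n_hidden = 1,
                     active_params = c("tau_1", "theta_1", "W_1_1", "tau_2",
                                       "theta_2", "x0_2", "W_2_2", "W_2_1",
                                       "W_1_2"))
  cfg <- fit_config()
  set.seed(33)
  for (rep in 1:20) {
    vals <- c(tau_1 = runif(1, 0.2, 4), theta_1 = rnorm(1), W_1_1 = rnorm(1, 0, 4),
              tau_2 = runif(1, 0.2, 4), theta_2 = rnorm(1), x0_2 = rnorm(1),
              W_2_2 = rnorm(1), W_2_1 = rnorm(1), W_1_2 = rnorm(1))
    pv <- dynadapt:::new_param_vector(vals, spec)
    # independent evaluation: normals on log tau, linear elsewhere
    manual <- dnorm(log(vals[["tau_1"]]), 0, log(10), log = TRUE) +
      dnorm(log(vals[["tau_2"]]), 0, log(10), log = TRUE) +
      sum(dnorm(vals[c("theta_1", "W_1_1", "theta_2", "x0_2", "W_2_2",
                       "W_2_1", "W_1_2")], 0, 10, log = TRUE))
    expect_equal(log_prior(pv, cfg), manual, tolerance = 1e-12)
  }
  at_mean <- dynadapt:::new_param_vector(
    c(tau_1 = 1, theta_1 = 0, W_1_1 = 0, tau_2 = 1, theta_2 = 0, x0_2 = 0,
      W_2_2 = 0, W_2_1 = 0, W_1_2 = 0), spec)
  shifted <- dynadapt:::new_param_vector(
    c(tau_1 = 1, theta_1 = 2, W_1_1 = 0, tau_2 = 1, theta_2 = 0, x0_2 = 0,
      W_2_2 = 0, W_2_1 = 0, W_1_2 = 0), spec)
  expect_gt(log_prior(at_mean, cfg), log_prior(shifted, cfg))
  # doubling a deviation decreases the log prior by the quadratic increment
  shifted4 <- dynadapt:::new_param_vector(
    c(tau_1 = 1, theta_1 = 4, W_1_1 = 0, tau_2 = 1, theta_2 = 0, x0_2 = 0,
      W_2_2 = 0, W_2_1 = 0, W_1_2 = 0), spec)
  expect_equal(log_prior(at_mean, cfg) - log_prior(shifted4, cfg),
               4 * (log_prior(at_mean, cfg) - log_prior(shifted, cfg)),
               tolerance = 1e-10)
})

test_that("fitting recovers the relaxation time from noisy decay data", {
  dd <- make_decay_data(N = 50, tau_true = 2, noise = 0.05, seed = 42)
  fit <- fit_model(dd$spec, dd$data,
                   config = fit_config(seed = 7, n_stages = 8,
                                       n_proposals = 25, optim_maxit = 60))
  expect_equal(fit$status, "ok")
  expect_equal(fit$params[["tau_1"]], 2, tolerance = 0.05)
})

test_that("a fit never worsens its starting point and is seed-reproducible", {
  dd <- make_decay_data(N = 20, seed = 5)
  cfg <- fit_config(seed = 12, n_stages = 3, n_proposals = 8,
                    optim_maxit = 20)
  start <- dd$params # the true optimum neighbourhood
  c_start <- chi_squared(dd$spec, start, dd$data) / 2 -
    log_prior(start, cfg)
  fit <- fit_model(dd$spec, dd$data, start = start, config = cfg)
  c_fit <- fit$chi2 / 2 - log_prior(fit$params, cfg)
  expect_lte(c_fit, c_start + 1e-9)
  fit2 <- fit_model(dd$spec, dd$data, start = start, config = cfg)
  expect_identical(as.numeric(fit$params), as.numeric(fit2$params))
  expect_identical(fit$chi2, fit2$chi2)
  expect_identical(fit$Lhat, fit2$Lhat)
})

test_that("fit results expose nominal counts, eigenvalues and tidy methods", {
  dd <- make_decay_data(N = 15, seed = 2)
  fit <- fit_model(dd$spec, dd$data,
                   config = fit_config(seed = 1, n_stages = 2,
                                       n_proposals = 5, optim_maxit = 10))
  expect_equal(fit$n_nominal, 3)
  expect_length(fit$hessian_eigenvalues, 3)
  expect_lte(fit$n_effective, fit$n_nominal)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "transform"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_true(gl$status %in% c("ok", "degenerate"))
})

test_that("posterior samples follow the Laplace covariance on a quadratic toy", {
  # synthetic quadratic fit: known curvature, no data involved
  spec <- model_spec("sigmoidal", 1,
                     active_params = c("theta_1", "W_1_1"))
  pv <- dynadapt:::new_param_vector(c(theta_1 = 1, W_1_1 = -2), spec)
  H <- matrix(c(40, 8, 8, 20), 2, 2)
  fake_fit <- structure(list(params = pv, chi2 = 0, log_prior = 0,
                             hessian_eigenvalues = eigen(H)$values,
                             hessian_phi = H, n_nominal = 2, n_effective = 2,
                             Lhat = 0, status = "ok"), class = "dyn_fit")
  cfg <- fit_config()
  draws <- posterior_sample(fake_fit, spec, NULL, n_samples = 10000, seed = 8,
                            config = cfg)
  expect_length(draws, 10000)
  mat <- t(vapply(draws, as.numeric, numeric(2)))
  expect_equal(colMeans(mat), c(1, -2), tolerance = 0.05)
  Sigma <- solve(H + diag(1 / 100, 2))
  expect_equal(stats::cov(mat), Sigma, tolerance = 0.1)
  expect_length(posterior_sample(fake_fit, spec, NULL, 0), 0)
})

test_that("warm-started chi-squared is monotone down the hierarchy", {
  dd <- make_decay_data(N = 30, seed = 77)
  h <- build_hierarchy("sigmoidal", 1, 0, max_models = 3)
  cfg <- select_config(fit = fit_config(seed = 5, n_stages = 3,
                                        n_proposals = 8, optim_maxit = 25))
  trace <- select_model(h, dd$data, cfg)
  chis <- sapply(trace$fits, function(f) f$chi2)
  expect_true(all(diff(chis) <= 1e-6))
})
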