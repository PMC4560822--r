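test_that("effective-parameter counting compares data curvature with prior curvature", {
  expect_equal(count_effective_parameters(numeric(0)), 0L)
  expect_equal(count_effective_parameters(c(0, 0, 0)), 0)
  expect_equal(count_effective_parameters(c(1e6, 1e5, 1e4)), 3)
  expect_equal(count_effective_parameters(c(1e6, 0.5, 1e-4)), 1)
  # explicit prior precisions
  expect_equal(count_effective_parameters(c(5, 5, 5), prior_precisions = c(1, 10, 4)), 2)
  expect_warning(count_effective_parameters(c(10, -3)), "negative curvature")
})

test_that("the log-likelihood estimate penalizes only constrained directions", {
  spec <- model_spec("sigmoidal", 1,
                     active_params = c("tau_1", "theta_1", "W_1_1"))
  pv <- pack_params(sigmoidal_params(1, matrix(0, 1, 1), 0), spec)
  mk <- function(chi2, lp, lam)
    structure(list(params = pv, chi2 = chi2, log_prior = lp,
                   hessian_eigenvalues = lam, n_nominal = length(lam),
                   n_effective = sum(lam > 1), Lhat = NA, status = "ok"),
              class = "dyn_fit")
  # unconstrained directions carry no penalty
  expect_equal(estimate_log_likelihood(mk(10, -1, c(0, 0.5))), -10 / 2 - 1)
  # adding a constrained direction that does not reduce chi2 lowers the score
  expect_lt(estimate_log_likelihood(mk(10, -1, c(100, 0.5))),
            estimate_log_likelihood(mk(10, -1, c(0.5))))
  expect_equal(estimate_log_likelihood(mk(10, 0, 100)),
               -5 - 0.5 * log(101))
})

test_that("the estimate reproduces BIC differences on a linear-Gaussian toy", {
  # y = X beta + eps, sigma = 1; curvature of chi2/2 is X'X, whitened by the
  # prior precision 1/s^2. An independent closed-form BIC oracle gives
  # delta = -chi2/2 - (k/2) log N per model.
  set.seed(91)
  s <- 2 # flat-ish: prior sd far wider than the posterior (~N^{-1/2})
  for (N in c(200, 2000)) {
    X <- cbind(1, scale(rnorm(N)), scale(rnorm(N)))
    beta <- c(0.5, 1, 0) # third regressor irrelevant
    y <- as.vector(X %*% beta) + rnorm(N)
    fits <- lapply(1:3, function(k) {
      Xk <- X[, 1:k, drop = FALSE]
      bh <- solve(crossprod(Xk), crossprod(Xk, y))
      r <- y - Xk %*% bh
      lam_w <- eigen(crossprod(Xk) * s^2, symmetric = TRUE)$values
      lp <- sum(dnorm(bh / s, log = TRUE) - log(s))
      structure(list(chi2 = sum(r^2), log_prior = lp,
                     hessian_eigenvalues = lam_w, n_nominal = k,
                     n_effective = sum(lam_w > 1), Lhat = NA, status = "ok"),
                class = "dyn_fit")
    })
    Lh <- vapply(fits, estimate_log_likelihood, numeric(1))
    bic_half <- vapply(1:3, function(k)
      -fits[[k]]$chi2 / 2 - k / 2 * log(N), numeric(1))
    # pairwise differences agree to O(1) log-units per added parameter
    d_mine <- diff(Lh)
    d_bic <- diff(bic_half)
    expect_lt(max(abs(d_mine - d_bic)), 3)
    # both scores identify the 2-parameter truth
    expect_equal(which.max(Lh), 2)
    expect_equal(which.max(bic_half), 2)
  }
  # the penalty difference across N matches the (1/2) log N BIC scaling
  lam_of <- function(N) 0.5 * log1p(N * 1 * 100)
  expect_equal(lam_of(20000) - lam_of(200), 0.5 * log(100), tolerance = 1e-3)
})

test_that("a single-model hierarchy is selected with hierarchy_exhausted", {
  dd <- make_decay_data(N = 15, seed = 3)
  h <- build_hierarchy("sigmoidal", 1, 0, max_models = 1)
  trace <- select_model(h, dd$data,
                        select_config(fit = fit_config(seed = 2, n_stages = 2,
                                                       n_proposals = 5,
                                                       optim_maxit = 15)))
  expect_equal(trace$selected_index, 1)
  expect_equal(trace$stop_reason, "hierarchy_exhausted")
})

test_that("a zero evaluation budget yields an empty budget_exhausted trace", {
  dd <- make_decay_data(N = 10, seed = 3)
  h <- build_hierarchy("sigmoidal", 1, 0, max_models = 2)
  trace <- select_model(h, dd$data, select_config(max_model_evals = 0))
  expect_equal(trace$stop_reason, "budget_exhausted")
  expect_true(is.na(trace$selected_index))
  expect_length(trace$fits, 0)
})

test_that("selected complexity does not grow with N on in-class simple data", {
  # data generated by the minimal model: more data must not inflate the
  # selected model (overfitting avoidance)
  h <- build_hierarchy("sigmoidal", 1, 0, max_models = 2)
  sel <- sapply(c(50, 200), function(N) {
    dd <- make_decay_data(N = N, seed = 100 + N)
    cfg <- select_config(fit = fit_config(seed = 9, n_stages = 3,
                                          n_proposals = 10, optim_maxit = 30))
    select_model(h, dd$data, cfg)$selected_index
  })
  expect_equal(sel[2], sel[1])
  expect_equal(sel[1], 1)
})

test_that("selection traces serialize and tidy", {
  dd <- make_decay_data(N = 10, seed = 3)
  h <- build_hierarchy("sigmoidal", 1, 0, max_models = 2)
  trace <- select_model(h, dd$data,
                        select_config(fit = fit_config(seed = 2, n_stages = 2,
                                                       n_proposals = 5,
                                                       optim_maxit = 10)))
  td <- tidy(trace)
  expect_equal(nrow(td), length(trace$fits))
  expect_true(all(td$n_effective <= td$n_nominal, na.rm = TRUE))
  js <- jsonlite::fromJSON(trace_to_json(trace), simplifyVector = TRUE)
  expect_equal(js$selected_index, trace$selected_index)
  expect_equal(nrow(js$models), length(trace$fits))
  gl <- glance(trace)
  expect_equal(gl$n_models, length(trace$fits))
})
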