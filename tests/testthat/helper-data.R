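# fixtures are built in code; all randomness under explicit seeds

# single-condition noisy observations of exponential decay (sigmoidal class
# with all weights zero, tau = tau_true)
make_decay_data <- function(N = 50, tau_true = 2, noise = 0.05, seed = 42,
                            x0 = 1, t_max = 6) {
  spec <- model_spec("sigmoidal", 1,
                     active_params = c("tau_1", "theta_1", "W_1_1"))
  pv <- pack_params(sigmoidal_params(tau_true, matrix(0, 1, 1), 0), spec)
  set.seed(seed)
  tt <- sort(stats::runif(N, 0.1, t_max))
  tr <- integrate_model(spec, pv, x0, NULL, c(0, tt))
  truth <- tr$states[-1, 1]
  sig <- pmax(noise * abs(truth), 0.01)
  recs <- tibble::tibble(condition = "c1", time = tt, variable = "x",
                         value = truth + stats::rnorm(N, 0, sig), sigma = sig)
  data <- timeseries_set(recs, list(c1 = list(x0 = c(x = x0))),
                         variables = "x")
  list(spec = spec, params = pv, data = data, truth = truth)
}

# the 2-variable (1 observed + 1 hidden) sigmoidal ground truth used in the
# recovery study: cross-coupled with opposite signs, so the observed variable
# is non-monotonic -- unreachable for any 1-variable autonomous model
twovar_truth <- function() {
  h <- build_hierarchy("sigmoidal", 1, 0, max_models = 2)
  spec <- h$specs[[2]]
  vals <- c(tau_1 = 1, theta_1 = 1, W_1_1 = 0, tau_2 = 1, theta_2 = 1,
            x0_2 = 0, W_2_2 = 0, W_2_1 = 8, W_1_2 = -8)
  list(spec = spec, params = dynadapt:::new_param_vector(vals, spec))
}

# multi-condition data from the 2-variable truth, 5 records per condition
make_twovar_data <- function(N = 100, noise = 0.05, seed = 11) {
  tv <- twovar_truth()
  set.seed(seed)
  n_cond <- ceiling(N / 5)
  recs <- list(); conds <- list()
  for (i in seq_len(n_cond)) {
    x0 <- stats::runif(1, 0.5, 2)
    id <- sprintf("c%03d", i)
    tts <- sort(stats::runif(5, 0.2, 6))
    tr <- integrate_model(tv$spec, tv$params, x0, NULL, c(0, tts))
    truth <- tr$states[-1, 1]
    sig <- pmax(noise * abs(truth), 0.01)
    recs[[i]] <- tibble::tibble(condition = id, time = tts, variable = "x",
                                value = truth + stats::rnorm(5, 0, sig),
                                sigma = sig)
    conds[[id]] <- list(x0 = c(x = x0))
  }
  recs <- dplyr::bind_rows(recs)[seq_len(N), ]
  data <- timeseries_set(recs, conds[unique(recs$condition)], variables = "x")
  attr(data, "truth") <- list(
    fun = function(condition, times) {
      tr <- integrate_model(tv$spec, tv$params, condition$x0[["x"]], NULL,
                            times)
      tr$states[, 1, drop = FALSE]
    })
  list(truth = tv, data = data)
}

# random in-dimension parameter sets for rhs oracle checks
random_ssystem <- function(J, K) {
  ssystem_params(alpha = stats::runif(J, 0, 3), beta = stats::runif(J, 0, 3),
                 g = matrix(stats::runif(J * (J + K), -2, 2), J),
                 h = matrix(stats::runif(J * (J + K), -2, 2), J))
}

random_sigmoidal <- function(J, K) {
  sigmoidal_params(tau = stats::runif(J, 0.2, 5),
                   W = matrix(stats::rnorm(J * (J + K), 0, 3), J),
                   theta = stats::rnorm(J + K, 0, 2))
}

# literal term-by-term reference implementations (independent oracles)
ssystem_rhs_oracle <- function(state, inputs, p) {
  J <- length(p$alpha)
  x <- c(state, inputs)
  out <- numeric(J)
  for (i in seq_len(J)) {
    prod <- p$alpha[i]; deg <- p$beta[i]
    for (j in seq_along(x)) {
      prod <- prod * x[j]^p$g[i, j]
      deg <- deg * x[j]^p$h[i, j]
    }
    out[i] <- prod - deg
  }
  out
}

sigmoidal_rhs_oracle <- function(state, inputs, p) {
  J <- length(p$tau)
  x <- c(state, inputs)
  out <- numeric(J)
  for (i in seq_len(J)) {
    s <- -state[i] / p$tau[i]
    for (j in seq_along(x))
      s <- s + p$W[i, j] / (1 + exp(p$theta[j] - x[j]))
    out[i] <- s
  }
  out
}

spec_dim_test <- function(spec) spec$n_observed + spec$n_hidden

ts_conditions_test <- function(data) attr(data, "conditions")
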