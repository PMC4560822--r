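#' Out-of-sample predicted-vs-true time-course correlation
#'
#' For each held-out condition, both the fitted model and the truth oracle
#' are integrated over a common time grid; the Pearson correlation between
#' prediction and truth is computed per observed species over the time
#' course, then averaged over species within a condition and finally over
#' conditions. Conditions whose model integration fails score correlation 0
#' (not excluded, to avoid survivorship inflation).
#'
#' @param spec,params The selected model ([model_spec()] and its fitted
#'   `param_vector`).
#' @param data A benchmark [timeseries_set()] carrying a `truth` attribute
#'   (the conditions evaluated are `data`'s own; generate the held-out set
#'   with the benchmark generator at an independent seed/range scale).
#' @param horizon Evaluation horizon (time units); the grid is `n_grid`
#'   uniform points over `[0, horizon]`.
#' @param n_grid Number of grid points.
#' @param control Solver control.
#' @return An `evaluation_report`: tibble of per-condition correlations with
#'   attributes `mean_correlation`, `protocol`.
#' @export
out_of_sample_correlation <- function(spec, params, data, horizon = 5,
                                      n_grid = 100L,
                                      control = default_control()) {
  truth <- attr(data, "truth")
  if (is.null(truth)) stop("data carries no truth oracle")
  conds <- ts_conditions(data)
  vars <- ts_variables(data)
  grid <- seq(0, horizon, length.out = n_grid)
  per_cond <- purrr::map_dfr(names(conds), function(cid) {
    cnd <- conds[[cid]]
    true_mat <- truth$fun(cnd, grid)
    traj <- integrate_model(spec, params, as.numeric(cnd$x0[vars]),
                            cnd$inputs, grid, control)
    if (traj$status != "ok") {
      return(tibble::tibble(condition = cid, correlation = 0,
                            integration = traj$status))
    }
    cors <- vapply(seq_along(vars), function(j) {
      tv <- true_mat[, j]; pv <- traj$states[, j]
      if (stats::sd(tv) == 0 || stats::sd(pv) == 0) return(0)
      stats::cor(pv, tv)
    }, numeric(1))
    tibble::tibble(condition = cid, correlation = mean(cors),
                   integration = "ok")
  })
  structure(per_cond,
            mean_correlation = mean(per_cond$correlation),
            protocol = list(horizon = horizon, n_grid = n_grid,
                            correlation = "pearson",
                            aggregation = "species within condition, then conditions"),
            class = c("evaluation_report", class(per_cond)))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d condition(s), mean correlation %.3f\n",
              nrow(x), attr(x, "mean_correlation")))
  invisible(x)
}

#' Mean correlation of an evaluation report
#' @param report An `evaluation_report`.
#' @return Scalar mean over conditions.
#' @export
mean_correlation <- function(report) attr(report, "mean_correlation")

# out-of-sample root-mean-square prediction error of a predictor closure
# against a benchmark's truth oracle, over a dense grid
oos_rmse <- function(predict_fun, data, horizon, n_grid = 50L) {
  truth <- attr(data, "truth")
  conds <- ts_conditions(data)
  grid <- seq(0, horizon, length.out = n_grid)
  errs <- vapply(names(conds), function(cid) {
    cnd <- conds[[cid]]
    tv <- truth$fun(cnd, grid)
    pv <- predict_fun(cnd, grid)
    if (is.null(pv) || anyNA(pv)) return(NA_real_)
    sqrt(mean((pv - tv)^2))
  }, numeric(1))
  errs[is.na(errs)] <- max(errs, na.rm = TRUE) # failed predictions: worst case
  mean(errs)
}

# least-squares fit of the simple 5-parameter phosphorylation model
fit_simple_phospho <- function(data) {
  obj <- function(p) {
    conds <- ts_conditions(data)
    pr <- vapply(seq_len(nrow(data)), function(r) {
      V <- conds[[data$condition[r]]]$inputs
      simple_phospho_model(c(p[1], p[2], exp(p[3]), exp(p[4]), p[5]),
                           data$time[r], V)
    }, numeric(1))
    sum(((pr - data$value) / data$sigma)^2)
  }
  start <- c(A = max(data$value), V0 = 1, logw = 0, logtau = 0, c = 0)
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  c(A = opt$par[[1]], V0 = opt$par[[2]], w = exp(opt$par[[3]]),
    tau = exp(opt$par[[4]]), c = opt$par[[5]])
}

# maximum-likelihood refit of the full microstate network (V, K on log scale)
fit_full_phospho <- function(data, network, maxit = 200L) {
  tr0 <- network$transitions
  V0 <- log(network$rate_params$V$V)
  K0 <- log(network$rate_params$K$K)
  nV <- length(V0)
  keyV <- paste(tr0$site, tr0$dir, tr0$pattern)
  keyV_tab <- paste(network$rate_params$V$site, network$rate_params$V$dir,
                    network$rate_params$V$pattern)
  keyK <- paste(tr0$site, tr0$dir)
  keyK_tab <- paste(network$rate_params$K$site, network$rate_params$K$dir)
  iV <- match(keyV, keyV_tab); iK <- match(keyK, keyK_tab)
  conds <- ts_conditions(data)
  obj <- function(p) {
    net <- network
    net$transitions$V <- exp(p[iV])
    net$transitions$K <- exp(p[nV + iK])
    pr <- rep(NA_real_, nrow(data))
    for (cid in unique(data$condition)) {
      rows <- which(data$condition == cid)
      tt <- sort(unique(c(0, data$time[rows])))
      trj <- integrate_phospho(net, conds[[cid]]$inputs, tt)
      if (trj$status != "ok") return(BIG_COST)
      pr[rows] <- trj$observable[match(data$time[rows], tt)]
    }
    sum(((pr - data$value) / data$sigma)^2)
  }
  start <- c(V0, K0) + stats::rnorm(nV + length(K0), 0, 0.5)
  opt <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = maxit, ndeps = rep(1e-4, nV + length(K0))))
  net <- network
  net$transitions$V <- exp(opt$par[iV])
  net$transitions$K <- exp(opt$par[nV + iK])
  net
}

#' Prediction error of competing models as data volume grows
#'
#' The benchmark comparison protocol of the phosphorylation study: for each
#' data size `N` and each replicate, generate a training set, fit each
#' competitor -- the full microstate model by maximum likelihood, the simple
#' 5-parameter saturation model, and the adaptive hierarchy selection -- and
#' measure the out-of-sample RMS prediction error on an independently
#' generated held-out set. Means and standard deviations of the mean over
#' replicates are reported, along with the (nominal) parameter count each
#' competitor used.
#'
#' @param data_sizes Increasing integer vector of training record counts.
#' @param n_replicates Replicates per size (10 in the reference protocol).
#' @param seed Base seed; replicate r of size N uses a deterministic
#'   derivative of it.
#' @param models Subset of `c("full", "simple", "adaptive")`.
#' @param config Phosphorylation [benchmark_config()] template.
#' @param select_cfg [select_config()] for the adaptive competitor.
#' @param hierarchy_max Models enumerated in the adaptive hierarchy.
#' @param n_holdout Held-out conditions for the error measurement.
#' @return A tibble with columns `N`, `model`, `mean_error`, `sd_mean`,
#'   `mean_n_params`.
#' @export
prediction_error_vs_N <- function(data_sizes, n_replicates = 10L, seed = 1L,
                                  models = c("full", "simple", "adaptive"),
                                  config = benchmark_config("phosphorylation", N = 50),
                                  select_cfg = select_config(),
                                  hierarchy_max = 8L, n_holdout = 10L) {
  stopifnot(!is.unsorted(data_sizes))
  models <- match.arg(models, several.ok = TRUE)
  rows <- list()
  for (N in data_sizes) {
    errs <- matrix(NA_real_, n_replicates, length(models),
                   dimnames = list(NULL, models))
    npar <- errs
    for (r in seq_len(n_replicates)) {
      cfg <- config
      cfg$N <- as.integer(N)
      cfg$seed <- (seed + 1000L * r + N) %% .Machine$integer.max
      train <- generate_phospho_data(cfg)
      cfg_out <- cfg
      cfg_out$N <- as.integer(n_holdout * cfg$n_per_condition)
      cfg_out$seed <- cfg$seed + 500L
      holdout <- generate_phospho_data(cfg_out)
      horizon <- config$t_max
      for (mod in models) {
        if (mod == "simple") {
          p5 <- fit_simple_phospho(train)
          pf <- function(cnd, grid)
            matrix(simple_phospho_model(p5, grid, cnd$inputs), ncol = 1)
          np <- 5
        } else if (mod == "full") {
          net <- fit_full_phospho(train, attr(train, "truth")$network)
          pf <- function(cnd, grid)
            matrix(integrate_phospho(net, cnd$inputs, grid)$observable, ncol = 1)
          np <- net$n_parameters
        } else {
          hier <- build_hierarchy("sigmoidal", n_observed = 1, n_inputs = 1,
                                  max_models = hierarchy_max)
          scfg <- select_cfg
          scfg$fit$seed <- cfg$seed
          tracee <- select_model(hier, train, scfg)
          fit <- tracee$selected_fit
          sspec <- attr(fit$params, "spec")
          pf <- function(cnd, grid) {
            trj <- integrate_model(sspec, fit$params, 0, cnd$inputs, grid)
            if (trj$status != "ok") return(NULL)
            trj$states[, 1, drop = FALSE]
          }
          np <- fit$n_nominal
        }
        errs[r, mod] <- oos_rmse(pf, holdout, horizon)
        npar[r, mod] <- np
      }
    }
    for (mod in models) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        N = N, model = mod, mean_error = mean(errs[, mod]),
        sd_mean = stats::sd(errs[, mod]) / sqrt(n_replicates),
        mean_n_params = mean(npar[, mod]))
    }
  }
  dplyr::bind_rows(rows)
}

#' Posterior-median predictions with 90% confidence bands
#'
#' Integrates each of `n_samples` draws from the Laplace approximation of
#' the parameter posterior under the given (possibly time-varying) input and
#' returns the pointwise median and the 5th/95th percentiles of the predicted
#' observed time courses.
#'
#' @param fit A successful `dyn_fit`.
#' @param spec Its [model_spec()].
#' @param data The training [timeseries_set()] (supplies priors and, through
#'   `x0`, the representative initial condition when `observed_x0` is NULL).
#' @param inputs Input signal for the prediction ([pw_input()] or constant).
#' @param observed_x0 Initial observed values for the predicted course.
#' @param times Prediction time grid.
#' @param n_samples Posterior samples (100 in the reference protocol).
#' @param seed Seed for the posterior draws.
#' @param config The [fit_config()] used in the fit.
#' @return A tibble with `time`, `variable`, `median`, `lower`, `upper`
#'   (5th/95th percentiles).
#' @export
posterior_prediction_bands <- function(fit, spec, data, inputs = NULL,
                                       observed_x0 = NULL, times,
                                       n_samples = 100L, seed = 1L,
                                       config = fit_config()) {
  vars <- ts_variables(data)
  if (is.null(observed_x0)) {
    cnd <- ts_conditions(data)[[1]]
    observed_x0 <- as.numeric(cnd$x0[vars])
    if (is.null(inputs)) inputs <- cnd$inputs
  }
  draws <- posterior_sample(fit, spec, data, n_samples, seed, config)
  arr <- array(NA_real_, c(length(times), spec$n_observed, n_samples))
  for (k in seq_along(draws)) {
    trj <- integrate_model(spec, draws[[k]], observed_x0, inputs, times,
                           control_of(config))
    if (trj$status == "ok")
      arr[, , k] <- trj$states[, seq_len(spec$n_observed)]
  }
  qs <- apply(arr, c(1, 2), function(v)
    stats::quantile(v, c(0.05, 0.5, 0.95), na.rm = TRUE))
  purrr::map_dfr(seq_len(spec$n_observed), function(j)
    tibble::tibble(time = times, variable = vars[j],
                   median = qs[2, , j], lower = qs[1, , j], upper = qs[3, , j]))
}

#' Plot posterior prediction bands
#'
#' @param bands Output of [posterior_prediction_bands()].
#' @return A ggplot with the median line and the 90% ribbon per variable.
#' @export
plot_prediction_bands <- function(bands) {
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time", y = "predicted value")
}
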