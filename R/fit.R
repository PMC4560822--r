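#' Experimental time-series measurement set
#'
#' The data object consumed by the inference engine: a tibble of measurement
#' records (`condition`, `time`, `variable`, `value`, `sigma`) with
#' per-condition metadata (constant or piecewise-constant inputs, and known
#' initial values of the observed variables) held in attributes.
#'
#' @param records A data frame with columns `condition`, `time`, `variable`,
#'   `value`, `sigma` (`sigma` > 0, `time` >= 0).
#' @param conditions Named list, one entry per condition id, each a list with
#'   elements `x0` (named numeric, observed initial values) and optionally
#'   `inputs` (numeric vector or [pw_input()]).
#' @param variables Character vector of observed variable names in model
#'   order; defaults to the names of the first condition's `x0`.
#' @return A tibble of class `timeseries_set`.
#' @export
timeseries_set <- function(records, conditions, variables = NULL) {
  records <- tibble::as_tibble(records)
  req <- c("condition", "time", "variable", "value", "sigma")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0)
    stop("records is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0) stop("records must contain at least one measurement")
  if (any(records$sigma <= 0))
    stop("all record sigmas must be strictly positive")
  if (any(records$time < 0)) stop("record times must be non-negative")
  if (is.null(variables)) variables <- names(conditions[[1]]$x0)
  if (!all(records$variable %in% variables))
    stop("every record's variable must be an observed variable")
  if (!all(unique(records$condition) %in% names(conditions)))
    stop("every record's condition must appear in `conditions`")
  structure(records,
            conditions = conditions,
            variables = variables,
            class = c("timeseries_set", class(records)))
}

ts_conditions <- function(data) attr(data, "conditions")
ts_variables <- function(data) attr(data, "variables")

#' Number of measurement records
#' @param data A [timeseries_set()].
#' @return Integer count N of records.
#' @export
n_records <- function(data) nrow(data)

#' Fitting configuration
#'
#' Collects the priors, the phase-1 annealed-exploration schedule, the phase-2
#' local-optimizer settings and the solver tolerances used by [fit_model()].
#' Priors are independent Gaussians on the fitting scale: linear scale for
#' exponents, weights, offsets and sigmoidal hidden initial values; log scale
#' (log-normal) for positive-constrained parameters (`alpha`, `beta`, `tau`,
#' S-system hidden initial values).
#'
#' @param prior_scale_linear Gaussian prior s.d. for linear-scale parameters.
#' @param prior_sdlog Gaussian prior s.d. on the log scale for
#'   positive-constrained parameters.
#' @param n_scatter Exploration-ensemble size: candidate starts drawn around
#'   the warm start before annealing (full prior scale on newly activated
#'   parameters, mild jitter on inherited ones); the best becomes the
#'   walker's start.
#' @param n_stages,n_proposals Annealing stages and random-walk proposals per
#'   stage in phase 1.
#' @param temp_hi,temp_lo Geometric temperature ladder endpoints.
#' @param proposal_frac Proposal s.d. as a fraction of the prior s.d.
#' @param optim_maxit Maximum iterations of the phase-2 BFGS refinement.
#' @param hessian_step Relative finite-difference step for posterior curvature.
#' @param rtol,atol,maxsteps Solver control (see [default_control()]).
#' @param seed Integer seed making the fit reproducible.
#' @param log_file Optional path; when set, per-stage cost summaries are
#'   appended as JSON lines.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(prior_scale_linear = 10, prior_sdlog = log(10),
                       n_scatter = 20L, n_stages = 20L, n_proposals = 50L,
                       temp_hi = 10, temp_lo = 1, proposal_frac = 0.05,
                       optim_maxit = 100L, hessian_step = 0.1,
                       rtol = 1e-6, atol = 1e-8, maxsteps = 5000L,
                       seed = 1L, log_file = NULL) {
  structure(list(prior_scale_linear = prior_scale_linear,
                 prior_sdlog = prior_sdlog,
                 n_scatter = as.integer(n_scatter),
                 n_stages = as.integer(n_stages),
                 n_proposals = as.integer(n_proposals),
                 temp_hi = temp_hi, temp_lo = temp_lo,
                 proposal_frac = proposal_frac,
                 optim_maxit = as.integer(optim_maxit),
                 hessian_step = hessian_step,
                 rtol = rtol, atol = atol, maxsteps = as.integer(maxsteps),
                 seed = as.integer(seed), log_file = log_file),
            class = "fit_config")
}

control_of <- function(config)
  default_control(rtol = config$rtol, atol = config$atol,
                  maxsteps = config$maxsteps)

# --- transformed (fitting-scale) coordinates --------------------------------

# phi = log(p) for positive-constrained parameters, identity otherwise
to_phi <- function(v) {
  spec <- attr(v, "spec")
  tr <- param_transform(names(v), spec$model_class)
  phi <- as.numeric(v)
  phi[tr == "log"] <- log(phi[tr == "log"])
  stats::setNames(phi, names(v))
}

from_phi <- function(phi, spec) {
  tr <- param_transform(names(phi), spec$model_class)
  val <- phi
  # clamp so extreme line-search excursions stay strictly positive and finite
  val[tr == "log"] <- exp(pmin(pmax(val[tr == "log"], -700), 700))
  new_param_vector(val, spec)
}

# prior standard deviations on the fitting scale, aligned with active_params
prior_sds <- function(spec, config) {
  tr <- param_transform(spec$active_params, spec$model_class)
  stats::setNames(ifelse(tr == "log", config$prior_sdlog,
                         config$prior_scale_linear), spec$active_params)
}

#' Log prior density of a parameter vector
#'
#' Sum of independent Gaussian log densities on the fitting scale: `N(0, s)`
#' for exponents, weights, offsets and sigmoidal hidden initial values;
#' log-normal (Gaussian on `log p`) for `alpha`, `beta`, `tau` and S-system
#' hidden initial values. Maximal when every parameter sits at its prior
#' mean.
#'
#' @param params A `param_vector`.
#' @param config A [fit_config()].
#' @return The log prior density (real).
#' @export
log_prior <- function(params, config = fit_config()) {
  spec <- attr(params, "spec")
  phi <- to_phi(params)
  s <- prior_sds(spec, config)
  sum(stats::dnorm(phi, mean = 0, sd = s, log = TRUE))
}

# --- goodness of fit --------------------------------------------------------

# precomputed per-condition layout of a measurement set: record rows, time
# grids and index maps, plus stacked initial values and constant inputs for
# the batched solver path (conditions with piecewise inputs fall back to the
# one-by-one path)
data_layout <- function(spec, data) {
  vars <- ts_variables(data)
  conds <- ts_conditions(data)
  ids <- unique(data$condition)
  pw <- any(vapply(conds, function(c) inherits(c$inputs, "pw_input"),
                   logical(1)))
  rows <- list(); tts <- list(); ti <- list(); vi <- list()
  x0 <- matrix(0, length(ids), spec$n_observed)
  inp <- matrix(0, length(ids), spec$n_inputs)
  for (c in seq_along(ids)) {
    rows[[c]] <- which(data$condition == ids[c])
    cnd <- conds[[ids[c]]]
    tts[[c]] <- sort(unique(c(0, data$time[rows[[c]]])))
    ti[[c]] <- match(data$time[rows[[c]]], tts[[c]])
    vi[[c]] <- match(data$variable[rows[[c]]], vars)
    x0[c, ] <- as.numeric(cnd$x0[vars])
    if (!pw && spec$n_inputs > 0) inp[c, ] <- as.numeric(cnd$inputs)
  }
  list(ids = ids, pw = pw, rows = rows, times = tts, ti = ti, vi = vi,
       x0 = x0, inputs = inp, conds = conds)
}

# model predictions aligned with the rows of `data`; NULL where integration
# fails (handled by callers as an infinite-cost sentinel)
predict_records <- function(spec, params, data, control = default_control(),
                            layout = NULL) {
  if (is.null(layout)) layout <- data_layout(spec, data)
  out <- rep(NA_real_, nrow(data))
  if (layout$pw) {
    for (c in seq_along(layout$ids)) {
      cnd <- layout$conds[[layout$ids[c]]]
      traj <- integrate_model(spec, params, layout$x0[c, ], cnd$inputs,
                              layout$times[[c]], control)
      if (traj$status != "ok") return(NULL)
      out[layout$rows[[c]]] <- traj$states[cbind(layout$ti[[c]], layout$vi[[c]])]
    }
    return(out)
  }
  cls <- unpack_params(params)
  x0s <- cbind(layout$x0,
               matrix(rep(cls$hidden_x0, each = nrow(layout$x0)),
                      nrow(layout$x0)))
  code <- if (spec$model_class == "s_system") 1L else 2L
  res <- cpp_predict_batch(code, pack_for_cpp(cls), x0s, layout$inputs,
                           layout$times, control$rtol, control$atol,
                           spec$model_class == "s_system", control$blowup,
                           control$maxsteps)
  .counters$model_evaluations <- .counters$model_evaluations + res$n_done
  .counters$rhs_evaluations <- .counters$rhs_evaluations + res$n_rhs
  if (res$status != 0L) return(NULL)
  for (c in seq_along(layout$ids))
    out[layout$rows[[c]]] <-
      res$states[[c]][cbind(layout$ti[[c]], layout$vi[[c]])]
  out
}

#' Weighted least-squares goodness of fit
#'
#' \eqn{\chi^2 = \sum_r ((m_r - d_r)/\sigma_r)^2} over all measurement
#' records, with model predictions obtained by integrating the parameterized
#' model for each condition. Any condition whose integration fails (including
#' S-system positivity violations) makes the cost `Inf`, which the search
#' treats as a rejected parameter set.
#'
#' @param spec A [model_spec()].
#' @param params A `param_vector` for `spec`.
#' @param data A [timeseries_set()].
#' @param control Solver control.
#' @return Non-negative real (possibly `Inf`).
#' @export
chi_squared <- function(spec, params, data, control = default_control()) {
  pred <- predict_records(spec, params, data, control)
  if (is.null(pred) || anyNA(pred)) return(Inf)
  sum(((pred - data$value) / data$sigma)^2)
}

# posterior cost on the fitting scale: chi^2/2 - log_prior (finite sentinel
# for failed integrations so line searches can back off)
BIG_COST <- 1e12

make_cost <- function(spec, data, config) {
  control <- control_of(config)
  s <- prior_sds(spec, config)
  layout <- data_layout(spec, data)
  values <- data$value; sigmas <- data$sigma
  function(phi) {
    pv <- from_phi(stats::setNames(phi, spec$active_params), spec)
    pred <- predict_records(spec, pv, data, control, layout)
    if (is.null(pred) || anyNA(pred)) return(BIG_COST)
    c2 <- sum(((pred - values) / sigmas)^2)
    if (!is.finite(c2)) return(BIG_COST)
    c2 / 2 + sum(phi^2 / (2 * s^2)) + sum(log(s * sqrt(2 * pi)))
  }
}

# data-only half-chi-squared, for curvature estimation; integrates at
# tightened tolerances so finite-difference curvature noise stays well below
# the prior precision in whitened units
make_data_cost <- function(spec, data, config) {
  control <- control_of(config)
  control$rtol <- min(control$rtol, 1e-9)
  control$atol <- min(control$atol, 1e-11)
  layout <- data_layout(spec, data)
  values <- data$value; sigmas <- data$sigma
  function(phi) {
    pv <- from_phi(stats::setNames(phi, spec$active_params), spec)
    pred <- predict_records(spec, pv, data, control, layout)
    if (is.null(pred) || anyNA(pred)) return(NA_real_)
    sum(((pred - values) / sigmas)^2) / 2
  }
}

log_jsonl <- function(config, record) {
  if (is.null(config$log_file)) return(invisible(NULL))
  cat(jsonlite::toJSON(record, auto_unbox = TRUE), "\n",
      file = config$log_file, append = TRUE)
  invisible(NULL)
}

# central-difference Hessian of f at phi; f may return NA (replaced by a
# large value relative to f0 so curvature stays finite)
fd_hessian <- function(f, phi, step) {
  n <- length(phi)
  h <- step * pmax(1, abs(phi))
  f0 <- f(phi)
  if (is.na(f0)) f0 <- BIG_COST
  fv <- function(p) { v <- f(p); if (is.na(v)) f0 + 1e6 else v }
  H <- matrix(0, n, n)
  fp <- numeric(n); fm <- numeric(n)
  for (i in seq_len(n)) {
    ei <- numeric(n); ei[i] <- h[i]
    fp[i] <- fv(phi + ei); fm[i] <- fv(phi - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ei <- numeric(n); ei[i] <- h[i]
      ej <- numeric(n); ej[j] <- h[j]
      fpp <- fv(phi + ei + ej); fmm <- fv(phi - ei - ej)
      fpm <- fv(phi + ei - ej); fmp <- fv(phi - ei + ej)
      H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

#' Fit one model to data by annealed exploration plus local refinement
#'
#' Phase 1 performs a temperature-annealed random-walk search around the
#' starting point (typically a warm start from the previous model in the
#' hierarchy), accepting moves by the posterior cost
#' \eqn{\chi^2/2 - \log \mathrm{prior}}; phase 2 refines the best point found
#' with a derivative-based (BFGS) minimization. The returned fit never has a
#' higher cost than the starting point. The posterior curvature at the
#' optimum is then measured by central finite differences of the data-only
#' cost, its eigenvalues are computed in the prior-whitened basis, and the
#' effective parameter count and generalized-BIC log-likelihood estimate are
#' attached.
#'
#' @param spec A [model_spec()].
#' @param data A [timeseries_set()].
#' @param start A `param_vector` starting point (see [warm_start_params()]);
#'   defaults to neutral values.
#' @param config A [fit_config()].
#' @return An object of class `dyn_fit` with elements `params`, `chi2`,
#'   `log_prior`, `hessian_eigenvalues` (prior-whitened), `hessian_phi`
#'   (raw curvature on the fitting scale), `n_nominal`, `n_effective`,
#'   `Lhat`, `status`, `n_model_evals`.
#' @export
fit_model <- function(spec, data, start = NULL, config = fit_config(),
                      boost = character()) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "timeseries_set"))
  if (is.null(start)) {
    vals <- vapply(spec$active_params, neutral_value,
                   numeric(1), model_class = spec$model_class)
    start <- new_param_vector(vals, spec)
  }
  if (!identical(names(start), spec$active_params))
    stop("start does not match spec's active parameters")
  evals0 <- eval_counter()[["model_evaluations"]]
  cost <- make_cost(spec, data, config)
  phi0 <- to_phi(start)
  n <- length(phi0)
  set.seed(config$seed %% .Machine$integer.max)

  c_start <- cost(phi0)
  phi_best <- phi0; c_best <- c_start
  phi_cur <- phi0; c_cur <- c_start
  pr_sd <- prior_sds(spec, config)
  # phase 0: exploration ensemble. The warm start can sit in the basin of the
  # simpler model's optimum; best-of-K prior-scale draws on the newly
  # activated parameters give the walk a chance to start elsewhere.
  scatter_top <- list() # best two scatter candidates, refined later
  if (config$n_scatter > 0 && n > 0) {
    sc_sd <- if (length(boost) > 0)
      ifelse(names(phi0) %in% boost, pr_sd, 0.2 * pr_sd)
    else pr_sd
    cand <- matrix(NA_real_, config$n_scatter, n)
    cand_cost <- rep(Inf, config$n_scatter)
    for (k in seq_len(config$n_scatter)) {
      cand[k, ] <- phi0 + stats::rnorm(n, 0, sc_sd)
      cand_cost[k] <- cost(cand[k, ])
    }
    ord <- order(cand_cost)[seq_len(min(2, config$n_scatter))]
    for (k in ord) if (cand_cost[k] < BIG_COST)
      scatter_top[[length(scatter_top) + 1]] <-
        list(phi = stats::setNames(cand[k, ], names(phi0)),
             cost = cand_cost[k])
    best_k <- ord[1]
    if (cand_cost[best_k] < c_cur) {
      phi_cur <- stats::setNames(cand[best_k, ], names(phi0))
      c_cur <- cand_cost[best_k]
      if (c_cur < c_best) { phi_best <- phi_cur; c_best <- c_cur }
    }
  }
  prop_sd <- config$proposal_frac * pr_sd
  # newly activated parameters start at a neutral saddle (e.g. a hidden
  # variable pinned at its fixed point); widen their proposals during the hot
  # half of the ladder so the walker can break the degeneracy
  boost_sd <- prop_sd
  boost_sd[names(prop_sd) %in% boost] <- 10 * boost_sd[names(prop_sd) %in% boost]
  temps <- config$temp_hi *
    (config$temp_lo / config$temp_hi)^(seq_len(config$n_stages) / config$n_stages)
  n_fail <- 0L; n_tried <- 0L
  for (st in seq_along(temps)) {
    Tt <- temps[st]
    sd_st <- if (st <= config$n_stages / 2) boost_sd else prop_sd
    for (k in seq_len(config$n_proposals)) {
      phi_new <- phi_cur + stats::rnorm(n, 0, sd_st)
      c_new <- cost(phi_new)
      n_tried <- n_tried + 1L
      if (c_new >= BIG_COST) n_fail <- n_fail + 1L
      if (is.finite(c_new) &&
          (c_new <= c_cur || stats::runif(1) < exp((c_cur - c_new) / Tt))) {
        phi_cur <- phi_new; c_cur <- c_new
        if (c_new < c_best) { phi_best <- phi_new; c_best <- c_new }
      }
    }
    log_jsonl(config, list(event = "anneal_stage", stage = st,
                           temperature = Tt, best_cost = c_best))
  }
  if (n_tried > 0 && n_fail == n_tried && c_start >= BIG_COST) {
    return(structure(list(params = start, chi2 = Inf, log_prior = NA_real_,
                          hessian_eigenvalues = rep(NA_real_, n),
                          hessian_phi = NULL,
                          n_nominal = n, n_effective = NA_integer_,
                          Lhat = -Inf, status = "failed",
                          n_model_evals = eval_counter()[["model_evaluations"]] - evals0),
                     class = "dyn_fit"))
  }

  # phase 2: local refinement -- a simplex pre-polish (robust to the
  # ruggedness of failure boundaries) then a derivative-based BFGS descent,
  # run from the annealed best and from the leading scatter candidates
  # (multi-descent: the warm-start basin is not always the right one)
  fcap <- function(p) min(cost(p), BIG_COST)
  descend <- function(phi, value) {
    if (n > 1) {
      nm <- tryCatch(
        stats::optim(phi, fcap, method = "Nelder-Mead",
                     control = list(maxit = 5L * config$optim_maxit)),
        error = function(e) NULL)
      if (!is.null(nm) && is.finite(nm$value) && nm$value < value) {
        phi <- nm$par; value <- nm$value
      }
    }
    opt <- tryCatch(
      stats::optim(phi, fcap, method = "BFGS",
                   control = list(maxit = config$optim_maxit, reltol = 1e-10,
                                  ndeps = rep(1e-5, n))),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && opt$value < value) {
      phi <- opt$par; value <- opt$value
    }
    list(phi = phi, value = value)
  }
  starts <- c(list(list(phi = phi_best, cost = c_best)), scatter_top)
  for (st2 in starts) {
    res2 <- descend(st2$phi, st2$cost)
    if (res2$value < c_best) { phi_best <- res2$phi; c_best <- res2$value }
  }
  # fit never worsens the warm start
  if (c_start < c_best) { phi_best <- phi0; c_best <- c_start }

  pv <- from_phi(stats::setNames(phi_best, spec$active_params), spec)
  c2 <- chi_squared(spec, pv, data, control_of(config))
  lp <- log_prior(pv, config)
  status <- if (is.finite(c2)) "ok" else "failed"

  lam_w <- rep(NA_real_, n); H <- NULL; n_eff <- NA_integer_; Lhat <- -Inf
  if (status == "ok") {
    dc <- make_data_cost(spec, data, config)
    H <- fd_hessian(dc, phi_best, config$hessian_step)
    s <- prior_sds(spec, config)
    Hw <- H / outer(1 / s, 1 / s) # D^{-1/2} H D^{-1/2}, D = diag(1/s^2)
    ev <- eigen(Hw, symmetric = TRUE, only.values = TRUE)$values
    tol_neg <- 1e-3 * max(1, abs(ev))
    if (any(ev < -tol_neg)) {
      warning("negative curvature at optimum; eigenvalues clamped to 0 (degenerate optimum)")
      status <- "degenerate"
    }
    lam_w <- pmax(ev, 0)
    n_eff <- count_effective_parameters(lam_w, n_records(data))
    Lhat <- -c2 / 2 + lp - 0.5 * sum(log1p(lam_w[lam_w > 1]))
  }
  log_jsonl(config, list(event = "fit_done", chi2 = c2, Lhat = Lhat,
                         n_nominal = n, n_effective = n_eff, status = status))
  structure(list(params = pv, chi2 = c2, log_prior = lp,
                 hessian_eigenvalues = lam_w, hessian_phi = H,
                 n_nominal = n, n_effective = n_eff, Lhat = Lhat,
                 status = status,
                 n_model_evals = eval_counter()[["model_evaluations"]] - evals0),
            class = "dyn_fit")
}

#' @export
print.dyn_fit <- function(x, ...) {
  cat(sprintf("<dyn_fit> %s: chi2 = %.4g, Lhat = %.4g, %d nominal / %s effective parameter(s)\n",
              x$status, x$chi2, x$Lhat, x$n_nominal,
              ifelse(is.na(x$n_effective), "?", x$n_effective)))
  invisible(x)
}

#' Tidy a fitted model's parameters
#'
#' @param x A `dyn_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, and the fitting-scale `transform`.
#' @method tidy dyn_fit
#' @export
tidy.dyn_fit <- function(x, ...) {
  spec <- attr(x$params, "spec")
  tibble::tibble(term = names(x$params),
                 estimate = as.numeric(x$params),
                 transform = param_transform(names(x$params), spec$model_class))
}

#' One-row summary of a fitted model
#'
#' @param x A `dyn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `chi2`, `log_prior`, `Lhat`, `n_nominal`,
#'   `n_effective`, `status`.
#' @method glance dyn_fit
#' @export
glance.dyn_fit <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, log_prior = x$log_prior, Lhat = x$Lhat,
                 n_nominal = x$n_nominal, n_effective = x$n_effective,
                 status = x$status)
}

#' Sample from the Laplace approximation of the parameter posterior
#'
#' Draws from the Gaussian approximation centred at the best fit with
#' covariance the inverse of the regularized posterior curvature (data
#' curvature plus prior precision) on the fitting scale; samples are mapped
#' back to natural scale. Used for posterior-median predictions and 90%
#' bands. A singular curvature falls back to the pseudo-inverse
#' (eigenvalues clamped).
#'
#' @param fit A `dyn_fit` with `status = "ok"`.
#' @param spec The fitted [model_spec()].
#' @param data The [timeseries_set()] used in the fit.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param config The [fit_config()] used in the fit.
#' @return A list of `param_vector`s of length `n_samples`.
#' @export
posterior_sample <- function(fit, spec, data, n_samples, seed = 1L,
                             config = fit_config()) {
  stopifnot(inherits(fit, "dyn_fit"))
  if (!fit$status %in% c("ok", "degenerate"))
    stop("posterior_sample requires a successful fit")
  if (n_samples == 0) return(list())
  phi_hat <- to_phi(fit$params)
  n <- length(phi_hat)
  s <- prior_sds(spec, config)
  H <- fit$hessian_phi
  if (is.null(H)) H <- matrix(0, n, n)
  Hp <- H + diag(1 / s^2, n)
  ed <- eigen((Hp + t(Hp)) / 2, symmetric = TRUE)
  # a direction with (numerically) negative data curvature falls back to the
  # prior precision, never beyond it
  lam <- pmax(ed$values, 1 / max(s)^2)
  # covariance square root: V lam^{-1/2}
  A <- ed$vectors %*% diag(1 / sqrt(lam), n)
  set.seed(seed %% .Machine$integer.max)
  z <- matrix(stats::rnorm(n * n_samples), n, n_samples)
  draws <- phi_hat + A %*% z
  lapply(seq_len(n_samples), function(k)
    from_phi(stats::setNames(draws[, k], spec$active_params), spec))
}
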