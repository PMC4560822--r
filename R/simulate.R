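# package-level counters for cost accounting: one "model evaluation" is one
# trajectory integration over one condition; raw rhs calls are logged
# separately since solver effort varies per trajectory
.counters <- new.env(parent = emptyenv())
.counters$model_evaluations <- 0
.counters$rhs_evaluations <- 0

#' Model-evaluation counters
#'
#' Cumulative counts of trajectory integrations (`model_evaluations`) and of
#' raw right-hand-side calls (`rhs_evaluations`) performed by [integrate_model()]
#' since the last reset. The integration count is the unit used when budgeting
#' a selection run.
#'
#' @return A named numeric vector with both counters.
#' @export
eval_counter <- function() {
  c(model_evaluations = .counters$model_evaluations,
    rhs_evaluations = .counters$rhs_evaluations)
}

#' @rdname eval_counter
#' @export
reset_eval_counter <- function() {
  .counters$model_evaluations <- 0
  .counters$rhs_evaluations <- 0
  invisible(NULL)
}

#' Piecewise-constant input signal
#'
#' Inputs enter the model classes as constant pseudo-variables; time-varying
#' signals are supported as piecewise-constant steps. `times` are the left
#' edges of the steps (the first must equal the initial time of the
#' integration, typically 0) and `values` holds one row per step.
#'
#' @param times Numeric vector of step start times, strictly increasing.
#' @param values Numeric matrix (steps x K) or vector (K = 1) of input values.
#' @return An object of class `pw_input`.
#' @export
pw_input <- function(times, values) {
  values <- as.matrix(values)
  stopifnot(length(times) == nrow(values), !is.unsorted(times, strictly = TRUE))
  structure(list(times = as.numeric(times), values = values), class = "pw_input")
}

input_dim <- function(inputs) {
  if (is.null(inputs)) 0L
  else if (inherits(inputs, "pw_input")) ncol(inputs$values)
  else length(inputs)
}

STATUS_LEVELS <- c("ok", "positivity_violation", "blow_up", "solver_failure")

default_control <- function(rtol = 1e-6, atol = 1e-8, maxsteps = 5000L,
                            blowup = 1e10) {
  list(rtol = rtol, atol = atol, maxsteps = as.integer(maxsteps),
       blowup = blowup)
}

# low-level: integrate one C++ model over (possibly piecewise) inputs.
# times[1] is the initial time. Returns list(times, states, status, n_rhs).
integrate_raw <- function(code, pars, x0, inputs, times, control, positivity) {
  stopifnot(length(times) >= 1, !is.unsorted(times, strictly = TRUE))
  if (inherits(inputs, "pw_input")) {
    # chain constant-input segments, carrying the state across breakpoints
    nT <- length(times)
    states <- matrix(NA_real_, nT, length(x0))
    states[1, ] <- x0
    n_rhs <- 0; status <- 0L
    x <- x0; t_cur <- times[1]
    bp <- inputs$times
    t_max <- times[nT]
    for (seg in seq_along(bp)) {
      if (status != 0L || t_cur >= t_max) break
      seg_hi <- if (seg < length(bp)) bp[seg + 1] else Inf
      if (seg_hi <= t_cur) next
      t_end <- min(seg_hi, t_max)
      idx <- which(times > t_cur & times <= t_end)
      tt <- unique(sort(c(t_cur, times[idx], t_end)))
      res <- cpp_integrate(code, pars, x, inputs$values[seg, ], tt,
                           control$rtol, control$atol, positivity,
                           control$blowup, control$maxsteps)
      n_rhs <- n_rhs + res$n_rhs
      status <- res$status
      ok_n <- res$last_ok_index
      if (length(idx) > 0) {
        pos <- match(times[idx], tt)
        keep <- pos <= ok_n
        states[idx[keep], ] <- res$states[pos[keep], , drop = FALSE]
      }
      x <- res$states[ok_n, ]
      t_cur <- tt[ok_n]
    }
    list(states = states, status = status, n_rhs = n_rhs)
  } else {
    iv <- if (is.null(inputs)) numeric() else as.numeric(inputs)
    res <- cpp_integrate(code, pars, x0, iv, times, control$rtol,
                         control$atol, positivity, control$blowup,
                         control$maxsteps)
    list(states = res$states, status = res$status, n_rhs = res$n_rhs)
  }
}

#' Integrate a parameterized model over time
#'
#' Solves the class ODEs from known observed initial values (hidden initial
#' values come from the parameter vector) with an adaptive embedded
#' Runge-Kutta 5(4) scheme. Failures never raise: the returned trajectory
#' carries a status flag (`positivity_violation` for S-systems reaching
#' non-positive states, `blow_up` past the divergence bound, `solver_failure`
#' otherwise) and the partial trajectory up to the failure.
#'
#' @param spec A [model_spec()].
#' @param params A `param_vector` for `spec`.
#' @param observed_x0 Numeric vector of observed initial values, length
#'   `spec$n_observed`.
#' @param inputs `NULL`, a constant numeric vector of length `spec$n_inputs`,
#'   or a [pw_input()] signal.
#' @param times Strictly increasing times; the first element is the initial
#'   time.
#' @param control Solver control from [default_control()].
#' @return A `dyn_trajectory`: list with `times`, `states` (rows = times,
#'   columns = dynamical variables, observed first), `status`, `n_rhs_evals`.
#' @export
integrate_model <- function(spec, params, observed_x0, inputs = NULL, times,
                            control = default_control()) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(observed_x0) != spec$n_observed)
    stop("observed_x0 must have length n_observed")
  if (input_dim(inputs) != spec$n_inputs)
    stop("inputs must have length n_inputs")
  cls <- unpack_params(params)
  x0 <- c(as.numeric(observed_x0), cls$hidden_x0)
  code <- if (spec$model_class == "s_system") 1L else 2L
  res <- integrate_raw(code, pack_for_cpp(cls), x0, inputs, times, control,
                       positivity = spec$model_class == "s_system")
  .counters$model_evaluations <- .counters$model_evaluations + 1
  .counters$rhs_evaluations <- .counters$rhs_evaluations + res$n_rhs
  structure(list(times = as.numeric(times), states = res$states,
                 status = STATUS_LEVELS[res$status + 1L],
                 n_rhs_evals = res$n_rhs, spec = spec),
            class = "dyn_trajectory")
}

#' @export
print.dyn_trajectory <- function(x, ...) {
  cat(sprintf("<dyn_trajectory> %d time points, %d variable(s), status: %s\n",
              length(x$times), ncol(x$states), x$status))
  invisible(x)
}

#' Tidy a trajectory into long format
#'
#' @param x A `dyn_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `variable`, `value`.
#' @method tidy dyn_trajectory
#' @export
tidy.dyn_trajectory <- function(x, ...) {
  nv <- ncol(x$states)
  nm <- colnames(x$states)
  if (is.null(nm)) nm <- paste0("x", seq_len(nv))
  tibble::tibble(
    time = rep(x$times, nv),
    variable = rep(nm, each = length(x$times)),
    value = as.vector(x$states))
}

#' Plot a trajectory
#'
#' @param object A `dyn_trajectory`.
#' @param ... Unused.
#' @return A ggplot object, one line per variable.
#' @method autoplot dyn_trajectory
#' @export
autoplot.dyn_trajectory <- function(object, ...) {
  df <- tidy.dyn_trajectory(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "value", colour = NULL)
}

#' Reduced radial two-body dynamics
#'
#' Right-hand side of the radial Kepler problem: \eqn{dr/dt = v}, \eqn{dv/dt =
#' \ell^2/r^3 - \mu/r^2}, where `ell` is the (conserved) angular momentum per
#' unit mass and `mu` the gravitational parameter. The radial velocity `v` is
#' the benchmark's hidden variable.
#'
#' @param r Distance from the central mass, > 0.
#' @param v Radial velocity.
#' @param ell Angular momentum per unit mass.
#' @param mu Gravitational parameter.
#' @return Numeric vector `c(dr, dv)`.
#' @export
gravity_rhs <- function(r, v, ell, mu) {
  if (r <= 0) stop("domain error: r must be positive")
  c(v, ell^2 / r^3 - mu / r^2)
}

#' Integrate the radial-gravity truth model
#'
#' Solves [gravity_rhs()] from `(r0, v0)`; counts toward the model-evaluation
#' budget like any other integration.
#'
#' @param r0 Initial distance (> 0).
#' @param v0 Initial radial velocity.
#' @param ell Angular momentum per unit mass.
#' @param mu Gravitational parameter.
#' @param times Strictly increasing times.
#' @param control Solver control.
#' @return A `dyn_trajectory` with state columns `(r, v)`.
#' @export
integrate_gravity <- function(r0, v0 = 0, ell, mu = 1, times,
                              control = default_control()) {
  res <- integrate_raw(3L, c(ell, mu), c(r0, v0), NULL, times, control,
                       positivity = FALSE)
  .counters$model_evaluations <- .counters$model_evaluations + 1
  .counters$rhs_evaluations <- .counters$rhs_evaluations + res$n_rhs
  structure(list(times = as.numeric(times), states = res$states,
                 status = STATUS_LEVELS[res$status + 1L],
                 n_rhs_evals = res$n_rhs),
            class = "dyn_trajectory")
}
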