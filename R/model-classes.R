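#' Numerically stable logistic sigmoid
#'
#' The saturating interaction function of the sigmoidal network class,
#' \eqn{\xi(y) = 1/(1+e^y)}. Decreasing in `y`, with \eqn{\xi(0) = 1/2} and
#' \eqn{\xi(y) + \xi(-y) = 1}. Evaluation is stable over the whole double
#' range (saturates at 0/1 instead of overflowing).
#'
#' @param y Numeric vector.
#' @return Numeric vector of values in (0, 1).
#' @export
#' @examples
#' sigmoid(0)     # 0.5
#' sigmoid(1)     # 1 / (1 + e)
sigmoid <- function(y) {
  out <- numeric(length(y))
  pos <- !is.na(y) & y > 0
  out[pos] <- exp(-y[pos]) / (1 + exp(-y[pos]))
  out[!pos] <- 1 / (1 + exp(y[!pos]))
  out[is.na(y)] <- NA_real_
  out
}

MODEL_CLASSES <- c("s_system", "sigmoidal")

# sigmoid-argument convention tag stored in every serialized model: one offset
# theta_j per source variable, sigmoid applied per source before the weighted
# sum (continuous-time recurrent-network convention).
SIGMOID_CONVENTION <- "per_source_offset"

#' Describe one model in the hierarchy
#'
#' A `model_spec` fixes the model class, the split of dynamical variables into
#' observed and hidden, the number of external inputs, and the ordered list of
#' active (fitted) parameters. Inactive parameters are pinned at neutral
#' values (exponents and weights 0), so every spec is nested inside any spec
#' whose active list extends its own.
#'
#' @param model_class `"s_system"` or `"sigmoidal"`.
#' @param n_observed Number of observed dynamical variables (>= 1).
#' @param n_hidden Number of hidden dynamical variables (>= 0). Hidden
#'   variables follow the observed ones in the variable ordering; inputs come
#'   last as constant pseudo-variables.
#' @param n_inputs Number of external inputs (>= 0).
#' @param active_params Character vector of active parameter names, in
#'   hierarchy order (hidden initial values `x0_<i>` included).
#' @param hierarchy_index Integer position in the generating hierarchy.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model_class, n_observed, n_hidden = 0L, n_inputs = 0L,
                       active_params = character(), hierarchy_index = NA_integer_) {
  model_class <- match.arg(model_class, MODEL_CLASSES)
  stopifnot(n_observed >= 1, n_hidden >= 0, n_inputs >= 0)
  spec <- structure(
    list(model_class = model_class,
         n_observed = as.integer(n_observed),
         n_hidden = as.integer(n_hidden),
         n_inputs = as.integer(n_inputs),
         active_params = as.character(active_params),
         hierarchy_index = as.integer(hierarchy_index)),
    class = "model_spec")
  full <- full_param_names(spec)
  bad <- setdiff(spec$active_params, full)
  if (length(bad) > 0)
    stop("unknown parameter names for this spec: ", paste(bad, collapse = ", "))
  spec
}

# total dynamical dimension
spec_dim <- function(spec) spec$n_observed + spec$n_hidden

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %d observed + %d hidden, %d input(s), %d active parameter(s)\n",
              x$model_class, x$n_observed, x$n_hidden, x$n_inputs,
              length(x$active_params)))
  invisible(x)
}

# All parameter names that exist for (class, J, K), in a canonical
# (non-hierarchy) enumeration; used for validation only.
full_param_names <- function(spec) {
  J <- spec_dim(spec); K <- spec$n_inputs
  hid <- if (spec$n_hidden > 0) paste0("x0_", (spec$n_observed + 1):J) else character()
  if (spec$model_class == "s_system") {
    nm <- c(paste0("alpha_", 1:J), paste0("beta_", 1:J))
    for (i in 1:J) nm <- c(nm, paste0("g_", i, "_", 1:J), paste0("h_", i, "_", 1:J))
    if (K > 0) for (i in 1:J) nm <- c(nm, paste0("gin_", i, "_", 1:K), paste0("hin_", i, "_", 1:K))
  } else {
    nm <- c(paste0("tau_", 1:J), paste0("theta_", 1:J))
    if (K > 0) nm <- c(nm, paste0("thetain_", 1:K))
    for (i in 1:J) nm <- c(nm, paste0("W_", i, "_", 1:J))
    if (K > 0) for (i in 1:J) nm <- c(nm, paste0("Win_", i, "_", 1:K))
  }
  c(nm, hid)
}

# parameter type by name prefix: "log" parameters are positive-constrained and
# fitted on the log scale
param_transform <- function(names, model_class) {
  prefix <- sub("_.*$", "", names)
  log_prefixes <- c("alpha", "beta", "tau")
  tr <- ifelse(prefix %in% log_prefixes, "log", "identity")
  if (model_class == "s_system") tr[prefix == "x0"] <- "log"
  tr
}

#' S-system parameter set
#'
#' Container for the full parameter arrays of a power-law (S-system) network:
#' per-variable production and degradation prefactors `alpha`, `beta` (>= 0)
#' and real-valued exponent matrices `g`, `h` of dimension `J x (J+K)`
#' (dynamical variables first, inputs last). Exponents are unconstrained in
#' sign or integrality.
#'
#' @param alpha,beta Numeric vectors, length `J`, non-negative.
#' @param g,h Numeric matrices, `J` rows, `J+K` columns.
#' @param hidden_x0 Positive initial values of the hidden variables.
#' @return An object of class `ssystem_params`.
#' @export
ssystem_params <- function(alpha, beta, g, h, hidden_x0 = numeric()) {
  g <- as.matrix(g); h <- as.matrix(h)
  J <- length(alpha)
  stopifnot(length(beta) == J, nrow(g) == J, nrow(h) == J,
            ncol(g) == ncol(h))
  if (any(alpha < 0) || any(beta < 0))
    stop("alpha and beta must be non-negative")
  if (length(hidden_x0) > 0 && any(hidden_x0 <= 0))
    stop("S-system hidden initial values must be positive")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 g = g, h = h, hidden_x0 = as.numeric(hidden_x0)),
            class = "ssystem_params")
}

#' Sigmoidal-network parameter set
#'
#' Container for a continuous-time sigmoidal network: per-variable relaxation
#' times `tau` (> 0), interaction weights `W` (`J x (J+K)`), and one sigmoid
#' offset `theta` per source (dynamical variables then inputs).
#'
#' @param tau Positive numeric vector, length `J` (time units).
#' @param W Numeric matrix, `J x (J+K)`.
#' @param theta Numeric vector, length `J+K`.
#' @param hidden_x0 Initial values of the hidden variables (real).
#' @return An object of class `sigmoidal_params`.
#' @export
sigmoidal_params <- function(tau, W, theta, hidden_x0 = numeric()) {
  W <- as.matrix(W)
  J <- length(tau)
  stopifnot(nrow(W) == J, length(theta) == ncol(W))
  if (any(tau <= 0)) stop("tau must be strictly positive")
  structure(list(tau = as.numeric(tau), W = W, theta = as.numeric(theta),
                 hidden_x0 = as.numeric(hidden_x0)),
            class = "sigmoidal_params")
}

# pack class params into the flat layout the C++ core expects
pack_for_cpp <- function(params) {
  if (inherits(params, "ssystem_params")) {
    J <- length(params$alpha); JK <- ncol(params$g)
    c(J, JK - J, params$alpha, params$beta,
      as.vector(t(params$g)), as.vector(t(params$h)))
  } else if (inherits(params, "sigmoidal_params")) {
    J <- length(params$tau); JK <- ncol(params$W)
    c(J, JK - J, params$tau, params$theta, as.vector(t(params$W)))
  } else stop("unknown parameter class")
}

#' Right-hand side of an S-system network
#'
#' Evaluates \eqn{dx_i/dt = \alpha_i \prod_j x_j^{g_{ij}} - \beta_i \prod_j
#' x_j^{h_{ij}}}, with inputs appended as constant pseudo-variables
#' \eqn{x_{J+k} = I_k}. The class is ill-defined for non-positive states, so
#' those raise an error.
#'
#' @param state Strictly positive numeric vector, length `J`.
#' @param inputs Strictly positive numeric vector, length `K` (may be empty).
#' @param params An [ssystem_params()] object.
#' @return Numeric vector of time derivatives, length `J`.
#' @export
ssystem_rhs <- function(state, inputs, params) {
  stopifnot(inherits(params, "ssystem_params"))
  if (length(state) != length(params$alpha))
    stop("state length does not match parameter dimension")
  if (any(state <= 0))
    stop("positivity violation: S-system dynamics are ill-defined for non-positive states")
  if (length(inputs) > 0 && any(inputs <= 0))
    stop("positivity violation: S-system inputs must be positive")
  cpp_rhs(1L, pack_for_cpp(params), as.numeric(state), as.numeric(inputs))
}

#' Right-hand side of a sigmoidal (continuous-time recurrent) network
#'
#' Evaluates \eqn{dx_i/dt = -x_i/\tau_i + \sum_j W_{ij}\, \xi(\theta_j - x_j)}
#' with \eqn{\xi(y) = 1/(1+e^y)} and inputs as constant pseudo-variables.
#'
#' @inheritParams ssystem_rhs
#' @param params A [sigmoidal_params()] object.
#' @return Numeric vector of time derivatives, length `J`.
#' @export
sigmoidal_rhs <- function(state, inputs, params) {
  stopifnot(inherits(params, "sigmoidal_params"))
  if (length(state) != length(params$tau))
    stop("state length does not match parameter dimension")
  if (any(params$tau <= 0)) stop("invalid parameter: tau must be positive")
  cpp_rhs(2L, pack_for_cpp(params), as.numeric(state), as.numeric(inputs))
}

# --- packing between named parameter vectors and class parameter sets -------

parse_param_name <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  list(prefix = parts[1],
       i = if (length(parts) >= 2) as.integer(parts[2]) else NA_integer_,
       j = if (length(parts) >= 3) as.integer(parts[3]) else NA_integer_)
}

#' Pack class-specific parameters into a named parameter vector
#'
#' Extracts the values of a spec's active parameters (plus hidden initial
#' values) into a flat named vector; [unpack_params()] inverts the operation
#' exactly, pinning inactive parameters at neutral values.
#'
#' @param params An [ssystem_params()] or [sigmoidal_params()] object whose
#'   dimensions match `spec`.
#' @param spec A [model_spec()].
#' @return A named numeric vector of class `param_vector` with `spec` attached.
#' @export
pack_params <- function(params, spec) {
  J <- spec_dim(spec); K <- spec$n_inputs
  if (spec$model_class == "s_system") {
    stopifnot(inherits(params, "ssystem_params"))
    if (length(params$alpha) != J || ncol(params$g) != J + K)
      stop("parameter dimensions do not match spec")
  } else {
    stopifnot(inherits(params, "sigmoidal_params"))
    if (length(params$tau) != J || ncol(params$W) != J + K)
      stop("parameter dimensions do not match spec")
  }
  if (length(params$hidden_x0) != spec$n_hidden)
    stop("hidden_x0 length does not match spec$n_hidden")
  vals <- vapply(spec$active_params, function(nm) {
    p <- parse_param_name(nm)
    switch(p$prefix,
      alpha = params$alpha[p$i], beta = params$beta[p$i],
      g = params$g[p$i, p$j], h = params$h[p$i, p$j],
      gin = params$g[p$i, J + p$j], hin = params$h[p$i, J + p$j],
      tau = params$tau[p$i], theta = params$theta[p$i],
      thetain = params$theta[J + p$i],
      W = params$W[p$i, p$j], Win = params$W[p$i, J + p$j],
      x0 = params$hidden_x0[p$i - spec$n_observed],
      stop("unknown parameter prefix: ", p$prefix))
  }, numeric(1))
  new_param_vector(vals, spec)
}

new_param_vector <- function(values, spec) {
  if (!setequal(names(values), spec$active_params) ||
      length(values) != length(spec$active_params))
    stop("param_vector keys must equal the spec's active parameters")
  structure(as.numeric(values)[match(spec$active_params, names(values))],
            names = spec$active_params, class = "param_vector", spec = spec)
}

#' @export
print.param_vector <- function(x, ...) {
  cat("<param_vector> ", length(x), " parameter(s)\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Unpack a named parameter vector into full class parameter arrays
#'
#' Inactive parameters take their neutral values: exponents and weights 0,
#' offsets 0, prefactors of absent terms 0, `tau` 1.
#'
#' @param v A `param_vector` produced by [pack_params()] or fitted by
#'   [fit_model()].
#' @return An [ssystem_params()] or [sigmoidal_params()] object.
#' @export
unpack_params <- function(v) {
  spec <- attr(v, "spec")
  stopifnot(inherits(v, "param_vector"), inherits(spec, "model_spec"))
  J <- spec_dim(spec); K <- spec$n_inputs
  if (spec$model_class == "s_system") {
    alpha <- numeric(J); beta <- numeric(J)
    g <- matrix(0, J, J + K); h <- matrix(0, J, J + K)
    hidden_x0 <- rep(1, spec$n_hidden)
  } else {
    tau <- rep(1, J); theta <- numeric(J + K)
    W <- matrix(0, J, J + K)
    hidden_x0 <- rep(0, spec$n_hidden)
  }
  for (nm in names(v)) {
    p <- parse_param_name(nm)
    val <- unname(v[[nm]])
    switch(p$prefix,
      alpha = { alpha[p$i] <- val }, beta = { beta[p$i] <- val },
      g = { g[p$i, p$j] <- val }, h = { h[p$i, p$j] <- val },
      gin = { g[p$i, J + p$j] <- val }, hin = { h[p$i, J + p$j] <- val },
      tau = { tau[p$i] <- val }, theta = { theta[p$i] <- val },
      thetain = { theta[J + p$i] <- val },
      W = { W[p$i, p$j] <- val }, Win = { W[p$i, J + p$j] <- val },
      x0 = { hidden_x0[p$i - spec$n_observed] <- val })
  }
  if (spec$model_class == "s_system")
    ssystem_params(alpha, beta, g, h, hidden_x0)
  else
    sigmoidal_params(tau, W, theta, hidden_x0)
}

# named vector of hidden initial values from a param_vector (model order)
hidden_x0_of <- function(v) {
  spec <- attr(v, "spec")
  if (spec$n_hidden == 0) return(numeric())
  nm <- paste0("x0_", (spec$n_observed + 1):spec_dim(spec))
  as.numeric(v[nm])
}
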