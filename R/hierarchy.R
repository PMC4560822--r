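#' Ordered, nested model hierarchies
#'
#' The search hierarchy enumerates models of a class in a fixed a-priori
#' order that interleaves two directions of growth: adding interaction terms
#' (nonlinearity) at the current dimension, and adding hidden variables. Each
#' model's active-parameter list is a prefix of the next one's, so every
#' earlier model is recoverable from any later one by pinning the added
#' parameters at neutral values.
#'
#' The addition order is: (1) a minimal block (per-variable relaxation /
#' production-degradation parameters for the observed variables); (2) the
#' remaining interaction parameters at the current dimension, row-major over
#' (target, source), with each new source's sigmoid offset activated together
#' with its first weight; (3) once the current dimension is fully connected, a
#' hidden-variable bundle (its own relaxation parameters, initial value, self
#' term and cross terms to the most recently added variable), after which (2)
#' resumes at the enlarged dimension.
#'
#' @name hierarchy
NULL

# The global addition sequence as a list of steps; each step is a list
# (names, n_hidden). Generates steps until max_models steps are produced or
# n_hidden would exceed max_hidden with connectivity exhausted.
param_sequence <- function(model_class, n_observed, n_inputs, max_steps,
                           max_hidden = Inf) {
  J0 <- n_observed; K <- n_inputs
  steps <- vector("list", max_steps)
  active <- character()
  n_hidden <- 0L
  s <- 0L

  add_step <- function(names, nh) {
    s <<- s + 1L
    steps[[s]] <<- list(names = names, n_hidden = nh)
    active <<- c(active, names)
  }

  # minimal block
  if (model_class == "sigmoidal") {
    add_step(c(paste0("tau_", 1:J0), paste0("theta_", 1:J0),
               paste0("W_", 1:J0, "_", 1:J0)), 0L)
  } else {
    add_step(c(paste0("alpha_", 1:J0), paste0("beta_", 1:J0),
               paste0("h_", 1:J0, "_", 1:J0)), 0L)
  }

  repeat {
    if (s >= max_steps) break
    J <- J0 + n_hidden
    # candidate interaction parameters at dimension J, row-major
    added <- FALSE
    for (i in 1:J) {
      for (j in seq_len(J + K)) {
        cand <- interaction_step(model_class, i, j, J, K, active)
        if (length(cand) > 0) {
          add_step(cand, n_hidden)
          added <- TRUE
          break
        }
      }
      if (added) break
    }
    if (added) next
    # fully connected at this dimension: add a hidden variable
    if (n_hidden + 1 > max_hidden) break
    m <- J + 1L
    prev <- J
    n_hidden <- n_hidden + 1L
    if (model_class == "sigmoidal") {
      add_step(c(paste0("tau_", m), paste0("theta_", m), paste0("x0_", m),
                 paste0("W_", m, "_", m),
                 paste0("W_", m, "_", prev), paste0("W_", prev, "_", m)),
               n_hidden)
    } else {
      add_step(c(paste0("alpha_", m), paste0("beta_", m),
                 paste0("h_", m, "_", m), paste0("x0_", m),
                 paste0("g_", m, "_", prev), paste0("g_", prev, "_", m)),
               n_hidden)
    }
  }
  steps[seq_len(s)]
}

# the next inactive interaction parameter(s) for pair (i, j); j > J indexes
# inputs. Returns character() if everything for the pair is active.
interaction_step <- function(model_class, i, j, J, K, active) {
  is_input <- j > J
  k <- j - J
  if (model_class == "sigmoidal") {
    w <- if (is_input) paste0("Win_", i, "_", k) else paste0("W_", i, "_", j)
    if (w %in% active) return(character())
    th <- if (is_input) paste0("thetain_", k) else paste0("theta_", j)
    if (th %in% active) w else c(w, th)
  } else {
    g <- if (is_input) paste0("gin_", i, "_", k) else paste0("g_", i, "_", j)
    h <- if (is_input) paste0("hin_", i, "_", k) else paste0("h_", i, "_", j)
    if (!(g %in% active)) return(g)
    if (!(h %in% active)) return(h)
    character()
  }
}

#' Build the a-priori ordered model hierarchy
#'
#' @param model_class `"s_system"` or `"sigmoidal"`.
#' @param n_observed Number of observed variables.
#' @param n_inputs Number of inputs.
#' @param max_models Maximum number of models to enumerate.
#' @param max_hidden Optional cap on the number of hidden variables.
#' @return An object of class `model_hierarchy`: a list with the class,
#'   dimensions and `specs`, an ordered list of [model_spec()]s with strictly
#'   increasing nominal parameter counts.
#' @export
#' @examples
#' h <- build_hierarchy("sigmoidal", n_observed = 1, n_inputs = 0, max_models = 5)
#' sapply(h$specs, function(s) length(s$active_params))
build_hierarchy <- function(model_class, n_observed, n_inputs = 0L,
                            max_models = 20L, max_hidden = Inf) {
  model_class <- match.arg(model_class, MODEL_CLASSES)
  stopifnot(n_observed >= 1, max_models >= 1)
  steps <- param_sequence(model_class, n_observed, n_inputs, max_models,
                          max_hidden)
  active <- character()
  specs <- vector("list", length(steps))
  for (m in seq_along(steps)) {
    active <- c(active, steps[[m]]$names)
    specs[[m]] <- model_spec(model_class, n_observed,
                             n_hidden = steps[[m]]$n_hidden,
                             n_inputs = n_inputs,
                             active_params = active,
                             hierarchy_index = m)
  }
  structure(list(model_class = model_class, n_observed = as.integer(n_observed),
                 n_inputs = as.integer(n_inputs), specs = specs),
            class = "model_hierarchy")
}

#' @export
print.model_hierarchy <- function(x, ...) {
  cat(sprintf("<model_hierarchy> %s, %d observed, %d input(s): %d models, %d-%d parameters\n",
              x$model_class, x$n_observed, x$n_inputs, length(x$specs),
              length(x$specs[[1]]$active_params),
              length(x$specs[[length(x$specs)]]$active_params)))
  invisible(x)
}

# number of fitted (nominal) parameters of a spec
n_nominal_params <- function(spec) length(spec$active_params)

# TRUE if the active list of `a` is a strict or equal prefix of that of `b`
is_nested_in <- function(a, b) {
  na <- length(a$active_params)
  na <= length(b$active_params) &&
    identical(a$active_params, b$active_params[seq_len(na)]) &&
    a$model_class == b$model_class &&
    a$n_observed == b$n_observed && a$n_inputs == b$n_inputs
}

# neutral starting value for a newly activated parameter
neutral_value <- function(name, model_class) {
  prefix <- sub("_.*$", "", name)
  switch(prefix,
         tau = 1, alpha = 1, beta = 1,
         x0 = if (model_class == "s_system") 1 else 0,
         0)
}

#' Warm-start a model from the previous model's best fit
#'
#' Copies all shared parameter values from the simpler model's fit and
#' initializes newly activated parameters at neutral values (exponents and
#' weights 0, relaxation times 1, hidden initial values at their class
#' default), so that the richer model's initial trajectories -- and hence its
#' chi-squared at the warm start -- equal those of the simpler model's
#' optimum.
#'
#' @param prev_fit A `param_vector` for the preceding model (e.g.
#'   `fit$params`).
#' @param next_spec The [model_spec()] of the richer model; its active list
#'   must extend `prev_fit`'s as a prefix.
#' @return A `param_vector` for `next_spec`.
#' @export
warm_start_params <- function(prev_fit, next_spec) {
  prev_spec <- attr(prev_fit, "spec")
  if (!is_nested_in(prev_spec, next_spec))
    stop("specs are not nested: the previous model's parameters are not a prefix of the next model's")
  vals <- stats::setNames(numeric(length(next_spec$active_params)),
                          next_spec$active_params)
  vals[names(prev_fit)] <- as.numeric(prev_fit)
  new_names <- setdiff(next_spec$active_params, names(prev_fit))
  for (nm in new_names) vals[nm] <- neutral_value(nm, next_spec$model_class)
  new_param_vector(vals, next_spec)
}

#' Serialize a hierarchy to JSON
#'
#' @param hierarchy A `model_hierarchy`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly if written to `path`.
#' @export
hierarchy_to_json <- function(hierarchy, path = NULL) {
  specs <- lapply(hierarchy$specs, function(s)
    list(model_class = s$model_class, n_observed = s$n_observed,
         n_hidden = s$n_hidden, n_inputs = s$n_inputs,
         hierarchy_index = s$hierarchy_index, active_params = s$active_params))
  js <- jsonlite::toJSON(specs, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
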