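#' Count effectively constrained parameter directions
#'
#' Given eigenvalues of the data-only cost curvature (\eqn{\chi^2/2} at the
#' optimum) and the prior precision in each direction, counts the directions
#' where the data curvature exceeds the prior curvature -- the directions the
#' data actually constrain. With prior-whitened eigenvalues the prior
#' precision is 1 in every direction (the default).
#'
#' @param eigenvalues Numeric vector of curvature eigenvalues.
#' @param N Number of measurement records (kept for the interface; the count
#'   itself depends only on the curvature comparison).
#' @param prior_precisions Prior curvature per direction (scalar or vector).
#' @param neg_tol Eigenvalues below `-neg_tol * max(|eigenvalue|, 1)` trigger a
#'   degenerate-optimum warning; all negatives are clamped to 0.
#' @return Integer count, `<=` the number of eigenvalues.
#' @export
count_effective_parameters <- function(eigenvalues, N = NULL,
                                       prior_precisions = 1, neg_tol = 1e-6) {
  if (length(eigenvalues) == 0) return(0L)
  if (any(eigenvalues < -neg_tol * max(abs(eigenvalues), 1)))
    warning("negative curvature eigenvalue beyond tolerance; clamped to 0 (degenerate optimum)")
  lam <- pmax(eigenvalues, 0)
  sum(lam > prior_precisions)
}

#' Generalized-BIC estimate of the Bayesian log-likelihood
#'
#' \deqn{\hat L = -\chi^2_{best}/2 + \log \mathrm{prior}(best) - \tfrac12
#'   \sum_{i: \lambda_i > p_i} \log\frac{\lambda_i + p_i}{p_i}}
#' where the sum runs over the effectively constrained directions
#' (\eqn{\lambda_i} data curvature, \eqn{p_i} prior precision, both on the
#' fitting scale). The Occam penalty applies only to directions the data
#' constrain; when all \eqn{k} directions are data-dominated with
#' \eqn{\lambda_i \propto N}, the penalty recovers the standard
#' \eqn{(k/2)\log N} scaling of the Bayesian Information Criterion.
#'
#' @param fit A `dyn_fit` with `status` `"ok"` or `"degenerate"`; its
#'   `hessian_eigenvalues` are prior-whitened, so `p_i = 1`.
#' @param N Number of measurement records (interface; the estimate is built
#'   from the stored curvature).
#' @return The scalar estimate \eqn{\hat L}.
#' @export
estimate_log_likelihood <- function(fit, N = NULL) {
  stopifnot(inherits(fit, "dyn_fit"))
  if (fit$status == "failed") return(-Inf)
  lam <- pmax(fit$hessian_eigenvalues, 0)
  -fit$chi2 / 2 + fit$log_prior - 0.5 * sum(log1p(lam[lam > 1]))
}

#' Selection configuration
#'
#' @param margin Stop once the running \eqn{\hat L} has dropped this many
#'   log-units below its maximum (for `patience` consecutive models).
#' @param patience Consecutive below-margin models required to stop.
#' @param max_model_evals Budget cap on trajectory integrations.
#' @param tie_tol \eqn{\hat L} ties within this amount break toward the
#'   simpler model.
#' @param fit A [fit_config()] used for every per-model fit; its seed is
#'   varied deterministically per model.
#' @return A list of class `select_config`.
#' @export
select_config <- function(margin = 2, patience = 3L, max_model_evals = Inf,
                          tie_tol = 1e-6, fit = fit_config()) {
  structure(list(margin = margin, patience = as.integer(patience),
                 max_model_evals = max_model_evals, tie_tol = tie_tol,
                 fit = fit),
            class = "select_config")
}

#' Search the hierarchy and select the best-supported model
#'
#' Fits models in hierarchy order, warm-starting each from the previous
#' optimum, and scores each with the generalized-BIC estimate \eqn{\hat L}.
#' The search stops once \eqn{\hat L} has fallen more than `margin` log-units
#' below the running maximum for `patience` consecutive models (the estimate
#' has a single peak up to statistical fluctuations), or when the hierarchy
#' or the evaluation budget is exhausted. The model with maximal \eqn{\hat L}
#' is selected; ties within `tie_tol` go to the simpler model.
#'
#' @param hierarchy A [build_hierarchy()] result.
#' @param data A [timeseries_set()].
#' @param config A [select_config()].
#' @return An object of class `selection_trace`: list with `fits` (per-model
#'   `dyn_fit`s in hierarchy order), `Lhat`, `selected_index`, `selected_fit`,
#'   `stop_reason` (`"peak_passed"`, `"hierarchy_exhausted"` or
#'   `"budget_exhausted"`), and `eval_counter`.
#' @export
select_model <- function(hierarchy, data, config = select_config()) {
  stopifnot(inherits(hierarchy, "model_hierarchy"),
            length(hierarchy$specs) >= 1)
  evals0 <- eval_counter()[["model_evaluations"]]
  fits <- list(); Lhats <- numeric(0)
  best_L <- -Inf; below <- 0L
  stop_reason <- "hierarchy_exhausted"
  prev_params <- NULL
  for (m in seq_along(hierarchy$specs)) {
    used <- eval_counter()[["model_evaluations"]] - evals0
    if (used >= config$max_model_evals) { stop_reason <- "budget_exhausted"; break }
    spec <- hierarchy$specs[[m]]
    start <- if (is.null(prev_params)) NULL
             else warm_start_params(prev_params, spec)
    new_names <- if (is.null(prev_params)) character()
                 else setdiff(spec$active_params, names(prev_params))
    cfg <- config$fit
    cfg$seed <- (cfg$seed + 997L * m) %% .Machine$integer.max
    fit <- fit_model(spec, data, start = start, config = cfg,
                     boost = new_names)
    fits[[m]] <- fit
    Lhats[m] <- fit$Lhat
    if (fit$status != "failed") prev_params <- fit$params
    if (is.finite(fit$Lhat) && fit$Lhat > best_L) {
      best_L <- fit$Lhat
      below <- 0L
    } else if (is.finite(best_L) && best_L - fit$Lhat > config$margin) {
      below <- below + 1L
      if (below >= config$patience) { stop_reason <- "peak_passed"; break }
    }
  }
  if (length(fits) == 0) {
    return(structure(list(fits = list(), Lhat = numeric(0),
                          selected_index = NA_integer_, selected_fit = NULL,
                          stop_reason = stop_reason,
                          eval_counter = eval_counter()),
                     class = "selection_trace"))
  }
  ok <- which(is.finite(Lhats))
  if (length(ok) == 0)
    stop("every model in the hierarchy failed to fit; last status: ",
         fits[[length(fits)]]$status)
  # argmax with ties toward the simpler model
  sel <- ok[Lhats[ok] > max(Lhats[ok]) - config$tie_tol][1]
  structure(list(fits = fits, Lhat = Lhats, selected_index = sel,
                 selected_fit = fits[[sel]], stop_reason = stop_reason,
                 eval_counter = eval_counter()),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d model(s) fit, selected #%s (%s)\n",
              length(x$fits),
              ifelse(is.na(x$selected_index), "none", x$selected_index),
              x$stop_reason))
  invisible(x)
}

#' Tidy a selection trace
#'
#' @param x A `selection_trace`.
#' @param ... Unused.
#' @return A tibble with one row per fitted model: `hierarchy_index`, `chi2`,
#'   `Lhat`, `n_nominal`, `n_effective`, `n_hidden`, `status`, `selected`.
#' @method tidy selection_trace
#' @export
tidy.selection_trace <- function(x, ...) {
  if (length(x$fits) == 0) {
    return(tibble::tibble(hierarchy_index = integer(), chi2 = numeric(),
                          Lhat = numeric(), n_nominal = integer(),
                          n_effective = integer(), n_hidden = integer(),
                          status = character(), selected = logical()))
  }
  purrr::map_dfr(seq_along(x$fits), function(m) {
    f <- x$fits[[m]]
    spec <- attr(f$params, "spec")
    tibble::tibble(hierarchy_index = m, chi2 = f$chi2, Lhat = f$Lhat,
                   n_nominal = f$n_nominal,
                   n_effective = as.integer(f$n_effective),
                   n_hidden = spec$n_hidden, status = f$status,
                   selected = identical(m, x$selected_index) ||
                     (!is.na(x$selected_index) && m == x$selected_index))
  })
}

#' @rdname tidy.selection_trace
#' @param object A `selection_trace`.
#' @return For `glance`: a one-row tibble summarizing the selection.
#' @method glance selection_trace
#' @export
glance.selection_trace <- function(object, ...) {
  x <- object
  tibble::tibble(n_models = length(x$fits),
                 selected_index = x$selected_index,
                 selected_Lhat = if (is.na(x$selected_index)) NA_real_
                                 else x$Lhat[x$selected_index],
                 stop_reason = x$stop_reason,
                 model_evaluations = unname(x$eval_counter["model_evaluations"]))
}

#' Plot the log-likelihood trace over the hierarchy
#'
#' @param object A `selection_trace`.
#' @param ... Unused.
#' @return A ggplot of \eqn{\hat L} against nominal parameter count, selected
#'   model highlighted.
#' @method autoplot selection_trace
#' @export
autoplot.selection_trace <- function(object, ...) {
  df <- tidy.selection_trace(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_nominal, y = .data$Lhat)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "nominal parameters", y = expression(hat(L)))
}

#' Serialize a selection trace to JSON
#'
#' @param trace A `selection_trace`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
trace_to_json <- function(trace, path = NULL) {
  per_model <- lapply(seq_along(trace$fits), function(m) {
    f <- trace$fits[[m]]
    spec <- attr(f$params, "spec")
    list(hierarchy_index = m, chi2 = f$chi2, Lhat = f$Lhat,
         n_nominal = f$n_nominal, n_effective = f$n_effective,
         n_hidden = spec$n_hidden, status = f$status,
         n_model_evals = f$n_model_evals)
  })
  obj <- list(models = per_model, selected_index = trace$selected_index,
              stop_reason = trace$stop_reason,
              eval_counter = as.list(trace$eval_counter))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
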