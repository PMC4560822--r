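#' Benchmark configuration
#'
#' Study conditions for the three built-in synthetic test systems. Every
#' generator is seed-deterministic and attaches its noiseless truth oracle to
#' the returned data, so downstream evaluation never re-implements the true
#' model. Measurement noise is Gaussian with s.d.
#' `max(noise * |value|, 0.01 * dynamic range)` (the floor avoids zero-sigma
#' records at zero-valued observations).
#'
#' @param system `"gravity"`, `"phosphorylation"` or `"glycolysis"`.
#' @param N Number of experimental conditions.
#' @param noise Noise fraction (0.1 = 10% of the measured value).
#' @param seed Integer seed for sampling conditions, times and noise.
#' @param ... System-specific overrides:
#'   gravity: `r0_range` (default `c(0.5, 3)`, straddling the circular-orbit
#'   radius so the set mixes elliptical and hyperbolic trajectories), `v0`
#'   (1), `mu` (1), `t_max` (20, long enough that bound orbits complete
#'   revolutions);
#'   phosphorylation: `n_sites` (5), `n_per_condition` (5 records per input
#'   condition), `t_max` (10), `V_range` (`c(0.1, 10)`, log-uniform input
#'   sampling), `rate_seed` (777; the frozen seed of the true rate constants);
#'   glycolysis: `range_scale` (1; factor applied to the in-sample
#'   initial-condition ranges about their midpoints), `t_max` (5, minutes),
#'   `observed` (`c("S1", "S2", "S3")`).
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(system = c("gravity", "phosphorylation", "glycolysis"),
                             N = 150L, noise = 0.1, seed = 1L, ...) {
  system <- match.arg(system)
  stopifnot(noise >= 0, N >= 1)
  defaults <- switch(system,
    gravity = list(r0_range = c(0.5, 3), v0 = 1, mu = 1, t_max = 20),
    phosphorylation = list(n_sites = 5L, n_per_condition = 5L, t_max = 10,
                           V_range = c(0.1, 10), rate_seed = 777L),
    glycolysis = list(range_scale = 1, t_max = 5,
                      observed = c("S1", "S2", "S3")))
  extra <- list(...)
  bad <- setdiff(names(extra), names(defaults))
  if (length(bad) > 0) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  defaults[names(extra)] <- extra
  structure(c(list(system = system, N = as.integer(N), noise = noise,
                   seed = as.integer(seed)), defaults),
            class = "benchmark_config")
}

noise_sigma <- function(values, noise) {
  floor_ <- 0.01 * diff(range(values))
  pmax(noise * abs(values), pmax(floor_, 1e-8))
}

# measurement error draws: exactly zero when the noise fraction is zero (the
# reported sigma keeps its positive floor either way)
noise_draw <- function(sigma, noise) {
  if (noise == 0) rep(0, length(sigma)) else stats::rnorm(length(sigma), 0, sigma)
}

# --- gravity ----------------------------------------------------------------

#' Generate the radial-gravity benchmark data
#'
#' Each condition releases a particle at distance `r0` (uniform in
#' `r0_range`) with tangential speed `v0` and zero radial velocity; the
#' angular momentum per mass is therefore `ell = r0 * v0` and the radial
#' dynamics follow [gravity_rhs()]. A single noisy observation of `r` is
#' recorded at a uniform random time in `[0, t_max]`.
#'
#' @param config A [benchmark_config()] with `system = "gravity"`.
#' @return A [timeseries_set()] with one record per condition and a `truth`
#'   attribute: `list(fun(condition, times))` returning the noiseless
#'   observed time course.
#' @export
generate_gravity_data <- function(config = benchmark_config("gravity")) {
  stopifnot(config$system == "gravity")
  set.seed(config$seed)
  N <- config$N
  r0 <- stats::runif(N, config$r0_range[1], config$r0_range[2])
  t_obs <- stats::runif(N, 0, config$t_max)
  ids <- sprintf("c%03d", seq_len(N))
  truth_val <- numeric(N)
  control <- default_control()
  for (i in seq_len(N)) {
    tt <- sort(unique(c(0, t_obs[i])))
    tr <- integrate_gravity(r0[i], v0 = 0, ell = r0[i] * config$v0,
                            mu = config$mu, times = tt, control = control)
    truth_val[i] <- tr$states[match(t_obs[i], tt), 1]
  }
  sig <- noise_sigma(truth_val, config$noise)
  value <- truth_val + noise_draw(sig, config$noise)
  records <- tibble::tibble(condition = ids, time = t_obs, variable = "r",
                            value = value, sigma = sig)
  # the release distance doubles as a condition input: the angular momentum
  # ell = r0 * v0 enters the true radial force law, so the fitted model gets
  # r0 as a constant input pseudo-variable
  conditions <- stats::setNames(lapply(seq_len(N), function(i)
    list(x0 = c(r = r0[i]), inputs = r0[i],
         truth = list(ell = r0[i] * config$v0, v0 = 0, mu = config$mu))),
    ids)
  data <- timeseries_set(records, conditions, variables = "r")
  attr(data, "truth") <- list(
    fun = function(condition, times) {
      tr <- integrate_gravity(condition$x0[["r"]], v0 = condition$truth$v0,
                              ell = condition$truth$ell, mu = condition$truth$mu,
                              times = times)
      tr$states[, 1, drop = FALSE]
    },
    noiseless = truth_val)
  attr(data, "config") <- config
  data
}

# --- multisite phosphorylation ----------------------------------------------

# nearest-neighbour occupancy pattern of site `site` in bitmask state `s`
nbr_pattern <- function(s, site, n_sites) {
  left <- if (site > 1) bitwAnd(bitwShiftR(s, site - 2L), 1L) else NA_integer_
  right <- if (site < n_sites) bitwAnd(bitwShiftR(s, site), 1L) else NA_integer_
  paste0(ifelse(is.na(left), "-", left), ifelse(is.na(right), "-", right))
}

#' True rate constants of the phosphorylation benchmark
#'
#' Draws the Michaelis-Menten rate constants of the multisite network once
#' from a fixed seed: a maximal rate `V` for every (site, direction,
#' neighbour-occupancy pattern) combination and a Michaelis constant `K`
#' shared across neighbour patterns for each (site, direction), all
#' log-uniform in `[0.1, 10]`. The draw is frozen by its seed, so the true
#' model is exactly known to any consumer.
#'
#' @param n_sites Number of phosphorylation sites in the linear chain.
#' @param seed Seed of the frozen draw.
#' @return A list with tibbles `V` and `K` and the scalar `n_parameters`.
#' @export
phospho_rate_params <- function(n_sites = 5L, seed = 777L) {
  set.seed(seed)
  runif_log <- function(n) exp(stats::runif(n, log(0.1), log(10)))
  combos <- list()
  for (site in seq_len(n_sites)) {
    pats <- unique(vapply(0:(2^n_sites - 1), nbr_pattern, character(1),
                          site = site, n_sites = n_sites))
    for (dir in c("up", "down"))
      combos[[length(combos) + 1]] <-
        tibble::tibble(site = site, dir = dir, pattern = pats)
  }
  V <- dplyr::bind_rows(combos)
  V$V <- runif_log(nrow(V))
  K <- dplyr::distinct(V[, c("site", "dir")])
  K$K <- runif_log(nrow(K))
  list(V = V, K = K, n_parameters = nrow(V) + nrow(K))
}

#' Build the multisite-phosphorylation microstate network
#'
#' A receptor with `n_sites` sites in a linear chain occupies one of
#' `2^n_sites` microstates. Each transition flips one site with
#' Michaelis-Menten rate `V * x/(K + x)` in the microstate concentration `x`,
#' where `(V, K)` depend on the flipped site, the direction, and the
#' occupancy of the nearest neighbouring sites. Total concentration over
#' microstates is conserved. The transition "phosphorylation of site 2 with
#' site 3 occupied" is flagged input-controlled: its maximal rate is replaced
#' by the external input `V`.
#'
#' @param n_sites Number of sites (>= 1).
#' @param rate_params Output of [phospho_rate_params()]; drawn from its
#'   default frozen seed when `NULL`.
#' @return A list of class `phospho_network`: `n_sites`, `n_states`,
#'   `transitions` (tibble), `site_counts` (phosphorylated-site count per
#'   microstate), `rate_params`, `n_parameters`.
#' @export
build_phospho_network <- function(n_sites = 5L, rate_params = NULL) {
  stopifnot(n_sites >= 1)
  if (is.null(rate_params)) rate_params <- phospho_rate_params(n_sites)
  n_states <- 2L^n_sites
  rows <- list()
  for (s in 0:(n_states - 1L)) {
    for (site in seq_len(n_sites)) {
      occupied <- bitwAnd(bitwShiftR(s, site - 1L), 1L) == 1L
      dir <- if (occupied) "down" else "up"
      to <- bitwXor(s, bitwShiftL(1L, site - 1L))
      pat <- nbr_pattern(s, site, n_sites)
      input_flag <- site == 2L && dir == "up" && n_sites >= 3L &&
        bitwAnd(bitwShiftR(s, 2L), 1L) == 1L # site 3 occupied
      rows[[length(rows) + 1]] <- tibble::tibble(
        from = s, to = to, site = site, dir = dir, pattern = pat,
        input_flag = input_flag)
    }
  }
  tr <- dplyr::bind_rows(rows)
  tr <- dplyr::left_join(tr, rate_params$V, by = c("site", "dir", "pattern"))
  tr <- dplyr::left_join(tr, rate_params$K, by = c("site", "dir"))
  structure(list(n_sites = as.integer(n_sites), n_states = n_states,
                 transitions = tr,
                 site_counts = vapply(0:(n_states - 1L), function(s)
                   sum(bitwAnd(bitwShiftR(s, 0:(n_sites - 1L)), 1L)),
                   numeric(1)),
                 rate_params = rate_params,
                 n_parameters = rate_params$n_parameters),
            class = "phospho_network")
}

# C++ packing for the microstate network; V may be overridden per transition
phospho_pars <- function(network, V_override = NULL) {
  tr <- network$transitions
  V <- if (is.null(V_override)) tr$V else V_override
  c(network$n_states, nrow(tr),
    as.vector(rbind(tr$from, tr$to, V, tr$K, as.numeric(tr$input_flag))))
}

#' Integrate the phosphorylation microstate network
#'
#' @param network A [build_phospho_network()] result.
#' @param inputs Scalar input `V` (the input-controlled maximal rate) or a
#'   [pw_input()] signal.
#' @param times Strictly increasing times starting at the initial time.
#' @param x0 Initial microstate concentrations (default: all mass in the
#'   unphosphorylated state).
#' @param control Solver control.
#' @return A `dyn_trajectory` over the microstates, with an additional
#'   `observable` element: the total phosphorylation
#'   \eqn{\sum_s (\mathrm{sites\ occupied\ in\ } s)\, x_s} at each time.
#' @export
integrate_phospho <- function(network, inputs, times,
                              x0 = c(1, rep(0, network$n_states - 1)),
                              control = default_control()) {
  res <- integrate_raw(4L, phospho_pars(network), x0, inputs, times, control,
                       positivity = FALSE)
  .counters$model_evaluations <- .counters$model_evaluations + 1
  .counters$rhs_evaluations <- .counters$rhs_evaluations + res$n_rhs
  obs <- as.vector(res$states %*% network$site_counts)
  structure(list(times = as.numeric(times), states = res$states,
                 status = STATUS_LEVELS[res$status + 1L],
                 n_rhs_evals = res$n_rhs, observable = obs),
            class = "dyn_trajectory")
}

#' Generate the multisite-phosphorylation benchmark data
#'
#' Conditions vary the input `V` (log-uniform in `V_range`); in each
#' condition the total phosphorylation is measured at `n_per_condition`
#' equally spaced times in `(0, t_max]`, starting from the fully
#' unphosphorylated state, and corrupted with noise at the scale of 10% of
#' the values (floored, see [benchmark_config()]).
#'
#' @param config A [benchmark_config()] with `system = "phosphorylation"`;
#'   `N` counts measurement records, so `ceiling(N / n_per_condition)`
#'   conditions are generated.
#' @return A [timeseries_set()] with observed variable `phi_total`, plus
#'   `truth` (oracle closure and the network) and `config` attributes.
#' @export
generate_phospho_data <- function(config = benchmark_config("phosphorylation", N = 100)) {
  stopifnot(config$system == "phosphorylation")
  network <- build_phospho_network(config$n_sites,
                                   phospho_rate_params(config$n_sites,
                                                       config$rate_seed))
  set.seed(config$seed)
  n_cond <- ceiling(config$N / config$n_per_condition)
  V <- exp(stats::runif(n_cond, log(config$V_range[1]), log(config$V_range[2])))
  ids <- sprintf("c%03d", seq_len(n_cond))
  t_grid <- seq(0, config$t_max, length.out = config$n_per_condition + 1)[-1]
  recs <- list()
  for (i in seq_len(n_cond)) {
    tr <- integrate_phospho(network, V[i], c(0, t_grid))
    vals <- tr$observable[-1]
    recs[[i]] <- tibble::tibble(condition = ids[i], time = t_grid,
                                variable = "phi_total", value = vals,
                                sigma = NA_real_, truth = vals)
  }
  recs <- dplyr::bind_rows(recs)
  recs <- recs[seq_len(min(config$N, nrow(recs))), ]
  recs$sigma <- noise_sigma(recs$truth, config$noise)
  recs$value <- recs$truth + noise_draw(recs$sigma, config$noise)
  truth_vals <- recs$truth
  recs$truth <- NULL
  conditions <- stats::setNames(lapply(seq_len(n_cond), function(i)
    list(x0 = c(phi_total = 0), inputs = V[i])), ids)
  kept <- unique(recs$condition)
  data <- timeseries_set(recs, conditions[kept], variables = "phi_total")
  attr(data, "truth") <- list(
    fun = function(condition, times) {
      tr <- integrate_phospho(network, condition$inputs, times)
      matrix(tr$observable, ncol = 1)
    },
    network = network, noiseless = truth_vals)
  attr(data, "config") <- config
  data
}

#' Simple saturating model of total phosphorylation
#'
#' The hand-built 5-parameter reference model: exponential saturation in time
#' with an asymptote that depends sigmoidally on the input,
#' \deqn{x(t; V) = A\, \xi\!\left(\frac{V_0 - V}{w}\right) (1 - e^{-t/\tau}) + c,}
#' with \eqn{\xi} the logistic sigmoid of [sigmoid()] (note \eqn{\xi(-\infty)
#' = 1}, so the asymptote approaches `A + c` for large `V`).
#'
#' @param params Named numeric vector `c(A, V0, w, tau, c)`.
#' @param times Times at which to evaluate.
#' @param V Scalar input.
#' @return Numeric vector of predicted total phosphorylation.
#' @export
simple_phospho_model <- function(params, times, V) {
  stopifnot(length(params) == 5)
  p <- as.numeric(params)
  p[1] * sigmoid((p[2] - V) / p[3]) * (1 - exp(-times / p[4])) + p[5]
}

# --- yeast glycolysis --------------------------------------------------------

#' Constants of the yeast glycolysis oscillator
#'
#' The 16 constants of the 7-species glycolysis model (concentrations in mM,
#' time in minutes): influx `J0`, rate constants `k1`-`k6`, `k`, `kappa`,
#' the allosteric inhibition constant `K1` with Hill coefficient `q`, the
#' transmembrane coupling fraction `psi`, conserved totals `Ntot` (NADH +
#' NAD) and `Atot` (ATP + ADP), and the stoichiometric coefficients
#' `n_triose` (trioses per glucose) and `n_atp` (ATP per lumped reaction),
#' both 2.
#'
#' @return Named numeric vector of length 16.
#' @export
glycolysis_constants <- function() {
  c(J0 = 2.5, k1 = 100, K1 = 0.52, q = 4, k2 = 6, k3 = 16, k4 = 100,
    k5 = 1.28, k6 = 12, k = 1.8, kappa = 13, psi = 0.1, Ntot = 1, Atot = 4,
    n_triose = 2, n_atp = 2)
}

#' Build the 7-species yeast glycolysis oscillator
#'
#' Coupled ODEs for glucose (`S1`), triose pool (`S2`), 1,3-BPG (`S3`),
#' pyruvate/acetaldehyde pool (`S4`), NADH (`S5`), ATP (`S6`) and
#' extracellular acetaldehyde (`S7`), sustaining limit-cycle oscillations
#' with a period near one minute at the constants of
#' [glycolysis_constants()]. In-sample initial-condition ranges for the
#' benchmark protocol are attached.
#'
#' @return A list of class `glycolysis_model`: `constants`, `species`,
#'   `rhs(state)`, `in_ranges` (7 x 2 matrix), `x0_cycle` (a point near the
#'   limit cycle).
#' @export
build_glycolysis_model <- function() {
  constants <- glycolysis_constants()
  species <- paste0("S", 1:7)
  in_ranges <- rbind(S1 = c(0.15, 1.60), S2 = c(0.19, 2.16),
                     S3 = c(0.04, 0.20), S4 = c(0.10, 0.35),
                     S5 = c(0.08, 0.30), S6 = c(0.14, 2.67),
                     S7 = c(0.05, 0.10))
  structure(list(constants = constants, species = species,
                 rhs = function(state) cpp_rhs(5L, constants, state, numeric()),
                 in_ranges = in_ranges,
                 x0_cycle = c(0.321, 1.101, 0.175, 0.295, 0.140, 1.893, 0.094)),
            class = "glycolysis_model")
}

#' Integrate the glycolysis truth model
#'
#' @param model A [build_glycolysis_model()] result.
#' @param x0 Initial concentrations, length 7.
#' @param times Strictly increasing times (minutes).
#' @param control Solver control.
#' @return A `dyn_trajectory` over the 7 species.
#' @export
integrate_glycolysis <- function(model, x0, times, control = default_control()) {
  res <- integrate_raw(5L, model$constants, as.numeric(x0), NULL, times,
                       control, positivity = FALSE)
  .counters$model_evaluations <- .counters$model_evaluations + 1
  .counters$rhs_evaluations <- .counters$rhs_evaluations + res$n_rhs
  states <- res$states
  colnames(states) <- model$species
  structure(list(times = as.numeric(times), states = states,
                 status = STATUS_LEVELS[res$status + 1L],
                 n_rhs_evals = res$n_rhs),
            class = "dyn_trajectory")
}

# initial-condition ranges scaled about their midpoints
scaled_ranges <- function(ranges, scale) {
  mid <- rowMeans(ranges)
  half <- (ranges[, 2] - ranges[, 1]) / 2 * scale
  cbind(pmax(mid - half, 1e-3), mid + half)
}

#' Generate the yeast-glycolysis benchmark data
#'
#' Each condition samples all 7 initial concentrations uniformly from the
#' (possibly scaled) in-sample ranges; the three observed species are
#' measured once, at a single uniform random time in `[0, t_max]`, with
#' multiplicative noise. Hidden species are never measured; only the observed
#' initial values are reported to the fitter.
#'
#' @param config A [benchmark_config()] with `system = "glycolysis"`; `N` is
#'   the number of conditions (3 records each). `range_scale` scales the
#'   sampling ranges about their midpoints (2 for the hard out-of-sample
#'   protocol).
#' @return A [timeseries_set()] with `truth` (oracle closure and the model)
#'   and `config` attributes; each condition stores the full true initial
#'   state in `truth_x0`.
#' @export
generate_glycolysis_data <- function(config = benchmark_config("glycolysis", N = 40)) {
  stopifnot(config$system == "glycolysis")
  model <- build_glycolysis_model()
  obs <- config$observed
  oi <- match(obs, model$species)
  stopifnot(!anyNA(oi))
  set.seed(config$seed)
  N <- config$N
  rng <- scaled_ranges(model$in_ranges, config$range_scale)
  ids <- sprintf("c%03d", seq_len(N))
  x0s <- sapply(seq_len(7), function(j) stats::runif(N, rng[j, 1], rng[j, 2]))
  t_obs <- stats::runif(N, 0, config$t_max)
  recs <- list()
  truth_all <- matrix(NA_real_, N, length(obs))
  for (i in seq_len(N)) {
    tt <- sort(unique(c(0, t_obs[i])))
    tr <- integrate_glycolysis(model, x0s[i, ], tt)
    truth_all[i, ] <- tr$states[match(t_obs[i], tt), oi]
  }
  sig <- matrix(noise_sigma(as.vector(truth_all), config$noise), N)
  vals <- truth_all + matrix(noise_draw(sig, config$noise), nrow(sig))
  for (i in seq_len(N)) {
    recs[[i]] <- tibble::tibble(condition = ids[i], time = t_obs[i],
                                variable = obs, value = vals[i, ],
                                sigma = sig[i, ])
  }
  conditions <- stats::setNames(lapply(seq_len(N), function(i)
    list(x0 = stats::setNames(x0s[i, oi], obs), inputs = NULL,
         truth_x0 = stats::setNames(x0s[i, ], model$species))), ids)
  data <- timeseries_set(dplyr::bind_rows(recs), conditions, variables = obs)
  attr(data, "truth") <- list(
    fun = function(condition, times) {
      tr <- integrate_glycolysis(model, condition$truth_x0, times)
      tr$states[, oi, drop = FALSE]
    },
    model = model, noiseless = truth_all)
  attr(data, "config") <- config
  data
}

#' Peak-to-peak oscillation period
#'
#' Median spacing of interior local maxima of a time course; a simple
#' numerical period estimate for limit-cycle trajectories sampled on a dense
#' grid.
#'
#' @param times Sampling times.
#' @param values Sampled values.
#' @return Median peak-to-peak spacing, or `NA` with fewer than two peaks.
#' @export
oscillation_period <- function(times, values) {
  n <- length(values)
  if (n < 3) return(NA_real_)
  pk <- which(values[2:(n - 1)] > values[1:(n - 2)] &
                values[2:(n - 1)] >= values[3:n]) + 1
  if (length(pk) < 2) return(NA_real_)
  stats::median(diff(times[pk]))
}
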