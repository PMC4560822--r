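---
title: "Adaptive inference of phenomenological dynamical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive inference of phenomenological dynamical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many dynamical systems in cell biology (and elsewhere) are observed sparsely:
a handful of species are measured, at a few noisy time points, while most of
the interacting components remain hidden. Fitting the "true" mechanistic
model in this regime invites overfitting; hand-built toy models saturate and
miss real structure. `dynadapt` takes the middle road: it searches an
a-priori **ordered, nested hierarchy** of phenomenological ODE models --
growing both in nonlinearity and in number of hidden variables -- and selects
the single model whose complexity the data actually support.

The generic form is

$$\dot{\mathbf x} = F_x(\mathbf x, \mathbf y, \mathbf I), \qquad
  \dot{\mathbf y} = F_y(\mathbf x, \mathbf y, \mathbf I),$$

with $\mathbf x$ observed variables, $\mathbf y$ hidden variables, and
$\mathbf I$ external inputs, treated as constant (or piecewise-constant)
pseudo-variables. Intrinsic stochasticity is neglected: repeated runs from
the same initial state differ only by measurement noise.

## Model classes

Two complete classes are implemented; each can approximate any smooth
dynamics given enough hidden variables.

**S-systems (power-law networks).** Each variable has a production and a
degradation term, each a product of powers of all variables:
$$\dot x_i = \alpha_i \prod_{j=1}^{J+K} x_j^{g_{ij}}
           - \beta_i \prod_{j=1}^{J+K} x_j^{h_{ij}},$$
with $\alpha_i, \beta_i \ge 0$ and real-valued exponents. The class
generalizes mass-action kinetics but is ill-defined at non-positive states;
the solver flags any trajectory that reaches zero, and the fitting loop
treats such parameter sets as infinitely poor fits rather than exceptions.

**Sigmoidal (continuous-time recurrent) networks.** Each variable relaxes
with a time constant and is driven by a weighted sum of saturating
interactions:
$$\dot x_i = -\frac{x_i}{\tau_i}
  + \sum_{j=1}^{J+K} W_{ij}\, \xi(\theta_j - x_j), \qquad
  \xi(y) = \frac{1}{1+e^{y}}.$$

The exact argument convention for $\xi$ is a genuine design choice: we use
one offset $\theta_j$ per *source* variable with the sigmoid applied before
the weighted sum (the classical continuous-time recurrent-network form). The
alternative -- a sigmoid of a linear combination -- is a different model
class and is deliberately not implemented. Every serialized model carries a
`sigmoid_convention` tag so exported files are unambiguous.

## The hierarchy

`build_hierarchy()` enumerates models in a fixed order: a minimal block
(per-observed-variable relaxation or production/degradation parameters),
then one interaction parameter at a time in row-major (target, source) order,
then -- once the current dimension is fully connected -- a hidden-variable
bundle (its relaxation parameters, initial value, self-interaction and cross
terms to the most recently added variable). Every model's active-parameter
list is a prefix of the next one's, so the earlier model is always
recoverable from the later one by pinning the added parameters at neutral
values (weights and exponents 0). The exact interleaving is known to matter
little compared to the choice of model class; ours is one deterministic,
documented choice.

Hidden initial values are fit parameters shared across experimental
conditions (observed initial values are known per condition). When a
condition-specific quantity shapes the dynamics -- like the release distance
in the gravity benchmark below -- it should be supplied as an input instead.

## Fitting and scoring

Each model is fit by a two-phase search of the posterior cost
$\chi^2/2 - \log(\text{prior})$, preceded by a small exploration ensemble:

0. **Exploration ensemble**: `n_scatter` (default 20) candidate starts drawn
   around the warm start -- full prior scale on newly activated parameters,
   mild jitter on inherited ones. The warm start sits, by construction, in
   the *simpler* model's optimum, which is not always the basin of the
   richer model's optimum; the ensemble gives the search a way out.
1. **Annealed exploration**: a random-walk Metropolis search from the best
   candidate, with a geometric temperature ladder (default $10 \to 1$ over
   20 stages, 50 proposals per stage) and proposal scales tied to the prior
   scales. Parameter sets whose integration fails (positivity violation,
   blow-up, step exhaustion) are rejected outright. Parameters that were
   just activated by the hierarchy start at a neutral *saddle* -- a hidden
   variable pinned at its fixed point leaves the cost exactly flat in its
   couplings -- so their proposals are widened tenfold during the hot half
   of the ladder to break the degeneracy before the walk cools.
2. **Local refinement**: a Nelder-Mead polish followed by BFGS descent, run
   from the annealed best *and* from the two leading ensemble candidates
   (multi-descent), keeping the overall best. The fit never returns a point
   worse than its warm start, which makes $\chi^2$ monotone non-increasing
   along the hierarchy.

Priors are weakly informative, independent Gaussians on the fitting scale:
s.d. 10 on weights, exponents, offsets and sigmoidal hidden initial values;
log-normal with $\sigma_{\log} = \ln 10$ on $\alpha$, $\beta$, $\tau$ and
positive hidden initial values. Warm starts take the previous optimum and
initialize new parameters neutrally (new $\tau$ at 1, hidden initial values
at 1 for S-systems -- positivity -- and 0 for sigmoidal networks).

**Scoring.** At the optimum we estimate the Bayesian log-likelihood with a
generalized information criterion:
$$\hat L = -\tfrac{1}{2}\chi^2 + \log \text{prior}
  - \tfrac{1}{2}\sum_{i:\ \lambda_i > p_i} \log\frac{\lambda_i + p_i}{p_i},$$
where $\lambda_i$ are eigenvalues of the curvature of the data-only cost
($\chi^2/2$) in the prior-whitened basis and $p_i$ the prior precisions
(1 after whitening). Only directions the data actually constrain
($\lambda_i > p_i$) are penalized; their count is the **effective number of
parameters**, always at most the nominal count. When all $k$ directions are
data-dominated with $\lambda_i \propto N$ the penalty recovers the standard
$(k/2)\log N$ behaviour of the Bayesian Information Criterion, which the
test suite verifies on a linear-Gaussian toy against the closed form.

The curvature is measured by central finite differences (default relative
step 0.1 on the fitting scale) with the integrator tightened to
`rtol = 1e-9` during differencing; with looser settings, finite-difference
noise in whitened units can exceed the prior precision and corrupt the
effective-parameter count. Eigenvalues that come out slightly negative are
clamped to zero; negative curvature beyond a relative tolerance of $10^{-3}$
flags the fit as `degenerate`.

**Selection** walks the hierarchy with warm starts, tracks the running
maximum of $\hat L$, and stops once $\hat L$ has dropped more than `margin`
(default 2 log-units) below the maximum for `patience` (default 3)
consecutive models -- the estimate has a single peak up to statistical
fluctuations, so the maximum is then certain to have been passed. Ties
within $10^{-6}$ go to the simpler model. At strongly reduced annealing
budgets the trace can dip right after a hidden-variable bundle is added
(its parameters are not yet fit) and recover a few models later once the
couplings are constrained; studies run at such budgets should set `patience`
to cover a full dimension block, as the gravity study in the test suite
does. A configurable budget of model
evaluations (one evaluation = one trajectory integration over one condition)
can stop the search early; counters are kept package-wide by
`eval_counter()`.

## Numerical choices

The core integrator is an adaptive embedded Dormand-Prince 5(4) Runge-Kutta
scheme written in C++ (default `rtol = 1e-6`, `atol = 1e-8`). The fitted
model classes are non-stiff in the regimes the search visits, and a compiled
explicit solver keeps a single selection run within minutes; the independent
stiff solver `deSolve::lsoda` is used in the test suite as a cross-check
oracle on the glycolysis oscillator. Failure handling is deliberate:
a blow-up bound of $10^{10}$, a per-segment step cap (default 5,000; bad
parameter regions fail fast instead of consuming the budget), positivity
checks for S-systems at every accepted step, and an underflowing step size
all downgrade the trajectory to a status flag that the fitting loop treats
as an infinite-cost point.

## The benchmark generators

The generators define the package's study conditions; each is
seed-deterministic and exposes its noiseless truth oracle, so downstream
evaluation never re-implements the truth. Measurement noise is Gaussian with
s.d. $\max(f\,|v|,\ 0.01\,\Delta)$ where $f$ is the noise fraction and
$\Delta$ the dynamic range of the generated values -- the floor avoids
zero-sigma records at zero-valued observations (a noise fraction of exactly
0 adds no noise but keeps the positive reported sigma).

**Radial gravity.** A particle is released at distance $r_0$ (uniform in
$[0.5, 3]$) with tangential speed $v_0 = 1$ around a centre with $\mu = 1$;
the radial dynamics are $\dot r = v$, $\dot v = \ell^2/r^3 - \mu/r^2$ with
$\ell = r_0 v_0$. The range straddles both the circular-orbit radius
($\mu/v_0^2 = 1$) and the escape radius ($2\mu/v_0^2 = 2$), so the set mixes
elliptical (oscillatory) and hyperbolic (monotonic) trajectories. One noisy
observation of $r$ at a uniform random time in $[0, 20]$ is recorded per
condition; the window is long enough for bound orbits to complete
revolutions, otherwise the data would not witness the oscillation at all.
Because $\ell$ depends on $r_0$, the release distance is passed to the
fitted model as a constant input; with hidden variable $y = v + c$ the true
dynamics are then *exactly* representable in the S-system hierarchy
($\dot x = y - c$, $\dot y = x^{-3} I^2 - x^{-2}$), and the velocity is the
single hidden variable the selection should discover.

**Multisite phosphorylation.** A receptor with 5 sites in a linear chain
occupies $2^5 = 32$ microstates; each transition flips one site with
Michaelis-Menten rate $V x/(K + x)$, where $(V, K)$ depend on the site, the
direction, and the occupancy of the nearest neighbours. The maximal rates
(one per site/direction/neighbour pattern, 32 of them) and Michaelis
constants (shared across neighbour patterns, 10) are drawn log-uniformly in
$[0.1, 10]$ from a frozen seed -- 42 recorded constants in total; the exact
sharing pattern of the reference system's 52 constants is not public, so the
generator records its own draw and the test suite asserts against that. The
input is the maximal rate of phosphorylation of site 2 when site 3 is
occupied; the observable is the total phosphorylation
$\sum_s (\text{occupied sites in } s)\, x_s$ starting from the
unphosphorylated state, measured at 5 equally spaced times per condition
with 10% noise. A hand-built 5-parameter reference model
$x(t;V) = A\,\xi((V_0-V)/w)(1 - e^{-t/\tau}) + c$ and a maximum-likelihood
refit of the full 42-constant network serve as comparison baselines in
`prediction_error_vs_N()`.

**Yeast glycolysis.** The 7-species oscillator model with 16 constants
(influx 2.5 mM/min, the literature rate constants, conserved NAD and adenine
pools, and the two stoichiometric coefficients of the lumped reactions);
at these constants the limit cycle has a period of about 1.2 min with the
sharp, non-sinusoidal peaks that make the system a demanding benchmark.
Each condition samples all 7 initial concentrations uniformly from the
in-sample ranges (taken from the published protocol of the comparison
study); the three species S1-S3 are observed once, at a single uniform
random time in $[0, 5]$ min, with 10% noise. Out-of-sample sets scale the
ranges about their midpoints (factor 2 for the hard test). Which three of
the seven species were observed in the reference run is not public; we fix
S1-S3 and record the choice in the data's config attribute.

## Evaluation protocols

`out_of_sample_correlation()` integrates the selected model and the truth
oracle over a common grid (100 points over the horizon; 5 min for
glycolysis), computes the Pearson correlation per observed species over the
time course, averages over species within a condition and then over
conditions, and scores failed model integrations as correlation 0 rather
than dropping them (survivorship would inflate the mean). Whether to pool
species before or after conditions is unstated in the reference protocol;
the report's metadata records our order. `posterior_prediction_bands()`
draws from the Laplace approximation of the posterior at the optimum
(regularized so that unconstrained directions fall back to the prior, never
beyond it) and reports pointwise medians with 90% bands.

## What the tests do and do not show

All fits in the test suite run at desk scale: short annealing ladders, small
hierarchies (up to a few hidden variables), and minutes rather than hours of
search. The acceptance checks verify the machinery end to end -- exact
right-hand sides, BIC limits, warm-start identities, recovery of an
in-hierarchy 2-variable model from 100 noisy points, the gravity hidden
variable, and the generators' invariants. The full glycolysis study
(saturating at tens of effective parameters with 3 hidden variables and
out-of-sample correlations of 0.6-0.9) is a stochastic, compute-heavy
outcome: its test runs the same protocol at reduced search depth, and the
corresponding assertions document the overnight-scale targets rather than a
desk-scale guarantee. Passing tests demonstrate correctness of the engine on
synthetic data generated by the stated models with the stated noise; they do
not certify behaviour on real data whose noise model, sampling design or
dynamics depart from these assumptions.

## Known limitations

- Hidden initial values are global fit parameters; systems where hidden
  states vary across conditions are only effectively approximated (the
  gravity benchmark sidesteps this via its input; glycolysis does not, which
  is part of what makes it hard).
- S-system fitting discards trajectories that reach non-positive values, so
  large parts of parameter space are invisible to the search; this is a
  property of the class, not of the implementation.
- The annealing schedule and prior scales are defaults chosen for
  robustness, not a calibrated reproduction of any particular published
  schedule; both are fully configurable through `fit_config()`.
- Model selection assumes independent Gaussian measurement noise with the
  recorded sigmas taken at face value; no error-model re-estimation is
  performed.
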