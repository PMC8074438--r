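---
title: "Methods: variance-based sensitivity analysis of FBA models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance-based sensitivity analysis of FBA models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxsens)
```

## The model and its assumptions

A constraint-based metabolic model is the triple of a stoichiometric
matrix $S$ (metabolites $\times$ reactions), flux bounds
$v_l \le v \le v_u$, and a linear objective $w$ — in practice the
biomass pseudo-reaction whose flux proxies growth rate. Flux balance
analysis (FBA) solves

$$\max_v \; w^\top v \quad \text{s.t.} \quad S v = 0,\; v_l \le v \le v_u,$$

a linear program whose optimal *value* is unique even when the optimal
flux *vector* is not. `fluxsens` deliberately consumes only the value:
no flux-variability or parsimonious-FBA post-processing is applied,
because the sensitivity analysis is an analysis of the growth optimum,
not of the flux distribution behind it.

Exchange reactions — columns of $S$ with a single nonzero entry — couple
the network to its environment; under the usual sign convention a
negative flux is intake, so the exchange *lower* bound is the intake
capacity of a nutrient. Those capacities are the uncertain factors. Each
selected factor is varied independently and uniformly over a common
interval, by default $[-10, 0]$ mM/h: wide enough to realize essentially
all ratios between nutrient availabilities, low enough in magnitude that
internal reaction bounds (conventionally $\pm 1000$) never become the
binding constraint. Only the lower bound is perturbed; the upper bound
(secretion) stays as in the source model. Units are carried as an opaque
label and never converted.

Exchange detection is structural (single nonzero column) rather than
id-based (`EX_` prefixes), because identifier conventions differ across
model dialects; an `id_pattern` override exists for models that tag
boundary reactions by name. Whether non-factor exchanges should keep
their source-model bounds or be closed is a modelling decision the
package does not make for you: the model is taken exactly as loaded, and
`apply_intake_bounds()` lets you impose any baseline medium beforehand.

## The Saltelli design

Variance-based indices are estimated from the classic cross-sampling
scheme. $N$ points of a $2D$-dimensional Sobol' sequence are split
column-wise into two independent $N \times D$ blocks $A$ and $B$; the
hybrid block $A_B^{(i)}$ equals $A$ with column $i$ taken from $B$.
Estimation of all first-order and total-effect indices then costs
$N(D+2)$ model evaluations. A `second_order = TRUE` design adds the
mirrored hybrids $B_A^{(i)}$ ($N(2D+2)$ rows) and enables second-order
indices. The $N(D+2)$ scheme is the default: it is the cheapest design
that delivers both indices, and it is the scheme whose run counts match
published genome-scale sweeps of this kind (e.g.
$2^{15} \times (693+2) = 22\,773\,760$).

The quasi-random generator is a base-2 Sobol' sequence in Gray-code
order with the standard Joe–Kuo direction-number parameterization,
shipped for 64 dimensions (32 factors with the paired-block
construction). Determinism is part of the contract: the same $(N, D,
\text{skip})$ always yields bitwise-identical designs. The first point
of the raw sequence is the origin, which after scaling would set *every*
intake to its most negative bound simultaneously in the first row of
$A$; the default `skip = 1` drops it. The skip policy is recorded in the
design and the run manifest. $N$ should be a power of two — the
dyadic balance properties that make the sequence better than plain Monte
Carlo hold exactly at powers of two — and other values are accepted with
a warning.

## Estimators, failures, and the bootstrap

With $f_A$, $f_B$, $f_{AB^{(i)}}$ the outputs on the blocks and $V$ the
(population) variance of $Y$ over $A \cup B$:

- first order: $\hat S_i = \mathrm{mean}\!\left(f_B (f_{AB^{(i)}} - f_A)\right) / V$
  (Saltelli-2010 cross-block estimator);
- total effect: $\hat S_{T_i} = \mathrm{mean}\!\left((f_A - f_{AB^{(i)}})^2\right) / (2V)$
  (Jansen estimator).

These are the defaults of the widely used community implementations,
which keeps results comparable across toolchains. Estimates are reported
unclipped: values slightly below 0 or above 1 are Monte-Carlo noise, and
clipping them would bias averages; the result object flags excursions
larger than the CI half-width. A constant output (zero variance) is a
degenerate input and raises an error naming the constant — indices are
simply undefined there.

Rows whose LP is infeasible or unbounded are handled by policy. The
default imputes $Y = 0$ with a logged count: for a growth maximization,
"no feasible flux state" and "no growth" are the same biological
statement. The alternative `"abort"` policy stops the sweep instead.

Confidence intervals come from resampling the $N$ base samples with
replacement 100 times (default) and recomputing both estimators per
resample; the half-width is $z_{0.975} \cdot \mathrm{sd}$ of the
bootstrap distribution. Resampling is *row-coupled*: a base sample's
$A$, $B$ and all hybrid rows move together, because the estimators
difference exactly those pairings — independent row resampling would
destroy the design structure being resampled. The bootstrap is the only
stochastic step of the whole workflow and is driven by an explicit seed;
library code saves and restores the caller's RNG state.

The interaction gap $S_{T_i} - S_i$ summarizes how much of a factor's
influence is carried by interactions. Negative gaps can occur from
estimator noise; they are preserved and flagged, never zeroed. Rankings
sort descending by the chosen index with lexicographic tie-breaking, so
re-runs are stable.

## Execution layer

The sweep contract is determinism: `Y[k]` is the FBA optimum of design
row `k` whatever the backend or worker count, so serial and parallel
runs are bitwise identical and the estimators never see scheduling
noise. Distribution is static — contiguous row chunks, sizes differing
by at most one, remainder to the earlier workers — because FBA cost does
not depend on the bound values, so balanced chunk sizes are balanced
work. `max_batch_size()` exposes the memory arithmetic
(`floor(mem / (D * bytes * overhead))`) used to size row batches on
memory-constrained nodes. The process-pool backend uses forked workers
(Unix); a message-passing backend can be plugged in by honouring the
same ordered-results contract. An optional progress file records
completed chunks so an interrupted sweep resumes without recomputing
them; completed chunks are trusted verbatim.

## The LP engine

The solver is a dense two-phase bounded-variable primal simplex with
Bland's anti-cycling rule. Phase I drives one artificial variable per
row to zero (handling rank-deficient stoichiometries without
preprocessing: redundant rows leave their artificial basic at zero,
pinned by `[0,0]` bounds in phase II); phase II optimizes the true
objective. Infeasibility and unboundedness are first-class statuses, not
exceptions, and infinite bounds are represented natively. The
feasibility tolerance defaults to `1e-9`; phase-I infeasibility is
declared above `1e-7` relative to the right-hand-side scale. The engine
sits behind a one-function backend contract (`fba(backend = ...)`), so
an external solver can be injected without touching anything else.
Dense linear algebra bounds its comfort zone at curated-model scale
(hundreds of reactions); genome-scale sweeps would want an injected
sparse solver.

Correctness is checked two independent ways in the test suite: against
brute-force vertex enumeration (exhaustive over basic solutions, exact
for small models) on dozens of random models, and against an
independently implemented LP solver on shifted-variable reformulations.

## Morris screening and the local comparator

Morris trajectories move each factor once per trajectory by
$\pm\delta$ on the unit scale, in random order from a random grid point
(`levels = 4`, $\delta = 2/3$ — the standard convention, stated as a
default rather than asserted as anyone's historical setting). The
elementary effect is the signed finite difference across the moving
step; $\mu^*$ averages absolute effects, $\sigma$ is their standard
deviation. For additive responses every elementary effect of a factor is
identical, so $\sigma = 0$ — exactly so when grid coordinates and optima
are binary-representable (a dyadic grid), and to within $10^{-12}$
otherwise, since a $1/3$-step grid is not exactly representable in
floating point. Plain randomized trajectories are used; optimized
trajectory selection is deliberately out of scope.

The single-flux comparator multiplies one intake capacity at a time by
$(1-\text{fraction})$ and reports the relative growth reduction. Pairing
the 100% and 50% responses (with the 50% column also reported rescaled
by the perturbation size) gives the bisector diagnostic: points off the
bisector are factors whose effect depends on where in the input space
you probe — precisely what a one-shot local perturbation cannot reveal,
and what the interaction gap quantifies globally.

## What the toy generators emulate — and what they do not

The fixtures are built so that every estimator has a closed-form target:

- `make_linear_chain_model(yields)`: independent nutrient pathways, FBA
  optimum $\sum_i y_i |lb_i|$ — purely additive, analytic
  $S_i = S_{T_i} = y_i^2 / \sum_j y_j^2$;
- `make_min_coupled_model()`: 1:1 co-consumption, optimum
  $\min(|lb_A|, |lb_B|)$ — for uniform factors
  $E[\min \mid X_1 = x] = x - x^2/2$ on the unit scale, giving
  $\mathrm{Var}[E] = 1/45$ against $\mathrm{Var}[\min] = 1/18$, hence
  $S_1 = S_2 = 0.4$ and by the two-factor complement
  $S_{T} = 0.6$;
- `make_random_small_model()`: random stoichiometry with zero flux
  always feasible and all bounds finite, sized for the vertex oracle;
- `analytic_test_function()`: additive, pure-interaction
  (centered product) and min responses evaluated without any LP, to
  separate estimator defects from solver defects.

These fixtures reproduce the *mathematical* structure the estimators
must resolve (additivity, Liebig-type coupling, pure interaction), not
the *biological* structure of genome-scale reconstructions: no shared
intermediates, no redundant pathways, no maintenance demands, two or
three orders of magnitude fewer reactions, and no degenerate alternate
optima beyond the trivial. Passing tests therefore certify the
machinery — design, solver, executor, estimators — under known truth;
they do not certify that any particular genome-scale ranking is
biologically meaningful, which depends on the reconstruction and the
medium assumptions fed in.

Validation runs use $N = 1024$ (4096 LP solves per fixture sweep), where
the quasi-random estimates sit well inside the $\pm 0.05$ band around
the analytic indices, and bootstrap tightening is demonstrated between
$N = 256$ and $N = 4096$; these sizes are chosen to make the full suite
a sub-minute affair on a laptop while leaving comfortable margins.

## Known limitations

- Dense simplex: fine to a few hundred reactions, not for Recon-scale
  models — inject a sparse LP backend for those.
- Direction numbers ship for 64 dimensions; larger factor sets need an
  extended table (the generator checks and refuses rather than recycling).
- The process pool relies on `fork()`; on platforms without it the
  serial backend is the fallback.
- Morris confidence intervals resample trajectories; they are reported
  but not calibrated against any external reference.
- Second-order indices use the plain cross-block formula, which is noisy
  for weak interactions; the estimate on the pure-interaction fixture is
  validated at $N = 2048$ with a $\pm 0.1$ band.
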