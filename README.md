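# fluxsens

Global sensitivity analysis of nutrient uptake in constraint-based
metabolic models.

## The problem

Flux balance analysis (FBA) predicts a cell's growth rate as the optimum
of a linear program: maximize the biomass objective **w·v** over flux
distributions **v** satisfying steady-state mass balance **S·v = 0** and
bounds **v_l ≤ v ≤ v_u**. The lower bounds of the exchange reactions set
how fast each nutrient may enter the network (intake has negative sign),
and in genome-scale models those values are largely conventional. Which
of the hundreds of intake capacities actually matter for growth — alone
and through interactions — is a global question that one-at-a-time
perturbation cannot answer.

`fluxsens` treats the intake lower bounds as uncertain factors on a
common interval (default **[-10, 0] mM/h**) and performs variance-based
global sensitivity analysis:

- **Saltelli cross-sampling**: a base-2 Sobol' quasi-random sequence in
  2D dimensions is split into matrices A and B and column-swapped
  hybrids A_B^(i), giving `N(D+2)` parameterizations (`N(2D+2)` when
  second-order indices are requested).
- **Massively repeated FBA**: every design row is an LP solve; a
  deterministic serial/process-pool executor with contiguous chunking
  and checkpoint/resume handles the sweep, and a built-in two-phase
  bounded-variable simplex does the solving.
- **Sobol indices**: the first-order index
  `S_i = Var[E(Y|X_i)] / Var(Y)` (Saltelli 2010 cross-block estimator)
  and the total-effect index `S_Ti = 1 − Var[E(Y|X_~i)] / Var(Y)`
  (Jansen estimator), with bootstrap confidence intervals (100
  row-coupled resamples, 95% by default) and rankings. The gap
  `S_Ti − S_i` isolates interaction effects.
- **Comparators**: Morris elementary-effects screening (μ*, σ over
  one-at-a-time trajectories) and single-flux depletion analysis
  (relative growth reduction at 100% and 50% intake reduction).

Models load from COBRA-style JSON or SBML (Level 3 FBC and the legacy
Level 2 dialect). Toy generators with closed-form sensitivities
(`make_linear_chain_model()`, `make_min_coupled_model()`) make every
estimator testable without external downloads.

## Worked example

The two-nutrient coupled fixture consumes A and B 1:1, so growth is
`min(|lb_A|, |lb_B|)` and the analytic indices are S1 = 0.4, ST = 0.6
per factor (20% of the variance lives in the interaction):

```r
library(fluxsens)
model <- load_model(system.file("extdata", "min_coupled.json",
                                package = "fluxsens"))
run <- run_gsa(model, n = 1024, seed = 1)
print(run)
#> <gsa_run> min_coupled | scheme N(D+2), 4096 rows
#> <sobol_sa> 2 factors, N = 1024 (100 bootstrap resamples, 95% CI)
#> # A tibble: 2 x 8
#>   factor    s1 s1_conf    st st_conf   gap rank_first rank_total
#>   <chr>  <dbl>   <dbl> <dbl>   <dbl> <dbl>      <int>      <int>
#> 1 EX_A   0.397   0.114 0.604  0.0576 0.206          2          2
#> 2 EX_B   0.398   0.115 0.604  0.0626 0.207          1          1
```

Both intakes explain ~40% of the growth variance alone and ~60% in
total; the ~0.2 gap is the coupled (Liebig-type) interaction. The local
comparator shows why a single perturbation can mislead — halving the
non-limiting intake does nothing:

```r
run_perturbation(apply_intake_bounds(model, c("EX_A", "EX_B"),
                                     c(-10, -4)))$table
#> # A tibble: 2 x 5
#>   factor reduction_100 reduction_50 reduction_50_scaled bisector_deviation
#>   <chr>          <dbl>        <dbl>               <dbl>              <dbl>
#> 1 EX_A               1          0                     0                  1
#> 2 EX_B               1          0.5                   1                  0
```

`autoplot()` renders ranked index bars with CI whiskers (`sobol_sa`),
the μ*/σ screening plane (`morris_sa`), and the depletion-vs-half
bisector scatter (`perturbation_run`). A command-line front end for the
same workflows lives at `inst/cli/fluxsens.R`
(subcommands `gsa | morris | perturb | fixtures`).

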