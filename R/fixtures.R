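# Toy model generators with analytically known sensitivity structure.
# These are first-class, tested constructors: every estimator in the package
# can be validated against closed-form Sobol indices without external model
# downloads.

#' Additive linear-chain toy model
#'
#' One nutrient per yield, each imported by its own exchange reaction
#' (bounds `[-10, 0]` mM/h) and consumed by an independent growth reaction
#' contributing `yield[i]` per unit flux to the objective. The FBA optimum
#' is `sum(yields * abs(lower_bounds))`, i.e. perfectly additive in the
#' intake capacities, so under independent uniform factors the analytic
#' Sobol indices are `S_i = S_Ti = yields[i]^2 / sum(yields^2)`.
#'
#' @param yields positive numeric vector, one per nutrient.
#' @return A [metabolic_model()] with `2 * length(yields)` reactions.
#' @export
#' @examples
#' fba(make_linear_chain_model(c(1, 1)))$objective_value  # 20
make_linear_chain_model <- function(yields = c(1, 1)) {
  stopifnot(length(yields) >= 1, all(yields > 0))
  k <- length(yields)
  nutrients <- paste0("N", seq_len(k))
  # columns: EX_1..EX_k then GROW_1..GROW_k
  S <- cbind(-diag(k), -diag(k))
  metabolic_model(
    S,
    lower_bounds = c(rep(-10, k), rep(0, k)),
    upper_bounds = c(rep(0, k), rep(1000, k)),
    objective_coeffs = c(rep(0, k), yields),
    metabolite_ids = nutrients,
    reaction_ids = c(paste0("EX_", nutrients), paste0("GROW_", nutrients)),
    name = sprintf("linear_chain_%d", k)
  )
}

#' Min-coupled two-nutrient toy model
#'
#' Two nutrients A and B imported through exchanges with bounds `[-10, 0]`
#' and consumed 1:1 by a single growth reaction: the FBA optimum is
#' `min(|lb_A|, |lb_B|)` (Liebig-style limitation). Under independent
#' uniform factors on a common interval the analytic indices are
#' `S_1 = S_2 = 0.4` and `S_T1 = S_T2 = 0.6`, making it the canonical
#' interaction fixture: 20% of the output variance is attributable only to
#' the joint action of the two intakes.
#'
#' @return A [metabolic_model()] with 2 metabolites and 3 reactions.
#' @export
make_min_coupled_model <- function() {
  S <- matrix(c(-1, 0,
                0, -1,
                -1, -1), nrow = 2)
  metabolic_model(
    S,
    lower_bounds = c(-10, -10, 0),
    upper_bounds = c(0, 0, 1000),
    objective_coeffs = c(0, 0, 1),
    metabolite_ids = c("A", "B"),
    reaction_ids = c("EX_A", "EX_B", "GROWTH"),
    name = "min_coupled"
  )
}

#' Random small metabolic model
#'
#' Generates a random sparse stoichiometry with all bounds finite and
#' containing zero, so the zero flux vector is always feasible and the
#' optimum is always bounded. Sized for exhaustive vertex-enumeration
#' cross-checks (`r <= 12`).
#'
#' @param m metabolite count (>= 1).
#' @param r reaction count (`m < r <= 12`).
#' @param seed integer seed; identical seeds give identical models.
#' @return A [metabolic_model()].
#' @export
make_random_small_model <- function(m = 4, r = 7, seed = 1) {
  stopifnot(r <= 12, m >= 1, r > m)
  with_seed(seed, {
    repeat {
      S <- matrix(0, m, r)
      for (j in seq_len(r)) {
        nz <- sample(1:min(2L, m), 1)
        S[sample(m, nz), j] <- sample(c(-2, -1, 1, 2), nz, replace = TRUE)
      }
      if (all(rowSums(S != 0) > 0)) break  # no orphan metabolites
    }
    lb <- round(runif(r, -10, 0), 1)
    ub <- round(runif(r, 0, 10), 1)
    w <- numeric(r)
    w[sample(r, 1)] <- 1
    metabolic_model(S, lb, ub, w,
                    name = sprintf("random_small_m%d_r%d_seed%d", m, r, seed))
  })
}

#' Closed-form test responses for estimator validation
#'
#' Analytic functions of the unit-scaled factors used to isolate estimator
#' behaviour from the LP engine (see [evaluate_function()]):
#' * `additive`: `sum(x)` — purely additive, equal first-order shares, zero
#'   interaction.
#' * `centered_product`: `prod(x - 1/2)` — zero main effects, all variance
#'   from the interaction.
#' * `min`: `min(x)` — the coupled-limitation response of
#'   [make_min_coupled_model()].
#'
#' @param which one of `"additive"`, `"centered_product"`, `"min"`.
#' @return A function mapping a numeric vector (one design row, on any
#'   common scale) to a scalar response.
#' @export
analytic_test_function <- function(which = c("additive", "centered_product",
                                             "min")) {
  which <- match.arg(which)
  switch(which,
    additive = function(x) sum(x),
    centered_product = function(x) prod(x - 0.5),
    min = function(x) min(x)
  )
}
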