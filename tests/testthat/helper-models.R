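# Small model builders shared by several test files.

min_coupled_at <- function(lb_a = -10, lb_b = -4) {
  apply_intake_bounds(make_min_coupled_model(), c("EX_A", "EX_B"),
                      c(lb_a, lb_b))
}

# model where intake below 1 unit of nutrient A is infeasible: a
# maintenance reaction consuming A is forced to run at >= 1
maintenance_model <- function() {
  S <- matrix(c(-1, -1, -1), nrow = 1)
  metabolic_model(
    S,
    lower_bounds = c(-10, 1, 0),
    upper_bounds = c(0, 1000, 1000),
    objective_coeffs = c(0, 0, 1),
    metabolite_ids = "A",
    reaction_ids = c("EX_A", "MAINT", "GROWTH"),
    name = "maintenance"
  )
}

# ten-exchange additive fixture for factor-subset tests
ten_exchange_model <- function() {
  make_linear_chain_model(rep(1, 10))
}
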