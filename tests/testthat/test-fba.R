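test_that("FBA recovers the closed-form optima of the toy fixtures", {
  expect_equal(fba(make_linear_chain_model(1))$objective_value, 10)
  expect_equal(fba(make_linear_chain_model(c(1, 1)))$objective_value, 20)
  expect_equal(fba(min_coupled_at(-10, -4))$objective_value, 4)
  expect_equal(fba(min_coupled_at(-6, -3))$objective_value, 3)
})

test_that("optimal results satisfy the FBA contract", {
  tol <- 1e-7
  for (seed in c(2, 7, 11)) {
    mod <- make_random_small_model(m = 3, r = 7, seed = seed)
    res <- fba(mod)
    expect_identical(res$status, "optimal")
    v <- unname(res$fluxes)
    expect_lt(max(abs(as.matrix(mod$S) %*% v)), tol)
    expect_true(all(v >= mod$lower_bounds - tol))
    expect_true(all(v <= mod$upper_bounds + tol))
    expect_equal(res$objective_value, sum(mod$objective_coeffs * v),
                 tolerance = tol)
  }
})

test_that("FBA agrees with brute-force vertex enumeration", {
  for (seed in 1:10) {
    mod <- make_random_small_model(m = 2 + seed %% 3, r = 6 + seed %% 3,
                                   seed = seed)
    expect_equal(fba(mod)$objective_value,
                 vertex_enumeration_optimum(mod),
                 tolerance = 1e-6, label = sprintf("seed %d", seed))
  }
})

test_that("FBA agrees with an independent LP implementation", {
  skip_if_not_installed("pracma")
  for (seed in c(3, 8, 21)) {
    mod <- make_random_small_model(m = 3, r = 8, seed = seed)
    # shift to nonnegative variables for the reference solver
    S <- as.matrix(mod$S)
    lb <- mod$lower_bounds
    ref <- pracma::linprog(
      cc = -mod$objective_coeffs,
      A = diag(ncol(S)), b = mod$upper_bounds - lb,
      Aeq = S, beq = as.vector(-S %*% lb),
      maxiter = 500, bigM = 1e5)
    expect_equal(fba(mod)$objective_value,
                 -ref$fval + sum(mod$objective_coeffs * lb),
                 tolerance = 1e-6)
  }
})

test_that("optimal objective scales with the bounds (LP homogeneity)", {
  mod <- min_coupled_at(-10, -4)
  base <- fba(mod)$objective_value
  for (c_scale in c(0.5, 2, 10)) {
    scaled <- mod
    scaled$lower_bounds <- mod$lower_bounds * c_scale
    scaled$upper_bounds <- mod$upper_bounds * c_scale
    expect_equal(fba(scaled)$objective_value, c_scale * base,
                 tolerance = 1e-9)
  }
})

test_that("tightening an intake bound never increases the optimum", {
  mod <- make_linear_chain_model(c(1, 2))
  prev <- fba(mod)$objective_value
  for (lb in c(-8, -5, -2, 0)) {
    cur <- fba(apply_intake_bounds(mod, "EX_N1", lb))$objective_value
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("models whose bounds all contain zero are never infeasible", {
  for (seed in 4:9) {
    mod <- make_random_small_model(m = 3, r = 6, seed = seed)
    expect_identical(fba(mod)$status, "optimal")
  }
})

test_that("infeasible and unbounded programs return their status", {
  # production forced but nothing consumes: S v = 0 impossible
  inf <- metabolic_model(matrix(1, 1, 1), 1, 2, 1,
                         metabolite_ids = "A", reaction_ids = "r1")
  res <- fba(inf)
  expect_identical(res$status, "infeasible")
  expect_true(is.na(res$objective_value))

  # unconstrained cycle with an objective on it
  cyc <- metabolic_model(matrix(c(1, -1), 1), c(-Inf, -Inf), c(Inf, Inf),
                         c(1, 0), metabolite_ids = "A",
                         reaction_ids = c("r1", "r2"))
  expect_identical(fba(cyc)$status, "unbounded")
})

test_that("a user-supplied solver backend is honoured", {
  canned <- function(model, tol) {
    list(status = "optimal", objective = 42,
         fluxes = rep(0, ncol(model$S)))
  }
  expect_equal(fba(make_min_coupled_model(), backend = canned)$objective_value,
               42)
  expect_error(fba(make_min_coupled_model(), backend = "no_such"),
               class = "fluxsens_configuration_error")
})
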