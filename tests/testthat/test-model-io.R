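test_that("COBRA JSON write/read is the identity on model structure", {
  mod <- make_linear_chain_model(c(1, 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_cobra_json(mod, path)
  back <- load_model(path)
  expect_equal(as.matrix(back$S), as.matrix(mod$S), ignore_attr = TRUE)
  expect_equal(back$lower_bounds, mod$lower_bounds)
  expect_equal(back$upper_bounds, mod$upper_bounds)
  expect_equal(back$objective_coeffs, mod$objective_coeffs)
  expect_equal(back$reaction_ids, mod$reaction_ids)
  expect_equal(back$metabolite_ids, mod$metabolite_ids)

  again <- load_model(path)
  expect_equal(again[names(again) != "S"], back[names(back) != "S"])
  expect_equal(as.matrix(again$S), as.matrix(back$S))
})

test_that("SBML (FBC) and COBRA JSON readers agree on the same model", {
  json <- system.file("extdata", "min_coupled.json", package = "fluxsens")
  xml <- system.file("extdata", "min_coupled_fbc.xml", package = "fluxsens")
  a <- load_model(json)
  b <- load_model(xml)
  expect_equal(as.matrix(a$S), as.matrix(b$S), ignore_attr = TRUE)
  expect_equal(a$lower_bounds, b$lower_bounds)
  expect_equal(a$upper_bounds, b$upper_bounds)
  expect_equal(a$objective_coeffs, b$objective_coeffs)
  expect_equal(fba(b)$objective_value, 10)
})

test_that("invalid models are rejected with informative errors", {
  # bound order violation
  expect_error(
    metabolic_model(matrix(c(-1, 1), 1), lower_bounds = c(5, 0),
                    upper_bounds = c(0, 10), objective_coeffs = c(0, 1),
                    metabolite_ids = "A", reaction_ids = c("r1", "r2")),
    class = "fluxsens_validation_error")
  # a JSON file with inverted bounds fails at load time
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"id":"bad","metabolites":[{"id":"A"}],
    "reactions":[{"id":"r1","metabolites":{"A":-1},
    "lower_bound":5,"upper_bound":0,"objective_coefficient":1}]}', path)
  expect_error(load_model(path), class = "fluxsens_validation_error")
  # missing objective
  path2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"id":"noobj","metabolites":[{"id":"A"}],
    "reactions":[{"id":"r1","metabolites":{"A":-1},
    "lower_bound":-1,"upper_bound":0}]}', path2)
  expect_error(load_model(path2), class = "fluxsens_validation_error")
  # unparseable content
  path3 <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", path3)
  expect_error(load_model(path3), class = "fluxsens_format_error")
  # duplicate reaction ids
  expect_error(
    metabolic_model(matrix(c(-1, -1), 1), c(-1, -1), c(0, 0), c(1, 1),
                    metabolite_ids = "A", reaction_ids = c("r", "r")),
    class = "fluxsens_validation_error")
})

test_that("exchange reactions are detected by column structure", {
  # one boundary column, one internal A->B column
  S <- matrix(c(-1, 0,
                -1, 1), nrow = 2)
  mod <- metabolic_model(S, c(-10, 0), c(0, 10), c(0, 1),
                         metabolite_ids = c("A", "B"),
                         reaction_ids = c("EX_A", "CONV"))
  expect_identical(find_exchange_reactions(mod), 1L)

  # intake_only excludes boundary reactions with lower_bound = 0
  mod2 <- make_min_coupled_model()
  mod2$lower_bounds[2] <- 0
  expect_identical(find_exchange_reactions(mod2), c(1L, 2L))
  expect_identical(find_exchange_reactions(mod2, intake_only = TRUE), 1L)

  # declaration order, both boundary columns of the coupled fixture
  expect_identical(find_exchange_reactions(make_min_coupled_model(),
                                           intake_only = TRUE),
                   c(1L, 2L))

  # id-pattern override
  expect_identical(
    find_exchange_reactions(make_min_coupled_model(),
                            id_pattern = "^EX_"),
    c(1L, 2L))
})

test_that("exchange detection is invariant under metabolite row permutation", {
  mod <- make_linear_chain_model(c(1, 1, 1))
  perm <- c(3, 1, 2)
  mod2 <- metabolic_model(as.matrix(mod$S)[perm, ],
                          mod$lower_bounds, mod$upper_bounds,
                          mod$objective_coeffs,
                          metabolite_ids = mod$metabolite_ids[perm],
                          reaction_ids = mod$reaction_ids)
  expect_identical(find_exchange_reactions(mod2),
                   find_exchange_reactions(mod))
})

test_that("apply_intake_bounds updates only the requested lower bounds", {
  mod <- make_min_coupled_model()
  out <- apply_intake_bounds(mod, "EX_A", -5)
  expect_equal(out$lower_bounds, c(-5, -10, 0))
  expect_equal(out$upper_bounds, mod$upper_bounds)
  expect_equal(mod$lower_bounds, c(-10, -10, 0))  # input untouched

  # identity when values equal existing bounds
  same <- apply_intake_bounds(mod, c("EX_A", "EX_B"), c(-10, -10))
  expect_equal(same, mod)

  # -10 accepted against ub = 0; +1 rejected
  expect_silent(apply_intake_bounds(mod, "EX_A", -10))
  expect_error(apply_intake_bounds(mod, "EX_A", 1),
               class = "fluxsens_bound_error")

  # read-back identity on supplied values
  vals <- c(-3.25, -7.5)
  out2 <- apply_intake_bounds(mod, c(1L, 2L), vals)
  expect_identical(out2$lower_bounds[1:2], vals)
})
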