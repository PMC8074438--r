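# Analytic reference values used below (independent U[0,1] factors):
#   additive f = x1 + x2:            S1 = S2 = 1/2, ST = S1 (no interaction)
#   centered product (x1-.5)(x2-.5): S1 = S2 = 0, ST1 = ST2 = 1
#   min(x1, x2):   E[min | X1 = x] = x - x^2/2, Var of that = 1/45,
#                  Var(min) = 1/18, so S1 = S2 = (1/45)/(1/18) = 0.4
#                  and by two-factor complement ST = 1 - 0.4 = 0.6.

test_that("estimators recover analytic indices of the reference functions", {
  des <- saltelli_design(1024, c("x1", "x2"), bounds = c(0, 1))

  add <- evaluate_function(analytic_test_function("additive"), des)
  expect_equal(unname(estimate_first_order(add, des)), c(0.5, 0.5),
               tolerance = 0.05)
  expect_equal(unname(estimate_total_order(add, des)), c(0.5, 0.5),
               tolerance = 0.05)

  cp <- evaluate_function(analytic_test_function("centered_product"), des)
  expect_equal(unname(estimate_first_order(cp, des)), c(0, 0),
               tolerance = 0.05)
  expect_equal(unname(estimate_total_order(cp, des)), c(1, 1),
               tolerance = 0.05)

  mn <- evaluate_function(analytic_test_function("min"), des)
  expect_equal(unname(estimate_first_order(mn, des)), c(0.4, 0.4),
               tolerance = 0.05)
  expect_equal(unname(estimate_total_order(mn, des)), c(0.6, 0.6),
               tolerance = 0.05)
})

test_that("indices are invariant to the factor scale (bounds [-10,0] vs [0,1])", {
  des <- saltelli_design(512, c("EX_A", "EX_B"), bounds = c(-10, 0))
  mn <- evaluate_function(function(x) min(abs(x)), des)
  expect_equal(unname(estimate_first_order(mn, des)), c(0.4, 0.4),
               tolerance = 0.05)
  expect_equal(unname(estimate_total_order(mn, des)), c(0.6, 0.6),
               tolerance = 0.05)
})

test_that("additive chains put variance shares proportional to yield^2", {
  # optimum = y1|lb1| + y2|lb2| => S_i = y_i^2 / sum(y^2), here 0.2 / 0.8
  mod <- make_linear_chain_model(c(1, 2))
  run <- suppressMessages(run_gsa(mod, n = 512, n_boot = 10, seed = 3))
  expect_within(run$result$S1, c(0.2, 0.8), 0.05)
  expect_within(run$result$ST, c(0.2, 0.8), 0.05)
})

test_that("estimates agree with a double-loop conditional-variance oracle", {
  des <- saltelli_design(1024, c("x1", "x2"), bounds = c(0, 1))
  for (fn in c("additive", "min")) {
    f <- analytic_test_function(fn)
    ev <- evaluate_function(f, des)
    oracle <- double_loop_sobol(f, d = 2, n_outer = 300, n_inner = 300)
    s1 <- unname(estimate_first_order(ev, des))
    st <- unname(estimate_total_order(ev, des))
    expect_true(all(abs(s1 - oracle$S1) < 3 * oracle$S1_se),
                label = paste(fn, "S1 vs oracle"))
    expect_true(all(abs(st - oracle$ST) < 3 * oracle$ST_se),
                label = paste(fn, "ST vs oracle"))
  }
})

test_that("constant output raises a degenerate-output error naming the value", {
  des <- saltelli_design(16, c("a", "b"))
  ev <- evaluate_function(function(x) 7, des)
  expect_error(estimate_first_order(ev, des), "7",
               class = "fluxsens_degenerate_output_error")
})

test_that("misaligned Y is refused", {
  des <- saltelli_design(16, c("a", "b"))
  expect_error(estimate_first_order(evaluation_set(rnorm(10)), des),
               class = "fluxsens_alignment_error")
  expect_error(evaluation_set(c(1, NA)),
               class = "fluxsens_validation_error")
})

test_that("bootstrap CIs are deterministic, shaped, and shrink with N", {
  des <- saltelli_design(256, c("x1", "x2"), bounds = c(0, 1))
  ev <- evaluate_function(analytic_test_function("additive"), des)
  c1 <- bootstrap_confidence(ev, des, n_boot = 50, seed = 11)
  c2 <- bootstrap_confidence(ev, des, n_boot = 50, seed = 11)
  expect_identical(c1, c2)
  expect_length(c1$S1_conf, 2)
  expect_length(c1$ST_conf, 2)
  expect_true(all(c1$S1_conf >= 0 & c1$ST_conf >= 0))

  des_big <- saltelli_design(4096, c("x1", "x2"), bounds = c(0, 1))
  ev_big <- evaluate_function(analytic_test_function("additive"), des_big)
  c_big <- bootstrap_confidence(ev_big, des_big, n_boot = 50, seed = 11)
  expect_lt(mean(c_big$S1_conf) + mean(c_big$ST_conf),
            mean(c1$S1_conf) + mean(c1$ST_conf))
})

test_that("bootstrap does not disturb the caller's RNG stream", {
  des <- saltelli_design(64, c("x1", "x2"), bounds = c(0, 1))
  ev <- evaluate_function(analytic_test_function("additive"), des)
  set.seed(42)
  before <- runif(1)
  set.seed(42)
  invisible(bootstrap_confidence(ev, des, n_boot = 10, seed = 5))
  expect_identical(runif(1), before)
})

test_that("interaction gap separates additive from coupled responses", {
  des <- saltelli_design(1024, c("x1", "x2"), bounds = c(0, 1))
  add <- sobol_indices(
    evaluate_function(analytic_test_function("additive"), des),
    des, n_boot = 20, seed = 1)
  expect_within(interaction_gap(add), 0, 0.05)

  mn <- sobol_indices(
    evaluate_function(analytic_test_function("min"), des),
    des, n_boot = 20, seed = 1)
  expect_within(interaction_gap(mn), 0.2, 0.05)

  cp <- sobol_indices(
    evaluate_function(analytic_test_function("centered_product"), des),
    des, n_boot = 20, seed = 1)
  expect_within(interaction_gap(cp), 1, 0.05)
  # negative gaps are preserved and flagged, never clipped
  gap <- interaction_gap(add)
  expect_identical(as.logical(attr(gap, "negative_flagged")),
                   as.logical(gap < 0))
})

test_that("factor ranking is descending with lexicographic tie-break", {
  res <- structure(list(
    factor_names = c("c", "a", "b"),
    S1 = c(c = 0.1, a = 0.5, b = 0.3),
    ST = c(c = 0.2, a = 0.2, b = 0.2)), class = "sobol_sa")
  expect_identical(rank_factors(res, by = "first"), c("a", "b", "c"))
  expect_identical(rank_factors(res, by = "total"), c("a", "b", "c"))
})

test_that("first-order and total-effect rankings can genuinely differ", {
  # x1 has the only main effect; the x2:x3 interaction dominates totals
  des <- saltelli_design(1024, c("x1", "x2", "x3"), bounds = c(0, 1))
  res <- sobol_indices(evaluate_function(ranking_swap_function, des),
                       des, n_boot = 10, seed = 2)
  expect_identical(res$ranking_first[1], "x1")
  expect_true(res$ranking_total[1] %in% c("x2", "x3"))
})

test_that("second-order design estimates the pair interaction", {
  des <- saltelli_design(2048, c("x1", "x2"), bounds = c(0, 1),
                         second_order = TRUE)
  ev <- evaluate_function(analytic_test_function("centered_product"), des)
  res <- sobol_indices(ev, des, n_boot = 10, seed = 4)
  expect_equal(res$S2["x1", "x2"], 1, tolerance = 0.1)
})

test_that("tidy/glance expose the tabular views", {
  des <- saltelli_design(128, c("x1", "x2"), bounds = c(0, 1))
  res <- sobol_indices(
    evaluate_function(analytic_test_function("additive"), des),
    des, n_boot = 10, seed = 1)
  td <- tidy(res)
  expect_named(td, c("factor", "s1", "s1_conf", "st", "st_conf", "gap",
                     "rank_first", "rank_total"))
  expect_equal(nrow(td), 2)
  expect_setequal(td$rank_total, 1:2)
  gl <- glance(res)
  expect_equal(gl$rows, 128 * 4)
})
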