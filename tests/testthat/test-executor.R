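test_that("partition_design yields balanced contiguous ranges", {
  p <- partition_design(10, 3)
  expect_equal(p$size, c(4, 3, 3))  # remainder goes to earlier workers
  expect_equal(p$start[1], 1)
  expect_equal(p$end[3], 10)
  expect_true(all(p$start[-1] == p$end[-3] + 1))  # disjoint cover

  # genome-scale sweep arithmetic: runs per core and per 16-core node
  p22 <- partition_design(22773760, 256)
  expect_true(all(p22$size == 88960))
  p3d <- partition_design(12787712, 256)
  expect_true(all(p3d$size == 49952))
  expect_equal(sum(partition_design(22773760, 16)$size[1]), 1423360)
})

test_that("max_batch_size follows the memory formula", {
  expect_equal(max_batch_size(8e9, 1000, 8, 1), 1e6)
  expect_equal(max_batch_size(8e9, 1000, 8, 2), 5e5)  # overhead halves it
  expect_error(max_batch_size(100, 1000, 8, 1),
               class = "fluxsens_capacity_error")
})

test_that("serial and process-pool backends agree bitwise", {
  mod <- make_min_coupled_model()
  des <- saltelli_design(16, c("EX_A", "EX_B"))
  ref <- evaluate_design(mod, des, backend = "serial")
  for (w in c(1L, 2L, 4L)) {
    par <- evaluate_design(mod, des, backend = "process_pool",
                           n_workers = w)
    expect_identical(par$Y, ref$Y, label = sprintf("%d workers", w))
    expect_identical(par$n_failed, ref$n_failed)
  }
})

test_that("evaluation follows design row order and the fixture algebra", {
  mod <- make_min_coupled_model()
  des <- saltelli_design(8, c("EX_A", "EX_B"))
  ev <- evaluate_design(mod, des)
  expect_length(ev$Y, nrow(des$matrix))
  # Y[k] must equal min(|lb_A|, |lb_B|) of row k
  expect_equal(ev$Y, apply(abs(des$matrix), 1, min), tolerance = 1e-9)
  # a specific parameterization: bounds (-6, -3) -> growth 3
  des$matrix[1, ] <- c(-6, -3)
  ev2 <- evaluate_design(mod, des)
  expect_equal(ev2$Y[1], 3, tolerance = 1e-9)
})

test_that("failure policy imputes zero and counts, or aborts", {
  mod <- maintenance_model()  # infeasible when intake magnitude < 1
  des <- saltelli_design(8, "EX_A", bounds = c(-10, 0))
  des$matrix[2, 1] <- -0.5  # force one infeasible row
  ev <- evaluate_design(mod, des, failure_policy = "zero")
  expect_equal(ev$Y[2], 0)
  expect_gte(ev$n_failed, 1)
  expect_error(
    evaluate_design(mod, des, failure_policy = "abort"),
    class = "fluxsens_evaluation_error")
})

test_that("a sweep resumes from its progress file without recomputation", {
  mod <- make_min_coupled_model()
  des <- saltelli_design(8, c("EX_A", "EX_B"))
  pf_full <- withr::local_tempfile(fileext = ".tsv")
  ref <- evaluate_design(mod, des, n_workers = 4, progress_file = pf_full)
  expect_true(file.exists(pf_full))

  # keep only the first two completed chunks, as after an interruption
  tab <- read.delim(pf_full)
  pf_part <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab[tab$chunk <= 2, ], pf_part, sep = "\t",
              row.names = FALSE, quote = FALSE)
  resumed <- evaluate_design(mod, des, n_workers = 4,
                             progress_file = pf_part)
  expect_identical(resumed$Y, ref$Y)

  # completed chunks are trusted: resuming against a full progress file
  # does not re-solve (bounds changes are invisible)
  mod2 <- apply_intake_bounds(mod, "EX_A", -1)
  cached <- evaluate_design(mod2, des, n_workers = 4,
                            progress_file = pf_full)
  expect_identical(cached$Y, ref$Y)
})

test_that("analytic function evaluation matches direct application", {
  des <- saltelli_design(8, c("a", "b"), bounds = c(0, 1))
  f <- function(x) x[1]^2 + x[2]
  ev <- evaluate_function(f, des)
  expect_equal(ev$Y, apply(des$matrix, 1, f))
  evv <- evaluate_function(function(X) X[, 1]^2 + X[, 2], des,
                           vectorized = TRUE)
  expect_equal(evv$Y, ev$Y)
})
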