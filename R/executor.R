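# Master-worker evaluation of design rows.
#
# The contract that matters is determinism: Y[k] is the FBA optimum for
# design row k regardless of backend, worker count or completion order, so
# the estimators see bitwise-identical inputs however the sweep was run.
# Distribution is static (contiguous chunks): FBA cost does not depend on
# the bound values, so work-stealing buys nothing.

#' Partition design rows into contiguous worker chunks
#'
#' Sizes differ by at most one; earlier chunks absorb the remainder.
#'
#' @param total_rows total number of design rows.
#' @param n_workers number of chunks (>= 1).
#' @return A tibble with columns `chunk`, `start`, `end`, `size`
#'   (1-based, inclusive).
#' @export
#' @examples
#' partition_design(22773760, 256)$size[1]  # 88960 rows per core
partition_design <- function(total_rows, n_workers) {
  total_rows <- assert_scalar_count(total_rows, "total_rows", min = 0L)
  n_workers <- assert_scalar_count(n_workers, "n_workers")
  base <- total_rows %/% n_workers
  extra <- total_rows %% n_workers
  sizes <- rep(base, n_workers) + c(rep(1L, extra),
                                    rep(0L, n_workers - extra))
  ends <- cumsum(sizes)
  tibble(chunk = seq_len(n_workers),
         start = ends - sizes + 1,
         end = ends,
         size = sizes)
}

#' Memory-aware batch sizing
#'
#' Largest number of design rows a node can hold, given the per-value
#' storage cost and a safety factor for runtime overhead.
#'
#' @param available_memory bytes available on the node.
#' @param d factors per row.
#' @param bytes_per_value storage per matrix entry (default 8, double
#'   precision).
#' @param overhead_factor multiplicative safety margin `>= 1`.
#' @return `floor(available_memory / (d * bytes_per_value *
#'   overhead_factor))`, at least 1; smaller capacities raise an error
#'   reporting the per-row footprint.
#' @export
max_batch_size <- function(available_memory, d, bytes_per_value = 8,
                           overhead_factor = 1) {
  stopifnot(available_memory > 0, d > 0, bytes_per_value > 0,
            overhead_factor >= 1)
  per_row <- d * bytes_per_value * overhead_factor
  size <- floor(available_memory / per_row)
  if (size < 1) {
    abort(sprintf(
      "Node memory (%g bytes) cannot hold a single design row (%g bytes/row).",
      available_memory, per_row), class = "fluxsens_capacity_error")
  }
  size
}

#' Evaluate every design row with FBA
#'
#' For each row the factor reactions' lower bounds are set to the row's
#' values and the FBA optimum recorded. Non-optimal rows (infeasible or
#' unbounded programs) are handled per `failure_policy`: `"zero"` imputes
#' a zero objective — no growth is the natural value for an infeasible
#' growth problem — and counts the row; `"abort"` raises instead.
#'
#' @param model a [metabolic_model()].
#' @param design a [saltelli_design()] (or any object with fields `matrix`
#'   and `factor_names`); factor names must resolve to reactions of
#'   `model`, or be positional when unnamed.
#' @param backend `"serial"` or `"process_pool"` (forked workers via the
#'   parallel package; results are reassembled in row order so both
#'   backends produce bitwise-identical output).
#' @param n_workers worker count for the process pool.
#' @param failure_policy `"zero"` or `"abort"`.
#' @param progress_file optional checkpoint path: completed chunks are
#'   appended as tab-separated `(chunk, row, y, failed)` records, and a
#'   rerun pointing at the same file skips them, so an interrupted sweep
#'   resumes without recomputation.
#' @param tol LP feasibility tolerance, passed to [fba()].
#' @return An [evaluation_set()].
#' @export
#' @examples
#' des <- saltelli_design(8, c("EX_A", "EX_B"))
#' evaluate_design(make_min_coupled_model(), des)
evaluate_design <- function(model, design,
                            backend = c("serial", "process_pool"),
                            n_workers = 1L,
                            failure_policy = c("zero", "abort"),
                            progress_file = NULL,
                            tol = 1e-9) {
  backend <- match.arg(backend)
  failure_policy <- match.arg(failure_policy)
  n_workers <- assert_scalar_count(n_workers, "n_workers")
  validate_metabolic_model(model)

  rows <- design$matrix
  factor_idx <- resolve_reactions(model, design$factor_names)
  total <- nrow(rows)

  n_chunks <- if (backend == "serial") max(1L, n_workers) else n_workers
  parts <- partition_design(total, n_chunks)

  eval_chunk <- function(k) {
    rng <- parts$start[k]:parts$end[k]
    y <- numeric(length(rng))
    failed <- logical(length(rng))
    mod <- model
    for (ii in seq_along(rng)) {
      mod$lower_bounds[factor_idx] <- rows[rng[ii], ]
      res <- fba(mod, tol = tol)
      if (identical(res$status, "optimal")) {
        y[ii] <- res$objective_value
      } else if (failure_policy == "zero") {
        y[ii] <- 0
        failed[ii] <- TRUE
      } else {
        abort(sprintf("FBA %s at design row %d.", res$status, rng[ii]),
              class = "fluxsens_evaluation_error")
      }
    }
    list(chunk = k, y = y, failed = failed)
  }

  done <- read_progress(progress_file, parts)
  todo <- setdiff(parts$chunk, done$chunks)

  results <- vector("list", n_chunks)
  for (k in done$chunks) {
    results[[k]] <- done$records[[k]]
  }
  if (length(todo) > 0) {
    fresh <- if (backend == "process_pool" && n_workers > 1L) {
      out <- parallel::mclapply(todo, eval_chunk, mc.cores = n_workers,
                                mc.preschedule = FALSE)
      bad <- vapply(out, inherits, logical(1), "try-error")
      if (any(bad)) {
        abort("A worker failed; completed chunks are in the progress file.",
              class = "fluxsens_partial_result_error")
      }
      out
    } else {
      lapply(todo, eval_chunk)
    }
    for (res in fresh) {
      results[[res$chunk]] <- res
      append_progress(progress_file, parts, res)
    }
  }

  y <- unlist(lapply(results, `[[`, "y"), use.names = FALSE)
  nf <- sum(unlist(lapply(results, `[[`, "failed"), use.names = FALSE))
  evaluation_set(y, n_failed = nf)
}

read_progress <- function(path, parts) {
  if (is.null(path) || !file.exists(path) || file.size(path) == 0) {
    return(list(chunks = integer(0), records = list()))
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  records <- list()
  complete <- integer(0)
  for (k in unique(tab$chunk)) {
    sub <- tab[tab$chunk == k, ]
    expected <- parts$start[k]:parts$end[k]
    if (identical(sort(sub$row), as.numeric(expected)) ||
        identical(sort(sub$row), expected)) {
      sub <- sub[order(sub$row), ]
      records[[k]] <- list(chunk = k, y = sub$y,
                           failed = as.logical(sub$failed))
      complete <- c(complete, k)
    }
  }
  list(chunks = complete, records = records)
}

append_progress <- function(path, parts, res) {
  if (is.null(path)) return(invisible(NULL))
  k <- res$chunk
  rec <- data.frame(chunk = k, row = parts$start[k]:parts$end[k],
                    y = res$y, failed = res$failed)
  new <- !file.exists(path) || file.size(path) == 0
  suppressWarnings(utils::write.table(
    rec, path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = new, append = !new))
  invisible(NULL)
}

#' Evaluate an analytic response over a design
#'
#' Bypasses the LP engine entirely: applies a closed-form function to each
#' design row. Used to validate the estimators independently of FBA (see
#' [analytic_test_function()]), and for any scalar response of interest.
#'
#' @param f function of one numeric vector (a design row) returning a
#'   scalar, or a vectorized function of the full matrix when
#'   `vectorized = TRUE`.
#' @param design a design object with a `matrix` field.
#' @param unit_scale evaluate on the unit-hypercube coordinates instead of
#'   the factor-scaled ones.
#' @param vectorized is `f` matrix-vectorized?
#' @return An [evaluation_set()].
#' @export
evaluate_function <- function(f, design, unit_scale = FALSE,
                              vectorized = FALSE) {
  X <- if (unit_scale) design$unit_matrix else design$matrix
  y <- if (vectorized) f(X) else apply(X, 1, f)
  evaluation_set(y)
}
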