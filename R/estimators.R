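# Variance-based Sobol index estimation from design-aligned outputs.
#
# Estimator forms are the community defaults for the Saltelli scheme:
#   S_i  = mean(f_B * (f_ABi - f_A)) / V          (Saltelli-2010 cross-block)
#   S_Ti = mean((f_A - f_ABi)^2) / (2 V)          (Jansen)
# with V the variance of Y over the independent A and B blocks. Estimates
# are reported unclipped: small negative values or excursions above 1 are
# legitimate Monte-Carlo noise and are flagged, not hidden.

#' Bundle design-aligned outputs into an evaluation set
#'
#' @param Y numeric vector of model outputs (optimal objective values),
#'   aligned one-to-one with the rows of a design.
#' @param n_failed number of rows whose FBA was non-optimal and whose output
#'   was imputed (see [evaluate_design()]).
#' @return An `evaluation_set`.
#' @export
evaluation_set <- function(Y, n_failed = 0L) {
  Y <- as.numeric(Y)
  if (anyNA(Y) || any(!is.finite(Y))) {
    abort("Evaluation outputs must be finite; impute failed rows first.",
          class = "fluxsens_validation_error")
  }
  structure(list(Y = Y, n_failed = as.integer(n_failed)),
            class = "evaluation_set")
}

#' @export
print.evaluation_set <- function(x, ...) {
  cat(sprintf("<evaluation_set> %d outputs (%d imputed), range [%g, %g]\n",
              length(x$Y), x$n_failed, min(x$Y), max(x$Y)))
  invisible(x)
}

# Split Y into the per-block columns the estimators consume.
split_blocks <- function(Y, design) {
  stopifnot(inherits(design, "saltelli_design"))
  if (inherits(Y, "evaluation_set")) Y <- Y$Y
  if (length(Y) != nrow(design$matrix)) {
    abort(sprintf("Y has length %d but the design has %d rows.",
                  length(Y), nrow(design$matrix)),
          class = "fluxsens_alignment_error")
  }
  bl <- design$row_blocks
  d <- design$d
  list(
    fA = Y[bl == "A"],
    fB = Y[bl == "B"],
    fAB = vapply(seq_len(d), function(i) Y[bl == paste0("AB", i)],
                 numeric(design$n)),
    fBA = if (design$second_order) {
      vapply(seq_len(d), function(i) Y[bl == paste0("BA", i)],
             numeric(design$n))
    } else NULL
  )
}

pop_var <- function(x) mean((x - mean(x))^2)

total_variance <- function(bl) {
  v <- pop_var(c(bl$fA, bl$fB))
  if (v <= .Machine$double.eps * max(1, mean(c(bl$fA, bl$fB))^2)) {
    abort(sprintf(
      "Output has zero variance (constant value %g); sensitivity indices are undefined.",
      bl$fA[1]), class = "fluxsens_degenerate_output_error")
  }
  v
}

first_order_from_blocks <- function(bl, idx = seq_along(bl$fA),
                                    V = NULL) {
  V <- V %||% pop_var(c(bl$fA[idx], bl$fB[idx]))
  colMeans(bl$fB[idx] * (bl$fAB[idx, , drop = FALSE] - bl$fA[idx])) / V
}

total_order_from_blocks <- function(bl, idx = seq_along(bl$fA),
                                    V = NULL) {
  V <- V %||% pop_var(c(bl$fA[idx], bl$fB[idx]))
  colMeans((bl$fA[idx] - bl$fAB[idx, , drop = FALSE])^2) / (2 * V)
}

#' First-order Sobol indices
#'
#' Estimates `S_i = Var[E(Y|X_i)] / Var(Y)`, the fraction of output
#' variance attributable to factor i alone, from a Saltelli-designed
#' evaluation set.
#'
#' @param Y an [evaluation_set()] (or bare numeric vector) aligned with
#'   `design` rows.
#' @param design the [saltelli_design()] that produced `Y`.
#' @return Named numeric vector of D unclipped first-order indices.
#' @export
estimate_first_order <- function(Y, design) {
  bl <- split_blocks(Y, design)
  setNames(first_order_from_blocks(bl, V = total_variance(bl)),
           design$factor_names)
}

#' Total-effect Sobol indices
#'
#' Estimates `S_Ti = 1 - Var[E(Y|X_~i)] / Var(Y)`, the fraction of output
#' variance involving factor i through any order of interaction (Jansen
#' estimator).
#'
#' @inheritParams estimate_first_order
#' @return Named numeric vector of D unclipped total-effect indices.
#' @export
estimate_total_order <- function(Y, design) {
  bl <- split_blocks(Y, design)
  setNames(total_order_from_blocks(bl, V = total_variance(bl)),
           design$factor_names)
}

second_order_from_blocks <- function(bl, S1, V) {
  d <- ncol(bl$fAB)
  S2 <- matrix(NA_real_, d, d)
  for (i in seq_len(d - 1)) {
    for (j in (i + 1):d) {
      Vij <- mean(bl$fBA[, i] * bl$fAB[, j] - bl$fA * bl$fB) / V
      S2[i, j] <- S2[j, i] <- Vij - S1[i] - S1[j]
    }
  }
  S2
}

#' Bootstrap confidence intervals for Sobol indices
#'
#' Resamples the N base samples with replacement, keeping each base
#' sample's A, B and hybrid rows together (row-coupled resampling — the
#' cross-block pairing is what the estimators difference, so rows cannot be
#' resampled independently), recomputes both indices per resample, and
#' returns normal-approximation half-widths at the requested level.
#'
#' @inheritParams estimate_first_order
#' @param n_boot number of bootstrap resamples (default 100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed making the resampling deterministic.
#' @return List with numeric vectors `S1_conf` and `ST_conf` (length D,
#'   half-widths >= 0).
#' @export
bootstrap_confidence <- function(Y, design, n_boot = 100, level = 0.95,
                                 seed = NULL) {
  n_boot <- assert_scalar_count(n_boot, "n_boot", min = 2L)
  bl <- split_blocks(Y, design)
  total_variance(bl)  # fail early on degenerate output
  n <- design$n
  z <- qnorm(0.5 + level / 2)
  with_seed(seed, {
    s1 <- matrix(NA_real_, n_boot, design$d)
    st <- matrix(NA_real_, n_boot, design$d)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      s1[b, ] <- first_order_from_blocks(bl, idx)
      st[b, ] <- total_order_from_blocks(bl, idx)
    }
    list(S1_conf = z * apply(s1, 2, sd),
         ST_conf = z * apply(st, 2, sd))
  })
}

#' Full Sobol sensitivity analysis of an evaluation set
#'
#' Combines the first-order and total-effect estimators, bootstrap
#' confidence intervals, optional second-order indices, and factor rankings
#' into one result object.
#'
#' @inheritParams bootstrap_confidence
#' @return A `sobol_sa` object; see [tidy.sobol_sa()] for the tabular view.
#' @export
#' @examples
#' des <- saltelli_design(256, c("x1", "x2"), bounds = c(0, 1))
#' ev <- evaluate_function(analytic_test_function("additive"), des)
#' sobol_indices(ev, des, seed = 1)
sobol_indices <- function(Y, design, n_boot = 100, level = 0.95,
                          seed = NULL) {
  bl <- split_blocks(Y, design)
  V <- total_variance(bl)
  S1 <- setNames(first_order_from_blocks(bl, V = V), design$factor_names)
  ST <- setNames(total_order_from_blocks(bl, V = V), design$factor_names)
  conf <- bootstrap_confidence(Y, design, n_boot = n_boot, level = level,
                               seed = seed)
  S2 <- if (design$second_order && design$d >= 2) {
    structure(second_order_from_blocks(bl, S1, V),
              dimnames = list(design$factor_names, design$factor_names))
  } else NULL
  res <- structure(
    list(
      factor_names = design$factor_names,
      S1 = S1, S1_conf = setNames(conf$S1_conf, design$factor_names),
      ST = ST, ST_conf = setNames(conf$ST_conf, design$factor_names),
      S2 = S2,
      variance = V,
      n = design$n, d = design$d, second_order = design$second_order,
      n_boot = n_boot, level = level, seed = seed,
      n_failed = if (inherits(Y, "evaluation_set")) Y$n_failed else 0L
    ),
    class = "sobol_sa")
  res$ranking_total <- rank_factors(res, by = "total")
  res$ranking_first <- rank_factors(res, by = "first")
  # flag excursions beyond [0,1] larger than the CI half-width
  out_of_range <- (res$S1 < -res$S1_conf) | (res$S1 > 1 + res$S1_conf) |
    (res$ST < -res$ST_conf) | (res$ST > 1 + res$ST_conf)
  if (any(out_of_range)) {
    warn(sprintf(
      "Indices outside [0, 1] by more than their CI half-width for: %s.",
      paste(res$factor_names[out_of_range], collapse = ", ")))
  }
  res
}

#' Interaction gap S_Ti - S_i
#'
#' The elementwise difference between total-effect and first-order index: a
#' near-zero gap means the output responds (nearly) additively to the
#' factor, while a large gap indicates variance carried by interactions
#' with other factors. Negative gaps can arise from Monte-Carlo noise and
#' are preserved, with an attribute flagging them.
#'
#' @param result a `sobol_sa` object.
#' @return Named numeric vector of gaps with attribute
#'   `"negative_flagged"` (logical vector).
#' @export
interaction_gap <- function(result) {
  stopifnot(inherits(result, "sobol_sa"))
  gap <- result$ST - result$S1
  attr(gap, "negative_flagged") <- gap < 0
  gap
}

#' Rank factors by sensitivity index
#'
#' @param result a `sobol_sa` object.
#' @param by rank by `"total"` (default) or `"first"` order index.
#' @return Character vector of factor names, descending by the chosen
#'   index; ties broken lexicographically for reproducibility.
#' @export
rank_factors <- function(result, by = c("total", "first")) {
  stopifnot(inherits(result, "sobol_sa"))
  by <- match.arg(by)
  vals <- if (by == "total") result$ST else result$S1
  result$factor_names[order(-vals, result$factor_names)]
}

#' @export
print.sobol_sa <- function(x, ...) {
  cat(sprintf(
    "<sobol_sa> %d factors, N = %d (%d bootstrap resamples, %g%% CI)\n",
    x$d, x$n, x$n_boot, 100 * x$level))
  if (x$n_failed > 0) cat(sprintf("  %d imputed evaluations\n", x$n_failed))
  print(tidy(x), n = min(x$d, 10))
  invisible(x)
}

#' Tidy a Sobol sensitivity result
#'
#' @param x a `sobol_sa` object.
#' @param ... unused.
#' @return A tibble with one row per factor: `factor`, `s1`, `s1_conf`,
#'   `st`, `st_conf`, `gap` (= st - s1), `rank_first`, `rank_total`.
#' @export
tidy.sobol_sa <- function(x, ...) {
  tibble(
    factor = x$factor_names,
    s1 = unname(x$S1),
    s1_conf = unname(x$S1_conf),
    st = unname(x$ST),
    st_conf = unname(x$ST_conf),
    gap = unname(x$ST - x$S1),
    rank_first = match(x$factor_names, x$ranking_first),
    rank_total = match(x$factor_names, x$ranking_total)
  )
}

#' @export
glance.sobol_sa <- function(x, ...) {
  tibble(n = x$n, d = x$d, rows = nrow_design(x),
         variance = x$variance, n_boot = x$n_boot, level = x$level,
         n_failed = x$n_failed, top_factor = x$ranking_total[1])
}

nrow_design <- function(x) {
  design_row_count(x$n, x$d, isTRUE(x$second_order))
}
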