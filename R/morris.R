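# Morris elementary-effects screening: the one-at-a-time comparator to the
# variance-based indices. Plain randomized trajectories on a p-level grid
# (no optimized trajectory selection): each trajectory moves every factor
# exactly once by +/- delta on the unit scale.

#' Generate Morris one-at-a-time trajectories
#'
#' Each trajectory starts at a random point of the `levels`-level grid and
#' takes D unit-scale steps of magnitude `delta`, one per factor in random
#' order with random sign, so consecutive rows differ in exactly one
#' coordinate. With the conventional `levels = 4`, `delta = 2/3` the grid
#' and steps cover the input space evenly.
#'
#' @param r number of trajectories.
#' @param factor_names character vector of D factor identifiers.
#' @param levels even number of grid levels per factor (default 4).
#' @param delta step size on the unit scale; default `levels / (2 *
#'   (levels - 1))`, the standard choice.
#' @param bounds per-factor `(low, high)` pairs as in [saltelli_design()].
#' @param seed integer seed; trajectories are deterministic given it.
#' @return A `morris_design` with fields `matrix` (`r * (D+1)` rows on the
#'   factor scale), `unit_matrix`, `trajectories` (per-trajectory factor
#'   order and step signs), `delta`, `levels`.
#' @export
#' @examples
#' morris_trajectories(4, c("EX_A", "EX_B"), seed = 1)
morris_trajectories <- function(r, factor_names, levels = 4,
                                delta = levels / (2 * (levels - 1)),
                                bounds = c(-10, 0), seed = NULL) {
  r <- assert_scalar_count(r, "r")
  levels <- assert_scalar_count(levels, "levels", min = 2L)
  if (levels %% 2 != 0) {
    abort("`levels` must be even.", class = "fluxsens_argument_error")
  }
  factor_names <- as.character(factor_names)
  d <- length(factor_names)
  bounds <- normalize_bounds(bounds, d)
  grid_step <- 1 / (levels - 1)
  if (abs(delta / grid_step - round(delta / grid_step)) > 1e-9) {
    abort("`delta` must be a multiple of 1/(levels - 1).",
          class = "fluxsens_argument_error")
  }
  # base coordinates from which a +delta move stays inside [0, 1]
  base_levels <- seq(0, 1 - delta + 1e-12, by = grid_step)

  with_seed(seed, {
    rows <- matrix(NA_real_, r * (d + 1), d)
    traj <- vector("list", r)
    for (t in seq_len(r)) {
      base <- base_levels[sample.int(length(base_levels), d,
                                     replace = TRUE)]
      signs <- sample(c(-1, 1), d, replace = TRUE)
      order_moved <- sample.int(d)
      # a factor moving downward starts at base + delta
      current <- base + delta * (signs < 0)
      off <- (t - 1) * (d + 1)
      rows[off + 1, ] <- current
      for (s in seq_len(d)) {
        i <- order_moved[s]
        current[i] <- current[i] + signs[i] * delta
        rows[off + 1 + s, ] <- current
      }
      traj[[t]] <- list(order = order_moved, signs = signs)
    }
    structure(
      list(factor_names = factor_names, bounds = bounds,
           r = r, d = d, levels = levels, delta = delta, seed = seed,
           unit_matrix = rows,
           matrix = scale_to_bounds(rows, bounds),
           trajectories = traj),
      class = "morris_design")
  })
}

#' @export
print.morris_design <- function(x, ...) {
  cat(sprintf(
    "<morris_design> %d trajectories x %d factors: %d rows (levels = %d, delta = %g)\n",
    x$r, x$d, nrow(x$matrix), x$levels, x$delta))
  invisible(x)
}

#' Elementary effects from trajectory outputs
#'
#' The elementary effect of factor i within a trajectory is the signed
#' finite difference `(Y_after - Y_before) / (sign * delta)` across the
#' step that moved that factor, on the unit scale. `mu_star` (mean of
#' absolute effects across trajectories) measures overall influence;
#' `sigma` (their standard deviation) measures nonlinearity and/or
#' interaction with other factors.
#'
#' @param Y numeric vector (or [evaluation_set()]) aligned with the rows
#'   of `design`.
#' @param design a `morris_design` from [morris_trajectories()].
#' @return A `morris_sa` object with fields `mu_star`, `sigma`, `effects`
#'   (the r x D matrix of elementary effects) and `n_trajectories`.
#' @export
elementary_effects <- function(Y, design) {
  stopifnot(inherits(design, "morris_design"))
  if (inherits(Y, "evaluation_set")) Y <- Y$Y
  if (length(Y) != nrow(design$matrix)) {
    abort(sprintf("Y has length %d but the design has %d rows.",
                  length(Y), nrow(design$matrix)),
          class = "fluxsens_alignment_error")
  }
  d <- design$d
  ee <- matrix(NA_real_, design$r, d)
  for (t in seq_len(design$r)) {
    off <- (t - 1) * (d + 1)
    tr <- design$trajectories[[t]]
    for (s in seq_len(d)) {
      i <- tr$order[s]
      dy <- Y[off + 1 + s] - Y[off + s]
      ee[t, i] <- dy / (tr$signs[i] * design$delta)
    }
  }
  structure(
    list(factor_names = design$factor_names,
         mu_star = setNames(colMeans(abs(ee)), design$factor_names),
         sigma = setNames(apply(ee, 2, sd), design$factor_names),
         effects = ee,
         n_trajectories = design$r,
         levels = design$levels, delta = design$delta),
    class = "morris_sa")
}

#' @export
print.morris_sa <- function(x, ...) {
  cat(sprintf("<morris_sa> %d factors, %d trajectories\n",
              length(x$factor_names), x$n_trajectories))
  print(tidy(x), n = min(length(x$factor_names), 10))
  invisible(x)
}

#' Tidy a Morris screening result
#'
#' @param x a `morris_sa` object.
#' @param ... unused.
#' @return A tibble with columns `factor`, `mu_star`, `sigma`, ordered as
#'   the factors were declared.
#' @export
tidy.morris_sa <- function(x, ...) {
  tibble(factor = x$factor_names,
         mu_star = unname(x$mu_star),
         sigma = unname(x$sigma))
}

#' @export
glance.morris_sa <- function(x, ...) {
  tibble(d = length(x$factor_names), n_trajectories = x$n_trajectories,
         levels = x$levels, delta = x$delta,
         top_factor = x$factor_names[which.max(x$mu_star)])
}

#' Bootstrap confidence intervals for Morris statistics
#'
#' Resamples whole trajectories with replacement and recomputes `mu_star`
#' and `sigma`, giving normal-approximation half-widths.
#'
#' @param result a `morris_sa` object.
#' @param n_boot number of resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return List with vectors `mu_star_conf` and `sigma_conf`.
#' @export
morris_confidence <- function(result, n_boot = 100, level = 0.95,
                              seed = NULL) {
  stopifnot(inherits(result, "morris_sa"))
  n_boot <- assert_scalar_count(n_boot, "n_boot", min = 2L)
  r <- result$n_trajectories
  z <- qnorm(0.5 + level / 2)
  with_seed(seed, {
    mu <- matrix(NA_real_, n_boot, ncol(result$effects))
    sg <- matrix(NA_real_, n_boot, ncol(result$effects))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(r, r, replace = TRUE)
      sub <- result$effects[idx, , drop = FALSE]
      mu[b, ] <- colMeans(abs(sub))
      sg[b, ] <- apply(sub, 2, sd)
    }
    list(mu_star_conf = z * apply(mu, 2, sd),
         sigma_conf = z * apply(sg, 2, sd))
  })
}
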