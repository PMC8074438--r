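# Single-exchange-flux perturbation: the naive local comparator to the
# global analysis. One factor at a time, its admitted intake (the magnitude
# of the exchange lower bound) is reduced multiplicatively while everything
# else stays at baseline, and the relative drop of the optimal objective is
# recorded.

#' Relative growth reduction under single-flux intake reduction
#'
#' For each factor independently, scales the intake capacity toward zero —
#' `fraction = 1` closes the intake entirely (total depletion),
#' `fraction = 0.5` halves it — re-solves FBA, and reports
#' `(f0 - f_pert) / f0` against the baseline optimum `f0`. Because
#' tightening a bound can only shrink the feasible region, reductions lie
#' in `[0, 1]` whenever the baseline optimum is positive.
#'
#' @param model a [metabolic_model()]; the baseline is the model as given.
#' @param factor_indices reaction indices or ids to perturb (default: all
#'   intake-capable exchanges).
#' @param fraction intake reduction fraction in `[0, 1]`.
#' @param tol LP tolerance passed to [fba()].
#' @return A tibble with columns `factor`, `fraction`, `reduction`.
#' @export
#' @examples
#' mod <- apply_intake_bounds(make_min_coupled_model(),
#'                            c("EX_A", "EX_B"), c(-10, -4))
#' single_flux_perturbation(mod, fraction = 1)
single_flux_perturbation <- function(model, factor_indices = NULL,
                                     fraction = 1, tol = 1e-9) {
  validate_metabolic_model(model)
  stopifnot(is.numeric(fraction), length(fraction) == 1,
            fraction >= 0, fraction <= 1)
  idx <- if (is.null(factor_indices)) {
    find_exchange_reactions(model, intake_only = TRUE)
  } else {
    resolve_reactions(model, factor_indices)
  }
  base <- fba(model, tol = tol)
  if (!identical(base$status, "optimal") || base$objective_value <= 0) {
    abort(sprintf(
      "Baseline FBA is %s with objective %s; relative reductions are undefined.",
      base$status, format(base$objective_value)),
      class = "fluxsens_baseline_degenerate_error")
  }
  f0 <- base$objective_value
  reduction <- vapply(idx, function(j) {
    mod <- model
    mod$lower_bounds[j] <- model$lower_bounds[j] * (1 - fraction)
    res <- fba(mod, tol = tol)
    fp <- if (identical(res$status, "optimal")) res$objective_value else 0
    (f0 - fp) / f0
  }, numeric(1))
  tibble(factor = model$reaction_ids[idx],
         fraction = fraction,
         reduction = reduction)
}

#' Total-depletion versus half-reduction response pairs
#'
#' Runs [single_flux_perturbation()] at 100% and at 50% intake reduction
#' and pairs the results per factor. If a factor's effect on growth were
#' region-invariant (linear in the perturbation size), the 50% response
#' would be exactly half the 100% one and, after rescaling the 50% column
#' by the perturbation size, every point would lie on the bisector of the
#' scatter; the `bisector_deviation` column measures the departure
#' `|reduction_100 - reduction_50_scaled|`. `reduction_50_scaled` is
#' `reduction_50 / 0.5` — both the raw and rescaled columns are reported.
#'
#' @inheritParams single_flux_perturbation
#' @return A tibble with columns `factor`, `reduction_100`,
#'   `reduction_50`, `reduction_50_scaled`, `bisector_deviation`.
#' @export
depletion_vs_half_pairs <- function(model, factor_indices = NULL,
                                    tol = 1e-9) {
  full <- single_flux_perturbation(model, factor_indices, fraction = 1,
                                   tol = tol)
  half <- single_flux_perturbation(model, factor_indices, fraction = 0.5,
                                   tol = tol)
  tibble(
    factor = full$factor,
    reduction_100 = full$reduction,
    reduction_50 = half$reduction,
    reduction_50_scaled = half$reduction / 0.5,
    bisector_deviation = abs(full$reduction - half$reduction / 0.5)
  )
}
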