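#' Solve the flux balance analysis linear program
#'
#' FBA finds a steady-state flux distribution maximizing the linear
#' objective `w·v` (typically biomass production) subject to mass balance
#' `S·v = 0` and the flux bounds `v_l <= v <= v_u`. Alternate optimal flux
#' distributions are not resolved: only the optimal objective value is
#' unique and it is the quantity the sensitivity analysis consumes.
#'
#' @param model a [metabolic_model()].
#' @param tol nonnegative feasibility tolerance for constraint residuals
#'   (default `1e-9`).
#' @param backend LP backend: the name of a registered backend (only
#'   `"simplex"`, the built-in bounded-variable simplex, is shipped) or a
#'   function `(model, tol) -> list(status, objective, fluxes)` implementing
#'   the same contract, so an external solver can be injected without
#'   touching the engine.
#' @return An object of class `fba_result` with fields `status` (one of
#'   `"optimal"`, `"infeasible"`, `"unbounded"`), `objective_value` and
#'   `fluxes` (both `NA` unless optimal).
#' @export
#' @examples
#' fba(make_min_coupled_model())$objective_value  # 4: B is limiting
fba <- function(model, tol = 1e-9, backend = "simplex") {
  validate_metabolic_model(model)
  stopifnot(is.numeric(tol), tol >= 0)
  solver <- if (is.function(backend)) {
    backend
  } else {
    switch(as.character(backend),
      simplex = fba_backend_simplex,
      abort(sprintf("Unknown LP backend '%s'.", backend),
            class = "fluxsens_configuration_error")
    )
  }
  res <- solver(model, tol)
  structure(
    list(status = res$status,
         objective_value = res$objective,
         fluxes = if (identical(res$status, "optimal")) {
           setNames(res$fluxes, model$reaction_ids)
         } else NULL),
    class = "fba_result")
}

fba_backend_simplex <- function(model, tol) {
  simplex_solve(
    A = as.matrix(model$S),
    b = rep(0, nrow(model$S)),
    cc = model$objective_coeffs,
    lo = model$lower_bounds,
    hi = model$upper_bounds,
    tol = max(tol, 1e-12)
  )
}

#' @export
print.fba_result <- function(x, ...) {
  cat(sprintf("<fba_result> status: %s", x$status))
  if (identical(x$status, "optimal")) {
    cat(sprintf(", objective: %g", x$objective_value))
  }
  cat("\n")
  invisible(x)
}

#' @export
glance.fba_result <- function(x, ...) {
  tibble(status = x$status, objective_value = x$objective_value)
}

#' @export
tidy.fba_result <- function(x, ...) {
  if (!identical(x$status, "optimal")) {
    return(tibble(reaction = character(), flux = numeric()))
  }
  tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}
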