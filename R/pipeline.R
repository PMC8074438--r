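# End-to-end workflows: config -> factor selection -> design -> FBA sweep
# -> indices -> ranked report. Each run returns its result object plus a
# machine-readable manifest echoing every defaulted decision, and optionally
# writes tab-separated tables to an output directory.

resolve_factors <- function(model, factors) {
  if (is.null(factors) || identical(factors, "all-intake")) {
    idx <- find_exchange_reactions(model, intake_only = TRUE)
    if (length(idx) == 0) {
      abort("Model has no intake-capable exchange reactions.",
            class = "fluxsens_configuration_error")
    }
    return(idx)
  }
  resolve_reactions(model, factors)
}

load_model_arg <- function(model, format = "auto") {
  if (inherits(model, "metabolic_model")) return(model)
  load_model(model, format = format)
}

write_tsv <- function(df, dir, file) {
  if (is.null(dir)) return(invisible(NULL))
  suppressWarnings(utils::write.table(
    df, file.path(dir, file), sep = "\t", quote = FALSE,
    row.names = FALSE))
  invisible(NULL)
}

#' Run a full variance-based sensitivity analysis
#'
#' The three-phase workflow: (1) build the Saltelli design over the chosen
#' intake factors, (2) evaluate the FBA optimum for every parameterization,
#' (3) estimate Sobol indices with bootstrap confidence intervals and rank
#' the factors. Every defaulted choice (skip policy, failure policy,
#' estimators, backend) is echoed into the returned manifest so a run is
#' auditable and exactly repeatable.
#'
#' @param model a [metabolic_model()] or a path to a model file.
#' @param factors `"all-intake"` (default: every intake-capable exchange
#'   reaction), or reaction ids/indices.
#' @param interval perturbation interval for the intake lower bounds,
#'   default `c(-10, 0)` mM/h.
#' @param n base sample count N; the sweep evaluates `N(D+2)` rows
#'   (`N(2D+2)` with `second_order`).
#' @param second_order estimate second-order indices too.
#' @param backend,n_workers,failure_policy,progress_file passed to
#'   [evaluate_design()].
#' @param n_boot,level bootstrap resamples and confidence level.
#' @param seed integer seed for the bootstrap (the design itself is
#'   deterministic given `skip`).
#' @param skip leading Sobol'-sequence points to drop (see
#'   [saltelli_design()]).
#' @param format model file format for path input.
#' @param out_dir optional directory; when given, writes
#'   `sensitivity_indices.tsv`, `interaction_gaps.tsv`, `design.tsv` and
#'   `manifest.txt` into it.
#' @return A list of class `gsa_run`: `result` (a `sobol_sa`), `design`,
#'   `evaluation`, `manifest` (named list).
#' @export
#' @examples
#' run <- run_gsa(make_min_coupled_model(), n = 128, seed = 1)
#' tidy(run$result)
run_gsa <- function(model, factors = "all-intake", interval = c(-10, 0),
                    n = 1024, second_order = FALSE,
                    backend = "serial", n_workers = 1L,
                    failure_policy = "zero", progress_file = NULL,
                    n_boot = 100, level = 0.95, seed = NULL, skip = 1,
                    format = "auto", out_dir = NULL) {
  n <- assert_scalar_count(n, "n", min = 2L)
  model <- load_model_arg(model, format)
  idx <- resolve_factors(model, factors)
  factor_names <- model$reaction_ids[idx]
  d <- length(idx)

  inform(sprintf("[design] N = %d, D = %d: %g rows", n, d,
                 design_row_count(n, d, second_order)))
  design <- saltelli_design(n, factor_names, bounds = interval,
                            second_order = second_order, skip = skip)
  inform(sprintf("[evaluate] backend = %s, workers = %d", backend,
                 n_workers))
  ev <- evaluate_design(model, design, backend = backend,
                        n_workers = n_workers,
                        failure_policy = failure_policy,
                        progress_file = progress_file)
  inform(sprintf("[collect] %d evaluated, %d imputed", length(ev$Y),
                 ev$n_failed))
  result <- sobol_indices(ev, design, n_boot = n_boot, level = level,
                          seed = seed)

  manifest <- list(
    model = model$name, n = n, d = d,
    scheme = if (second_order) "N(2D+2)" else "N(D+2)",
    rows = design_row_count(n, d, second_order),
    rows_evaluated = length(ev$Y), rows_imputed = ev$n_failed,
    interval_low = interval[1], interval_high = interval[2],
    factors = paste(factor_names, collapse = ","),
    sequence = "sobol", skip = skip,
    estimator_first = "saltelli2010", estimator_total = "jansen",
    n_boot = n_boot, level = level,
    seed = if (is.null(seed)) NA else seed,
    solver = "simplex", backend = backend, n_workers = n_workers,
    failure_policy = failure_policy)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(tidy(result), out_dir, "sensitivity_indices.tsv")
    gaps <- interaction_gap(result)
    write_tsv(tibble(factor = names(gaps), gap = as.numeric(gaps),
                     negative_flagged = attr(gaps, "negative_flagged")),
              out_dir, "interaction_gaps.tsv")
    write_design(design, file.path(out_dir, "design.tsv"))
    writeLines(paste(names(manifest), unlist(manifest), sep = "\t"),
               file.path(out_dir, "manifest.txt"))
  }
  structure(list(result = result, design = design, evaluation = ev,
                 manifest = manifest),
            class = "gsa_run")
}

#' @export
print.gsa_run <- function(x, ...) {
  cat(sprintf("<gsa_run> %s | scheme %s, %g rows\n", x$manifest$model,
              x$manifest$scheme, x$manifest$rows))
  print(x$result)
  invisible(x)
}

#' Run Morris elementary-effects screening on a model
#'
#' @inheritParams run_gsa
#' @param r number of trajectories (evaluates `r (D+1)` rows).
#' @param levels,delta grid geometry, see [morris_trajectories()].
#' @return A list of class `morris_run`: `result` (a `morris_sa`),
#'   `design`, `evaluation`, `confidence`, `manifest`.
#' @export
run_morris <- function(model, factors = "all-intake", interval = c(-10, 0),
                       r = 64, levels = 4,
                       delta = levels / (2 * (levels - 1)),
                       backend = "serial", n_workers = 1L,
                       failure_policy = "zero",
                       n_boot = 100, level = 0.95, seed = NULL,
                       format = "auto", out_dir = NULL) {
  model <- load_model_arg(model, format)
  idx <- resolve_factors(model, factors)
  factor_names <- model$reaction_ids[idx]
  design <- morris_trajectories(r, factor_names, levels = levels,
                                delta = delta, bounds = interval,
                                seed = seed)
  ev <- evaluate_design(model, design, backend = backend,
                        n_workers = n_workers,
                        failure_policy = failure_policy)
  result <- elementary_effects(ev, design)
  conf <- morris_confidence(result, n_boot = n_boot, level = level,
                            seed = seed)
  manifest <- list(model = model$name, method = "morris",
                   r = r, d = length(idx), rows = r * (length(idx) + 1),
                   levels = levels, delta = delta,
                   interval_low = interval[1], interval_high = interval[2],
                   seed = if (is.null(seed)) NA else seed,
                   backend = backend, n_workers = n_workers)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- tidy(result)
    out$mu_star_conf <- conf$mu_star_conf
    out$sigma_conf <- conf$sigma_conf
    write_tsv(out, out_dir, "morris_indices.tsv")
    writeLines(paste(names(manifest), unlist(manifest), sep = "\t"),
               file.path(out_dir, "manifest.txt"))
  }
  structure(list(result = result, design = design, evaluation = ev,
                 confidence = conf, manifest = manifest),
            class = "morris_run")
}

#' Run the single-flux perturbation analysis
#'
#' @inheritParams run_gsa
#' @return A list of class `perturbation_run`: `table` (the
#'   [depletion_vs_half_pairs()] tibble), `manifest`.
#' @export
run_perturbation <- function(model, factors = "all-intake",
                             format = "auto", out_dir = NULL) {
  model <- load_model_arg(model, format)
  idx <- resolve_factors(model, factors)
  tab <- depletion_vs_half_pairs(model, idx)
  manifest <- list(model = model$name, method = "single_flux_perturbation",
                   d = length(idx), fractions = "1,0.5")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(tab, out_dir, "perturbation.tsv")
    writeLines(paste(names(manifest), unlist(manifest), sep = "\t"),
               file.path(out_dir, "manifest.txt"))
  }
  structure(list(table = tab, manifest = manifest),
            class = "perturbation_run")
}
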