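#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` bundles the ingredients of a flux balance analysis
#' (FBA) problem: the stoichiometric matrix `S` (metabolites in rows,
#' reactions in columns), per-reaction flux bounds, and the linear objective
#' (typically the biomass pseudo-reaction). Fluxes are conventionally in
#' mM/h; units are carried as an opaque label and never converted.
#'
#' @param S numeric matrix or `Matrix` sparse matrix, m metabolites x
#'   r reactions.
#' @param lower_bounds,upper_bounds numeric vectors of length r, flux bounds
#'   with `lower_bounds <= upper_bounds` elementwise. Negative lower bounds
#'   on exchange reactions denote intake capacity.
#' @param objective_coeffs numeric vector of length r with at least one
#'   nonzero entry; FBA maximizes `sum(objective_coeffs * v)`.
#' @param metabolite_ids,reaction_ids unique character identifiers; defaults
#'   are generated when omitted.
#' @param name free-text model name.
#' @param units flux unit label (default `"mM/h"`); informational only.
#'
#' @return An object of class `metabolic_model`.
#' @seealso [load_model()], [find_exchange_reactions()],
#'   [apply_intake_bounds()], [fba()]
#' @export
#' @examples
#' mod <- make_min_coupled_model()
#' mod
metabolic_model <- function(S, lower_bounds, upper_bounds, objective_coeffs,
                            metabolite_ids = NULL, reaction_ids = NULL,
                            name = "model", units = "mM/h") {
  S <- Matrix::Matrix(S, sparse = TRUE)
  m <- nrow(S)
  r <- ncol(S)
  metabolite_ids <- metabolite_ids %||% paste0("m", seq_len(m))
  reaction_ids <- reaction_ids %||% paste0("r", seq_len(r))
  model <- structure(
    list(
      metabolite_ids = as.character(metabolite_ids),
      reaction_ids = as.character(reaction_ids),
      S = S,
      lower_bounds = as.numeric(lower_bounds),
      upper_bounds = as.numeric(upper_bounds),
      objective_coeffs = as.numeric(objective_coeffs),
      name = as.character(name)[1],
      units = as.character(units)[1]
    ),
    class = "metabolic_model"
  )
  validate_metabolic_model(model)
}

#' Validate a metabolic model
#'
#' Checks the structural invariants every `metabolic_model` must satisfy:
#' consistent dimensions, ordered bounds, a non-trivial objective, and
#' unique identifiers. Called by all constructors and readers.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly unchanged, if valid; otherwise an error of
#'   class `fluxsens_validation_error`.
#' @export
validate_metabolic_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  m <- nrow(model$S)
  r <- ncol(model$S)
  bad <- function(msg) abort(msg, class = "fluxsens_validation_error")
  if (length(model$metabolite_ids) != m) {
    bad(sprintf("S has %d rows but %d metabolite ids.", m,
                length(model$metabolite_ids)))
  }
  if (length(model$reaction_ids) != r) {
    bad(sprintf("S has %d columns but %d reaction ids.", r,
                length(model$reaction_ids)))
  }
  for (fld in c("lower_bounds", "upper_bounds", "objective_coeffs")) {
    if (length(model[[fld]]) != r) {
      bad(sprintf("`%s` has length %d, expected %d.", fld,
                  length(model[[fld]]), r))
    }
  }
  if (anyNA(model$lower_bounds) || anyNA(model$upper_bounds)) {
    bad("Flux bounds must not contain NA.")
  }
  viol <- which(model$lower_bounds > model$upper_bounds)
  if (length(viol) > 0) {
    bad(sprintf("lower_bound > upper_bound for reaction(s): %s.",
                paste(model$reaction_ids[viol], collapse = ", ")))
  }
  if (all(model$objective_coeffs == 0)) {
    bad("Objective has no nonzero coefficient.")
  }
  if (anyDuplicated(model$metabolite_ids)) bad("Metabolite ids not unique.")
  if (anyDuplicated(model$reaction_ids)) bad("Reaction ids not unique.")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s\n", x$name))
  cat(sprintf("  %d metabolites x %d reactions (%d nonzeros), units %s\n",
              nrow(x$S), ncol(x$S), Matrix::nnzero(x$S), x$units))
  nex <- length(find_exchange_reactions(x))
  cat(sprintf("  %d exchange reactions (%d intake-capable)\n",
              nex, length(find_exchange_reactions(x, intake_only = TRUE))))
  obj <- which(x$objective_coeffs != 0)
  cat(sprintf("  objective: %s\n",
              paste(sprintf("%+g %s", x$objective_coeffs[obj],
                            x$reaction_ids[obj]), collapse = " ")))
  invisible(x)
}

#' Identify exchange reactions
#'
#' Exchange (boundary) reactions connect the network to its environment and
#' are detected structurally: a reaction whose column of `S` has exactly one
#' nonzero stoichiometric entry. Under the usual sign convention a negative
#' flux on such a reaction is intake, so the intake-capable subset is the
#' one with a strictly negative lower bound. An id-pattern override is
#' available for model dialects where boundary reactions are tagged by name
#' (e.g. `"^EX_"`).
#'
#' @param model a `metabolic_model`.
#' @param intake_only if `TRUE`, keep only reactions with `lower_bound < 0`
#'   (those that can import a metabolite). These are the sensitivity-analysis
#'   factors of the workflow.
#' @param id_pattern optional regular expression; when supplied, reactions
#'   are selected by id match instead of by column structure.
#' @return Integer vector of reaction indices in `reaction_ids` order
#'   (possibly empty).
#' @export
#' @examples
#' find_exchange_reactions(make_min_coupled_model(), intake_only = TRUE)
find_exchange_reactions <- function(model, intake_only = FALSE,
                                    id_pattern = NULL) {
  validate_metabolic_model(model)
  if (!is.null(id_pattern)) {
    idx <- grep(id_pattern, model$reaction_ids)
  } else {
    nnz_per_col <- Matrix::colSums(model$S != 0)
    idx <- which(nnz_per_col == 1)
  }
  if (intake_only) {
    idx <- idx[model$lower_bounds[idx] < 0]
  }
  as.integer(idx)
}

#' Set intake capacities on selected reactions
#'
#' Returns a copy of the model with the *lower* bounds of the given
#' reactions replaced by `values`. Only lower bounds are touched: the upper
#' bound (secretion capacity) of a perturbed exchange stays as in the source
#' model. The input model is never modified.
#'
#' @param model a `metabolic_model`.
#' @param factor_indices integer reaction indices (or character reaction
#'   ids) to update.
#' @param values numeric vector of new lower bounds, same length as
#'   `factor_indices`; each must not exceed the reaction's upper bound.
#' @return A new `metabolic_model`.
#' @export
#' @examples
#' mod <- make_min_coupled_model()
#' perturbed <- apply_intake_bounds(mod, "EX_A", -5)
#' perturbed$lower_bounds
apply_intake_bounds <- function(model, factor_indices, values) {
  validate_metabolic_model(model)
  factor_indices <- resolve_reactions(model, factor_indices)
  values <- as.numeric(values)
  if (length(values) != length(factor_indices)) {
    abort(sprintf("Got %d values for %d reactions.", length(values),
                  length(factor_indices)),
          class = "fluxsens_argument_error")
  }
  over <- values > model$upper_bounds[factor_indices]
  if (any(over)) {
    abort(sprintf(
      "New lower bound exceeds upper bound for reaction(s): %s.",
      paste(model$reaction_ids[factor_indices[over]], collapse = ", ")),
      class = "fluxsens_bound_error")
  }
  model$lower_bounds[factor_indices] <- values
  model
}

# Map reaction ids or indices to validated integer indices, with
# near-match suggestions in the error message.
resolve_reactions <- function(model, ref) {
  if (is.character(ref)) {
    idx <- match(ref, model$reaction_ids)
    if (anyNA(idx)) {
      missing <- ref[is.na(idx)]
      hints <- vapply(missing, function(id) {
        paste(near_matches(id, model$reaction_ids), collapse = ", ")
      }, character(1))
      abort(paste0(
        "Unknown reaction id(s): ",
        paste(sprintf("'%s' (closest: %s)", missing, hints),
              collapse = "; "), "."),
        class = "fluxsens_configuration_error")
    }
    return(as.integer(idx))
  }
  idx <- as.integer(ref)
  if (any(idx < 1L | idx > ncol(model$S))) {
    abort("Reaction index out of range.",
          class = "fluxsens_configuration_error")
  }
  idx
}
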