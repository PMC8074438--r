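#' Read a COBRA-style JSON model
#'
#' Parses the community JSON dialect used by COBRA toolchains: a top-level
#' object with `metabolites` (list of `{id, ...}`) and `reactions` (list of
#' `{id, metabolites: {<met id>: <coef>}, lower_bound, upper_bound,
#' objective_coefficient}`). Bounds and objective coefficients are taken
#' verbatim; missing bounds default to the conventional -1000/1000 caps and
#' a missing `objective_coefficient` to 0.
#'
#' @param path path to a `.json` model file.
#' @return A validated [metabolic_model()].
#' @export
read_cobra_json <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Model file not found: %s", path),
          class = "fluxsens_io_error")
  }
  doc <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) abort(
      sprintf("Failed to parse '%s' as COBRA JSON: %s", path,
              conditionMessage(e)),
      class = "fluxsens_format_error")
  )
  if (is.null(doc$reactions) || is.null(doc$metabolites)) {
    abort(sprintf(
      "'%s' lacks a 'reactions' or 'metabolites' array.", path),
      class = "fluxsens_format_error")
  }
  met_ids <- vapply(doc$metabolites, function(m) as.character(m$id),
                    character(1))
  rxns <- doc$reactions
  rxn_ids <- vapply(rxns, function(r) as.character(r$id), character(1))
  m <- length(met_ids)
  r <- length(rxn_ids)

  i <- integer(0); j <- integer(0); xv <- numeric(0)
  for (k in seq_len(r)) {
    coefs <- rxns[[k]]$metabolites
    if (length(coefs) == 0) next
    rows <- match(names(coefs), met_ids)
    if (anyNA(rows)) {
      abort(sprintf(
        "Reaction '%s' references unknown metabolite(s): %s.",
        rxn_ids[k],
        paste(names(coefs)[is.na(rows)], collapse = ", ")),
        class = "fluxsens_format_error")
    }
    i <- c(i, rows)
    j <- c(j, rep.int(k, length(rows)))
    xv <- c(xv, vapply(coefs, as.numeric, numeric(1)))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = xv, dims = c(m, r))

  num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)
  lb <- vapply(rxns, function(rx) num_or(rx$lower_bound, -1000), numeric(1))
  ub <- vapply(rxns, function(rx) num_or(rx$upper_bound, 1000), numeric(1))
  w <- vapply(rxns, function(rx) num_or(rx$objective_coefficient, 0),
              numeric(1))
  if (all(w == 0)) {
    abort(sprintf("'%s' declares no objective reaction.", path),
          class = "fluxsens_validation_error")
  }
  metabolic_model(S, lb, ub, w,
                  metabolite_ids = met_ids, reaction_ids = rxn_ids,
                  name = as.character(doc$id %||% basename(path)))
}

#' Write a model as COBRA-style JSON
#'
#' Inverse of [read_cobra_json()]: emits the same dialect, so a model
#' written and re-read is structurally identical. Used by the fixture
#' generators so tests exercise the full I/O path.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cobra_json <- function(model, path) {
  validate_metabolic_model(model)
  Sd <- as.matrix(model$S)
  rxns <- lapply(seq_len(ncol(Sd)), function(k) {
    nz <- which(Sd[, k] != 0)
    list(
      id = model$reaction_ids[k],
      metabolites = as.list(setNames(Sd[nz, k], model$metabolite_ids[nz])),
      lower_bound = model$lower_bounds[k],
      upper_bound = model$upper_bounds[k],
      objective_coefficient = model$objective_coeffs[k]
    )
  })
  mets <- lapply(model$metabolite_ids, function(id) list(id = id))
  doc <- list(id = model$name, metabolites = mets, reactions = rxns)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a constraint-based model from file
#'
#' Dispatches on `format`, or on the file extension when `format = "auto"`
#' (`.json` for COBRA JSON; `.xml`/`.sbml` for SBML).
#'
#' @param path model file path.
#' @param format `"auto"`, `"cobra_json"` or `"sbml"`.
#' @return A validated [metabolic_model()].
#' @export
#' @examples
#' path <- tempfile(fileext = ".json")
#' write_cobra_json(make_min_coupled_model(), path)
#' load_model(path)
load_model <- function(path, format = c("auto", "cobra_json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      json = "cobra_json",
      xml = "sbml",
      sbml = "sbml",
      abort(sprintf(
        "Cannot infer model format from extension of '%s'.", path),
        class = "fluxsens_format_error")
    )
  }
  switch(format,
    cobra_json = read_cobra_json(path),
    sbml = read_sbml(path)
  )
}
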