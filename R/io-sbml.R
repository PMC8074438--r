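# SBML reader. Supports Level 3 models carrying bounds/objective through the
# FBC package (parameter-referenced bounds, fbc:listOfObjectives) and falls
# back to the older Level 2 COBRA dialect (LOWER_BOUND / UPPER_BOUND /
# OBJECTIVE_COEFFICIENT parameters inside each reaction's kineticLaw).
# Namespace prefixes vary across exporters, so elements are located with
# local-name() XPath and attributes by suffix match.

attr_by_suffix <- function(node, suffix) {
  at <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", suffix, "$"), names(at))
  if (length(hit) == 0) NA_character_ else unname(at[hit[1]])
}

#' Read an SBML model
#'
#' Reads a constraint-based model from SBML, accepting both Level 3 + FBC
#' (flux-bound parameters and an active flux objective) and the legacy
#' Level 2 dialect with per-reaction `kineticLaw` parameters. Species marked
#' `boundaryCondition="true"` are excluded from the mass-balance rows, per
#' convention.
#'
#' @param path path to an `.xml`/`.sbml` file.
#' @return A validated [metabolic_model()].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Model file not found: %s", path),
          class = "fluxsens_io_error")
  }
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort(
      sprintf("Failed to parse '%s' as XML: %s", path, conditionMessage(e)),
      class = "fluxsens_format_error")
  )

  species <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  sp_id <- xml2::xml_attr(species, "id")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  met_ids <- sp_id[!sp_boundary]
  if (length(met_ids) == 0) {
    abort(sprintf("'%s' contains no (non-boundary) species.", path),
          class = "fluxsens_format_error")
  }

  params <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  param_val <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                        xml2::xml_attr(params, "id"))

  rxn_nodes <- xml2::xml_find_all(
    doc,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rxn_nodes) == 0) {
    abort(sprintf("'%s' contains no reactions.", path),
          class = "fluxsens_format_error")
  }
  rxn_ids <- xml2::xml_attr(rxn_nodes, "id")
  m <- length(met_ids)
  r <- length(rxn_nodes)

  ii <- integer(0); jj <- integer(0); xv <- numeric(0)
  lb <- numeric(r); ub <- numeric(r); w <- numeric(r)

  for (k in seq_len(r)) {
    node <- rxn_nodes[[k]]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(
        node, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']",
                      side))
      if (length(refs) == 0) next
      sp <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      if (side == "listOfReactants") st <- -st
      rows <- match(sp, met_ids)
      keep <- !is.na(rows)  # boundary species fall outside mass balance
      ii <- c(ii, rows[keep])
      jj <- c(jj, rep.int(k, sum(keep)))
      xv <- c(xv, st[keep])
    }

    # bounds: FBC parameter references, then kineticLaw parameters, then
    # reversibility defaults
    lb_ref <- attr_by_suffix(node, "lowerFluxBound")
    ub_ref <- attr_by_suffix(node, "upperFluxBound")
    kl <- xml2::xml_find_all(
      node, ".//*[local-name()='kineticLaw']//*[local-name()='parameter' or local-name()='localParameter']")
    kl_val <- setNames(as.numeric(xml2::xml_attr(kl, "value")),
                       xml2::xml_attr(kl, "id"))
    pick <- function(ref, kl_id, default) {
      if (!is.na(ref) && ref %in% names(param_val)) return(param_val[[ref]])
      if (kl_id %in% names(kl_val)) return(kl_val[[kl_id]])
      default
    }
    reversible <- !identical(xml2::xml_attr(node, "reversible"), "false")
    lb[k] <- pick(lb_ref, "LOWER_BOUND", if (reversible) -1000 else 0)
    ub[k] <- pick(ub_ref, "UPPER_BOUND", 1000)
    w[k] <- if ("OBJECTIVE_COEFFICIENT" %in% names(kl_val)) {
      kl_val[["OBJECTIVE_COEFFICIENT"]]
    } else 0
  }

  # FBC objective overrides kineticLaw coefficients when present
  fobj <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfFluxObjectives']/*[local-name()='fluxObjective']")
  if (length(fobj) > 0) {
    w <- numeric(r)
    for (fo in fobj) {
      rx <- attr_by_suffix(fo, "reaction")
      coef <- as.numeric(attr_by_suffix(fo, "coefficient"))
      idx <- match(rx, rxn_ids)
      if (is.na(idx)) {
        abort(sprintf(
          "Flux objective references unknown reaction '%s'.", rx),
          class = "fluxsens_format_error")
      }
      w[idx] <- coef
    }
  }
  if (all(w == 0)) {
    abort(sprintf("'%s' declares no objective reaction.", path),
          class = "fluxsens_validation_error")
  }

  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xv, dims = c(m, r))
  mdl_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  nm <- xml2::xml_attr(mdl_node, "id")
  metabolic_model(S, lb, ub, w,
                  metabolite_ids = met_ids, reaction_ids = rxn_ids,
                  name = if (is.na(nm)) basename(path) else nm)
}
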