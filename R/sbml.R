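#' Load a metabolic model from SBML
#'
#' Reads SBML Level 3 with the FBC package (flux bounds as parameter
#' references, objective from the active FBC objective) and falls back to
#' Level 2 conventions (kinetic-law \code{LOWER_BOUND}/\code{UPPER_BOUND}
#' parameters). Species flagged as boundary condition are excluded from the
#' stoichiometric rows. Row/column order follows document order, so loading
#' the same file twice yields identical matrices.
#'
#' When a reaction has no bound information, COBRA-convention defaults are
#' used (0/1000 irreversible, -1000/1000 reversible) and a warning is
#' issued.
#'
#' @param path SBML file path.
#' @param objective optional reaction id overriding (or supplying) the
#'   objective; loading fails with a "no objective" error when neither the
#'   file nor this argument provides one.
#' @return a \code{metabolic_model}.
#' @export
load_model <- function(path, objective = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML format error: ", conditionMessage(e), call. = FALSE))
  mdl <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  if (inherits(mdl, "xml_missing"))
    stop("SBML format error: no <model> element")

  species <- xml2::xml_find_all(doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_id <- vapply(species, .sbml_attr, "", "id")
  sp_boundary <- vapply(species, function(s)
    identical(.sbml_attr(s, "boundaryCondition"), "true"), FALSE)
  sp_formula <- vapply(species, .sbml_attr, "", "chemicalFormula")
  met_ids <- sp_id[!sp_boundary]

  params <- xml2::xml_find_all(doc, "/*/*[local-name()='model']/*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pmap <- setNames(as.numeric(vapply(params, .sbml_attr, "", "value")),
                   vapply(params, .sbml_attr, "", "id"))

  reactions <- xml2::xml_find_all(doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(reactions)) stop("SBML format error: no <reaction> elements")
  n <- length(reactions)
  rxn_ids <- vapply(reactions, .sbml_attr, "", "id")
  if (any(!nzchar(rxn_ids)))
    stop("SBML format error: <reaction> without id")
  S <- matrix(0, length(met_ids), n, dimnames = list(met_ids, rxn_ids))
  lb <- numeric(n); ub <- numeric(n)
  missing_bounds <- FALSE
  for (j in seq_len(n)) {
    r <- reactions[[j]]
    rev_attr <- .sbml_attr(r, "reversible")
    rev <- !identical(rev_attr, "false")  # SBML default is reversible
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(r, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      for (ref in refs) {
        sp <- .sbml_attr(ref, "species")
        st <- .sbml_attr(ref, "stoichiometry")
        st <- if (nzchar(st)) as.numeric(st) else 1
        if (sp %in% met_ids) S[sp, j] <- S[sp, j] + sgn * st
      }
    }
    bounds <- .sbml_bounds(r, pmap, rev)
    if (is.null(bounds)) {
      missing_bounds <- TRUE
      bounds <- if (rev) c(-1000, 1000) else c(0, 1000)
    }
    lb[j] <- bounds[1]; ub[j] <- bounds[2]
  }
  if (missing_bounds)
    warning("reaction(s) without flux bounds; using defaults (0/1000, reversible -1000/1000)")

  obj_id <- .sbml_objective(doc)
  if (!is.null(objective)) obj_id <- objective
  if (is.na(obj_id))
    stop("no objective: the file defines none; pass `objective =` to set one")
  if (!obj_id %in% rxn_ids)
    stop("objective reaction '", obj_id, "' not found in the model")

  formulas <- setNames(sp_formula[!sp_boundary], met_ids)
  formulas <- formulas[nzchar(formulas)]
  metabolic_model(S, lb, ub, objective_id = obj_id,
                  annotations = if (length(formulas))
                    list(formula = formulas) else list())
}

# attribute lookup tolerant of namespace prefixes (fbc:..., etc.)
.sbml_attr <- function(node, name) {
  attrs <- xml2::xml_attrs(node)
  hit <- which(names(attrs) == name | endsWith(names(attrs), paste0(":", name)))
  if (length(hit)) attrs[[hit[1]]] else ""
}

.sbml_bounds <- function(rnode, pmap, rev) {
  lb_ref <- .sbml_attr(rnode, "lowerFluxBound")
  ub_ref <- .sbml_attr(rnode, "upperFluxBound")
  if (nzchar(lb_ref) && nzchar(ub_ref) &&
      lb_ref %in% names(pmap) && ub_ref %in% names(pmap))
    return(c(pmap[[lb_ref]], pmap[[ub_ref]]))
  # L2 fallback: kinetic-law parameters
  kl <- xml2::xml_find_all(rnode, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")
  if (length(kl)) {
    ids <- vapply(kl, .sbml_attr, "", "id")
    vals <- as.numeric(vapply(kl, .sbml_attr, "", "value"))
    lo <- vals[ids == "LOWER_BOUND"]; hi <- vals[ids == "UPPER_BOUND"]
    if (length(lo) && length(hi)) return(c(lo[1], hi[1]))
  }
  NULL
}

.sbml_objective <- function(doc) {
  lst <- xml2::xml_find_first(doc, "//*[local-name()='listOfObjectives']")
  if (inherits(lst, "xml_missing")) return(NA_character_)
  active <- .sbml_attr(lst, "activeObjective")
  objs <- xml2::xml_find_all(lst, "./*[local-name()='objective']")
  if (!length(objs)) return(NA_character_)
  chosen <- objs[[1]]
  if (nzchar(active)) {
    ids <- vapply(objs, .sbml_attr, "", "id")
    if (active %in% ids) chosen <- objs[[which(ids == active)[1]]]
  }
  fo <- xml2::xml_find_first(chosen, ".//*[local-name()='fluxObjective']")
  if (inherits(fo, "xml_missing")) return(NA_character_)
  rid <- .sbml_attr(fo, "reaction")
  if (nzchar(rid)) rid else NA_character_
}

#' Write a model as SBML Level 3 + FBC
#'
#' Minimal but valid L3v1/FBC-v2 serialization: species, reactions with
#' bound parameters, and the active objective. Round-trips through
#' \code{\link{load_model}}.
#'
#' @param model a \code{metabolic_model}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', esc("coupledesign_model")),
    '    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    "    <listOfSpecies>")
  forms <- model$annotations$formula
  for (met in model$metabolite_ids) {
    f <- if (!is.null(forms) && met %in% names(forms))
      sprintf(' fbc:chemicalFormula="%s"', forms[[met]]) else ""
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>',
      met, f))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (j in seq_along(model$reaction_ids)) {
    lines <- c(lines,
      sprintf('      <parameter id="lb_%d" value="%s" constant="true"/>', j,
              format(model$lb[j], scientific = FALSE)),
      sprintf('      <parameter id="ub_%d" value="%s" constant="true"/>', j,
              format(model$ub[j], scientific = FALSE)))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (j in seq_along(model$reaction_ids)) {
    rid <- model$reaction_ids[j]
    col <- model$S[, j]
    rev <- if (model$lb[j] < 0) "true" else "false"
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%d" fbc:upperFluxBound="ub_%d">',
      rid, rev, j, j))
    for (side in c(-1, 1)) {
      mets <- names(col)[sign(col) == side]
      if (!length(mets)) next
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      lines <- c(lines, sprintf("        <%s>", tag))
      for (met in mets)
        lines <- c(lines, sprintf(
          '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          met, format(abs(col[met]), scientific = FALSE)))
      lines <- c(lines, sprintf("        </%s>", tag))
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  if (!is.na(model$objective_id)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
              model$objective_id),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

#' Write the packaged toy networks as SBML fixtures
#'
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
make_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  for (nm in c("TOY-A", "TOY-B", "TOY-C")) {
    p <- file.path(dir, paste0(tolower(gsub("-", "", nm)), ".xml"))
    write_sbml(toy_network(nm), p)
    paths[nm] <- p
  }
  invisible(paths)
}
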