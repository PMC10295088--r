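#' Load a metabolic model from COBRA JSON or SBML Level 3 (fbc)
#'
#' Supports the two dialects genome-scale models are distributed in (e.g.
#' the BiGG database files for iJO1366): COBRA JSON and SBML Level 3 with
#' the fbc extension. The format is inferred from the file extension unless
#' given. Exchange reactions are auto-detected on load (single-metabolite
#' columns) unless `exchange` overrides them.
#'
#' @param path file path.
#' @param format `"auto"`, `"json"` or `"sbml"`.
#' @param exchange optional character vector overriding exchange detection.
#' @return A validated `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml"), exchange = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(sprintf("model file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(format,
         json = read_cobra_json(path, exchange),
         sbml = read_sbml_fbc(path, exchange))
}

#' Save a metabolic model
#'
#' Writes COBRA JSON or SBML Level 3 + fbc; a round trip through either
#' format preserves stoichiometry, bounds and the objective exactly.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @param format `"auto"` (from extension), `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(format,
         json = write_cobra_json(model, path),
         sbml = write_sbml_fbc(model, path))
  invisible(path)
}

read_cobra_json <- function(path, exchange = NULL) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) rlang::abort(sprintf(
                    "failed to parse COBRA JSON '%s': %s", path, conditionMessage(e))))
  if (is.null(doc$reactions) || is.null(doc$metabolites)) {
    rlang::abort("COBRA JSON must contain 'reactions' and 'metabolites'")
  }
  met_ids <- vapply(doc$metabolites, function(m) m$id, character(1))
  rxn_ids <- vapply(doc$reactions, function(r) r$id, character(1))
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  lower <- numeric(length(rxn_ids)); upper <- numeric(length(rxn_ids))
  obj_id <- NULL
  for (j in seq_along(doc$reactions)) {
    r <- doc$reactions[[j]]
    for (m in names(r$metabolites)) {
      if (!m %in% met_ids) {
        rlang::abort(sprintf("reaction '%s' references unknown metabolite '%s'", r$id, m))
      }
      S[m, j] <- as.numeric(r$metabolites[[m]])
    }
    lower[j] <- as.numeric(r$lower_bound %||% -1000)
    upper[j] <- as.numeric(r$upper_bound %||% 1000)
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0) {
      obj_id <- r$id
    }
  }
  if (is.null(obj_id)) obj_id <- rxn_ids[[1]]
  metabolic_model(S, lower, upper, obj_id, exchange = exchange,
                  id = as.character(doc$id %||% basename(path)))
}

write_cobra_json <- function(model, path) {
  rxns <- lapply(seq_along(model$reaction_ids), function(j) {
    col <- model$S[, j]
    nz <- which(col != 0)
    list(
      id = model$reaction_ids[j],
      metabolites = as.list(stats::setNames(unname(col[nz]), model$metabolite_ids[nz])),
      lower_bound = unname(model$lower[j]),
      upper_bound = unname(model$upper[j]),
      objective_coefficient = if (model$reaction_ids[j] == model$objective) 1 else 0
    )
  })
  mets <- lapply(model$metabolite_ids, function(m) list(id = m))
  doc <- list(id = model$id, metabolites = mets, reactions = rxns, genes = list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_sbml_fbc <- function(path, exchange = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) rlang::abort(sprintf(
                    "failed to parse SBML '%s': %s", path, conditionMessage(e))))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) rlang::abort("no <model> element in SBML file")

  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(species, "id")
  sp_boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  met_ids <- sp_id[!sp_boundary]

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) == 0) rlang::abort("SBML model has no reactions")
  rxn_ids <- xml2::xml_attr(rx, "id")
  S <- matrix(0, length(met_ids), length(rx), dimnames = list(met_ids, rxn_ids))
  lower <- numeric(length(rx)); upper <- numeric(length(rx))
  for (j in seq_along(rx)) {
    node <- rx[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, sprintf("./s:%s/s:speciesReference", side), ns)
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        st <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        if (is.na(st)) st <- 1
        if (side == "listOfReactants") st <- -st
        if (sp %in% met_ids) S[sp, j] <- S[sp, j] + st
      }
    }
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    lower[j] <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]] else -1000
    upper[j] <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]] else 1000
  }

  obj_ref <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  obj_id <- if (!inherits(obj_ref, "xml_missing")) {
    xml2::xml_attr(obj_ref, "reaction")
  } else rxn_ids[[1]]
  metabolic_model(S, lower, upper, obj_id, exchange = exchange,
                  id = xml2::xml_attr(model_node, "id") %||% basename(path))
}

write_sbml_fbc <- function(model, path) {
  bound_ids <- character(0)
  fmt_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0(
      "<sbml xmlns=\"%s\" xmlns:fbc=\"%s\" level=\"3\" version=\"1\" ",
      "fbc:required=\"false\">"), SBML_NS, FBC_NS),
    sprintf("  <model id=\"%s\" fbc:strict=\"true\">", model$id),
    "    <listOfCompartments>",
    "      <compartment id=\"c\" constant=\"true\"/>",
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    sprintf(paste0("      <species id=\"%s\" compartment=\"c\" constant=\"false\" ",
                   "boundaryCondition=\"false\" hasOnlySubstanceUnits=\"false\"/>"),
            model$metabolite_ids),
    "    </listOfSpecies>"
  )
  # bound parameters, deduplicated by value
  all_bounds <- unique(c(model$lower, model$upper))
  bnd_id <- function(v) sprintf("bnd_%s", gsub("[^0-9A-Za-z]", "_", fmt_num(v)))
  lines <- c(lines, "    <listOfParameters>",
             sprintf("      <parameter id=\"%s\" value=\"%s\" constant=\"true\"/>",
                     vapply(all_bounds, bnd_id, character(1)),
                     vapply(all_bounds, fmt_num, character(1))),
             "    </listOfParameters>",
             "    <listOfReactions>")
  for (j in seq_along(model$reaction_ids)) {
    col <- model$S[, j]
    reac <- which(col < 0); prod <- which(col > 0)
    lines <- c(lines, sprintf(paste0(
      "      <reaction id=\"%s\" reversible=\"%s\" fast=\"false\" ",
      "fbc:lowerFluxBound=\"%s\" fbc:upperFluxBound=\"%s\">"),
      model$reaction_ids[j], tolower(model$lower[j] < 0),
      bnd_id(model$lower[j]), bnd_id(model$upper[j])))
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>",
                 sprintf(paste0("          <speciesReference species=\"%s\" ",
                                "stoichiometry=\"%s\" constant=\"true\"/>"),
                         model$metabolite_ids[reac], fmt_num(-col[reac])),
                 "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>",
                 sprintf(paste0("          <speciesReference species=\"%s\" ",
                                "stoichiometry=\"%s\" constant=\"true\"/>"),
                         model$metabolite_ids[prod], fmt_num(col[prod])),
                 "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines,
    "    </listOfReactions>",
    "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
    "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
    "        <fbc:listOfFluxObjectives>",
    sprintf("          <fbc:fluxObjective fbc:reaction=\"%s\" fbc:coefficient=\"1\"/>",
            model$objective),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>",
    "</sbml>")
  writeLines(lines, path)
}
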