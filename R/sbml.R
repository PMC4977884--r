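# Minimal SBML Level 3 export of a built core model.  Exchange
# reactions keep their EX_ prefix; flux bounds travel in the fbc-style
# attributes of a reaction's notes block.  Import is out of scope.

#' Export a core model as SBML Level 3
#'
#' Writes compartments, species and reactions (with reversibility and
#' flux bounds) of a \code{core_model}.  Exchange reactions are
#' prefixed \code{EX_} as in the template.
#'
#' @param model a \code{core_model}.
#' @param file output path (.xml).
#' @return \code{file}, invisibly.
#' @export
write_sbml <- function(model, file) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("write_sbml() requires the 'xml2' package")
  template <- model$template
  rxns <- template$reactions[names(model$reactions)]
  cpds <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  ctab <- template$compounds[match(cpds, template$compounds$id), ]

  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model",
                             id = gsub("[^A-Za-z0-9_]", "_", model$genome_id))
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cmp in unique(ctab$compartment))
    xml2::xml_add_child(lc, "compartment",
                        id = substr(cmp, 1, 1), name = cmp, constant = "true")
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(ctab)))
    xml2::xml_add_child(ls, "species",
                        id = paste0("M_", ctab$id[i]), name = ctab$name[i],
                        compartment = substr(ctab$compartment[i], 1, 1),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in rxns) {
    rn <- xml2::xml_add_child(lr, "reaction",
                              id = paste0("R_", r$id), name = r$name,
                              reversible = if (r$lower < 0) "true" else "false",
                              fast = "false")
    notes <- xml2::xml_add_child(rn, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p",
                        sprintf("LOWER_BOUND: %g; UPPER_BOUND: %g; EVIDENCE: %s",
                                r$lower, r$upper, model$reactions[[r$id]]))
    reac <- r$stoich[r$stoich < 0]; prod <- r$stoich[r$stoich > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (j in seq_along(reac))
        xml2::xml_add_child(lre, "speciesReference",
                            species = paste0("M_", names(reac)[j]),
                            stoichiometry = format(abs(reac[[j]]), digits = 12),
                            constant = "true")
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (j in seq_along(prod))
        xml2::xml_add_child(lpr, "speciesReference",
                            species = paste0("M_", names(prod)[j]),
                            stoichiometry = format(prod[[j]], digits = 12),
                            constant = "true")
    }
  }
  xml2::write_xml(doc, file)
  invisible(file)
}
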