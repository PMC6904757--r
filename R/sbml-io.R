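# SBML Level 3 + FBC v2 reader/writer built on xml2.
#
# Scope: the constraint-based subset — compartments, species (with
# fbc:chemicalFormula), reactions with reactant/product stoichiometries,
# flux bounds as fbc:lowerFluxBound/upperFluxBound parameter references or
# plain numeric attributes, the active fbc objective, and
# fbc:geneProductAssociation trees. Kinetic-law or notes-field bound
# conventions are rejected with a clear error. The conventional M_/R_/G_
# id prefixes are added on write and stripped on read; bracketed
# compartment suffixes in ids ("G6P[c]") are recognised and stripped into
# the compartment field.

sbml_ns_core <- "http://www.sbml.org/sbml/level3/version1/core"
sbml_ns_fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

xml_attr1 <- function(node, names) {
  for (nm in names) {
    v <- xml2::xml_attr(node, nm)
    if (!is.na(v)) return(v)
  }
  NA_character_
}

strip_prefix <- function(id, prefix) {
  ifelse(startsWith(id, prefix), substring(id, nchar(prefix) + 1L), id)
}

# "G6P[c]" -> list(id = "G6P", compartment = "c"); no suffix -> compartment NA
split_compartment_suffix <- function(id) {
  m <- regmatches(id, regexec("^(.*)\\[([^][]+)\\]$", id))[[1]]
  if (length(m) == 3L) list(id = m[2], compartment = m[3])
  else list(id = id, compartment = NA_character_)
}

#' Read a metabolic model from SBML (Level 3 + FBC)
#'
#' Parses the constraint-based subset of SBML: species, compartments,
#' reactions with stoichiometries, FBC flux bounds (parameter references or
#' per-reaction numeric attributes, falling back to the reversibility flag
#' with the conventional -1000/0..1000 defaults), the active FBC objective,
#' and gene-product associations. The detected SBML level/version and FBC
#' namespace are reported via `message()`.
#'
#' @param path SBML file path.
#' @param quiet suppress the dialect-detection message (default FALSE).
#' @return a `metabolic_model` with attribute `provenance` (list: `path`,
#'   `format`, `dialect`).
#' @section Errors and warnings: a missing objective yields a warning and
#'   an empty objective; a species reference that does not resolve is a
#'   hard error naming the reaction; bounds expressed through kinetic laws
#'   are rejected.
#' @export
read_sbml <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  root <- xml2::xml_find_first(doc, "/*[local-name()='sbml']")
  if (inherits(root, "xml_missing")) stop("not an SBML document: ", path)
  level <- xml2::xml_attr(root, "level")
  version <- xml2::xml_attr(root, "version")
  nss <- xml2::xml_ns(doc)
  has_fbc <- any(grepl("/fbc/", unlist(nss)))
  dialect <- sprintf("SBML L%sV%s%s", level, version,
                     if (has_fbc) " + fbc" else " (no fbc namespace)")
  if (!quiet) message("read_sbml: detected ", dialect)

  # compartments
  comp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfCompartments']/*[local-name()='compartment']")
  comp_ids <- xml2::xml_attr(comp_nodes, "id")

  # species
  sp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(sp_nodes) == 0) stop("SBML file has no species: ", path)
  sp_raw_ids <- xml2::xml_attr(sp_nodes, "id")
  mets <- do.call(rbind, lapply(seq_along(sp_nodes), function(i) {
    raw <- sp_raw_ids[i]
    id <- strip_prefix(raw, "M_")
    comp <- xml2::xml_attr(sp_nodes[[i]], "compartment")
    sp <- split_compartment_suffix(id)
    if (is.na(comp) || !nzchar(comp)) comp <- sp$compartment
    # bracketed ids ("G6P[c]") keep a compartment-qualified id to stay unique
    if (!is.na(sp$compartment)) id <- paste0(sp$id, "_", sp$compartment)
    data.frame(id = id,
               name = {
                 nm <- xml2::xml_attr(sp_nodes[[i]], "name")
                 if (is.na(nm)) id else nm
               },
               compartment = if (is.na(comp)) "c" else comp,
               formula = xml_attr1(sp_nodes[[i]], c("fbc:chemicalFormula", "chemicalFormula")),
               stringsAsFactors = FALSE)
  }))
  id_map <- stats::setNames(mets$id, sp_raw_ids)  # raw species id -> model id

  # global parameters (bound values)
  par_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_vals <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                              xml2::xml_attr(par_nodes, "id"))

  # gene products
  gp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_ids <- vapply(gp_nodes, function(n) xml_attr1(n, c("fbc:id", "id")), character(1))
  gp_genes <- strip_prefix(gp_ids, "G_")
  gp_map <- stats::setNames(gp_genes, gp_ids)

  # reactions
  rx_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0) stop("SBML file has no reactions: ", path)
  rxn_rows <- vector("list", length(rx_nodes))
  stoich <- list()
  for (i in seq_along(rx_nodes)) {
    node <- rx_nodes[[i]]
    raw_id <- xml2::xml_attr(node, "id")
    rid <- strip_prefix(raw_id, "R_")
    kl <- xml2::xml_find_all(node, "./*[local-name()='kineticLaw']")
    lbref <- xml_attr1(node, c("fbc:lowerFluxBound", "lowerFluxBound"))
    ubref <- xml_attr1(node, c("fbc:upperFluxBound", "upperFluxBound"))
    if (length(kl) > 0 && (is.na(lbref) || is.na(ubref)))
      stop("reaction ", rid, " encodes bounds via a kineticLaw; ",
           "only FBC flux bounds are supported")
    num_or_ref <- function(ref) {
      if (is.na(ref)) return(NA_real_)
      v <- suppressWarnings(as.numeric(ref))
      if (!is.na(v)) return(v)
      if (ref %in% names(par_vals)) return(par_vals[[ref]])
      stop("reaction ", rid, " references undefined bound parameter '", ref, "'")
    }
    lb <- num_or_ref(lbref); ub <- num_or_ref(ubref)
    if (is.na(lb) || is.na(ub)) {
      rev <- identical(xml2::xml_attr(node, "reversible"), "true")
      if (is.na(lb)) lb <- if (rev) -1000 else 0
      if (is.na(ub)) ub <- 1000
    }
    # stoichiometry
    coef <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      for (sr in refs) {
        sp <- xml2::xml_attr(sr, "species")
        if (!(sp %in% names(id_map)))
          stop("reaction ", rid, " references unknown species '", sp, "'")
        st <- xml2::xml_attr(sr, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        sgn <- if (side == "listOfReactants") -1 else 1
        key <- id_map[[sp]]
        coef[key] <- (if (key %in% names(coef)) coef[[key]] else 0) + sgn * st
      }
    }
    if (length(coef) == 0)
      stop("reaction ", rid, " has an empty stoichiometry")
    # GPR
    gpa <- xml2::xml_find_first(node, "./*[local-name()='geneProductAssociation']")
    gpr_str <- if (inherits(gpa, "xml_missing")) "" else {
      child <- xml2::xml_find_first(gpa, "./*")
      if (inherits(child, "xml_missing")) "" else
        gpr_to_string(parse_gpr(sbml_gpa_to_string(child, gp_map)))  # canonical form
    }
    rxn_rows[[i]] <- data.frame(
      id = rid,
      name = { nm <- xml2::xml_attr(node, "name"); if (is.na(nm)) rid else nm },
      lower_bound = lb, upper_bound = ub, gpr = gpr_str,
      subsystem = NA_character_, stringsAsFactors = FALSE)
    stoich[[rid]] <- coef
  }
  reactions <- do.call(rbind, rxn_rows)

  # objective
  objective <- numeric()
  fo_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfFluxObjectives']/*[local-name()='fluxObjective']")
  if (length(fo_nodes) == 0) {
    warning("SBML file declares no objective; model has an empty objective")
  } else {
    for (fo in fo_nodes) {
      rref <- strip_prefix(xml_attr1(fo, c("fbc:reaction", "reaction")), "R_")
      cf <- as.numeric(xml_attr1(fo, c("fbc:coefficient", "coefficient")))
      objective[rref] <- if (is.na(cf)) 1 else cf
    }
  }
  genes <- unique(c(gp_genes, unlist(lapply(reactions$gpr, gpr_genes))))
  model <- metabolic_model(mets, reactions, stoich,
                           genes = genes, objective = objective)
  attr(model, "provenance") <- list(path = path, format = "sbml", dialect = dialect)
  model
}

# fbc:and / fbc:or / fbc:geneProductRef subtree -> rule string
sbml_gpa_to_string <- function(node, gp_map) {
  lname <- xml2::xml_name(node)  # xml_name drops the namespace prefix
  if (lname == "geneProductRef") {
    ref <- xml_attr1(node, c("fbc:geneProduct", "geneProduct"))
    return(if (ref %in% names(gp_map)) gp_map[[ref]] else strip_prefix(ref, "G_"))
  }
  if (!(lname %in% c("and", "or"))) stop("unsupported GPR element <", lname, ">")
  parts <- vapply(xml2::xml_find_all(node, "./*"), sbml_gpa_to_string,
                  character(1), gp_map = gp_map)
  paste0("(", paste(parts, collapse = paste0(" ", lname, " ")), ")")
}

#' Write a metabolic model to SBML Level 3 + FBC v2
#'
#' Canonical write format: flux bounds as shared global parameters
#' referenced via `fbc:lowerFluxBound`/`fbc:upperFluxBound`, one active
#' maximisation objective, gene products with `fbc:label`, and
#' `fbc:geneProductAssociation` trees mirroring the GPR rules. Ids receive
#' the conventional `M_`/`R_`/`G_` prefixes.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param model_id SBML model id (default "model").
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path, model_id = "model") {
  validate_model(model)
  doc <- xml2::xml_new_root("sbml",
    "xmlns" = sbml_ns_core, "xmlns:fbc" = sbml_ns_fbc,
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = model_id, "fbc:strict" = "true")

  comps <- unique(model$metabolites$compartment)
  lc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cp in comps)
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")

  ls <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    sp <- xml2::xml_add_child(ls, "species",
      id = paste0("M_", model$metabolites$id[i]),
      name = model$metabolites$name[i],
      compartment = model$metabolites$compartment[i],
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    f <- model$metabolites$formula[i]
    if (!is.na(f) && nzchar(f)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", f)
  }

  # shared bound parameters, one per distinct value
  vals <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  fmt1 <- function(x) format(x, digits = 17, trim = TRUE)
  par_ids <- stats::setNames(sprintf("fb_%d", seq_along(vals)),
                             vapply(vals, fmt1, character(1)))
  lp <- xml2::xml_add_child(mnode, "listOfParameters")
  for (k in seq_along(vals))
    xml2::xml_add_child(lp, "parameter", id = par_ids[[k]],
                        value = fmt1(vals[k]),
                        constant = "true", sboTerm = "SBO:0000626")
  bound_id <- function(v) par_ids[[fmt1(v)]]

  lr <- xml2::xml_add_child(mnode, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    rnode <- xml2::xml_add_child(lr, "reaction",
      id = paste0("R_", rid), name = model$reactions$name[i],
      reversible = if (model$reactions$lower_bound[i] < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bound_id(model$reactions$lower_bound[i]),
      "fbc:upperFluxBound" = bound_id(model$reactions$upper_bound[i]))
    sto <- model$stoichiometry[[rid]]
    reac <- sto[sto < 0]; prod <- sto[sto > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rnode, "listOfReactants")
      for (m in names(reac))
        xml2::xml_add_child(lre, "speciesReference", species = paste0("M_", m),
                            stoichiometry = format(-reac[[m]], digits = 17),
                            constant = "true")
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rnode, "listOfProducts")
      for (m in names(prod))
        xml2::xml_add_child(lpr, "speciesReference", species = paste0("M_", m),
                            stoichiometry = format(prod[[m]], digits = 17),
                            constant = "true")
    }
    rule <- model$reactions$gpr[i]
    if (nzchar(rule)) {
      gpa <- xml2::xml_add_child(rnode, "fbc:geneProductAssociation")
      sbml_add_gpa(gpa, unclass(parse_gpr(rule)))
    }
  }

  lo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives", "fbc:activeObjective" = "obj")
  on <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj", "fbc:type" = "maximize")
  if (length(model$objective)) {
    lfo <- xml2::xml_add_child(on, "fbc:listOfFluxObjectives")
    for (rid in names(model$objective))
      xml2::xml_add_child(lfo, "fbc:fluxObjective",
                          "fbc:reaction" = paste0("R_", rid),
                          "fbc:coefficient" = format(model$objective[[rid]], digits = 17))
  }

  if (length(model$genes)) {
    lg <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in model$genes)
      xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = paste0("G_", g),
                          "fbc:label" = g)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_add_gpa <- function(parent, node) {
  switch(node$kind,
    gene = xml2::xml_add_child(parent, "fbc:geneProductRef",
                               "fbc:geneProduct" = paste0("G_", node$gene)),
    op = {
      el <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
      for (a in node$args) sbml_add_gpa(el, a)
    },
    stop("cannot serialise empty GPR node"))
  invisible(parent)
}
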