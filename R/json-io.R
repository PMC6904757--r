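#' Write a model to the package's JSON dialect
#'
#' A flat, self-describing JSON schema close to the common COBRA JSON
#' layout:
#' \preformatted{
#' {
#'   "id": "...",
#'   "metabolites": [{"id","name","compartment","formula"}, ...],
#'   "reactions":  [{"id","name","metabolites":{met: coeff, ...},
#'                   "lower_bound","upper_bound","gene_reaction_rule",
#'                   "subsystem","objective_coefficient"}, ...],
#'   "genes": ["g1", ...],
#'   "hypothetical": ["EX_x_hyp", ...]
#' }
#' }
#' Round trips are lossless for every field the package models.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param id model identifier stored in the file (default "model").
#' @return `path`, invisibly.
#' @export
write_json_model <- function(model, path, id = "model") {
  validate_model(model)
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    rid <- model$reactions$id[i]
    sto <- model$stoichiometry[[rid]]
    list(id = rid,
         name = model$reactions$name[i],
         metabolites = as.list(sto),
         lower_bound = model$reactions$lower_bound[i],
         upper_bound = model$reactions$upper_bound[i],
         gene_reaction_rule = model$reactions$gpr[i],
         subsystem = model$reactions$subsystem[i],
         objective_coefficient =
           if (rid %in% names(model$objective)) unname(model$objective[rid]) else 0)
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    list(id = model$metabolites$id[i],
         name = model$metabolites$name[i],
         compartment = model$metabolites$compartment[i],
         formula = model$metabolites$formula[i])
  })
  doc <- list(id = id, metabolites = mets, reactions = rxns,
              genes = as.list(model$genes),
              hypothetical = as.list(model$hypothetical))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a model from the package's JSON dialect
#'
#' @param path file written by [write_json_model()] (or hand-authored to
#'   the same schema; missing bounds default to the conventional
#'   reversible (-1000, 1000)).
#' @return a `metabolic_model`.
#' @export
read_json_model <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("not a model JSON file (missing 'metabolites' or 'reactions'): ", path)
  null_na <- function(x, default = NA_character_) if (is.null(x)) default else x
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) data.frame(
    id = m$id, name = null_na(m$name, m$id),
    compartment = null_na(m$compartment, "c"),
    formula = null_na(m$formula), stringsAsFactors = FALSE)))
  rxn_rows <- list(); stoich <- list(); objective <- numeric()
  for (r in doc$reactions) {
    lb <- if (is.null(r$lower_bound)) -1000 else r$lower_bound
    ub <- if (is.null(r$upper_bound)) 1000 else r$upper_bound
    rxn_rows[[length(rxn_rows) + 1L]] <- data.frame(
      id = r$id, name = null_na(r$name, r$id),
      lower_bound = lb, upper_bound = ub,
      gpr = null_na(r$gene_reaction_rule, ""),
      subsystem = null_na(r$subsystem), stringsAsFactors = FALSE)
    sto <- unlist(r$metabolites)
    stoich[[r$id]] <- stats::setNames(as.numeric(sto), names(sto))
    oc <- r$objective_coefficient
    if (!is.null(oc) && oc != 0) objective[r$id] <- oc
  }
  genes <- unlist(doc$genes)
  metabolic_model(mets, do.call(rbind, rxn_rows), stoich,
                  genes = if (is.null(genes)) NULL else as.character(genes),
                  objective = objective,
                  hypothetical = as.character(unlist(doc$hypothetical)))
}

#' Write an analysis result as a TSV table
#'
#' Deterministic tabular output: fixed column order, a header row, floats
#' printed at 6 significant digits. Accepts the package's tabular result
#' classes and plain named vectors/data frames.
#'
#' @param result an `fva_result`, `flux_sum_result`, `flux_sum_profile`,
#'   `phenotype_calls`, `dose_response_curve`, data frame, or named numeric
#'   vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(result, path) {
  df <- if (inherits(result, "flux_sum_result")) {
    data.frame(metabolite = names(result), flux_sum = as.numeric(result),
               stringsAsFactors = FALSE)
  } else if (inherits(result, "flux_sum_profile")) {
    data.frame(metabolite = rownames(result$phi),
               as.data.frame(result$phi, check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  } else if (inherits(result, "fva_result")) {
    as.data.frame(result)[, c("reaction", "min", "max")]
  } else if (is.data.frame(result)) {
    as.data.frame(result)
  } else if (is.numeric(result) && !is.null(names(result))) {
    data.frame(id = names(result), value = as.numeric(result),
               stringsAsFactors = FALSE)
  } else stop("unsupported result type for write_table")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
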