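#' Simulate gene knockouts
#'
#' A gene knockout closes every reaction whose GPR rule evaluates inactive
#' with the deleted genes set to absent: both flux bounds go to zero.
#' Reactions with an isozyme (`or`) escape route, and reactions with no gene
#' association, are untouched. Reactions are never removed, so the same
#' model object supports repeated what-if queries.
#'
#' @param model a `metabolic_model`.
#' @param genes character vector of gene ids to delete (must be registered
#'   in the model).
#' @return a modified copy of the model.
#' @examples
#' m <- make_toy_core()
#' solve_fba(knockout_genes(m, "g1"))$objective_value  # transport gone: 0
#' @export
knockout_genes <- function(model, genes) {
  genes <- as.character(genes)
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) stop("unknown gene id: ", unknown[1])
  if (length(genes) == 0) return(model)
  for (i in seq_len(nrow(model$reactions))) {
    rule <- model$reactions$gpr[i]
    if (!nzchar(rule)) next
    if (!gpr_active(parse_gpr(rule), deleted = genes)) {
      model$reactions$lower_bound[i] <- 0
      model$reactions$upper_bound[i] <- 0
    }
  }
  model
}

#' Close a set of reactions
#'
#' Sets both bounds of each listed reaction to zero.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids character vector of reaction ids.
#' @return a modified copy of the model.
#' @export
knockout_reactions <- function(model, reaction_ids) {
  i <- reaction_index(model, as.character(reaction_ids))
  model$reactions$lower_bound[i] <- 0
  model$reactions$upper_bound[i] <- 0
  model
}

#' Apply a medium to a model
#'
#' Implements the standard in-silico minimal-medium procedure: the lower
#' bound of every exchange reaction is set to zero (nothing can be taken
#' up), except the exchanges named in the medium, whose lower bounds are set
#' to minus the stated uptake magnitude. Upper (secretion) bounds are left
#' untouched. Applying the same medium twice is a no-op.
#'
#' @param model a `metabolic_model`.
#' @param medium a [medium()] object or named non-negative numeric vector
#'   keyed by exchange reaction id.
#' @return a modified copy of the model.
#' @export
apply_medium <- function(model, medium) {
  if (!inherits(medium, "medium")) medium <- medium(medium)
  ex <- exchange_reactions(model)
  not_ex <- setdiff(names(medium), ex)
  if (length(not_ex))
    stop("medium key is not an exchange reaction of the model: ", not_ex[1])
  i_ex <- reaction_index(model, ex)
  model$reactions$lower_bound[i_ex] <- 0
  if (length(medium)) {
    i_med <- reaction_index(model, names(medium))
    model$reactions$lower_bound[i_med] <- -as.numeric(medium)
  }
  model
}

#' Add an interim hypothetical transporter for a cytosolic metabolite
#'
#' For a metabolite that lacks a known membrane carrier, adds (1) an
#' extracellular twin species, (2) a reversible transport reaction between
#' the extracellular and intracellular forms with no gene association, and
#' (3) an exchange reaction for the twin. All three are flagged as
#' hypothetical so a screening loop can scope them to a single
#' carbon-source simulation and drop them otherwise.
#'
#' @param model a `metabolic_model`.
#' @param metabolite_id id of an existing intracellular metabolite.
#' @param extracellular_compartment compartment id for the twin (default `"e"`).
#' @return a modified copy of the model with new ids `<met>_e_hyp`,
#'   `T_<met>_hyp` and `EX_<met>_hyp`, recorded in `model$hypothetical`.
#' @export
add_hypothetical_transporter <- function(model, metabolite_id,
                                         extracellular_compartment = "e") {
  mi <- match(metabolite_id, model$metabolites$id)
  if (is.na(mi)) stop("unknown metabolite: ", metabolite_id)
  if (model$metabolites$compartment[mi] == extracellular_compartment)
    stop(metabolite_id, " is already extracellular")
  # existing transporter = any reaction touching this metabolite and a
  # metabolite of another compartment
  for (rid in model$reactions$id) {
    sto <- model$stoichiometry[[rid]]
    if (!(metabolite_id %in% names(sto))) next
    comps <- model$metabolites$compartment[match(names(sto), model$metabolites$id)]
    if (length(unique(comps)) > 1L)
      stop("a transporter for ", metabolite_id, " already exists (", rid, ")")
  }
  ex_id <- paste0("EX_", metabolite_id, "_hyp")
  t_id <- paste0("T_", metabolite_id, "_hyp")
  twin_id <- paste0(metabolite_id, "_e_hyp")
  if (any(c(ex_id, t_id) %in% model$reactions$id))
    stop("hypothetical transporter for ", metabolite_id, " already added")
  model$metabolites <- rbind(model$metabolites, data.frame(
    id = twin_id,
    name = paste0(model$metabolites$name[mi], " (extracellular, hypothetical)"),
    compartment = extracellular_compartment,
    formula = model$metabolites$formula[mi],
    stringsAsFactors = FALSE))
  new_rxn <- data.frame(
    id = c(ex_id, t_id),
    name = c(paste0("Hypothetical exchange of ", metabolite_id),
             paste0("Hypothetical transport of ", metabolite_id)),
    lower_bound = c(0, -1000),
    upper_bound = c(1000, 1000),
    gpr = c("", ""),
    subsystem = c("Exchange", "Transport"),
    stringsAsFactors = FALSE)
  model$reactions <- rbind(model$reactions, new_rxn)
  model$stoichiometry[[ex_id]] <- stats::setNames(-1, twin_id)
  model$stoichiometry[[t_id]] <- stats::setNames(c(-1, 1), c(twin_id, metabolite_id))
  model$hypothetical <- union(model$hypothetical, c(ex_id, t_id))
  validate_model(model)
  model
}

#' Assemble the stoichiometric matrix
#'
#' Builds the sparse matrix S (metabolites in rows, reactions in columns)
#' whose entries are the signed stoichiometric coefficients, so that steady
#' state is `S %*% v == 0`.
#'
#' @param model a `metabolic_model`.
#' @param sparse return a `Matrix::sparseMatrix` (default) or base matrix.
#' @return a metabolites-by-reactions matrix with dimnames.
#' @export
build_stoich_matrix <- function(model, sparse = TRUE) {
  mids <- model$metabolites$id
  rids <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rids)) {
    sto <- model$stoichiometry[[rids[j]]]
    ii <- c(ii, match(names(sto), mids))
    jj <- c(jj, rep.int(j, length(sto)))
    xx <- c(xx, as.numeric(sto))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(mids), length(rids)),
                            dimnames = list(mids, rids))
  if (sparse) S else as.matrix(S)
}
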