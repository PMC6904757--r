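#' Construct a metabolic model
#'
#' The central container for constraint-based analysis: a stoichiometric
#' network with flux bounds, GPR rules, and a linear objective. The
#' representation is deliberately plain — two data frames, a stoichiometry
#' list, a gene vector and a named objective — so every analysis function is
#' a pure function of the model.
#'
#' Sign conventions follow the field standard: for an exchange reaction a
#' negative flux is uptake and a positive flux is secretion, so a medium that
#' allows uptake of up to `u` mmol/gDW/h sets the exchange lower bound to
#' `-u`. All bounds must be finite; where a bound is not stated, use the
#' conventional (-1000, 1000) for reversible and (0, 1000) for irreversible
#' reactions.
#'
#' @param metabolites data frame with columns `id`, `name`, `compartment`
#'   and optionally `formula` (e.g. `"C6H12O6"`, used for carbon counting).
#' @param reactions data frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gpr` (rule string, `""` for none) and optionally
#'   `subsystem`.
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of signed coefficients keyed by metabolite id (negative
#'   = consumed, positive = produced).
#' @param genes character vector of gene ids; defaults to the union of all
#'   genes referenced by the GPR rules.
#' @param objective named numeric vector of objective coefficients keyed by
#'   reaction id (typically `c(GROWTH = 1)` for the biomass pseudo-reaction).
#' @param hypothetical character vector of reaction ids flagged as interim
#'   hypothetical transport/exchange reactions (see
#'   [add_hypothetical_transporter()]).
#' @return an object of class `metabolic_model`.
#' @seealso [solve_fba()], [apply_medium()], [knockout_genes()]
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            genes = NULL, objective = numeric(),
                            hypothetical = character()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- NA_character_
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(reactions$gpr, gpr_genes)))
    if (is.null(genes)) genes <- character()
  }
  model <- structure(
    list(metabolites = metabolites,
         reactions = reactions,
         stoichiometry = stoichiometry,
         genes = as.character(genes),
         objective = objective,
         hypothetical = as.character(hypothetical)),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate the internal consistency of a metabolic model
#'
#' Checks the structural invariants every analysis relies on: unique
#' non-empty ids, non-empty compartments, `lower_bound <= upper_bound` and
#' finite bounds, non-empty stoichiometries whose keys resolve to
#' metabolites, GPR leaves that resolve to registered genes, and objective
#' keys that resolve to reactions.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met <- model$metabolites
  rxn <- model$reactions
  if (nrow(met) > 0) {
    if (any(!nzchar(met$id)) || anyNA(met$id)) stop("metabolite ids must be non-empty")
    if (anyDuplicated(met$id)) stop("duplicate metabolite id: ",
                                    met$id[duplicated(met$id)][1])
    if (any(!nzchar(met$compartment)) || anyNA(met$compartment))
      stop("metabolite compartments must be non-empty")
  }
  if (nrow(rxn) > 0) {
    if (any(!nzchar(rxn$id)) || anyNA(rxn$id)) stop("reaction ids must be non-empty")
    if (anyDuplicated(rxn$id)) stop("duplicate reaction id: ",
                                    rxn$id[duplicated(rxn$id)][1])
    bad <- rxn$lower_bound > rxn$upper_bound
    if (any(bad)) stop("lower_bound > upper_bound for reaction ", rxn$id[bad][1])
    if (any(!is.finite(rxn$lower_bound)) || any(!is.finite(rxn$upper_bound)))
      stop("flux bounds must be finite (use the +-1000 convention)")
  }
  if (!setequal(names(model$stoichiometry), rxn$id))
    stop("stoichiometry list must have exactly one entry per reaction")
  for (rid in rxn$id) {
    sto <- model$stoichiometry[[rid]]
    if (length(sto) == 0) stop("empty stoichiometry for reaction ", rid)
    missing_met <- setdiff(names(sto), met$id)
    if (length(missing_met))
      stop("reaction ", rid, " references unknown metabolite ", missing_met[1])
    leaves <- gpr_genes(rxn$gpr[rxn$id == rid])
    unknown <- setdiff(leaves, model$genes)
    if (length(unknown))
      stop("reaction ", rid, " GPR references unregistered gene ", unknown[1])
  }
  if (length(model$objective)) {
    unknown <- setdiff(names(model$objective), rxn$id)
    if (length(unknown)) stop("objective references unknown reaction ", unknown[1])
  }
  invisible(model)
}

#' Build a medium definition
#'
#' A medium maps exchange-reaction ids to non-negative uptake magnitudes
#' (mmol/gDW/h). Applying a medium sets the lower bound of every exchange
#' reaction to zero except those listed, which get lower bound `-value`;
#' secretion (upper) bounds are untouched. See [apply_medium()].
#'
#' @param ... named uptake magnitudes, or a single named numeric vector.
#' @return a named numeric vector of class `medium`.
#' @examples
#' medium(EX_glc = 1.52, EX_ac = 0.15)
#' @export
medium <- function(...) {
  args <- list(...)
  vals <- if (length(args) == 1L && is.null(names(args))) args[[1]]
          else unlist(args)
  if (is.null(vals) || length(vals) == 0) vals <- numeric()
  if (length(vals) && (is.null(names(vals)) || any(!nzchar(names(vals)))))
    stop("medium entries must be named by exchange reaction id")
  if (any(vals < 0)) stop("medium uptake magnitudes must be non-negative")
  structure(as.numeric(vals), names = names(vals), class = "medium")
}

# ---- accessors -------------------------------------------------------------

#' Exchange reactions of a model
#'
#' A reaction is an exchange (boundary) reaction when it involves exactly
#' one metabolite; the conventional `EX_` id prefix is accepted as a
#' secondary hint but the single-metabolite rule decides on conflict.
#' Reactions carrying a nonzero objective coefficient are never exchanges:
#' a biomass drain is a pseudo-reaction, not a boundary flux, even when it
#' consumes a single precursor (as small didactic networks do).
#'
#' @param model a `metabolic_model`.
#' @return character vector of exchange reaction ids.
#' @export
exchange_reactions <- function(model) {
  n_met <- vapply(model$stoichiometry[model$reactions$id], length, integer(1))
  obj <- names(model$objective)[model$objective != 0]
  setdiff(model$reactions$id[n_met == 1L], obj)
}

reaction_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) stop("unknown reaction id: ", id[is.na(i)][1])
  i
}

#' Set the bounds of one reaction
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lower,upper new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, id, lower = NULL, upper = NULL) {
  i <- reaction_index(model, id)
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  if (model$reactions$lower_bound[i] > model$reactions$upper_bound[i])
    stop("lower_bound > upper_bound for reaction ", id)
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  st <- model_stats(x)
  cat("<metabolic_model> ", st$n_reactions, " reactions, ",
      st$n_metabolites, " metabolites, ", st$n_genes, " genes (",
      st$n_exchange, " exchanges)\n", sep = "")
  if (length(x$objective)) {
    cat("  objective:", paste(sprintf("%g*%s", x$objective, names(x$objective)),
                              collapse = " + "), "\n")
  } else cat("  objective: (none)\n")
  invisible(x)
}

#' Summary statistics of a metabolic model
#'
#' Reports the counts used to characterise a reconstruction: numbers of
#' reactions, metabolites, genes and exchange reactions, plus the percentage
#' of non-exchange reactions carrying a gene association (rounded to whole
#' percent, the resolution at which such figures are conventionally quoted).
#'
#' @param model a `metabolic_model`.
#' @return a list with `n_reactions`, `n_metabolites`, `n_genes`,
#'   `n_exchange` and `pct_gene_associated_excluding_exchange`.
#' @export
model_stats <- function(model) {
  ex <- exchange_reactions(model)
  non_ex <- setdiff(model$reactions$id, ex)
  has_gpr <- nzchar(model$reactions$gpr[match(non_ex, model$reactions$id)])
  pct <- if (length(non_ex)) round(100 * sum(has_gpr) / length(non_ex)) else NA_real_
  list(n_reactions = nrow(model$reactions),
       n_metabolites = nrow(model$metabolites),
       n_genes = length(model$genes),
       n_exchange = length(ex),
       pct_gene_associated_excluding_exchange = pct)
}
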