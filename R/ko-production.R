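#' Two-stage production capacity at near-maximal growth
#'
#' The standard engineering query for a production strain: first maximise
#' biomass (stage 1, giving `mu_max`), then fix growth to at least
#' `fraction * mu_max` and maximise the flux through a target reaction
#' (stage 2). With `fraction = 1` all resources are committed to growth and
#' the divertible production is whatever the optimum leaves free; lowering
#' the fraction trades growth for product.
#'
#' @param model a `metabolic_model` with a biomass objective (after any
#'   knockouts and medium application).
#' @param target_reaction_id reaction whose flux is maximised in stage 2.
#' @param fraction required fraction of `mu_max` in (0, 1] (default 0.9).
#' @return a list of class `production_result`: `mu_max`, `production`,
#'   `fraction`, `target`, `status`. An infeasible stage 1 gives
#'   `mu_max = 0`, `production = 0`.
#' @examples
#' m <- apply_medium(make_branched_toy(), medium(EX_A = 10))
#' production_capacity(m, "EX_P", fraction = 0.9)$production  # 1
#' @export
production_capacity <- function(model, target_reaction_id, fraction = 0.9) {
  stopifnot(fraction > 0, fraction <= 1)
  idx <- reaction_index(model, target_reaction_id)
  fba <- solve_fba(model)
  if (fba$status != "optimal") {
    return(structure(list(mu_max = 0, production = 0, fraction = fraction,
                          target = target_reaction_id, status = fba$status),
                     class = "production_result"))
  }
  cvec <- objective_vector(model)
  e <- rep(0, nrow(model$reactions)); e[idx] <- 1
  stage2 <- model_lp(model, e, maximize = TRUE,
                     A_ub = matrix(-cvec, nrow = 1),
                     b_ub = -fraction * fba$objective_value)
  structure(list(mu_max = fba$objective_value,
                 production = if (stage2$status == "optimal") stage2$objval else 0,
                 fraction = fraction,
                 target = target_reaction_id,
                 status = stage2$status),
            class = "production_result")
}

#' @export
print.production_result <- function(x, ...) {
  cat(sprintf("<production_result> target %s: mu_max = %.4g 1/h, production = %.4g at >= %g%% of mu_max (%s)\n",
              x$target, x$mu_max, x$production, 100 * x$fraction, x$status))
  invisible(x)
}

#' Production panel across carbon sources for a knockout strain
#'
#' Applies a gene knockout once, then for each carbon source sets up a
#' medium with the source's measured uptake rate (e.g. estimated from
#' batch data via [uptake_series()]) on top of a common base medium, and
#' runs the two-stage [production_capacity()] simulation. The panel is
#' order-independent: each source is an independent simulation.
#'
#' @param model a `metabolic_model`.
#' @param knockouts character vector of genes to delete (may be empty for
#'   the wild type).
#' @param sources_with_uptakes named numeric vector: exchange reaction id
#'   -> uptake magnitude (mmol/gDW/h).
#' @param target_reaction target flux to maximise in stage 2.
#' @param fraction growth floor fraction (default 0.9).
#' @param base_medium common [medium()] applied in every run (default empty).
#' @return data frame: `source`, `uptake`, `mu_max`, `production`,
#'   `status`.
#' @export
carbon_source_panel <- function(model, knockouts = character(),
                                sources_with_uptakes, target_reaction,
                                fraction = 0.9, base_medium = medium()) {
  ko <- knockout_genes(model, genes = knockouts)
  rows <- lapply(names(sources_with_uptakes), function(src) {
    u <- sources_with_uptakes[[src]]
    med <- medium(stats::setNames(c(as.numeric(base_medium), u),
                                  c(names(base_medium), src)))
    pr <- production_capacity(apply_medium(ko, med), target_reaction, fraction)
    data.frame(source = src, uptake = u, mu_max = pr$mu_max,
               production = pr$production, status = pr$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dose-response scan of a forced uptake flux
#'
#' Probes growth sensitivity to a compound (e.g. a toxin such as
#' formaldehyde) by forcing its uptake at each value of an increasing grid
#' — both bounds of the exchange reaction are pinned to `-dose`, so uptake
#' is obligatory, not optional (a free lower bound would let the optimiser
#' ignore the compound entirely) — and solving FBA at each step. If the
#' compound's extracellular metabolite has no exchange reaction, one is
#' added first. The rest of the medium (e.g. the glucose bound) is taken
#' from the model as passed and held fixed across the grid.
#'
#' A flat biomass curve means the network can only dispose of the compound
#' without metabolic cost; an increasing curve reveals assimilation into
#' biomass; an infeasible status marks doses beyond the network's disposal
#' capacity.
#'
#' @param model a `metabolic_model`, medium already applied.
#' @param exchange_id exchange reaction of the dosed compound; if missing
#'   from the model and `metabolite_id` is given, an exchange is added.
#' @param grid strictly increasing non-negative dose values, mmol/gDW/h.
#' @param metabolite_id extracellular metabolite for which to create the
#'   exchange when `exchange_id` is absent from the model.
#' @return a data frame of class `dose_response_curve`: `dose`, `biomass`,
#'   `status`.
#' @export
dose_response_scan <- function(model, exchange_id, grid, metabolite_id = NULL) {
  stopifnot(length(grid) >= 1, all(grid >= 0))
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (!(exchange_id %in% model$reactions$id)) {
    if (is.null(metabolite_id))
      stop("exchange ", exchange_id, " not in model; supply metabolite_id to add it")
    mi <- match(metabolite_id, model$metabolites$id)
    if (is.na(mi)) stop("unknown metabolite: ", metabolite_id)
    model$reactions <- rbind(model$reactions, data.frame(
      id = exchange_id, name = paste("exchange of", metabolite_id),
      lower_bound = 0, upper_bound = 1000, gpr = "", subsystem = "Exchange",
      stringsAsFactors = FALSE))
    model$stoichiometry[[exchange_id]] <- stats::setNames(-1, metabolite_id)
    validate_model(model)
  }
  rows <- lapply(grid, function(d) {
    m <- set_bounds(model, exchange_id, lower = -d, upper = -d)
    fba <- solve_fba(m)
    data.frame(dose = d,
               biomass = if (fba$status == "optimal") fba$objective_value else NA_real_,
               status = fba$status, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), exchange = exchange_id,
            class = c("dose_response_curve", "data.frame"))
}
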