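#' Screen growth on sole carbon sources
#'
#' Emulates a phenotype-microarray comparison in silico: for every carbon
#' source an independent simulation is run on the base (salts) medium with
#' only that source's exchange opened to `uptake_bound`, and growth is
#' called when the FBA objective exceeds `growth_threshold` (a small
#' positive cutoff so solver noise never counts as growth).
#'
#' Sources are identified by metabolite id. When a source metabolite exists
#' only intracellularly (no exchange reaction reaches it) and
#' `allow_hypothetical` is `TRUE`, an interim hypothetical transporter is
#' added for that single run and the call is flagged; with
#' `allow_hypothetical = FALSE` such sources are simply called no-growth.
#' A source metabolite absent from the model is recorded as no-growth with
#' reason `"absent"`.
#'
#' @param model a `metabolic_model` with a biomass objective.
#' @param base_medium a [medium()] of non-carbon components; must not
#'   contain any exchange of a source under test.
#' @param sources character vector of source metabolite ids (extracellular
#'   or intracellular).
#' @param uptake_bound uptake magnitude for the source under test,
#'   mmol/gDW/h (default 5).
#' @param growth_threshold growth call cutoff on the objective, 1/h
#'   (default 1e-6).
#' @param allow_hypothetical add scoped hypothetical transporters for
#'   transporter-less sources (default FALSE).
#' @return a data frame of class `phenotype_calls`: `source`, `predicted`,
#'   `used_hypothetical_transporter`, `objective`, `reason`.
#' @export
screen_carbon_sources <- function(model, base_medium = medium(), sources,
                                  uptake_bound = 5, growth_threshold = 1e-6,
                                  allow_hypothetical = FALSE) {
  stopifnot(uptake_bound >= 0, growth_threshold >= 0)
  rows <- lapply(sources, function(src) {
    call <- list(source = src, predicted = FALSE,
                 used_hypothetical_transporter = FALSE,
                 objective = 0, reason = "")
    if (!(src %in% model$metabolites$id)) {
      call$reason <- "absent"
      return(as.data.frame(call, stringsAsFactors = FALSE))
    }
    m <- model
    ex_id <- find_exchange_for(m, src)
    if (is.null(ex_id)) {
      if (!allow_hypothetical) {
        call$reason <- "no transporter"
        return(as.data.frame(call, stringsAsFactors = FALSE))
      }
      m <- add_hypothetical_transporter(m, src)
      ex_id <- paste0("EX_", src, "_hyp")
      call$used_hypothetical_transporter <- TRUE
    }
    med <- medium(stats::setNames(c(as.numeric(base_medium), uptake_bound),
                                  c(names(base_medium), ex_id)))
    fba <- solve_fba(apply_medium(m, med))
    call$objective <- if (fba$status == "optimal") fba$objective_value else 0
    call$predicted <- fba$status == "optimal" &&
      fba$objective_value > growth_threshold
    as.data.frame(call, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("phenotype_calls", "data.frame"))
}

# Exchange reaction whose metabolite is `met` itself, or whose metabolite is
# connected to `met` by a transport reaction (a reaction spanning
# compartments). Returns NULL when the metabolite is unreachable from the
# boundary.
find_exchange_for <- function(model, met) {
  ex <- exchange_reactions(model)
  for (rid in ex) {
    ex_met <- names(model$stoichiometry[[rid]])
    if (ex_met == met) return(rid)
    # transported twin: a reaction containing both ex_met and met
    for (tid in setdiff(model$reactions$id, ex)) {
      sto <- names(model$stoichiometry[[tid]])
      if (ex_met %in% sto && met %in% sto) return(rid)
    }
  }
  NULL
}

#' Concordance between predicted and observed growth calls
#'
#' Confusion counts and accuracy for a screen against experimental binary
#' growth calls, plus the list of discrepant sources (ordered by source id).
#'
#' @param calls a `phenotype_calls` data frame from
#'   [screen_carbon_sources()], or any data frame with `source` and
#'   `predicted` columns.
#' @param observed named logical (or 0/1) vector keyed by source id;
#'   sources without an observation are excluded from the counts.
#' @return a list of class `concordance_report`: `tp`, `tn`, `fp`, `fn`,
#'   `n`, `accuracy` (percent), `discrepancies` (character).
#' @export
compare_calls <- function(calls, observed) {
  obs_names <- names(observed)
  if (is.null(obs_names)) stop("observed must be named by source id")
  keep <- calls$source %in% obs_names
  pred <- calls$predicted[keep]
  src <- calls$source[keep]
  obs <- as.logical(observed[src])
  tp <- sum(pred & obs); tn <- sum(!pred & !obs)
  fp <- sum(pred & !obs); fn <- sum(!pred & obs)
  n <- length(src)
  disc <- sort(src[pred != obs])
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, n = n,
                 accuracy = if (n > 0) 100 * (tp + tn) / n else NA_real_,
                 discrepancies = disc),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d/%d concordant (accuracy %.1f%%)\n",
              x$tp + x$tn, x$n, x$accuracy))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n", x$tp, x$tn, x$fp, x$fn))
  if (length(x$discrepancies))
    cat("  discrepant:", paste(x$discrepancies, collapse = ", "), "\n")
  invisible(x)
}
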