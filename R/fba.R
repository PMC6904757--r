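#' Flux balance analysis
#'
#' Solves the canonical FBA linear program: maximise the objective
#' `Z = sum_j c_j v_j` subject to steady state (`S v = 0`) and the
#' reaction flux bounds. With a biomass objective, `Z` approximates the
#' specific growth rate in 1/h; all other fluxes are in mmol/gDW/h.
#'
#' When alternate optima exist the returned flux distribution is the
#' solver's vertex; use [min_total_flux()] when a unique, parsimonious
#' distribution is needed downstream (e.g. for flux-sum analysis).
#'
#' @param model a `metabolic_model` with a non-empty objective.
#' @return an object of class `fba_result`: `objective_value`, `fluxes`
#'   (named numeric over all reactions), and `status` (`"optimal"` or
#'   `"infeasible"`; finite bounds preclude unbounded problems).
#'   Infeasibility is returned as a status, never raised.
#' @examples
#' m <- apply_medium(make_toy_core(), medium(EX_A = 10))
#' solve_fba(m)$objective_value  # 20
#' @export
solve_fba <- function(model) {
  validate_model(model)
  if (!length(model$objective)) stop("model has no objective")
  res <- model_lp(model, objective_vector(model), maximize = TRUE)
  fluxes <- stats::setNames(res$x, model$reactions$id)
  structure(list(objective_value = if (res$status == "optimal") res$objval else NA_real_,
                 fluxes = fluxes,
                 status = res$status),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result> status:", x$status)
  if (x$status == "optimal") cat("  Z =", format(x$objective_value, digits = 8))
  cat("\n")
  invisible(x)
}

# Shared scaffolding: optimal objective value and the inequality row
# enforcing c'v >= fraction * Z*.
objective_floor <- function(model, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  fba <- solve_fba(model)
  if (fba$status != "optimal")
    stop("cannot constrain the objective: FBA status is ", fba$status)
  cvec <- objective_vector(model)
  list(zstar = fba$objective_value, cvec = cvec,
       # c'v >= f Z*  <=>  -c'v <= -f Z*
       A_ub = matrix(-cvec, nrow = 1),
       b_ub = -fraction * fba$objective_value,
       fba = fba)
}

#' Minimum-total-flux distribution
#'
#' Among all flux distributions reaching at least `fraction` of the FBA
#' optimum, returns one minimising the total absolute flux
#' `sum_j |v_j|`. This is the standard disambiguation of alternate FBA
#' optima: futile cycles carry zero flux because they only add `|v|`, and
#' the distribution is the parsimonious one used for flux-sum turnover.
#' Implemented by the usual split `v = p - q`, `p, q >= 0`, minimising
#' `sum(p + q)`.
#'
#' @param model a `metabolic_model` with a non-empty objective.
#' @param fraction required fraction of the FBA optimum in (0, 1];
#'   default 1 (hold the objective at its optimum).
#' @return named numeric flux vector over all reactions.
#' @export
min_total_flux <- function(model, fraction = 1) {
  fl <- objective_floor(model, fraction)
  n <- nrow(model$reactions)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  S <- as.matrix(build_stoich_matrix(model, sparse = FALSE))
  # variables (p, q): v = p - q with p in [0, max(ub,0)], q in [0, max(-lb,0)]
  A_eq <- cbind(S, -S)
  b_eq <- rep(0, nrow(S))
  # box: p - q must also respect lb <= v <= ub
  A_ub <- rbind(cbind(diag(n), -diag(n)),              # v <= ub
                cbind(-diag(n), diag(n)),              # -v <= -lb
                matrix(c(-fl$cvec, fl$cvec), nrow = 1))  # -c'v <= -f Z*
  b_ub <- c(ub, -lb, fl$b_ub)
  obj <- rep(1, 2 * n)
  res <- solve_lp(obj, A_eq = A_eq, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub,
                  lb = rep(0, 2 * n),
                  ub = c(pmax(ub, 0), pmax(-lb, 0)),
                  maximize = FALSE)
  if (res$status != "optimal")
    stop("min_total_flux LP did not solve: ", res$status)
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  stats::setNames(v, model$reactions$id)
}

#' Flux variability analysis
#'
#' For every reaction, computes the minimum and maximum flux attainable
#' while steady state, the bounds, and an objective floor
#' `c'v >= fraction * Z*` hold (`Z*` from FBA). `fraction = 1` gives
#' classical FVA at the optimum; `fraction = 0.9` is the usual
#' "suboptimal" FVA that tolerates up to 10% growth loss. Two LPs are
#' solved per reaction.
#'
#' Endpoints that sit on the reaction's own bound are flagged as
#' bound-limited (`min_at_bound` / `max_at_bound`): the flux is
#' unconstrained by the network there and the reported endpoint is just
#' the box bound (the conventional +-1000).
#'
#' @param model a `metabolic_model` with a non-empty objective.
#' @param fraction required fraction of the FBA optimum in (0, 1].
#' @param reactions reaction ids to analyse (default: all).
#' @param tol tolerance for the bound-limited flags.
#' @return an object of class `fva_result`: a data frame with columns
#'   `reaction`, `min`, `max`, `min_at_bound`, `max_at_bound`, and
#'   attributes `fraction` and `objective_value`.
#' @export
fva <- function(model, fraction = 0.9, reactions = NULL, tol = 1e-6) {
  fl <- objective_floor(model, fraction)
  if (is.null(reactions)) reactions <- model$reactions$id
  idx <- reaction_index(model, reactions)
  n <- nrow(model$reactions)
  lo <- hi <- numeric(length(idx))
  for (k in seq_along(idx)) {
    e <- rep(0, n); e[idx[k]] <- 1
    rmin <- model_lp(model, e, maximize = FALSE, A_ub = fl$A_ub, b_ub = fl$b_ub)
    rmax <- model_lp(model, e, maximize = TRUE, A_ub = fl$A_ub, b_ub = fl$b_ub)
    if (rmin$status != "optimal" || rmax$status != "optimal")
      stop("FVA LP failed for reaction ", reactions[k], " (", rmin$status, "/",
           rmax$status, ")")
    lo[k] <- rmin$objval; hi[k] <- rmax$objval
  }
  out <- data.frame(reaction = reactions, min = lo, max = hi,
                    min_at_bound = lo <= model$reactions$lower_bound[idx] + tol,
                    max_at_bound = hi >= model$reactions$upper_bound[idx] - tol,
                    stringsAsFactors = FALSE)
  structure(out, fraction = fraction, objective_value = fl$zstar,
            class = c("fva_result", "data.frame"))
}

#' @export
print.fva_result <- function(x, ...) {
  cat("<fva_result> fraction =", attr(x, "fraction"),
      " Z* =", format(attr(x, "objective_value"), digits = 8), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more reactions)\n", sep = "")
  invisible(x)
}

#' Normalise fluxes or flux intervals to a reference reaction
#'
#' Expresses fluxes as percentages of the magnitude of a reference flux —
#' conventionally the glucose uptake flux, so a value of 100 means a flux
#' equal in magnitude to glucose uptake. Intervals are mapped endpoint-wise
#' and endpoint order is preserved.
#'
#' @param x a named numeric vector of fluxes, or an `fva_result`.
#' @param reference_flux the reference flux value (its absolute value is
#'   used); must be nonzero.
#' @return object of the same shape with values in percent.
#' @export
normalize_to_reference <- function(x, reference_flux) {
  if (abs(reference_flux) <= 0) stop("reference flux magnitude must be > 0")
  f <- 100 / abs(reference_flux)
  if (inherits(x, "fva_result")) {
    x$min <- x$min * f
    x$max <- x$max * f
    x
  } else {
    x * f
  }
}

#' Does a flux value fall inside an FVA interval?
#'
#' The containment check used to confront measured fluxes (e.g. from
#' 13C labelling experiments) with the variability interval predicted at a
#' given objective fraction.
#'
#' @param fva an `fva_result`.
#' @param reaction_id reaction to look up.
#' @param value observed flux (same units/normalisation as the intervals).
#' @param tol slack added on both sides (default 1e-6).
#' @return logical scalar.
#' @export
interval_contains <- function(fva, reaction_id, value, tol = 1e-6) {
  i <- match(reaction_id, fva$reaction)
  if (is.na(i)) stop("reaction not in FVA result: ", reaction_id)
  value >= fva$min[i] - tol && value <= fva$max[i] + tol
}
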