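#' Flux-sum (metabolite turnover) of a flux distribution
#'
#' The flux-sum of metabolite i is `phi_i = 0.5 * sum_j |S_ij * v_j|`. At
#' steady state production and consumption of every metabolite balance, so
#' phi equals the total production rate (= total consumption rate) of the
#' metabolite — its turnover through the network, in mmol/gDW/h.
#'
#' Because FBA optima are generally non-unique, a parsimonious distribution
#' from [min_total_flux()] should be supplied; futile cycles would otherwise
#' inflate turnover arbitrarily.
#'
#' @param model a `metabolic_model`.
#' @param dist named flux vector over the model's reactions (e.g. from
#'   [min_total_flux()] or an `fba_result$fluxes`).
#' @param check_steady_state verify `max |S v|` <= `tol` first (default TRUE).
#' @param tol steady-state tolerance (default 1e-6).
#' @return an object of class `flux_sum_result`: named numeric `phi` over
#'   metabolites plus the distribution used, as attribute `fluxes`.
#' @examples
#' m <- apply_medium(make_toy_core(), medium(EX_A = 10))
#' compute_flux_sum(m, min_total_flux(m))
#' @export
compute_flux_sum <- function(model, dist, check_steady_state = TRUE, tol = 1e-6) {
  if (inherits(dist, "fba_result")) dist <- dist$fluxes
  if (!setequal(names(dist), model$reactions$id))
    stop("flux distribution keys must match the model's reactions exactly")
  dist <- dist[model$reactions$id]
  S <- build_stoich_matrix(model, sparse = FALSE)
  if (check_steady_state) {
    imbalance <- max(abs(S %*% dist))
    if (imbalance > tol)
      stop(sprintf("distribution violates steady state (max |S v| = %.3g > %.3g)",
                   imbalance, tol))
  }
  phi <- 0.5 * rowSums(abs(S * rep(dist, each = nrow(S))))
  structure(stats::setNames(as.numeric(phi), rownames(S)),
            fluxes = dist, class = "flux_sum_result")
}

#' @export
print.flux_sum_result <- function(x, ...) {
  cat("<flux_sum_result>", length(x), "metabolites; top turnover:\n")
  v <- sort(unclass(x), decreasing = TRUE)
  print(utils::head(v, 5))
  invisible(x)
}

#' Carbon atoms per molecule from a chemical formula
#'
#' Parses element counts out of a Hill-style formula string (`"C6H12O6"` ->
#' 6). Carbon must be the element C itself, not part of a two-letter symbol
#' (Co, Ca, Cl, ... are not counted).
#'
#' @param formula character vector of formulas.
#' @return integer vector of carbon counts (`NA` where the formula is
#'   missing or carbon-free formulas give 0).
#' @export
carbon_count <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_integer_)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    starts <- as.integer(m); lens <- attr(m, "match.length")
    total <- 0L
    for (k in seq_along(starts)) {
      tok <- substr(f, starts[k], starts[k] + lens[k] - 1L)
      el <- sub("[0-9]*$", "", tok)
      cnt <- sub("^[A-Za-z]+", "", tok)
      if (el == "C") total <- total + if (nzchar(cnt)) as.integer(cnt) else 1L
    }
    total
  }, integer(1), USE.NAMES = FALSE)
}

#' Flux-sum profile across carbon sources
#'
#' Compares metabolite turnover across alternative sole carbon sources on
#' an equal-carbon basis: each source's uptake is limited to
#' `carbon_basis / (carbon atoms per molecule)` mmol/gDW/h, i.e.
#' `carbon_basis` mmol carbon/gDW/h regardless of molecule size (glucose
#' with 6 carbons gets 1/6 at the default basis of 1). Per source the model
#' is solved by FBA, the parsimonious distribution is taken at
#' `fraction` of the optimum via [min_total_flux()], and flux-sums are
#' assembled into a metabolites-by-sources matrix.
#'
#' @param model a `metabolic_model`.
#' @param base_medium a [medium()] of non-carbon components applied to every
#'   run (may be empty).
#' @param carbon_sources character vector of exchange reaction ids, one per
#'   source.
#' @param carbon_basis carbon uptake basis, mmol carbon/gDW/h (default 1).
#' @param carbon_counts optional named integer vector (per exchange id)
#'   overriding formula-derived carbon counts.
#' @param fraction objective fraction passed to [min_total_flux()]
#'   (default 1).
#' @return an object of class `flux_sum_profile`: matrix `phi` (metabolites
#'   x sources) with attribute `uptake_bounds`.
#' @export
flux_sum_profile <- function(model, base_medium = medium(), carbon_sources,
                             carbon_basis = 1, carbon_counts = NULL,
                             fraction = 1) {
  stopifnot(length(carbon_sources) >= 1)
  ex <- exchange_reactions(model)
  bad <- setdiff(carbon_sources, ex)
  if (length(bad)) stop("not an exchange reaction: ", bad[1])
  counts <- numeric(length(carbon_sources))
  for (k in seq_along(carbon_sources)) {
    rid <- carbon_sources[k]
    if (!is.null(carbon_counts) && rid %in% names(carbon_counts)) {
      counts[k] <- carbon_counts[[rid]]
    } else {
      met <- names(model$stoichiometry[[rid]])
      cc <- carbon_count(model$metabolites$formula[match(met, model$metabolites$id)])
      if (is.na(cc) || cc <= 0)
        stop("carbon count unknown for source ", rid, " (metabolite ", met,
             "); supply carbon_counts")
      counts[k] <- cc
    }
  }
  bounds <- carbon_basis / counts
  cols <- lapply(seq_along(carbon_sources), function(k) {
    med <- medium(stats::setNames(c(as.numeric(base_medium), bounds[k]),
                                  c(names(base_medium), carbon_sources[k])))
    m2 <- apply_medium(model, med)
    dist <- min_total_flux(m2, fraction = fraction)
    as.numeric(compute_flux_sum(m2, dist))
  })
  phi <- do.call(cbind, cols)
  dimnames(phi) <- list(model$metabolites$id, carbon_sources)
  structure(list(phi = phi,
                 uptake_bounds = stats::setNames(bounds, carbon_sources),
                 normalized = FALSE),
            class = "flux_sum_profile")
}

#' Row-normalise a flux-sum profile
#'
#' Divides each metabolite's row by its maximum across sources, so every
#' row has maximum 1 (all-zero rows stay zero) — the scaling used to
#' compare turnover patterns across carbon sources on a common colour
#' scale. Idempotent.
#'
#' @param profile a `flux_sum_profile`.
#' @return the profile with `phi` row-normalised and `normalized = TRUE`.
#' @export
normalize_rows <- function(profile) {
  stopifnot(inherits(profile, "flux_sum_profile"))
  mx <- apply(profile$phi, 1, max)
  scale <- ifelse(mx > 0, 1 / mx, 0)
  profile$phi <- profile$phi * scale
  profile$normalized <- TRUE
  profile
}

#' @export
print.flux_sum_profile <- function(x, ...) {
  cat("<flux_sum_profile> ", nrow(x$phi), " metabolites x ", ncol(x$phi),
      " sources", if (x$normalized) " (row-normalised)", "\n", sep = "")
  print(utils::head(x$phi, 8))
  invisible(x)
}
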