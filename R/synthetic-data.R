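#' Four-reaction toy network with a known optimum
#'
#' The smallest fixture exercising the whole stack: an exchange `EX_A`
#' (bounds -10..1000), a gene-gated transport `T_A` (`A_e -> A_c`, GPR
#' `g1`), a carbon-doubling conversion `R1` (`A_c -> 2 B_c`, GPR
#' `(g2 and g3) or g4`) and a biomass drain `GROWTH` (`B_c ->`, objective
#' coefficient 1). At the default uptake of 10 the hand-solved LP optimum is
#' Z = 20: uptake 10, transport 10, conversion 10, growth 20.
#'
#' @return a `metabolic_model`.
#' @export
make_toy_core <- function() {
  metabolites <- data.frame(
    id = c("A_e", "A_c", "B_c"),
    name = c("substrate A (extracellular)", "substrate A (cytosol)",
             "biomass precursor B"),
    compartment = c("e", "c", "c"),
    formula = c("C3", "C3", "C3"),
    stringsAsFactors = FALSE)
  reactions <- data.frame(
    id = c("EX_A", "T_A", "R1", "GROWTH"),
    name = c("A exchange", "A transport", "A to 2B conversion", "biomass drain"),
    lower_bound = c(-10, 0, 0, 0),
    upper_bound = c(1000, 1000, 1000, 1000),
    gpr = c("", "g1", "(g2 and g3) or g4", ""),
    subsystem = c("Exchange", "Transport", "Core", "Biomass"),
    stringsAsFactors = FALSE)
  stoich <- list(
    EX_A = c(A_e = -1),
    T_A = c(A_e = -1, A_c = 1),
    R1 = c(A_c = -1, B_c = 2),
    GROWTH = c(B_c = -1))
  metabolic_model(metabolites, reactions, stoich,
                  genes = c("g1", "g2", "g3", "g4"),
                  objective = c(GROWTH = 1))
}

#' Branched toy network for production simulations
#'
#' Extends [make_toy_core()] with a product branch: `R2` converts `A_c` to
#' the product `P_c` (gated by gene `g5`) and `EX_P` secretes it. Carbon
#' taken up (10 mmol/gDW/h of A) can go to biomass (via `R1`, yielding 2
#' growth units per A) or product (1 P per A), so with the biomass floor at
#' a fraction `f` of the maximum growth 20, the divertible product flux is
#' `10 * (1 - f)`: 0 at f = 1, 1 at f = 0.9, 5 at f = 0.5.
#'
#' @return a `metabolic_model`.
#' @export
make_branched_toy <- function() {
  m <- make_toy_core()
  m$metabolites <- rbind(m$metabolites, data.frame(
    id = "P_c", name = "product P", compartment = "c", formula = "C3",
    stringsAsFactors = FALSE))
  m$reactions <- rbind(m$reactions, data.frame(
    id = c("R2", "EX_P"),
    name = c("A to P branch", "P secretion"),
    lower_bound = c(0, 0),
    upper_bound = c(1000, 1000),
    gpr = c("g5", ""),
    subsystem = c("Core", "Exchange"),
    stringsAsFactors = FALSE))
  m$stoichiometry$R2 <- c(A_c = -1, P_c = 1)
  m$stoichiometry$EX_P <- c(P_c = -1)
  m$genes <- union(m$genes, "g5")
  validate_model(m)
  m
}

#' Random viable network with a planted flux vector
#'
#' Generates a random sparse stoichiometric network that is feasible by
#' construction: a strictly positive "planted" flux vector is drawn first
#' and each reaction's random stoichiometry is balanced against it, so the
#' planted vector satisfies `S v = 0` exactly. Bounds are drawn to contain
#' the planted vector, one reaction is designated the objective, and the
#' planted objective value is a certified lower bound on the LP optimum.
#' Everything is a pure function of the seed.
#'
#' @param n_metabolites,n_reactions network size; `n_reactions >=
#'   n_metabolites >= 2`.
#' @param seed integer RNG seed (mandatory; no global RNG state is used).
#' @return a list of class `planted_network`: `model`, `planted_fluxes`
#'   (named), `planted_objective`, `seed`.
#' @export
random_viable_network <- function(n_metabolites = 4, n_reactions = 6, seed) {
  if (missing(seed)) stop("seed is a mandatory argument")
  stopifnot(n_reactions >= n_metabolites, n_metabolites >= 2)
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    mids <- sprintf("M%02d", seq_len(n_metabolites))
    rids <- sprintf("R%02d", seq_len(n_reactions))
    v <- round(stats::runif(n_reactions, 0.5, 5), 3)
    # build S column by column; track the running imbalance b = S v so the
    # last reaction can cancel it and keep the planted vector at steady state
    S <- matrix(0, n_metabolites, n_reactions, dimnames = list(mids, rids))
    for (j in seq_len(n_reactions - 1L)) {
      k <- sample(2:min(3, n_metabolites), 1)
      rows <- sample(n_metabolites, k)
      S[rows, j] <- round(stats::runif(k, -2, 2), 2)
    }
    resid <- as.vector(S[, seq_len(n_reactions - 1L), drop = FALSE] %*%
                         v[seq_len(n_reactions - 1L)])
    S[, n_reactions] <- -resid / v[n_reactions]
    # drop all-zero columns' risk: ensure last column nonzero
    if (all(abs(S[, n_reactions]) < 1e-12)) S[1, n_reactions] <- 0  # keep zero, fixed below
    for (j in seq_len(n_reactions)) {
      if (all(abs(S[, j]) < 1e-12)) {
        # give the reaction a self-cancelling pair so stoichiometry is
        # non-empty while preserving S v = 0 (coefficients are zero)
        S[1, j] <- 0
      }
    }
    lb <- round(v - stats::runif(n_reactions, 0.5, 3), 3)
    ub <- round(v + stats::runif(n_reactions, 0.5, 3), 3)
    list(mids = mids, rids = rids, v = v, S = S, lb = lb, ub = ub)
  })
  S <- rng$S
  # stoichiometry entries must be non-empty; include explicit zeros where a
  # column cancelled out entirely (rare, seed-dependent)
  stoich <- lapply(seq_along(rng$rids), function(j) {
    nz <- which(abs(S[, j]) > 1e-12)
    if (!length(nz)) nz <- 1L
    stats::setNames(S[nz, j], rng$mids[nz])
  })
  names(stoich) <- rng$rids
  obj_rxn <- rng$rids[length(rng$rids)]
  model <- metabolic_model(
    metabolites = data.frame(id = rng$mids, name = rng$mids,
                             compartment = "c", stringsAsFactors = FALSE),
    reactions = data.frame(id = rng$rids, name = rng$rids,
                           lower_bound = rng$lb, upper_bound = rng$ub,
                           gpr = "", stringsAsFactors = FALSE),
    stoichiometry = stoich,
    genes = character(),
    objective = stats::setNames(1, obj_rxn))
  structure(list(model = model,
                 planted_fluxes = stats::setNames(rng$v, rng$rids),
                 planted_objective = rng$v[length(rng$v)],
                 seed = seed),
            class = "planted_network")
}

#' Closed-form batch culture simulator
#'
#' Simulates exponential growth at constant specific growth rate `mu` with
#' constant biomass-specific substrate flux `v_substrate` (negative =
#' consumption, matching the exchange convention):
#' `x(t) = x0 * exp(mu * t)` and, over each interval,
#' `C[i+1] = C[i] + v_substrate * x[i] * (exp(mu * dt[i]) - 1) / mu`.
#' This is the exact closed form whose interval-wise inversion is
#' [growth_rate_series()] and [uptake_series()], so parameter recovery from
#' simulated data is exact to machine precision.
#'
#' @param mu specific growth rate, 1/h (> 0).
#' @param v_substrate biomass-specific substrate flux, mmol/gDW/h
#'   (negative for consumption).
#' @param x0 initial biomass, gDW/L (> 0).
#' @param C0 initial substrate, mmol/L (must stay non-negative over the
#'   requested times).
#' @param times strictly increasing time grid, h.
#' @return a `batch_time_course` (see [batch_time_course()]).
#' @export
simulate_batch <- function(mu, v_substrate, x0, C0, times) {
  stopifnot(mu > 0, x0 > 0, length(times) >= 2, all(diff(times) > 0))
  x <- x0 * exp(mu * times)
  C <- numeric(length(times))
  C[1] <- C0
  for (i in seq_len(length(times) - 1L)) {
    dt <- times[i + 1L] - times[i]
    C[i + 1L] <- C[i] + v_substrate * x[i] * (exp(mu * dt) - 1) / mu
  }
  if (any(C < -1e-9))
    stop("substrate is exhausted before the last time point; increase C0")
  batch_time_course(times, x, pmax(C, 0))
}

#' Brute-force LP oracle by vertex enumeration
#'
#' Independent check for [solve_fba()] on small networks (<= 8 reactions):
#' every vertex of the flux polytope has at least `n - rank(S)` fluxes
#' pinned at a bound, so the oracle enumerates all such pinnings, solves the
#' remaining square steady-state system, keeps feasible points and returns
#' the best objective value. Exponential in the reaction count; intended
#' only for tests.
#'
#' @param model a `metabolic_model` with <= 8 reactions and a non-empty
#'   objective.
#' @param tol feasibility tolerance.
#' @return list with `objective_value` (`-Inf` when no feasible vertex
#'   exists) and `fluxes` at the best vertex (or `NULL`).
#' @export
brute_force_lp_oracle <- function(model, tol = 1e-7) {
  n <- nrow(model$reactions)
  if (n > 8) stop("oracle is restricted to models with <= 8 reactions")
  S <- as.matrix(build_stoich_matrix(model, sparse = FALSE))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  cvec <- objective_vector(model)
  r <- if (nrow(S)) qr(S)$rank else 0L
  n_fix <- n - r
  best <- -Inf; best_v <- NULL
  consider <- function(v) {
    if (is.null(v)) return()
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    if (nrow(S) && max(abs(S %*% v)) > tol * max(1, max(abs(v)))) return()
    z <- sum(cvec * v)
    if (z > best) { best <<- z; best_v <<- v }
  }
  fixed_sets <- if (n_fix == 0) list(integer(0)) else
    utils::combn(n, n_fix, simplify = FALSE)
  for (fix in fixed_sets) {
    free <- setdiff(seq_len(n), fix)
    # each fixed flux at lower or upper bound
    grids <- rep(list(c(1L, 2L)), length(fix))
    combos <- if (length(fix)) expand.grid(grids) else data.frame(row.names = 1)
    for (ci in seq_len(nrow(combos))) {
      v <- numeric(n)
      if (length(fix)) {
        side <- as.integer(combos[ci, ])
        v[fix] <- ifelse(side == 1L, lb[fix], ub[fix])
      }
      if (length(free)) {
        A <- S[, free, drop = FALSE]
        b <- if (length(fix)) -S[, fix, drop = FALSE] %*% v[fix] else rep(0, nrow(S))
        sol <- tryCatch(qr.solve(A, b, tol = 1e-10), error = function(e) NULL)
        if (is.null(sol)) next
        # qr.solve gives a least-squares answer for rank-deficient A; only a
        # true solution is a vertex candidate
        if (max(abs(A %*% sol - b)) > tol) next
        v[free] <- as.numeric(sol)
      }
      consider(v)
    }
  }
  list(objective_value = best,
       fluxes = if (is.null(best_v)) NULL else
         stats::setNames(best_v, model$reactions$id))
}

#' Toxin-dosing toy networks
#'
#' Two minimal fixtures for dose-response scans, built on
#' [make_toy_core()] with a dosed compound `F_c`:
#' \itemize{
#'   \item `make_detox_toy()` gives `F_c` only a degradation sink
#'     (`SINK_F`, capacity-limited via `capacity`): forced uptake costs the
#'     network nothing, so biomass stays flat until the dose exceeds the
#'     sink capacity, where the problem turns infeasible.
#'   \item `make_assimilating_toy()` additionally converts `F_c` into the
#'     biomass precursor (`ASSIM`): biomass rises monotonically with dose.
#' }
#' Together they restate, at fixture scale, the qualitative contrast
#' between a model that merely tolerates a compound and one that
#' co-metabolises it.
#'
#' @param capacity upper bound of the degradation sink, mmol/gDW/h
#'   (default 1000, i.e. effectively unlimited).
#' @return a `metabolic_model` (medium not yet applied).
#' @export
make_detox_toy <- function(capacity = 1000) {
  m <- make_toy_core()
  m$metabolites <- rbind(m$metabolites, data.frame(
    id = "F_c", name = "dosed compound", compartment = "c", formula = "C1",
    stringsAsFactors = FALSE))
  m$reactions <- rbind(m$reactions, data.frame(
    id = "SINK_F", name = "degradation sink", lower_bound = 0,
    upper_bound = capacity, gpr = "", subsystem = "Detox",
    stringsAsFactors = FALSE))
  m$stoichiometry$SINK_F <- c(F_c = -1)
  validate_model(m)
  m
}

#' @rdname make_detox_toy
#' @export
make_assimilating_toy <- function(capacity = 1000) {
  m <- make_detox_toy(capacity)
  m$reactions <- rbind(m$reactions, data.frame(
    id = "ASSIM", name = "assimilation into biomass precursor",
    lower_bound = 0, upper_bound = 1000, gpr = "", subsystem = "Core",
    stringsAsFactors = FALSE))
  m$stoichiometry$ASSIM <- c(F_c = -1, B_c = 1)
  validate_model(m)
  m
}
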