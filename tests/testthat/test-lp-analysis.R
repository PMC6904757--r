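test_that("FBA reproduces hand-solved optima on the toy fixtures", {
  m <- apply_medium(make_toy_core(), medium(EX_A = 10))
  f <- solve_fba(m)
  expect_equal(f$status, "optimal")
  expect_equal(f$objective_value, 20, tolerance = 1e-9)
  # optimal distribution is at steady state and within bounds
  expect_lt(steady_state_error(m, f$fluxes), 1e-6)
  expect_true(all(f$fluxes >= m$reactions$lower_bound - 1e-9))
  expect_true(all(f$fluxes <= m$reactions$upper_bound + 1e-9))

  expect_equal(solve_fba(apply_medium(make_toy_core(), medium()))$objective_value, 0)
  expect_error(solve_fba(metabolic_model(
    data.frame(id = "X", name = "X", compartment = "c"),
    data.frame(id = "R", name = "R", lower_bound = 0, upper_bound = 1, gpr = ""),
    list(R = c(X = -1)))), "no objective")
})

test_that("FBA agrees with the vertex-enumeration oracle on 50 seeded networks", {
  for (s in 1:50) {
    pn <- random_viable_network(4, 6, seed = s)
    f <- solve_fba(pn$model)
    o <- brute_force_lp_oracle(pn$model)
    expect_equal(f$status, "optimal", info = paste("seed", s))
    expect_equal(f$objective_value, o$objective_value, tolerance = 1e-6,
                 info = paste("seed", s))
    # the planted circulation certifies a feasible lower bound
    expect_gte(f$objective_value, pn$planted_objective - 1e-9)
  }
})

test_that("min_total_flux is steady-state feasible, floor-respecting and parsimonious", {
  # linear chain: no alternate optima, so the distribution equals FBA's
  ch <- make_chain_toy(u = 1)
  v <- min_total_flux(ch, fraction = 1)
  expect_equal(unname(v), unname(solve_fba(ch)$fluxes), tolerance = 1e-9)

  # futile cycle carries zero flux and changes nothing else
  m <- apply_medium(make_toy_core(), medium(EX_A = 10))
  mc <- apply_medium(make_cycle_toy(), medium(EX_A = 10))
  expect_equal(solve_fba(mc)$objective_value, solve_fba(m)$objective_value,
               tolerance = 1e-9)
  vc <- min_total_flux(mc, fraction = 1)
  expect_equal(unname(vc["CYC1"]), 0, tolerance = 1e-9)
  expect_equal(unname(vc["CYC2"]), 0, tolerance = 1e-9)
  expect_lte(sum(abs(vc)) - sum(abs(min_total_flux(m, 1))), 1e-6)

  # relaxing the objective floor can only lower the total flux
  b <- apply_medium(make_branched_toy(), medium(EX_A = 10))
  expect_lte(sum(abs(min_total_flux(b, 0.9))), sum(abs(min_total_flux(b, 1))) + 1e-9)

  # floor is satisfied
  cvec <- ifelse(b$reactions$id == "GROWTH", 1, 0)
  v9 <- min_total_flux(b, 0.9)
  expect_gte(sum(cvec * v9), 0.9 * 20 - 1e-6)
  expect_lt(steady_state_error(b, v9), 1e-6)
})

test_that("FVA intervals behave as LP theory demands", {
  # linear chain at fraction 1: every interval degenerate at the optimum
  ch <- make_chain_toy(u = 1)
  res <- fva(ch, fraction = 1)
  expect_true(all(abs(res$max - res$min) < 1e-9))

  # parallel equivalent paths at fraction 1 span [0, total]
  par <- metabolic_model(
    data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c"),
    data.frame(id = c("EX_A", "P1", "P2", "DRAIN"),
               name = c("uptake", "path 1", "path 2", "drain"),
               lower_bound = c(-4, 0, 0, 0), upper_bound = 1000, gpr = ""),
    list(EX_A = c(A = -1), P1 = c(A = -1, B = 1), P2 = c(A = -1, B = 1),
         DRAIN = c(B = -1)),
    objective = c(DRAIN = 1))
  rp <- fva(par, fraction = 1, reactions = c("P1", "P2"))
  expect_equal(rp$min, c(0, 0), tolerance = 1e-9)
  expect_equal(rp$max, c(4, 4), tolerance = 1e-9)

  # fraction 0.9 intervals contain fraction 1 intervals; FBA optimum lies
  # inside the fraction-1 intervals
  for (model in list(apply_medium(make_branched_toy(), medium(EX_A = 10)),
                     random_viable_network(4, 6, seed = 3)$model)) {
    r1 <- fva(model, fraction = 1)
    r9 <- fva(model, fraction = 0.9)
    expect_true(all(r9$min <= r1$min + 1e-7))
    expect_true(all(r9$max >= r1$max - 1e-7))
    f <- solve_fba(model)$fluxes
    expect_true(all(f >= r1$min - 1e-6 & f <= r1$max + 1e-6))
    # intervals stay within the reaction bounds
    expect_true(all(r9$min >= model$reactions$lower_bound - 1e-7))
    expect_true(all(r9$max <= model$reactions$upper_bound + 1e-7))
  }
})

test_that("reference normalisation and interval containment", {
  expect_equal(normalize_to_reference(c(a = 1.52), -1.52), c(a = 100))
  expect_equal(normalize_to_reference(c(a = 0), -1.52), c(a = 0))
  expect_error(normalize_to_reference(c(a = 1), 0), "magnitude")

  m <- apply_medium(make_toy_core(), medium(EX_A = 10))
  res <- fva(m, fraction = 0.9)
  resn <- normalize_to_reference(res, -10)
  expect_true(all(resn$min <= resn$max))
  expect_equal(resn$max[resn$reaction == "GROWTH"], 200, tolerance = 1e-9)

  expect_true(interval_contains(res, "GROWTH", 19))
  expect_true(interval_contains(res, "GROWTH", 20))
  expect_false(interval_contains(res, "GROWTH", 21))
  fv <- data.frame(reaction = "r", min = 5, max = 5)
  class(fv) <- c("fva_result", "data.frame")
  expect_true(interval_contains(fv, "r", 5))
  expect_false(interval_contains(fv, "r", 5.1))
})
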