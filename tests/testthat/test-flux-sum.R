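test_that("flux-sum equals metabolite turnover on hand-solved cases", {
  # chain A -> B -> C at flux 1: phi_B = (1 + 1)/2 = 1
  ch <- make_chain_toy(u = 1)
  fs <- compute_flux_sum(ch, min_total_flux(ch))
  expect_equal(unname(unclass(fs)["B"]), 1, tolerance = 1e-9)

  # A -> 2B at flux 10, drain takes 20: phi_B = (20 + 20)/2 = 20
  m <- apply_medium(make_toy_core(), medium(EX_A = 10))
  fs2 <- compute_flux_sum(m, min_total_flux(m))
  expect_equal(unname(unclass(fs2)["B_c"]), 20, tolerance = 1e-9)

  # all-zero distribution: all phi zero
  z <- stats::setNames(rep(0, 4), m$reactions$id)
  expect_true(all(unclass(compute_flux_sum(m, z)) == 0))

  # non-steady-state distributions are rejected
  bad <- stats::setNames(c(1, 0, 0, 0), m$reactions$id)
  expect_error(compute_flux_sum(m, bad), "steady state")
  expect_error(compute_flux_sum(m, z[1:3]), "match the model")
})

test_that("flux-sum conservation: production = consumption = phi at steady state", {
  fixtures <- list(
    apply_medium(make_toy_core(), medium(EX_A = 10)),
    apply_medium(make_branched_toy(), medium(EX_A = 10)),
    random_viable_network(4, 6, seed = 5)$model,
    random_viable_network(5, 7, seed = 9)$model)
  for (model in fixtures) {
    v <- min_total_flux(model, fraction = 1)
    phi <- unclass(compute_flux_sum(model, v))
    S <- as.matrix(build_stoich_matrix(model, sparse = FALSE))
    contrib <- S * rep(v, each = nrow(S))
    production <- rowSums(pmax(contrib, 0))
    consumption <- rowSums(pmax(-contrib, 0))
    expect_equal(unname(production), unname(consumption), tolerance = 1e-6)
    expect_equal(as.numeric(phi), unname(production), tolerance = 1e-6)
    expect_true(all(phi >= 0))
  }
})

test_that("flux-sum scales linearly with uptake on a linear network", {
  f1 <- compute_flux_sum(make_chain_toy(1), min_total_flux(make_chain_toy(1)))
  f2 <- compute_flux_sum(make_chain_toy(2), min_total_flux(make_chain_toy(2)))
  expect_equal(as.numeric(f2), 2 * as.numeric(f1), tolerance = 1e-9)
})

test_that("carbon counting parses Hill formulas and ignores Co/Ca/Cl", {
  expect_equal(carbon_count(c("C6H12O6", "C", "H2O", "CoCl2", "C15H31COOH")),
               c(6L, 1L, 0L, 0L, 16L))
  expect_true(is.na(carbon_count(NA_character_)))
  expect_true(is.na(carbon_count("")))
})

test_that("flux-sum profile puts sources on an equal-carbon basis", {
  # two interchangeable 3-carbon sources feeding the same pool
  m <- make_toy_core()
  m$metabolites <- rbind(m$metabolites, data.frame(
    id = "A2_e", name = "second source", compartment = "e", formula = "C3",
    stringsAsFactors = FALSE))
  m$reactions <- rbind(m$reactions, data.frame(
    id = c("EX_A2", "T_A2"), name = c("A2 exchange", "A2 transport"),
    lower_bound = c(0, 0), upper_bound = 1000, gpr = "",
    subsystem = NA_character_, stringsAsFactors = FALSE))
  m$stoichiometry$EX_A2 <- c(A2_e = -1)
  m$stoichiometry$T_A2 <- c(A2_e = -1, A_c = 1)
  validate_model(m)

  prof <- flux_sum_profile(m, carbon_sources = c("EX_A", "EX_A2"), carbon_basis = 1)
  # 3 carbons at basis 1 -> uptake bound 1/3
  expect_equal(unname(prof$uptake_bounds), c(1 / 3, 1 / 3))
  # symmetric sources give identical turnover of the shared pool
  expect_equal(prof$phi["A_c", 1], prof$phi["A_c", 2], tolerance = 1e-9)
  expect_equal(prof$phi["B_c", 1], prof$phi["B_c", 2], tolerance = 1e-9)

  # unknown carbon count is an error naming the source
  m$metabolites$formula[m$metabolites$id == "A2_e"] <- NA_character_
  expect_error(flux_sum_profile(m, carbon_sources = "EX_A2"), "EX_A2")
  # but an explicit carbon table fixes it
  expect_silent(flux_sum_profile(m, carbon_sources = "EX_A2",
                                 carbon_counts = c(EX_A2 = 3)))
})

test_that("row normalisation scales each metabolite to its maximum and is idempotent", {
  prof <- structure(list(
    phi = matrix(c(2, 4, 1, 0, 8, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("m1", "m2"), c("s1", "s2", "s3"))),
    uptake_bounds = c(s1 = 1, s2 = 1, s3 = 1), normalized = FALSE),
    class = "flux_sum_profile")
  n1 <- normalize_rows(prof)
  expect_equal(unname(n1$phi["m1", ]), c(0.5, 1, 0.25))
  expect_equal(unname(n1$phi["m2", ]), c(0, 1, 0))
  expect_equal(normalize_rows(n1)$phi, n1$phi)

  # single column: all rows become 1 (or stay 0)
  p1 <- prof; p1$phi <- prof$phi[, 1, drop = FALSE]
  expect_equal(unname(normalize_rows(p1)$phi[, 1]), c(1, 0))

  # all-zero row stays zero
  p0 <- prof; p0$phi["m2", ] <- 0
  expect_equal(unname(normalize_rows(p0)$phi["m2", ]), c(0, 0, 0))
})
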