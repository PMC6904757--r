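test_that("two-stage production matches the hand LP on the branched toy", {
  b <- apply_medium(make_branched_toy(), medium(EX_A = 10))
  # carbon budget: 10 A; growth floor f*20 consumes f*10 A; rest to product
  for (f in c(1, 0.9, 0.5)) {
    pr <- production_capacity(b, "EX_P", fraction = f)
    expect_equal(pr$mu_max, 20, tolerance = 1e-9)
    expect_equal(pr$production, 10 * (1 - f), tolerance = 1e-9, info = paste("f =", f))
  }
  # target = biomass reaction itself: production = mu_max
  pr <- production_capacity(b, "GROWTH", fraction = 0.9)
  expect_equal(pr$production, pr$mu_max, tolerance = 1e-9)

  # production is monotone non-increasing in the growth-floor fraction
  fr <- c(0.2, 0.4, 0.6, 0.8, 0.95, 1)
  prod <- vapply(fr, function(f) production_capacity(b, "EX_P", f)$production,
                 numeric(1))
  expect_true(all(diff(prod) <= 1e-9))

  # starving model: mu_max = 0, production 0, no error
  starved <- apply_medium(make_branched_toy(), medium())
  pr0 <- production_capacity(starved, "EX_P", 0.9)
  expect_equal(pr0$mu_max, 0)
  expect_equal(pr0$production, 0, tolerance = 1e-9)
})

test_that("the carbon-source panel applies knockouts once and is order-independent", {
  b <- make_branched_toy()
  uptakes <- c(EX_A = 10)
  wt <- carbon_source_panel(b, knockouts = character(),
                            sources_with_uptakes = uptakes,
                            target_reaction = "EX_P", fraction = 0.5)
  expect_equal(wt$production, 5, tolerance = 1e-9)

  # closing the product branch (gene g5 gates R2) kills production everywhere
  ko <- carbon_source_panel(b, knockouts = "g5",
                            sources_with_uptakes = c(EX_A = 10),
                            target_reaction = "EX_P", fraction = 0.5)
  expect_equal(ko$production, 0, tolerance = 1e-9)
  expect_equal(ko$mu_max, 20, tolerance = 1e-9)  # growth unaffected

  # panel over two sources is independent of listing order
  m2 <- b
  m2$metabolites <- rbind(m2$metabolites, data.frame(
    id = "A2_e", name = "alt source", compartment = "e", formula = "C3",
    stringsAsFactors = FALSE))
  m2$reactions <- rbind(m2$reactions, data.frame(
    id = c("EX_A2", "T_A2"), name = c("alt exchange", "alt transport"),
    lower_bound = 0, upper_bound = 1000, gpr = "", subsystem = NA_character_,
    stringsAsFactors = FALSE))
  m2$stoichiometry$EX_A2 <- c(A2_e = -1)
  m2$stoichiometry$T_A2 <- c(A2_e = -1, A_c = 1)
  validate_model(m2)
  p1 <- carbon_source_panel(m2, sources_with_uptakes = c(EX_A = 10, EX_A2 = 4),
                            target_reaction = "EX_P", fraction = 0.9)
  p2 <- carbon_source_panel(m2, sources_with_uptakes = c(EX_A2 = 4, EX_A = 10),
                            target_reaction = "EX_P", fraction = 0.9)
  expect_equal(p1[order(p1$source), ], p2[order(p2$source), ],
               ignore_attr = TRUE)
})

test_that("forced-uptake dose response separates disposal from assimilation", {
  grid <- seq(0, 5, by = 0.5)
  med <- medium(EX_A = 10)

  # disposal-only network: biomass flat across the whole grid
  detox <- apply_medium(make_detox_toy(), med)
  flat <- dose_response_scan(detox, "EX_F", grid, metabolite_id = "F_c")
  expect_true(all(flat$status == "optimal"))
  expect_lt(max(flat$biomass) - min(flat$biomass), 1e-9)
  expect_equal(flat$biomass[1], 20, tolerance = 1e-9)

  # assimilating network: biomass strictly increases with dose, slope 1
  assim <- apply_medium(make_assimilating_toy(), med)
  up <- dose_response_scan(assim, "EX_F", grid, metabolite_id = "F_c")
  expect_true(all(diff(up$biomass) > 0))
  expect_equal(up$biomass, 20 + grid, tolerance = 1e-9)

  # doses beyond the detox capacity are infeasible, not silently clipped
  capped <- apply_medium(make_detox_toy(capacity = 2), med)
  lim <- dose_response_scan(capped, "EX_F", grid, metabolite_id = "F_c")
  expect_true(all(lim$status[lim$dose <= 2] == "optimal"))
  expect_true(all(lim$status[lim$dose > 2] == "infeasible"))

  expect_error(dose_response_scan(detox, "EX_F", c(1, 1, 2), metabolite_id = "F_c"),
               "increasing")
  expect_error(dose_response_scan(detox, "EX_NOPE", grid), "metabolite_id")
})
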