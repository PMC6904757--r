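test_that("model validation rejects structural inconsistencies", {
  m <- make_toy_core()
  expect_silent(validate_model(m))

  bad <- m; bad$reactions$id[2] <- "EX_A"
  expect_error(validate_model(bad), "duplicate reaction id")

  bad <- m; bad$reactions$lower_bound[1] <- 5; bad$reactions$upper_bound[1] <- -5
  expect_error(validate_model(bad), "lower_bound > upper_bound")

  bad <- m; bad$stoichiometry$R1 <- c(A_c = -1, NOPE = 2)
  expect_error(validate_model(bad), "unknown metabolite")

  bad <- m; bad$reactions$gpr[2] <- "g99"
  expect_error(validate_model(bad), "unregistered gene")

  bad <- m; bad$reactions$upper_bound[1] <- Inf
  expect_error(validate_model(bad), "finite")
})

test_that("model statistics count reactions, metabolites, genes and exchanges", {
  st <- model_stats(make_toy_core())
  expect_equal(st$n_reactions, 4)
  expect_equal(st$n_metabolites, 3)
  expect_equal(st$n_genes, 4)
  expect_equal(st$n_exchange, 1)  # biomass drain is not an exchange
  # gene-associated non-exchange reactions: T_A, R1 of {T_A, R1, GROWTH}
  expect_equal(st$pct_gene_associated_excluding_exchange, round(100 * 2 / 3))
})

test_that("stoichiometric matrix columns round-trip the stoichiometry maps", {
  for (model in list(make_toy_core(), make_branched_toy(),
                     random_viable_network(4, 6, seed = 11)$model)) {
    S <- build_stoich_matrix(model, sparse = FALSE)
    expect_equal(dim(S), c(nrow(model$metabolites), nrow(model$reactions)))
    for (rid in model$reactions$id) {
      col <- S[, rid]
      nz <- col[col != 0]
      sto <- model$stoichiometry[[rid]]
      sto <- sto[sto != 0]
      expect_equal(sort(names(nz)), sort(names(sto)), info = rid)
      expect_equal(nz[names(sto)], sto, info = rid)
    }
  }
  S <- build_stoich_matrix(make_toy_core())
  expect_s4_class(S, "sparseMatrix")
  expect_equal(as.numeric(S["A_e", "EX_A"]), -1)
})

test_that("gene knockouts close exactly the reactions whose GPR goes inactive", {
  m <- make_toy_core()
  ko <- knockout_genes(m, "g1")
  expect_equal(ko$reactions$upper_bound[ko$reactions$id == "T_A"], 0)
  expect_equal(ko$reactions$lower_bound[ko$reactions$id == "T_A"], 0)
  # all other reactions untouched
  other <- ko$reactions$id != "T_A"
  expect_equal(ko$reactions$lower_bound[other], m$reactions$lower_bound[other])

  # one gene of the (g2 and g3) complex: g4 isozyme keeps R1 open
  ko2 <- knockout_genes(m, "g2")
  expect_equal(ko2$reactions$upper_bound[ko2$reactions$id == "R1"], 1000)
  ko3 <- knockout_genes(m, c("g2", "g4"))
  expect_equal(ko3$reactions$upper_bound[ko3$reactions$id == "R1"], 0)

  expect_identical(knockout_genes(m, character()), m)
  expect_error(knockout_genes(m, "gX"), "unknown gene")
})

test_that("reaction knockouts and knockout monotonicity of the FBA optimum", {
  m <- apply_medium(make_toy_core(), medium(EX_A = 10))
  expect_identical(knockout_reactions(m, character(0)), m)
  ko <- knockout_reactions(m, "R1")
  expect_equal(solve_fba(ko)$objective_value, 0)  # only biomass producer closed

  # every gene subset can only lower the optimum
  z0 <- solve_fba(m)$objective_value
  genes <- m$genes
  for (mask in 1:(2^length(genes) - 1)) {
    del <- genes[bitwAnd(mask, 2^(seq_along(genes) - 1)) > 0]
    zk <- solve_fba(knockout_genes(m, del))$objective_value
    expect_lte(zk, z0 + 1e-9)
  }
})

test_that("apply_medium zeroes non-listed exchange uptake and is idempotent", {
  m <- make_toy_core()
  m1 <- apply_medium(m, medium(EX_A = 1.52))
  expect_equal(m1$reactions$lower_bound[m1$reactions$id == "EX_A"], -1.52)
  # secretion bound untouched
  expect_equal(m1$reactions$upper_bound[m1$reactions$id == "EX_A"], 1000)
  m2 <- apply_medium(m1, medium(EX_A = 1.52))
  expect_identical(m1$reactions, m2$reactions)

  # empty medium closes all uptake: nothing to eat, no growth
  m0 <- apply_medium(make_toy_core(), medium())
  expect_equal(solve_fba(m0)$objective_value, 0)

  expect_error(apply_medium(m, medium(R1 = 5)), "not an exchange")
  expect_error(medium(EX_A = -1), "non-negative")
})

test_that("hypothetical transporters open a path and refuse duplicates", {
  m <- make_toy_core()
  # B_c has no transporter: growth on B is impossible until one is added
  expect_null(megaflux:::find_exchange_for(m, "B_c"))
  m2 <- add_hypothetical_transporter(m, "B_c")
  expect_true(all(c("EX_B_c_hyp", "T_B_c_hyp") %in% m2$reactions$id))
  expect_setequal(m2$hypothetical, c("EX_B_c_hyp", "T_B_c_hyp"))
  z <- solve_fba(apply_medium(m2, medium(EX_B_c_hyp = 5)))$objective_value
  expect_equal(z, 5)
  expect_error(add_hypothetical_transporter(m2, "B_c"), "already")
  # the original model is untouched (per-run scoping is the caller's copy)
  expect_false("EX_B_c_hyp" %in% m$reactions$id)
})
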