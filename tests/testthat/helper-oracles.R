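# Shared oracles and generators, all independent of the implementation
# paths they check.

# Evaluate a GPR rule string through R's own parser: keywords become
# logical operators, gene ids become TRUE/FALSE variables. Independent of
# parse_gpr()/gpr_active().
eval_gpr_via_r <- function(rule, deleted, genes) {
  if (!nzchar(trimws(rule))) return(TRUE)
  expr <- gsub("\\band\\b", "&", gsub("\\bor\\b", "|", rule, ignore.case = TRUE),
               ignore.case = TRUE)
  env <- new.env()
  for (g in genes) assign(g, !(g %in% deleted), envir = env)
  isTRUE(eval(parse(text = expr), envir = env))
}

# Random GPR rule over <= n_genes gene ids, depth-limited.
random_gpr <- function(n_genes, depth = 3) {
  genes <- paste0("g", seq_len(n_genes))
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.35) return(sample(genes, 1))
    op <- sample(c("and", "or"), 1)
    k <- sample(2:3, 1)
    kids <- vapply(seq_len(k), function(i) build(d - 1L), character(1))
    paste0("(", paste(kids, collapse = paste0(" ", op, " ")), ")")
  }
  build(depth)
}

# Max steady-state violation of a flux vector on a model.
steady_state_error <- function(model, v) {
  S <- build_stoich_matrix(model, sparse = FALSE)
  max(abs(as.matrix(S) %*% v[model$reactions$id]))
}

# Tiny linear chain A -> B -> C with uptake bound u; biomass drains C.
make_chain_toy <- function(u = 1) {
  metabolic_model(
    metabolites = data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                             compartment = "c", stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("EX_A", "R_AB", "R_BC", "DRAIN"),
      name = c("uptake", "A to B", "B to C", "drain"),
      lower_bound = c(-u, 0, 0, 0), upper_bound = c(1000, 1000, 1000, 1000),
      gpr = "", stringsAsFactors = FALSE),
    stoichiometry = list(EX_A = c(A = -1), R_AB = c(A = -1, B = 1),
                         R_BC = c(B = -1, C = 1), DRAIN = c(C = -1)),
    objective = c(DRAIN = 1))
}

# Toy with a 2-reaction futile cycle bolted onto the core toy.
make_cycle_toy <- function() {
  m <- make_toy_core()
  m$metabolites <- rbind(m$metabolites, data.frame(
    id = "D_c", name = "cycle intermediate", compartment = "c",
    formula = NA_character_, stringsAsFactors = FALSE))
  m$reactions <- rbind(m$reactions, data.frame(
    id = c("CYC1", "CYC2"), name = c("cycle fwd", "cycle back"),
    lower_bound = 0, upper_bound = 1000, gpr = "",
    subsystem = NA_character_, stringsAsFactors = FALSE))
  m$stoichiometry$CYC1 <- c(A_c = -1, D_c = 1)
  m$stoichiometry$CYC2 <- c(D_c = -1, A_c = 1)
  validate_model(m)
  m
}
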