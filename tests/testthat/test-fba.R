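# FBA engine: medium application, knockouts, optimality against the
# vertex-enumeration oracle, and the steady-state/monotonicity properties.

test_that("TOY-CORE growth matches the closed form and the LP oracle", {
  toy <- make_core_toy()
  sol <- fba(toy$model, medium = toy$medium)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, toy$manifest$mu_full, tolerance = 1e-8)
  m <- apply_medium(toy$model, toy$medium)
  expect_equal(sol$objective_value, oracle_fba_mu(m), tolerance = 1e-6)
})

test_that("randomized toy variants match closed form and oracle", {
  for (seed in c(11, 23, 37)) {
    toy <- make_core_toy(seed = seed)
    m <- apply_medium(toy$model, toy$medium)
    sol <- solve_fba(m)
    expect_equal(sol$objective_value, toy$manifest$mu_full, tolerance = 1e-6)
    expect_equal(sol$objective_value, oracle_fba_mu(m), tolerance = 1e-6)
  }
})

test_that("apply_medium sets uptake bounds and is idempotent", {
  toy <- make_core_toy()
  med <- medium_spec(EX_glc = 10)
  m <- apply_medium(toy$model, med)
  k <- match(c("EX_glc", "EX_aan", "EX_aam", "EX_lac"), m$rxns$id)
  expect_equal(m$rxns$lb[k], c(-10, 0, 0, 0))
  expect_equal(m$rxns$ub[k], rep(1000, 4))   # secretion untouched
  m2 <- apply_medium(m, med)
  expect_identical(m$rxns, m2$rxns)
  expect_error(apply_medium(toy$model, medium_spec(EX_nope = 1)),
               "EX_nope")
  expect_error(medium_spec(EX_glc = -5), "non-negative")
  ## empty medium closes all uptakes: no growth
  closed <- solve_fba(apply_medium(toy$model, medium_spec()))
  expect_lt(closed$objective_value, 1e-6)
})

test_that("knockouts follow GPR semantics exactly", {
  toy <- make_core_toy()$model
  ## single-gene rule disables its reaction
  ko <- knock_out(toy, "g3")
  k <- match("LDH", ko$rxns$id)
  expect_equal(c(ko$rxns$lb[k], ko$rxns$ub[k]), c(0, 0))
  ## isozyme rescues
  ko2 <- knock_out(toy, "g2a")
  k2 <- match("GLY", ko2$rxns$id)
  expect_equal(ko2$rxns$ub[k2], 1000)
  ## complex subunit kills
  ko3 <- knock_out(toy, "g6")
  k3 <- match("AAMS", ko3$rxns$id)
  expect_equal(ko3$rxns$ub[k3], 0)
  expect_error(knock_out(toy, "not_a_gene"), "unknown gene")

  ## property: disabled reaction set equals truth-table evaluation of each
  ## GPR under random deletion sets
  set.seed(99)
  for (trial in 1:20) {
    del <- sample(toy$genes, sample(1:4, 1))
    ko <- knock_out(toy, del)
    for (rid in toy$rxns$id) {
      rule <- gpr_to_string(toy$gpr[[rid]])
      expected_on <- oracle_gpr_eval(rule, setdiff(toy$genes, del))
      k <- match(rid, ko$rxns$id)
      disabled <- ko$rxns$lb[k] == 0 && ko$rxns$ub[k] == 0 &&
        !(toy$rxns$lb[k] == 0 && toy$rxns$ub[k] == 0)
      expect_identical(!disabled, expected_on,
                       label = sprintf("reaction %s under {%s}", rid,
                                       paste(del, collapse = ",")))
    }
  }
})

test_that("returned solutions satisfy steady state and bounds", {
  toy <- make_core_toy()
  fixtures <- list(
    apply_medium(toy$model, toy$medium),
    apply_medium(make_futile_cycle_model()$model, toy$medium),
    apply_medium(synthetic_strain_models()$atcc334,
                 synthetic_strain_models()$media$cdm))
  for (m in fixtures) {
    sol <- solve_fba(m)
    expect_identical(sol$status, "optimal")
    S <- build_stoich_matrix(m)
    resid <- max(abs(as.vector(S %*% sol$fluxes)))
    expect_lt(resid, 1e-6)
    expect_true(all(sol$fluxes >= m$rxns$lb - 1e-8))
    expect_true(all(sol$fluxes <= m$rxns$ub + 1e-8))
  }
})

test_that("growth is monotone in medium size and antitone in deletions", {
  toy <- make_core_toy()
  set.seed(5)
  base_med <- medium_spec(EX_glc = 5, EX_aan = 5, EX_aam = 5)
  mu_base <- fba(toy$model, medium = base_med)$objective_value
  for (trial in 1:5) {
    bigger <- medium_spec(EX_glc = 5 + stats::runif(1, 0, 10),
                          EX_aan = 5 + stats::runif(1, 0, 10),
                          EX_aam = 5 + stats::runif(1, 0, 10))
    expect_gte(fba(toy$model, medium = bigger)$objective_value,
               mu_base - 1e-8)
  }
  del1 <- sample(toy$model$genes, 2)
  del2 <- union(del1, sample(toy$model$genes, 2))
  mu1 <- fba(toy$model, medium = toy$medium, knockouts = del1)$objective_value
  mu2 <- fba(toy$model, medium = toy$medium, knockouts = del2)$objective_value
  expect_lte(mu2, mu1 + 1e-8)
})

test_that("infeasible and unbounded models surface their status", {
  ## forced flux into a dead-end metabolite: infeasible
  mets <- list(metabolite("a_c"), metabolite("b_c"))
  m <- metabolic_model("bad", mets, list(
    reaction("FORCED", c(a_c = 1), lb = 1, ub = 10, kind = "sink"),
    reaction("BIO", c(a_c = -1, b_c = 1), kind = "biomass"),
    reaction("DRAIN", c(b_c = -1), kind = "sink", lb = 0, ub = 0)),
    objective_id = "BIO")
  sol <- solve_fba(m)
  expect_identical(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))

  ## unbounded objective through an uncapped internal cycle
  m2 <- metabolic_model("unb", list(metabolite("a_c"), metabolite("b_c")), list(
    reaction("FWD", c(a_c = -1, b_c = 1), lb = 0, ub = Inf),
    reaction("BIO", c(b_c = -1, a_c = 1), lb = 0, ub = Inf, kind = "biomass")),
    objective_id = "BIO")
  sol2 <- solve_fba(m2)
  expect_identical(sol2$status, "unbounded")

  ## no objective at all is an explicit error
  m3 <- remove_reactions(make_core_toy()$model, "BIOMASS")
  expect_error(solve_fba(m3), "no objective")
})
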