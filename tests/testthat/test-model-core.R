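# Domain-type invariants, stoichiometric matrix assembly and component
# counting.

test_that("model constructor enforces the structural invariants", {
  mets <- list(metabolite("a_c"), metabolite("b_c"), metabolite("x_e"))
  ok <- metabolic_model("m", mets, list(
    reaction("R1", c(a_c = -1, b_c = 1)),
    reaction("EX_x", c(x_e = -1), kind = "exchange"),
    reaction("BIO", c(b_c = -1), kind = "biomass")), objective_id = "BIO")
  expect_s3_class(ok, "metabolic_model")

  expect_error(metabolic_model("m", mets, list(
    reaction("R1", c(nope_c = -1, b_c = 1)))), "unknown metabolites")
  expect_error(metabolic_model("m", mets, list(
    reaction("EX_x", c(a_c = -1), kind = "exchange"))),
    "exactly one extracellular")
  expect_error(metabolic_model("m", mets, list(
    reaction("EX_x", c(x_e = -1, a_c = 1), kind = "exchange"))),
    "exactly one extracellular")
  expect_error(metabolic_model("m", mets, list(
    reaction("R1", c(a_c = -1, b_c = 1))), objective_id = "R1"),
    "not of kind 'biomass'")
  expect_error(reaction("R1", c(a_c = -1), lb = 5, ub = 1),
               "lower bound exceeds upper")
  expect_error(metabolic_model("m", c(mets, list(metabolite("a_c"))),
                               list(reaction("R1", c(a_c = -1)))),
               "duplicate metabolite")
  expect_error(metabolic_model("m", mets, list(
    reaction("R1", c(a_c = -1), gpr = "gX")), genes = "gY"),
    "absent from the gene list")
})

test_that("compartments are inferred from id suffixes", {
  expect_identical(infer_compartment("glc_e"), "extracellular")
  expect_identical(infer_compartment("glc[e0]"), "extracellular")
  expect_identical(infer_compartment("glc_c"), "cytoplasm")
  expect_identical(infer_compartment("glc[c0]"), "cytoplasm")
})

test_that("stoichiometric matrix reproduces reaction columns exactly", {
  mets <- list(metabolite("A_c"), metabolite("B_c"), metabolite("glc_e"))
  m <- metabolic_model("m", mets, list(
    reaction("conv", c(A_c = -1, B_c = 1)),
    reaction("EX_glc", c(glc_e = -1), kind = "exchange")))
  S <- build_stoich_matrix(m)
  expect_identical(dim(S), c(3L, 2L))
  expect_equal(S["A_c", "conv"], -1)
  expect_equal(S["B_c", "conv"], 1)
  expect_equal(S["glc_e", "EX_glc"], -1)
  expect_equal(Matrix::nnzero(S), 3)

  toy <- make_core_toy()$model
  St <- build_stoich_matrix(toy)
  expect_identical(dim(St), c(nrow(toy$mets), nrow(toy$rxns)))
  expect_equal(Matrix::nnzero(St),
               sum(lengths(toy$stoich)))
  for (rid in toy$rxns$id) {
    col <- St[, rid]
    expect_equal(col[col != 0][names(toy$stoich[[rid]])],
                 toy$stoich[[rid]][names(toy$stoich[[rid]])])
  }
})

test_that("component counts are consistent and classification sums hold", {
  toy <- make_core_toy()$model
  cs <- model_summary(toy)
  expect_equal(cs$metabolites, 12)
  expect_equal(cs$reactions, 14)
  expect_equal(cs$reactions_exchange + cs$reactions_metabolic +
                 cs$reactions_non_metabolic, cs$reactions)
  expect_equal(cs$metabolic_with_gpr + cs$metabolic_without_gpr,
               cs$reactions_metabolic)
  expect_equal(cs$metabolites_intracellular + cs$metabolites_extracellular,
               cs$metabolites)

  empty <- metabolic_model("void", list(), list())
  ce <- model_summary(empty)
  expect_true(all(unlist(ce[-1]) == 0))
})

test_that("adding and removing reactions keeps the model valid", {
  toy <- make_core_toy()$model
  m2 <- add_reactions(toy, reaction("NEW", c(pyr_c = -1, newmet_c = 1)))
  expect_true("NEW" %in% m2$rxns$id)
  expect_true("newmet_c" %in% m2$mets$id)
  expect_error(add_reactions(m2, reaction("NEW", c(pyr_c = -1))),
               "already in model")
  m3 <- remove_reactions(m2, "NEW")
  expect_false("NEW" %in% m3$rxns$id)
  expect_identical(validate_model(m3), m3)
  ## removing the biomass reaction clears the objective
  m4 <- remove_reactions(toy, "BIOMASS")
  expect_true(is.na(m4$objective_id))
})
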