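# Mass/charge balance checking and energy-cycle detection.

balance_fixture <- function() {
  mets <- list(
    metabolite("glc_c", formula = "C6H12O6", charge = 0L),
    metabolite("atp_c", formula = "C10H12N5O13P3", charge = -4L),
    metabolite("g6p_c", formula = "C6H11O9P", charge = -2L),
    metabolite("adp_c", formula = "C10H12N5O10P2", charge = -3L),
    metabolite("h_c", formula = "H", charge = 1L),
    metabolite("a_c", formula = "C6H12O6", charge = 0L),
    metabolite("b_c", formula = "C6H10O5", charge = 0L),
    metabolite("na_c", formula = "Na", charge = 1L),
    metabolite("na0_c", formula = "Na", charge = 0L),
    metabolite("unk_c", formula = "null", charge = NA_integer_))
  metabolic_model("bal", mets, list(
    reaction("HEXOKINASE",
             c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1, h_c = 1)),
    reaction("DEHYDRATION", c(a_c = -1, b_c = 1)),
    reaction("SWAP", c(na_c = -1, na0_c = 1)),
    reaction("MYSTERY", c(a_c = -1, unk_c = 1))))
}

test_that("textbook hexokinase is balanced; planted imbalances are found", {
  m <- balance_fixture()
  hk <- check_balance("HEXOKINASE", m)
  expect_identical(hk$verdict, "balanced")
  expect_length(hk$element_diff, 0)
  expect_equal(hk$charge_diff, 0)

  ## C6H12O6 -> C6H10O5 loses H2 and O
  de <- check_balance("DEHYDRATION", m)
  expect_identical(de$verdict, "unbalanced")
  expect_equal(de$element_diff[["H"]], -2)
  expect_equal(de$element_diff[["O"]], -1)

  ## mass-balanced but charge wrong: charge acts as an extra element row
  sw <- check_balance("SWAP", m)
  expect_identical(sw$verdict, "unbalanced")
  expect_equal(sw$charge_diff, -1)

  my <- check_balance("MYSTERY", m)
  expect_identical(my$verdict, "undetermined")
  expect_identical(my$undetermined_mets, "unk_c")
})

test_that("formula parser handles Hill notation with groups", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("Ca(OH)2"), c(Ca = 1, O = 2, H = 2))
  expect_equal(parse_formula("H"), c(H = 1))
  expect_equal(parse_formula("C10H12N5O13P3"),
               c(C = 10, H = 12, N = 5, O = 13, P = 3))
  expect_null(parse_formula("null"))
  expect_null(parse_formula(""))
  expect_null(parse_formula(NA_character_))
  expect_null(parse_formula("12abc"))
  expect_null(parse_formula("C6H12("))
})

test_that("balance verdicts agree with the elemental-matrix null space", {
  m <- balance_fixture()
  ## independent check: build the (elements+charge) x metabolites matrix and
  ## test E %*% s == 0 per reaction
  known <- m$mets$id[m$mets$formula != "null" & !is.na(m$mets$formula)]
  els <- sort(unique(unlist(lapply(m$mets$formula[match(known, m$mets$id)],
                                   function(f) names(parse_formula(f))))))
  E <- matrix(0, length(els) + 1, length(known),
              dimnames = list(c(els, ".charge"), known))
  for (mid in known) {
    f <- parse_formula(m$mets$formula[match(mid, m$mets$id)])
    E[names(f), mid] <- f
    E[".charge", mid] <- m$mets$charge[match(mid, m$mets$id)]
  }
  for (rid in c("HEXOKINASE", "DEHYDRATION", "SWAP")) {
    st <- m$stoich[[rid]]
    sv <- numeric(length(known)); names(sv) <- known
    sv[names(st)] <- st
    in_null <- max(abs(E %*% sv)) < 1e-9
    expect_identical(check_balance(rid, m)$verdict == "balanced", in_null,
                     label = rid)
  }
})

test_that("planted ATP cycle is detected with its witness and repair works", {
  fc <- make_futile_cycle_model()
  rep <- detect_energy_cycles(fc$model)
  expect_identical(rep$verdict, "infeasible-cycle")
  expect_gt(rep$dissipation_flux, 1e-6)
  expect_true(all(fc$manifest$witness %in% rep$witness))

  ## repair property: forbidding the cycle direction of any single witness
  ## reaction strictly reduces the maximum dissipation flux
  fixes <- suggest_cycle_fixes(fc$model, rep)
  for (i in seq_len(nrow(fixes))) {
    m2 <- fc$model
    k <- match(fixes$reaction_id[i], m2$rxns$id)
    m2$rxns$lb[k] <- fixes$suggested_lb[i]
    m2$rxns$ub[k] <- fixes$suggested_ub[i]
    rep2 <- detect_energy_cycles(m2)
    expect_lt(rep2$dissipation_flux + 1e-9, rep$dissipation_flux)
  }

  ## the shipped repaired variant and the plain toy are clean
  expect_identical(detect_energy_cycles(
    make_futile_cycle_model(repaired = TRUE)$model)$verdict, "clean")
  expect_identical(detect_energy_cycles(make_core_toy()$model)$verdict,
                   "clean")
})

test_that("cycle verdicts agree with exhaustive sign-pattern search", {
  for (fix in list(make_futile_cycle_model(),
                   make_futile_cycle_model(repaired = TRUE),
                   make_core_toy())) {
    model <- fix$model
    verdict <- detect_energy_cycles(model)$verdict
    exists <- oracle_cycle_exists(model)
    expect_identical(verdict == "infeasible-cycle", exists,
                     label = model$id)
  }
})

test_that("cardinality witness is no larger than the L1 witness", {
  fc <- make_futile_cycle_model()
  l1 <- detect_energy_cycles(fc$model, witness = "l1")
  card <- detect_energy_cycles(fc$model, witness = "cardinality")
  expect_lte(length(card$witness), length(l1$witness))
  expect_true(all(fc$manifest$witness %in% card$witness))
})

test_that("missing dissipation metabolites are an error", {
  toy <- make_core_toy()$model
  expect_error(detect_energy_cycles(toy, dissipation = c(nadh_c = -1,
                                                         nad_c = 1)),
               "absent from model")
})
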