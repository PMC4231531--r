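# Amino-acid omission and carbohydrate utilization screens, and the
# accuracy scoring conventions.

test_that("planted auxotrophy is called R and the synthesizable one NR", {
  toy <- make_core_toy()
  aa_map <- c(aan = "EX_aan", aam = "EX_aam")
  calls <- scan_amino_acids(toy$model, toy$medium, aa_map)
  expect_identical(calls$predicted[calls$compound == "aan"], "R")
  expect_identical(calls$predicted[calls$compound == "aam"], "NR")
  ## adding a synthesis route flips the auxotrophy call
  fixed <- add_reactions(toy$model,
                         reaction("AANS", c(pyr_c = -1, aan_c = 1)))
  calls2 <- scan_amino_acids(fixed, toy$medium, aa_map)
  expect_identical(calls2$predicted[calls2$compound == "aan"], "NR")
})

test_that("a non-growing baseline makes the amino-acid screen an error", {
  toy <- make_core_toy()
  expect_error(scan_amino_acids(toy$model, medium_spec(EX_glc = 10),
                                c(aan = "EX_aan")),
               "does not grow on the full medium")
})

test_that("screens are side-effect free and deterministic", {
  toy <- make_core_toy()
  before <- toy$model
  aa_map <- c(aan = "EX_aan", aam = "EX_aam")
  c1 <- scan_amino_acids(toy$model, toy$medium, aa_map)
  expect_identical(toy$model, before)
  c2 <- scan_amino_acids(toy$model, toy$medium, aa_map)
  expect_identical(c1, c2)
})

test_that("carbohydrate screen distinguishes transport, catabolism and absence", {
  toy <- make_core_toy()
  ## baseline: amino acids only, no carbon source
  base_med <- medium_spec(EX_aan = 10, EX_aam = 10)
  carb_map <- c(glucose = "EX_glc", fructose = "EX_fru", xylose = NA)
  calls <- scan_carbohydrates(toy$model, base_med, carb_map)
  expect_identical(calls$predicted[calls$compound == "glucose"], "G")
  ## fructose exchange does not exist in TOY-CORE
  expect_identical(calls$predicted[calls$compound == "fructose"], "NG")
  expect_identical(calls$reason[calls$compound == "fructose"],
                   "no transporter")
  expect_identical(calls$predicted[calls$compound == "xylose"], "NG")

  ## planting transporter + catabolism makes the compound usable
  ext <- add_reactions(toy$model, list(
    reaction("EX_fru", c(fru_e = -1), kind = "exchange", lb = 0, ub = 1000),
    reaction("FRUt", c(fru_e = -1, fru_c = 1)),
    reaction("FRUCAT", c(fru_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1))))
  calls2 <- scan_carbohydrates(ext, base_med, carb_map)
  expect_identical(calls2$predicted[calls2$compound == "fructose"], "G")
})

test_that("amino acids required on the full medium stay blocking on sub-media", {
  bundle <- synthetic_strain_models()
  calls <- scan_amino_acids(bundle$atcc334, bundle$media$cdm,
                            bundle$amino_acid_exchanges)
  required <- calls$compound[calls$predicted == "R"]
  sub_med <- bundle$media$essential_atcc334
  for (aa in required) {
    ex <- bundle$amino_acid_exchanges[[aa]]
    med2 <- medium_spec(sub_med[setdiff(names(sub_med), ex)])
    sol <- solve_fba(apply_medium(bundle$atcc334, med2))
    expect_lt(sol$objective_value, 1e-6)
  }
})

test_that("scoring follows the growth-positive convention", {
  toy <- make_core_toy()
  aa_map <- c(aan = "EX_aan", aam = "EX_aam")
  calls <- scan_amino_acids(toy$model, toy$medium, aa_map)

  ## identical predictions and observations: perfect score
  obs_same <- stats::setNames(calls$predicted, calls$compound)
  acc <- score_predictions(calls, obs_same)
  expect_equal(acc$n_correct, acc$n_compared)
  expect_equal(acc$false_positives, 0)
  expect_equal(acc$false_negatives, 0)

  ## predicted NR but observed R: a false positive (growth predicted where
  ## none happens); predicted R but observed NR: a false negative
  obs_fp <- c(aan = "R", aam = "R")     # aam predicted NR -> FP
  acc_fp <- score_predictions(calls, obs_fp)
  expect_equal(acc_fp$false_positives, 1)
  expect_equal(acc_fp$false_negatives, 0)
  obs_fn <- c(aan = "NR", aam = "NR")   # aan predicted R -> FN
  acc_fn <- score_predictions(calls, obs_fn)
  expect_equal(acc_fn$false_negatives, 1)
  expect_equal(acc_fn$false_positives, 0)

  ## W counts as growth by default, so W agrees with NR but not with R
  obs_w <- c(aan = "W", aam = "W")
  acc_w <- score_predictions(calls, obs_w)
  expect_identical(acc_w$table$agrees[acc_w$table$compound == "aam"], TRUE)
  expect_identical(acc_w$table$agrees[acc_w$table$compound == "aan"], FALSE)
  acc_w2 <- score_predictions(calls, obs_w, w_policy = "no_growth")
  expect_identical(acc_w2$table$agrees[acc_w2$table$compound == "aan"], TRUE)

  expect_error(score_predictions(calls, c(aan = "R")), "no observed call")
  expect_error(score_predictions(calls, c(aan = "R", aam = "maybe")),
               "unknown observed symbol")
})
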