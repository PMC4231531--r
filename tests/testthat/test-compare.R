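# Differential gene-deletion comparison: planted categories, symmetry,
# minimality, and equivalence with brute-force enumeration.

test_that("planted paired fixtures are recovered with the right category", {
  for (category in c("genetic", "orthology", "metabolic")) {
    pf <- make_paired_models(category)
    cmp <- compare_models(pf$model_a, pf$model_b, pf$orthologs, pf$medium,
                          max_set_size = 2)
    expect_gt(length(cmp$sets), 0)
    cats <- vapply(cmp$sets, `[[`, character(1), "category")
    expect_true(all(cats == category), label = category)
    expect_setequal(vapply(cmp$sets, `[[`, character(1), "lethal_in"),
                    pf$manifest$lethal_in)
    ## the manifest's defining rescue reaction is reported
    for (s in cmp$sets) {
      expect_true(any(pf$manifest$rescue %in% s$rescue),
                  label = sprintf("%s rescue", category))
    }
    ## exactly one side is lethal in every reported set
    for (s in cmp$sets) {
      expect_true(xor(s$mu_a < 1e-6, s$mu_b < 1e-6))
    }
  }
})

test_that("identical models yield no differential sets", {
  pf <- make_paired_models("none")
  cmp <- compare_models(pf$model_a, pf$model_b, pf$orthologs, pf$medium,
                        max_set_size = 2)
  expect_length(cmp$sets, 0)
})

test_that("comparison is symmetric up to label flipping", {
  pf <- make_paired_models("genetic")
  fwd <- compare_models(pf$model_a, pf$model_b, pf$orthologs, pf$medium,
                        max_set_size = 1)
  swapped <- data.frame(gene_a = pf$orthologs$gene_b,
                        gene_b = pf$orthologs$gene_a,
                        stringsAsFactors = FALSE)
  rev <- compare_models(pf$model_b, pf$model_a, swapped, pf$medium,
                        max_set_size = 1)
  expect_identical(comparison_set_labels(fwd), comparison_set_labels(rev))
  flip <- c(A = "B", B = "A")
  expect_identical(
    sort(unname(flip[vapply(fwd$sets, `[[`, character(1), "lethal_in")])),
    sort(vapply(rev$sets, `[[`, character(1), "lethal_in")))
})

test_that("results equal brute-force enumeration at toy scale", {
  for (category in c("genetic", "orthology", "metabolic", "none")) {
    pf <- make_paired_models(category)
    cmp <- compare_models(pf$model_a, pf$model_b, pf$orthologs, pf$medium,
                          max_set_size = 2)
    expect_identical(comparison_set_labels(cmp),
                     oracle_compare(pf$model_a, pf$model_b, pf$orthologs,
                                    pf$medium, max_set_size = 2),
                     label = category)
  }
})

test_that("size-2 differential sets are minimal (no differential singleton inside)", {
  ## construct a pair where only a joint deletion is differential: A's LDH
  ## has isozymes g3/g3c, B's has g3/g3b; g3 mapped, g3b/g3c unique
  pf <- make_paired_models("genetic")       # B: "g3 or g3b"
  a <- pf$model_a
  a$gpr[["LDH"]] <- parse_gpr("g3 or g3c")
  a$genes <- union(a$genes, "g3c")
  cmp <- compare_models(a, pf$model_b, pf$orthologs, pf$medium,
                        max_set_size = 2)
  expect_gt(length(cmp$sets), 0)
  two <- Filter(function(s) length(s$units) == 2, cmp$sets)
  expect_gt(length(two), 0)
  labels1 <- comparison_set_labels(
    compare_models(a, pf$model_b, pf$orthologs, pf$medium, max_set_size = 1))
  for (s in two) {
    for (u in s$units) expect_false(u %in% labels1)
  }
  ## and brute force agrees on the whole result
  expect_identical(comparison_set_labels(cmp),
                   oracle_compare(a, pf$model_b, pf$orthologs, pf$medium,
                                  max_set_size = 2))
})

test_that("single-gene deletion scan handles GPR-free genes and transporters", {
  toy <- make_core_toy()
  model <- toy$model
  model$genes <- union(model$genes, "orphan")   # gene in no GPR
  mus <- single_deletion_scan(model, toy$medium,
                              genes = c("orphan", "gT", "g5"))
  base <- fba(model, medium = toy$medium)$objective_value
  expect_equal(unname(mus["orphan"]), base)
  ## sole glucose transporter gene: no ATP, no growth
  expect_lt(unname(mus["gT"]), 1e-6)
  ## aam importer is rescued by the synthesis route
  expect_gt(unname(mus["g5"]), 1e-6)
})

test_that("comparison preconditions are enforced", {
  pf <- make_paired_models("none")
  expect_error(compare_models(pf$model_a, pf$model_b, pf$orthologs,
                              medium_spec(), max_set_size = 1),
               "must grow")
  bad_map <- rbind(pf$orthologs,
                   data.frame(gene_a = "ghost", gene_b = "ghost2"))
  expect_error(compare_models(pf$model_a, pf$model_b, bad_map, pf$medium),
               "unknown genes")
  dup_map <- rbind(pf$orthologs, pf$orthologs[1, ])
  expect_error(compare_models(pf$model_a, pf$model_b, dup_map, pf$medium),
               "one-to-one")
})
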