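# Synthetic stand-in models for Lactobacillus casei ATCC 334 and 12A.
#
# These are NOT the published genome-scale reconstructions: they are
# deliberately small synthetic networks whose topology encodes the
# genotype-level facts reported for the two strains, so that the package's
# screens and comparison can *compute* the strain phenotypes rather than
# look them up. Encoded facts:
#
# * no biosynthesis route for the seven essential amino acids (arginine,
#   isoleucine, leucine, phenylalanine, tryptophan, tyrosine, valine);
#   generic pyruvate-based synthesis for the other non-essential ones;
# * glutamate synthesizable from glutamine in both strains
#   (glucosamine-fructose-6-phosphate aminotransferase, EC 2.6.1.16), with
#   a de-novo glutamate route present only in ATCC 334 - so omitting
#   glutamate alone is never predicted lethal, the known residual error of
#   the 12A model;
# * fermentative core: glucose -> glycolysis proxy -> pyruvate -> lactate,
#   with the pyruvate kinase step carrying an extra isozyme in 12A (a
#   genetic difference) and the lactate dehydrogenase genes deliberately
#   absent from the ortholog map (an orthology difference);
# * the folate motif: glycine/serine hydroxymethyltransferase feeds
#   5,10-methylene-THF, normally oxidized to 10-formyl-THF by
#   5,10-methylene-THF dehydrogenase (EC 1.5.1.5) for purine synthesis;
#   both strains carry the alternative pair EC 2.1.2.11 + formate:THF
#   ligase (EC 6.3.4.3) plus the pantoate steps (EC 1.1.1.169, 3.5.1.22),
#   but only 12A has the pantothenate exporter (with no gene association),
#   so the dehydrogenase deletion is lethal only in ATCC 334 - a metabolic
#   difference;
# * carbohydrate panel: transport + catabolism for the shared sugars in
#   both strains; transporters/enzymes for D-raffinose, panose, pullulan
#   and myo-inositol only in 12A (myo-inositol being the model's known
#   false positive against in-vivo data); amygdalin degradation releases
#   mandelonitrile, consumed by a sink reaction.
#
# Observed in-vivo phenotype tables for both strains ship alongside as
# scoring inputs.

AA_CODES <- c(ala = "Alanine", arg = "Arginine", asn = "Asparagine",
              asp = "Aspartate", cys = "Cysteine", glu = "Glutamate",
              gln = "Glutamine", gly = "Glycine", his = "Histidine",
              ile = "Isoleucine", leu = "Leucine", lys = "Lysine",
              met = "Methionine", phe = "Phenylalanine", pro = "Proline",
              ser = "Serine", thr = "Threonine", trp = "Tryptophan",
              tyr = "Tyrosine", val = "Valine")

ESSENTIAL_AA <- c("arg", "ile", "leu", "phe", "trp", "tyr", "val")

## aa with the generic 2 pyruvate -> aa synthesis route (gly, glu, gln are
## special-cased; the essential seven have no route)
GENERIC_SYN_AA <- c("ala", "asn", "asp", "cys", "his", "lys", "met", "pro",
                    "ser", "thr")

## shared carbohydrate panel: hexose-unit yield per molecule
SHARED_CARBS <- c(
  amygdalin = 1, cellobiose = 2, fructose = 1, galactose = 1,
  glucosamine = 1, lactitol = 2, maltose = 2, mannose = 1, melezitose = 3,
  ribose = 1, sorbitol = 1, turanose = 2, galactosamine = 1, gluconate = 1,
  inulin = 5, isomaltose = 2, lactose = 2, lactulose = 2, maltotriose = 3,
  nacetylgalactosamine = 1, nacetylglucosamine = 1, polydextrose = 5,
  sucrose = 2)

## carbohydrates with transport/catabolism only in strain 12A
L12A_CARBS <- c(raffinose = 3, panose = 3, pullulan = 6, myoinositol = 1)

## carbohydrates neither strain can use: no exchange, no transporter
UNUSABLE_CARBS <- c(
  "beta_cyclodextrin", "gamma_cyclodextrin", "amylopectin", "amylase",
  "arabinogalactan", "carboxymethyl_cellulose", "ribitol", "arabinose",
  "arabitol", "dextrin", "maltitol", "xylitol", "xylose", "fucose",
  "galacturonic_acid", "glucuronic_acid", "heparin", "lignin",
  "meso_erythritol", "mucin", "phytic_acid", "rhamnose", "sialic_acid",
  "stachyose", "xylan", "alpha_cyclodextrin")

build_strain_model <- function(strain = c("atcc334", "l12a")) {
  strain <- match.arg(strain)
  gpfx <- if (strain == "atcc334") "L334" else "L12A"
  gene <- function(key) paste0(gpfx, "_", key)
  rxns <- list()
  addr <- function(...) rxns[[length(rxns) + 1L]] <<- reaction(...)

  ## fermentative core
  addr("EX_glc_e", c(glc_e = -1), kind = "exchange", lb = 0, ub = 1000)
  addr("GLCt", c(glc_e = -1, glc_c = 1), gpr = gene("glct"))
  addr("HEX", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
       gpr = gene("hex"))
  addr("PYK", c(g6p_c = -1, adp_c = -2, pyr_c = 2, atp_c = 2),
       gpr = if (strain == "atcc334") gene("pyk") else
         paste(gene("pyk"), "or", gene("pykB")))
  addr("LDH", c(pyr_c = -1, lac_c = 1), gpr = gene("ldh"))
  addr("LACt", c(lac_c = -1, lac_e = 1))
  addr("EX_lac_e", c(lac_e = -1), kind = "exchange", lb = 0, ub = 1000)
  addr("PFL", c(pyr_c = -1, for_c = 1, ac_c = 1), gpr = gene("pfl"))
  addr("ACt", c(ac_c = -1, ac_e = 1))
  addr("EX_ac_e", c(ac_e = -1), kind = "exchange", lb = 0, ub = 1000)
  addr("ATPM", c(atp_c = -1, adp_c = 1))

  ## amino acids: exchange + transporter for all 20; synthesis as encoded
  for (aa in names(AA_CODES)) {
    addr(paste0("EX_", aa, "_e"), stats::setNames(-1, paste0(aa, "_e")),
         kind = "exchange", lb = 0, ub = 1000)
    addr(paste0("T_", aa),
         stats::setNames(c(-1, 1), paste0(aa, c("_e", "_c"))),
         gpr = gene(paste0("t_", aa)))
  }
  for (aa in GENERIC_SYN_AA) {
    addr(paste0("SYN_", aa),
         stats::setNames(c(-2, 1), c("pyr_c", paste0(aa, "_c"))),
         gpr = gene(paste0("syn_", aa)))
  }
  ## glutamine synthetase and glutamine->glutamate aminotransferase
  ## (EC 2.6.1.16), both strains
  addr("GLNS", c(glu_c = -1, atp_c = -1, gln_c = 1, adp_c = 1),
       gpr = gene("glns"))
  addr("GFAT", c(gln_c = -1, glu_c = 1), gpr = gene("gfat"),
       ec_numbers = "2.6.1.16")
  if (strain == "atcc334") {
    ## de-novo glutamate route present only in ATCC 334
    addr("GDH", c(pyr_c = -2, glu_c = 1), gpr = gene("gdh"))
  }

  ## folate / purine motif (Fig.-3-style topology)
  addr("GHMT", c(ser_c = -1, thf_c = -1, gly_c = 1, ch2thf_c = 1),
       gpr = gene("ghmt"), ec_numbers = "2.1.2.1")
  addr("MTHFD", c(ch2thf_c = -1, chothf_c = 1), gpr = gene("mthfd"),
       ec_numbers = "1.5.1.5")
  addr("FTL", c(for_c = -1, thf_c = -1, atp_c = -1,
                chothf_c = 1, adp_c = 1),
       gpr = gene("ftl"), ec_numbers = "6.3.4.3")
  addr("KTPF", c(ch2thf_c = -1, mob_c = -1, thf_c = 1, dhpan_c = 1),
       gpr = gene("ktpf"), ec_numbers = "2.1.2.11")
  addr("MOBS", c(pyr_c = -2, mob_c = 1), gpr = gene("mobs"))
  addr("PURS", c(chothf_c = -1, pyr_c = -2, atp_c = -1,
                 purine_c = 1, thf_c = 1, adp_c = 1),
       gpr = gene("purs"))
  addr("DPR", c(dhpan_c = -1, pantoate_c = 1), gpr = gene("dpr"),
       ec_numbers = "1.1.1.169")
  addr("PTH", c(pantoate_c = -1, pan_c = 1), gpr = gene("pth"),
       ec_numbers = "3.5.1.22")
  if (strain == "l12a") {
    ## pantothenate exporter unique to 12A; carries no gene association
    addr("PANt", c(pan_c = -1, pan_e = 1))
    addr("EX_pan_e", c(pan_e = -1), kind = "exchange", lb = 0, ub = 1000)
  }

  ## carbohydrate panel
  carbs <- SHARED_CARBS
  if (strain == "l12a") carbs <- c(carbs, L12A_CARBS)
  for (cb in names(carbs)) {
    ce <- paste0(cb, "_e"); cc <- paste0(cb, "_c")
    addr(paste0("EX_", cb, "_e"), stats::setNames(-1, ce),
         kind = "exchange", lb = 0, ub = 1000)
    addr(paste0("T_", cb), stats::setNames(c(-1, 1), c(ce, cc)),
         gpr = gene(paste0("t_", cb)))
    if (cb == "amygdalin") {
      addr("CAT_amygdalin", c(amygdalin_c = -1, atp_c = -1,
                              g6p_c = 1, mnit_c = 1, adp_c = 1),
           gpr = gene("cat_amygdalin"))
      addr("SK_mnit", c(mnit_c = -1), kind = "sink", lb = 0, ub = 1000)
    } else {
      st <- stats::setNames(c(-1, -1, carbs[[cb]], 1),
                            c(cc, "atp_c", "g6p_c", "adp_c"))
      addr(paste0("CAT_", cb), st, gpr = gene(paste0("cat_", cb)))
    }
  }

  ## biomass: 0.1 of each amino acid except glycine (0.05, stoichiometrically
  ## coupled to the purine demand through the folate cycle), 0.05 purine,
  ## 5 ATP
  bm <- stats::setNames(rep(-0.1, 19),
                        paste0(setdiff(names(AA_CODES), "gly"), "_c"))
  bm <- c(bm, gly_c = -0.05, purine_c = -0.05, atp_c = -5, adp_c = 5)
  addr("BIOMASS", bm, kind = "biomass", lb = 0, ub = 1000)

  mets <- lapply(sort(unique(unlist(lapply(rxns, function(r) names(r$stoich))))),
                 metabolite)
  mid <- if (strain == "atcc334") "sLca334" else "sLca12A"
  metabolic_model(mid, mets, rxns, objective_id = "BIOMASS")
}

#' Synthetic stand-in models for two L. casei strains
#'
#' Builds small synthetic genome-scale models emulating the strain-level
#' metabolic differences between *Lactobacillus casei* ATCC 334 and 12A
#' (see the package vignette for exactly which facts are encoded and which
#' are not). Returns everything the screening and comparison workflow
#' needs: the two models, the ortholog map (lactate dehydrogenase
#' deliberately unmapped), media, compound-to-exchange maps, and the
#' observed in-vivo phenotype tables used for scoring.
#'
#' @return list with elements `atcc334`, `l12a` (models), `orthologs`
#'   (data frame `gene_a`/`gene_b`), `media` (list: `cdm`, per-strain
#'   essential media with/without a carbon source, comparison conditions),
#'   `amino_acid_exchanges`, `carbohydrate_exchanges` (named by compound;
#'   `NA` for compounds without an exchange anywhere),
#'   `observed` (in-vivo call tables) and `manifest` (planted differences).
#' @export
synthetic_strain_models <- function() {
  a <- build_strain_model("atcc334")
  b <- build_strain_model("l12a")

  ## ortholog map: pair L334_x with L12A_x for every shared gene key except
  ## lactate dehydrogenase (planted orthology difference)
  keys_a <- sub("^L334_", "", a$genes)
  keys_b <- sub("^L12A_", "", b$genes)
  shared <- setdiff(intersect(keys_a, keys_b), "ldh")
  orthologs <- data.frame(gene_a = paste0("L334_", sort(shared)),
                          gene_b = paste0("L12A_", sort(shared)),
                          stringsAsFactors = FALSE)

  aa_ex <- stats::setNames(paste0("EX_", names(AA_CODES), "_e"),
                           names(AA_CODES))
  all_carbs <- c(names(SHARED_CARBS), "glucose", names(L12A_CARBS),
                 UNUSABLE_CARBS)
  carb_ex <- stats::setNames(rep(NA_character_, length(all_carbs)), all_carbs)
  carb_ex[names(SHARED_CARBS)] <- paste0("EX_", names(SHARED_CARBS), "_e")
  carb_ex["glucose"] <- "EX_glc_e"
  carb_ex[names(L12A_CARBS)] <- paste0("EX_", names(L12A_CARBS), "_e")

  rate <- 10
  cdm <- medium_spec(stats::setNames(
    rep(rate, 21), c("EX_glc_e", unname(aa_ex))))
  ess_ex <- unname(aa_ex[ESSENTIAL_AA])
  media <- list(
    cdm = cdm,
    essential_atcc334 = medium_spec(stats::setNames(
      rep(rate, 8), c("EX_glc_e", ess_ex))),
    essential_l12a = medium_spec(stats::setNames(
      rep(rate, 9), c("EX_glc_e", ess_ex, "EX_glu_e"))),
    carb_baseline_atcc334 = medium_spec(stats::setNames(rep(rate, 7), ess_ex)),
    carb_baseline_l12a = medium_spec(stats::setNames(
      rep(rate, 8), c(ess_ex, "EX_glu_e"))),
    compare_essential = medium_spec(stats::setNames(
      rep(rate, 9), c("EX_glc_e", ess_ex, "EX_glu_e"))),
    compare_all = cdm
  )

  observed_aa <- data.frame(
    compound = names(AA_CODES),
    atcc334 = ifelse(names(AA_CODES) %in% ESSENTIAL_AA, "R",
                     ifelse(names(AA_CODES) %in% c("asp", "glu"), "W", "NR")),
    l12a = ifelse(names(AA_CODES) %in% c(ESSENTIAL_AA, "glu"), "R",
                  ifelse(names(AA_CODES) == "asp", "W", "NR")),
    stringsAsFactors = FALSE)

  ng_334 <- c("raffinose", "myoinositol", "panose", "pullulan",
              UNUSABLE_CARBS)
  ng_12a <- c("myoinositol", UNUSABLE_CARBS)
  observed_carb <- data.frame(
    compound = all_carbs,
    atcc334 = ifelse(all_carbs %in% ng_334, "NG", "G"),
    l12a = ifelse(all_carbs %in% ng_12a, "NG", "G"),
    stringsAsFactors = FALSE)

  manifest <- list(
    essential_amino_acids = ESSENTIAL_AA,
    glutamate_discrepancy_strain = "l12a",
    myoinositol_false_positive_strain = "l12a",
    unique_carb_capabilities_l12a = names(L12A_CARBS),
    planted_differences = list(
      list(units = "pyk pair", lethal_in = "A", category = "genetic",
           conditions = c("essential", "all")),
      list(units = "mthfd pair", lethal_in = "A", category = "metabolic",
           conditions = "essential", rescue_unique = "PANt"),
      list(units = "L334_ldh", lethal_in = "A", category = "orthology",
           conditions = c("essential", "all")),
      list(units = "L12A_ldh", lethal_in = "B", category = "orthology",
           conditions = c("essential", "all")),
      list(units = "t_glu pair", lethal_in = "B", category = "metabolic",
           conditions = "essential")
    )
  )

  list(atcc334 = a, l12a = b, orthologs = orthologs, media = media,
       amino_acid_exchanges = aa_ex, carbohydrate_exchanges = carb_ex,
       observed = list(amino_acids = observed_aa,
                       carbohydrates = observed_carb),
       manifest = manifest)
}
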