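# Synthetic model generators.
#
# Three tiers: a linear chain with an analytically known optimum, a
# branched toy exercising FVA degeneracy and cofactor accounting, and a
# mini central-carbon model of the C. glutamicum type (EMP, oxidative PPP,
# TCA with NADP-dependent isocitrate dehydrogenase, anaplerosis, glutamate/
# proline/lysine branches including the PutA cycle). All fixtures use real
# chemical formulas so the balance QC is exercised honestly; the biomass
# pseudo-reaction is built to drain exactly 1 g per gDCW.

#' Linear chain toy model with known optimum
#'
#' Substrate uptake (fixed as an equality), `n_steps` internal
#' conversions, and a product exchange as objective. The documented FBA
#' optimum equals the uptake rate; every conversion carries a single-gene
#' GPR `gene_i`, so deleting any one gene abolishes growth.
#'
#' @param n_steps number of internal conversion steps (>= 1).
#' @param uptake substrate uptake rate in mmol/gDCW/h (> 0).
#' @return a `metabolic_model` with `n_steps + 2` reactions.
#' @export
make_chain_model <- function(n_steps = 3, uptake = 10) {
  stopifnot(n_steps >= 1, uptake > 0)
  species <- paste0("x", 0:n_steps, "_e")
  mets <- do.call(rbind, lapply(species, function(id) {
    metabolite(id, formula = "C6H12O6", charge = 0L)
  }))
  rxns <- list(
    reaction("EX_x0_e", c(x0_e = -1), name = "substrate exchange",
             lb = -uptake, ub = -uptake)
  )
  for (i in seq_len(n_steps)) {
    st <- stats::setNames(c(-1, 1), c(species[i], species[i + 1]))
    rxns <- c(rxns, list(
      reaction(paste0("CONV", i), st, name = paste("conversion", i),
               lb = 0, ub = 1000, gpr = paste0("gene_", i))
    ))
  }
  rxns <- c(rxns, list(
    reaction(paste0("EX_x", n_steps, "_e"),
             stats::setNames(-1, species[n_steps + 1]),
             name = "product exchange", lb = 0, ub = 1000)
  ))
  m <- metabolic_model(mets, rxns,
                       objective = paste0("EX_x", n_steps, "_e"))
  attr(m, "documented_optimum") <- uptake
  m
}

#' Branched toy model with degenerate optima and a cofactor cycle
#'
#' Fixed uptake of 10, two stoichiometrically identical parallel routes
#' from A to B (each NAD-coupled), and a reoxidation side branch venting
#' H2. Documented truths: at the optimum the product export is 10, each
#' parallel route has FVA range (0, 10) at objective fraction 1, total
#' NADH production is 10 and equals the side-branch demand.
#'
#' @return a `metabolic_model`.
#' @export
make_branched_model <- function() {
  mets <- rbind(
    metabolite("a_e", formula = "C6H12O6"),
    metabolite("a_c", formula = "C6H12O6"),
    metabolite("b_c", formula = "C6H10O6"),
    metabolite("b_e", formula = "C6H10O6"),
    metabolite("nad_c", formula = "X"),
    metabolite("nadh_c", formula = "XH2"),
    metabolite("h2_c", formula = "H2"),
    metabolite("h2_e", formula = "H2")
  )
  rxns <- list(
    reaction("EX_a_e", c(a_e = -1), lb = -10, ub = -10),
    reaction("At", c(a_e = -1, a_c = 1), lb = 0, gpr = "gene_t"),
    reaction("P1", c(a_c = -1, nad_c = -1, b_c = 1, nadh_c = 1),
             lb = 0, gpr = "gene_p1"),
    reaction("P2", c(a_c = -1, nad_c = -1, b_c = 1, nadh_c = 1),
             lb = 0, gpr = "gene_p2"),
    reaction("REOX", c(nadh_c = -1, nad_c = 1, h2_c = 1), lb = 0,
             gpr = "gene_r"),
    reaction("H2t", c(h2_c = -1, h2_e = 1), lb = 0),
    reaction("EX_h2_e", c(h2_e = -1), lb = 0),
    reaction("Bt", c(b_c = -1, b_e = 1), lb = 0),
    reaction("EX_b_e", c(b_e = -1), lb = 0)
  )
  m <- metabolic_model(mets, rxns, objective = "EX_b_e")
  attr(m, "documented_optimum") <- 10
  attr(m, "documented_cofactor_demand") <- 10
  m
}

# metabolite catalogue for the mini central-carbon model:
# BiGG-style ids, formulas and charges of the major microbial species.
.minicore_mets <- function() {
  spec <- list(
    # id (without compartment), name, formula, charge, compartments
    c("glc__D", "D-glucose", "C6H12O6", 0, "e"),
    c("g6p", "glucose 6-phosphate", "C6H11O9P", -2, "c"),
    c("f6p", "fructose 6-phosphate", "C6H11O9P", -2, "c"),
    c("fdp", "fructose 1,6-bisphosphate", "C6H10O12P2", -4, "c"),
    c("dhap", "dihydroxyacetone phosphate", "C3H5O6P", -2, "c"),
    c("g3p", "glyceraldehyde 3-phosphate", "C3H5O6P", -2, "c"),
    c("13dpg", "3-phospho-D-glyceroyl phosphate", "C3H4O10P2", -4, "c"),
    c("3pg", "3-phospho-D-glycerate", "C3H4O7P", -3, "c"),
    c("2pg", "D-glycerate 2-phosphate", "C3H4O7P", -3, "c"),
    c("pep", "phosphoenolpyruvate", "C3H2O6P", -3, "c"),
    c("pyr", "pyruvate", "C3H3O3", -1, "c"),
    c("6pgc", "6-phospho-D-gluconate", "C6H10O10P", -3, "c"),
    c("ru5p__D", "D-ribulose 5-phosphate", "C5H9O8P", -2, "c"),
    c("r5p", "D-ribose 5-phosphate", "C5H9O8P", -2, "c"),
    c("xu5p__D", "D-xylulose 5-phosphate", "C5H9O8P", -2, "c"),
    c("s7p", "sedoheptulose 7-phosphate", "C7H13O10P", -2, "c"),
    c("e4p", "D-erythrose 4-phosphate", "C4H7O7P", -2, "c"),
    c("accoa", "acetyl-CoA", "C23H34N7O17P3S", -4, "c"),
    c("coa", "coenzyme A", "C21H32N7O16P3S", -4, "c"),
    c("actp", "acetyl phosphate", "C2H3O5P", -2, "c"),
    c("ac", "acetate", "C2H3O2", -1, c("c", "e")),
    c("lac__L", "L-lactate", "C3H5O3", -1, c("c", "e")),
    c("oaa", "oxaloacetate", "C4H2O5", -2, "c"),
    c("cit", "citrate", "C6H5O7", -3, "c"),
    c("icit", "isocitrate", "C6H5O7", -3, "c"),
    c("akg", "2-oxoglutarate", "C5H4O5", -2, "c"),
    c("succoa", "succinyl-CoA", "C25H35N7O19P3S", -5, "c"),
    c("succ", "succinate", "C4H4O4", -2, "c"),
    c("fum", "fumarate", "C4H2O4", -2, "c"),
    c("mal__L", "L-malate", "C4H4O5", -2, "c"),
    c("glx", "glyoxylate", "C2HO3", -1, "c"),
    c("nad", "NAD+", "C21H26N7O14P2", -1, "c"),
    c("nadh", "NADH", "C21H27N7O14P2", -2, "c"),
    c("nadp", "NADP+", "C21H25N7O17P3", -3, "c"),
    c("nadph", "NADPH", "C21H26N7O17P3", -4, "c"),
    c("atp", "ATP", "C10H12N5O13P3", -4, "c"),
    c("adp", "ADP", "C10H12N5O10P2", -3, "c"),
    c("pi", "phosphate", "HO4P", -2, c("c", "e")),
    c("h2o", "water", "H2O", 0, c("c", "e")),
    c("h", "proton", "H", 1, c("c", "e")),
    c("co2", "carbon dioxide", "CO2", 0, c("c", "e")),
    c("o2", "oxygen", "O2", 0, c("c", "e")),
    c("nh4", "ammonium", "H4N", 1, c("c", "e")),
    c("glu__L", "L-glutamate", "C5H8NO4", -1, "c"),
    c("glu5p", "L-glutamate 5-phosphate", "C5H8NO7P", -2, "c"),
    c("glu5sa", "L-glutamate 5-semialdehyde", "C5H9NO3", 0, "c"),
    c("1pyr5c", "1-pyrroline-5-carboxylate", "C5H6NO2", -1, "c"),
    c("pro__L", "L-proline", "C5H9NO2", 0, c("c", "e")),
    c("asp__L", "L-aspartate", "C4H6NO4", -1, "c"),
    c("4pasp", "4-phospho-L-aspartate", "C4H6NO7P", -2, "c"),
    c("aspsa", "L-aspartate 4-semialdehyde", "C4H7NO3", 0, "c"),
    c("hom__L", "L-homoserine", "C4H9NO3", 0, "c"),
    c("thr__L", "L-threonine", "C4H9NO3", 0, "c"),
    c("23dhdp", "2,3-dihydrodipicolinate", "C7H5NO4", -2, "c"),
    c("thdp", "2,3,4,5-tetrahydrodipicolinate", "C7H7NO4", -2, "c"),
    c("26dap__M", "meso-2,6-diaminoheptanedioate", "C7H14N2O4", 0, "c"),
    c("lys__L", "L-lysine", "C6H15N2O2", 1, c("c", "e")),
    c("3mob", "3-methyl-2-oxobutanoate", "C5H7O3", -1, "c"),
    c("val__L", "L-valine", "C5H11NO2", 0, c("c", "e")),
    c("ala__L", "L-alanine", "C3H7NO2", 0, "c"),
    c("glyc", "glycerol", "C3H8O3", 0, "e"),
    c("xyl__D", "D-xylose", "C5H10O5", 0, c("c", "e"))
  )
  rows <- list()
  for (sp in spec) {
    for (comp in sp[5:length(sp)]) {
      rows[[length(rows) + 1L]] <- metabolite(
        paste0(sp[1], "_", comp), name = sp[2], formula = sp[3],
        charge = as.integer(sp[4]), compartment = comp
      )
    }
  }
  do.call(rbind, rows)
}

# reaction catalogue: id | equation | gpr | subsystem | lb | ub | drg
# lb/ub of NA mean "from arrow" (0/1000 forward, -1000/1000 reversible)
.minicore_rxns <- function(glc_uptake) {
  u <- as.character(-glc_uptake)
  rx <- list(
    # exchanges (glucose open at the default uptake; other carbon closed)
    c("EX_glc__D_e", "glc__D_e <=>", "", "exchange", u, "1000", NA),
    c("EX_ac_e", "ac_e <=>", "", "exchange", "0", "1000", NA),
    c("EX_lac__L_e", "lac__L_e <=>", "", "exchange", "0", "1000", NA),
    c("EX_glyc_e", "glyc_e <=>", "", "exchange", "0", "1000", NA),
    c("EX_xyl__D_e", "xyl__D_e <=>", "", "exchange", "0", "1000", NA),
    c("EX_o2_e", "o2_e <=>", "", "exchange", "-1000", "1000", NA),
    c("EX_co2_e", "co2_e <=>", "", "exchange", "-1000", "1000", NA),
    c("EX_h2o_e", "h2o_e <=>", "", "exchange", "-1000", "1000", NA),
    c("EX_h_e", "h_e <=>", "", "exchange", "-1000", "1000", NA),
    c("EX_nh4_e", "nh4_e <=>", "", "exchange", "-1000", "1000", NA),
    c("EX_pi_e", "pi_e <=>", "", "exchange", "-1000", "1000", NA),
    c("EX_lys__L_e", "lys__L_e <=>", "", "exchange", "0", "1000", NA),
    c("EX_pro__L_e", "pro__L_e <=>", "", "exchange", "0", "1000", NA),
    c("EX_val__L_e", "val__L_e <=>", "", "exchange", "0", "1000", NA),
    # transport
    c("O2t", "o2_e <=> o2_c", "", "transport", NA, NA, NA),
    c("CO2t", "co2_e <=> co2_c", "", "transport", NA, NA, NA),
    c("H2Ot", "h2o_e <=> h2o_c", "", "transport", NA, NA, NA),
    c("Ht", "h_e <=> h_c", "", "transport", NA, NA, NA),
    c("NH4t", "nh4_e <=> nh4_c", "", "transport", NA, NA, NA),
    c("PIt", "pi_e <=> pi_c", "", "transport", NA, NA, NA),
    c("ACt", "ac_e <=> ac_c", "", "transport", NA, NA, NA),
    c("LLACt", "lac__L_e <=> lac__L_c", "", "transport", NA, NA, NA),
    c("XYLt", "xyl__D_e <=> xyl__D_c", "", "transport", NA, NA, NA),
    c("LYSt", "lys__L_c -> lys__L_e", "lysE", "transport", NA, NA, NA),
    c("PROt", "pro__L_c -> pro__L_e", "", "transport", NA, NA, NA),
    c("VALt", "val__L_c -> val__L_e", "", "transport", NA, NA, NA),
    # glycolysis (EMP)
    c("GLCpts", "glc__D_e + pep_c -> g6p_c + pyr_c", "ptsG",
      "glycolysis", NA, NA, "-45"),
    c("PGI", "g6p_c <=> f6p_c", "pgi", "glycolysis", NA, NA, "-1.4"),
    c("PFK", "f6p_c + atp_c -> fdp_c + adp_c + h_c", "pfkA",
      "glycolysis", NA, NA, NA),
    c("FBP", "fdp_c + h2o_c -> f6p_c + pi_c", "fbp",
      "gluconeogenesis", NA, NA, NA),
    c("FBA", "fdp_c <=> dhap_c + g3p_c", "fda", "glycolysis",
      NA, NA, "1.0"),
    c("TPI", "dhap_c <=> g3p_c", "tpiA", "glycolysis", NA, NA, "-5.0"),
    c("GAPD", "g3p_c + nad_c + pi_c <=> 13dpg_c + nadh_c + h_c", "gap",
      "glycolysis", NA, NA, NA),
    c("PGK", "13dpg_c + adp_c <=> 3pg_c + atp_c", "pgk",
      "glycolysis", NA, NA, NA),
    c("PGM", "3pg_c <=> 2pg_c", "gpmA", "glycolysis", NA, NA, NA),
    c("ENO", "2pg_c <=> pep_c + h2o_c", "eno", "glycolysis", NA, NA, NA),
    c("PYK", "pep_c + adp_c + h_c -> pyr_c + atp_c", "pyk",
      "glycolysis", NA, NA, "-31"),
    c("PDH", "pyr_c + coa_c + nad_c -> accoa_c + co2_c + nadh_c", "aceE",
      "glycolysis", NA, NA, "-34"),
    # oxidative and non-oxidative PPP
    c("G6PDH2r", "g6p_c + nadp_c + h2o_c -> 6pgc_c + nadph_c + 2 h_c",
      "zwf", "pentose phosphate pathway", NA, NA, NA),
    c("GND", "6pgc_c + nadp_c -> ru5p__D_c + co2_c + nadph_c", "gnd",
      "pentose phosphate pathway", NA, NA, NA),
    c("RPE", "ru5p__D_c <=> xu5p__D_c", "rpe",
      "pentose phosphate pathway", NA, NA, NA),
    c("RPI", "r5p_c <=> ru5p__D_c", "rpi",
      "pentose phosphate pathway", NA, NA, NA),
    c("TKT1", "xu5p__D_c + r5p_c <=> g3p_c + s7p_c", "tkt",
      "pentose phosphate pathway", NA, NA, NA),
    c("TALA", "g3p_c + s7p_c <=> e4p_c + f6p_c", "tal",
      "pentose phosphate pathway", NA, NA, NA),
    c("TKT2", "xu5p__D_c + e4p_c <=> g3p_c + f6p_c", "tkt",
      "pentose phosphate pathway", NA, NA, NA),
    # TCA cycle, glyoxylate shunt, anaplerosis
    c("CS", "accoa_c + oaa_c + h2o_c -> cit_c + coa_c + h_c", "gltA",
      "TCA cycle", NA, NA, "-35"),
    c("ACONT", "cit_c <=> icit_c", "acn", "TCA cycle", NA, NA, "6.6"),
    c("ICDHyr", "icit_c + nadp_c -> akg_c + co2_c + nadph_c", "icd",
      "TCA cycle", NA, NA, NA),
    c("AKGDH", "akg_c + coa_c + nad_c -> succoa_c + co2_c + nadh_c",
      "kgd", "TCA cycle", NA, NA, "-37"),
    c("SUCOAS", "succoa_c + adp_c + pi_c <=> succ_c + coa_c + atp_c",
      "sucC and sucD", "TCA cycle", NA, NA, NA),
    c("SUCDi", "succ_c + 0.5 o2_c -> fum_c + h2o_c", "sdhA and sdhB",
      "TCA cycle", NA, NA, NA),
    c("FUM", "fum_c + h2o_c <=> mal__L_c", "fum", "TCA cycle",
      NA, NA, "-3.4"),
    c("MDH", "mal__L_c + nad_c <=> oaa_c + nadh_c + h_c", "mdh",
      "TCA cycle", NA, NA, "25"),
    c("ICL", "icit_c -> succ_c + glx_c", "aceA", "glyoxylate shunt",
      NA, NA, NA),
    c("MALS", "accoa_c + glx_c + h2o_c -> mal__L_c + coa_c + h_c",
      "aceB", "glyoxylate shunt", NA, NA, NA),
    c("PC", "pyr_c + atp_c + co2_c + h2o_c -> oaa_c + adp_c + pi_c + 2 h_c",
      "pyc", "anaplerosis", NA, NA, NA),
    c("PPCK", "oaa_c + atp_c -> pep_c + co2_c + adp_c", "pck",
      "anaplerosis", NA, NA, NA),
    # overflow metabolism
    c("ACKr", "ac_c + atp_c <=> actp_c + adp_c", "ackA",
      "overflow metabolism", NA, NA, NA),
    c("PTAr", "actp_c + coa_c <=> accoa_c + pi_c", "pta",
      "overflow metabolism", NA, NA, NA),
    c("LDH_L", "pyr_c + nadh_c + h_c <=> lac__L_c + nad_c", "ldh",
      "overflow metabolism", NA, NA, NA),
    # respiration (lumped NADH oxidation with P/O = 2) and maintenance
    c("NADHOX",
      "nadh_c + 0.5 o2_c + 2 adp_c + 2 pi_c + 3 h_c -> nad_c + 3 h2o_c + 2 atp_c",
      "ndh", "oxidative phosphorylation", NA, NA, NA),
    c("ATPM", "atp_c + h2o_c -> adp_c + pi_c + h_c", "",
      "maintenance", "2", "1000", NA),
    # nitrogen assimilation and glutamate family
    c("GDH", "akg_c + nh4_c + nadph_c + h_c -> glu__L_c + nadp_c + h2o_c",
      "gdh", "glutamate metabolism", NA, NA, NA),
    c("GLU5K", "glu__L_c + atp_c -> glu5p_c + adp_c", "proB",
      "proline biosynthesis", NA, NA, NA),
    c("G5SD", "glu5p_c + nadph_c + h_c -> glu5sa_c + nadp_c + pi_c",
      "proA", "proline biosynthesis", NA, NA, NA),
    c("G5SADs", "glu5sa_c -> 1pyr5c_c + h2o_c + h_c", "",
      "proline biosynthesis", NA, NA, NA),
    c("P5CR", "1pyr5c_c + 2 h_c + nadph_c -> pro__L_c + nadp_c", "proC",
      "proline biosynthesis", NA, NA, NA),
    # PutA cycle: proline degradation back to glutamate
    c("PROD2", "pro__L_c + 0.5 o2_c -> 1pyr5c_c + h2o_c + h_c", "putA",
      "proline degradation", NA, NA, NA),
    c("P5CD", "1pyr5c_c + 2 h2o_c + nad_c -> glu__L_c + nadh_c + h_c",
      "putA", "proline degradation", NA, NA, NA),
    # aspartate family and lysine branch
    c("ASPTA", "oaa_c + glu__L_c <=> asp__L_c + akg_c", "aspB",
      "aspartate metabolism", NA, NA, NA),
    c("ASPK", "asp__L_c + atp_c <=> 4pasp_c + adp_c", "lysC",
      "lysine biosynthesis", NA, NA, NA),
    c("ASAD", "4pasp_c + nadph_c + h_c <=> aspsa_c + nadp_c + pi_c",
      "asd", "lysine biosynthesis", NA, NA, NA),
    c("HSDy", "aspsa_c + nadph_c + h_c -> hom__L_c + nadp_c", "hom",
      "threonine biosynthesis", NA, NA, NA),
    c("THRS_L",
      "hom__L_c + atp_c + h2o_c -> thr__L_c + adp_c + pi_c + h_c",
      "thrB and thrC", "threonine biosynthesis", NA, NA, NA),
    c("DHDPS", "aspsa_c + pyr_c -> 23dhdp_c + 2 h2o_c + h_c", "dapA",
      "lysine biosynthesis", NA, NA, NA),
    c("DHDPRy", "23dhdp_c + nadph_c + h_c -> thdp_c + nadp_c", "dapB",
      "lysine biosynthesis", NA, NA, NA),
    c("DDH", "thdp_c + nh4_c + 2 h_c + nadph_c -> 26dap__M_c + nadp_c",
      "ddh", "lysine biosynthesis", NA, NA, NA),
    c("DAPDC", "26dap__M_c + h_c -> lys__L_c + co2_c", "lysA",
      "lysine biosynthesis", NA, NA, NA),
    # pyruvate family
    c("ALATA", "pyr_c + glu__L_c <=> ala__L_c + akg_c", "alaT",
      "alanine metabolism", NA, NA, NA),
    c("KIVS",
      "2 pyr_c + nadph_c + 2 h_c -> 3mob_c + co2_c + nadp_c + h2o_c",
      "ilvB and ilvN", "valine biosynthesis", NA, NA, NA),
    c("VALTA", "3mob_c + glu__L_c -> val__L_c + akg_c", "ilvE",
      "valine biosynthesis", NA, NA, NA)
  )
  rx
}

# biomass composition: relative precursor demands (mmol per gDCW before
# scaling). Acetyl-CoA contributes only its acetyl mass (CoA is returned).
.minicore_biomass_demands <- c(
  g6p_c = 0.8, r5p_c = 0.4, e4p_c = 0.3, pep_c = 0.5, pyr_c = 1.0,
  accoa_c = 1.5, glu__L_c = 1.5, asp__L_c = 1.0, ala__L_c = 1.0,
  val__L_c = 0.6, thr__L_c = 0.5, pro__L_c = 0.4, lys__L_c = 0.4
)
.minicore_gam <- 35  # growth-associated ATP hydrolysis, mmol/gDCW

#' Mini central-carbon model of the C. glutamicum type
#'
#' A deterministic ~80-reaction fixture with EMP glycolysis, oxidative PPP
#' (2 NADPH per glucose 6-phosphate routed in), full TCA with
#' NADP-dependent isocitrate dehydrogenase, glyoxylate shunt, anaplerosis
#' (pyruvate carboxylase and PEP carboxykinase), nitrogen assimilation via
#' glutamate dehydrogenase, the proline route (proB, proA, spontaneous
#' cyclization, proC) with the PutA back-conversion cycle, the lysine
#' branch (lysC through lysA with the C. glutamicum ddh shortcut),
#' threonine/valine/alanine drains, exchanges for glucose, acetate,
#' lactate, oxygen and inorganic nutrients, plus dead-end glycerol and
#' xylose exchanges (growth on those requires heterologous additions). All
#' internal reactions are mass- and charge-balanced using real formulas;
#' the lumped biomass reaction drains 1.000 g of precursors per gDCW and
#' includes growth-associated ATP hydrolysis, whose mass cancels.
#'
#' @param glc_uptake default glucose uptake rate pinned on the glucose
#'   exchange (mmol/gDCW/h), default 4.
#' @return a `metabolic_model` with objective `"BIOMASS"`.
#' @export
make_minicore_model <- function(glc_uptake = 4) {
  mets <- .minicore_mets()
  mw <- stats::setNames(
    vapply(mets$formula, molecular_weight, numeric(1)), mets$id)
  dem <- .minicore_biomass_demands
  unit_mass <- vapply(names(dem), function(m) {
    if (m == "accoa_c") mw[["accoa_c"]] - mw[["coa_c"]] else mw[[m]]
  }, numeric(1))
  scale <- 1000 / sum(dem * unit_mass)
  coefs <- round(dem * scale, 4)

  gam <- .minicore_gam
  st <- c(-coefs,
          atp_c = -gam, h2o_c = -gam,
          adp_c = gam, pi_c = gam, h_c = gam,
          coa_c = unname(coefs[["accoa_c"]]))
  biomass <- reaction("BIOMASS", st, name = "biomass (1 g DCW)",
                      lb = 0, ub = 1000, gpr = "", subsystem = "biomass")

  rxns <- lapply(.minicore_rxns(glc_uptake), function(row) {
    eq <- parse_equation(row[2])
    lb <- if (is.na(row[5])) (if (eq$reversible) -1000 else 0) else
      as.numeric(row[5])
    ub <- if (is.na(row[6])) 1000 else as.numeric(row[6])
    reaction(id = row[1], stoichiometry = eq$stoichiometry, name = row[1],
             lb = lb, ub = ub, gpr = row[3], subsystem = row[4],
             drg = if (is.na(row[7])) NA_real_ else as.numeric(row[7]))
  })
  metabolic_model(mets, c(rxns, list(biomass)), objective = "BIOMASS")
}

# central reactions covered by emulated 13C flux tables (branch points of
# glycolysis, PPP, TCA, anaplerosis, plus the measured growth rate)
.minicore_c13_reactions <- c(
  "GLCpts", "PGI", "PFK", "FBA", "GAPD", "PYK", "PDH", "G6PDH2r", "GND",
  "TKT1", "TKT2", "TALA", "CS", "ACONT", "ICDHyr", "AKGDH", "SUCOAS",
  "SUCDi", "FUM", "MDH", "PC", "PPCK", "ICL", "MALS", "GDH", "ATPM",
  "BIOMASS"
)

#' Reference wild-type flux state of the mini central-carbon model
#'
#' The parsimonious FBA solution on glucose with a small amount of
#' anaplerotic cycling pinned on PEP carboxykinase, emulating the
#' simultaneous pyruvate carboxylase / PEP carboxykinase activity that
#' carbon-labeling studies observe in C. glutamicum (a pure parsimonious
#' solution would zero the ATP-dissipating cycle).
#'
#' @param model the mini-core model (or a derivative sharing its ids).
#' @param ppck_flux pinned PEP carboxykinase flux (default 0.3
#'   mmol/gDCW/h).
#' @return a `flux_distribution`.
#' @export
minicore_wt_fluxes <- function(model = make_minicore_model(),
                               ppck_flux = 0.3) {
  cs <- constraint_set("PPCK", ppck_flux, ppck_flux)
  minimize_total_flux_at_optimum(model, constraints = cs,
                                 objective = "BIOMASS")
}

#' Generate a 13C-style flux-bound table around a known distribution
#'
#' Emulates the bound tables derived from carbon-labeling experiments:
#' for each selected central reaction the interval is
#' `center +/- half`, where `half = max(width_fraction * |flux|, 0.5)`
#' (the 0.5 mmol/gDCW/h floor reflects measurement resolution) and the
#' center is jittered by up to half of `width_fraction * |flux|` so the
#' true flux always stays inside the interval. Deterministic for a given
#' seed.
#'
#' @param model a `metabolic_model`.
#' @param true_distribution a feasible `flux_distribution` (e.g. from
#'   [minicore_wt_fluxes()]).
#' @param width_fraction relative half-width of the intervals (>= 0),
#'   default 0.05.
#' @param seed integer seed for the center jitter.
#' @param reactions reactions to constrain; defaults to the mini-core
#'   central set (intersected with the model's reactions).
#' @return a `constraint_set`.
#' @export
make_c13_constraints <- function(model, true_distribution,
                                 width_fraction = 0.05, seed = 20170630,
                                 reactions = NULL) {
  stopifnot(width_fraction >= 0)
  reactions <- reactions %||%
    intersect(.minicore_c13_reactions, model$reactions$id)
  v <- true_distribution$fluxes[reactions]
  if (any(is.na(v))) {
    stop("true distribution lacks fluxes for some requested reactions",
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  half <- pmax(width_fraction * abs(v), 0.5)
  jitter <- stats::runif(length(v), -1, 1) * 0.5 * width_fraction * abs(v)
  center <- v + jitter
  constraint_set(reactions, center - half, center + half,
                 mode = "override")
}

#' Digest of a model's canonical serialization
#'
#' MD5 of the canonical tabular serialization; used to pin fixture
#' versions so that refactors cannot silently change documented truths.
#'
#' @param model a `metabolic_model`.
#' @return a 32-character hex digest.
#' @export
model_digest <- function(model) {
  tmp_r <- tempfile(fileext = ".tsv")
  tmp_m <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tmp_r, tmp_m)))
  write_model_tables(model, tmp_r, tmp_m)
  combined <- tempfile()
  on.exit(unlink(combined), add = TRUE)
  writeLines(c(readLines(tmp_r), readLines(tmp_m),
               paste("objective:", model$objective)), combined)
  unname(tools::md5sum(combined))
}
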