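# Heterologous pathway library.
#
# Named reaction sets from the E. coli / L. lactis engineering literature
# used to extend C. glutamicum-type models: glycerol utilization (glpF,
# glpK, glpD), xylose utilization (xylA, xylB), 1,2-propanediol synthesis
# from dihydroxyacetone phosphate (mgsA, gldA, yqhD), and isobutanol
# synthesis from 3-methyl-2-oxobutanoate (kivd plus the native adhA).
# Synthesis pathways ship with the transport/exchange pseudo-reactions
# needed for the product to leave the cell.

.pathway_defs <- function() {
  list(
    glycerol_ecoli = list(
      description = "glycerol utilization: aquaglyceroporin (glpF), glycerol kinase (glpK), glycerol 3-phosphate dehydrogenase (glpD)",
      metabolites = rbind(
        metabolite("glyc_e", "glycerol", "C3H8O3", 0L),
        metabolite("glyc_c", "glycerol", "C3H8O3", 0L),
        metabolite("glyc3p_c", "sn-glycerol 3-phosphate", "C3H7O6P", -2L),
        metabolite("dhap_c", "dihydroxyacetone phosphate", "C3H5O6P", -2L)
      ),
      core = c("GLYCt", "GLYK", "G3PD"),
      reactions = list(
        reaction("GLYCt", c(glyc_e = -1, glyc_c = 1), lb = -1000,
                 gpr = "glpF", subsystem = "heterologous"),
        reaction("GLYK",
                 c(glyc_c = -1, atp_c = -1, glyc3p_c = 1, adp_c = 1,
                   h_c = 1),
                 lb = 0, gpr = "glpK", subsystem = "heterologous"),
        reaction("G3PD",
                 c(glyc3p_c = -1, o2_c = -0.5, dhap_c = 1, h2o_c = 1),
                 lb = 0, gpr = "glpD", subsystem = "heterologous")
      ),
      target_exchange = NULL
    ),
    xylose_ecoli = list(
      description = "xylose utilization: xylose isomerase (xylA), xylulokinase (xylB)",
      metabolites = rbind(
        metabolite("xyl__D_c", "D-xylose", "C5H10O5", 0L),
        metabolite("xylu__D_c", "D-xylulose", "C5H10O5", 0L)
      ),
      core = c("XYLI", "XYLK"),
      reactions = list(
        reaction("XYLI", c(xyl__D_c = -1, xylu__D_c = 1), lb = -1000,
                 gpr = "xylA", subsystem = "heterologous"),
        reaction("XYLK",
                 c(xylu__D_c = -1, atp_c = -1, xu5p__D_c = 1, adp_c = 1,
                   h_c = 1),
                 lb = 0, gpr = "xylB", subsystem = "heterologous")
      ),
      target_exchange = NULL
    ),
    pdo_ecoli = list(
      description = "1,2-propanediol synthesis from dhap: methylglyoxal synthase (mgsA), glycerol dehydrogenase (gldA), aldehyde reductase (yqhD)",
      metabolites = rbind(
        metabolite("mthgxl_c", "methylglyoxal", "C3H4O2", 0L),
        metabolite("acetol_c", "acetol", "C3H6O2", 0L),
        metabolite("12ppd_c", "1,2-propanediol", "C3H8O2", 0L),
        metabolite("12ppd_e", "1,2-propanediol", "C3H8O2", 0L)
      ),
      core = c("MGSA", "GLDA", "YQHD"),
      reactions = list(
        reaction("MGSA", c(dhap_c = -1, mthgxl_c = 1, pi_c = 1), lb = 0,
                 gpr = "mgsA", subsystem = "heterologous"),
        reaction("GLDA",
                 c(mthgxl_c = -1, nadh_c = -1, h_c = -1, acetol_c = 1,
                   nad_c = 1),
                 lb = 0, gpr = "gldA", subsystem = "heterologous"),
        reaction("YQHD",
                 c(acetol_c = -1, nadph_c = -1, h_c = -1, `12ppd_c` = 1,
                   nadp_c = 1),
                 lb = 0, gpr = "yqhD", subsystem = "heterologous"),
        reaction("12PPDt", c(`12ppd_c` = -1, `12ppd_e` = 1), lb = 0,
                 subsystem = "transport"),
        reaction("EX_12ppd_e", c(`12ppd_e` = -1), lb = 0,
                 subsystem = "exchange")
      ),
      target_exchange = "EX_12ppd_e"
    ),
    isobutanol_kivd_adhA = list(
      description = "isobutanol synthesis from 3-methyl-2-oxobutanoate: keto acid decarboxylase (kivd, L. lactis) and native alcohol dehydrogenase (adhA)",
      metabolites = rbind(
        metabolite("2mppal_c", "2-methylpropanal", "C4H8O", 0L),
        metabolite("ibutoh_c", "isobutanol", "C4H10O", 0L),
        metabolite("ibutoh_e", "isobutanol", "C4H10O", 0L)
      ),
      core = c("KIVD", "ADHA"),
      reactions = list(
        reaction("KIVD", c(`3mob_c` = -1, h_c = -1, `2mppal_c` = 1,
                           co2_c = 1),
                 lb = 0, gpr = "kivd", subsystem = "heterologous"),
        reaction("ADHA",
                 c(`2mppal_c` = -1, nadph_c = -1, h_c = -1, ibutoh_c = 1,
                   nadp_c = 1),
                 lb = 0, gpr = "adhA", subsystem = "heterologous"),
        reaction("IBUTOHt", c(ibutoh_c = -1, ibutoh_e = 1), lb = 0,
                 subsystem = "transport"),
        reaction("EX_ibutoh_e", c(ibutoh_e = -1), lb = 0,
                 subsystem = "exchange")
      ),
      target_exchange = "EX_ibutoh_e"
    )
  )
}

#' Known heterologous pathway names
#' @return character vector of pathway names accepted by
#'   [pathway_additions()] and scenario configs.
#' @export
known_pathways <- function() names(.pathway_defs())

#' Reactions and metabolites of a named heterologous pathway
#'
#' @param name one of [known_pathways()].
#' @return list with `description`, `metabolites` (data.frame),
#'   `reactions` (list of [reaction()]), `core` (ids of the enzymatic
#'   reactions, excluding transport/exchange plumbing), and
#'   `target_exchange` (product exchange id or `NULL`).
#' @export
pathway_additions <- function(name) {
  defs <- .pathway_defs()
  if (!name %in% names(defs)) {
    stop(sprintf("unknown pathway '%s'; known pathways: %s", name,
                 paste(names(defs), collapse = ", ")), call. = FALSE)
  }
  defs[[name]]
}

#' Graft a named pathway onto a model
#'
#' Adds the pathway's reactions and any missing metabolites via
#' [augment_model()]; reactions already present in the model are skipped.
#'
#' @param model a `metabolic_model`.
#' @param name pathway name from [known_pathways()].
#' @return the augmented model.
#' @export
add_pathway <- function(model, name) {
  pw <- pathway_additions(name)
  keep <- vapply(pw$reactions, function(r) {
    !(r$id %in% model$reactions$id)
  }, logical(1))
  if (!any(keep)) return(model)
  augment_model(model, pw$reactions[keep], metabolites = pw$metabolites)
}
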