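test_that("mass/charge balance classifies reactions correctly", {
  mets <- rbind(
    metabolite("glc_c", formula = "C6H12O6", charge = 0L),
    metabolite("lac_c", formula = "C3H6O3", charge = 0L),
    metabolite("pyr_c", formula = "C3H3O3", charge = -1L),
    metabolite("glc_e", formula = "C6H12O6", charge = 0L)
  )
  m <- metabolic_model(mets, list(
    reaction("EX_glc", c(glc_e = -1), lb = -10),
    reaction("GLCt", c(glc_e = -1, glc_c = 1), lb = 0),
    reaction("FERM", c(glc_c = -1, lac_c = 2), lb = 0),
    reaction("BADPYR", c(glc_c = -1, pyr_c = 2), lb = 0)
  ))
  bal <- check_mass_charge_balance(m)
  get <- function(rid) bal[bal$reaction_id == rid, ]
  expect_equal(get("FERM")$status, "balanced")
  expect_equal(get("EX_glc")$status, "exempt")
  bad <- get("BADPYR")
  expect_equal(bad$status, "imbalanced")
  expect_equal(bad$residuals[[1]][["H"]], -6)
  expect_equal(bad$charge_residual, -2)
})

test_that("missing formulas in non-exempt reactions are an error", {
  mets <- rbind(metabolite("a_c", formula = "C"),
                metabolite("b_c", formula = ""))
  m <- metabolic_model(mets, list(reaction("R1", c(a_c = -1, b_c = 1),
                                           lb = 0)))
  expect_error(check_mass_charge_balance(m), "without formula.*b_c")
})

test_that("biomass weight equals the precursor mass drain", {
  mets <- rbind(
    metabolite("x_c", formula = "C5H8O3"),   # MW 128.147
    metabolite("y_c", formula = "C3H7NO2"),  # MW 89.094
    metabolite("atp_c", formula = "C10H12N5O13P3", charge = -4L),
    metabolite("adp_c", formula = "C10H12N5O10P2", charge = -3L),
    metabolite("pi_c", formula = "HO4P", charge = -2L),
    metabolite("h2o_c", formula = "H2O"),
    metabolite("h_c", formula = "H", charge = 1L)
  )
  m <- metabolic_model(mets, list(
    reaction("BIOMASS", c(x_c = -5, y_c = -5), lb = 0)
  ), objective = "BIOMASS")
  expected <- (5 * molecular_weight("C5H8O3") +
                 5 * molecular_weight("C3H7NO2")) / 1000
  expect_equal(check_biomass_weight(m), expected, tolerance = 1e-12)
  # adding an ATP maintenance term leaves the net mass unchanged
  m2 <- metabolic_model(mets, list(
    reaction("BIOMASS", c(x_c = -5, y_c = -5, atp_c = -20, h2o_c = -20,
                          adp_c = 20, pi_c = 20, h_c = 20), lb = 0)
  ), objective = "BIOMASS")
  expect_equal(check_biomass_weight(m2), expected, tolerance = 1e-9)
  # a lightweight biomass is reported as such, not hidden
  m3 <- metabolic_model(mets, list(
    reaction("BIOMASS", c(x_c = -1, h2o_c = -1), lb = 0)
  ), objective = "BIOMASS")
  expect_lt(check_biomass_weight(m3), 0.2)
})

test_that("the mini-core passes reconstruction QC", {
  m <- minicore_cached()
  bal <- check_mass_charge_balance(m)
  expect_true(all(bal$status %in% c("balanced", "exempt")))
  expect_equal(check_biomass_weight(m), 1.000, tolerance = 1e-3)
})

test_that("Gibbs-energy directionality follows the cutoff rule", {
  mets <- rbind(metabolite("a_c", formula = "C"),
                metabolite("b_c", formula = "C"))
  mk <- function(drg) metabolic_model(mets, list(
    reaction("R1", c(a_c = -1, b_c = 1), lb = -1000, ub = 1000,
             drg = drg)))
  b <- function(m) unlist(m$reactions[1, c("lb", "ub")], use.names = FALSE)
  expect_equal(b(assign_directionality(mk(-45))), c(0, 1000))
  expect_equal(b(assign_directionality(mk(45))), c(-1000, 0))
  expect_equal(b(assign_directionality(mk(-5))), c(-1000, 1000))
  # reactions without a value are left untouched and reported
  m_na <- assign_directionality(mk(NA_real_))
  expect_equal(b(m_na), c(-1000, 1000))
  expect_identical(attr(m_na, "skipped"), "R1")
})

test_that("directionality is monotone in the Gibbs energy", {
  mets <- rbind(metabolite("a_c", formula = "C"),
                metabolite("b_c", formula = "C"))
  drgs <- sort(runif(25, -80, 80))
  forward_allowed <- vapply(drgs, function(d) {
    m <- metabolic_model(mets, list(
      reaction("R1", c(a_c = -1, b_c = 1), drg = d)))
    assign_directionality(m)$reactions$ub[1] > 0
  }, logical(1))
  # lowering the Gibbs energy never removes the forward direction:
  # over increasing drg the forward-allowed flags are non-increasing
  expect_true(!is.unsorted(rev(as.integer(forward_allowed))))
})
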