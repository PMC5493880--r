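test_that("scenario configs validate their fields", {
  cfg <- read_scenario(
    "carbon_source: EX_glc__D_e\nuptake_rate: 4.0\nobjective: BIOMASS")
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$uptake_rate, 4.0)
  expect_equal(cfg$uptake_mode, "fix")
  expect_error(read_scenario("carbon_source: EX_glc__D_e\nuptake_rate: -3"),
               "positive")
  expect_error(read_scenario("additions: [no_such_pathway]"),
               "known pathways")
  # the xylose pathway expands to the two reported enzymatic reactions
  cfg2 <- read_scenario("additions: [xylose_ecoli]")
  expect_length(scenario_expansions(cfg2), 2)
  expect_length(scenario_expansions(
    read_scenario("additions: [glycerol_ecoli]")), 3)
})

test_that("unknown carbon sources are rejected with candidates listed", {
  m <- minicore_cached()
  expect_error(
    run_growth_scenario(m, scenario_config(carbon_source = "EX_nope",
                                           uptake_rate = 1)),
    "candidates")
})

test_that("growth is non-decreasing in the uptake rate", {
  m <- minicore_cached()
  rates <- c(1, 2, 4, 6)
  mu <- vapply(rates, function(u) {
    run_growth_scenario(m, scenario_config(carbon_source = "EX_glc__D_e",
                                           uptake_rate = u))$growth_rate
  }, numeric(1))
  expect_true(all(diff(mu) > -1e-9))
})

test_that("oxygen pinning changes the solution space", {
  m <- minicore_cached()
  free_o2 <- run_growth_scenario(m, scenario_config(
    carbon_source = "EX_glc__D_e", uptake_rate = 4))
  pinned <- run_growth_scenario(m, scenario_config(
    carbon_source = "EX_glc__D_e", uptake_rate = 4, oxygen_rate = 2))
  expect_equal(pinned$distribution$fluxes[["EX_o2_e"]], -2,
               tolerance = 1e-6)
  expect_lt(pinned$growth_rate, free_o2$growth_rate)
})

test_that("flux normalization follows the per-100-substrate convention", {
  m <- minicore_cached()
  res <- run_growth_scenario(m, scenario_config(
    carbon_source = "EX_glc__D_e", uptake_rate = 4, name = "glc"))
  tab <- normalize_and_report(res, "EX_glc__D_e")
  expect_equal(abs(tab$normalized[tab$reaction_id == "EX_glc__D_e"]), 100,
               tolerance = 1e-9)
  # spot arithmetic: flux 1.5396 at uptake 4.0 is 38.49 per 100
  expect_equal(100 * 1.5396 / 4.0, 38.49, tolerance = 1e-12)
  v <- res$distribution$fluxes[["G6PDH2r"]]
  expect_equal(tab$normalized[tab$reaction_id == "G6PDH2r"],
               100 * v / 4, tolerance = 1e-9)
  # zero reference is an error
  expect_error(normalize_and_report(res, "EX_lys__L_e"), "zero flux")
})

test_that("degenerate fluxes are flagged when uniqueness is checked", {
  br <- make_branched_model()
  res <- run_growth_scenario(
    br, scenario_config(carbon_source = "EX_a_e", uptake_rate = 10),
    check_uniqueness = TRUE)
  fl <- res$fluxes
  expect_true(fl$degenerate[fl$reaction_id == "P1"])
  expect_false(fl$degenerate[fl$reaction_id == "EX_b_e"])
})

test_that("rerunning a scenario reproduces the recorded numbers", {
  m <- minicore_cached()
  cfg <- scenario_config(carbon_source = "EX_glc__D_e", uptake_rate = 4)
  r1 <- run_growth_scenario(m, cfg)
  r2 <- run_growth_scenario(m, cfg)
  expect_identical(r1$growth_rate, r2$growth_rate)
  expect_identical(r1$distribution$fluxes, r2$distribution$fluxes)
  expect_identical(r1$provenance$model_digest, r2$provenance$model_digest)
})
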